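mkDiv <- function(p, L = 1000L) {
  ## construct an exact divergence fixture: S mismatches over L sites
  S <- round(p * L)
  a <- strrep("A", L)
  b <- paste0(strrep("G", S), strrep("A", L - S))
  countDivergence(a, b)
}

test_that("paired-LTR ages follow the two-rate clock exactly", {
  cp <- clockParameters()
  ## identical LTRs: age 0, young flag set
  est0 <- estimateProvirusAge(mkDiv(0), cp)
  expect_equal(est0$ageLow, 0)
  expect_equal(est0$ageHigh, 0)
  expect_true(est0$youngFlag)
  ## p = 0.009 -> 0.9/0.45 = 2.0 and 0.9/0.24 = 3.75 Myr
  est <- estimateProvirusAge(mkDiv(0.009), cp)
  expect_equal(est$ageLow, 2.0)
  expect_equal(est$ageHigh, 3.75)
  expect_equal(est$agePoint, (2.0 + 3.75) / 2)
  ## the bound ratio is rate_high/rate_low = 1.875 for every p > 0
  set.seed(41)
  for (p in runif(20, 0.001, 0.2)) {
    e <- estimateProvirusAge(mkDiv(p, 5000L), cp)
    expect_equal(e$ageHigh / e$ageLow, 0.45 / 0.24)
    expect_equal(e$ageHigh / e$ageLow, 1.875)
  }
  ## reporting: young proviruses print as "< 2"
  expect_equal(formatAgeEstimate(est0, cp), "< 2")
  old <- estimateProvirusAge(mkDiv(0.05), cp)
  expect_match(formatAgeEstimate(old, cp), "^11\\.11-20\\.83$")
})

test_that("JC and K2P distances match closed-form oracles", {
  ## p = 0.0068 -> JC d = -0.75 log(1 - 4p/3)
  a <- strrep("A", 10000)
  b <- paste0(strrep("G", 68), strrep("A", 10000 - 68))
  expect_equal(consensusDistance(a, b, "raw"), 0.0068)
  expect_equal(consensusDistance(a, b, "JC"), -0.75 * log(1 - 4 * 0.0068 / 3),
               tolerance = 1e-12)
  ## all-transition case: P = 0.01, Q = 0 -> K2P d = -0.5 log(0.98)
  a2 <- strrep("A", 1000)
  b2 <- paste0(strrep("G", 10), strrep("A", 990))   # A->G are transitions
  expect_equal(consensusDistance(a2, b2, "K2P"), -0.5 * log(0.98), tolerance = 1e-12)
  ## identical sequences: zero under every model
  for (m in c("raw", "JC", "K2P")) expect_equal(consensusDistance(a, a, m), 0)
  ## saturation guards
  sat <- paste(rep(c("C", "G", "T", "A"), 250), collapse = "")
  expect_error(consensusDistance(strrep("A", 1000), sat, "JC"), "saturated")
})

test_that("model distances agree with ape's estimators on gap-free pairs", {
  set.seed(42)
  for (i in 1:10) {
    n <- 600
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    mut <- sample(n, 30)
    for (m in mut) b[m] <- sample(setdiff(c("A", "C", "G", "T"), b[m]), 1)
    bin <- ape::as.DNAbin(matrix(tolower(c(a, b)), nrow = 2, byrow = TRUE))
    expect_equal(consensusDistance(paste(a, collapse = ""), paste(b, collapse = ""), "JC"),
                 as.numeric(ape::dist.dna(bin, model = "JC69")), tolerance = 1e-9)
    expect_equal(consensusDistance(paste(a, collapse = ""), paste(b, collapse = ""), "K2P"),
                 as.numeric(ape::dist.dna(bin, model = "K80")), tolerance = 1e-9)
  }
})

test_that("distance corrections are ordered and converge as p -> 0", {
  set.seed(43)
  for (p in c(0.02, 0.05, 0.1)) {
    dv <- mkDiv(p, 10000L)
    raw <- dv$p
    a <- strrep("A", 10000)
    b <- paste0(strrep("G", round(p * 10000)), strrep("A", 10000 - round(p * 10000)))
    expect_gte(consensusDistance(a, b, "JC"), raw)
    expect_gte(consensusDistance(a, b, "K2P"), raw)
  }
  ## first-order agreement at p <= 0.001 (corrections are O(p^2))
  a <- strrep("A", 100000)
  b <- paste0(strrep("G", 100), strrep("A", 99900))
  expect_lt(abs(consensusDistance(a, b, "JC") - 0.001), 5e-6)
  expect_lt(abs(consensusDistance(a, b, "K2P") - 0.001), 5e-6)
})

test_that("through-origin calibration matches the closed form and lm", {
  cal <- calibrateCorrectionFactor(c(1, 2, 5), c(1, 2, 5))
  expect_equal(cal$slope, 1)
  ## slope = sum(xy)/sum(x^2) exactly
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  cal2 <- calibrateCorrectionFactor(x, y)
  expect_equal(cal2$slope, sum(x * y) / sum(x^2))
  expect_equal(cal2$slope, 2)
  ## independent route: lm without intercept
  set.seed(44)
  x3 <- runif(40, 1, 20); y3 <- 0.8 * x3 + rnorm(40, 0, 0.5)
  cal3 <- calibrateCorrectionFactor(x3, y3)
  fit <- lm(y3 ~ 0 + x3)
  expect_equal(cal3$slope, unname(coef(fit)), tolerance = 1e-12)
  ci <- confint(fit, level = 0.95)
  expect_equal(cal3$ciLow, ci[1], tolerance = 1e-8)
  expect_equal(cal3$ciHigh, ci[2], tolerance = 1e-8)
  ## degenerate inputs
  expect_error(calibrateCorrectionFactor(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibrateCorrectionFactor(c(0, 0, 0), c(1, 2, 3)), "zero")
})

test_that("calibration CI covers a known slope across replicates", {
  set.seed(45)
  hits <- replicate(200, {
    x <- runif(50, 1, 20)
    y <- 0.8 * x + rnorm(50, 0, 0.1 * mean(0.8 * x))
    cal <- calibrateCorrectionFactor(x, y)
    cal$ciLow <= 0.8 && 0.8 <= cal$ciHigh
  })
  expect_gte(mean(hits), 0.9)
})

test_that("solo-consensus ages scale distance by the solo rate and slope", {
  cp <- clockParameters()
  cons <- strrep("ACGT", 250)
  ## identical to the consensus, slope 1 -> age 0
  est0 <- estimateSoloAge(cons, cons, cp)
  expect_equal(est0$agePoint, 0)
  ## d_avg = 0.0068, slope 1 -> 0.68/0.34 = 2.0 Myr
  a <- strrep("A", 10000)
  b <- paste0(strrep("G", 68), strrep("A", 10000 - 68))
  est <- estimateSoloAge(b, a, cp)
  dAvg <- (consensusDistance(b, a, "JC") + consensusDistance(b, a, "K2P")) / 2
  expect_equal(est$agePoint, 100 * dAvg / 0.34)
  expect_equal(est$agePoint, 2.0, tolerance = 0.01)
  ## the calibration slope rescales point and bounds
  cp2 <- applyCalibration(cp, list(slope = 1.5, ciLow = 1.2, ciHigh = 1.8))
  est2 <- estimateSoloAge(b, a, cp2)
  expect_equal(est2$agePoint, 1.5 * est$agePoint)
  expect_equal(est2$ageLow, 1.2 * est$agePoint)
  expect_equal(est2$ageHigh, 1.8 * est$agePoint)
})

test_that("age intervals cover the truth for sufficiently diverged proviruses", {
  set.seed(46)
  cfg <- simulationConfig(seed = 46)
  anc <- makeSubgroupAncestors(seed = 46)
  ltr <- strsplit(alignmentRow(anc$ancestors, "LTR5Hs"), "")[[1]]
  tmpl <- strsplit(strrep("ACG", 20), "")[[1]]
  cp <- clockParameters()
  res <- t(replicate(120, {
    age <- runif(1, 1, 30)
    pr <- simulateProvirus(ltr, tmpl, age, cfg)
    dv <- countDivergence(paste(pr$ltr5, collapse = ""), paste(pr$ltr3, collapse = ""))
    est <- estimateProvirusAge(dv, cp)
    c(age = age, S = dv$S, cov = est$ageLow <= age && age <= est$ageHigh)
  }))
  sel <- res[, "S"] >= 5
  expect_gte(mean(res[sel, "cov"]), 0.8)
})
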