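mkSummaries <- function(y, x) {
  data.frame(chrom = paste0("chr", seq_along(y)), length = 1e6 * seq_along(y),
             n_genes = x, n_proviruses = 0L, n_solo_ltrs = y,
             stringsAsFactors = FALSE)
}

test_that("NB regression reports nested log-likelihoods and a valid LR test", {
  set.seed(61)
  x <- runif(22, 0, 4)
  y <- rnbinom(22, mu = exp(1 + 0.5 * x), size = 1 / 0.3)
  fit <- fitNbRegression(mkSummaries(y, x), "n_solo_ltrs", "n_genes")
  expect_gte(fit$lrStat, -1e-6)
  expect_gte(fit$llFull, fit$llNull - 1e-6)
  expect_equal(fit$lrStat, -2 * (fit$llNull - fit$llFull))
  expect_equal(fit$pValue, pchisq(fit$lrStat, 1, lower.tail = FALSE))
  expect_equal(fit$alpha, 1 / fit$theta)
  ## band covers the fitted mean
  expect_true(all(fit$band$lower <= fit$band$fitted & fit$band$fitted <= fit$band$upper))
  ## degenerate inputs
  expect_error(fitNbRegression(mkSummaries(rep(0L, 22), x), "n_solo_ltrs", "n_genes"),
               "all-zero")
  expect_error(fitNbRegression(mkSummaries(y, rep(1, 22)), "n_solo_ltrs", "n_genes"),
               "variance")
  expect_error(fitNbRegression(mkSummaries(y, x)[1:4, ], "n_solo_ltrs", "n_genes"),
               "at least 5")
})

test_that("NB regression recovers planted coefficients", {
  set.seed(62)
  b1 <- replicate(60, {
    x <- runif(22, 0, 4)
    y <- rnbinom(22, mu = exp(1 + 0.5 * x), size = 1 / 0.3)
    tryCatch(fitNbRegression(mkSummaries(y, x), "n_solo_ltrs", "n_genes")$beta1,
             error = function(e) NA)
  })
  expect_lte(abs(mean(b1, na.rm = TRUE) - 0.5), 0.1)
})

test_that("NB fit approaches the Poisson fit on equidispersed counts", {
  set.seed(63)
  x <- runif(40, 0, 3)
  y <- rpois(40, exp(1.2 + 0.4 * x))
  nb <- fitNbRegression(mkSummaries(y, x), "n_solo_ltrs", "n_genes")
  po <- glm(y ~ x, family = poisson)
  se <- sqrt(diag(vcov(po)))
  expect_lte(abs(nb$beta0 - coef(po)[1]), 2 * se[1])
  expect_lte(abs(nb$beta1 - coef(po)[2]), 2 * se[2])
})

test_that("outlier flagging follows the 95% mean-prediction band", {
  set.seed(64)
  x <- seq(0.5, 4, length.out = 22)
  ## near-deterministic counts on the regression line: no outliers
  y <- round(exp(1 + 0.5 * x))
  fit <- fitNbRegression(mkSummaries(y, x), "n_solo_ltrs", "n_genes")
  expect_equal(nrow(flagOutliers(fit)), 0L)
  ## tripling one chromosome's count flags it as over-represented
  y2 <- y; y2[7] <- y2[7] * 3L
  fit2 <- fitNbRegression(mkSummaries(y2, x), "n_solo_ltrs", "n_genes")
  out <- flagOutliers(fit2)
  expect_true("chr7" %in% out$chrom)
  expect_equal(out$direction[out$chrom == "chr7"], "over")
})

test_that("the nine pairwise regressions run on simulated catalogs", {
  sim <- simulateCatalog(simulationConfig(seed = 65, nProviruses = 50, nSoloLtrs = 150))
  prov <- callProviruses(sim$hits)
  solo <- callSoloLtrs(sim$hits, prov)
  cat0 <- ErvCatalog(rbind(as.data.frame(prov), as.data.frame(solo)))
  summ <- chromosomeSummary(cat0, sim$genes, sim$chromSizes)
  expect_equal(nrow(summ), nrow(sim$chromSizes))
  expect_equal(sum(summ$n_proviruses) + sum(summ$n_solo_ltrs), length(cat0))
  reg <- fitAllNbRegressions(summ)
  expect_equal(nrow(reg), 9L)
  expect_setequal(unique(reg$predictor), c("length", "n_proviruses", "n_solo_ltrs", "n_genes"))
})

test_that("gene proximity counts match an exhaustive interval oracle", {
  ## hand-laid fixture: 10 elements, 3 genes
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(10000L, 100000L, 50000L),
                      end = c(40000L, 150000L, 90000L),
                      strand = c("+", "-", "+"))
  el <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr3", "chr1"),
    start = c(15000L, 41000L, 95000L, 120000L, 300000L, 60000L, 95000L, 200000L, 1000L, 130000L),
    end = c(16000L, 42000L, 96000L, 121000L, 301000L, 61000L, 96000L, 201000L, 2000L, 131000L),
    strand = c("+", "+", "-", "+", "+", "+", "-", "-", "+", "-"))
  gr <- GenomicRanges::GRanges(el$chrom, IRanges::IRanges(el$start, el$end), strand = el$strand)
  ggr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end),
                                strand = genes$strand)
  S4Vectors::mcols(ggr)$feature <- "gene"
  res <- geneProximitySummary(gr, ggr, window = 30000)
  or <- oracleProximity(el, genes, 30000)
  expect_equal(res$nWithinWindow, or$nWithinWindow)
  expect_equal(res$nIntronic, or$nIntronic)
  expect_equal(res$nIntronicAntisense, or$nIntronicAntisense)
  expect_equal(res$nTotal, 10L)
  ## ordering invariance and gene splitting into abutting pieces
  perm <- sample(length(gr))
  res2 <- geneProximitySummary(gr[perm], ggr, window = 30000)
  expect_equal(res2$nWithinWindow, res$nWithinWindow)
  expect_equal(res2$nIntronicAntisense, res$nIntronicAntisense)
  ## element inside an intron on the opposite strand counts in all buckets
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20000, 21000), strand = "-")
  r1 <- geneProximitySummary(one, ggr, window = 30000)
  expect_equal(r1$nWithinWindow, 1L)
  expect_equal(r1$nIntronic, 1L)
  expect_equal(r1$nIntronicAntisense, 1L)
})
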