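test_that("divergence counting applies the indel-event rule", {
  ## identity
  r <- strrep("ACGT", 125)
  dv <- countDivergence(r, r)
  expect_equal(dv$S, 0)
  expect_equal(dv$L, 500)
  expect_equal(dv$p, 0)

  ## a single 1-bp indel is one event and one unit of length
  dv <- countDivergence("ACGT-A", "ACGTTA")
  expect_equal(dv$S, 1)
  expect_equal(dv$L, 6)
  expect_equal(dv$indelEvents, 1)

  ## 1000 columns, 9 mismatches, one 5-bp gap run -> S=10, L=996
  a <- rep("A", 1000)
  b <- rep("A", 1000)
  b[seq(10, 90, by = 10)] <- "G"
  b[501:505] <- "-"
  dv <- countDivergence(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(dv$S, 10)
  expect_equal(dv$L, 996)
  expect_equal(dv$p, 10 / 996)

  ## strict mode counts short runs per column
  dvs <- countDivergence("ACGT-A", "ACGTTA", indelMode = "strict")
  expect_equal(dvs$S, 1)   # run of length 1 -> 1 column
  a2 <- "AAAA---AAAA--A"
  b2 <- "AAAAAAAAAAAAAA"
  expect_equal(countDivergence(a2, b2)$S, 2)                      # 2 events
  expect_equal(countDivergence(a2, b2, indelMode = "strict")$S, 3) # 3bp run=1, 2bp run=2

  ## empty overlap errors
  expect_error(countDivergence("----", "AAAA"), "empty overlap")
})

test_that("divergence counting matches a per-column brute-force interpreter", {
  set.seed(71)
  for (i in 1:100) {
    pr <- randomAlignedPair(sample(20:200, 1))
    dv <- countDivergence(pr$a, pr$b)
    or <- tryCatch(oracleDivergence(pr$a, pr$b), error = function(e) NULL)
    if (dv$L == 0) next
    expect_equal(dv$S, or$S)
    expect_equal(dv$L, or$L)
    expect_equal(dv$indelEvents, or$events)
  }
})

test_that("divergence counting is symmetric and gap-column invariant", {
  set.seed(72)
  for (i in 1:25) {
    pr <- randomAlignedPair(150)
    d1 <- countDivergence(pr$a, pr$b)
    d2 <- countDivergence(pr$b, pr$a)
    expect_equal(d1$S, d2$S)
    expect_equal(d1$L, d2$L)
    ## appending both-gap columns changes nothing
    d3 <- countDivergence(paste0(pr$a, "-----"), paste0(pr$b, "-----"))
    expect_equal(d3$p, d1$p)
  }
})

test_that("pairwise identity is percent matching over base columns", {
  expect_equal(pairwiseIdentity("ACGT", "ACGT"), 100)
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 98), "GG")
  expect_equal(pairwiseIdentity(a, b), 98)
  ## indel columns excluded from the denominator
  expect_equal(pairwiseIdentity("ACGT-", "ACGTT"), 100)
  expect_equal(pairwiseIdentity("AC", "AC"), pairwiseIdentity("CA", "CA"))
  expect_error(pairwiseIdentity("--", "AA"), "empty overlap")
})

test_that("consensus takes the per-column majority with deterministic ties", {
  aln <- ErvAlignment(c(a = "ACGT", b = "ACGT", c = "ACGT"), "a")
  expect_equal(buildConsensus(aln), "ACGT")
  ## A,A,G -> A; gap majority wins; on ties a base beats the gap and ties
  ## among bases resolve alphabetically
  aln2 <- ErvAlignment(c(a = "AAGA", b = "AGGG", c = "GG--"), "a")
  expect_equal(buildConsensus(aln2), "AGGA")
  aln3 <- ErvAlignment(c(a = "AN", b = "-N", c = "-N"), "a")
  expect_equal(buildConsensus(aln3), "-N")   # gap majority; N-only column -> N
  expect_error(buildConsensus(aln, members = character(0)), "empty")
})

test_that("consensus of mutated copies recovers the ancestor", {
  set.seed(73)
  anc <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  mutate1pct <- function(s) {
    v <- strsplit(s, "")[[1]]
    idx <- which(runif(1000) < 0.01)
    for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  rows <- setNames(replicate(5, mutate1pct(anc)), paste0("m", 1:5))
  cons <- buildConsensus(ErvAlignment(rows, "m1"))
  agree <- mean(strsplit(cons, "")[[1]] == strsplit(anc, "")[[1]])
  expect_gte(agree, 0.99)
  ## idempotence: adding the consensus to the set leaves it unchanged
  rows2 <- c(rows, cons = cons)
  expect_equal(buildConsensus(ErvAlignment(rows2, "m1")), cons)
})

test_that("region extraction slices reference-frame columns", {
  set.seed(74)
  w <- 9500
  row <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  aln <- ErvAlignment(c(K113 = row, x = row), "K113")
  ## gag region spans 2086 alignment columns
  expect_equal(alignmentWidth(extractRegion(aln, "gag")), 3168 - 1083 + 1)
  expect_equal(alignmentWidth(extractRegion(aln, "gag")), 2086)
  ## full-range slice is the identity
  full <- extractRegion(aln, cols = c(1, w))
  expect_equal(alignmentRow(full, "x"), row)
  ## pol and env slices are disjoint and ordered
  m <- geneRegionMap()
  expect_lt(m$pol[2], m$env[1])
  expect_lt(m$gag[2], m$pol[1])
  expect_error(extractRegion(aln, cols = c(0, 10)), "outside")
  expect_error(extractRegion(aln, "nosuch"), "unknown region")
})

test_that("aligned FASTA round-trips through ErvAlignment", {
  tmp <- tempfile(fileext = ".fasta")
  aln <- ErvAlignment(c(ref = "ACGT-ACGTN", s1 = "ACGTTACGT-"), "ref")
  writeAlignedFasta(aln, tmp)
  back <- readAlignedFasta(tmp, reference = "ref")
  expect_equal(alignmentNames(back), c("ref", "s1"))
  expect_equal(alignmentRow(back, "s1"), "ACGTTACGT-")
  ## lowercase soft-masked input is uppercased
  writeLines(c(">a", "acgt", ">b", "ACGT"), tmp)
  low <- readAlignedFasta(tmp)
  expect_equal(alignmentRow(low, "a"), "ACGT")
})
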