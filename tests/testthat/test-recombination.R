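test_that("three-taxon NJ solves the three-point formulas", {
  D <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- buildNjTree(D)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["B"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["C"]], (5 + 4 - 3) / 2)
})

test_that("NJ recovers additive trees exactly", {
  ## the canonical 4-taxon additive example ((A:1,B:2):1,(C:3,D:1))
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  D <- cophenetic(tr0)
  tr <- buildNjTree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr0)), 0,
               ignore_attr = TRUE)
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D, tolerance = 1e-12)
  ## 50 random 6-taxon additive matrices
  set.seed(51)
  for (i in 1:50) {
    rt <- ape::rtree(6)
    rd <- cophenetic(rt)
    t2 <- buildNjTree(rd)
    expect_equal(ape::dist.topo(ape::unroot(t2), ape::unroot(rt)), 0,
                 ignore_attr = TRUE)
    expect_equal(max(abs(cophenetic(t2)[rownames(rd), colnames(rd)] - rd)), 0,
                 tolerance = 1e-9)
  }
})

test_that("NJ matches the reference implementation on noisy matrices", {
  set.seed(52)
  for (i in 1:10) {
    n <- 8
    rt <- ape::rtree(n)
    rd <- cophenetic(rt) + matrix(runif(n * n, 0, 0.05), n, n)
    rd <- (rd + t(rd)) / 2; diag(rd) <- 0
    mine <- buildNjTree(rd)
    ref <- ape::nj(rd)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ validates its input matrix", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(buildNjTree(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(buildNjTree(D3), "symmetric")
  D4 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(buildNjTree(D4), "non-negative")
})

test_that("subgroups are monophyletic in LTR trees", {
  set.seed(53)
  anc <- makeSubgroupAncestors(seed = 53)
  mutate <- function(nm, p = 0.01) {
    row <- strsplit(alignmentRow(anc$ancestors, nm), "")[[1]]
    idx <- which(row %in% c("A", "C", "G", "T"))
    for (m in idx[runif(length(idx)) < p]) {
      row[m] <- sample(setdiff(c("A", "C", "G", "T"), row[m]), 1)
    }
    paste(row, collapse = "")
  }
  rows <- c(setNames(replicate(4, mutate("LTR5Hs")), paste0("hs", 1:4)),
            setNames(replicate(4, mutate("LTR5B")), paste0("b", 1:4)))
  aln <- ErvAlignment(rows, "hs1")
  dm <- ltrDistanceMatrix(aln, names = names(rows))
  tr <- buildNjTree(dm)
  rooted <- ape::root(tr, "hs1", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, paste0("b", 1:4)))
})

test_that("short LTR fragments are dropped from distance matrices", {
  rows <- c(a = strrep("ACGT", 100), b = strrep("ACGT", 100),
            frag = paste0(strrep("A", 100), strrep("-", 300)))
  aln <- ErvAlignment(rows, "a")
  expect_warning(dm <- ltrDistanceMatrix(aln, names = names(rows), minBases = 250),
                 "dropping")
  expect_equal(rownames(dm), c("a", "b"))
})

test_that("a constructed gene conversion is flagged unpaired", {
  set.seed(54)
  sim <- simulateCatalog(simulationConfig(seed = 54, nProviruses = 20, nSoloLtrs = 5,
                                          ageRange = c(3, 28)))
  aln <- sim$provirusAlignment; fr <- sim$frame
  ids <- sim$truth$element_id[sim$truth$kind == "provirus"]
  l5 <- extractRegion(aln, cols = fr$ltr5Cols)
  l3 <- extractRegion(aln, cols = fr$ltr3Cols)
  rows <- c(setNames(vapply(ids, function(i) alignmentRow(l5, i), ""), paste0(ids, "_5LTR")),
            setNames(vapply(ids, function(i) alignmentRow(l3, i), ""), paste0(ids, "_3LTR")))
  ## copy provirus A's 3' LTR over provirus B's 3' LTR
  donor <- ids[which.max(sim$truth$true_age[match(ids, sim$truth$element_id)])]
  recip <- ids[which.min(sim$truth$true_age[match(ids, sim$truth$element_id)])]
  rows[paste0(recip, "_3LTR")] <- rows[paste0(donor, "_3LTR")]
  dm <- ltrDistanceMatrix(ErvAlignment(rows, names(rows)[1]), names = names(rows))
  pairing <- data.frame(provirus_id = ids, ltr5 = paste0(ids, "_5LTR"),
                        ltr3 = paste0(ids, "_3LTR"), stringsAsFactors = FALSE)
  res <- detectUnpairedLtrs(dm, pairing, tree = buildNjTree(dm))
  expect_false(res$paired[res$provirus_id == recip])
})

test_that("clean simulations yield no unpaired flags", {
  for (seed in c(55, 56)) {
    sim <- simulateCatalog(simulationConfig(seed = seed, nProviruses = 22, nSoloLtrs = 5,
                                            ageRange = c(3, 28), conversionRate = 0))
    aln <- sim$provirusAlignment; fr <- sim$frame
    ids <- sim$truth$element_id[sim$truth$kind == "provirus"]
    l5 <- extractRegion(aln, cols = fr$ltr5Cols)
    l3 <- extractRegion(aln, cols = fr$ltr3Cols)
    rows <- c(setNames(vapply(ids, function(i) alignmentRow(l5, i), ""), paste0(ids, "_5LTR")),
              setNames(vapply(ids, function(i) alignmentRow(l3, i), ""), paste0(ids, "_3LTR")))
    dm <- ltrDistanceMatrix(ErvAlignment(rows, names(rows)[1]), names = names(rows))
    pairing <- data.frame(provirus_id = ids, ltr5 = paste0(ids, "_5LTR"),
                          ltr3 = paste0(ids, "_3LTR"), stringsAsFactors = FALSE)
    res <- detectUnpairedLtrs(dm, pairing, tree = buildNjTree(dm))
    expect_equal(sum(!res$paired), 0L)
  }
})

test_that("breakpoint scans localize constructed chimeras and tile the range", {
  set.seed(57)
  anc <- makeSubgroupAncestors(seed = 57)
  m <- as.matrix(anc$ancestors)
  hs <- m["LTR5Hs", ]; b5 <- m["LTR5B", ]
  cons <- list(LTR5Hs = paste(hs, collapse = ""), LTR5B = paste(b5, collapse = ""))
  ## pure sequence: a single segment, no breakpoints
  aln0 <- ErvAlignment(c(x = paste(hs, collapse = ""), ref = cons$LTR5Hs), "ref")
  seg0 <- scanBreakpoints(aln0, "x", cons, window = 200, step = 50, minCompared = 30)
  expect_equal(nrow(seg0), 1L)
  expect_equal(seg0$best_subgroup, "LTR5Hs")
  ## chimera switching ancestry at a known junction
  chim <- hs; chim[451:750] <- b5[451:750]
  aln <- ErvAlignment(c(x = paste(chim, collapse = ""), ref = cons$LTR5Hs), "ref")
  segs <- scanBreakpoints(aln, "x", cons, window = 200, step = 50, minCompared = 30)
  expect_gte(nrow(segs), 3L)
  mid <- segs[segs$best_subgroup == "LTR5B", ]
  expect_equal(nrow(mid), 1L)
  ## junctions localized within one window of the truth
  expect_lte(abs(mid$start_col - 451), 200)
  expect_lte(abs(mid$end_col - 750), 200)
  ## segments partition the scanned range without overlap
  expect_equal(segs$start_col[1], 1L)
  expect_equal(segs$end_col[nrow(segs)], alignmentWidth(aln))
  if (nrow(segs) > 1) {
    expect_equal(segs$start_col[-1], segs$end_col[-nrow(segs)] + 1L)
  }
  expect_error(scanBreakpoints(aln, "x", cons["LTR5Hs"]), "at least 2")
})
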