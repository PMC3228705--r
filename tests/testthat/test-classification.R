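## shared fixture: a synthetic provirus alignment with known frame
refSim <- simulateCatalog(simulationConfig(seed = 301, nProviruses = 12, nSoloLtrs = 8,
                                           type1Fraction = 0.5))

test_that("type calls recover planted 292-bp deletions", {
  aln <- refSim$provirusAlignment
  fr <- refSim$frame
  tr <- refSim$truth[refSim$truth$kind == "provirus", ]
  calls <- vapply(tr$element_id,
                  function(id) classifyType(aln, id, fr$deletionWindow)$call,
                  character(1))
  expect_equal(unname(calls), tr$type)
  ## counts over any partition sum to input size, one call per element
  expect_equal(sum(calls == "type1") + sum(calls == "type2") +
                 sum(calls == "undetermined"), nrow(tr))
})

test_that("large deletions spanning the window are undetermined", {
  aln <- refSim$provirusAlignment
  fr <- refSim$frame
  id <- refSim$truth$element_id[refSim$truth$type %in% "type2"][1]
  row <- strsplit(alignmentRow(aln, id), "")[[1]]
  big <- seq(fr$deletionWindow[1] - 1000, min(length(row), fr$deletionWindow[2] + 1000))
  row[big] <- "-"
  aln2 <- ErvAlignment(c(setNames(paste(row, collapse = ""), "del"),
                         frame_ref = alignmentRow(aln, "frame_ref")), "frame_ref")
  expect_equal(classifyType(aln2, "del", fr$deletionWindow)$call, "undetermined")
  ## the untouched reference row is type 2
  expect_equal(classifyType(aln2, "frame_ref", fr$deletionWindow)$call, "type2")
  expect_error(classifyType(aln2, "absent", fr$deletionWindow), "not in alignment")
})

test_that("the deletion window can be located from known type-1 rows", {
  aln <- refSim$provirusAlignment
  fr <- refSim$frame
  t1 <- refSim$truth$element_id[refSim$truth$type %in% "type1"]
  expect_gte(length(t1), 2)
  win <- findDeletionWindow(aln, t1)
  ## recovered window overlaps the planted window substantially
  ov <- min(win[2], fr$deletionWindow[2]) - max(win[1], fr$deletionWindow[1]) + 1
  expect_gte(ov / 292, 0.9)
})

test_that("subgroup calls follow the diagnostic-indel decision rule", {
  anc <- makeSubgroupAncestors(seed = 31)
  d <- anc$diagnostics
  for (nm in c("LTR5Hs", "LTR5A", "LTR5B")) {
    res <- classifySubgroup(alignmentRow(anc$ancestors, nm), d)
    expect_equal(res$subgroup, nm)
  }
  ## evidence flags: 5A carries both insertions, 5Hs neither
  a <- classifySubgroup(alignmentRow(anc$ancestors, "LTR5A"), d)
  expect_true(a$abPresent && a$aPresent)
  hs <- classifySubgroup(alignmentRow(anc$ancestors, "LTR5Hs"), d)
  expect_false(hs$abPresent)
  expect_true(hs$hsPresent)
  ## a fully gapped row is undetermined
  blank <- strrep("-", alignmentWidth(anc$ancestors))
  expect_equal(classifySubgroup(blank, d)$subgroup, "undetermined")
})

test_that("subgroup calls are invariant to off-diagnostic mutations", {
  set.seed(32)
  anc <- makeSubgroupAncestors(seed = 32)
  d <- anc$diagnostics
  diagCols <- c(d@hsCols, d@abCols, d@aCols)
  for (i in 1:30) {
    nm <- sample(c("LTR5Hs", "LTR5A", "LTR5B"), 1)
    row <- strsplit(alignmentRow(anc$ancestors, nm), "")[[1]]
    targets <- setdiff(which(row %in% c("A", "C", "G", "T")), diagCols)
    mut <- sample(targets, 40)
    for (m in mut) row[m] <- sample(setdiff(c("A", "C", "G", "T"), row[m]), 1)
    expect_equal(classifySubgroup(paste(row, collapse = ""), d)$subgroup, nm)
  }
})

test_that("clean synthetic LTRs classify to their true subgroup at >=99%", {
  set.seed(33)
  anc <- makeSubgroupAncestors(seed = 33)
  d <- anc$diagnostics
  n <- 300
  truth <- sample(c("LTR5Hs", "LTR5A", "LTR5B"), n, replace = TRUE)
  calls <- vapply(truth, function(nm) {
    row <- strsplit(alignmentRow(anc$ancestors, nm), "")[[1]]
    idx <- which(row %in% c("A", "C", "G", "T"))
    mut <- idx[runif(length(idx)) < 0.02]   # 2% random mutation
    for (m in mut) row[m] <- sample(setdiff(c("A", "C", "G", "T"), row[m]), 1)
    classifySubgroup(paste(row, collapse = ""), d)$subgroup
  }, character(1))
  expect_gte(mean(calls == truth), 0.99)
})

test_that("ORF calls scan forward frames against the reference length", {
  aln <- refSim$provirusAlignment
  fr <- refSim$frame
  ## the frame reference row is built from sense codons: all genes intact
  orf <- callOrfs(aln, "frame_ref", regions = fr$regionMap)
  expect_true(all(orf$intact))
  expect_true(all(orf$longest_orf_fraction >= 0.95))
  ## an internal stop at the midpoint breaks intactness
  row <- strsplit(alignmentRow(aln, "frame_ref"), "")[[1]]
  gag <- fr$regionMap$gag
  ## a stop on a codon boundary of the coding template, mid-gag
  mid <- fr$internalCols[1] - 1 + 451
  row[mid:(mid + 2)] <- c("T", "A", "A")
  aln2 <- ErvAlignment(c(stop = paste(row, collapse = ""),
                         frame_ref = alignmentRow(aln, "frame_ref")), "frame_ref")
  orf2 <- callOrfs(aln2, "stop", regions = fr$regionMap)
  expect_false(orf2$intact[orf2$gene == "gag"])
  ## a fully deleted region scores zero
  row[gag[1]:gag[2]] <- "-"
  aln3 <- ErvAlignment(c(del = paste(row, collapse = ""),
                         frame_ref = alignmentRow(aln, "frame_ref")), "frame_ref")
  orf3 <- callOrfs(aln3, "del", regions = fr$regionMap)
  expect_equal(orf3$longest_orf_fraction[orf3$gene == "gag"], 0)
  expect_false(orf3$intact[orf3$gene == "gag"])
})
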