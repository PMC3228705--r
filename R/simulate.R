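#' SimulationConfig: settings for the synthetic ERV-evolution generator
#'
#' The generator plants proviruses and solo LTRs with known insertion ages,
#' subgroups, types and recombination events, producing alignments,
#' repeat-annotation tables, gene layouts and a ground-truth table so every
#' pipeline stage can be validated against planted truth.
#'
#' Defaults mirror the study conditions: cognate-LTR divergence accrues at
#' 0.345 %/Myr (the midpoint of the 0.24-0.45 clock band, consistent with
#' the 0.34 solo rate), substitutions follow a K2P process with kappa = 2,
#' subgroup proportions reflect the observed provirus-LTR composition
#' (roughly 50/24/26 for 5Hs/5A/5B), the 292-bp type-1 deletion is applied
#' to a fraction of LTR5Hs proviruses (type 1 is a 5Hs feature), and a small
#' pre-integration divergence (0.5%) is shared by both LTRs at integration —
#' the reason the solo-LTR method needs calibration.
#'
#' @slot seed Integer RNG seed.
#' @slot nProviruses,nSoloLtrs Expected total element counts.
#' @slot subgroupProportions Named fractions over LTR5Hs/LTR5A/LTR5B.
#' @slot ageRange Uniform insertion-age range (Myr).
#' @slot divergenceRate Cognate-LTR divergence rate, %/Myr.
#' @slot kappa Transition/transversion rate ratio of the substitution
#'   process.
#' @slot type1Fraction Fraction of LTR5Hs proviruses given the 292-bp
#'   deletion.
#' @slot conversionRate Fraction of proviruses receiving an LTR gene-
#'   conversion event.
#' @slot indelRate Deletion events per site per Myr (per LTR lineage).
#' @slot preIntegrationDivergence Per-site private divergence acquired by
#'   each integrating virion during the replication burst preceding
#'   endogenization (shared by both LTRs of that provirus, but private to
#'   it).
#' @slot lineageRate Substitution rate (%/Myr) of the viral source lineage
#'   between successive integration events: each subgroup's integrations
#'   sample an evolving lineage, so proviruses integrated far apart in time
#'   differ by more than two recent integrations do.
#' @slot ltrLength,internalLength Ungapped ancestor LTR / internal lengths.
#' @slot chromosomeLayout data.frame `name`, `length`, `nGenes`.
#' @slot placementBeta1,placementDispersion NB placement model: per-
#'   chromosome expected counts proportional to exp(beta1 x scaled gene
#'   count), NB-dispersed.
#' @slot nNoiseHits Count of stray sub-750-bp LTR fragments added to the
#'   annotation.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(seed = "integer", nProviruses = "integer", nSoloLtrs = "integer",
            subgroupProportions = "numeric", ageRange = "numeric",
            divergenceRate = "numeric", kappa = "numeric",
            type1Fraction = "numeric", conversionRate = "numeric",
            indelRate = "numeric", preIntegrationDivergence = "numeric",
            lineageRate = "numeric",
            ltrLength = "integer", internalLength = "integer",
            chromosomeLayout = "data.frame", placementBeta1 = "numeric",
            placementDispersion = "numeric", nNoiseHits = "integer"))

setValidity("SimulationConfig", function(object) {
  p <- object@subgroupProportions
  if (abs(sum(p) - 1) > 1e-8) return("subgroupProportions must sum to 1")
  if (!all(c("LTR5Hs", "LTR5A", "LTR5B") %in% names(p))) {
    return("subgroupProportions must be named LTR5Hs/LTR5A/LTR5B")
  }
  if (any(c(object@divergenceRate, object@indelRate, object@conversionRate) < 0)) {
    return("rates must be non-negative")
  }
  if (object@internalLength %% 3L != 0L) return("internalLength must be a codon multiple")
  TRUE
})

#' Construct a SimulationConfig
#' @param seed,nProviruses,nSoloLtrs,subgroupProportions,ageRange,divergenceRate,kappa,type1Fraction,conversionRate,indelRate,preIntegrationDivergence,lineageRate,ltrLength,internalLength,chromosomeLayout,placementBeta1,placementDispersion,nNoiseHits
#'   See [SimulationConfig-class].
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nProviruses = 90L, nSoloLtrs = 200L,
                             subgroupProportions = c(LTR5Hs = 0.50, LTR5A = 0.24, LTR5B = 0.26),
                             ageRange = c(1, 30), divergenceRate = 0.345,
                             kappa = 2, type1Fraction = 0.44,
                             conversionRate = 0, indelRate = 1e-5,
                             preIntegrationDivergence = 0.005,
                             lineageRate = 0.35,
                             ltrLength = 1000L, internalLength = 3000L,
                             chromosomeLayout = defaultChromosomeLayout(),
                             placementBeta1 = 0.5, placementDispersion = 0.3,
                             nNoiseHits = 5L) {
  new("SimulationConfig", seed = as.integer(seed),
      nProviruses = as.integer(nProviruses), nSoloLtrs = as.integer(nSoloLtrs),
      subgroupProportions = subgroupProportions, ageRange = ageRange,
      divergenceRate = divergenceRate, kappa = kappa,
      type1Fraction = type1Fraction, conversionRate = conversionRate,
      indelRate = indelRate, preIntegrationDivergence = preIntegrationDivergence,
      lineageRate = lineageRate,
      ltrLength = as.integer(ltrLength), internalLength = as.integer(internalLength),
      chromosomeLayout = chromosomeLayout, placementBeta1 = placementBeta1,
      placementDispersion = placementDispersion, nNoiseHits = as.integer(nNoiseHits))
}

#' Default synthetic genome layout
#'
#' Twelve chromosomes spanning a range of sizes and gene counts, emulating
#' the size/gene-density spread of a mammalian karyotype at reduced scale.
#' @return data.frame `name`, `length`, `nGenes`.
#' @export
defaultChromosomeLayout <- function() {
  data.frame(
    name = paste0("chr", 1:12),
    length = as.integer(c(60, 55, 48, 45, 40, 36, 32, 28, 25, 22, 20, 18) * 1e6),
    nGenes = c(520, 310, 460, 220, 390, 140, 260, 90, 330, 60, 450, 170),
    stringsAsFactors = FALSE)
}

## -- substitution machinery ---------------------------------------------

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

## K2P substitution process collapsed to one binomial draw per branch; valid
## approximation for per-branch divergences < 5% (no multiple-hit bookkeeping)
.mutateSeq <- function(chars, pSub, kappa = 2, delRate = 0, maxDelLen = 6L) {
  idx <- which(.isBase(chars))
  if (length(idx) && pSub > 0) {
    nMut <- rbinom(1L, length(idx), min(pSub, 1))
    if (nMut > 0) {
      sites <- sample(idx, nMut)
      isTi <- runif(nMut) < kappa / (kappa + 2)
      for (k in seq_len(nMut)) {
        b <- chars[sites[k]]
        chars[sites[k]] <- if (isTi[k]) .TRANSITION[[b]] else sample(.TRANSVERSIONS[[b]], 1L)
      }
    }
  }
  if (delRate > 0 && length(idx)) {
    nDel <- rpois(1L, delRate * length(idx))
    for (k in seq_len(nDel)) {
      s <- sample(idx, 1L)
      len <- sample(seq_len(maxDelLen), 1L)
      span <- s:min(s + len - 1L, length(chars))
      chars[span[.isBase(chars[span])]] <- "-"
    }
  }
  chars
}

.randomBases <- function(n) sample(BASES, n, replace = TRUE)

## internal template made of sense codons so the ancestor carries intact ORFs
.randomCodingSeq <- function(nCodons) {
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

## -- ancestors -----------------------------------------------------------

#' Build the three LTR subgroup ancestors and their diagnostic map
#'
#' Constructs a shared single-LTR alignment frame in which the LTR5Hs
#' ancestor carries the 5Hs-associated 4-bp insertion, LTR5A carries both
#' the 5A/B-shared and the 5A-unique insertions, and LTR5B carries the
#' shared insertion only; outside the diagnostic columns the three ancestors
#' are minor variants of one family sequence (about 2% apart). Diagnostic
#' column anchors follow the published solo-consensus frame (5A-unique near
#' column 135, 5Hs near 461) with the shared insertion placed at column 806.
#'
#' @param seed Integer seed (ignored when `rngActive = TRUE`, for use inside
#'   a larger seeded simulation).
#' @param config A [SimulationConfig-class] supplying the LTR length.
#' @param rngActive Internal: set TRUE to consume the caller's RNG stream.
#' @return List: `ancestors` (an [ErvAlignment-class] with rows LTR5Hs,
#'   LTR5A, LTR5B), `diagnostics` (a [SubgroupDiagnostics-class] in the
#'   solo-consensus frame).
#' @export
makeSubgroupAncestors <- function(seed = 1L, config = simulationConfig(seed = seed),
                                  rngActive = FALSE) {
  if (!rngActive) set.seed(config@seed)
  ins <- 4L
  anchors <- c(a = 135L, hs = 461L, ab = 806L)
  W <- config@ltrLength + 3L * ins
  core <- .randomBases(W)   # bases everywhere; gaps punched per subgroup
  blocks <- lapply(anchors, function(p) seq(p, p + ins - 1L))
  mk <- function(carry) {
    s <- core
    for (b in names(blocks)) if (!(b %in% carry)) s[blocks[[b]]] <- "-"
    s
  }
  anc5B <- mk(c("ab"))
  anc5A <- mk(c("ab", "a"))
  anc5Hs <- mk(c("hs"))
  ## subgroup drift outside the diagnostic columns (~2% apart)
  nondiag <- setdiff(seq_len(W), unlist(blocks))
  drift <- function(s, p) {
    keep <- s
    sites <- nondiag[runif(length(nondiag)) < p]
    sites <- sites[.isBase(keep[sites])]
    for (i in sites) keep[i] <- sample(setdiff(BASES, keep[i]), 1L)
    keep
  }
  anc5A <- drift(anc5A, 0.012)
  anc5Hs <- drift(anc5Hs, 0.020)
  aln <- ErvAlignment(c(LTR5Hs = paste(anc5Hs, collapse = ""),
                        LTR5A = paste(anc5A, collapse = ""),
                        LTR5B = paste(anc5B, collapse = "")),
                      reference = "LTR5Hs")
  diag <- subgroupDiagnostics(frame = "solo_consensus",
                              hsCols = anchors[["hs"]], abCols = anchors[["ab"]],
                              aCols = anchors[["a"]], insertionWidth = ins)
  list(ancestors = aln, diagnostics = diag)
}

## -- provirus simulation -------------------------------------------------

#' Simulate one provirus of known age
#'
#' Both LTRs start as identical copies of the (optionally pre-diverged)
#' subgroup ancestor LTR and then accumulate substitutions independently at
#' half the cognate-LTR divergence rate per lineage, so the expected
#' inter-LTR divergence is `divergenceRate x age`. The internal region
#' evolves at the same per-lineage rate. The 292-column type-1 deletion is
#' applied on request.
#'
#' @param ancestorLtr Character vector: the subgroup ancestor LTR row (in
#'   the single-LTR frame).
#' @param internalTemplate Character vector: the internal-region template.
#' @param age True insertion age in Myr.
#' @param config A [SimulationConfig-class].
#' @param type1 Apply the 292-column pol-env deletion?
#' @param deletionWindow Columns of `internalTemplate` to delete for type 1.
#' @return List: `ltr5`, `internal`, `ltr3` (character vectors), `trueAge`.
#' @export
simulateProvirus <- function(ancestorLtr, internalTemplate, age, config,
                             type1 = FALSE, deletionWindow = NULL) {
  pBranch <- age * config@divergenceRate / 200   # per-site, per lineage
  delPerBranch <- config@indelRate * age
  atIntegration <- .mutateSeq(ancestorLtr, config@preIntegrationDivergence,
                              config@kappa)
  internalInt <- .mutateSeq(internalTemplate, config@preIntegrationDivergence,
                            config@kappa)
  ltr5 <- .mutateSeq(atIntegration, pBranch, config@kappa, delPerBranch)
  ltr3 <- .mutateSeq(atIntegration, pBranch, config@kappa, delPerBranch)
  internal <- .mutateSeq(internalInt, pBranch, config@kappa, delPerBranch)
  if (type1) {
    if (is.null(deletionWindow)) stop("type1 = TRUE requires a deletionWindow")
    internal[deletionWindow] <- "-"
  }
  list(ltr5 = ltr5, internal = internal, ltr3 = ltr3, trueAge = age)
}

## -- full catalog simulation ---------------------------------------------

#' Simulate a complete synthetic ERV catalog with ground truth
#'
#' Generates subgroup ancestors, proviruses and solo LTRs with known ages,
#' subgroups, types and (optionally) LTR gene-conversion events; places them
#' on a synthetic genome whose per-chromosome counts follow a negative-
#' binomial placement model driven by gene density; and emits everything the
#' pipeline consumes: a provirus alignment (with per-element 5'LTR/internal/
#' 3'LTR rows in a fixed frame), a solo-LTR alignment, a repeat-annotation
#' GRanges, gene intervals, chromosome sizes, and a ground-truth table.
#'
#' @param config A [SimulationConfig-class].
#' @param dir Optional output directory; when given, writes
#'   `alignment.fasta`, `solo_ltrs.fasta`, `repeats.bed`, `genes.bed`,
#'   `chrom_sizes.tsv` and `ground_truth.tsv` there.
#' @return A list: `provirusAlignment`, `soloAlignment` ([ErvAlignment-class]),
#'   `hits` (GRanges), `genes` (GRanges), `chromSizes` (data.frame), `truth`
#'   (data.frame), `frame` (coordinate bookkeeping: LTR/internal column
#'   spans, provirus- and solo-frame [SubgroupDiagnostics-class], the
#'   type-1 `deletionWindow`, and the internal gene-region map), `ancestors`,
#'   `config`.
#' @export
simulateCatalog <- function(config = simulationConfig(), dir = NULL) {
  set.seed(config@seed)
  anc <- makeSubgroupAncestors(config = config, rngActive = TRUE)
  ancM <- as.matrix(anc$ancestors)
  W <- ncol(ancM)
  I <- config@internalLength
  internalTemplate <- strsplit(.randomCodingSeq(I / 3L), "")[[1L]]

  ## internal-frame layout: gene regions and the 292-column pol-env window
  geneMapInternal <- list(gag = c(101L, 1100L), pol = c(1301L, 2100L),
                          env = c(2401L, 2900L))
  delWindowInternal <- seq(2101L, 2392L)
  stopifnot(max(delWindowInternal) < I)

  frame <- list(
    ltrWidth = W, internalWidth = I,
    ltr5Cols = c(1L, W), internalCols = c(W + 1L, W + I),
    ltr3Cols = c(W + I + 1L, 2L * W + I),
    deletionWindow = c(W + min(delWindowInternal), W + max(delWindowInternal)),
    regionMap = lapply(geneMapInternal, function(r) r + W),
    soloDiagnostics = anc$diagnostics,
    provirusDiagnostics = new("SubgroupDiagnostics", frame = "provirus_alignment",
                              hsCols = c(anc$diagnostics@hsCols, anc$diagnostics@hsCols + W + I),
                              abCols = c(anc$diagnostics@abCols, anc$diagnostics@abCols + W + I),
                              aCols = c(anc$diagnostics@aCols, anc$diagnostics@aCols + W + I)))

  ## per-chromosome counts from the NB placement model
  layout <- config@chromosomeLayout
  xg <- layout$nGenes / 100
  allocate <- function(total) {
    mu <- exp(config@placementBeta1 * xg)
    mu <- mu / sum(mu) * total
    rnbinom(nrow(layout), mu = mu, size = 1 / config@placementDispersion)
  }
  nPerChromP <- allocate(config@nProviruses)
  nPerChromS <- allocate(config@nSoloLtrs)
  nP <- sum(nPerChromP); nS <- sum(nPerChromS)

  props <- config@subgroupProportions
  sgP <- sample(names(props), nP, replace = TRUE, prob = props)
  sgS <- sample(names(props), nS, replace = TRUE, prob = props)
  ageP <- runif(nP, config@ageRange[1L], config@ageRange[2L])
  ageS <- runif(nS, config@ageRange[1L], config@ageRange[2L])
  typeP <- ifelse(sgP == "LTR5Hs" & runif(nP) < config@type1Fraction, "type1", "type2")

  ## simulate sequences along each subgroup's source lineage: integrations
  ## sample an evolving viral lineage (the ladder), oldest first, so
  ## proviruses integrated far apart in time are proportionally more
  ## diverged from one another than near-simultaneous integrations
  subgroupInternal <- lapply(stats::setNames(nm = names(props)), function(s) {
    .mutateSeq(internalTemplate, 0.015, config@kappa)
  })
  provRows <- vector("list", nP)
  soloRows <- vector("list", nS)
  for (s in names(props)) {
    iP <- which(sgP == s); iS <- which(sgS == s)
    agesAll <- c(ageP[iP], ageS[iS])
    isProv <- c(rep(TRUE, length(iP)), rep(FALSE, length(iS)))
    idxAll <- c(iP, iS)
    ord <- order(-agesAll)
    stemLtr <- ancM[s, ]
    stemInt <- subgroupInternal[[s]]
    tPrev <- config@ageRange[2L]
    for (k in ord) {
      dt <- max(0, tPrev - agesAll[k])
      stemLtr <- .mutateSeq(stemLtr, dt * config@lineageRate / 100, config@kappa)
      stemInt <- .mutateSeq(stemInt, dt * config@lineageRate / 100, config@kappa)
      tPrev <- agesAll[k]
      if (isProv[k]) {
        i <- idxAll[k]
        provRows[[i]] <- simulateProvirus(stemLtr, stemInt, agesAll[k], config,
                                          type1 = typeP[i] == "type1",
                                          deletionWindow = delWindowInternal)
      } else {
        i <- idxAll[k]
        atInt <- .mutateSeq(stemLtr, config@preIntegrationDivergence, config@kappa)
        soloRows[[i]] <- .mutateSeq(atInt, agesAll[k] * config@divergenceRate / 200,
                                    config@kappa, config@indelRate * agesAll[k])
      }
    }
  }
  ## conversion events: the recipient's 3' LTR is overwritten by a copy of a
  ## same-subgroup donor's 3' LTR at a recent conversion time
  conv <- rep(FALSE, nP); donor <- rep(NA_character_, nP)
  nConv <- round(config@conversionRate * nP)
  if (nConv > 0 && nP >= 2L) {
    recipients <- sample(nP, min(nConv, nP - 1L))
    for (r in recipients) {
      cand <- setdiff(which(sgP == sgP[r] & !conv), r)
      if (!length(cand)) cand <- setdiff(seq_len(nP), r)
      d <- cand[which.max(abs(ageP[cand] - ageP[r]))]
      tau <- runif(1, 0, 0.5)
      provRows[[r]]$ltr3 <- .mutateSeq(provRows[[d]]$ltr3,
                                       tau * config@divergenceRate / 100,
                                       config@kappa)
      conv[r] <- TRUE; donor[r] <- sprintf("P%03d", d)
    }
  }

  ## genome placement
  idP <- sprintf("P%03d", seq_len(nP))
  idS <- sprintf("S%03d", seq_len(nS))
  chromP <- rep(layout$name, nPerChromP)
  chromS <- rep(layout$name, nPerChromS)
  degapLen <- function(ch) sum(.isBase(ch))
  spanP <- vapply(provRows, function(r) degapLen(r$ltr5) + degapLen(r$internal) + degapLen(r$ltr3), numeric(1))
  spanS <- vapply(soloRows, degapLen, numeric(1))
  placements <- .placeElements(layout, chromP, spanP, chromS, spanS, minSep = 2000L)
  strandP <- sample(c("+", "-"), nP, replace = TRUE)
  strandS <- sample(c("+", "-"), nS, replace = TRUE)

  ## annotation hits (BED-style GRanges, 1-based inclusive internally)
  hits <- .buildHits(config, layout, idP, chromP, placements$startP, provRows,
                     sgP, strandP, idS, chromS, placements$startS, soloRows,
                     sgS, strandS)

  ## genes
  genes <- .placeGenes(layout)

  ## alignments
  refProv <- paste(c(ancM["LTR5Hs", ], internalTemplate, ancM["LTR5Hs", ]), collapse = "")
  provSeqs <- c(stats::setNames(
    vapply(provRows, function(r) paste(c(r$ltr5, r$internal, r$ltr3), collapse = ""), character(1)),
    idP), frame_ref = refProv)
  provAln <- ErvAlignment(provSeqs, reference = "frame_ref")
  soloSeqs <- c(stats::setNames(vapply(soloRows, paste, character(1), collapse = ""), idS),
                frame_ref = paste(ancM["LTR5Hs", ], collapse = ""))
  soloAln <- ErvAlignment(soloSeqs, reference = "frame_ref")

  truth <- data.frame(
    element_id = c(idP, idS),
    kind = c(rep("provirus", nP), rep("solo_ltr", nS)),
    chrom = c(chromP, chromS),
    start = c(placements$startP, placements$startS),
    end = c(placements$startP + spanP - 1, placements$startS + spanS - 1),
    strand = c(strandP, strandS),
    true_age = c(ageP, ageS),
    subgroup = c(sgP, sgS),
    type = c(typeP, rep(NA_character_, nS)),
    conversion = c(conv, rep(FALSE, nS)),
    donor = c(donor, rep(NA_character_, nS)),
    stringsAsFactors = FALSE)

  res <- list(provirusAlignment = provAln, soloAlignment = soloAln,
              hits = hits, genes = genes,
              chromSizes = data.frame(chrom = layout$name, length = layout$length,
                                      stringsAsFactors = FALSE),
              truth = truth, frame = frame, ancestors = anc, config = config)
  if (!is.null(dir)) .writeSimOutputs(res, dir)
  res
}

.placeElements <- function(layout, chromP, spanP, chromS, spanS, minSep = 2000L) {
  startP <- numeric(length(chromP)); startS <- numeric(length(chromS))
  for (ch in layout$name) {
    len <- layout$length[layout$name == ch]
    iP <- which(chromP == ch); iS <- which(chromS == ch)
    spans <- c(spanP[iP], spanS[iS])
    placed <- matrix(numeric(0), 0, 2)
    starts <- numeric(length(spans))
    for (k in seq_along(spans)) {
      ok <- FALSE
      for (try in 1:200) {
        s <- floor(runif(1, 1, len - spans[k] - 1))
        if (nrow(placed) == 0 ||
            all(s > placed[, 2] + minSep | s + spans[k] - 1 < placed[, 1] - minSep)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop(sprintf("could not place element on %s: chromosome too crowded", ch))
      placed <- rbind(placed, c(s, s + spans[k] - 1))
      starts[k] <- s
    }
    if (length(iP)) startP[iP] <- starts[seq_along(iP)]
    if (length(iS)) startS[iS] <- starts[length(iP) + seq_along(iS)]
  }
  list(startP = startP, startS = startS)
}

.buildHits <- function(config, layout, idP, chromP, startP, provRows, sgP, strandP,
                       idS, chromS, startS, soloRows, sgS, strandS) {
  rows <- list()
  deg <- function(ch) sum(.isBase(ch))
  for (i in seq_along(idP)) {
    l5 <- deg(provRows[[i]]$ltr5); int <- deg(provRows[[i]]$internal)
    l3 <- deg(provRows[[i]]$ltr3)
    s <- startP[i]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chromP[i],
      start = c(s, s + l5, s + l5 + int),
      end = c(s + l5 - 1, s + l5 + int - 1, s + l5 + int + l3 - 1),
      strand = strandP[i],
      repeat_name = c(sgP[i], "HERVK-int", sgP[i]),
      link_id = idP[i], stringsAsFactors = FALSE)
  }
  for (i in seq_along(idS)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chromS[i], start = startS[i], end = startS[i] + deg(soloRows[[i]]) - 1,
      strand = strandS[i], repeat_name = sgS[i], link_id = idS[i],
      stringsAsFactors = FALSE)
  }
  if (config@nNoiseHits > 0) {
    for (k in seq_len(config@nNoiseHits)) {
      ci <- sample(nrow(layout), 1L)
      w <- sample(150:600, 1L)   # below the 750-bp solo cutoff
      s <- floor(runif(1, 1, layout$length[ci] - w))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = layout$name[ci], start = s, end = s + w - 1,
        strand = sample(c("+", "-"), 1L),
        repeat_name = sample(c("LTR5Hs", "LTR5A", "LTR5B"), 1L),
        link_id = sprintf("noise%d", k), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    repeat_name = df$repeat_name, repeat_class = "LTR/ERVK",
    score = NA_real_, divergence = NA_real_, link_id = df$link_id,
    hit_id = paste0("hit_", seq_len(nrow(df))))
  gr
}

.placeGenes <- function(layout) {
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    n <- layout$nGenes[i]
    w <- sample(5000:50000, n, replace = TRUE)
    s <- floor(runif(n, 1, layout$length[i] - max(w)))
    rows[[i]] <- data.frame(chrom = layout$name[i], start = s, end = s + w - 1,
                            strand = sample(c("+", "-"), n, replace = TRUE),
                            gene_id = sprintf("%s_g%d", layout$name[i], seq_len(n)),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = df$gene_id, feature = "gene")
  gr
}

.writeSimOutputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAlignedFasta(res$provirusAlignment, file.path(dir, "alignment.fasta"))
  writeAlignedFasta(res$soloAlignment, file.path(dir, "solo_ltrs.fasta"))
  h <- res$hits
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(h)),
                    start0 = GenomicRanges::start(h) - 1L,
                    end = GenomicRanges::end(h),
                    name = S4Vectors::mcols(h)$repeat_name, score = 0,
                    strand = as.character(GenomicRanges::strand(h)))
  write.table(bed, file.path(dir, "repeats.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- res$genes
  gbed <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                     start0 = GenomicRanges::start(g) - 1L,
                     end = GenomicRanges::end(g),
                     name = S4Vectors::mcols(g)$gene_id, score = 0,
                     strand = as.character(GenomicRanges::strand(g)))
  write.table(gbed, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(res$chromSizes, file.path(dir, "chrom_sizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(res$truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a provirus set matching the published HML-2 catalog composition
#'
#' Builds a synthetic 91-provirus alignment whose planted composition mirrors
#' the published human HML-2 catalog: 45/21/23 LTR5Hs/5A/5B proviruses plus
#' two elements with no classifiable LTR; 20 type-1, 55 type-2 and 16
#' untypable elements (larger deletions spanning the pol-env feature, the
#' two LTR-less elements among them); six LTR gene-conversion events among
#' the independently evolving two-LTR proviruses; and an LTR5A duplication
#' clade of seven members containing a near-identical triplet (>99.9%
#' pairwise identity; about 96% mean identity across the clade). Ground
#' truth for every planted property is returned so classifier and detector
#' outputs can be validated at the published composition.
#'
#' Duplication-derived clade members share their LTR histories by
#' construction (a duplication copies the whole provirus), which violates
#' the independent-LTR-evolution assumption behind cognate-LTR pairing;
#' they are marked `duplication_cluster` in the truth table and excluded
#' from the pairing analysis, as their curation history requires.
#'
#' The per-integration private divergence is set to 1% here (above the
#' plain-catalog default) to reflect the inter-element divergence floor
#' observed among human-specific HML-2 LTRs.
#'
#' @param seed Integer seed.
#' @return List: `alignment` ([ErvAlignment-class] of 91 provirus rows),
#'   `frame` (as in [simulateCatalog()]), `truth` (data.frame with planted
#'   subgroup, type, conversion, donor and duplication flags), `config`.
#' @export
simulateReferenceComposition <- function(seed = 1L) {
  config <- simulationConfig(seed = seed, ageRange = c(1, 34),
                             preIntegrationDivergence = 0.01,
                             conversionRate = 0)
  set.seed(config@seed)
  anc <- makeSubgroupAncestors(config = config, rngActive = TRUE)
  ancM <- as.matrix(anc$ancestors)
  W <- ncol(ancM); I <- config@internalLength
  internalTemplate <- strsplit(.randomCodingSeq(I / 3L), "")[[1L]]
  geneMapInternal <- list(gag = c(101L, 1100L), pol = c(1301L, 2100L),
                          env = c(2401L, 2900L))
  delWindowInternal <- seq(2101L, 2392L)
  frame <- list(
    ltrWidth = W, internalWidth = I,
    ltr5Cols = c(1L, W), internalCols = c(W + 1L, W + I),
    ltr3Cols = c(W + I + 1L, 2L * W + I),
    deletionWindow = c(W + min(delWindowInternal), W + max(delWindowInternal)),
    regionMap = lapply(geneMapInternal, function(r) r + W),
    soloDiagnostics = anc$diagnostics,
    provirusDiagnostics = new("SubgroupDiagnostics", frame = "provirus_alignment",
                              hsCols = c(anc$diagnostics@hsCols, anc$diagnostics@hsCols + W + I),
                              abCols = c(anc$diagnostics@abCols, anc$diagnostics@abCols + W + I),
                              aCols = c(anc$diagnostics@aCols, anc$diagnostics@aCols + W + I)))

  ## planted composition
  nClade <- 7L
  sg <- c(rep("LTR5Hs", 45L), rep("LTR5A", 21L), rep("LTR5B", 23L),
          rep("no_ltr", 2L))
  n <- length(sg)                                   # 91
  age <- numeric(n)
  age[sg == "LTR5Hs"] <- runif(45L, 1, 14)
  age[sg == "LTR5A"] <- runif(21L, 14, 26)
  age[sg == "LTR5B"] <- runif(23L, 20, 34)
  age[sg == "no_ltr"] <- runif(2L, 10, 25)
  cladeIdx <- which(sg == "LTR5A")[seq_len(nClade)] # 7-member duplication clade
  age[cladeIdx] <- 14                                # shared original integration
  tripletIdx <- cladeIdx[1:3]

  ## type partition: all type 1 are LTR5Hs; 16 untypable (incl. the 2 LTR-less)
  type <- rep("type2", n)
  hs <- which(sg == "LTR5Hs")
  type[hs[1:20]] <- "type1"
  undet <- c(hs[21:25], setdiff(which(sg == "LTR5A"), cladeIdx)[1:5],
             which(sg == "LTR5B")[1:4], which(sg == "no_ltr"))
  type[undet] <- "undetermined"

  ## subgroup lineage ladders (clade members get one shared integration)
  rows <- vector("list", n)
  subgroupInternal <- lapply(stats::setNames(nm = c("LTR5Hs", "LTR5A", "LTR5B")),
                             function(s) .mutateSeq(internalTemplate, 0.015, config@kappa))
  for (s in c("LTR5Hs", "LTR5A", "LTR5B")) {
    members <- which(sg == s)
    members <- setdiff(members, setdiff(cladeIdx, cladeIdx[1L]))  # clade = one event
    stemLtr <- ancM[s, ]; stemInt <- subgroupInternal[[s]]
    tPrev <- config@ageRange[2L]
    for (i in members[order(-age[members])]) {
      dt <- max(0, tPrev - age[i])
      stemLtr <- .mutateSeq(stemLtr, dt * config@lineageRate / 100, config@kappa)
      stemInt <- .mutateSeq(stemInt, dt * config@lineageRate / 100, config@kappa)
      tPrev <- age[i]
      rows[[i]] <- simulateProvirus(stemLtr, stemInt, age[i], config,
                                    type1 = type[i] == "type1",
                                    deletionWindow = delWindowInternal)
    }
  }
  ## spread the duplication clade from its single integrated ancestor:
  ## whole-provirus copies with private branch divergence (triplet recent)
  cladeAnc <- rows[[cladeIdx[1L]]]
  tripletAnc <- lapply(cladeAnc, .mutateSeq, pSub = 0.019, kappa = config@kappa)
  for (k in seq_along(cladeIdx)) {
    i <- cladeIdx[k]
    src <- if (i %in% tripletIdx) tripletAnc else cladeAnc
    p <- if (i %in% tripletIdx) 2e-4 else 0.0235
    rows[[i]] <- list(ltr5 = .mutateSeq(src$ltr5, p, config@kappa),
                      internal = .mutateSeq(src$internal, p, config@kappa),
                      ltr3 = .mutateSeq(src$ltr3, p, config@kappa),
                      trueAge = age[i])
  }
  ## the two LTR-less elements: internal only, from the 5Hs stem
  for (i in which(sg == "no_ltr")) {
    pr <- simulateProvirus(ancM["LTR5Hs", ], subgroupInternal[["LTR5Hs"]],
                           age[i], config)
    pr$ltr5[] <- "-"; pr$ltr3[] <- "-"
    rows[[i]] <- pr
  }
  ## untypable elements: large deletion spanning the window and both flanks
  bigDel <- seq(max(1L, min(delWindowInternal) - 900L),
                min(I, max(delWindowInternal) + 900L))
  for (i in undet) rows[[i]]$internal[bigDel] <- "-"

  ## three conversion events among independently evolving two-LTR
  ## proviruses, donor and recipient in the same subgroup with an age gap of
  ## at least 5 Myr; each event leaves BOTH partners with non-paired LTRs
  ## (the donor's 3' LTR now has a near-identical twin in the recipient), so
  ## six proviruses in total carry the recombination signature
  eligible <- setdiff(seq_len(n), c(cladeIdx, which(sg == "no_ltr")))
  conv <- rep(FALSE, n); donor <- rep(NA_character_, n)
  involved <- rep(FALSE, n)
  for (s in c("LTR5Hs", "LTR5A", "LTR5B")) {
    members <- intersect(eligible, which(sg == s))
    d <- members[which.max(age[members])]          # oldest member donates
    rCand <- setdiff(members[age[members] <= age[d] - 5], d)
    r <- if (length(rCand)) sample(rCand, 1L) else setdiff(members, d)[1L]
    tau <- runif(1, 0, 0.5)                         # recent conversion (Myr)
    rows[[r]]$ltr3 <- .mutateSeq(rows[[d]]$ltr3, tau * config@divergenceRate / 100,
                                 config@kappa)
    conv[r] <- TRUE; donor[r] <- sprintf("RP%02d", d)
    involved[c(r, d)] <- TRUE
  }

  ids <- sprintf("RP%02d", seq_len(n))
  refRow <- paste(c(ancM["LTR5Hs", ], internalTemplate, ancM["LTR5Hs", ]),
                  collapse = "")
  seqs <- c(stats::setNames(
    vapply(rows, function(r) paste(c(r$ltr5, r$internal, r$ltr3), collapse = ""),
           character(1)), ids), frame_ref = refRow)
  truth <- data.frame(element_id = ids, subgroup = sg, true_age = age,
                      type = type, conversion = conv, donor = donor,
                      conversion_involved = involved,
                      duplication_cluster = seq_len(n) %in% cladeIdx,
                      triplet = seq_len(n) %in% tripletIdx,
                      pairing_eligible = seq_len(n) %in% eligible,
                      stringsAsFactors = FALSE)
  list(alignment = ErvAlignment(seqs, reference = "frame_ref"),
       frame = frame, truth = truth, config = config)
}
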