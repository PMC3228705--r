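#' SubgroupDiagnostics: diagnostic indel columns for LTR subgroup calls
#'
#' The three HML-2 LTR subgroups are distinguished by short insertions at
#' fixed alignment columns: a 4-bp insertion carried by most LTR5Hs elements,
#' an insertion shared by essentially all LTR5A and LTR5B elements (and by
#' none of LTR5Hs), and insertions unique to LTR5A. In the provirus-alignment
#' frame the canonical positions are 585/10718 (5Hs), 806/10957 (5A+5B) and
#' 182/10317 (5A); in a single-LTR (solo-consensus) frame the published
#' anchors are 461 (5Hs) and 135 (5A).
#'
#' @slot frame `"provirus_alignment"` or `"solo_consensus"`.
#' @slot hsCols Columns of the LTR5Hs-associated insertion (supporting
#'   evidence only; it is present in only >80% of 5Hs).
#' @slot abCols Columns of the LTR5A/B-shared insertion (primary
#'   discriminator vs 5Hs).
#' @slot aCols Columns of the LTR5A-unique insertion.
#' @exportClass SubgroupDiagnostics
setClass("SubgroupDiagnostics",
  slots = c(frame = "character", hsCols = "integer", abCols = "integer",
            aCols = "integer"))

setValidity("SubgroupDiagnostics", function(object) {
  if (!object@frame %in% c("provirus_alignment", "solo_consensus")) {
    return("frame must be 'provirus_alignment' or 'solo_consensus'")
  }
  if (any(c(object@hsCols, object@abCols, object@aCols) < 1L)) {
    return("diagnostic columns must be positive")
  }
  TRUE
})

#' Construct SubgroupDiagnostics
#'
#' Defaults are the published provirus-frame positions, each expanded to the
#' 4-column insertion width.
#'
#' @param frame Coordinate frame the columns refer to.
#' @param hsCols,abCols,aCols Integer column vectors (all copies of each
#'   insertion, e.g. both the 5'-LTR and 3'-LTR instances in a provirus
#'   frame).
#' @param insertionWidth Width (columns) to expand single anchor positions
#'   by, default 4.
#' @return A [SubgroupDiagnostics-class].
#' @export
subgroupDiagnostics <- function(frame = "provirus_alignment",
                                hsCols = c(585L, 10718L),
                                abCols = c(806L, 10957L),
                                aCols = c(182L, 10317L),
                                insertionWidth = 4L) {
  expand <- function(anchors) {
    as.integer(unlist(lapply(anchors, function(a) seq(a, a + insertionWidth - 1L))))
  }
  new("SubgroupDiagnostics", frame = frame, hsCols = expand(hsCols),
      abCols = expand(abCols), aCols = expand(aCols))
}

setMethod("show", "SubgroupDiagnostics", function(object) {
  cat(sprintf("SubgroupDiagnostics (%s frame): hs[%s] ab[%s] a[%s]\n",
              object@frame, paste(range(object@hsCols), collapse = "-"),
              paste(range(object@abCols), collapse = "-"),
              paste(range(object@aCols), collapse = "-")))
})

## presence of an insertion: fraction of its columns carrying a base
.insertionPresent <- function(row, cols, minFraction = 0.5) {
  cols <- cols[cols <= length(row)]
  if (!length(cols)) return(NA)
  mean(.isBase(row[cols])) >= minFraction
}

## is the row actually sequenced/aligned around the diagnostic columns?
.coveredAround <- function(row, cols, flank = 30L, minBases = 0.5) {
  cols <- cols[cols <= length(row)]
  if (!length(cols)) return(FALSE)
  lo <- max(1L, min(cols) - flank); hi <- min(length(row), max(cols) + flank)
  nb <- setdiff(seq(lo, hi), cols)
  length(nb) > 0 && mean(.isBase(row[nb])) >= minBases
}

#' Assign an LTR row to an LTR subgroup by diagnostic indels
#'
#' Decision rule: if the LTR5A/B-shared insertion is present, the row is
#' LTR5A when the 5A-unique insertion is also present and LTR5B otherwise;
#' if the shared insertion is absent, the row is LTR5Hs. Presence of the
#' 5Hs-associated insertion is recorded as supporting evidence only. A row
#' with no aligned sequence around the diagnostic columns is
#' `"undetermined"`.
#'
#' @param row Aligned LTR row (string or character vector) in the frame of
#'   `diag`.
#' @param diag A [SubgroupDiagnostics-class].
#' @return A list: `subgroup` (`"LTR5Hs"`, `"LTR5A"`, `"LTR5B"` or
#'   `"undetermined"`), and evidence flags `hsPresent`, `abPresent`,
#'   `aPresent`, `covered`.
#' @export
classifySubgroup <- function(row, diag) {
  row <- toupper(.splitRow(row))
  covered <- .coveredAround(row, diag@abCols) || .coveredAround(row, diag@aCols)
  if (!covered) {
    return(list(subgroup = "undetermined", hsPresent = NA, abPresent = NA,
                aPresent = NA, covered = FALSE))
  }
  ab <- isTRUE(.insertionPresent(row, diag@abCols))
  aa <- isTRUE(.insertionPresent(row, diag@aCols))
  hs <- isTRUE(.insertionPresent(row, diag@hsCols))
  subgroup <- if (ab) { if (aa) "LTR5A" else "LTR5B" } else "LTR5Hs"
  list(subgroup = subgroup, hsPresent = hs, abPresent = ab, aPresent = aa,
       covered = TRUE)
}

#' Classify a provirus as type 1 or type 2 by the 292-bp pol-env deletion
#'
#' Type 1 proviruses carry a 292-bp deletion at the pol-env junction; type 2
#' proviruses do not. The call inspects the configured deletion window in the
#' alignment: type 1 when at least `gapHigh` of the window columns are gapped
#' while both 100-column flanks retain sequence (at least `flankMin` bases),
#' type 2 when at most `gapLow` of the window is gapped, and undetermined
#' otherwise — in particular for larger deletions spanning the window and its
#' flanks, which cannot be typed by this feature.
#'
#' @param x An [ErvAlignment-class].
#' @param element Row name of the provirus to classify.
#' @param window `c(start_col, end_col)` of the deletion window (1-based
#'   inclusive alignment columns); see [findDeletionWindow()].
#' @param gapHigh,gapLow Gap-fraction thresholds for type 1 / type 2
#'   (defaults 0.9 / 0.1).
#' @param flankSize,flankMin Flank width (columns) and minimum base fraction
#'   required for intact flanks (defaults 100 / 0.5).
#' @return A list: `call` (`"type1"|"type2"|"undetermined"`), `element_id`,
#'   `window`, `fractionDeleted`, `flanksIntact`.
#' @export
classifyType <- function(x, element, window, gapHigh = 0.9, gapLow = 0.1,
                         flankSize = 100L, flankMin = 0.5) {
  row <- .splitRow(alignmentRow(x, element))
  w <- seq(window[1L], window[2L])
  if (window[1L] < 1L || window[2L] > length(row)) stop("window outside alignment")
  fracDeleted <- mean(!.isBase(row[w]))
  leftF <- if (window[1L] > 1L) seq(max(1L, window[1L] - flankSize), window[1L] - 1L) else integer(0)
  rightF <- if (window[2L] < length(row)) seq(window[2L] + 1L, min(length(row), window[2L] + flankSize)) else integer(0)
  flanksIntact <- length(leftF) > 0 && length(rightF) > 0 &&
    mean(.isBase(row[leftF])) >= flankMin && mean(.isBase(row[rightF])) >= flankMin
  call <- if (fracDeleted >= gapHigh && flanksIntact) "type1"
          else if (fracDeleted <= gapLow) "type2"
          else "undetermined"
  list(element_id = element, call = call, window = as.integer(window),
       fractionDeleted = fracDeleted, flanksIntact = flanksIntact)
}

#' Locate the 292-bp deletion window from known type-1 proviruses
#'
#' The deletion window is not a published alignment coordinate; it can be
#' recovered from the data as the longest run of columns gapped in all the
#' supplied known type-1 rows while the reference row carries bases.
#'
#' @param x An [ErvAlignment-class].
#' @param type1Elements Row names of known type-1 proviruses.
#' @return `c(start_col, end_col)`.
#' @export
findDeletionWindow <- function(x, type1Elements) {
  m <- as.matrix(x)
  ref <- m[referenceName(x), ]
  sub <- m[type1Elements, , drop = FALSE]
  gapAll <- colSums(sub == "-") == nrow(sub)
  cand <- gapAll & .isBase(ref)
  r <- rle(cand)
  if (!any(r$values)) stop("no shared gap block found among supplied type-1 rows")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)[which.max(r$lengths[r$values])]
  c(starts[k], ends[k])
}

#' Call intact ORFs per gene region
#'
#' For each region, the element's slice is degapped and all three forward
#' reading frames are scanned for the longest stop-codon-free stretch. A gene
#' is called intact when that stretch reaches `intactThreshold` of the
#' degapped reference (e.g. K113) length for the region. No splice-aware
#' logic is applied.
#'
#' @param x An [ErvAlignment-class].
#' @param element Row name.
#' @param regions Region map, default [geneRegionMap()].
#' @param intactThreshold Fraction of the reference gene length required
#'   (default 0.95).
#' @return data.frame with columns `element_id`, `gene`, `intact`,
#'   `longest_orf_fraction`.
#' @export
callOrfs <- function(x, element, regions = geneRegionMap(), intactThreshold = 0.95) {
  row <- alignmentRow(x, element)
  ref <- alignmentRow(x, referenceName(x))
  res <- lapply(names(regions), function(g) {
    cols <- regions[[g]]
    slice <- substr(row, cols[1L], cols[2L])
    refSlice <- substr(ref, cols[1L], cols[2L])
    seqD <- gsub("[^ACGT]", "", toupper(slice))
    refD <- gsub("[^ACGT]", "", toupper(refSlice))
    refLen <- nchar(refD)
    longest <- if (nchar(seqD) >= 3L) max(vapply(0:2, function(f) .longestOrf(seqD, f), numeric(1))) else 0
    frac <- if (refLen > 0) longest / refLen else 0
    data.frame(element_id = element, gene = g,
               intact = frac >= intactThreshold,
               longest_orf_fraction = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## longest stop-free stretch (nt) in one forward frame
.longestOrf <- function(seq, frame) {
  n <- nchar(seq)
  starts <- seq(1L + frame, n - 2L, by = 3L)
  if (!length(starts)) return(0)
  codons <- substring(seq, starts, starts + 2L)
  isStop <- codons %in% c("TAA", "TAG", "TGA")
  r <- rle(!isStop)
  if (!any(r$values)) return(0)
  3 * max(r$lengths[r$values])
}
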