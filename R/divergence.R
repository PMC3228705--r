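#' Count substitutions between two aligned rows
#'
#' Applies the LTR-dating divergence convention: columns where both rows carry
#' a base are compared per column (a mismatch scores one substitution), and
#' each maximal run of gap-vs-base columns (an insertion/deletion event) is
#' scored as a single substitution and contributes a single unit to the
#' comparable length, regardless of run length. Columns where both rows are
#' gapped, or where either row is N, are skipped entirely (and terminate indel
#' runs). With `indelMode = "strict"`, indel runs of 1-2 columns are instead
#' counted per column; runs longer than 2 remain single events.
#'
#' @param a,b Aligned rows of equal length: single strings or character
#'   vectors over A/C/G/T/N/-. Case-insensitive.
#' @param indelMode `"event"` (default: every maximal indel run is one event)
#'   or `"strict"` (runs of 1-2 columns counted per column).
#' @return A list of class `DivergenceCount` with components `S`
#'   (substitutions), `L` (comparable length), `p` (`S/L`), `indelEvents`,
#'   `comparedBases` (base-vs-base columns), `transitions` and
#'   `transversions` (among mismatching base columns).
#' @examples
#' countDivergence("ACGT-A", "ACGTTA")  # S = 1 (one indel event), L = 6
#' @export
countDivergence <- function(a, b, indelMode = c("event", "strict")) {
  indelMode <- match.arg(indelMode)
  a <- toupper(.splitRow(a)); b <- toupper(.splitRow(b))
  if (length(a) != length(b)) stop("rows must have equal length")
  baseA <- .isBase(a); baseB <- .isBase(b)
  gapA <- a == "-"; gapB <- b == "-"
  skip <- (!baseA & !gapA) | (!baseB & !gapB)   # N or other ambiguity
  both <- baseA & baseB & !skip
  mism <- both & (a != b)
  comparedBases <- sum(both)
  transitions <- sum(mism & .isTransition(a, b))
  transversions <- sum(mism) - transitions

  ## indel state: 1 = base in a over gap in b, 2 = gap in a over base in b;
  ## 0 (match columns, double gaps, ambiguity) terminates a run
  state <- integer(length(a))
  state[baseA & gapB & !skip] <- 1L
  state[baseB & gapA & !skip] <- 2L
  r <- rle(state)
  runLens <- r$lengths[r$values != 0L]

  if (indelMode == "event") {
    indelS <- length(runLens)
    indelL <- length(runLens)
  } else {
    short <- runLens[runLens <= 2L]
    long <- runLens[runLens > 2L]
    indelS <- sum(short) + length(long)
    indelL <- sum(short) + length(long)
  }
  S <- sum(mism) + indelS
  L <- comparedBases + indelL
  if (comparedBases == 0L) stop("empty overlap: no base-vs-base columns between rows")
  structure(list(S = S, L = L, p = S / L, indelEvents = length(runLens),
                 comparedBases = comparedBases,
                 transitions = transitions, transversions = transversions),
            class = "DivergenceCount")
}

#' @export
print.DivergenceCount <- function(x, ...) {
  cat(sprintf("DivergenceCount: S=%d L=%d p=%.5f (indel events: %d)\n",
              x$S, x$L, x$p, x$indelEvents))
  invisible(x)
}

#' Percent identity between two aligned rows
#'
#' 100 x (matching base columns) / (base-vs-base columns); indel and
#' ambiguous columns are excluded from both numerator and denominator.
#'
#' @inheritParams countDivergence
#' @return Percentage in `[0, 100]`.
#' @export
pairwiseIdentity <- function(a, b) {
  a <- toupper(.splitRow(a)); b <- toupper(.splitRow(b))
  if (length(a) != length(b)) stop("rows must have equal length")
  both <- .isBase(a) & .isBase(b)
  if (!any(both)) stop("empty overlap: no base-vs-base columns")
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Build a strict-majority consensus row
#'
#' Per column, the most frequent symbol among A/C/G/T/- over the selected
#' members (N and other ambiguity codes cast no vote). Ties are broken
#' deterministically: any base beats `-`, and tied bases resolve
#' alphabetically. Columns with no countable symbol emit `N`.
#'
#' @param x An [ErvAlignment-class] (or character matrix of rows x columns).
#' @param members Row names (or indices) to include; default all rows.
#' @return A single consensus string of the alignment width.
#' @export
buildConsensus <- function(x, members = NULL) {
  m <- if (is.matrix(x)) x else as.matrix(x)
  if (!is.null(members)) {
    m <- m[members, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty member set")
  m[!(m %in% c(BASES, "-"))] <- NA_character_
  symbols <- c(BASES, "-")
  counts <- vapply(symbols, function(s) colSums(m == s, na.rm = TRUE),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, symbols))
  ## ties: bases beat '-', alphabetical among bases — achieved by a strictly
  ## decreasing epsilon preference in column order A,C,G,T,-
  pref <- matrix(rep(c(4, 3, 2, 1, 0) * 1e-9, each = nrow(counts)), nrow = nrow(counts))
  winner <- symbols[max.col(counts + pref, ties.method = "first")]
  winner[rowSums(counts) == 0] <- "N"
  paste(winner, collapse = "")
}

#' Model-corrected distance of a row to a consensus (or any partner row)
#'
#' Computes the raw divergence proportion with [countDivergence()] and applies
#' the requested multiple-hit correction. Jukes-Cantor uses the full raw
#' proportion (indel events included, as in the divergence count); the Kimura
#' 2-parameter correction is a base-substitution concept, so its transition
#' (P) and transversion (Q) proportions are taken over base-vs-base columns
#' only.
#'
#' @inheritParams countDivergence
#' @param model `"raw"`, `"JC"` or `"K2P"`.
#' @param kappa Transition/transversion rate ratio; carried as metadata only
#'   (the K2P distance estimates P and Q from the data).
#' @return Distance in substitutions/site.
#' @examples
#' consensusDistance("ACGT", "ACGT", model = "JC")  # 0
#' @export
consensusDistance <- function(a, b, model = c("raw", "JC", "K2P"), kappa = 2) {
  model <- match.arg(model)
  dv <- countDivergence(a, b)
  switch(model,
    raw = dv$p,
    JC = {
      if (dv$p >= 0.75) stop("saturated: JC distance undefined for p >= 0.75")
      -0.75 * log(1 - 4 * dv$p / 3)
    },
    K2P = {
      if (dv$comparedBases == 0L) stop("empty overlap: no base-vs-base columns")
      P <- dv$transitions / dv$comparedBases
      Q <- dv$transversions / dv$comparedBases
      if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) {
        stop("saturated: K2P log arguments non-positive")
      }
      -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    })
}
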