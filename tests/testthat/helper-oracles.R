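## Independent brute-force oracles used across the suite. These deliberately
## re-derive the quantities with per-column state machines / exhaustive
## enumeration, independent of the package's vectorized implementations.

## per-column interpreter of the divergence-counting rules: base-vs-base
## columns compared singly; each maximal gap-vs-base run is one substitution
## and one unit of length; double gaps and ambiguity columns are skipped and
## terminate runs
oracleDivergence <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  isb <- function(x) x %in% c("A", "C", "G", "T")
  S <- 0L; L <- 0L; events <- 0L
  state <- "none"
  for (i in seq_along(a)) {
    ca <- a[i]; cb <- b[i]
    if ((!isb(ca) && ca != "-") || (!isb(cb) && cb != "-")) { state <- "none"; next }
    if (isb(ca) && isb(cb)) {
      L <- L + 1L; if (ca != cb) S <- S + 1L
      state <- "none"
    } else if (isb(ca) && cb == "-") {
      if (state != "a") { S <- S + 1L; L <- L + 1L; events <- events + 1L }
      state <- "a"
    } else if (isb(cb) && ca == "-") {
      if (state != "b") { S <- S + 1L; L <- L + 1L; events <- events + 1L }
      state <- "b"
    } else {
      state <- "none"   # both gapped
    }
  }
  list(S = S, L = L, p = S / L, events = events)
}

## random aligned pair over A/C/G/T/N/- with controllable gap and N rates
randomAlignedPair <- function(len, gapRate = 0.08, nRate = 0.02) {
  draw <- function() {
    sample(c("A", "C", "G", "T", "-", "N"), len, replace = TRUE,
           prob = c(rep((1 - gapRate - nRate) / 4, 4), gapRate, nRate))
  }
  list(a = paste(draw(), collapse = ""), b = paste(draw(), collapse = ""))
}

## exhaustive interval checker for the gene-proximity summary
oracleProximity <- function(el, genes, window) {
  ov <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1
  nW <- 0L; nI <- 0L; nA <- 0L
  for (i in seq_len(nrow(el))) {
    g <- genes[genes$chrom == el$chrom[i], , drop = FALSE]
    within <- FALSE; inside <- FALSE; host <- NA_integer_; bestOv <- -1
    for (j in seq_len(nrow(g))) {
      if (ov(el$start[i], el$end[i], g$start[j] - window, g$end[j] + window)) within <- TRUE
      if (el$start[i] >= g$start[j] && el$end[i] <= g$end[j]) {
        inside <- TRUE
        o <- min(el$end[i], g$end[j]) - max(el$start[i], g$start[j]) + 1
        if (o > bestOv) { bestOv <- o; host <- j }
      }
    }
    if (within) nW <- nW + 1L
    if (inside) {
      nI <- nI + 1L
      if (el$strand[i] != g$strand[host]) nA <- nA + 1L
    }
  }
  list(nWithinWindow = nW, nIntronic = nI, nIntronicAntisense = nA)
}

## literal application of the two provirus-calling rules to a chain table
## (used to hand-verify calling fixtures)
oracleProvirusCount <- function(chains) {
  sum(vapply(chains, function(ch) {
    ltr <- ch$ltr; fr <- ch$frac
    (ltr >= 1 && length(fr) >= 1) || (ltr == 0 && sum(fr > 0.5) >= 2)
  }, logical(1)))
}
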