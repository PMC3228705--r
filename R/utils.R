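#' @importFrom methods new validObject is slot
#' @importFrom stats qt rbinom rnbinom runif rpois pchisq logLik predict coef setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

## accept a single string or an already-split character vector
.splitRow <- function(r) {
  if (is.character(r) && length(r) == 1L && nchar(r) > 1L) {
    strsplit(r, "", fixed = TRUE)[[1L]]
  } else {
    as.character(r)
  }
}

.isBase <- function(x) x %in% BASES

## purines/pyrimidines for the transition/transversion split
PURINES <- c("A", "G")

.isTransition <- function(a, b) {
  (a %in% PURINES) == (b %in% PURINES)
}
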