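#' ErvCatalog: a catalog of called ERV elements
#'
#' Holds proviruses and solo LTRs as a [GenomicRanges::GRanges] (1-based
#' inclusive, the UCSC browser display convention used for all user-facing
#' coordinates) with per-element metadata: `element_id`, `kind`
#' (`"provirus"` or `"solo_ltr"`), optional component sub-intervals
#' (`ltr5_start`/`ltr5_end`, `internal_start`/`internal_end`,
#' `ltr3_start`/`ltr3_end`; `NA` where absent) and `provenance` (comma-joined
#' ids of the contributing repeat hits).
#'
#' @slot elements A `GRanges` with the metadata columns above.
#' @exportClass ErvCatalog
setClass("ErvCatalog", slots = c(elements = "GRanges"))

.CATALOG_MCOLS <- c("element_id", "kind", "ltr5_start", "ltr5_end",
                    "internal_start", "internal_end", "ltr3_start",
                    "ltr3_end", "provenance")

setValidity("ErvCatalog", function(object) {
  gr <- object@elements
  mc <- S4Vectors::mcols(gr)
  miss <- setdiff(.CATALOG_MCOLS, colnames(mc))
  if (length(miss)) return(sprintf("missing metadata columns: %s", paste(miss, collapse = ",")))
  if (length(gr) == 0L) return(TRUE)
  if (anyDuplicated(mc$element_id)) return("element_id values must be unique")
  if (!all(mc$kind %in% c("provirus", "solo_ltr"))) {
    return("kind must be 'provirus' or 'solo_ltr'")
  }
  if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-"))) {
    return("strand must be + or -")
  }
  for (comp in c("ltr5", "internal", "ltr3")) {
    s <- mc[[paste0(comp, "_start")]]; e <- mc[[paste0(comp, "_end")]]
    ok <- is.na(s) | (s >= GenomicRanges::start(gr) & e <= GenomicRanges::end(gr) & s <= e)
    if (!all(ok)) return(sprintf("%s sub-interval outside element span", comp))
  }
  solo <- mc$kind == "solo_ltr"
  if (any(solo & !is.na(mc$internal_start))) {
    return("solo LTR elements must not carry an internal sub-interval")
  }
  TRUE
})

#' Construct an ErvCatalog
#'
#' @param elements A `GRanges` carrying the catalog metadata columns, or a
#'   data.frame with columns `element_id`, `kind`, `chrom`, `strand`,
#'   `start`, `end` and optional sub-interval columns.
#' @return An [ErvCatalog-class].
#' @export
ErvCatalog <- function(elements) {
  if (is.data.frame(elements)) {
    df <- elements
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    for (col in .CATALOG_MCOLS) {
      S4Vectors::mcols(gr)[[col]] <- if (col %in% names(df)) df[[col]] else {
        if (col %in% c("element_id", "kind", "provenance")) {
          rep(NA_character_, length(gr))
        } else rep(NA_integer_, length(gr))
      }
    }
    elements <- gr
  }
  new("ErvCatalog", elements = elements)
}

#' @describeIn ErvCatalog-class Number of elements.
#' @param x An ErvCatalog.
#' @export
setMethod("length", "ErvCatalog", function(x) length(x@elements))

#' Accessors for ErvCatalog
#' @param x An [ErvCatalog-class].
#' @name ErvCatalog-accessors
NULL

#' @rdname ErvCatalog-accessors
#' @export
elementRanges <- function(x) x@elements

#' @rdname ErvCatalog-accessors
#' @export
elementIds <- function(x) S4Vectors::mcols(x@elements)$element_id

#' @rdname ErvCatalog-accessors
#' @export
elementKind <- function(x) S4Vectors::mcols(x@elements)$kind

#' @rdname ErvCatalog-accessors
#' @param kind `"provirus"` or `"solo_ltr"`.
#' @export
subsetByKind <- function(x, kind) {
  new("ErvCatalog", elements = x@elements[elementKind(x) == kind])
}

setMethod("show", "ErvCatalog", function(object) {
  k <- elementKind(object)
  cat(sprintf("ErvCatalog: %d elements (%d proviruses, %d solo LTRs) on %d sequences\n",
              length(object), sum(k == "provirus"), sum(k == "solo_ltr"),
              length(unique(as.character(GenomicRanges::seqnames(object@elements))))))
})

#' Convert a catalog to a plain data.frame (1-based inclusive coordinates)
#' @param x An [ErvCatalog-class].
#' @param row.names,optional,... Ignored.
#' @export
setMethod("as.data.frame", "ErvCatalog", function(x, row.names = NULL, optional = FALSE, ...) {
  gr <- x@elements
  mc <- as.data.frame(S4Vectors::mcols(gr))
  data.frame(element_id = mc$element_id, kind = mc$kind,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             mc[setdiff(colnames(mc), c("element_id", "kind"))],
             stringsAsFactors = FALSE)
})
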