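#' ErvAlignment: a reference-keyed multiple sequence alignment
#'
#' Container for a columnar multiple alignment of proviral or LTR sequences,
#' keyed to a reference row (e.g. the K113 provirus) whose columns define the
#' coordinate frame used for region extraction, typing and diagnostic-indel
#' classification.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width gapped sequences
#'   over the alphabet A, C, G, T, N, `-`.
#' @slot reference Name of the coordinate-defining row; must be one of
#'   `names(seqs)`.
#'
#' @exportClass ErvAlignment
setClass("ErvAlignment",
  slots = c(seqs = "DNAStringSet", reference = "character")
)

setValidity("ErvAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == "")) {
    return("all rows must be named")
  }
  if (anyDuplicated(names(s))) return("row names must be unique")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) return("all rows must have equal width")
  if (length(object@reference) != 1L || !(object@reference %in% names(s))) {
    return("'reference' must name exactly one row of the alignment")
  }
  freq <- Biostrings::alphabetFrequency(s, collapse = TRUE)
  allowed <- c("A", "C", "G", "T", "N", "-")
  bad <- freq[setdiff(names(freq), allowed)]
  if (sum(bad) > 0L) {
    return(sprintf("alignment contains disallowed letters: %s",
                   paste(names(bad)[bad > 0], collapse = ",")))
  }
  TRUE
})

#' Construct an ErvAlignment
#'
#' @param seqs A named character vector or [Biostrings::DNAStringSet] of
#'   equal-length gapped sequences (case-insensitive; lowercase soft-masked
#'   bases are uppercased on entry).
#' @param reference Name of the reference row.
#' @return An [ErvAlignment-class] object.
#' @examples
#' aln <- ErvAlignment(c(K113 = "ACGT-A", x = "ACGTTA"), reference = "K113")
#' alignmentWidth(aln)
#' @export
ErvAlignment <- function(seqs, reference) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  } else if (!methods::is(seqs, "DNAStringSet")) {
    stop("'seqs' must be a named character vector or a DNAStringSet")
  }
  new("ErvAlignment", seqs = seqs, reference = as.character(reference))
}

#' Read an aligned FASTA file into an ErvAlignment
#'
#' Gap character is `-`; input is case-insensitive (UCSC-style soft-masked
#' lowercase bases are treated as bases). Letters outside A/C/G/T/N/- are
#' mapped to N.
#'
#' @param path Path to an aligned (equal-width) FASTA file.
#' @param reference Name of the reference row (default: first row).
#' @return An [ErvAlignment-class].
#' @export
readAlignedFasta <- function(path, reference = NULL) {
  raw <- Biostrings::readBStringSet(path)
  txt <- toupper(as.character(raw))
  txt <- gsub("[^ACGTN-]", "N", txt)
  names(txt) <- sub("\\s.*$", "", names(raw))
  ErvAlignment(txt, reference = reference %||% names(txt)[1L])
}

#' Write an ErvAlignment to aligned FASTA
#' @param x An [ErvAlignment-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeAlignedFasta <- function(x, path) {
  Biostrings::writeXStringSet(x@seqs, path)
  invisible(path)
}

#' @describeIn ErvAlignment-class Number of rows.
#' @param x An ErvAlignment.
#' @export
setMethod("length", "ErvAlignment", function(x) length(x@seqs))

#' Accessors for ErvAlignment
#'
#' `alignmentNames()` returns the row names, `referenceName()` the reference
#' row name, `alignmentWidth()` the common row width, and `alignmentRow()` a
#' single row as a plain character string.
#'
#' @param x An [ErvAlignment-class].
#' @name ErvAlignment-accessors
NULL

#' @rdname ErvAlignment-accessors
#' @export
alignmentNames <- function(x) names(x@seqs)

#' @rdname ErvAlignment-accessors
#' @export
referenceName <- function(x) x@reference

#' @rdname ErvAlignment-accessors
#' @export
alignmentWidth <- function(x) Biostrings::width(x@seqs)[1L]

#' @rdname ErvAlignment-accessors
#' @param name Row name.
#' @export
alignmentRow <- function(x, name) {
  if (!name %in% names(x@seqs)) stop(sprintf("row '%s' not in alignment", name))
  as.character(x@seqs[[name]])
}

#' @describeIn ErvAlignment-class Subset rows by name or index, keeping the
#'   reference frame (the reference row is retained if dropped implicitly).
#' @param i Row names or indices.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "ErvAlignment", function(x, i, j, ..., drop = FALSE) {
  keep <- names(x@seqs[i])
  if (!(x@reference %in% keep)) keep <- c(x@reference, keep)
  new("ErvAlignment", seqs = x@seqs[keep], reference = x@reference)
})

#' @describeIn ErvAlignment-class Character-matrix view (rows x columns).
#' @export
setMethod("as.matrix", "ErvAlignment", function(x) {
  m <- t(vapply(as.character(x@seqs), function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                character(alignmentWidth(x))))
  rownames(m) <- names(x@seqs)
  m
})

setMethod("show", "ErvAlignment", function(object) {
  cat(sprintf("ErvAlignment: %d sequences x %d columns (reference: %s)\n",
              length(object@seqs), alignmentWidth(object), object@reference))
  nm <- head(names(object@seqs), 5L)
  cat("  rows:", paste(nm, collapse = ", "),
      if (length(object@seqs) > 5L) "..." else "", "\n")
})

#' Default gene-region map for the K113-keyed provirus alignment frame
#'
#' Alignment-column spans (1-based inclusive) of the gag, pol and env
#' sub-regions used for phylogeny, ORF calls and recombination scanning.
#'
#' @return Named list of `c(start_col, end_col)` integer pairs.
#' @export
geneRegionMap <- function() {
  list(gag = c(1083L, 3168L), pol = c(5242L, 5899L), env = c(8296L, 9252L))
}

#' Extract a column region from an alignment
#'
#' @param x An [ErvAlignment-class].
#' @param region Region name looked up in `map` (e.g. `"gag"`), or `NULL` to
#'   use `cols`.
#' @param cols Explicit `c(start, end)` 1-based inclusive column range.
#' @param map Region map, default [geneRegionMap()].
#' @return An [ErvAlignment-class] restricted to the requested columns.
#' @examples
#' aln <- ErvAlignment(c(ref = "ACGTACGTAC"), "ref")
#' alignmentWidth(extractRegion(aln, cols = c(3, 7)))
#' @export
extractRegion <- function(x, region = NULL, cols = NULL, map = geneRegionMap()) {
  if (!is.null(region)) {
    if (!region %in% names(map)) stop(sprintf("unknown region '%s'", region))
    cols <- map[[region]]
  }
  if (is.null(cols) || length(cols) != 2L) stop("provide 'region' or cols = c(start, end)")
  w <- alignmentWidth(x)
  if (cols[1L] < 1L || cols[2L] > w || cols[1L] > cols[2L]) {
    stop(sprintf("column range [%d,%d] outside alignment width %d", cols[1L], cols[2L], w))
  }
  new("ErvAlignment",
      seqs = Biostrings::subseq(x@seqs, start = cols[1L], end = cols[2L]),
      reference = x@reference)
}
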