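#' Read a repeat-annotation file into a GRanges of repeat hits
#'
#' Supports the RepeatMasker `.out` dialect (whitespace-delimited, up to three
#' header lines, 1-based inclusive coordinates, `C` orientation meaning the
#' minus strand) and BED6 TSV (0-based half-open; converted to the 1-based
#' inclusive convention used throughout). Each hit receives a stable
#' `hit_id` (`hit_<input line>`); the RepeatMasker linking ID (final column)
#' is kept as `link_id` when present.
#'
#' @param path File path.
#' @param dialect `"repeatmasker_out"` or `"bed_tsv"`.
#' @return A [GenomicRanges::GRanges] with metadata columns `repeat_name`,
#'   `repeat_class`, `score`, `divergence`, `link_id`, `hit_id`.
#' @export
readRepeatAnnotation <- function(path, dialect = c("repeatmasker_out", "bed_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (dialect == "repeatmasker_out") {
    .parseRmOut(lines, path)
  } else {
    .parseBed(lines, path)
  }
}

.parseRmOut <- function(lines, path) {
  ## header: initial lines whose first token is not a number, plus blanks
  isData <- grepl("^\\s*\\d", lines)
  firstData <- which(isData)[1L]
  if (is.na(firstData)) firstData <- length(lines) + 1L
  hdr <- seq_len(firstData - 1L)
  dataIdx <- setdiff(seq_along(lines), hdr)
  dataIdx <- dataIdx[nzchar(trimws(lines[dataIdx]))]
  rows <- lapply(dataIdx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 11L || is.na(suppressWarnings(as.numeric(f[6L])))) {
      stop(sprintf("malformed RepeatMasker line %d in %s", i, path))
    }
    list(score = as.numeric(f[1L]), divergence = as.numeric(f[2L]),
         chrom = f[5L], start = as.integer(f[6L]), end = as.integer(f[7L]),
         strand = if (f[9L] %in% c("C", "-")) "-" else "+",
         repeat_name = f[10L], repeat_class = f[11L],
         link_id = if (length(f) >= 15L) f[15L] else NA_character_,
         line = i)
  })
  .hitsFromRows(rows)
}

.parseBed <- function(lines, path) {
  dataIdx <- which(nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines))
  rows <- lapply(dataIdx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L || is.na(suppressWarnings(as.integer(f[2L])))) {
      stop(sprintf("malformed BED line %d in %s", i, path))
    }
    list(score = suppressWarnings(as.numeric(f[5L])), divergence = NA_real_,
         chrom = f[1L], start = as.integer(f[2L]) + 1L, end = as.integer(f[3L]),
         strand = if (f[6L] == "-") "-" else "+",
         repeat_name = f[4L], repeat_class = NA_character_,
         link_id = NA_character_, line = i)
  })
  .hitsFromRows(rows)
}

.hitsFromRows <- function(rows) {
  if (length(rows) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      repeat_name = character(0), repeat_class = character(0),
      score = numeric(0), divergence = numeric(0),
      link_id = character(0), hit_id = character(0))
    return(gr)
  }
  g <- function(k) sapply(rows, `[[`, k)
  bad <- which(g("start") > g("end"))
  if (length(bad)) stop(sprintf("malformed interval (start > end) at line %d", rows[[bad[1L]]]$line))
  gr <- GenomicRanges::GRanges(g("chrom"),
                               IRanges::IRanges(as.integer(g("start")), as.integer(g("end"))),
                               strand = g("strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    repeat_name = as.character(g("repeat_name")),
    repeat_class = as.character(g("repeat_class")),
    score = as.numeric(g("score")), divergence = as.numeric(g("divergence")),
    link_id = as.character(g("link_id")),
    hit_id = paste0("hit_", g("line")))
  gr
}

#' Default HML-2 internal gene lengths (bp) for the >50%-of-a-gene test
#'
#' Approximate K113-style gene lengths used to decide whether an internal hit
#' covers more than a configured fraction of a full gene. Override to match a
#' different reference annotation.
#' @return Named numeric vector (gag, pro, pol, env).
#' @export
defaultGeneLengths <- function() {
  c(gag = 2100, pro = 900, pol = 2700, env = 2100)
}

.isLtrHit <- function(nm) grepl("^LTR", nm, ignore.case = TRUE)
.isInternalHit <- function(nm) {
  grepl("int", nm, ignore.case = TRUE) | tolower(nm) %in% c("gag", "pro", "pol", "env")
}

## fraction of a full gene covered by an internal hit: gene taken from the
## repeat name when it names one, otherwise the mean gene length is used as
## the yardstick for generic *-int hits
.geneFraction <- function(hits, geneLengths) {
  nm <- tolower(S4Vectors::mcols(hits)$repeat_name)
  len <- GenomicRanges::width(hits)
  ref <- ifelse(nm %in% names(geneLengths), geneLengths[nm], mean(geneLengths))
  as.numeric(len / ref)
}

## chain hits: same chrom + strand, gap <= maxGap; chains sharing a link_id
## are then merged (RepeatMasker links fragments of one element)
.chainHits <- function(hits, maxGap) {
  if (length(hits) == 0L) return(integer(0))
  o <- order(as.character(GenomicRanges::seqnames(hits)),
             as.character(GenomicRanges::strand(hits)),
             GenomicRanges::start(hits))
  chain <- integer(length(hits))
  cur <- 0L
  lastEnd <- -Inf
  lastKey <- ""
  for (i in o) {
    key <- paste(GenomicRanges::seqnames(hits)[i], GenomicRanges::strand(hits)[i])
    if (key != lastKey || GenomicRanges::start(hits)[i] - lastEnd - 1L > maxGap) {
      cur <- cur + 1L
      lastEnd <- -Inf
    }
    chain[i] <- cur
    lastKey <- key
    lastEnd <- max(lastEnd, GenomicRanges::end(hits)[i])
  }
  ## merge chains sharing a link id
  link <- S4Vectors::mcols(hits)$link_id
  if (!is.null(link) && any(!is.na(link))) {
    for (lid in unique(link[!is.na(link)])) {
      members <- unique(chain[which(link == lid)])
      if (length(members) > 1L) chain[chain %in% members] <- members[1L]
    }
  }
  chain
}

#' Call proviruses from repeat hits
#'
#' A chain of same-strand hits within `maxGap` of one another is called a
#' provirus when (a) it contains at least one LTR hit together with internal
#' coding sequence covering more than `minGeneFractionWithLtr` of a full gene
#' (default 0: any associated internal sequence suffices), or (b) it has no
#' LTR but two internal hits each covering more than `minGeneFraction` of
#' their gene. LTR hits flanking the internal block become the 5'/3' LTR
#' sub-intervals (assigned strand-aware: on the minus strand the genomic-right
#' LTR is the 5' LTR).
#'
#' @param hits GRanges of repeat hits from [readRepeatAnnotation()].
#' @param geneLengths Named vector of reference gene lengths, default
#'   [defaultGeneLengths()].
#' @param minGeneFraction Gene-coverage fraction required of each internal
#'   hit on the no-LTR path (default 0.5).
#' @param minGeneFractionWithLtr Gene-coverage fraction required of the
#'   internal hit on the LTR path (default 0).
#' @param maxGap Maximum gap (bp) linking adjacent hits into one element
#'   (default 1000).
#' @return An [ErvCatalog-class] of provirus elements.
#' @export
callProviruses <- function(hits, geneLengths = defaultGeneLengths(),
                           minGeneFraction = 0.5, minGeneFractionWithLtr = 0,
                           maxGap = 1000) {
  empty <- ErvCatalog(data.frame(element_id = character(0), kind = character(0),
                                 chrom = character(0), strand = character(0),
                                 start = integer(0), end = integer(0)))
  if (length(hits) == 0L) return(empty)
  nm <- S4Vectors::mcols(hits)$repeat_name
  isLtr <- .isLtrHit(nm); isInt <- .isInternalHit(nm)
  frac <- .geneFraction(hits, geneLengths)
  chain <- .chainHits(hits, maxGap)
  out <- list()
  counters <- list()
  chainStart <- tapply(GenomicRanges::start(hits), chain, min)
  chainChrom <- tapply(as.character(GenomicRanges::seqnames(hits)), chain, `[`, 1L)
  cids <- as.integer(names(chainStart))[order(chainChrom, chainStart)]
  for (cid in cids) {
    idx <- which(chain == cid)
    li <- idx[isLtr[idx]]; ii <- idx[isInt[idx]]
    hasLtrPath <- length(li) >= 1L && length(ii) >= 1L &&
      any(frac[ii] > minGeneFractionWithLtr)
    hasIntPath <- length(li) == 0L && sum(frac[ii] > minGeneFraction) >= 2L
    if (!hasLtrPath && !hasIntPath) next
    chrom <- as.character(GenomicRanges::seqnames(hits)[idx[1L]])
    strand <- as.character(GenomicRanges::strand(hits)[idx[1L]])
    s <- min(GenomicRanges::start(hits)[idx]); e <- max(GenomicRanges::end(hits)[idx])
    ## component intervals
    intS <- intE <- l5s <- l5e <- l3s <- l3e <- NA_integer_
    if (length(ii)) {
      intS <- min(GenomicRanges::start(hits)[ii]); intE <- max(GenomicRanges::end(hits)[ii])
    }
    if (length(li)) {
      left <- li[is.na(intS) | GenomicRanges::end(hits)[li] <= intS]
      right <- li[!is.na(intS) & GenomicRanges::start(hits)[li] >= intE]
      if (length(left)) { aS <- min(GenomicRanges::start(hits)[left]); aE <- max(GenomicRanges::end(hits)[left]) } else aS <- aE <- NA_integer_
      if (length(right)) { bS <- min(GenomicRanges::start(hits)[right]); bE <- max(GenomicRanges::end(hits)[right]) } else bS <- bE <- NA_integer_
      if (strand == "+") {
        l5s <- aS; l5e <- aE; l3s <- bS; l3e <- bE
      } else {
        l5s <- bS; l5e <- bE; l3s <- aS; l3e <- aE
      }
    }
    counters[[chrom]] <- (counters[[chrom]] %||% 0L) + 1L
    out[[length(out) + 1L]] <- data.frame(
      element_id = sprintf("%s_P%d", chrom, counters[[chrom]]),
      kind = "provirus", chrom = chrom, strand = strand, start = s, end = e,
      ltr5_start = l5s, ltr5_end = l5e, internal_start = intS,
      internal_end = intE, ltr3_start = l3s, ltr3_end = l3e,
      provenance = paste(S4Vectors::mcols(hits)$hit_id[idx], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  ErvCatalog(do.call(rbind, out))
}

#' Call solo LTRs from repeat hits
#'
#' LTR hits of at least `minLen` bp that are not provirus components and not
#' within `exclusionWindow` bp of a same-strand internal hit or same-strand
#' called provirus are returned as solo LTR elements. The 750-bp default
#' length cutoff keeps only near-full-length LTRs.
#'
#' @param hits GRanges of repeat hits.
#' @param proviruses An [ErvCatalog-class] from [callProviruses()] (may be
#'   empty).
#' @param minLen Minimum LTR length in bp (default 750).
#' @param exclusionWindow Distance (bp) to internal sequence/proviruses that
#'   disqualifies a candidate (default 1000).
#' @return An [ErvCatalog-class] of solo LTR elements.
#' @export
callSoloLtrs <- function(hits, proviruses = NULL, minLen = 750,
                         exclusionWindow = 1000) {
  empty <- ErvCatalog(data.frame(element_id = character(0), kind = character(0),
                                 chrom = character(0), strand = character(0),
                                 start = integer(0), end = integer(0)))
  if (length(hits) == 0L) return(empty)
  nm <- S4Vectors::mcols(hits)$repeat_name
  cand <- which(.isLtrHit(nm) & GenomicRanges::width(hits) >= minLen)
  if (!is.null(proviruses) && length(proviruses) > 0L) {
    used <- unlist(strsplit(S4Vectors::mcols(elementRanges(proviruses))$provenance, ","))
    cand <- cand[!(S4Vectors::mcols(hits)$hit_id[cand] %in% used)]
  }
  if (!length(cand)) return(empty)
  ## same-strand proximity to internal hits or called proviruses
  internal <- hits[.isInternalHit(nm)]
  blockers <- internal
  if (!is.null(proviruses) && length(proviruses) > 0L) {
    blockers <- c(GenomicRanges::granges(internal), GenomicRanges::granges(elementRanges(proviruses)))
  }
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    h <- hits[cand[k]]
    near <- GenomicRanges::findOverlaps(
      GenomicRanges::resize(GenomicRanges::granges(h),
                            GenomicRanges::width(h) + 2 * exclusionWindow, fix = "center"),
      blockers, ignore.strand = FALSE)
    keep[k] <- length(near) == 0L
  }
  cand <- cand[keep]
  if (!length(cand)) return(empty)
  counters <- list()
  rows <- lapply(cand, function(i) {
    chrom <- as.character(GenomicRanges::seqnames(hits)[i])
    counters[[chrom]] <<- (counters[[chrom]] %||% 0L) + 1L
    data.frame(element_id = sprintf("%s_S%d", chrom, counters[[chrom]]),
               kind = "solo_ltr", chrom = chrom,
               strand = as.character(GenomicRanges::strand(hits)[i]),
               start = GenomicRanges::start(hits)[i], end = GenomicRanges::end(hits)[i],
               ltr5_start = NA_integer_, ltr5_end = NA_integer_,
               internal_start = NA_integer_, internal_end = NA_integer_,
               ltr3_start = NA_integer_, ltr3_end = NA_integer_,
               provenance = S4Vectors::mcols(hits)$hit_id[i],
               stringsAsFactors = FALSE)
  })
  ErvCatalog(do.call(rbind, rows))
}

#' Write / read a catalog TSV (1-based inclusive coordinates)
#'
#' The TSV mirrors the published table layout: one row per element with
#' locus id, kind, chromosome, orientation, span, component sub-intervals
#' (rendered `start-end` or `.`) and provenance. `readCatalog()` inverts
#' `writeCatalog()` exactly.
#'
#' @param x An [ErvCatalog-class].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeCatalog <- function(x, path) {
  df <- as.data.frame(x)
  if (anyDuplicated(df$element_id)) stop("duplicate element_id in catalog")
  fmt <- function(s, e) ifelse(is.na(s), ".", paste0(s, "-", e))
  out <- data.frame(element_id = df$element_id, kind = df$kind, chrom = df$chrom,
                    strand = df$strand, start_1based = df$start, end_1based = df$end,
                    ltr5 = fmt(df$ltr5_start, df$ltr5_end),
                    internal = fmt(df$internal_start, df$internal_end),
                    ltr3 = fmt(df$ltr3_start, df$ltr3_end),
                    provenance = ifelse(is.na(df$provenance), ".", df$provenance),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(element_id = "character", kind = "character",
                                  chrom = "character", strand = "character",
                                  ltr5 = "character", internal = "character",
                                  ltr3 = "character", provenance = "character"))
  un <- function(col, part) {
    v <- rep(NA_integer_, nrow(df))
    ok <- df[[col]] != "."
    if (any(ok)) {
      sp <- strsplit(df[[col]][ok], "-", fixed = TRUE)
      v[ok] <- as.integer(vapply(sp, `[[`, "", part))
    }
    v
  }
  if (nrow(df) == 0L) {
    return(ErvCatalog(data.frame(element_id = character(0), kind = character(0),
                                 chrom = character(0), strand = character(0),
                                 start = integer(0), end = integer(0))))
  }
  ErvCatalog(data.frame(element_id = df$element_id, kind = df$kind,
                        chrom = df$chrom, strand = df$strand,
                        start = df$start_1based, end = df$end_1based,
                        ltr5_start = un("ltr5", 1L), ltr5_end = un("ltr5", 2L),
                        internal_start = un("internal", 1L), internal_end = un("internal", 2L),
                        ltr3_start = un("ltr3", 1L), ltr3_end = un("ltr3", 2L),
                        provenance = ifelse(df$provenance == ".", NA_character_, df$provenance),
                        stringsAsFactors = FALSE))
}
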