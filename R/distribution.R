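#' Per-chromosome element/gene/size summary table
#'
#' Builds the unit of the chromosomal-distribution regression: one row per
#' chromosome with its length, gene count and the number of proviruses and
#' solo LTRs from a catalog.
#'
#' @param catalog An [ErvCatalog-class].
#' @param genes GRanges of gene intervals (feature `"gene"` rows counted; if
#'   no `feature` column, every range counts as a gene).
#' @param chromSizes data.frame with columns `chrom`, `length` (or a named
#'   numeric vector).
#' @return data.frame with columns `chrom`, `length`, `n_genes`,
#'   `n_proviruses`, `n_solo_ltrs`.
#' @export
chromosomeSummary <- function(catalog, genes, chromSizes) {
  if (is.numeric(chromSizes)) {
    chromSizes <- data.frame(chrom = names(chromSizes), length = as.numeric(chromSizes))
  }
  feat <- S4Vectors::mcols(genes)$feature
  geneGr <- if (is.null(feat)) genes else genes[feat == "gene"]
  geneChrom <- as.character(GenomicRanges::seqnames(geneGr))
  df <- as.data.frame(catalog)
  out <- lapply(seq_len(nrow(chromSizes)), function(i) {
    ch <- chromSizes$chrom[i]
    data.frame(chrom = ch, length = chromSizes$length[i],
               n_genes = sum(geneChrom == ch),
               n_proviruses = sum(df$chrom == ch & df$kind == "provirus"),
               n_solo_ltrs = sum(df$chrom == ch & df$kind == "solo_ltr"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Negative-binomial regression of element counts on a chromosome feature
#'
#' Fits counts ~ predictor with a log link and NB error (variance
#' mu + alpha mu^2, dispersion estimated by maximum likelihood), plus the
#' intercept-only null model. The likelihood-ratio statistic is
#' -2 (logLik(null) - logLik(full)), referred to chi-square with 1 degree of
#' freedom. The 95% band on the mean prediction comes from the standard
#' error of the linear predictor (delta method on the link scale).
#'
#' @param summaries data.frame from [chromosomeSummary()] (>= 5 rows).
#' @param response,predictor Column names, e.g. `"n_solo_ltrs"` on
#'   `"n_genes"`.
#' @param level Band confidence level (default 0.95).
#' @return A list of class `RegressionResult`: `response`, `predictor`,
#'   `beta0`, `beta1`, `theta`, `alpha` (= 1/theta), `llFull`, `llNull`,
#'   `lrStat`, `pValue`, `band` (data.frame chrom/observed/fitted/lower/
#'   upper) and `model` (the underlying fit).
#' @export
fitNbRegression <- function(summaries, response, predictor, level = 0.95) {
  if (nrow(summaries) < 5L) stop("need at least 5 chromosomes")
  y <- summaries[[response]]; x <- summaries[[predictor]]
  if (all(y == 0)) stop("all-zero response")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  dat <- data.frame(y = y, x = x)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ x, data = dat, control = stats::glm.control(maxit = 100))),
    error = function(e) stop(sprintf("NB regression did not converge: %s", conditionMessage(e))))
  fit0 <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ 1, data = dat, control = stats::glm.control(maxit = 100))),
    error = function(e) stop(sprintf("null NB model did not converge: %s", conditionMessage(e))))
  llFull <- as.numeric(logLik(fit)); llNull <- as.numeric(logLik(fit0))
  lrStat <- -2 * (llNull - llFull)
  pValue <- pchisq(max(lrStat, 0), df = 1, lower.tail = FALSE)
  pr <- predict(fit, se.fit = TRUE, type = "link")
  z <- stats::qnorm(1 - (1 - level) / 2)
  band <- data.frame(chrom = summaries$chrom, observed = y, x = x,
                     fitted = exp(pr$fit),
                     lower = exp(pr$fit - z * pr$se.fit),
                     upper = exp(pr$fit + z * pr$se.fit),
                     stringsAsFactors = FALSE)
  structure(list(response = response, predictor = predictor,
                 beta0 = unname(coef(fit)[1L]), beta1 = unname(coef(fit)[2L]),
                 theta = fit$theta, alpha = 1 / fit$theta,
                 llFull = llFull, llNull = llNull,
                 lrStat = lrStat, pValue = pValue, band = band, model = fit),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("NB regression %s ~ %s: beta1=%.4f (LR=%.2f, p=%.3g, alpha=%.3f)\n",
              x$response, x$predictor, x$beta1, x$lrStat, x$pValue, x$alpha))
  invisible(x)
}

#' Flag chromosomes outside the 95% mean-prediction band
#'
#' @param result A `RegressionResult` from [fitNbRegression()].
#' @return data.frame with columns `chrom`, `direction` (`"over"`/
#'   `"under"`), `observed`, `fitted`.
#' @export
flagOutliers <- function(result) {
  b <- result$band
  over <- b$observed > b$upper
  under <- b$observed < b$lower
  out <- rbind(
    data.frame(chrom = b$chrom[over], direction = rep("over", sum(over)),
               observed = b$observed[over], fitted = b$fitted[over]),
    data.frame(chrom = b$chrom[under], direction = rep("under", sum(under)),
               observed = b$observed[under], fitted = b$fitted[under]))
  rownames(out) <- NULL
  out
}

#' Run the nine pairwise count regressions
#'
#' All ordered pairs among proviruses, solo LTRs and genes per chromosome,
#' plus each of the three counts on chromosome length — the panel layout of
#' the chromosomal-distribution analysis.
#'
#' @param summaries data.frame from [chromosomeSummary()].
#' @return data.frame, one row per response x predictor pair, with beta1,
#'   LR statistic, p-value and outlier count.
#' @export
fitAllNbRegressions <- function(summaries) {
  counts <- c("n_proviruses", "n_solo_ltrs", "n_genes")
  pairs <- rbind(
    expand.grid(response = counts, predictor = "length", stringsAsFactors = FALSE),
    expand.grid(response = counts, predictor = counts, stringsAsFactors = FALSE))
  pairs <- pairs[pairs$response != pairs$predictor, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- tryCatch(fitNbRegression(summaries, pairs$response[i], pairs$predictor[i]),
                  error = function(e) NULL)
    if (is.null(r)) {
      return(data.frame(response = pairs$response[i], predictor = pairs$predictor[i],
                        beta1 = NA_real_, lr_stat = NA_real_, p_value = NA_real_,
                        n_outliers = NA_integer_, stringsAsFactors = FALSE))
    }
    data.frame(response = r$response, predictor = r$predictor, beta1 = r$beta1,
               lr_stat = r$lrStat, p_value = r$pValue,
               n_outliers = nrow(flagOutliers(r)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-proximity and orientation summary for a catalog
#'
#' Counts elements overlapping a gene or within `window` bp of one, elements
#' lying inside genes (fully within a gene span and, when exon intervals are
#' supplied, overlapping no exon — i.e. intronic), and the antisense subset
#' of those (element strand opposite the host gene; the host is the
#' overlapping gene with the largest overlap, ties to the first).
#'
#' @param catalog An [ErvCatalog-class] (or GRanges).
#' @param genes GRanges with optional metadata column `feature` containing
#'   `"gene"` and optionally `"exon"` rows.
#' @param window Proximity window in bp (default 30000).
#' @return A list of class `ProximitySummary` with counts `nTotal`,
#'   `nWithinWindow`, `nIntronic`, `nIntronicAntisense` and the matching
#'   fractions.
#' @export
geneProximitySummary <- function(catalog, genes, window = 30000L) {
  el <- if (methods::is(catalog, "ErvCatalog")) elementRanges(catalog) else catalog
  feat <- S4Vectors::mcols(genes)$feature
  geneGr <- if (is.null(feat)) genes else genes[feat == "gene"]
  exonGr <- if (is.null(feat)) genes[integer(0)] else genes[feat == "exon"]
  nTotal <- length(el)
  if (nTotal == 0L) {
    return(structure(list(nTotal = 0L, nWithinWindow = 0L, nIntronic = 0L,
                          nIntronicAntisense = 0L, fracWithinWindow = NA_real_,
                          fracIntronic = NA_real_, fracAntisenseOfIntronic = NA_real_),
                     class = "ProximitySummary"))
  }
  expanded <- suppressWarnings(GenomicRanges::trim(geneGr + window))
  within <- IRanges::overlapsAny(el, expanded, ignore.strand = TRUE)
  insideHits <- GenomicRanges::findOverlaps(el, geneGr, type = "within",
                                            ignore.strand = TRUE)
  inside <- rep(FALSE, nTotal)
  hostGene <- rep(NA_integer_, nTotal)
  if (length(insideHits)) {
    qh <- S4Vectors::queryHits(insideHits); sh <- S4Vectors::subjectHits(insideHits)
    ov <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(el)[qh], IRanges::ranges(geneGr)[sh]))
    for (q in unique(qh)) {
      cand <- which(qh == q)
      hostGene[q] <- sh[cand[which.max(ov[cand])]]
      inside[q] <- TRUE
    }
  }
  if (length(exonGr)) {
    exonHit <- IRanges::overlapsAny(el, exonGr, ignore.strand = TRUE)
    intronic <- inside & !exonHit
  } else {
    intronic <- inside
  }
  anti <- intronic & !is.na(hostGene) &
    as.character(GenomicRanges::strand(el)) !=
      as.character(GenomicRanges::strand(geneGr))[hostGene]
  structure(list(nTotal = nTotal, nWithinWindow = sum(within),
                 nIntronic = sum(intronic), nIntronicAntisense = sum(anti),
                 fracWithinWindow = mean(within),
                 fracIntronic = mean(intronic),
                 fracAntisenseOfIntronic = if (sum(intronic)) sum(anti) / sum(intronic) else NA_real_),
            class = "ProximitySummary")
}

#' @export
print.ProximitySummary <- function(x, ...) {
  cat(sprintf("ProximitySummary: %d elements; %d (%.0f%%) in/near genes; %d (%.0f%%) intronic; %d (%.0f%%) of intronic antisense\n",
              x$nTotal, x$nWithinWindow, 100 * (x$fracWithinWindow %||% 0),
              x$nIntronic, 100 * (x$fracIntronic %||% 0),
              x$nIntronicAntisense,
              100 * (if (is.na(x$fracAntisenseOfIntronic)) 0 else x$fracAntisenseOfIntronic)))
  invisible(x)
}
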