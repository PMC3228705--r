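#' ClockParameters: molecular-clock settings for ERV age estimation
#'
#' Bounds on the neutral substitution rate used for paired-LTR dating
#' (0.24-0.45 percent divergence between cognate LTRs per million years), the
#' average rate used for solo-LTR consensus dating (0.34 %/Myr), the
#' young-provirus reporting cutoff (2 Myr), the transition/transversion
#' ratio kappa carried as metadata for K2P, and the calibration slope (with
#' its 95% CI) mapping consensus-distance ages onto the paired-LTR scale.
#'
#' @slot rateLow,rateHigh Paired-LTR rate bounds in %/Myr (0.24, 0.45).
#' @slot rateSolo Solo-LTR rate in %/Myr (0.34).
#' @slot youngCutoff Age (Myr) below which paired estimates are reported
#'   as "< 2" (2).
#' @slot kappa Transition/transversion rate ratio (2); used by the synthetic
#'   generator's substitution model, not by the K2P distance estimator.
#' @slot correctionSlope Through-origin calibration slope (1 before
#'   calibration).
#' @slot correctionSlopeCI Length-2 numeric: 95% CI slopes.
#' @exportClass ClockParameters
setClass("ClockParameters",
  slots = c(rateLow = "numeric", rateHigh = "numeric", rateSolo = "numeric",
            youngCutoff = "numeric", kappa = "numeric",
            correctionSlope = "numeric", correctionSlopeCI = "numeric"))

setValidity("ClockParameters", function(object) {
  if (!(object@rateLow < object@rateSolo && object@rateSolo < object@rateHigh)) {
    return("rates must satisfy rateLow < rateSolo < rateHigh")
  }
  if (object@kappa <= 0) return("kappa must be positive")
  if (object@correctionSlope <= 0) return("correctionSlope must be positive")
  if (length(object@correctionSlopeCI) != 2L) return("correctionSlopeCI must have length 2")
  TRUE
})

#' Construct ClockParameters
#' @param rateLow,rateHigh,rateSolo,youngCutoff,kappa,correctionSlope,correctionSlopeCI
#'   See [ClockParameters-class]; defaults are the published values.
#' @return A [ClockParameters-class].
#' @export
clockParameters <- function(rateLow = 0.24, rateHigh = 0.45, rateSolo = 0.34,
                            youngCutoff = 2, kappa = 2, correctionSlope = 1,
                            correctionSlopeCI = c(1, 1)) {
  new("ClockParameters", rateLow = rateLow, rateHigh = rateHigh,
      rateSolo = rateSolo, youngCutoff = youngCutoff, kappa = kappa,
      correctionSlope = correctionSlope, correctionSlopeCI = correctionSlopeCI)
}

setMethod("show", "ClockParameters", function(object) {
  cat(sprintf(paste0("ClockParameters: paired %.2f-%.2f %%/Myr, solo %.2f %%/Myr, ",
                     "young cutoff %g Myr, kappa %g, slope %.3f [%.3f, %.3f]\n"),
              object@rateLow, object@rateHigh, object@rateSolo,
              object@youngCutoff, object@kappa, object@correctionSlope,
              object@correctionSlopeCI[1L], object@correctionSlopeCI[2L]))
})

#' Estimate a provirus age from cognate-LTR divergence
#'
#' The two LTRs of a provirus are identical at integration, so their
#' divergence proportion p dates the insertion: dividing the percent
#' divergence by the fast rate bound gives the lower age bound and by the
#' slow bound the upper. Estimates whose lower bound falls below the young
#' cutoff are flagged for "< 2" reporting (the numeric estimates are
#' retained).
#'
#' @param div A `DivergenceCount` from [countDivergence()] on the cognate
#'   5'/3' LTR rows.
#' @param params A [ClockParameters-class].
#' @param elementId Optional element identifier carried through.
#' @return A list: `element_id`, `method = "paired_ltr"`, `ageLow`,
#'   `agePoint`, `ageHigh` (Myr), `youngFlag`, `p`.
#' @examples
#' dv <- countDivergence(strrep("A", 100), paste0(strrep("A", 99), "G"))
#' estimateProvirusAge(dv, clockParameters())
#' @export
estimateProvirusAge <- function(div, params = clockParameters(), elementId = NA_character_) {
  if (div$L == 0) stop("empty divergence count")
  pctPerMyrLow <- params@rateLow; pctPerMyrHigh <- params@rateHigh
  ageLow <- 100 * div$p / pctPerMyrHigh
  ageHigh <- 100 * div$p / pctPerMyrLow
  list(element_id = elementId, method = "paired_ltr",
       ageLow = ageLow, agePoint = (ageLow + ageHigh) / 2, ageHigh = ageHigh,
       youngFlag = ageLow < params@youngCutoff, p = div$p)
}

#' Calibrate the solo-LTR age correction factor
#'
#' Least-squares line through the origin of paired-LTR age (y) on
#' consensus-distance age (x) over proviruses datable by both methods:
#' slope = sum(xy)/sum(x^2). The 95% CI slopes come from the standard error
#' of the through-origin slope and are used downstream for the minimum and
#' maximum corrected ages.
#'
#' @param consensusAge Numeric vector of consensus-method ages (Myr).
#' @param pairedAge Numeric vector of paired-LTR ages (Myr), same length.
#' @param level Confidence level (default 0.95).
#' @return A list: `slope`, `ciLow`, `ciHigh`, `se`, `n`.
#' @examples
#' calibrateCorrectionFactor(c(1, 2, 5), c(1, 2, 5))$slope  # 1
#' @export
calibrateCorrectionFactor <- function(consensusAge, pairedAge, level = 0.95) {
  x <- as.numeric(consensusAge); y <- as.numeric(pairedAge)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 calibration pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("consensus ages are all zero")
  slope <- sum(x * y) / sxx
  resid <- y - slope * x
  se <- sqrt(sum(resid^2) / (n - 1L) / sxx)
  tq <- qt(1 - (1 - level) / 2, df = n - 1L)
  list(slope = slope, ciLow = slope - tq * se, ciHigh = slope + tq * se,
       se = se, n = n)
}

#' Apply a calibration to ClockParameters
#' @param params A [ClockParameters-class].
#' @param calibration Result of [calibrateCorrectionFactor()].
#' @return Updated [ClockParameters-class].
#' @export
applyCalibration <- function(params, calibration) {
  params@correctionSlope <- calibration$slope
  params@correctionSlopeCI <- c(calibration$ciLow, calibration$ciHigh)
  validObject(params)
  params
}

#' Estimate a solo-LTR (or single-LTR provirus) age from consensus distance
#'
#' The element's distance to its subgroup consensus is computed under both
#' the Jukes-Cantor and Kimura 2-parameter corrections; their mean is the
#' model distance. The age is the percent distance divided by the solo rate,
#' scaled by the calibration slope (CI slopes give the age bounds).
#'
#' @param row Aligned LTR row.
#' @param consensus Aligned subgroup consensus row (same frame).
#' @param params A [ClockParameters-class] (calibrated or with slope 1).
#' @param elementId Optional identifier.
#' @return A list: `element_id`, `method = "solo_consensus"`, `ageLow`,
#'   `agePoint`, `ageHigh`, `youngFlag`, `dRaw`, `dJC`, `dK2P`, `dAvg`.
#' @export
estimateSoloAge <- function(row, consensus, params = clockParameters(),
                            elementId = NA_character_) {
  dRaw <- consensusDistance(row, consensus, model = "raw")
  dJC <- consensusDistance(row, consensus, model = "JC")
  dK2P <- consensusDistance(row, consensus, model = "K2P", kappa = params@kappa)
  dAvg <- (dJC + dK2P) / 2
  base <- 100 * dAvg / params@rateSolo
  agePoint <- params@correctionSlope * base
  bounds <- sort(params@correctionSlopeCI * base)
  list(element_id = elementId, method = "solo_consensus",
       ageLow = bounds[1L], agePoint = agePoint, ageHigh = bounds[2L],
       youngFlag = agePoint < params@youngCutoff,
       dRaw = dRaw, dJC = dJC, dK2P = dK2P, dAvg = dAvg)
}

#' Format an age estimate the way the catalog tables report it
#'
#' Paired estimates whose lower bound is below the young cutoff print as
#' `"< 2"`; others print as `"low-high"` rounded to 2 decimals.
#'
#' @param est An estimate from [estimateProvirusAge()] or
#'   [estimateSoloAge()].
#' @param params A [ClockParameters-class].
#' @return Character scalar.
#' @export
formatAgeEstimate <- function(est, params = clockParameters()) {
  if (isTRUE(est$youngFlag) && est$method == "paired_ltr") {
    sprintf("< %g", params@youngCutoff)
  } else {
    sprintf("%.2f-%.2f", est$ageLow, est$ageHigh)
  }
}
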