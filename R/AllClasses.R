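#' Assay quality-control summary (Z-prime factor)
#'
#' Container for the plate-quality statistic
#' \deqn{Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|}}
#' computed from positive- and negative-control readouts (here, percent live
#' acinar clusters of all live objects).  A Z' above 0.5 is the conventional
#' bound for a screen-ready assay.
#'
#' @slot zPrime numeric(1), the Z-prime factor (always <= 1).
#' @slot muPos,sdPos numeric(1), mean and SD of the positive-control readout.
#' @slot muNeg,sdNeg numeric(1), mean and SD of the negative-control readout.
#' @slot nPos,nNeg integer(1), control group sizes.
#'
#' @seealso [zPrimeFactor()]
#' @export
setClass("AssayQC",
  representation(zPrime = "numeric",
                 muPos = "numeric", sdPos = "numeric",
                 muNeg = "numeric", sdNeg = "numeric",
                 nPos = "integer", nNeg = "integer"))

setValidity("AssayQC", function(object) {
  msg <- NULL
  if (length(object@zPrime) != 1L || is.na(object@zPrime))
    msg <- c(msg, "zPrime must be a single non-NA number")
  else if (object@zPrime > 1 + 1e-12)
    msg <- c(msg, "zPrime cannot exceed 1")
  if (object@sdPos < 0 || object@sdNeg < 0)
    msg <- c(msg, "control SDs must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Full result of a simulated morphology screen
#'
#' Holds the per-well summaries, the per-compound hit table and the plate QC
#' of one screen run (inhibition or reversal mode).
#'
#' @slot mode character(1), \code{"inhibition"} or \code{"reversal"}.
#' @slot wells data.frame of per-well summaries (one row per well).
#' @slot hits data.frame of per-compound hit records.
#' @slot qc an [AssayQC-class] computed from the vehicle and positive-control
#'   wells.
#' @slot seed integer(1), the run seed.
#'
#' @seealso [runScreen()]
#' @export
setClass("ScreenResult",
  representation(mode = "character", wells = "data.frame",
                 hits = "data.frame", qc = "AssayQC", seed = "integer"))

setValidity("ScreenResult", function(object) {
  msg <- NULL
  if (!object@mode %in% c("inhibition", "reversal"))
    msg <- c(msg, "mode must be 'inhibition' or 'reversal'")
  need <- c("compound_id", "pass_i", "pass_ii", "pass_iii", "is_hit")
  if (!all(need %in% names(object@hits)))
    msg <- c(msg, "hit table is missing required columns")
  else if (!all(object@hits$is_hit ==
                (object@hits$pass_i & object@hits$pass_ii & object@hits$pass_iii)))
    msg <- c(msg, "is_hit must equal pass_i & pass_ii & pass_iii")
  if (is.null(msg)) TRUE else msg
})

#' Four-parameter logistic concentration-response fit
#'
#' Result of fitting \eqn{y = bottom + (top - bottom)/(1 + (x/IC50)^{hill})}
#' to a concentration-response series.  Fits are canonicalized so that
#' \code{bottom <= top} (the curve is unchanged under the swap
#' \code{(top, bottom, hill) -> (bottom, top, -hill)}).
#'
#' @slot top,bottom numeric(1), response asymptotes (percent readout).
#' @slot hill numeric(1), slope factor; negative values give a response that
#'   increases with concentration.
#' @slot ic50 numeric(1), inflection concentration in the input dose units.
#' @slot rss numeric(1), residual sum of squares of the returned fit.
#' @slot converged logical(1), whether the optimizer converged away from the
#'   parameter bounds.
#' @slot data data.frame with columns \code{dose}, \code{response} used in the
#'   fit.
#'
#' @seealso [fit4PL()]
#' @export
setClass("DoseResponseFit",
  representation(top = "numeric", bottom = "numeric", hill = "numeric",
                 ic50 = "numeric", rss = "numeric", converged = "logical",
                 data = "data.frame"))

setValidity("DoseResponseFit", function(object) {
  msg <- NULL
  if (object@ic50 <= 0) msg <- c(msg, "ic50 must be positive")
  if (object@bottom > object@top + 1e-9)
    msg <- c(msg, "bottom must not exceed top after canonicalization")
  if (is.null(msg)) TRUE else msg
})
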