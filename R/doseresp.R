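#' Geometric dilution series
#'
#' Descending geometric concentration series as used for validation
#' dose-response plates.  The default (6 points, factor 3.162, top 10 uM)
#' spans 10 uM down to about 32 nM in half-log steps.
#'
#' @param topDose highest dose, uM.
#' @param nPoints number of doses (>= 2).
#' @param factor dilution factor between adjacent doses (> 1).
#' @return Numeric vector of doses, descending.
#' @examples
#' makeDilutionSeries()           # 10 ... 0.0316 uM
#' makeDilutionSeries(factor = 3) # 10 ... 0.0412 uM
#' @export
makeDilutionSeries <- function(topDose = 10, nPoints = 6L, factor = 3.162) {
  stopifnot(topDose > 0, nPoints >= 2L, factor > 1)
  topDose / factor^(seq_len(nPoints) - 1L)
}

#' Evaluate the four-parameter logistic model
#'
#' \eqn{y = bottom + (top - bottom) / (1 + (x/ic50)^{hill})}.  Positive
#' \code{hill} gives a response decreasing with dose; negative \code{hill}
#' an increasing one.
#'
#' @param dose concentrations (> 0).
#' @param top,bottom,hill,ic50 curve parameters.
#' @return Numeric responses.
#' @export
fourPL <- function(dose, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Unweighted least-squares 4PL fit with multi-start initialization: the
#' IC50 start is gridded over the observed dose range (log-spaced) and both
#' slope directions are tried; the candidate with the smallest residual sum
#' of squares is returned.  The fit is canonicalized so that
#' \code{bottom <= top} (see [DoseResponseFit-class]); the IC50 is reported
#' in the units of the input doses.  The hill slope is constrained to
#' magnitude [0.1, 10]; a fit that ends on a parameter bound, or flat data,
#' is flagged \code{converged = FALSE}, never silently accepted.
#'
#' @param doses concentrations (> 0); at least 4 distinct values.
#' @param responses readouts (e.g. percent live clusters), same length.
#' @param weights optional per-point weights (default unweighted).
#' @return A [DoseResponseFit-class] object.
#' @examples
#' d <- rep(makeDilutionSeries(), each = 2)
#' y <- fourPL(d, top = 90, bottom = 5, hill = -1.5, ic50 = 1)
#' fit <- fit4PL(d, y)
#' ic50(fit)
#' @export
fit4PL <- function(doses, responses, weights = NULL) {
  stopifnot(length(doses) == length(responses), all(doses > 0),
            all(is.finite(responses)))
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct doses to fit a 4PL")
  if (is.null(weights)) weights <- rep(1, length(doses))
  dat <- data.frame(x = doses, y = responses, w = weights)

  yr <- range(responses)
  flat <- diff(yr) < 1e-10
  # intercept-only fallback for flat or unfittable data: flagged, never silent
  fallback <- function() {
    m <- mean(responses)
    methods::new("DoseResponseFit", top = m, bottom = m, hill = 1,
                 ic50 = exp(mean(log(range(doses)))),
                 rss = sum(weights * (responses - m)^2), converged = FALSE,
                 data = data.frame(dose = doses, response = responses))
  }
  if (flat) return(fallback())
  starts <- expand.grid(
    lic = log(exp(seq(log(min(doses)), log(max(doses)), length.out = 7))),
    hill = c(-2, -1, -0.5, 0.5, 1, 2))
  lower <- c(top = yr[1] - diff(yr) - 10, bottom = yr[1] - diff(yr) - 10,
             hill = NA, lic = log(min(doses)) - log(1e4))
  upper <- c(top = yr[2] + diff(yr) + 10, bottom = yr[2] + diff(yr) + 10,
             hill = NA, lic = log(max(doses)) + log(1e4))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    h0 <- starts$hill[i]
    hlo <- if (h0 > 0) 0.1 else -10
    hhi <- if (h0 > 0) 10 else -0.1
    start <- list(top = yr[2], bottom = yr[1], hill = h0, lic = starts$lic[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (log(x) - lic))),
        data = dat, start = start, weights = dat$w,
        lower = c(lower["top"], lower["bottom"], hlo, lower["lic"]),
        upper = c(upper["top"], upper["bottom"], hhi, upper["lic"]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(dat$w * stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss,
                   hbounds = c(hlo, hhi))
  }
  if (is.null(best)) return(fallback())

  p <- stats::coef(best$fit)
  top <- unname(p["top"]); bottom <- unname(p["bottom"])
  hill <- unname(p["hill"]); ic50 <- exp(unname(p["lic"]))
  # canonical orientation: bottom <= top (identical curve)
  if (bottom > top) {
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  onBound <- abs(abs(hill) - 10) < 1e-6 || abs(abs(hill) - 0.1) < 1e-6 ||
    ic50 <= min(doses) / 1e4 * 1.0001 || ic50 >= max(doses) * 1e4 * 0.9999
  converged <- !flat && !onBound
  methods::new("DoseResponseFit", top = top, bottom = bottom, hill = hill,
               ic50 = ic50, rss = best$rss, converged = converged,
               data = data.frame(dose = doses, response = responses))
}

#' Simulate replicate dose-response readouts from a 4PL truth
#'
#' Convenience generator for fitter-recovery studies: evaluates a 4PL at
#' each dose and adds Gaussian replicate noise.
#'
#' @param doses concentration series.
#' @param top,bottom,hill,ic50 true curve parameters (see [fourPL()]).
#' @param replicates wells per dose.
#' @param noiseSd readout noise SD in percentage points.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{dose}, \code{response},
#'   \code{replicate}.
#' @export
simulateDoseResponse <- function(doses, top = 90, bottom = 5, hill = -1.5,
                                 ic50 = 1, replicates = 4L, noiseSd = 3,
                                 seed = 1L) {
  stopifnot(all(doses > 0), replicates >= 1L, noiseSd >= 0)
  withSeed(seed, {
    d <- rep(doses, each = replicates)
    y <- fourPL(d, top, bottom, hill, ic50) +
      stats::rnorm(length(d), 0, noiseSd)
    data.frame(dose = d, response = y,
               replicate = rep(seq_len(replicates), times = length(doses)))
  })
}
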