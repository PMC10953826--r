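#' Default noise / baseline parameters for well simulation
#'
#' The defaults encode the study conditions the generator emulates: wells
#' seeded to yield about 50 organoids, a vehicle baseline of about 10 percent
#' live acinar clusters in the inhibition assay (untreated wild-type
#' organoids largely undergo ADM and form ducts) and about 5 percent in the
#' reversal assay (ducts already formed), with a well-to-well replicate SD
#' of about 3 percentage points on the percent-clusters readout.
#'
#' @param nObjectsMean expected number of organoids per well (Poisson mean).
#' @param wellSd well-to-well SD of the expected percent clusters, in
#'   percentage points.
#' @param baselineInhibition,baselineReversal vehicle-well expected percent
#'   clusters in each assay mode.
#' @param ductRadius mean rendered duct outer radius, pixels.
#' @param clusterRadius mean rendered cluster envelope radius, pixels.
#' @param lumenFraction duct lumen radius as a fraction of outer radius.
#' @return A named list of class \code{"NoiseParams"}.
#' @export
noiseParams <- function(nObjectsMean = 50, wellSd = 3,
                        baselineInhibition = 10, baselineReversal = 5,
                        ductRadius = 13, clusterRadius = 9,
                        lumenFraction = 0.5) {
  stopifnot(nObjectsMean > 0, wellSd >= 0,
            baselineInhibition >= 0, baselineInhibition <= 100,
            baselineReversal >= 0, baselineReversal <= 100,
            ductRadius > 0, clusterRadius > 0,
            lumenFraction > 0, lumenFraction < 1)
  structure(list(nObjectsMean = nObjectsMean, wellSd = wellSd,
                 baselineInhibition = baselineInhibition,
                 baselineReversal = baselineReversal,
                 ductRadius = ductRadius, clusterRadius = clusterRadius,
                 lumenFraction = lumenFraction),
            class = "NoiseParams")
}

#' Describe one well of a screening plate
#'
#' @param plateId plate identifier.
#' @param row,col 0-based well indices on the plate.
#' @param compoundId library compound id, or \code{"VEHICLE"} for the 0.5\%
#'   DMSO negative control.
#' @param dose concentration in uM; must be 0 for vehicle wells and positive
#'   otherwise.
#' @param mode assay mode, \code{"inhibition"} or \code{"reversal"}.
#' @param replicateIndex 1-based technical replicate counter.
#' @return A one-row data.frame.
#' @export
wellSpec <- function(plateId = "P1", row = 0L, col = 0L,
                     compoundId = "VEHICLE", dose = 0,
                     mode = c("inhibition", "reversal"),
                     replicateIndex = 1L) {
  mode <- match.arg(mode)
  if (identical(compoundId, "VEHICLE")) {
    if (dose != 0) stop("vehicle wells must have dose = 0")
  } else if (dose <= 0) stop("compound wells must have dose > 0")
  data.frame(plate_id = plateId, row = as.integer(row), col = as.integer(col),
             compound_id = compoundId, dose = dose, mode = mode,
             replicate_index = as.integer(replicateIndex),
             stringsAsFactors = FALSE)
}

# Draw a well-level percent-clusters value with mean exactly `p` (in [0,100])
# and SD ~ wellSd away from the boundaries, using a Beta distribution so that
# boundary expectations are honored exactly (no clamping bias).
.drawWellPct <- function(p, wellSd) {
  m <- p / 100
  if (m <= 0 || m >= 1 || wellSd <= 0) return(p)
  v <- min((wellSd / 100)^2, 0.5 * m * (1 - m))
  k <- m * (1 - m) / v - 1
  100 * stats::rbeta(1, m * k, (1 - m) * k)
}

#' Simulate the object-level ground truth of one well
#'
#' Draws a per-well organoid truth table: the number of objects is Poisson
#' around the seeding density, each object is a duct or an acinar cluster
#' with probability given by the mode baseline plus the compound's designed
#' shift (jittered by the replicate noise), each object is live or dead
#' according to the compound's cytotoxic fraction, and each object gets a
#' center and radii for later rendering.  Identical \code{seed} (with
#' identical inputs) gives identical output.
#'
#' @param spec a one-row well description from [wellSpec()].
#' @param record a one-row compound record from the library fixture, or
#'   \code{NULL} for vehicle wells.
#' @param noise a [noiseParams()] list.
#' @param seed integer RNG seed for this well.
#' @param frameSize edge length, in pixels, of the frame used to lay out
#'   object centers (must match the later render size).
#' @return A list of class \code{"SimWellTruth"} with elements \code{spec},
#'   \code{truth} (data.frame: \code{object_id}, \code{true_class},
#'   \code{true_live}, \code{cx}, \code{cy}, \code{radius},
#'   \code{lumen_radius}), \code{expected_pct_clusters} and \code{seed}.
#' @examples
#' lib <- generateLibraryFixture()
#' tr <- simulateWellObjects(wellSpec(compoundId = "VEHICLE"), NULL,
#'                           noiseParams(), seed = 1)
#' table(tr$truth$true_class)
#' @export
simulateWellObjects <- function(spec, record = NULL, noise = noiseParams(),
                                seed = 1L, frameSize = 512L) {
  stopifnot(inherits(noise, "NoiseParams"), nrow(spec) == 1L)
  baseline <- if (spec$mode == "inhibition") noise$baselineInhibition
              else noise$baselineReversal
  shift <- 0
  cytotox <- 0
  sizeFactor <- 1
  if (!is.null(record) && !identical(spec$compound_id, "VEHICLE")) {
    stopifnot(nrow(record) == 1L)
    shift <- if (spec$mode == "inhibition") record$cluster_shift_inh
             else record$cluster_shift_rev
    cytotox <- record$cytotox_frac
    sizeFactor <- record$duct_size_factor
  }
  pExp <- baseline + shift
  if (pExp < 0 || pExp > 100)
    stop(sprintf("expected percent clusters %.1f outside [0, 100] for %s",
                 pExp, spec$compound_id))
  if (cytotox < 0 || cytotox > 1)
    stop("cytotox_frac must lie in [0, 1]")

  withSeed(seed, {
    n <- stats::rpois(1, noise$nObjectsMean)
    pWell <- .drawWellPct(pExp, noise$wellSd)
    if (n == 0L) {
      truth <- data.frame(object_id = integer(0), true_class = character(0),
                          true_live = integer(0), cx = numeric(0),
                          cy = numeric(0), radius = numeric(0),
                          lumen_radius = numeric(0), stringsAsFactors = FALSE)
    } else {
      isCluster <- stats::rbinom(n, 1, pWell / 100) == 1
      live <- stats::rbinom(n, 1, 1 - cytotox)
      radius <- ifelse(isCluster,
                       pmax(5, stats::rnorm(n, noise$clusterRadius, 1)),
                       pmax(7, stats::rnorm(n, noise$ductRadius * sizeFactor, 1.5)))
      radius <- pmin(radius, 22)
      lumen <- ifelse(isCluster, 0, noise$lumenFraction * radius)
      # one object per shuffled grid cell so rendered objects never merge
      cell <- 56L
      ncell <- as.integer(frameSize %/% cell)
      if (n > ncell * ncell)
        stop("too many objects for the frame at the fixed grid density")
      cells <- sample.int(ncell * ncell, n) - 1L
      crow <- cells %/% ncell
      ccol <- cells %% ncell
      slack <- pmax(cell / 2 - radius - 2, 0)
      cx <- ccol * cell + cell / 2 + stats::runif(n, -1, 1) * slack
      cy <- crow * cell + cell / 2 + stats::runif(n, -1, 1) * slack
      truth <- data.frame(object_id = seq_len(n),
                          true_class = ifelse(isCluster, "cluster", "duct"),
                          true_live = live, cx = cx, cy = cy,
                          radius = radius, lumen_radius = lumen,
                          stringsAsFactors = FALSE)
    }
    structure(list(spec = spec, truth = truth,
                   expected_pct_clusters = pExp, seed = seed,
                   frame_size = as.integer(frameSize)),
              class = "SimWellTruth")
  })
}
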