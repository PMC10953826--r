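#' Summarize one well of classified, viability-scored objects
#'
#' Computes the screen readouts of a well: percent live ducts and percent
#' live acinar clusters among live objects, percent total clusters
#' (viable and nonviable) among all objects, and the viability fraction.
#' A well with no live objects (or no objects at all) cannot define the
#' live-percentage readouts and is returned flagged; flagged wells are
#' excluded from downstream tests with a warning rather than imputed.
#'
#' @param objects data.frame with one row per organoid and columns
#'   \code{predicted_class} (\code{"duct"} / \code{"cluster"}) and
#'   \code{live} (logical or 0/1).
#' @return A one-row data.frame with columns \code{n_objects},
#'   \code{n_live}, \code{pct_live_ducts}, \code{pct_live_clusters},
#'   \code{pct_total_clusters}, \code{viability_frac}, \code{flagged}.
#' @examples
#' obj <- data.frame(predicted_class = c("duct", "cluster", "cluster"),
#'                   live = c(TRUE, TRUE, FALSE))
#' summarizeWell(obj)
#' @export
summarizeWell <- function(objects) {
  .assertColumns(objects, c("predicted_class", "live"), "object table")
  live <- as.logical(objects$live)
  n <- nrow(objects)
  nLive <- sum(live)
  if (n == 0L || nLive == 0L)
    return(data.frame(n_objects = n, n_live = nLive,
                      pct_live_ducts = NA_real_,
                      pct_live_clusters = NA_real_,
                      pct_total_clusters = if (n) 100 * mean(objects$predicted_class == "cluster") else NA_real_,
                      viability_frac = if (n) 0 else NA_real_,
                      flagged = TRUE))
  data.frame(
    n_objects = n, n_live = nLive,
    pct_live_ducts = 100 * sum(live & objects$predicted_class == "duct") / nLive,
    pct_live_clusters = 100 * sum(live & objects$predicted_class == "cluster") / nLive,
    pct_total_clusters = 100 * mean(objects$predicted_class == "cluster"),
    viability_frac = nLive / n,
    flagged = FALSE)
}

#' Welch's two-sample t-test (unequal variances, two-tailed)
#'
#' Thin, typed wrapper around [stats::t.test()] with
#' \code{var.equal = FALSE}.  Degenerate inputs are resolved by convention:
#' if both samples have zero variance and equal means the test is
#' uninformative and \code{p = 1} (\code{t = 0}); zero variance with
#' unequal means gives \code{p = 0} (\code{t = +/-Inf}).
#'
#' @param a,b numeric readout vectors, each of length >= 2.
#' @return A list with \code{t} (statistic, sign of \code{mean(a)-mean(b)}),
#'   \code{df} (Welch-Satterthwaite degrees of freedom) and \code{p}
#'   (two-tailed).
#' @examples
#' welchTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welchTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welchTest needs at least 2 observations per sample")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Z-prime plate-quality factor
#'
#' \eqn{Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|}
#' from positive- and negative-control readouts.  Z' is invariant to
#' rescaling both groups and strictly decreases as either SD grows; values
#' above 0.5 indicate an assay well separated enough for screening.
#'
#' @param pos,neg numeric control readouts (each n >= 2).
#' @return An [AssayQC-class] object.
#' @examples
#' qc <- zPrimeFactor(rnorm(4, 90, 3), rnorm(4, 10, 3))
#' zPrime(qc)
#' @export
zPrimeFactor <- function(pos, neg) {
  if (length(pos) < 2L || length(neg) < 2L)
    stop("zPrimeFactor needs at least 2 readouts per control group")
  muP <- mean(pos); muN <- mean(neg)
  if (muP == muN)
    stop("Z-prime is undefined when control means are equal")
  z <- 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(muP - muN)
  methods::new("AssayQC", zPrime = z, muPos = muP, sdPos = stats::sd(pos),
               muNeg = muN, sdNeg = stats::sd(neg),
               nPos = length(pos), nNeg = length(neg))
}

#' Three-criterion hit selection against vehicle control
#'
#' Applies the screen's selection gates per compound: (i) higher percent
#' live acinar clusters than vehicle with a direction-gated two-tailed
#' Welch test at \code{alpha}; (ii) the same on percent total clusters
#' (viable and nonviable, as a percentage of all objects); (iii) at most
#' 50\% cytotoxicity, operationalized within-well as mean viability
#' fraction >= \code{viabilityFloor}.  A hit passes all three.  P-values
#' are reported raw (no multiplicity correction, matching the screen's
#' raw p <= 0.05 reading); set \code{bhCorrect = TRUE} for an optional
#' Benjamini-Hochberg variant.  Flagged (no-live-object) wells are dropped
#' from the means with a warning.  A vehicle-relative viability column is
#' reported as a diagnostic only.
#'
#' @param summaries data.frame of per-well summaries (rows from
#'   [summarizeWell()]) for compound wells, with a \code{compound_id}
#'   column.
#' @param vehicleSummaries the same for vehicle wells.
#' @param alpha significance level for criteria i and ii.
#' @param viabilityFloor minimum mean viability fraction for criterion iii.
#' @param bhCorrect apply Benjamini-Hochberg to the criterion i/ii p-values
#'   across compounds before gating.
#' @return data.frame with one row per compound: means, p-values, the three
#'   pass flags and \code{is_hit}.
#' @export
applySelectionCriteria <- function(summaries, vehicleSummaries,
                                   alpha = 0.05, viabilityFloor = 0.5,
                                   bhCorrect = FALSE) {
  .assertColumns(summaries, c("compound_id", "pct_live_clusters",
                              "pct_total_clusters", "viability_frac",
                              "flagged"), "well summary table")
  if (nrow(vehicleSummaries) == 0L)
    stop("vehicle summaries are required for hit selection")
  if (any(vehicleSummaries$flagged) || any(summaries$flagged)) {
    nf <- sum(vehicleSummaries$flagged) + sum(summaries$flagged)
    warning(sprintf("excluding %d flagged well(s) with no live objects", nf))
    vehicleSummaries <- vehicleSummaries[!vehicleSummaries$flagged, ]
    summaries <- summaries[!summaries$flagged, ]
  }
  vehLive <- vehicleSummaries$pct_live_clusters
  vehTotal <- vehicleSummaries$pct_total_clusters
  if (length(vehLive) < 2L)
    stop("need at least 2 usable vehicle wells")

  rows <- lapply(split(summaries, summaries$compound_id), function(sub) {
    if (nrow(sub) < 2L)
      stop(sprintf("compound %s has fewer than 2 usable wells",
                   sub$compound_id[1]))
    ti <- welchTest(sub$pct_live_clusters, vehLive)
    tii <- welchTest(sub$pct_total_clusters, vehTotal)
    data.frame(
      compound_id = sub$compound_id[1],
      mean_pct_live_clusters = mean(sub$pct_live_clusters),
      mean_pct_total_clusters = mean(sub$pct_total_clusters),
      viability_frac = mean(sub$viability_frac),
      vehicle_rel_viability = mean(sub$viability_frac) /
        mean(vehicleSummaries$viability_frac),
      p_live_clusters = ti$p, p_total_clusters = tii$p,
      higher_live = mean(sub$pct_live_clusters) > mean(vehLive),
      higher_total = mean(sub$pct_total_clusters) > mean(vehTotal),
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  pI <- hits$p_live_clusters
  pII <- hits$p_total_clusters
  if (bhCorrect) {
    pI <- stats::p.adjust(pI, "BH")
    pII <- stats::p.adjust(pII, "BH")
  }
  hits$pass_i <- hits$higher_live & pI <= alpha
  hits$pass_ii <- hits$higher_total & pII <= alpha
  hits$pass_iii <- hits$viability_frac >= viabilityFloor
  hits$is_hit <- hits$pass_i & hits$pass_ii & hits$pass_iii
  hits$higher_live <- hits$higher_total <- NULL
  hits
}

#' Run a full simulated morphology screen
#'
#' Simulates the complete screen of the packaged 144-compound library in
#' one assay mode at the object level: \code{replicates} wells per
#' compound at 1 uM, plus vehicle wells and a TSA-like positive-control
#' group (strong inhibition/reversal in over 80\% of organoids), then
#' summarizes wells, computes the Z-prime QC from the control groups and
#' applies the three selection criteria.  Per-well RNG substreams are
#' derived from the run seed with [wellSeed()], so the run is fully
#' reproducible.
#'
#' @param library compound library data.frame (default
#'   [generateLibraryFixture()]).
#' @param mode \code{"inhibition"} or \code{"reversal"}.
#' @param replicates wells per compound and per control group.
#' @param seed integer run seed.
#' @param noise [noiseParams()] used for every well.
#' @param alpha,viabilityFloor selection-criteria parameters.
#' @param positiveShift cluster shift (percentage points) of the TSA-like
#'   positive control.
#' @return A [ScreenResult-class] object.
#' @examples
#' \donttest{
#' res <- runScreen(mode = "inhibition", seed = 1)
#' hitTable(res)[hitTable(res)$is_hit, "compound_id"]
#' }
#' @export
runScreen <- function(library = generateLibraryFixture(),
                      mode = c("inhibition", "reversal"),
                      replicates = 4L, seed = 1L, noise = noiseParams(),
                      alpha = 0.05, viabilityFloor = 0.5,
                      positiveShift = 80) {
  mode <- match.arg(mode)
  stopifnot(replicates >= 2L)
  posRecord <- data.frame(compound_id = "TSA_POS", name = "TSA-like control",
                          target_class = "HDAC_Zn",
                          cluster_shift_inh = positiveShift,
                          cluster_shift_rev = positiveShift,
                          cytotox_frac = 0.05, duct_size_factor = 1,
                          stringsAsFactors = FALSE)
  groups <- rbind(
    data.frame(compound_id = "VEHICLE", stringsAsFactors = FALSE),
    data.frame(compound_id = "TSA_POS", stringsAsFactors = FALSE),
    data.frame(compound_id = library$compound_id, stringsAsFactors = FALSE))

  wells <- list()
  idx <- 0L
  for (g in groups$compound_id) {
    record <- if (g == "VEHICLE") NULL
      else if (g == "TSA_POS") posRecord
      else library[library$compound_id == g, ]
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      spec <- wellSpec(plateId = "SIM1",
                       row = as.integer((idx - 1L) %/% 24L),
                       col = as.integer((idx - 1L) %% 24L),
                       compoundId = g,
                       dose = if (g == "VEHICLE") 0 else 1,
                       mode = mode, replicateIndex = r)
      truth <- simulateWellObjects(spec, record, noise,
                                   seed = wellSeed(seed, idx))
      obj <- data.frame(predicted_class = truth$truth$true_class,
                        live = truth$truth$true_live == 1L)
      sm <- summarizeWell(obj)
      wells[[idx]] <- cbind(spec, sm)
    }
  }
  wellTab <- do.call(rbind, wells)

  veh <- wellTab[wellTab$compound_id == "VEHICLE", ]
  pos <- wellTab[wellTab$compound_id == "TSA_POS", ]
  qc <- zPrimeFactor(pos$pct_live_clusters, veh$pct_live_clusters)
  cmp <- wellTab[!wellTab$compound_id %in% c("VEHICLE", "TSA_POS"), ]
  hits <- applySelectionCriteria(cmp, veh, alpha = alpha,
                                 viabilityFloor = viabilityFloor)
  hits$mode <- mode
  methods::new("ScreenResult", mode = mode, wells = wellTab, hits = hits,
               qc = qc, seed = as.integer(seed))
}
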