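# Shared fixtures: object-level wells, rendered wells, and truth matching.

# a compound record row with the given designed effects
makeRecord <- function(shiftInh = 0, shiftRev = 0, cytotox = 0.05,
                       sizeFactor = 1, id = "TEST") {
  data.frame(compound_id = id, name = id, target_class = "other",
             cluster_shift_inh = shiftInh, cluster_shift_rev = shiftRev,
             cytotox_frac = cytotox, duct_size_factor = sizeFactor,
             stringsAsFactors = FALSE)
}

# object-level well summary for a given record (vehicle when record NULL)
simSummary <- function(record, seed, mode = "inhibition", dose = 1) {
  spec <- wellSpec(compoundId = if (is.null(record)) "VEHICLE"
                   else record$compound_id,
                   dose = if (is.null(record)) 0 else dose, mode = mode)
  tr <- simulateWellObjects(spec, record, noiseParams(), seed = seed)
  summarizeWell(data.frame(predicted_class = tr$truth$true_class,
                           live = tr$truth$true_live == 1L))
}

# render a well and run the full imaging chain; returns truth + analysis,
# with segmented objects matched to truth objects by nearest centroid
renderAndAnalyze <- function(seed, record = NULL, mode = "inhibition") {
  spec <- wellSpec(compoundId = if (is.null(record)) "VEHICLE" else
                   record$compound_id,
                   dose = if (is.null(record)) 0 else 1, mode = mode)
  tr <- simulateWellObjects(spec, record, noiseParams(), seed = seed)
  img <- renderWellImage(tr, seed = seed)
  res <- analyzeWellImage(img)
  tt <- tr$truth
  match_idx <- vapply(seq_len(nrow(res$objects)), function(i) {
    which.min((tt$cy - res$objects$centroid_row[i])^2 +
              (tt$cx - res$objects$centroid_col[i])^2)
  }, integer(1))
  list(truth = tt, labels = res$labels, objects = res$objects,
       match = match_idx)
}

# rasterize a disk (or annulus, rin > 0) as a 16-bit-like intensity image
rasterShape <- function(r, rin = 0, size = 2 * r + 41, value = 20000) {
  m <- matrix(0, size, size)
  cc <- (size + 1) / 2
  for (i in seq_len(size)) {
    d2 <- (i - cc)^2 + (seq_len(size) - cc)^2
    m[i, d2 <= r^2 & d2 > rin^2] <- value
  }
  m
}

noSmoothParams <- function(...)
  segmentationParams(smoothingSigma = 0, thresholdMethod = "fixed",
                     fixedThreshold = 10000, ...)
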