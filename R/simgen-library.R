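#' Build the packaged 144-compound epigenetic-library fixture
#'
#' Returns the synthetic annotation table for a 144-compound small-molecule
#' epigenetic modulator library, one row per compound, with ground-truth
#' simulation effects attached.  Effects are parameterized directly on the
#' readout scale: \code{cluster_shift_inh} / \code{cluster_shift_rev} are the
#' percentage-points added to the expected percent live acinar clusters in
#' the ADM-inhibition and ADM-reversal assay modes, \code{cytotox_frac} is
#' the expected fraction of objects rendered dead, and
#' \code{duct_size_factor} scales the rendered duct radius (sub-threshold
#' morphological effects such as duct enlargement or shrinkage).
#'
#' The designed truth follows the screen structure: six compounds carry a
#' positive inhibition-mode shift (chaetocin, apicidin, IBET151, OTX015,
#' 3-deazaneplanocin A, B32B3), four of which are cytotoxic
#' (\code{cytotox_frac} > 0.5), leaving apicidin and chaetocin as inhibition
#' hits; three compounds carry a positive reversal-mode shift (chaetocin,
#' apicidin, tubastatin A), with tubastatin A cytotoxic, leaving the same
#' pair as reversal hits.  Target-class composition matches the screened
#' library: 34 Zn2+-dependent and 9 NAD+-dependent HDAC inhibitors among the
#' 144 compounds.
#'
#' @return A data.frame with 144 rows and columns \code{compound_id},
#'   \code{name}, \code{target_class}, \code{cluster_shift_inh},
#'   \code{cluster_shift_rev}, \code{cytotox_frac}, \code{duct_size_factor}.
#' @examples
#' lib <- generateLibraryFixture()
#' table(lib$target_class)
#' subset(lib, cluster_shift_inh > 0 & cytotox_frac <= 0.5)$name
#' @export
generateLibraryFixture <- function() {
  named <- data.frame(
    name = c("chaetocin", "apicidin", "IBET151", "OTX015",
             "3-deazaneplanocin A", "B32B3", "tubastatin A",
             "IBET762", "(+)-JQ1", "PFI-1", "LAQ824", "lestaurtinib"),
    target_class = c("HMT", "HDAC_Zn", "BET", "BET",
                     "HMT", "other", "HDAC_Zn",
                     "BET", "BET", "BET", "HDAC_Zn", "other"),
    cluster_shift_inh = c(60, 50, 55, 60, 55, 60, 0, 0, 0, 0, 0, 0),
    cluster_shift_rev = c(60, 30, 0, 0, 0, 0, 55, 0, 0, 0, 0, 0),
    cytotox_frac      = c(0.05, 0.10, 0.65, 0.70, 0.65, 0.70, 0.65,
                          0.10, 0.05, 0.05, 0.10, 0.05),
    duct_size_factor  = c(1, 1, 1.4, 1, 1, 1, 1, 1.4, 1.4, 1.4, 0.7, 0.7),
    stringsAsFactors = FALSE)

  # class totals across the full library; HDAC counts match the screened
  # library composition (34 Zn-dependent, 9 NAD-dependent of 43 HDACi)
  totals <- c(BET = 10, DMT = 12, HDM = 15, HMT = 14, HAT = 12,
              HDAC_Zn = 34, HDAC_NAD = 9, PARP = 10, other = 28)
  filler <- totals - table(factor(named$target_class, levels = names(totals)))
  fill <- data.frame(
    name = character(0), target_class = character(0),
    cluster_shift_inh = numeric(0), cluster_shift_rev = numeric(0),
    cytotox_frac = numeric(0), duct_size_factor = numeric(0),
    stringsAsFactors = FALSE)
  for (cl in names(totals)) {
    n <- as.integer(filler[[cl]])
    if (n > 0)
      fill <- rbind(fill, data.frame(
        name = sprintf("%s-%02d", cl, seq_len(n)),
        target_class = cl,
        cluster_shift_inh = 0, cluster_shift_rev = 0,
        cytotox_frac = 0.05, duct_size_factor = 1,
        stringsAsFactors = FALSE))
  }
  lib <- rbind(named, fill)
  lib <- lib[order(lib$target_class, lib$name, method = "radix"), ]
  lib <- data.frame(compound_id = sprintf("ESL%03d", seq_len(nrow(lib))),
                    lib, row.names = NULL, stringsAsFactors = FALSE)
  stopifnot(nrow(lib) == 144L)
  lib
}
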