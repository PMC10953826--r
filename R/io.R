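.libraryCols <- c("compound_id", "name", "target_class",
                  "cluster_shift_inh", "cluster_shift_rev",
                  "cytotox_frac", "duct_size_factor")
.ctCols <- c("sample_id", "treatment", "gene", "ct")
.deCols <- c("gene", "log2fc", "fdr")

# all table writers format numerics to 6 significant digits so identical
# runs give byte-identical files
.writeTable <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmtNum(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

.readTable <- function(path, cols, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .assertColumns(df, cols, sprintf("%s file '%s'", what, path))
  df
}

#' Read and write the typed CSV tables of the pipeline
#'
#' Plain-CSV readers/writers (comma separator, mandatory header, UTF-8,
#' "." decimal) for the pipeline's typed tables, with schema validation on
#' read (missing columns are reported by name) and fixed 6-significant-digit
#' numeric formatting on write so that identical runs round-trip
#' byte-identically.
#'
#' @param df the table to write.
#' @param path file path.
#' @return Readers return the validated data.frame; writers return the path
#'   invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeCompoundLibrary <- function(df, path) {
  .assertColumns(df, .libraryCols, "compound library")
  .writeTable(df[, .libraryCols], path)
}

#' @rdname tableIO
#' @export
readCompoundLibrary <- function(path) {
  df <- .readTable(path, .libraryCols, "compound library")
  ok <- c("BET", "DMT", "HDM", "HMT", "HAT", "HDAC_Zn", "HDAC_NAD",
          "PARP", "other")
  bad <- setdiff(unique(df$target_class), ok)
  if (length(bad))
    stop(sprintf("compound library file '%s' has unknown target_class: %s",
                 path, paste(bad, collapse = ", ")))
  df
}

#' @rdname tableIO
#' @export
writeCtTable <- function(df, path) {
  .assertColumns(df, .ctCols, "CT table")
  .writeTable(df[, .ctCols], path)
}

#' @rdname tableIO
#' @export
readCtTable <- function(path) .readTable(path, .ctCols, "CT table")

#' @rdname tableIO
#' @export
writeDeTable <- function(df, path) {
  .assertColumns(df, .deCols, "DE table")
  .writeTable(df[, .deCols], path)
}

#' @rdname tableIO
#' @export
readDeTable <- function(path) .readTable(path, .deCols, "DE table")

#' @rdname tableIO
#' @export
writeObjectTable <- function(df, path) .writeTable(df, path)

#' @rdname tableIO
#' @export
readObjectTable <- function(path)
  .readTable(path, c("object_id"), "object table")

#' Write / read a two-channel well image as 16-bit multi-page TIFF
#'
#' Page 1 is the morphology channel, page 2 the green/viability channel;
#' values are integer counts in [0, 65535].  A sidecar JSON
#' (\code{<path>.json}) records the render parameters and seed when the
#' image carries them.
#'
#' @param img \code{h x w x 2} array from [renderWellImage()].
#' @param path output TIFF path.
#' @return \code{writeWellImage} returns the path invisibly;
#'   \code{readWellImage} returns the image array.
#' @export
writeWellImage <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 2L)
  pages <- list(img[, , 1] / 65535, img[, , 2] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  render <- attr(img, "render")
  truth <- attr(img, "truth")
  meta <- list(channels = c("morphology", "green_viability"),
               pixel_convention = "0-based, row-major, origin top-left",
               bits = 16L)
  if (!is.null(render)) meta$render <- unclass(render)
  if (!is.null(truth)) meta$seed <- truth$seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeWellImage
#' @export
readWellImage <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop(sprintf("image file '%s' must have 2 pages (morphology, green)",
                 path))
  img <- array(0, dim = c(dim(pages[[1]]), 2L))
  img[, , 1] <- round(pages[[1]] * 65535)
  img[, , 2] <- round(pages[[2]] * 65535)
  img
}

#' Write screen outputs (well summaries, hit table, QC JSON)
#'
#' @param result a [ScreenResult-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeScreenResult <- function(result, dir) {
  stopifnot(methods::is(result, "ScreenResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    wells = file.path(dir, sprintf("wells_%s.csv", result@mode)),
    hits = file.path(dir, sprintf("hits_%s.csv", result@mode)),
    qc = file.path(dir, sprintf("qc_%s.json", result@mode)))
  .writeTable(result@wells, paths["wells"])
  .writeTable(result@hits, paths["hits"])
  writeAssayQC(result@qc, paths["qc"])
  invisible(paths)
}

#' Write / read assay QC as JSON
#'
#' @param qc an [AssayQC-class].
#' @param path JSON path.
#' @export
writeAssayQC <- function(qc, path) {
  stopifnot(methods::is(qc, "AssayQC"))
  jsonlite::write_json(
    list(z_prime = qc@zPrime, mu_pos = qc@muPos, sd_pos = qc@sdPos,
         mu_neg = qc@muNeg, sd_neg = qc@sdNeg,
         n_pos = qc@nPos, n_neg = qc@nNeg),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeAssayQC
#' @export
readAssayQC <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("AssayQC", zPrime = x$z_prime, muPos = x$mu_pos,
               sdPos = x$sd_pos, muNeg = x$mu_neg, sdNeg = x$sd_neg,
               nPos = as.integer(x$n_pos), nNeg = as.integer(x$n_neg))
}

#' Write a dose-response fit as JSON plus a fitted-curve CSV
#'
#' @param fit a [DoseResponseFit-class].
#' @param prefix output path prefix; writes \code{<prefix>.json} and
#'   \code{<prefix>_curve.csv} (101 log-spaced points for plotting).
#' @export
writeDoseResponseFit <- function(fit, prefix) {
  stopifnot(methods::is(fit, "DoseResponseFit"))
  jsonlite::write_json(
    list(top = fit@top, bottom = fit@bottom, hill = fit@hill,
         ic50 = fit@ic50, rss = fit@rss, converged = fit@converged),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dr <- range(fit@data$dose)
  xs <- exp(seq(log(dr[1]), log(dr[2]), length.out = 101))
  .writeTable(data.frame(dose = xs,
                         response = fourPL(xs, fit@top, fit@bottom,
                                           fit@hill, fit@ic50)),
              paste0(prefix, "_curve.csv"))
  invisible(prefix)
}

#' Serialize / restore a run configuration
#'
#' A run configuration (mode, seed, replicate counts, noise, segmentation
#' and selection parameters) is fully JSON-serializable; re-running from
#' the emitted configuration and seed reproduces output tables exactly.
#'
#' @param config named list of run settings.
#' @param path JSON path.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(lapply(config, function(x)
    if (is.list(x)) unclass(x) else x),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
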