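#' Segmentation parameters
#'
#' @param smoothingSigma Gaussian pre-smoothing width, pixels.
#' @param thresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param fixedThreshold intensity threshold in 16-bit counts, used when
#'   \code{thresholdMethod = "fixed"}.
#' @param minObjectArea smallest object kept, px^2.
#' @param holeFillMax holes up to this area (px^2) are treated as noise and
#'   filled before labeling; duct lumens must stay above it to survive.
#' @param borderPolicy \code{"keep"} (default) or \code{"drop"} objects
#'   touching the image border.
#' @return A named list of class \code{"SegmentationParams"}.
#' @export
segmentationParams <- function(smoothingSigma = 1,
                               thresholdMethod = c("otsu", "fixed"),
                               fixedThreshold = NA_real_,
                               minObjectArea = 50,
                               holeFillMax = 25,
                               borderPolicy = c("keep", "drop")) {
  thresholdMethod <- match.arg(thresholdMethod)
  borderPolicy <- match.arg(borderPolicy)
  stopifnot(minObjectArea > 0, holeFillMax >= 0)
  if (thresholdMethod == "fixed" && !is.finite(fixedThreshold))
    stop("fixedThreshold must be given for thresholdMethod = 'fixed'")
  structure(list(smoothingSigma = smoothingSigma,
                 thresholdMethod = thresholdMethod,
                 fixedThreshold = fixedThreshold,
                 minObjectArea = minObjectArea,
                 holeFillMax = holeFillMax,
                 borderPolicy = borderPolicy),
            class = "SegmentationParams")
}

# fill only holes whose area is <= maxArea (small thresholding noise),
# leaving larger holes (duct lumens) open
.fillSmallHoles <- function(mask, maxArea) {
  if (maxArea <= 0) return(mask)
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(mask)))
  holes <- filled == 1 & mask == 0
  if (!any(holes)) return(mask)
  hl <- EBImage::bwlabel(EBImage::Image(holes * 1))
  sizes <- tabulate(as.integer(hl)[as.integer(hl) > 0])
  small <- which(sizes <= maxArea)
  mask[as.matrix(hl) %in% small] <- 1
  mask
}

#' Segment organoid objects from the morphology channel
#'
#' Smooths the channel, thresholds it (Otsu by default), fills
#' sub-threshold noise holes, labels connected components and removes
#' objects below the minimum area.  Touching organoids are not declumped:
#' components merged at rendering or imaging stay one object (documented
#' limitation).  Labels are positive integers with background 0; pixel
#' convention is 0-based, row-major, origin top-left.
#'
#' @param channel 2-D numeric matrix of morphology intensities (16-bit
#'   counts), e.g. \code{img[, , 1]} from [renderWellImage()].
#' @param params a [segmentationParams()] list.
#' @return An integer label matrix with attribute \code{"nObjects"}.  An
#'   all-background image gives 0 objects, not an error.
#' @examples
#' tr <- simulateWellObjects(wellSpec(), NULL, noiseParams(), seed = 5)
#' img <- renderWellImage(tr, seed = 5)
#' labels <- segmentObjects(img[, , 1])
#' attr(labels, "nObjects")
#' @export
segmentObjects <- function(channel, params = segmentationParams()) {
  if (length(dim(channel)) != 2L)
    stop("segmentObjects expects a single 2-D image channel")
  stopifnot(inherits(params, "SegmentationParams"))
  x <- channel / 65535
  if (params$smoothingSigma > 0)
    x <- as.matrix(EBImage::gblur(EBImage::Image(x),
                                  sigma = params$smoothingSigma))
  thr <- if (params$thresholdMethod == "otsu") {
    if (stats::sd(x) < 1e-6) Inf else EBImage::otsu(EBImage::Image(x))
  } else params$fixedThreshold / 65535
  mask <- (x > thr) * 1
  mask <- .fillSmallHoles(mask, params$holeFillMax)
  labels <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0], nbins = max(labels))
    drop <- sizes < params$minObjectArea
    if (params$borderPolicy == "drop") {
      border <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
      drop[border[border > 0]] <- TRUE
    }
    keep <- which(!drop)
    relabel <- integer(max(labels))
    relabel[keep] <- seq_along(keep)
    labels[labels > 0] <- relabel[labels[labels > 0]]
  }
  storage.mode(labels) <- "integer"
  attr(labels, "nObjects") <- max(labels)
  labels
}

# crack-length perimeter with the pi/4 isotropic correction (exact in
# expectation for smooth boundaries; exact for disks)
.crackPerimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- sum(mask[1, ]) + sum(mask[h, ]) + sum(mask[, 1]) + sum(mask[, w])
  p <- p + sum(abs(mask[-1, ] - mask[-h, ])) +
       sum(abs(mask[, -1] - mask[, -w]))
  p * pi / 4
}

.hullArea <- function(rows, cols) {
  if (length(rows) < 3L) return(length(rows))
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3L) return(nrow(pts))
  h <- grDevices::chull(pts)
  ph <- pts[h, , drop = FALSE]
  n <- nrow(ph)
  i2 <- c(2:n, 1)
  abs(sum(ph[, 1] * ph[i2, 2] - ph[i2, 1] * ph[, 2])) / 2
}

#' Extract per-object shape and intensity features
#'
#' For every labeled object computes: centroid (0-based row/col), area
#' (px^2), perimeter (crack-length estimate with isotropic correction),
#' form factor \eqn{4\pi A/P^2}, solidity (area over convex-hull area),
#' eccentricity (from image moments), lumen ratio
#' \eqn{(A_{filled} - A)/A_{filled}} using the hole-filled mask, and the
#' mean green-channel intensity.  Feature extraction never changes the
#' object count.
#'
#' @param labels integer label matrix from [segmentObjects()].
#' @param morphology,green aligned intensity channels (the green channel
#'   may be \code{NULL} if viability is not needed).
#' @return data.frame with one row per object: \code{object_id},
#'   \code{centroid_row}, \code{centroid_col}, \code{area},
#'   \code{perimeter}, \code{form_factor}, \code{solidity},
#'   \code{eccentricity}, \code{lumen_ratio}, \code{mean_green}.
#' @export
extractFeatures <- function(labels, morphology = NULL, green = NULL) {
  if (!is.null(morphology) && !identical(dim(labels), dim(morphology)))
    stop("label image and morphology channel dimensions differ")
  if (!is.null(green) && !identical(dim(labels), dim(green)))
    stop("label image and green channel dimensions differ")
  n <- max(labels, 0L)
  if (n == 0L)
    return(data.frame(object_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area = numeric(0),
                      perimeter = numeric(0), form_factor = numeric(0),
                      solidity = numeric(0), eccentricity = numeric(0),
                      lumen_ratio = numeric(0), mean_green = numeric(0)))
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(labels)))
  ecc <- suppressWarnings(
    EBImage::computeFeatures.moment(EBImage::Image(labels))[, "m.eccentricity"])
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels)
  cols <- (idx - 1L) %/% nrow(labels)
  area <- tabulate(lab, nbins = n)
  filledArea <- tabulate(filled[filled > 0], nbins = n)
  out <- data.frame(object_id = seq_len(n),
                    centroid_row = as.numeric(tapply(rows, lab, mean)),
                    centroid_col = as.numeric(tapply(cols, lab, mean)),
                    area = as.numeric(area), perimeter = NA_real_,
                    form_factor = NA_real_, solidity = NA_real_,
                    eccentricity = as.numeric(ecc),
                    lumen_ratio = (filledArea - area) / pmax(filledArea, 1),
                    mean_green = NA_real_)
  for (i in seq_len(n)) {
    sel <- lab == i
    r0 <- range(rows[sel]); c0 <- range(cols[sel])
    sub <- (labels[(r0[1] + 1):(r0[2] + 1),
                   (c0[1] + 1):(c0[2] + 1), drop = FALSE] == i) * 1
    out$perimeter[i] <- .crackPerimeter(sub)
    out$solidity[i] <- min(1, out$area[i] / max(.hullArea(rows[sel], cols[sel]), 1))
    if (!is.null(green))
      out$mean_green[i] <- mean(green[idx[sel]])
  }
  out$form_factor <- 4 * pi * out$area / out$perimeter^2
  out
}

#' Classify organoids as duct-like or cluster-like
#'
#' Default is a transparent rule on shape features: an object is a duct if
#' it has a visible lumen (\code{lumen_ratio >= tauLumen}) or is large and
#' non-solid (\code{area >= tauArea} and \code{solidity <= tauSolidity});
#' otherwise it is a compact acinar cluster.  Alternatively pass a trained
#' model from [trainOrganoidClassifier()] for a learned decision
#' (CellProfiler-Analyst-style).  Every object gets exactly one of the two
#' classes.
#'
#' @param objects feature table from [extractFeatures()].
#' @param classifier \code{NULL} for the default rule, or an rpart model.
#' @param tauLumen,tauArea,tauSolidity rule thresholds (applied as >=
#'   / <= respectively).
#' @return \code{objects} with a \code{predicted_class} column added.
#' @export
classifyObjects <- function(objects, classifier = NULL,
                            tauLumen = 0.08, tauArea = 380,
                            tauSolidity = 0.85) {
  need <- c("area", "solidity", "lumen_ratio", "form_factor", "eccentricity")
  .assertColumns(objects, need, "feature table")
  if (any(!stats::complete.cases(objects[, need])) && nrow(objects) > 0)
    stop("feature table contains missing feature values")
  if (is.null(classifier)) {
    duct <- objects$lumen_ratio >= tauLumen |
      (objects$area >= tauArea & objects$solidity <= tauSolidity)
  } else {
    if (!inherits(classifier, "rpart"))
      stop("classifier must be NULL (default rule) or an rpart model")
    duct <- as.character(stats::predict(classifier, objects,
                                        type = "class")) == "duct"
  }
  objects$predicted_class <- ifelse(duct, "duct", "cluster")
  objects
}

#' Train a decision-tree duct/cluster classifier on labeled objects
#'
#' Fits an rpart classification tree on the standard shape features, for
#' use as the \code{classifier} argument of [classifyObjects()].  Training
#' data is typically a rendered synthetic set with generator truth labels
#' (see [simulateWellObjects()] / [renderWellImage()]).
#'
#' @param objects feature table from [extractFeatures()].
#' @param trueClass character vector of \code{"duct"} / \code{"cluster"}
#'   labels, one per object.
#' @return An rpart model.
#' @export
trainOrganoidClassifier <- function(objects, trueClass) {
  stopifnot(nrow(objects) == length(trueClass),
            all(trueClass %in% c("duct", "cluster")))
  dat <- objects[, c("area", "solidity", "lumen_ratio", "form_factor",
                     "eccentricity")]
  dat$class <- factor(trueClass, levels = c("cluster", "duct"))
  rpart::rpart(class ~ ., data = dat, method = "class")
}

#' Score per-object viability from the green (calcein-like) channel
#'
#' An object is live when at least \code{liveThresholdFraction} of its
#' pixels exceed the green intensity cut.  The default cut (2000 counts)
#' sits between the rendered green background and live-object signal;
#' thresholds are applied as >=.
#'
#' @param objects feature table (needs \code{object_id}).
#' @param labels label matrix aligned with \code{green}.
#' @param green green-channel intensity matrix.
#' @param liveThresholdFraction fraction of object pixels that must be
#'   green-positive, in (0, 1).
#' @param greenCut intensity cut in counts.
#' @return \code{objects} with logical \code{live} and numeric
#'   \code{green_fraction} columns added.
#' @export
scoreViability <- function(objects, labels, green,
                           liveThresholdFraction = 0.5, greenCut = 2000) {
  if (!identical(dim(labels), dim(green)))
    stop("label image and green channel dimensions differ")
  stopifnot(liveThresholdFraction > 0, liveThresholdFraction < 1)
  idx <- which(labels > 0)
  lab <- labels[idx]
  pos <- green[idx] >= greenCut
  frac <- as.numeric(tapply(pos, lab, mean))
  ids <- as.integer(names(tapply(pos, lab, mean)))
  objects$green_fraction <- frac[match(objects$object_id, ids)]
  objects$green_fraction[is.na(objects$green_fraction)] <- 0
  objects$live <- objects$green_fraction >= liveThresholdFraction
  objects
}

#' Segment, featurize, classify and viability-score one rendered well
#'
#' Convenience wrapper chaining [segmentObjects()], [extractFeatures()],
#' [classifyObjects()] and [scoreViability()] on a two-channel well image.
#'
#' @param img \code{h x w x 2} array (morphology, green) as produced by
#'   [renderWellImage()] or read from TIFF.
#' @param params segmentation parameters.
#' @param classifier optional trained classifier for [classifyObjects()].
#' @param ... passed on to [scoreViability()].
#' @return A list with \code{labels} and the completed object table
#'   \code{objects}.
#' @export
analyzeWellImage <- function(img, params = segmentationParams(),
                             classifier = NULL, ...) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 2L)
  labels <- segmentObjects(img[, , 1], params)
  objects <- extractFeatures(labels, img[, , 1], img[, , 2])
  objects <- classifyObjects(objects, classifier = classifier)
  objects <- scoreViability(objects, labels, img[, , 2], ...)
  list(labels = labels, objects = objects)
}
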