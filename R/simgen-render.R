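#' Rendering parameters for synthetic well images
#'
#' @param width,height image size in pixels (minimum 256).
#' @param background morphology-channel background level, 16-bit counts.
#' @param signal added object signal in the morphology channel, counts.
#' @param greenBackground,greenSignal analogous levels for the viability
#'   (calcein-like) channel; only live objects carry green signal.
#' @param blurSigma Gaussian blur width in pixels applied to both channels.
#' @param noiseSd Gaussian read-noise SD in counts.
#' @return A named list of class \code{"RenderParams"}.
#' @export
renderParams <- function(width = 512L, height = 512L,
                         background = 500, signal = 5000,
                         greenBackground = 200, greenSignal = 8000,
                         blurSigma = 1, noiseSd = 40) {
  stopifnot(width >= 256L, height >= 256L, blurSigma >= 0, noiseSd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, signal = signal,
                 greenBackground = greenBackground, greenSignal = greenSignal,
                 blurSigma = blurSigma, noiseSd = noiseSd),
            class = "RenderParams")
}

# binary mask of one object on a height x width frame (row = y, col = x;
# 0-based pixel centers, origin top-left)
.objectMask <- function(obj, width, height) {
  r <- obj$radius
  x0 <- max(1L, floor(obj$cx - r - 8)); x1 <- min(width,  ceiling(obj$cx + r + 8))
  y0 <- max(1L, floor(obj$cy - r - 8)); y1 <- min(height, ceiling(obj$cy + r + 8))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- outer((ys - 1) - obj$cy, rep(1, length(xs)))^2
  dy2 <- outer(rep(1, length(ys)), (xs - 1) - obj$cx)^2
  m <- matrix(0, height, width)
  if (obj$true_class == "duct") {
    d2 <- dx2 + dy2
    sub <- (d2 <= r^2) & (d2 > obj$lumen_radius^2)
    m[ys, xs] <- sub * 1
  } else {
    # berry-like union of lobes plus a core disk (no enclosed hole)
    nl <- 7L
    ang <- seq(0, 2 * pi, length.out = nl + 1L)[-1] + stats::runif(1, 0, pi)
    off <- 0.55 * r
    lr <- 0.45 * r
    sub <- dx2 + dy2 <= (0.55 * r)^2
    for (k in seq_len(nl)) {
      lx <- obj$cx + off * cos(ang[k]); ly <- obj$cy + off * sin(ang[k])
      d2 <- outer((ys - 1) - ly, rep(1, length(xs)))^2 +
            outer(rep(1, length(ys)), (xs - 1) - lx)^2
      sub <- sub | (d2 <= lr^2)
    }
    m[ys, xs] <- sub * 1
  }
  m
}

#' Render a two-channel 16-bit well image from an object truth table
#'
#' Draws each truth object into a morphology channel (ducts as annuli with a
#' visible lumen, acinar clusters as compact berry-like unions of disks) and
#' a green viability channel in which only live objects carry signal, then
#' applies Gaussian blur and read noise and quantizes to 16-bit.  Pixel
#' convention: 0-based, row-major, origin at the top-left; channel 1 is
#' morphology, channel 2 is the green/viability channel.  Objects whose
#' footprint would leave the frame are repositioned inside it with a
#' warning, never dropped.
#'
#' @param truth a \code{"SimWellTruth"} from [simulateWellObjects()].
#' @param render a [renderParams()] list.
#' @param seed integer RNG seed for lobe orientation and noise.
#' @return A \code{height x width x 2} numeric array of integer counts in
#'   [0, 65535], with attributes \code{"truth"} and \code{"render"}.
#' @examples
#' tr <- simulateWellObjects(wellSpec(), NULL, noiseParams(), seed = 3)
#' img <- renderWellImage(tr, renderParams(), seed = 3)
#' dim(img)
#' @export
renderWellImage <- function(truth, render = renderParams(), seed = 1L) {
  stopifnot(inherits(truth, "SimWellTruth"), inherits(render, "RenderParams"))
  w <- render$width; h <- render$height
  tab <- truth$truth
  withSeed(seed, {
    morph <- matrix(0, h, w)
    green <- matrix(0, h, w)
    if (nrow(tab)) {
      lo <- tab$radius + 2
      outside <- tab$cx < lo | tab$cx > (w - 1 - lo) |
                 tab$cy < lo | tab$cy > (h - 1 - lo)
      if (any(outside)) {
        warning(sprintf("%d object(s) repositioned to fit the frame",
                        sum(outside)))
        tab$cx <- pmin(pmax(tab$cx, lo), w - 1 - lo)
        tab$cy <- pmin(pmax(tab$cy, lo), h - 1 - lo)
      }
      for (i in seq_len(nrow(tab))) {
        m <- .objectMask(tab[i, ], w, h)
        morph <- pmax(morph, m)
        if (tab$true_live[i] == 1L) green <- pmax(green, m)
      }
    }
    morph <- render$background + render$signal * morph
    green <- render$greenBackground + render$greenSignal * green
    if (render$blurSigma > 0) {
      morph <- as.matrix(EBImage::gblur(EBImage::Image(morph / 65535),
                                        sigma = render$blurSigma)) * 65535
      green <- as.matrix(EBImage::gblur(EBImage::Image(green / 65535),
                                        sigma = render$blurSigma)) * 65535
    }
    morph <- morph + stats::rnorm(length(morph), 0, render$noiseSd)
    green <- green + stats::rnorm(length(green), 0, render$noiseSd)
    img <- array(0, dim = c(h, w, 2))
    img[, , 1] <- round(pmin(pmax(morph, 0), 65535))
    img[, , 2] <- round(pmin(pmax(green, 0), 65535))
    attr(img, "truth") <- truth
    attr(img, "render") <- render
    img
  })
}
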