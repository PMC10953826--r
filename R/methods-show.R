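#' @rdname AssayQC-class
#' @export
setMethod("zPrime", "AssayQC", function(object) object@zPrime)

#' @rdname ScreenResult-class
#' @export
setMethod("zPrime", "ScreenResult", function(object) object@qc@zPrime)

#' @rdname ScreenResult-class
#' @export
setMethod("hitTable", "ScreenResult", function(object) object@hits)

#' @rdname ScreenResult-class
#' @export
setMethod("wellTable", "ScreenResult", function(object) object@wells)

#' @rdname ScreenResult-class
#' @export
setMethod("assayQC", "ScreenResult", function(object) object@qc)

#' @rdname ScreenResult-class
#' @export
setMethod("screenMode", "ScreenResult", function(object) object@mode)

#' @rdname DoseResponseFit-class
#' @export
setMethod("ic50", "DoseResponseFit", function(object) object@ic50)

#' @rdname DoseResponseFit-class
#' @export
setMethod("coef", "DoseResponseFit", function(object)
  c(top = object@top, bottom = object@bottom,
    hill = object@hill, ic50 = object@ic50))

setMethod("show", "AssayQC", function(object) {
  cat("AssayQC (Z-prime plate quality)\n")
  cat(sprintf("  Z' = %.4f\n", object@zPrime))
  cat(sprintf("  positive control: mean %.2f, sd %.2f (n = %d)\n",
              object@muPos, object@sdPos, object@nPos))
  cat(sprintf("  negative control: mean %.2f, sd %.2f (n = %d)\n",
              object@muNeg, object@sdNeg, object@nNeg))
  invisible(NULL)
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult: %s mode, seed %d\n", object@mode, object@seed))
  cat(sprintf("  %d wells, %d compounds tested\n",
              nrow(object@wells), nrow(object@hits)))
  cat(sprintf("  Z' = %.3f\n", object@qc@zPrime))
  hits <- object@hits$compound_id[object@hits$is_hit]
  cat(sprintf("  hits (%d): %s\n", length(hits),
              if (length(hits)) paste(hits, collapse = ", ") else "none"))
  invisible(NULL)
})

setMethod("show", "DoseResponseFit", function(object) {
  cat("DoseResponseFit (4PL)\n")
  cat(sprintf("  top %.2f, bottom %.2f, hill %.3f\n",
              object@top, object@bottom, object@hill))
  cat(sprintf("  IC50 = %.4g (dose units), rss = %.3g, converged: %s\n",
              object@ic50, object@rss, object@converged))
  invisible(NULL)
})
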