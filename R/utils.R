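#' @importFrom methods new is validObject slot
#' @importFrom stats rnorm rpois rbinom runif sd pnorm pt p.adjust
#'   median quantile coef resid t.test predict
#' @importFrom utils read.csv write.csv head
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed)
      old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has.seed)
        assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a per-well RNG substream seed from a run seed
#'
#' A run-level seed is expanded to independent per-well seeds by a fixed
#' counter scheme, so adding wells to a layout never perturbs the draws of
#' existing wells.  The scheme is \code{(seed + 1000003 * index) mod (2^31-1)}
#' with a 1-based well index.
#'
#' @param seed Integer run seed.
#' @param index 1-based well counter within the run.
#' @return An integer seed below \code{2^31}.
#' @export
wellSeed <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) == 1L, index >= 1)
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647)
}

.assertColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# Fixed 6-significant-digit formatting used by all table writers so that
# identical runs produce byte-identical output files.
.fmtNum <- function(x) {
  ifelse(is.na(x), NA_character_, as.character(signif(x, 6)))
}
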