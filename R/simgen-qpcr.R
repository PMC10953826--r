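.qpcrBaselineCt <- c(Amy2a = 24, Cela1 = 23, Cpa2 = 25,
                     Krt19 = 26, Krt7 = 27, Sox9 = 26, `18S` = 10)

#' Simulate a qRT-PCR CT table under configured log2 effects
#'
#' Generates cycle-threshold (CT) records for treated and vehicle samples
#' under the relative-quantification model that \code{\link{deltaDeltaCt}}
#' inverts: a gene with configured log2 effect \eqn{e} in a treated sample
#' has \eqn{CT = CT_0 - e + o_s + \epsilon}, where \eqn{CT_0} is the gene's
#' baseline cycle number, \eqn{o_s} is a per-sample loading offset shared by
#' all genes of that sample (it cancels in the within-sample delta-CT), and
#' \eqn{\epsilon} is Gaussian technical noise.  The reference gene (18S)
#' always has effect 0.
#'
#' @param effects named list: for each treatment label, a named numeric
#'   vector of per-gene log2 fold-change effects.  Every vector must cover
#'   the reference gene (with effect 0); vehicle samples are generated
#'   automatically with all effects 0.
#' @param replicates number of samples per treatment (and for vehicle).
#' @param noiseSd technical CT noise SD in cycles (default 0.15).
#' @param offsetSd SD of the per-sample loading offset in cycles.
#' @param referenceGene reference gene symbol, default \code{"18S"}.
#' @param vehicleLabel treatment label used for vehicle samples.
#' @param baselineCt named numeric vector of baseline CTs per gene; genes
#'   missing from it default to 25 cycles.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{sample_id}, \code{treatment},
#'   \code{gene}, \code{ct}.
#' @examples
#' eff <- list(drugA_1uM = c(Amy2a = 3, Cela1 = 3.32, Cpa2 = 3.58,
#'                           Krt19 = -1, Krt7 = 0, Sox9 = -1, `18S` = 0))
#' ct <- simulateQpcr(eff, replicates = 3, noiseSd = 0, seed = 1)
#' head(ct)
#' @export
simulateQpcr <- function(effects, replicates = 3L, noiseSd = 0.15,
                         offsetSd = 0.3, referenceGene = "18S",
                         vehicleLabel = "VEHICLE",
                         baselineCt = .qpcrBaselineCt, seed = 1L) {
  stopifnot(is.list(effects), length(effects) >= 1L, replicates >= 1L)
  for (tr in names(effects)) {
    if (!referenceGene %in% names(effects[[tr]]))
      stop(sprintf("effect map for '%s' must include the reference gene %s",
                   tr, referenceGene))
    if (effects[[tr]][[referenceGene]] != 0)
      stop("the reference gene must have effect 0")
  }
  genes <- names(effects[[1]])
  base <- ifelse(genes %in% names(baselineCt), baselineCt[genes], 25)
  names(base) <- genes
  treatments <- c(stats::setNames(list(stats::setNames(rep(0, length(genes)),
                                                       genes)),
                                  vehicleLabel),
                  effects)
  withSeed(seed, {
    out <- vector("list", length(treatments) * replicates)
    k <- 0L
    for (tr in names(treatments)) {
      eff <- treatments[[tr]][genes]
      for (r in seq_len(replicates)) {
        k <- k + 1L
        offset <- stats::rnorm(1, 0, offsetSd)
        ct <- base - eff + offset + stats::rnorm(length(genes), 0, noiseSd)
        out[[k]] <- data.frame(
          sample_id = sprintf("%s_rep%d", tr, r), treatment = tr,
          gene = genes, ct = as.numeric(ct), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a differential-expression table with a reversal signature
#'
#' Emulates the transcriptome-level signature of ADM reversal: acinar panel
#' genes are drawn with positive mean log2 fold change, ductal/PDAC panel
#' genes with negative mean, and background genes around zero.  Each gene's
#' reported FDR is obtained by simulating a per-gene standard error, testing
#' the observed log2FC against zero and Benjamini-Hochberg-adjusting across
#' the whole table, so larger observed effects get smaller FDR on average.
#'
#' @param panel a gene panel from [genePanel()].
#' @param reversalStrength mean |log2 fold change| assigned to panel genes
#'   (0 gives a null table).
#' @param nBackgroundGenes number of unrelated background genes.
#' @param se per-gene standard error of the log2FC estimate.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{fdr}.
#' @examples
#' de <- simulateDeTable(genePanel(), reversalStrength = 4, seed = 1)
#' head(de)
#' @export
simulateDeTable <- function(panel, reversalStrength = 2,
                            nBackgroundGenes = 1000L, se = 0.25, seed = 1L) {
  stopifnot(inherits(panel, "GenePanel"), reversalStrength >= 0)
  genes <- c(panel$acinar, panel$ductal_pdac,
             if (nBackgroundGenes > 0) sprintf("BG%04d", seq_len(nBackgroundGenes)))
  mu <- c(rep(reversalStrength, length(panel$acinar)),
          rep(-reversalStrength, length(panel$ductal_pdac)),
          rep(0, nBackgroundGenes))
  if (!length(genes))
    return(data.frame(gene = character(0), log2fc = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  withSeed(seed, {
    obs <- stats::rnorm(length(genes), mu, se)
    p <- 2 * stats::pnorm(-abs(obs) / se)
    data.frame(gene = genes, log2fc = obs,
               fdr = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
}
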