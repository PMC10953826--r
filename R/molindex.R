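#' Acinar and ductal/PDAC gene panels for volcano annotation
#'
#' The packaged default panel has 27 acinar genes and 23 ductal/PDAC genes,
#' disjoint, and includes the six qPCR endpoint genes (acinar: Amy2a, Cela1,
#' Cpa2; ductal: Krt19, Krt7, Sox9).  Beyond those six, symbols are
#' representative mouse acinar digestive-enzyme / acinar-TF genes and
#' ductal / PDAC-progression genes; the panel is synthetic in composition
#' and can be replaced by any user-supplied lists of the same structure.
#'
#' @param acinar,ductalPdac optional replacement character vectors.
#' @return A list of class \code{"GenePanel"} with elements \code{acinar}
#'   and \code{ductal_pdac}.
#' @examples
#' p <- genePanel()
#' lengths(p)
#' @export
genePanel <- function(acinar = NULL, ductalPdac = NULL) {
  if (is.null(acinar))
    acinar <- c("Amy2a", "Cela1", "Cpa2", "Amy1", "Cela2a", "Cela3b",
                "Cpa1", "Cpb1", "Ctrb1", "Prss1", "Prss2", "Pnlip",
                "Pnliprp1", "Pnliprp2", "Cel", "Clps", "Ctrc", "Ctrl",
                "Sycn", "Reg1", "Reg3b", "Zg16", "Serpini2", "Ptf1a",
                "Rbpjl", "Bhlha15", "Nr5a2")
  if (is.null(ductalPdac))
    ductalPdac <- c("Krt19", "Krt7", "Sox9", "Krt8", "Krt18", "Muc1",
                    "Cftr", "Car2", "Hnf1b", "Onecut1", "Onecut2", "Spp1",
                    "Mmp7", "S100a4", "Msln", "Ceacam1", "Tff1", "Tff2",
                    "Agr2", "Gata6", "Foxq1", "Klf5", "Id2")
  if (anyDuplicated(c(acinar, ductalPdac)))
    stop("acinar and ductal/PDAC panels must be disjoint and duplicate-free")
  structure(list(acinar = acinar, ductal_pdac = ductalPdac),
            class = "GenePanel")
}

#' Relative qPCR quantification by the 2^-ddCT method
#'
#' For every sample, \eqn{\Delta CT = CT_{gene} - CT_{ref}}; per gene and
#' treatment, \eqn{\Delta\Delta CT = \overline{\Delta CT}_{treated} -
#' \overline{\Delta CT}_{vehicle}} and the linear fold change is
#' \eqn{2^{-\Delta\Delta CT}}.  Mean delta-CTs are taken before
#' exponentiation (the standard presentation); set
#' \code{perReplicate = TRUE} to instead average per-replicate fold changes
#' on the linear scale.
#'
#' @param ctTable data.frame with columns \code{sample_id},
#'   \code{treatment}, \code{gene}, \code{ct}.
#' @param referenceGene reference gene symbol (default \code{"18S"}).
#' @param vehicleLabel treatment label of the vehicle-control samples.
#' @param perReplicate average fold changes per replicate instead of
#'   averaging delta-CTs first.
#' @return data.frame with columns \code{treatment}, \code{gene}, \code{fc}
#'   (linear fold change) and \code{n_replicates}.
#' @examples
#' ct <- simulateQpcr(list(drug = c(Amy2a = 3, `18S` = 0)),
#'                    replicates = 3, noiseSd = 0, seed = 1)
#' deltaDeltaCt(ct)
#' @export
deltaDeltaCt <- function(ctTable, referenceGene = "18S",
                         vehicleLabel = "VEHICLE", perReplicate = FALSE) {
  .assertColumns(ctTable, c("sample_id", "treatment", "gene", "ct"),
                 "CT table")
  if (!vehicleLabel %in% ctTable$treatment)
    stop(sprintf("no vehicle samples labeled '%s' in the CT table",
                 vehicleLabel))
  ref <- ctTable[ctTable$gene == referenceGene, ]
  noRef <- setdiff(unique(ctTable$sample_id), unique(ref$sample_id))
  if (length(noRef))
    stop(sprintf("sample(s) missing the reference gene %s: %s",
                 referenceGene, paste(noRef, collapse = ", ")))
  refCt <- stats::setNames(ref$ct, ref$sample_id)
  tab <- ctTable[ctTable$gene != referenceGene, ]
  tab$dct <- tab$ct - refCt[tab$sample_id]

  out <- list()
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, ]
    veh <- sub$dct[sub$treatment == vehicleLabel]
    if (!length(veh))
      stop(sprintf("no vehicle measurements for gene %s", g))
    for (tr in setdiff(unique(sub$treatment), vehicleLabel)) {
      trt <- sub$dct[sub$treatment == tr]
      fc <- if (perReplicate)
        mean(2^-(trt - mean(veh)))
      else
        2^-(mean(trt) - mean(veh))
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, gene = g, fc = fc, n_replicates = length(trt),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(treatment = character(0), gene = character(0),
                      fc = numeric(0), n_replicates = integer(0)))
  do.call(rbind, out)
}

#' ADM Reversal Index (ADMRI)
#'
#' The ADMRI of a treatment is the arithmetic mean of the linear fold
#' changes of the acinar endpoint genes divided by the arithmetic mean of
#' the linear fold changes of the ductal endpoint genes.  Higher values
#' indicate stronger molecular reversal of acinar-to-ductal metaplasia
#' (acinar program re-expressed, ductal program suppressed).
#'
#' @param foldChanges data.frame from [deltaDeltaCt()] (columns
#'   \code{treatment}, \code{gene}, \code{fc}), or a named numeric vector of
#'   per-gene fold changes for a single treatment.
#' @param acinar,ductal gene symbols entering the numerator / denominator
#'   means; all must be present for every treatment (missing genes are an
#'   error, never silently dropped).
#' @return data.frame with columns \code{treatment}, \code{mean_acinar_fc},
#'   \code{mean_ductal_fc}, \code{admri}.
#' @examples
#' fc <- c(Amy2a = 8, Cela1 = 10, Cpa2 = 12, Krt19 = 0.5, Krt7 = 1, Sox9 = 0.5)
#' computeAdmri(fc)  # admri = 15
#' @export
computeAdmri <- function(foldChanges,
                         acinar = c("Amy2a", "Cela1", "Cpa2"),
                         ductal = c("Krt19", "Krt7", "Sox9")) {
  if (is.numeric(foldChanges) && !is.null(names(foldChanges)))
    foldChanges <- data.frame(treatment = "treatment",
                              gene = names(foldChanges),
                              fc = as.numeric(foldChanges),
                              stringsAsFactors = FALSE)
  .assertColumns(foldChanges, c("treatment", "gene", "fc"),
                 "fold-change table")
  out <- lapply(split(foldChanges, foldChanges$treatment), function(sub) {
    fc <- stats::setNames(sub$fc, sub$gene)
    missing <- setdiff(c(acinar, ductal), names(fc))
    if (length(missing))
      stop(sprintf("treatment '%s' is missing gene(s): %s",
                   sub$treatment[1], paste(missing, collapse = ", ")))
    ma <- mean(fc[acinar]); md <- mean(fc[ductal])
    data.frame(treatment = sub$treatment[1], mean_acinar_fc = ma,
               mean_ductal_fc = md, admri = ma / md,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank treatments by ADMRI within dose groups
#'
#' Dense descending ranking of ADMRI values within each dose group (rank 1 =
#' largest ADMRI; equal values share a rank and the next distinct value gets
#' the next integer).  Ties in ordering are broken lexicographically by
#' compound id for reproducible row order.
#'
#' @param records data.frame with columns \code{compound_id}, \code{dose},
#'   \code{admri}.
#' @return The input with an integer \code{rank} column added, ordered by
#'   dose then rank.
#' @examples
#' rankAdmri(data.frame(compound_id = c("A", "B"), dose = 1,
#'                      admri = c(2, 5)))
#' @export
rankAdmri <- function(records) {
  .assertColumns(records, c("compound_id", "dose", "admri"), "ADMRI table")
  out <- lapply(split(records, records$dose), function(sub) {
    sub <- sub[order(-sub$admri, sub$compound_id), ]
    sub$rank <- as.integer(match(-sub$admri, sort(unique(-sub$admri))))
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate a differential-expression table against a gene panel
#'
#' Labels every gene by panel membership (\code{acinar},
#' \code{ductal_pdac}, \code{background}) and significance direction
#' (\code{up-significant}, \code{down-significant}, \code{ns}) using the
#' fixed cut-offs: linear fold change above \code{fcCut} in either direction
#' (\code{|log2fc| > log2(fcCut)}) and \code{fdr < fdrCut}.  The concordance
#' summary is the fraction of panel genes changing in the direction expected
#' under ADM reversal (acinar up, ductal down).
#'
#' @param deTable data.frame with columns \code{gene}, \code{log2fc},
#'   \code{fdr}.
#' @param panel a [genePanel()].
#' @param fcCut linear fold-change cut (default 1.5).
#' @param fdrCut FDR cut (default 0.05).
#' @return A list with \code{table} (annotated data.frame; extra columns
#'   \code{panel}, \code{status}) and \code{concordance} (numeric, NA when no
#'   panel genes are present).
#' @examples
#' de <- simulateDeTable(genePanel(), reversalStrength = 4, seed = 1)
#' annotateVolcano(de, genePanel())$concordance
#' @export
annotateVolcano <- function(deTable, panel = genePanel(),
                            fcCut = 1.5, fdrCut = 0.05) {
  .assertColumns(deTable, c("gene", "log2fc", "fdr"), "DE table")
  stopifnot(inherits(panel, "GenePanel"), fcCut > 1)
  tab <- deTable
  tab$panel <- ifelse(tab$gene %in% panel$acinar, "acinar",
                ifelse(tab$gene %in% panel$ductal_pdac, "ductal_pdac",
                       "background"))
  sig <- abs(tab$log2fc) > log2(fcCut) & tab$fdr < fdrCut
  tab$status <- ifelse(!sig, "ns",
                 ifelse(tab$log2fc > 0, "up-significant", "down-significant"))
  nPanel <- sum(tab$panel != "background")
  concordance <- if (nPanel == 0) NA_real_ else
    (sum(tab$panel == "acinar" & tab$status == "up-significant") +
     sum(tab$panel == "ductal_pdac" & tab$status == "down-significant")) /
    nPanel
  list(table = tab, concordance = concordance)
}
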