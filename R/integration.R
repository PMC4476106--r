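#' Pearson correlation of all deregulated miRNA x mRNA pairs
#'
#' The core of the integrative analysis: every miRNA labeled deregulated
#' (q_associated or a_associated) is correlated against every deregulated
#' mRNA across the shared HSC samples (quiescent + activated; reference cell
#' types have no miRNA profile and are excluded). The per-pair p-value is
#' the two-sided test of r = 0 on n - 2 degrees of freedom,
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}. Benjamini-Hochberg adjusted values
#' are filled across all pairs as one family.
#'
#' @param mirnaNdct -dCt matrix or \code{SummarizedExperiment} over HSC
#'   samples.
#' @param geneExprMat log2 expression matrix or \code{SummarizedExperiment};
#'   samples are matched to the miRNA matrix by column name.
#' @param mirnaDE,geneDE Differential tables from [classifyMirnas()] /
#'   [classifyGenes()]; only non-\code{"unchanged"} features enter.
#' @return A pair table: \code{data.frame} with one row per
#'   (deregulated miRNA) x (deregulated gene) combination and columns
#'   \code{mirna_id}, \code{gene_id}, \code{pearson_r}, \code{cor_p},
#'   \code{n_samples}, \code{fdr}. Zero-variance features yield missing r
#'   and are excluded from the FDR family.
#' @export
pearsonAllPairs <- function(mirnaNdct, geneExprMat, mirnaDE, geneDE) {
  if (methods::is(mirnaNdct, "SummarizedExperiment"))
    mirnaNdct <- SummarizedExperiment::assay(mirnaNdct)
  if (methods::is(geneExprMat, "SummarizedExperiment"))
    geneExprMat <- SummarizedExperiment::assay(geneExprMat)
  shared <- intersect(colnames(mirnaNdct), colnames(geneExprMat))
  if (length(shared) < 3)
    stop(sprintf("need at least 3 shared samples, found %d", length(shared)))
  mIds <- mirnaDE$feature_id[mirnaDE$class_label != "unchanged"]
  gIds <- geneDE$feature_id[geneDE$class_label != "unchanged"]
  mIds <- intersect(mIds, rownames(mirnaNdct))
  gIds <- intersect(gIds, rownames(geneExprMat))
  if (!length(mIds) || !length(gIds))
    return(data.frame(mirna_id = character(), gene_id = character(),
                      pearson_r = numeric(), cor_p = numeric(),
                      n_samples = integer(), fdr = numeric()))
  M <- t(mirnaNdct[mIds, shared, drop = FALSE])
  G <- t(geneExprMat[gIds, shared, drop = FALSE])
  r <- suppressWarnings(stats::cor(M, G, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(M), !is.na(G))  # complete observations per pair
  r[n < 3] <- NA
  tstat <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), pmax(n - 2, 1))
  p[!is.na(r) & abs(r) == 1] <- 0  # degenerate perfect correlation
  out <- data.frame(
    mirna_id = rep(mIds, times = length(gIds)),
    gene_id = rep(gIds, each = length(mIds)),
    pearson_r = as.vector(r), cor_p = as.vector(p),
    n_samples = as.integer(as.vector(n)),
    stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  ok <- !is.na(out$cor_p)
  out$fdr[ok] <- bhAdjust(out$cor_p[ok])
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across one family of tests.
#' Inputs outside [0, 1] (or missing) are an error; callers decide the
#' family membership before adjusting.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted values, order-preserving, each in [0, 1].
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  stopIfNotProb(p, "p-values")
  stats::p.adjust(p, method = "BH")
}

#' Select functional miRNA-mRNA pairs
#'
#' A pair is called a potential functional interaction when all three
#' conditions hold: significant negative correlation (FDR < \code{fdrCut}
#' and Pearson r < 0) and a database prediction with
#' \code{p_database} < \code{pdbCut}. Pairs absent from the prediction
#' table are retained with missing \code{p_database} and
#' \code{selected = FALSE}, so database coverage stays auditable.
#'
#' @param pairs Pair table from [pearsonAllPairs()] (column \code{fdr}
#'   filled).
#' @param predictions Prediction table with \code{mirna_id}, \code{gene_id},
#'   \code{p_database}.
#' @param fdrCut FDR cut-off, strict (default 0.05).
#' @param pdbCut Database p-value cut-off, strict (default 0.05).
#' @return \code{pairs} with columns \code{p_database} and \code{selected}
#'   added.
#' @export
selectFunctionalPairs <- function(pairs, predictions, fdrCut = 0.05,
                                  pdbCut = 0.05) {
  if (nrow(predictions)) {
    stopIfNotProb(predictions$p_database, "p_database")
    key <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
    pkey <- paste(predictions$mirna_id, predictions$gene_id, sep = "\r")
    if (anyDuplicated(pkey))
      stop("duplicate (mirna_id, gene_id) rows in prediction table")
    pairs$p_database <- predictions$p_database[match(key, pkey)]
  } else {
    pairs$p_database <- NA_real_
  }
  pairs$selected <- !is.na(pairs$fdr) & pairs$fdr < fdrCut &
    !is.na(pairs$pearson_r) & pairs$pearson_r < 0 &
    !is.na(pairs$p_database) & pairs$p_database < pdbCut
  pairs
}
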