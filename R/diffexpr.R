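#' Classify miRNAs as quiescence- or activation-associated
#'
#' Applies the miRNA differential-expression rules: a miRNA is
#' quiescence-associated (down-regulated during culture-induced activation)
#' when FC(q vs a) >= \code{fcDown} with p <= \code{alpha}; it is
#' activation-associated (up-regulated during activation) when
#' FC(a vs q) >= \code{fcUp} with p <= \code{alpha}; otherwise unchanged.
#' The detection filter ([detectExpressed()]) is expected to have been
#' applied upstream.
#'
#' @param ndct A \code{SummarizedExperiment} of -dCt values over HSC samples
#'   (from [negDeltaCt()]), or a numeric matrix.
#' @param sheet Sample sheet \code{data.frame} (needed when \code{ndct} is a
#'   bare matrix); must contain \code{sample_id} and \code{state}.
#' @param fcDown Linear fold-change cut-off for quiescence-associated miRNAs
#'   (default 1.5).
#' @param fcUp Linear fold-change cut-off for activation-associated miRNAs
#'   (default 2).
#' @param alpha Significance level of the Student t-test (default 0.05,
#'   non-strict: p <= alpha).
#' @param paired Use a donor-paired t-test (default \code{FALSE}).
#' @return A differential table: \code{data.frame} with \code{feature_id},
#'   \code{feature_kind = "miRNA"}, \code{fc_q_vs_a}, \code{fc_signed},
#'   \code{p_value}, \code{class_label}.
#' @export
classifyMirnas <- function(ndct, sheet = NULL, fcDown = 1.5, fcUp = 2,
                           alpha = 0.05, paired = FALSE) {
  if (methods::is(ndct, "SummarizedExperiment")) {
    if (is.null(sheet))
      sheet <- as.data.frame(SummarizedExperiment::colData(ndct))
    ndct <- SummarizedExperiment::assay(ndct)
  }
  if (is.null(sheet) || !all(c("sample_id", "state") %in% names(sheet)))
    stop("'sheet' with columns sample_id and state is required")
  q <- sheet$sample_id[!is.na(sheet$state) & sheet$state == "quiescent"]
  a <- sheet$sample_id[!is.na(sheet$state) & sheet$state == "activated"]
  if (!length(q) || !length(a))
    stop("both quiescent and activated HSC samples are required")
  st <- groupFoldChange(ndct, q, a, paired = paired)
  sig <- !is.na(st$p_value) & st$p_value <= alpha
  label <- rep("unchanged", nrow(st))
  label[sig & st$fc_linear >= fcDown] <- "q_associated"
  label[sig & st$fc_linear <= 1 / fcUp] <- "a_associated"
  data.frame(feature_id = st$feature_id, feature_kind = "miRNA",
             fc_q_vs_a = st$fc_linear, fc_signed = st$fc_signed,
             p_value = st$p_value, class_label = label,
             stringsAsFactors = FALSE)
}

#' Classify genes with cell-type enrichment rules
#'
#' A gene is qHSC-specific (quiescence-associated) when it is at least
#' \code{fcEnrich}-fold higher in qHSCs than in \emph{both} hepatocytes and
#' LSECs \emph{and} down-regulated upon activation by at least
#' \code{fcDown}-fold (FC qHSC vs aHSC >= 1.5; no significance requirement
#' on this contrast, following the stated rule). A gene is
#' activation-associated when it is at least \code{fcEnrich}-fold higher in
#' aHSCs than in both reference cell types and significantly up-regulated
#' from qHSC to aHSC (p <= \code{alpha} and FC a vs q > 1). The enrichment
#' contrasts against hepatocytes and LSECs are fold-change-only filters.
#'
#' @param expr A \code{SummarizedExperiment} of log2 expression over HSC,
#'   hepatocyte and LSEC samples, or a numeric matrix plus \code{sheet}.
#' @param sheet Sample sheet with \code{sample_id}, \code{cell_type},
#'   \code{state}.
#' @param fcEnrich Cell-type enrichment cut-off (default 2).
#' @param fcDown Down-regulation cut-off for the q vs a contrast of
#'   qHSC-specific genes (default 1.5).
#' @param alpha Significance level for the q vs a contrast of
#'   activation-associated genes (default 0.05).
#' @param paired Donor-paired t-test for the q vs a contrast.
#' @return A differential table with \code{feature_id},
#'   \code{feature_kind = "gene"}, the intermediate enrichment fold changes
#'   (\code{fc_q_vs_hep}, \code{fc_q_vs_lsec}, \code{fc_a_vs_hep},
#'   \code{fc_a_vs_lsec}), \code{fc_q_vs_a}, \code{fc_signed},
#'   \code{p_value} (q vs a) and \code{class_label}.
#' @export
classifyGenes <- function(expr, sheet = NULL, fcEnrich = 2, fcDown = 1.5,
                          alpha = 0.05, paired = FALSE) {
  if (methods::is(expr, "SummarizedExperiment")) {
    if (is.null(sheet))
      sheet <- as.data.frame(SummarizedExperiment::colData(expr))
    expr <- SummarizedExperiment::assay(expr)
  }
  need <- c("sample_id", "cell_type", "state")
  if (is.null(sheet) || !all(need %in% names(sheet)))
    stop("'sheet' with columns sample_id, cell_type, state is required")
  pick <- function(type, state = NULL) {
    sel <- sheet$cell_type == type
    if (!is.null(state)) sel <- sel & !is.na(sheet$state) &
        sheet$state == state
    sheet$sample_id[sel]
  }
  q <- pick("HSC", "quiescent"); a <- pick("HSC", "activated")
  hep <- pick("hepatocyte"); lsec <- pick("LSEC")
  for (nm in c(q = "quiescent HSC", a = "activated HSC",
               hep = "hepatocyte", lsec = "LSEC")[
                 !c(length(q), length(a), length(hep), length(lsec))])
    stop(sprintf("missing cell-type group: %s", nm))

  qa <- groupFoldChange(expr, q, a, paired = paired)
  qh <- groupFoldChange(expr, q, hep)
  ql <- groupFoldChange(expr, q, lsec)
  ah <- groupFoldChange(expr, a, hep)
  al <- groupFoldChange(expr, a, lsec)

  qRule <- qh$fc_linear >= fcEnrich & ql$fc_linear >= fcEnrich &
    qa$fc_linear >= fcDown
  aRule <- ah$fc_linear >= fcEnrich & al$fc_linear >= fcEnrich &
    !is.na(qa$p_value) & qa$p_value <= alpha & qa$fc_linear < 1
  label <- rep("unchanged", nrow(qa))
  label[qRule] <- "q_associated"
  label[aRule] <- "a_associated"
  data.frame(feature_id = qa$feature_id, feature_kind = "gene",
             fc_q_vs_hep = qh$fc_linear, fc_q_vs_lsec = ql$fc_linear,
             fc_a_vs_hep = ah$fc_linear, fc_a_vs_lsec = al$fc_linear,
             fc_q_vs_a = qa$fc_linear, fc_signed = qa$fc_signed,
             p_value = qa$p_value, class_label = label,
             stringsAsFactors = FALSE)
}
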