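#' Pipeline configuration
#'
#' All thresholds of the end-to-end analysis in one validated list. Defaults
#' are the printed study values: detection at Ct 35 (undetermined wells at
#' cycle 40), 2-fold enrichment versus reference cell types, 1.5-fold
#' down-regulation for quiescence-associated features, 2-fold up-regulation
#' for activation-associated miRNAs, p <= 0.05 t-tests, FDR < 0.05 and
#' p_database < 0.05 pair selection, and a panel threshold of more than 6
#' targets.
#'
#' @param maxDetectCt Detection Ct threshold (default 35).
#' @param minSamplesPerGroup Detected samples required per group;
#'   \code{NULL} (default) means half the group, rounded up.
#' @param undetectedAsMissing Treat Ct at the platform maximum as missing
#'   during normalization (default \code{FALSE}: keep the numeric cycle).
#' @param mirnaFcDown,mirnaFcUp miRNA classification cut-offs (1.5 / 2).
#' @param geneFcEnrich,geneFcDown Gene classification cut-offs (2 / 1.5).
#' @param alpha t-test significance level (0.05, non-strict).
#' @param fdrCut,pdbCut Pair-selection cut-offs (0.05 each, strict).
#' @param panelMin,panelStrict Panel threshold (6) and strictness
#'   (\code{TRUE}: strictly more than \code{panelMin} targets).
#' @param paired Donor-paired t-tests (default \code{FALSE}).
#' @return Named list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig()
#' cfg$fdrCut
#' @export
pipelineConfig <- function(maxDetectCt = 35, minSamplesPerGroup = NULL,
                           undetectedAsMissing = FALSE,
                           mirnaFcDown = 1.5, mirnaFcUp = 2,
                           geneFcEnrich = 2, geneFcDown = 1.5,
                           alpha = 0.05, fdrCut = 0.05, pdbCut = 0.05,
                           panelMin = 6, panelStrict = TRUE,
                           paired = FALSE) {
  cfg <- list(maxDetectCt = maxDetectCt,
              minSamplesPerGroup = minSamplesPerGroup,
              undetectedAsMissing = undetectedAsMissing,
              mirnaFcDown = mirnaFcDown, mirnaFcUp = mirnaFcUp,
              geneFcEnrich = geneFcEnrich, geneFcDown = geneFcDown,
              alpha = alpha, fdrCut = fdrCut, pdbCut = pdbCut,
              panelMin = panelMin, panelStrict = panelStrict,
              paired = paired)
  validatePipelineConfig(cfg)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

validatePipelineConfig <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop(sprintf("invalid config: %s", what),
                                          call. = FALSE)
  chk(cfg$maxDetectCt > 0, "maxDetectCt must be positive")
  chk(is.null(cfg$minSamplesPerGroup) ||
        (cfg$minSamplesPerGroup >= 1 &&
           cfg$minSamplesPerGroup == floor(cfg$minSamplesPerGroup)),
      "minSamplesPerGroup must be a whole number >= 1 or NULL")
  chk(cfg$mirnaFcDown >= 1 && cfg$mirnaFcUp >= 1 &&
        cfg$geneFcEnrich >= 1 && cfg$geneFcDown >= 1,
      "fold-change cut-offs must be >= 1")
  for (nm in c("alpha", "fdrCut", "pdbCut"))
    chk(cfg[[nm]] >= 0 && cfg[[nm]] <= 1,
        sprintf("%s must lie in [0, 1]", nm))
  chk(cfg$panelMin >= 0, "panelMin must be >= 0")
  chk(is.logical(cfg$undetectedAsMissing) && is.logical(cfg$panelStrict) &&
        is.logical(cfg$paired), "flags must be logical")
  invisible(cfg)
}

#' @rdname pipelineConfig
#' @param cfg A \code{PipelineConfig}.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' Run the integrated miRNA-mRNA analysis end to end
#'
#' Executes the stages in order: detection filter, -dCt normalization,
#' miRNA and gene differential classification, all-pairs negative-
#' correlation integration with FDR control and prediction-table
#' intersection, and network summarization. Every intermediate table is
#' returned, together with a log of feature/pair counts per stage (input =
#' kept + dropped at each filter). When the study carries a planted truth,
#' the selected pairs are also evaluated against it.
#'
#' @param study An [HscStudy-class].
#' @param config A [pipelineConfig()] list.
#' @return List with elements \code{detected} (assay ids), \code{ndct},
#'   \code{mirnaDE}, \code{geneDE}, \code{pairs}, \code{report}
#'   (a \code{SummaryReport}), \code{evaluation} (precision/recall vs truth
#'   or \code{NULL}) and \code{log} (\code{data.frame} of
#'   stage/key/value count lines).
#' @examples
#' res <- runPipeline(simulateStudy(simParams(seed = 1)))
#' res$report$class_counts
#' @export
runPipeline <- function(study, config = pipelineConfig()) {
  validatePipelineConfig(config)
  logRows <- list()
  note <- function(stage, ...) {
    kv <- c(...)
    logRows[[length(logRows) + 1]] <<- data.frame(
      stage = stage, key = names(kv), value = unname(kv),
      stringsAsFactors = FALSE)
  }
  ct <- mirnaCt(study)

  detected <- detectExpressed(ct, maxDetectCt = config$maxDetectCt,
                              minSamplesPerGroup = config$minSamplesPerGroup)
  detected <- union(detected, referenceAssay(ct))
  note("detect", input = nrow(ct), kept = length(detected),
       dropped = nrow(ct) - length(detected))

  ndct <- negDeltaCt(ct[detected, ],
                     undetectedAsMissing = config$undetectedAsMissing)
  ndct <- ndct[setdiff(rownames(ndct), referenceAssay(ct)), ]
  note("normalize", assays = nrow(ndct), samples = ncol(ndct))

  mirnaDE <- classifyMirnas(ndct, fcDown = config$mirnaFcDown,
                            fcUp = config$mirnaFcUp, alpha = config$alpha,
                            paired = config$paired)
  note("classify_mirna", input = nrow(mirnaDE),
       q_associated = sum(mirnaDE$class_label == "q_associated"),
       a_associated = sum(mirnaDE$class_label == "a_associated"),
       unchanged = sum(mirnaDE$class_label == "unchanged"))

  geneDE <- classifyGenes(geneExpr(study), fcEnrich = config$geneFcEnrich,
                          fcDown = config$geneFcDown, alpha = config$alpha,
                          paired = config$paired)
  note("classify_gene", input = nrow(geneDE),
       q_associated = sum(geneDE$class_label == "q_associated"),
       a_associated = sum(geneDE$class_label == "a_associated"),
       unchanged = sum(geneDE$class_label == "unchanged"))

  pairs <- pearsonAllPairs(ndct, geneExpr(study), mirnaDE, geneDE)
  pairs <- selectFunctionalPairs(pairs, predictionTable(study),
                                 fdrCut = config$fdrCut,
                                 pdbCut = config$pdbCut)
  note("integrate", pairs = nrow(pairs),
       selected = sum(pairs$selected),
       not_selected = nrow(pairs) - sum(pairs$selected))

  report <- summarizeNetwork(pairs, mirnaDE, geneDE,
                             panelMin = config$panelMin,
                             strict = config$panelStrict)
  note("summarize", panel = nrow(report$panel),
       covered_genes = report$coverage$n_covered)

  evaluation <- if (!is.null(regulatoryTruth(study)))
    evaluateAgainstTruth(pairs, regulatoryTruth(study)) else NULL

  list(detected = detected, ndct = ndct, mirnaDE = mirnaDE,
       geneDE = geneDE, pairs = pairs, report = report,
       evaluation = evaluation,
       log = do.call(rbind, logRows))
}

#' Evaluate selected pairs against a planted truth
#'
#' @param pairs Pair table with \code{selected} flags.
#' @param truth A [RegulatoryTruth-class] or a \code{data.frame} of true
#'   pairs (\code{mirna_id}, \code{gene_id}).
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{n_selected},
#'   \code{n_true}, \code{precision} (missing when nothing is selected),
#'   \code{recall}, \code{empirical_fdr} (1 - precision).
#' @export
evaluateAgainstTruth <- function(pairs, truth) {
  tp_df <- if (methods::is(truth, "RegulatoryTruth")) truth@pairs else truth
  trueKey <- paste(tp_df$mirna_id, tp_df$gene_id, sep = "\r")
  sel <- pairs[pairs$selected, , drop = FALSE]
  selKey <- paste(sel$mirna_id, sel$gene_id, sep = "\r")
  tp <- sum(selKey %in% trueKey)
  fp <- nrow(sel) - tp
  precision <- if (nrow(sel)) tp / nrow(sel) else NA_real_
  recall <- if (length(trueKey)) tp / length(trueKey) else NA_real_
  list(tp = tp, fp = fp, fn = length(trueKey) - tp,
       n_selected = nrow(sel), n_true = length(trueKey),
       precision = precision, recall = recall,
       empirical_fdr = if (is.na(precision)) NA_real_ else 1 - precision)
}
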