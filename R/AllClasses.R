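#' @include AllGenerics.R
NULL

#' CtExperiment: raw qPCR-array threshold cycles
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding raw Ct
#' values (assays x samples) from a TaqMan-style array, together with the
#' identity of the endogenous-control assay used for normalization and the
#' maximal cycle number at which undetermined wells are reported.
#'
#' Lower Ct means higher abundance. Undetermined wells are conventionally
#' exported at the maximal cycle (\code{maxCt}, default 40) or as \code{NA};
#' both are accepted and handled downstream by [detectExpressed()].
#'
#' @slot referenceAssay Character scalar; must match a row name.
#' @slot maxCt Numeric scalar; all finite Ct values must lie in
#'   \code{[0, maxCt]}.
#'
#' @param ct Numeric matrix of Ct values, assays in rows, samples in columns,
#'   with row and column names.
#' @param referenceAssay Row name of the endogenous control (default
#'   \code{"RNU6"}).
#' @param sampleData Optional \code{data.frame} of per-sample annotation
#'   (one row per column of \code{ct}).
#' @param maxCt Maximal cycle number (default 40).
#'
#' @return \code{CtExperiment()} returns a validated object.
#' @examples
#' ct <- rbind(RNU6 = c(20, 20), `miR-1` = c(25, 23))
#' colnames(ct) <- c("s1", "s2")
#' x <- CtExperiment(ct)
#' referenceAssay(x)
#' SummarizedExperiment::assay(negDeltaCt(x))
#' @aliases CtExperiment
#' @export CtExperiment
#' @exportClass CtExperiment
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("CtExperiment",
  contains = "SummarizedExperiment",
  slots = c(referenceAssay = "character", maxCt = "numeric")
)

setValidity("CtExperiment", function(object) {
  msg <- character()
  if (!"Ct" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'Ct' is required")
  if (length(object@referenceAssay) != 1L || is.na(object@referenceAssay))
    msg <- c(msg, "'referenceAssay' must be a single assay id")
  else if (!object@referenceAssay %in% rownames(object))
    msg <- c(msg, sprintf("reference assay '%s' not found among assay rows",
                          object@referenceAssay))
  if (length(object@maxCt) != 1L || !is.finite(object@maxCt) ||
      object@maxCt <= 0)
    msg <- c(msg, "'maxCt' must be a positive number")
  if ("Ct" %in% SummarizedExperiment::assayNames(object)) {
    v <- SummarizedExperiment::assay(object, "Ct")
    bad <- v[!is.na(v)]
    if (length(bad) && (any(bad < 0) || any(bad > object@maxCt)))
      msg <- c(msg, sprintf("Ct values must lie in [0, %g]", object@maxCt))
  }
  if (length(msg)) msg else TRUE
})

CtExperiment <- function(ct, referenceAssay = "RNU6", sampleData = NULL,
                         maxCt = 40) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must have row (assay) and column (sample) names")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate assay ids in Ct matrix")
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(ct))
  } else {
    S4Vectors::DataFrame(sampleData, row.names = colnames(ct))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(Ct = ct), colData = cd)
  methods::new("CtExperiment", se, referenceAssay = referenceAssay,
               maxCt = as.numeric(maxCt))
}

#' @rdname CtExperiment-class
#' @export
setMethod("referenceAssay", "CtExperiment", function(x) x@referenceAssay)

#' @describeIn CtExperiment-class maximal cycle number of the platform.
#' @param x,object A \code{CtExperiment}.
#' @export
maxCt <- function(x) x@maxCt

setMethod("show", "CtExperiment", function(object) {
  methods::callNextMethod()
  cat("referenceAssay:", object@referenceAssay,
      " maxCt:", object@maxCt, "\n")
})

#' RegulatoryTruth: a planted miRNA-target repression network
#'
#' Ground truth for simulated studies: which miRNAs and genes belong to the
#' quiescence-associated or activation-associated compartment, and which
#' (miRNA, gene) pairs carry a planted repressive interaction. A repressive
#' pair always links features whose planted state change goes in opposite
#' directions (a quiescence-enriched miRNA silences an activation-induced
#' gene, and vice versa).
#'
#' @slot mirnas \code{data.frame} with columns \code{mirna_id},
#'   \code{class} (\code{"q_associated"} / \code{"a_associated"}).
#' @slot genes \code{data.frame} with columns \code{gene_id},
#'   \code{class} (\code{"q_specific"} / \code{"a_associated"} /
#'   \code{"background"}).
#' @slot pairs \code{data.frame} with columns \code{mirna_id},
#'   \code{gene_id}, \code{coupling} (per-pair repression strength on the
#'   log2 scale, >= 0).
#' @aliases RegulatoryTruth
#' @export RegulatoryTruth
#' @exportClass RegulatoryTruth
setClass("RegulatoryTruth",
  slots = c(mirnas = "data.frame", genes = "data.frame", pairs = "data.frame")
)

setValidity("RegulatoryTruth", function(object) {
  msg <- character()
  m <- object@mirnas; g <- object@genes; p <- object@pairs
  if (!all(c("mirna_id", "class") %in% names(m)))
    msg <- c(msg, "'mirnas' needs columns mirna_id, class")
  if (!all(c("gene_id", "class") %in% names(g)))
    msg <- c(msg, "'genes' needs columns gene_id, class")
  if (!all(c("mirna_id", "gene_id", "coupling") %in% names(p)))
    msg <- c(msg, "'pairs' needs columns mirna_id, gene_id, coupling")
  if (length(msg)) return(msg)
  if (anyDuplicated(m$mirna_id)) msg <- c(msg, "duplicate mirna ids")
  if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicate gene ids")
  if (!all(m$class %in% c("q_associated", "a_associated")))
    msg <- c(msg, "miRNA classes must be q_associated/a_associated")
  if (!all(g$class %in% c("q_specific", "a_associated", "background")))
    msg <- c(msg, "gene classes must be q_specific/a_associated/background")
  if (nrow(p)) {
    if (anyDuplicated(p[c("mirna_id", "gene_id")]))
      msg <- c(msg, "duplicate planted pairs")
    if (!all(p$mirna_id %in% m$mirna_id) || !all(p$gene_id %in% g$gene_id))
      msg <- c(msg, "planted pairs reference unknown feature ids")
    else {
      mc <- m$class[match(p$mirna_id, m$mirna_id)]
      gc <- g$class[match(p$gene_id, g$gene_id)]
      opposite <- (mc == "q_associated" & gc == "a_associated") |
        (mc == "a_associated" & gc == "q_specific")
      if (!all(opposite))
        msg <- c(msg,
          "planted pairs must link features with opposite state changes")
    }
    if (any(!is.finite(p$coupling)) || any(p$coupling < 0))
      msg <- c(msg, "pair couplings must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

RegulatoryTruth <- function(mirnas, genes, pairs) {
  methods::new("RegulatoryTruth",
    mirnas = as.data.frame(mirnas), genes = as.data.frame(genes),
    pairs = as.data.frame(pairs))
}

#' @rdname RegulatoryTruth-class
#' @param x,object A \code{RegulatoryTruth}.
#' @export
setMethod("truePairs", "RegulatoryTruth", function(x) x@pairs)

#' @describeIn RegulatoryTruth-class per-miRNA class table.
#' @export
truthMirnas <- function(x) x@mirnas

#' @describeIn RegulatoryTruth-class per-gene class table.
#' @export
truthGenes <- function(x) x@genes

setMethod("show", "RegulatoryTruth", function(object) {
  cat(sprintf(
    "RegulatoryTruth: %d miRNAs (%d q / %d a), %d genes, %d planted pairs\n",
    nrow(object@mirnas),
    sum(object@mirnas$class == "q_associated"),
    sum(object@mirnas$class == "a_associated"),
    nrow(object@genes), nrow(object@pairs)))
})

#' HscStudy: one integrated miRNA + mRNA profiling study
#'
#' Container pairing a miRNA Ct experiment (HSC samples only) with a log2
#' gene-expression experiment (HSC plus hepatocyte and LSEC reference
#' samples), the miRNA-to-gene target-prediction table, and — for simulated
#' studies — the planted [RegulatoryTruth-class].
#'
#' @slot mirnaCt A [CtExperiment-class] over the HSC samples.
#' @slot geneExpr A [SummarizedExperiment::SummarizedExperiment] of log2
#'   expression over all samples; \code{colData} holds the sample sheet.
#' @slot predictions \code{data.frame} with columns \code{mirna_id},
#'   \code{gene_id}, \code{p_database}.
#' @slot truth A [RegulatoryTruth-class], or \code{NULL} for real data.
#' @aliases HscStudy
#' @export HscStudy
#' @exportClass HscStudy
setClass("HscStudy",
  slots = c(mirnaCt = "CtExperiment", geneExpr = "SummarizedExperiment",
            predictions = "data.frame", truth = "ANY")
)

setValidity("HscStudy", function(object) {
  msg <- character()
  sheet <- as.data.frame(SummarizedExperiment::colData(object@geneExpr))
  need <- c("sample_id", "cell_type", "state", "donor_id")
  if (!all(need %in% names(sheet)))
    return(sprintf("geneExpr colData must contain %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(sheet$sample_id)) msg <- c(msg, "duplicate sample ids")
  hsc <- sheet$cell_type == "HSC"
  if (any(is.na(sheet$state[hsc])))
    msg <- c(msg, "every HSC sample needs an activation state")
  if (!all(colnames(object@mirnaCt) %in% sheet$sample_id))
    msg <- c(msg, "miRNA Ct samples missing from the sample sheet")
  if (nrow(object@predictions) &&
      !all(c("mirna_id", "gene_id", "p_database") %in%
           names(object@predictions)))
    msg <- c(msg, "predictions need columns mirna_id, gene_id, p_database")
  if (!is.null(object@truth) && !methods::is(object@truth, "RegulatoryTruth"))
    msg <- c(msg, "'truth' must be NULL or a RegulatoryTruth")
  if (length(msg)) msg else TRUE
})

HscStudy <- function(mirnaCt, geneExpr, predictions =
                       data.frame(mirna_id = character(),
                                  gene_id = character(),
                                  p_database = numeric()),
                     truth = NULL) {
  methods::new("HscStudy", mirnaCt = mirnaCt, geneExpr = geneExpr,
               predictions = as.data.frame(predictions), truth = truth)
}

#' @rdname HscStudy-class
#' @param x,object An \code{HscStudy}.
#' @export
setMethod("mirnaCt", "HscStudy", function(x) x@mirnaCt)

#' @rdname HscStudy-class
#' @export
setMethod("geneExpr", "HscStudy", function(x) x@geneExpr)

#' @rdname HscStudy-class
#' @export
setMethod("predictionTable", "HscStudy", function(x) x@predictions)

#' @rdname HscStudy-class
#' @export
setMethod("regulatoryTruth", "HscStudy", function(x) x@truth)

#' @rdname HscStudy-class
#' @export
setMethod("truePairs", "HscStudy", function(x) {
  if (is.null(x@truth)) stop("study carries no regulatory truth")
  x@truth@pairs
})

#' @rdname HscStudy-class
#' @export
setMethod("sampleSheet", "HscStudy", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x@geneExpr))
  rownames(df) <- NULL
  df
})

setMethod("show", "HscStudy", function(object) {
  sheet <- sampleSheet(object)
  cat(sprintf(
    paste0("HscStudy: %d miRNA assays x %d HSC samples; ",
           "%d genes x %d samples (%s)\n"),
    nrow(object@mirnaCt), ncol(object@mirnaCt),
    nrow(object@geneExpr), ncol(object@geneExpr),
    paste(sprintf("%d %s", table(sheet$cell_type),
                  names(table(sheet$cell_type))), collapse = ", ")))
  cat(sprintf("  prediction table: %d pairs; truth: %s\n",
              nrow(object@predictions),
              if (is.null(object@truth)) "none" else "planted"))
})
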