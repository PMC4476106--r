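#' @title Package generics
#' @description Generics for the core data containers.
#' @name miRTargetCor-generics
#' @keywords internal
NULL

#' Reference assay identifier of a Ct experiment
#'
#' @param x A [CtExperiment-class].
#' @return Character scalar, the row name of the endogenous-control assay
#'   (e.g. \code{"RNU6"}) every other assay is normalized against.
#' @export
setGeneric("referenceAssay", function(x) standardGeneric("referenceAssay"))

#' Reference-normalized abundance (-dCt)
#'
#' Computes \eqn{-\Delta Ct = -(Ct_{assay} - Ct_{reference})} per sample, a
#' log2-scale abundance relative to the endogenous control.
#'
#' @param x A [CtExperiment-class].
#' @param ... Further arguments passed to methods.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"negDeltaCt"}; the reference row itself maps to 0 in every sample.
#' @export
setGeneric("negDeltaCt", function(x, ...) standardGeneric("negDeltaCt"))

#' Sample annotation sheet
#'
#' @param x An object carrying per-sample annotation (cell type, activation
#'   state, donor).
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{cell_type}, \code{state}, \code{donor_id}.
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' Planted miRNA-target pairs of a regulatory truth
#'
#' @param x A [RegulatoryTruth-class] or [HscStudy-class].
#' @return \code{data.frame} with columns \code{mirna_id}, \code{gene_id},
#'   \code{coupling}.
#' @export
setGeneric("truePairs", function(x) standardGeneric("truePairs"))

#' @rdname HscStudy-class
#' @export
setGeneric("mirnaCt", function(x) standardGeneric("mirnaCt"))

#' @rdname HscStudy-class
#' @export
setGeneric("geneExpr", function(x) standardGeneric("geneExpr"))

#' @rdname HscStudy-class
#' @export
setGeneric("regulatoryTruth", function(x) standardGeneric("regulatoryTruth"))

#' @rdname HscStudy-class
#' @export
setGeneric("predictionTable", function(x) standardGeneric("predictionTable"))
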