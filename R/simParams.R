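#' SimParams: configuration of the synthetic HSC study generator
#'
#' All knobs of the simulated paired-donor quiescent/activated HSC study.
#' Defaults describe the study design the generator emulates: 4 donors each
#' contributing one quiescent and one culture-activated HSC sample, 2
#' hepatocyte and 3 LSEC reference samples, a miRNA compartment in which
#' quiescence-enriched miRNAs each repress many activation-induced genes
#' (Poisson mean 15 targets) while activation-enriched miRNAs repress few
#' (mean 1.5), a planted state effect of 3 log2 units, and Gaussian noise of
#' 0.25 SD on the -dCt / log2 scale.
#'
#' @slot nDonors Donors; each contributes a quiescent and an activated HSC
#'   sample.
#' @slot nMirnaQ,nMirnaA Numbers of quiescence- / activation-enriched miRNAs.
#' @slot nMirnaAbsent miRNA assays planted as undetected (Ct at \code{maxCt})
#'   to exercise the detection filter.
#' @slot nGenesQ,nGenesA,nGenesBg qHSC-specific, activation-induced and
#'   background (state-independent) genes.
#' @slot nHepatocytes,nLsec Reference-cell sample counts.
#' @slot targetsPerQMirna,targetsPerAMirna Mean planted target counts per
#'   miRNA class; drawn Poisson (or fixed, see \code{targetsDistribution}).
#' @slot targetsDistribution \code{"poisson"} or \code{"fixed"} (every miRNA
#'   gets exactly the stated count, which must then be a whole number).
#' @slot effectLog2 Planted state fold change, log2 scale.
#' @slot noiseSd SD of additive Gaussian noise on the -dCt / log2 scale.
#' @slot donorSd SD of the per-miRNA, per-sample latent term shared (with
#'   opposite sign) between a miRNA and its planted targets; induces
#'   within-group miRNA-target correlation beyond the group-mean contrast.
#' @slot coupling Fraction of the miRNA latent term transmitted (negated) to
#'   each planted target.
#' @slot mirnaBase,geneBase Baseline -dCt / log2-expression levels.
#' @slot refCt Mean Ct of the endogenous control (state-independent).
#' @slot refNoiseSd Measurement noise SD of the endogenous control.
#' @slot sampleShiftSd SD of a per-sample global Ct shift (loading
#'   differences); removed by -dCt normalization.
#' @slot maxCt Cycle number reported for undetected wells.
#' @slot dbSensitivity Probability a true pair is listed with
#'   \code{p_database} < 0.05.
#' @slot dbFpr Probability a non-pair is listed with \code{p_database} < 0.05.
#' @slot dbNonsigCoverage Probability a non-pair is listed with a
#'   non-significant \code{p_database}.
#' @slot seed Integer seed; all stages derive deterministic child streams.
#'
#' @param ... Named values overriding the defaults listed above.
#' @return \code{simParams()} returns a validated \code{SimParams} object.
#' @examples
#' p <- simParams(nDonors = 4, seed = 7)
#' p
#' @aliases SimParams
#' @export simParams
#' @exportClass SimParams
setClass("SimParams",
  representation(
    nDonors = "numeric", nMirnaQ = "numeric", nMirnaA = "numeric",
    nMirnaAbsent = "numeric", nGenesQ = "numeric", nGenesA = "numeric",
    nGenesBg = "numeric", nHepatocytes = "numeric", nLsec = "numeric",
    targetsPerQMirna = "numeric", targetsPerAMirna = "numeric",
    targetsDistribution = "character",
    effectLog2 = "numeric", noiseSd = "numeric", donorSd = "numeric",
    coupling = "numeric", mirnaBase = "numeric", geneBase = "numeric",
    refCt = "numeric", refNoiseSd = "numeric", sampleShiftSd = "numeric",
    maxCt = "numeric", dbSensitivity = "numeric", dbFpr = "numeric",
    dbNonsigCoverage = "numeric", seed = "numeric"),
  prototype(
    nDonors = 4, nMirnaQ = 20, nMirnaA = 30, nMirnaAbsent = 10,
    nGenesQ = 60, nGenesA = 200, nGenesBg = 140,
    nHepatocytes = 2, nLsec = 3,
    targetsPerQMirna = 15, targetsPerAMirna = 1.5,
    targetsDistribution = "poisson",
    effectLog2 = 3, noiseSd = 0.25, donorSd = 0.3, coupling = 0.5,
    mirnaBase = -5, geneBase = 6,
    refCt = 20, refNoiseSd = 0.05, sampleShiftSd = 0.3, maxCt = 40,
    dbSensitivity = 0.9, dbFpr = 0.01, dbNonsigCoverage = 0.05, seed = 1)
)

setValidity("SimParams", function(object) {
  msg <- character()
  counts <- c(nDonors = object@nDonors, nMirnaQ = object@nMirnaQ,
              nMirnaA = object@nMirnaA, nGenesQ = object@nGenesQ,
              nGenesA = object@nGenesA,
              nHepatocytes = object@nHepatocytes, nLsec = object@nLsec)
  bad <- counts < 1 | counts != floor(counts)
  if (any(bad))
    msg <- c(msg, sprintf("counts must be whole numbers >= 1: %s",
                          paste(names(counts)[bad], collapse = ", ")))
  extras <- c(nMirnaAbsent = object@nMirnaAbsent,
              nGenesBg = object@nGenesBg)
  if (any(extras < 0 | extras != floor(extras)))
    msg <- c(msg, "nMirnaAbsent and nGenesBg must be whole numbers >= 0")
  probs <- c(dbSensitivity = object@dbSensitivity, dbFpr = object@dbFpr,
             dbNonsigCoverage = object@dbNonsigCoverage)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "database probabilities must lie in [0, 1]")
  sds <- c(noiseSd = object@noiseSd, donorSd = object@donorSd,
           refNoiseSd = object@refNoiseSd,
           sampleShiftSd = object@sampleShiftSd)
  if (any(sds < 0)) msg <- c(msg, "standard deviations must be >= 0")
  if (object@targetsPerQMirna < 0 || object@targetsPerAMirna < 0)
    msg <- c(msg, "mean target counts must be >= 0")
  if (!object@targetsDistribution %in% c("poisson", "fixed"))
    msg <- c(msg, "targetsDistribution must be 'poisson' or 'fixed'")
  if (object@targetsDistribution == "fixed" &&
      (object@targetsPerQMirna != floor(object@targetsPerQMirna) ||
       object@targetsPerAMirna != floor(object@targetsPerAMirna)))
    msg <- c(msg, "fixed target counts must be whole numbers")
  if (object@coupling < 0) msg <- c(msg, "coupling must be >= 0")
  if (object@maxCt <= 0) msg <- c(msg, "maxCt must be positive")
  if (length(object@seed) != 1 || !is.finite(object@seed))
    msg <- c(msg, "seed must be a single finite number")
  if (length(msg)) msg else TRUE
})

simParams <- function(...) {
  methods::new("SimParams", ...)
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    paste0("SimParams: %d donors (paired q/a HSC), %d+%d hep/LSEC; ",
           "%d q-miRNAs (~%g targets), %d a-miRNAs (~%g targets), ",
           "%d undetected;\n  genes %d q / %d a / %d bg; ",
           "effect=%g log2, noise=%g, donorSd=%g; db sens=%g fpr=%g; ",
           "seed=%d\n"),
    object@nDonors, object@nHepatocytes, object@nLsec,
    object@nMirnaQ, object@targetsPerQMirna,
    object@nMirnaA, object@targetsPerAMirna, object@nMirnaAbsent,
    object@nGenesQ, object@nGenesA, object@nGenesBg,
    object@effectLog2, object@noiseSd, object@donorSd,
    object@dbSensitivity, object@dbFpr, as.integer(object@seed)))
})
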