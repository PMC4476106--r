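#' Generate a planted miRNA-target repression network
#'
#' Draws the ground-truth regulatory structure of a synthetic HSC study:
#' quiescence-enriched miRNAs repress activation-induced genes (many targets
#' each), activation-enriched miRNAs repress qHSC-specific genes (few targets
#' each). Target counts come from a Poisson distribution with the class mean
#' (or are fixed, see [simParams()]); targets are sampled without replacement
#' from the opposite-class gene pool.
#'
#' @param params A [SimParams-class].
#' @return A [RegulatoryTruth-class]. Deterministic given \code{params@seed}.
#' @examples
#' truth <- generateTruth(simParams(seed = 1))
#' truth
#' @export
generateTruth <- function(params) {
  methods::validObject(params)
  mirnas <- data.frame(
    mirna_id = c(sprintf("miR-Q%02d", seq_len(params@nMirnaQ)),
                 sprintf("miR-A%02d", seq_len(params@nMirnaA))),
    class = rep(c("q_associated", "a_associated"),
                c(params@nMirnaQ, params@nMirnaA)),
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c(sprintf("GENEQ%03d", seq_len(params@nGenesQ)),
                sprintf("GENEA%03d", seq_len(params@nGenesA)),
                if (params@nGenesBg > 0)
                  sprintf("GENEB%03d", seq_len(params@nGenesBg))),
    class = rep(c("q_specific", "a_associated", "background"),
                c(params@nGenesQ, params@nGenesA, params@nGenesBg)),
    stringsAsFactors = FALSE)

  withr::with_seed(childSeed(params@seed, 1L), {
    drawCounts <- function(n, mean) {
      if (params@targetsDistribution == "fixed") rep(as.integer(mean), n)
      else stats::rpois(n, mean)
    }
    nq <- drawCounts(params@nMirnaQ, params@targetsPerQMirna)
    na <- drawCounts(params@nMirnaA, params@targetsPerAMirna)
    counts <- c(nq, na)
    pool <- list(q_associated = genes$gene_id[genes$class == "a_associated"],
                 a_associated = genes$gene_id[genes$class == "q_specific"])
    pairs <- vector("list", nrow(mirnas))
    for (i in seq_len(nrow(mirnas))) {
      avail <- pool[[mirnas$class[i]]]
      if (counts[i] > length(avail))
        stop(sprintf(
          "miRNA %s requests %d targets but only %d opposite-class genes exist (shortfall %d)",
          mirnas$mirna_id[i], counts[i], length(avail),
          counts[i] - length(avail)))
      if (counts[i] > 0)
        pairs[[i]] <- data.frame(
          mirna_id = mirnas$mirna_id[i],
          gene_id = sample(avail, counts[i]),
          coupling = params@coupling,
          stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pairs) %||% data.frame(
      mirna_id = character(), gene_id = character(), coupling = numeric())
    rownames(pairs) <- NULL
    RegulatoryTruth(mirnas, genes, pairs)
  })
}

# Sample sheet of the emulated design: paired q/a HSC samples per donor,
# plus hepatocyte and LSEC reference samples.
buildSampleSheet <- function(params) {
  donors <- sprintf("D%d", seq_len(params@nDonors))
  hsc <- data.frame(
    sample_id = c(paste0("qHSC_", donors), paste0("aHSC_", donors)),
    cell_type = "HSC",
    state = rep(c("quiescent", "activated"), each = params@nDonors),
    donor_id = rep(donors, 2),
    stringsAsFactors = FALSE)
  hep <- data.frame(
    sample_id = sprintf("HEP_%d", seq_len(params@nHepatocytes)),
    cell_type = "hepatocyte", state = NA_character_,
    donor_id = sprintf("H%d", seq_len(params@nHepatocytes)))
  lsec <- data.frame(
    sample_id = sprintf("LSEC_%d", seq_len(params@nLsec)),
    cell_type = "LSEC", state = NA_character_,
    donor_id = sprintf("L%d", seq_len(params@nLsec)))
  rbind(hsc, hep, lsec)
}

#' Generate expression data for a planted regulatory network
#'
#' Simulates the two expression layers of the study: (i) a miRNA Ct matrix
#' over the paired HSC samples, on the raw cycle scale with the endogenous
#' control included and a per-sample loading shift, so the -dCt
#' normalization stage is exercised; (ii) a log2 gene-expression matrix over
#' HSC, hepatocyte and LSEC samples, with qHSC-specific genes elevated only
#' in quiescent HSCs and activation-induced genes only in activated HSCs.
#'
#' Planted effects shift group means by \code{effectLog2} in the planted
#' direction. Each truth miRNA additionally carries a per-sample latent term
#' (SD \code{donorSd}) transmitted with opposite sign and weight
#' \code{coupling} to its planted targets, so true pairs are anticorrelated
#' beyond the group-mean contrast. Additive Gaussian noise
#' (SD \code{noiseSd}) acts on the -dCt / log2 scale.
#'
#' @param truth A [RegulatoryTruth-class] from [generateTruth()].
#' @param params The same [SimParams-class] used to generate \code{truth}.
#' @return A list with elements \code{mirnaCt} ([CtExperiment-class]),
#'   \code{geneExpr} (\code{SummarizedExperiment}) and \code{sheet}
#'   (sample-sheet \code{data.frame}).
#' @export
generateExpression <- function(truth, params) {
  methods::validObject(params)
  sheet <- buildSampleSheet(params)
  hsc <- sheet[sheet$cell_type == "HSC", ]
  nHsc <- nrow(hsc)
  isQ <- hsc$state == "quiescent"

  mir <- truth@mirnas
  gen <- truth@genes

  withr::with_seed(childSeed(params@seed, 2L), {
    # latent per-miRNA, per-HSC-sample term shared with planted targets
    latent <- matrix(stats::rnorm(nrow(mir) * nHsc, 0, params@donorSd),
                     nrow(mir), nHsc,
                     dimnames = list(mir$mirna_id, hsc$sample_id))

    # miRNA abundance on the -dCt ("true") scale
    ndct <- matrix(params@mirnaBase, nrow(mir), nHsc,
                   dimnames = dimnames(latent))
    ndct[mir$class == "q_associated", isQ] <-
      ndct[mir$class == "q_associated", isQ] + params@effectLog2
    ndct[mir$class == "a_associated", !isQ] <-
      ndct[mir$class == "a_associated", !isQ] + params@effectLog2
    ndct <- ndct + latent +
      matrix(stats::rnorm(length(ndct), 0, params@noiseSd),
             nrow(ndct), ncol(ndct))

    # gene expression, log2 scale, all samples
    expr <- matrix(params@geneBase, nrow(gen), nrow(sheet),
                   dimnames = list(gen$gene_id, sheet$sample_id))
    qCols <- sheet$sample_id[!is.na(sheet$state) &
                               sheet$state == "quiescent"]
    aCols <- sheet$sample_id[!is.na(sheet$state) &
                               sheet$state == "activated"]
    expr[gen$class == "q_specific", qCols] <-
      expr[gen$class == "q_specific", qCols] + params@effectLog2
    expr[gen$class == "a_associated", aCols] <-
      expr[gen$class == "a_associated", aCols] + params@effectLog2
    pr <- truth@pairs
    for (k in seq_len(nrow(pr)))
      expr[pr$gene_id[k], hsc$sample_id] <-
        expr[pr$gene_id[k], hsc$sample_id] -
        pr$coupling[k] * latent[pr$mirna_id[k], ]
    expr <- expr + matrix(stats::rnorm(length(expr), 0, params@noiseSd),
                          nrow(expr), ncol(expr))

    # back-transform miRNAs to the Ct scale with a per-sample loading shift;
    # the endogenous control is state-independent with small measurement noise
    shift <- stats::rnorm(nHsc, 0, params@sampleShiftSd)
    refObs <- params@refCt + shift + stats::rnorm(nHsc, 0, params@refNoiseSd)
    ct <- sweep(-ndct, 2, params@refCt + shift, `+`)
    if (params@nMirnaAbsent > 0) {
      absent <- matrix(params@maxCt, params@nMirnaAbsent, nHsc,
                       dimnames = list(
                         sprintf("miR-X%02d", seq_len(params@nMirnaAbsent)),
                         hsc$sample_id))
      ct <- rbind(ct, absent)
    }
    ct <- rbind(ct, RNU6 = refObs)
    ct <- pmin(pmax(ct, 0), params@maxCt)

    mirnaCt <- CtExperiment(ct, referenceAssay = "RNU6",
                            sampleData = hsc, maxCt = params@maxCt)
    geneExpr <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = expr),
      colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample_id))
    list(mirnaCt = mirnaCt, geneExpr = geneExpr, sheet = sheet)
  })
}

#' Generate a MicroCosm-style target-prediction table
#'
#' Emulates a sequence-based prediction database: every planted pair is
#' listed, with \code{p_database} significant (< 0.05) with probability
#' \code{dbSensitivity}; each non-pair is listed significant with
#' probability \code{dbFpr} and listed non-significant with probability
#' \code{dbNonsigCoverage}. Significant p-values are drawn uniformly from
#' [0.001, 0.049] and non-significant ones from [0.051, 0.999], so the 0.05
#' threshold is never ambiguous.
#'
#' @param truth A [RegulatoryTruth-class].
#' @param params A [SimParams-class].
#' @return \code{data.frame} with columns \code{mirna_id}, \code{gene_id},
#'   \code{p_database}. Deterministic given \code{params@seed}.
#' @export
generatePredictionTable <- function(truth, params) {
  methods::validObject(params)
  withr::with_seed(childSeed(params@seed, 3L), {
    mir <- truth@mirnas$mirna_id
    gen <- truth@genes$gene_id
    all <- expand.grid(mirna_id = mir, gene_id = gen,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(all$mirna_id, all$gene_id, sep = "\r")
    trueKey <- paste(truth@pairs$mirna_id, truth@pairs$gene_id, sep = "\r")
    isTrue <- key %in% trueKey
    u <- stats::runif(nrow(all))
    sig <- ifelse(isTrue, u < params@dbSensitivity, u < params@dbFpr)
    listed <- isTrue | sig |
      (stats::runif(nrow(all)) < params@dbNonsigCoverage & !isTrue)
    p <- numeric(nrow(all))
    p[sig] <- stats::runif(sum(sig), 0.001, 0.049)
    p[!sig] <- stats::runif(sum(!sig), 0.051, 0.999)
    out <- all[listed, ]
    out$p_database <- p[listed]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete synthetic HSC study
#'
#' Convenience wrapper chaining [generateTruth()], [generateExpression()] and
#' [generatePredictionTable()] into one [HscStudy-class] carrying its planted
#' truth.
#'
#' @param params A [SimParams-class]; see [simParams()] for the study design
#'   the defaults emulate.
#' @return An [HscStudy-class].
#' @examples
#' study <- simulateStudy(simParams(seed = 1))
#' study
#' @export
simulateStudy <- function(params = simParams()) {
  truth <- generateTruth(params)
  ex <- generateExpression(truth, params)
  pred <- generatePredictionTable(truth, params)
  HscStudy(mirnaCt = ex$mirnaCt, geneExpr = ex$geneExpr,
           predictions = pred, truth = truth)
}
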