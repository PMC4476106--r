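#' Read an expression or Ct matrix from TSV
#'
#' Expects a tab-separated file with feature ids in the first column and a
#' header row of sample ids. Empty cells and the token \code{NA} are read as
#' missing; any other non-numeric cell is an error naming the offending row
#' and column.
#'
#' @param path File path.
#' @return Numeric matrix, features in rows.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                          colClasses = "character",
                          na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("expected a feature-id column plus sample columns")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate feature id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  num <- matrix(num, nrow = length(ids),
                dimnames = list(ids, colnames(vals)))
  num
}

#' Write an expression or Ct matrix to TSV
#'
#' @param x Numeric matrix, features in rows.
#' @param path File path.
#' @param idColumn Header of the feature-id column (default
#'   \code{"feature_id"}).
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Tab-separated with columns \code{sample_id}, \code{cell_type},
#' \code{state}, \code{donor_id}. Sample ids must be unique and every HSC
#' sample must carry an activation state.
#'
#' @param path File path.
#' @return \code{readSampleSheet}: a validated \code{data.frame}.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("", "NA", "n/a"))
  need <- c("sample_id", "cell_type", "state", "donor_id")
  if (!all(need %in% names(df)))
    stop(sprintf("sample sheet needs columns: %s",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  hsc <- df$cell_type == "HSC"
  if (any(is.na(df$state[hsc])))
    stop("every HSC sample needs a state")
  df
}

#' @rdname readSampleSheet
#' @param sheet Sample-sheet \code{data.frame}.
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read / write a target-prediction table
#'
#' Tab-separated with columns \code{mirna_id}, \code{gene_id},
#' \code{p_database} (each p in [0, 1]; pairs unique).
#'
#' @param path File path.
#' @return \code{readPredictionTable}: a validated \code{data.frame}.
#' @export
readPredictionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "p_database")
  if (!all(need %in% names(df)))
    stop(sprintf("prediction table needs columns: %s",
                 paste(need, collapse = ", ")))
  stopIfNotProb(df$p_database, "p_database")
  if (anyDuplicated(df[c("mirna_id", "gene_id")]))
    stop("duplicate (mirna_id, gene_id) pairs")
  df
}

#' @rdname readPredictionTable
#' @param predictions Prediction \code{data.frame}.
#' @export
writePredictionTable <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Parse one printed numeric token: decimal commas ("22,55"), and
# middle-dot scientific notation ("2.06·10–5", en dash or hyphen, comma or
# dot mantissa). Errors name the token.
parsePrintedNumber <- function(tok) {
  tok <- trimws(tok)
  raw <- tok
  if (grepl("·10", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "·10", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed numeric token '%s'", raw))
    mant <- suppressWarnings(as.numeric(gsub(",", ".", parts[1], fixed = TRUE)))
    expo <- suppressWarnings(as.numeric(
      gsub("–", "-", gsub("−", "-", parts[2]))))
    if (is.na(mant) || is.na(expo))
      stop(sprintf("malformed numeric token '%s'", raw))
    return(mant * 10^expo)
  }
  val <- suppressWarnings(as.numeric(gsub(",", ".", tok, fixed = TRUE)))
  if (is.na(val)) stop(sprintf("malformed numeric token '%s'", raw))
  val
}

#' Parse a printed quiescent-miRNA panel table
#'
#' Faithful parser for the as-printed panel of quiescence-enriched miRNAs
#' (miRNA id, linear fold change q vs a, p-value, number of deregulated
#' predicted target genes). Printed dialects are accepted: decimal commas
#' ("22,55" is 22.55, "5643,5" is 5643.5) and middle-dot scientific
#' notation ("2.06·10–5" is 2.06e-5, with comma mantissas allowed). A
#' bundled fixture of the 31-row panel ships in
#' \code{system.file("extdata", "table1_qhsc_panel.txt",
#' package = "miRTargetCor")}, together with a normalized plain-decimal
#' form (\code{table1_qhsc_panel_normalized.tsv}).
#'
#' @param path File path (tab-separated, header
#'   \code{miRNA / FC_Q_vs_A / p_value / n_targets}).
#' @return \code{data.frame} with columns \code{mirna_id},
#'   \code{fc_q_vs_a}, \code{p_value}, \code{n_targets} (integer).
#' @examples
#' panel <- parsePanelTable(system.file("extdata", "table1_qhsc_panel.txt",
#'                                      package = "miRTargetCor"))
#' nrow(panel)  # 31
#' @export
parsePanelTable <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) != 4)
    stop("expected 4 columns: miRNA, fold change, p-value, target count")
  fc <- vapply(df[[2]], parsePrintedNumber, numeric(1), USE.NAMES = FALSE)
  p <- vapply(df[[3]], parsePrintedNumber, numeric(1), USE.NAMES = FALSE)
  nt <- vapply(df[[4]], parsePrintedNumber, numeric(1), USE.NAMES = FALSE)
  if (any(nt != floor(nt)) || any(nt < 0))
    stop("target counts must be non-negative whole numbers")
  if (any(fc <= 0)) stop("fold changes must be positive")
  stopIfNotProb(p, "p-values")
  data.frame(mirna_id = df[[1]], fc_q_vs_a = fc, p_value = p,
             n_targets = as.integer(nt), stringsAsFactors = FALSE)
}

#' Write / read a regulatory-truth sidecar (JSON)
#'
#' The synthetic-data module records its planted network as a JSON sidecar
#' so downstream evaluation never depends on R objects.
#'
#' @param truth A [RegulatoryTruth-class].
#' @param path File path.
#' @return \code{writeTruthSidecar}: \code{path} invisibly;
#'   \code{readTruthSidecar}: a [RegulatoryTruth-class].
#' @export
writeTruthSidecar <- function(truth, path) {
  jsonlite::write_json(
    list(mirnas = truth@mirnas, genes = truth@genes, pairs = truth@pairs),
    path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname writeTruthSidecar
#' @export
readTruthSidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- as.data.frame(x$pairs)
  if (!nrow(pairs))
    pairs <- data.frame(mirna_id = character(), gene_id = character(),
                        coupling = numeric())
  RegulatoryTruth(as.data.frame(x$mirnas), as.data.frame(x$genes), pairs)
}

#' Export / import a study as plain-text tables
#'
#' Writes the miRNA Ct matrix, gene expression matrix, sample sheet and
#' prediction table as TSV plus (for simulated studies) the truth sidecar
#' JSON; \code{readStudy()} reassembles the [HscStudy-class].
#'
#' @param study An [HscStudy-class].
#' @param dir Directory (created if needed).
#' @param referenceAssay,maxCt Passed to [CtExperiment()] on import.
#' @return The directory (invisibly) / the reassembled study.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(SummarizedExperiment::assay(mirnaCt(study), "Ct"),
                        file.path(dir, "mirna_ct.tsv"), idColumn = "assay_id")
  writeExpressionMatrix(SummarizedExperiment::assay(geneExpr(study)),
                        file.path(dir, "gene_expr.tsv"), idColumn = "gene_id")
  writeSampleSheet(sampleSheet(study), file.path(dir, "sample_sheet.tsv"))
  writePredictionTable(predictionTable(study),
                       file.path(dir, "predictions.tsv"))
  if (!is.null(regulatoryTruth(study)))
    writeTruthSidecar(regulatoryTruth(study), file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname writeStudy
#' @export
readStudy <- function(dir, referenceAssay = "RNU6", maxCt = 40) {
  sheet <- readSampleSheet(file.path(dir, "sample_sheet.tsv"))
  ct <- readExpressionMatrix(file.path(dir, "mirna_ct.tsv"))
  expr <- readExpressionMatrix(file.path(dir, "gene_expr.tsv"))
  hsc <- sheet[match(colnames(ct), sheet$sample_id), ]
  mirnaCt <- CtExperiment(ct, referenceAssay = referenceAssay,
                          sampleData = hsc, maxCt = maxCt)
  geneExpr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = expr),
    colData = S4Vectors::DataFrame(
      sheet[match(colnames(expr), sheet$sample_id), ],
      row.names = colnames(expr)))
  truthPath <- file.path(dir, "truth.json")
  HscStudy(mirnaCt = mirnaCt, geneExpr = geneExpr,
           predictions = readPredictionTable(
             file.path(dir, "predictions.tsv")),
           truth = if (file.exists(truthPath))
             readTruthSidecar(truthPath) else NULL)
}
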