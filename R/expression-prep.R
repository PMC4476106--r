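#' @include AllClasses.R
NULL

#' @describeIn negDeltaCt Reference-normalize a Ct experiment.
#'
#' @param undetectedAsMissing Logical; if \code{TRUE}, Ct values at the
#'   platform maximum (\code{maxCt}) are treated as undetected and mapped to
#'   \code{NA} instead of a numeric -dCt. Array exports differ in whether
#'   undetermined wells are written as the maximal cycle or left blank; both
#'   policies are supported.
#' @export
setMethod("negDeltaCt", "CtExperiment",
  function(x, undetectedAsMissing = FALSE) {
    ct <- SummarizedExperiment::assay(x, "Ct")
    ref <- ct[x@referenceAssay, ]
    if (any(is.na(ref)))
      stop(sprintf("reference assay '%s' missing in sample(s): %s",
                   x@referenceAssay,
                   paste(colnames(ct)[is.na(ref)], collapse = ", ")))
    if (undetectedAsMissing)
      ct[ct >= x@maxCt] <- NA
    ndct <- sweep(-ct, 2, ref, `+`)  # -(Ct_assay - Ct_ref)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(negDeltaCt = ndct),
      colData = SummarizedExperiment::colData(x))
  })

#' Detection filter for qPCR-array assays
#'
#' Keeps an assay if its Ct is at or below \code{maxDetectCt} in at least
#' \code{minSamplesPerGroup} samples of at least one group — the standard
#' TaqMan-array practice of requiring consistent detection within a
#' biological group before testing.
#'
#' @param ct A [CtExperiment-class] or a numeric Ct matrix.
#' @param groups A list of character vectors of sample ids (or a factor /
#'   vector over columns) partitioning the samples into groups. For a
#'   \code{CtExperiment} whose \code{colData} has a \code{state} column the
#'   default groups samples by state.
#' @param maxDetectCt Detection threshold on the cycle scale (default 35).
#' @param minSamplesPerGroup Minimum detected samples within a group;
#'   default \code{ceiling(n_group / 2)} per group.
#' @return Character vector of detected assay ids (reference assay included
#'   when detected). The reference assay must itself be detected everywhere
#'   for normalization; [negDeltaCt()] enforces that separately.
#' @examples
#' ct <- rbind(RNU6 = c(20, 20, 20, 20),
#'             `miR-1` = c(25, 26, 40, 40),
#'             `miR-2` = c(40, 40, 40, 40))
#' colnames(ct) <- c("q1", "q2", "a1", "a2")
#' detectExpressed(ct, groups = list(q = c("q1", "q2"), a = c("a1", "a2")))
#' @export
detectExpressed <- function(ct, groups = NULL, maxDetectCt = 35,
                            minSamplesPerGroup = NULL) {
  if (methods::is(ct, "CtExperiment")) {
    if (is.null(groups)) {
      st <- SummarizedExperiment::colData(ct)$state
      if (is.null(st))
        stop("no 'groups' given and colData has no 'state' column")
      groups <- split(colnames(ct), st)
    }
    ct <- SummarizedExperiment::assay(ct, "Ct")
  }
  if (is.factor(groups) || (is.atomic(groups) && !is.list(groups)))
    groups <- split(colnames(ct), groups)
  if (!length(groups) || any(!lengths(groups)))
    stop("every group must contain at least one sample")
  bad <- setdiff(unlist(groups), colnames(ct))
  if (length(bad))
    stop(sprintf("unknown sample id(s): %s", paste(bad, collapse = ", ")))
  detected <- !is.na(ct) & ct <= maxDetectCt
  keep <- rep(FALSE, nrow(ct))
  for (g in groups) {
    need <- minSamplesPerGroup %||% ceiling(length(g) / 2)
    keep <- keep | rowSums(detected[, g, drop = FALSE]) >= need
  }
  rownames(ct)[keep]
}

#' Signed fold-change convention
#'
#' Linear ratios of at least 1 are reported as-is; ratios below 1 as the
#' negative reciprocal, so a relative expression of 0.68 is printed as a
#' fold change of -1.47. Values never fall in the open interval (-1, 1).
#'
#' @param fc Numeric vector of linear fold changes (> 0).
#' @return Numeric vector of signed fold changes.
#' @examples
#' signedFoldChange(c(8, 1, 0.68))
#' @export
signedFoldChange <- function(fc) {
  if (any(!is.na(fc) & fc <= 0))
    stop("linear fold changes must be positive")
  ifelse(fc >= 1, fc, -1 / fc)
}

#' Two-sided Student t-test with zero-variance conventions
#'
#' Classic equal-variance (pooled) two-sided t-test. When the pooled
#' variance is exactly zero the test statistic is undefined; the documented
#' convention is p = 1 for equal group means and p = 0 for unequal means.
#'
#' @param a,b Numeric vectors (each at least 2 non-missing values for a
#'   p-value; otherwise \code{NA} is returned).
#' @param paired Logical; paired test (donor-matched design). Default
#'   \code{FALSE}: the group-mean fold-change formulation treats groups as
#'   independent.
#' @return Two-sided p-value in [0, 1], or \code{NA}.
#' @examples
#' studentTTest(c(1, 2, 3), c(3, 1, 2))  # identical sets -> variance > 0
#' studentTTest(c(0, 0), c(5, 5))        # zero variance, unequal means
#' @export
studentTTest <- function(a, b, paired = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (paired && length(a) != length(b))
    stop("paired test requires equal group sizes")
  if (paired) {
    d <- a - b
    if (stats::var(d) == 0) return(if (mean(d) == 0) 1 else 0)
    return(stats::t.test(a, b, paired = TRUE)$p.value)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Per-feature group fold change and significance
#'
#' Fold changes are computed from the means of each group on the log2 /
#' -dCt scale and then exponentiated:
#' \eqn{FC = 2^{\bar x_A - \bar x_B}}. Significance is a two-sided Student
#' t-test per feature. Missing values are dropped per feature; a group with
#' fewer than 2 observed values yields a missing p-value (the fold change is
#' still computed when at least one value is present).
#'
#' @param x Numeric matrix (features x samples) on a log2-compatible scale,
#'   or a \code{SummarizedExperiment} (first assay used).
#' @param groupA,groupB Character vectors of column (sample) ids.
#' @param paired Passed to [studentTTest()].
#' @return \code{data.frame} with columns \code{feature_id}, \code{mean_a},
#'   \code{mean_b}, \code{fc_linear}, \code{fc_signed}, \code{p_value}.
#' @examples
#' m <- rbind(g1 = c(5, 5, 2, 2), g2 = c(3, 3, 3, 3))
#' colnames(m) <- c("q1", "q2", "a1", "a2")
#' groupFoldChange(m, c("q1", "q2"), c("a1", "a2"))
#' @export
groupFoldChange <- function(x, groupA, groupB, paired = FALSE) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x)
  x <- as.matrix(x)
  miss <- c(setdiff(groupA, colnames(x)), setdiff(groupB, colnames(x)))
  if (length(miss))
    stop(sprintf("sample id(s) not in matrix: %s",
                 paste(miss, collapse = ", ")))
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  A <- x[, groupA, drop = FALSE]
  B <- x[, groupB, drop = FALSE]
  ma <- rowMeans(A, na.rm = TRUE)
  mb <- rowMeans(B, na.rm = TRUE)
  p <- vapply(seq_len(nrow(x)),
              function(i) studentTTest(A[i, ], B[i, ], paired = paired),
              numeric(1))
  fc <- 2^(ma - mb)
  data.frame(feature_id = rownames(x), mean_a = ma, mean_b = mb,
             fc_linear = fc, fc_signed = signedFoldChange(fc),
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Comparative-Ct relative expression (2^-ddCt)
#'
#' Relative expression of a sample versus a calibrator after reference
#' normalization: \eqn{2^{-(\Delta Ct_{sample} - \Delta Ct_{calibrator})}}.
#' A calibrator compared against itself gives 1.
#'
#' @param dctSample,dctCalibrator dCt values (assay Ct minus reference Ct).
#' @return Relative expression (linear scale).
#' @examples
#' ddctRelativeExpression(5, 5)  # 1
#' ddctRelativeExpression(6, 5)  # 0.5
#' @export
ddctRelativeExpression <- function(dctSample, dctCalibrator) {
  2^(-(dctSample - dctCalibrator))
}
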