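#' Selected target counts per miRNA
#'
#' @param pairs Pair table with \code{selected} flags
#'   ([selectFunctionalPairs()]).
#' @param mirnaIds Optional character vector of miRNAs that must appear in
#'   the result (with 0 when they have no selected pair); defaults to all
#'   miRNAs present in \code{pairs}.
#' @return Named integer vector: number of selected target genes per miRNA.
#' @export
targetsPerMirna <- function(pairs, mirnaIds = NULL) {
  mirnaIds <- mirnaIds %||% unique(pairs$mirna_id)
  sel <- pairs[pairs$selected, , drop = FALSE]
  tab <- table(factor(sel$mirna_id, levels = mirnaIds))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Quiescence-associated miRNA panel
#'
#' The panel collects quiescence-associated miRNAs whose number of selected
#' target genes strictly exceeds \code{panelMin} (default 6, i.e. "more than
#' 6 targets"), carrying the q-vs-a fold change and p-value, sorted by
#' target count (descending) then miRNA id.
#'
#' @param de miRNA differential table ([classifyMirnas()] output, or any
#'   table with \code{feature_id}, \code{fc_q_vs_a}, \code{p_value},
#'   \code{class_label}).
#' @param counts Named target counts from [targetsPerMirna()].
#' @param panelMin Threshold on target count (default 6).
#' @param strict Use a strict inequality (default \code{TRUE}); set
#'   \code{FALSE} for "at least \code{panelMin}".
#' @return \code{data.frame} with columns \code{mirna_id}, \code{fc_q_vs_a},
#'   \code{p_value}, \code{n_targets}.
#' @export
buildPanel <- function(de, counts, panelMin = 6, strict = TRUE) {
  qs <- de[de$class_label == "q_associated", , drop = FALSE]
  n <- counts[match(qs$feature_id, names(counts))]
  n[is.na(n)] <- 0L
  keep <- if (strict) n > panelMin else n >= panelMin
  out <- data.frame(mirna_id = qs$feature_id[keep],
                    fc_q_vs_a = qs$fc_q_vs_a[keep],
                    p_value = qs$p_value[keep],
                    n_targets = as.integer(n[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class target-count statistics
#'
#' For each deregulated miRNA class, the arithmetic mean and sample (n - 1)
#' standard deviation of selected-target counts, the same statistics over
#' only the miRNAs with at least one target, and the percentage of the
#' class strictly above \code{panelMin} targets (rounded to the nearest
#' integer, half away from zero).
#'
#' @param de miRNA differential table.
#' @param counts Named counts from [targetsPerMirna()].
#' @param panelMin Panel threshold (default 6).
#' @return \code{data.frame}, one row per class, with \code{class_label},
#'   \code{n_mirnas}, \code{mean_targets}, \code{sd_targets},
#'   \code{mean_targets_nonzero}, \code{sd_targets_nonzero},
#'   \code{n_above_panel_min}, \code{pct_above_panel_min}. Empty classes
#'   get missing statistics.
#' @export
classTargetStats <- function(de, counts, panelMin = 6) {
  classes <- c("q_associated", "a_associated")
  rows <- lapply(classes, function(cl) {
    ids <- de$feature_id[de$class_label == cl]
    x <- counts[match(ids, names(counts))]
    x[is.na(x)] <- 0L
    if (!length(x))
      return(data.frame(class_label = cl, n_mirnas = 0L,
                        mean_targets = NA_real_, sd_targets = NA_real_,
                        mean_targets_nonzero = NA_real_,
                        sd_targets_nonzero = NA_real_,
                        n_above_panel_min = 0L,
                        pct_above_panel_min = NA_real_))
    nz <- x[x > 0]
    data.frame(
      class_label = cl, n_mirnas = length(x),
      mean_targets = mean(x),
      sd_targets = if (length(x) > 1) stats::sd(x) else NA_real_,
      mean_targets_nonzero = if (length(nz)) mean(nz) else NA_real_,
      sd_targets_nonzero = if (length(nz) > 1) stats::sd(nz) else NA_real_,
      n_above_panel_min = sum(x > panelMin),
      pct_above_panel_min = roundHalfUp(100 * sum(x > panelMin) / length(x)))
  })
  do.call(rbind, rows)
}

#' Target coverage and most-targeted gene
#'
#' Coverage is the fraction of activation-associated genes reached by the
#' panel: |union of selected target genes of panel miRNAs| divided by the
#' number of a_associated genes. The most-targeted gene maximizes the number
#' of distinct miRNAs with a selected pair against it (over all selected
#' pairs); ties are broken alphabetically and all tied genes are reported.
#'
#' @param pairs Pair table with \code{selected} flags.
#' @param de Gene differential table (counts the a_associated denominator).
#' @param panel Panel from [buildPanel()].
#' @return List with \code{n_covered}, \code{n_a_genes}, \code{coverage}
#'   (fraction), \code{coverage_pct} (rounded percentage),
#'   \code{most_targeted} (\code{data.frame} of all argmax genes with
#'   \code{gene_id}, \code{n_mirnas}).
#' @export
coverageStats <- function(pairs, de, panel) {
  aGenes <- de$feature_id[de$feature_kind == "gene" &
                            de$class_label == "a_associated"]
  if (!length(aGenes))
    stop("no activation-associated genes: coverage denominator is zero")
  sel <- pairs[pairs$selected, , drop = FALSE]
  panelSel <- sel[sel$mirna_id %in% panel$mirna_id, , drop = FALSE]
  covered <- unique(panelSel$gene_id)
  mostTab <- if (nrow(sel)) {
    byGene <- tapply(sel$mirna_id, sel$gene_id,
                     function(m) length(unique(m)))
    top <- names(byGene)[byGene == max(byGene)]
    data.frame(gene_id = sort(top),
               n_mirnas = as.integer(byGene[sort(top)]),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), n_mirnas = integer())
  }
  list(n_covered = length(covered), n_a_genes = length(aGenes),
       coverage = length(covered) / length(aGenes),
       coverage_pct = roundHalfUp(100 * length(covered) / length(aGenes)),
       most_targeted = mostTab)
}

#' Deregulated class counts and percentages
#'
#' Counts quiescence- and activation-associated features among the
#' deregulated (non-unchanged) total, with integer-rounded percentages
#' (half away from zero).
#'
#' @param de Differential table.
#' @return \code{data.frame} with \code{class_label}, \code{n}, \code{pct}.
#' @examples
#' de <- data.frame(feature_id = sprintf("m%03d", 1:259),
#'                  class_label = rep(c("q_associated", "a_associated"),
#'                                    c(47, 212)))
#' classCountSummary(de)  # 18% / 82%
#' @export
classCountSummary <- function(de) {
  der <- de[de$class_label != "unchanged", , drop = FALSE]
  classes <- c("q_associated", "a_associated")
  n <- vapply(classes, function(cl) sum(der$class_label == cl), integer(1))
  tot <- sum(n)
  data.frame(class_label = classes, n = n,
             pct = if (tot) roundHalfUp(100 * n / tot) else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Network-level summary report
#'
#' Bundles the network summaries of one integrated run: targets per miRNA
#' and the count histogram, the quiescence panel, per-class target
#' statistics, class counts, and target coverage.
#'
#' @param pairs Pair table with \code{selected} flags.
#' @param mirnaDE,geneDE Differential tables.
#' @param panelMin Panel threshold (default 6).
#' @param strict Strict panel inequality (default \code{TRUE}).
#' @return List of class \code{"SummaryReport"} with elements
#'   \code{targets_per_mirna}, \code{histogram} (\code{data.frame}
#'   \code{n_targets} / \code{n_mirnas}), \code{panel},
#'   \code{class_stats}, \code{class_counts}, \code{coverage}.
#' @export
summarizeNetwork <- function(pairs, mirnaDE, geneDE, panelMin = 6,
                             strict = TRUE) {
  dereg <- mirnaDE$feature_id[mirnaDE$class_label != "unchanged"]
  counts <- targetsPerMirna(pairs, mirnaIds = dereg)
  panel <- buildPanel(mirnaDE, counts, panelMin = panelMin, strict = strict)
  hist <- if (length(counts)) {
    h <- as.data.frame(table(n_targets = counts), stringsAsFactors = FALSE)
    data.frame(n_targets = as.integer(h[[1]]), n_mirnas = as.integer(h[[2]]))
  } else {
    data.frame(n_targets = integer(), n_mirnas = integer())
  }
  hasAGenes <- any(geneDE$feature_kind == "gene" &
                     geneDE$class_label == "a_associated")
  cov <- if (hasAGenes) {
    coverageStats(pairs, geneDE, panel)
  } else {
    # degenerate run (e.g. null simulation): coverage undefined
    list(n_covered = NA_integer_, n_a_genes = 0L, coverage = NA_real_,
         coverage_pct = NA_real_,
         most_targeted = data.frame(gene_id = character(),
                                    n_mirnas = integer()))
  }
  out <- list(
    targets_per_mirna = counts,
    histogram = hist,
    panel = panel,
    panel_min = panelMin,
    class_stats = classTargetStats(mirnaDE, counts, panelMin = panelMin),
    class_counts = classCountSummary(mirnaDE),
    coverage = cov)
  class(out) <- c("SummaryReport", class(out))
  out
}

#' @export
print.SummaryReport <- function(x, ...) {
  cat("Integrated miRNA-mRNA network summary\n")
  cat(sprintf("  selected pairs: %d; deregulated miRNAs: %d\n",
              sum(x$targets_per_mirna), length(x$targets_per_mirna)))
  cc <- x$class_counts
  cat(sprintf("  class counts: %s\n",
              paste(sprintf("%s %d (%g%%)", cc$class_label, cc$n, cc$pct),
                    collapse = ", ")))
  cat(sprintf("  panel (> %d targets): %d miRNAs; coverage %d/%d (%g%%)\n",
              x$panel_min, nrow(x$panel), x$coverage$n_covered,
              x$coverage$n_a_genes, x$coverage$coverage_pct))
  invisible(x)
}
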