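fixturePanel <- function() {
  parsePanelTable(system.file("extdata", "table1_qhsc_panel.txt",
                              package = "miRTargetCor"))
}

# differential table + counts mirroring the parsed printed panel
fixtureAsDe <- function(panel) {
  de <- data.frame(feature_id = panel$mirna_id, feature_kind = "miRNA",
                   fc_q_vs_a = panel$fc_q_vs_a, p_value = panel$p_value,
                   class_label = "q_associated", stringsAsFactors = FALSE)
  counts <- setNames(panel$n_targets, panel$mirna_id)
  list(de = de, counts = counts)
}

test_that("targets per miRNA counts selected pairs, zeros included", {
  pairs <- data.frame(mirna_id = c("m1", "m1", "m1", "m2"),
                      gene_id = c("g1", "g2", "g3", "g1"),
                      selected = c(TRUE, TRUE, TRUE, FALSE))
  counts <- targetsPerMirna(pairs, mirnaIds = c("m1", "m2", "m3"))
  expect_equal(counts, c(m1 = 3L, m2 = 0L, m3 = 0L))
  expect_equal(sum(targetsPerMirna(pairs)), sum(pairs$selected))

  none <- pairs; none$selected <- FALSE
  expect_true(all(targetsPerMirna(none) == 0))
})

test_that("panel building keeps strictly-more-than-threshold miRNAs", {
  fx <- fixtureAsDe(fixturePanel())
  panel6 <- buildPanel(fx$de, fx$counts, panelMin = 6)
  expect_equal(nrow(panel6), 31)   # printed panel minimum is 7 targets
  expect_equal(panel6$mirna_id[1], "miR-200b")
  expect_equal(panel6$n_targets[1], 45L)

  panel44 <- buildPanel(fx$de, fx$counts, panelMin = 44)
  expect_equal(panel44$mirna_id, "miR-200b")

  # a miRNA with exactly panelMin targets is excluded under strictness
  de1 <- data.frame(feature_id = "mX", fc_q_vs_a = 2, p_value = 0.01,
                    class_label = "q_associated")
  expect_equal(nrow(buildPanel(de1, c(mX = 6L), panelMin = 6)), 0)
  expect_equal(nrow(buildPanel(de1, c(mX = 6L), panelMin = 6,
                               strict = FALSE)), 1)
  # membership is monotone decreasing in the threshold
  sizes <- vapply(c(0, 6, 14, 20, 44, 45), function(k)
    nrow(buildPanel(fx$de, fx$counts, panelMin = k)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("class target statistics match direct arithmetic", {
  de <- data.frame(feature_id = c("a", "b", "c"), feature_kind = "miRNA",
                   class_label = "q_associated")
  st <- classTargetStats(de, c(a = 2L, b = 2L, c = 2L))
  expect_equal(st$mean_targets[1], 2)
  expect_equal(st$sd_targets[1], 0)
  expect_true(is.na(st$mean_targets[2]))  # empty a-class

  st2 <- classTargetStats(de, c(a = 45L, b = 38L, c = 35L))
  expect_equal(st2$mean_targets[1], mean(c(45, 38, 35)))
  expect_equal(st2$sd_targets[1], sd(c(45, 38, 35)))

  # 31 of 47 q-miRNAs above the panel threshold -> 66%
  de47 <- data.frame(feature_id = sprintf("m%02d", 1:47),
                     feature_kind = "miRNA", class_label = "q_associated")
  counts47 <- setNames(c(rep(10L, 31), rep(2L, 16)), de47$feature_id)
  st3 <- classTargetStats(de47, counts47, panelMin = 6)
  expect_equal(st3$n_above_panel_min[1], 31L)
  expect_equal(st3$pct_above_panel_min[1], 66)
})

test_that("coverage and most-targeted gene follow the definitions", {
  # panel miRNAs covering 267 distinct genes of 998 up-regulated -> 27%
  geneIds <- sprintf("G%03d", 1:998)
  deG <- data.frame(feature_id = geneIds, feature_kind = "gene",
                    class_label = "a_associated")
  pairs <- data.frame(mirna_id = rep(sprintf("m%02d", 1:31),
                                     length.out = 267),
                      gene_id = geneIds[1:267], selected = TRUE)
  panel <- data.frame(mirna_id = sprintf("m%02d", 1:31))
  cov <- coverageStats(pairs, deG, panel)
  expect_equal(cov$n_covered, 267)
  expect_equal(cov$coverage, 267 / 998)
  expect_equal(cov$coverage_pct, 27)

  # full coverage when the panel reaches every up-regulated gene
  all <- data.frame(mirna_id = "m01", gene_id = geneIds, selected = TRUE)
  expect_equal(coverageStats(all, deG, panel)$coverage, 1)

  # most-targeted gene equals a brute-force recount on a synthetic run
  res <- runPipeline(simulateStudy(simParams(seed = 41)))
  sel <- res$pairs[res$pairs$selected, ]
  byGene <- sort(tapply(sel$mirna_id, sel$gene_id,
                        function(m) length(unique(m))), decreasing = TRUE)
  top <- res$report$coverage$most_targeted
  expect_equal(unique(top$n_mirnas), unname(byGene[1]))
  expect_setequal(top$gene_id,
                  names(byGene)[byGene == byGene[1]])

  expect_error(coverageStats(pairs, deG[0, ], panel), "denominator")
})

test_that("class count summary reproduces printed-style percentages", {
  de <- data.frame(feature_id = sprintf("m%03d", 1:300),
                   class_label = c(rep("q_associated", 47),
                                   rep("a_associated", 212),
                                   rep("unchanged", 41)))
  cc <- classCountSummary(de)
  expect_equal(cc$n, c(47L, 212L))
  expect_equal(cc$pct, c(18, 82))

  one <- classCountSummary(data.frame(feature_id = "m1",
                                      class_label = "a_associated"))
  expect_equal(one$pct, c(0, 100))

  # recount property on an arbitrary label table
  set.seed(7)
  lab <- sample(c("q_associated", "a_associated", "unchanged"), 200,
                replace = TRUE)
  cc2 <- classCountSummary(data.frame(feature_id = seq_along(lab),
                                      class_label = lab))
  expect_equal(cc2$n, c(sum(lab == "q_associated"),
                        sum(lab == "a_associated")))
  expect_equal(cc2$pct, floor(100 * cc2$n / sum(cc2$n) + 0.5))
})

test_that("network summary conserves pair counts and fixture statistics", {
  res <- runPipeline(simulateStudy(simParams(seed = 43)))
  rep <- res$report
  expect_equal(sum(rep$targets_per_mirna), sum(res$pairs$selected))
  expect_equal(sum(rep$histogram$n_mirnas), length(rep$targets_per_mirna))

  panel <- fixturePanel()
  expect_equal(nrow(panel), 31)
  expect_equal(max(panel$n_targets), 45)
  expect_equal(min(panel$n_targets), 7)
  expect_equal(max(panel$fc_q_vs_a), 5643.5)
})
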