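test_that("planted truth honours forced target counts and determinism", {
  p <- simParams(nMirnaQ = 1, nMirnaA = 1, nGenesQ = 5, nGenesA = 10,
                 nGenesBg = 0, targetsPerQMirna = 3, targetsPerAMirna = 1,
                 targetsDistribution = "fixed", seed = 11)
  t1 <- generateTruth(p)
  expect_equal(sum(truePairs(t1)$mirna_id == "miR-Q01"), 3)
  t2 <- generateTruth(p)
  expect_identical(truePairs(t1), truePairs(t2))
  expect_identical(truthGenes(t1), truthGenes(t2))

  # whole-study determinism: identical params + seed, identical outputs
  s1 <- simulateStudy(simParams(seed = 5))
  s2 <- simulateStudy(simParams(seed = 5))
  expect_identical(SummarizedExperiment::assay(mirnaCt(s1), "Ct"),
                   SummarizedExperiment::assay(mirnaCt(s2), "Ct"))
  expect_identical(SummarizedExperiment::assay(geneExpr(s1)),
                   SummarizedExperiment::assay(geneExpr(s2)))
  expect_identical(predictionTable(s1), predictionTable(s2))
})

test_that("target-count asymmetry follows the class means", {
  p <- simParams(nMirnaQ = 20, nMirnaA = 50, nGenesQ = 80, nGenesA = 200,
                 targetsPerQMirna = 15, targetsPerAMirna = 1, seed = 3)
  truth <- generateTruth(p)
  pr <- truePairs(truth)
  cls <- truthMirnas(truth)
  perMirna <- table(factor(pr$mirna_id, levels = cls$mirna_id))
  qMean <- mean(perMirna[cls$class == "q_associated"])
  aMean <- mean(perMirna[cls$class == "a_associated"])
  expect_gt(qMean, aMean)
  # direct recount: every pair links opposite planted directions
  g <- truthGenes(truth)
  mc <- cls$class[match(pr$mirna_id, cls$mirna_id)]
  gc <- g$class[match(pr$gene_id, g$gene_id)]
  expect_true(all((mc == "q_associated" & gc == "a_associated") |
                  (mc == "a_associated" & gc == "q_specific")))
  expect_false(anyDuplicated(pr[c("mirna_id", "gene_id")]) > 0)
})

test_that("requesting more targets than opposite-class genes errors", {
  p <- simParams(nMirnaQ = 1, nMirnaA = 1, nGenesQ = 2, nGenesA = 4,
                 nGenesBg = 0, targetsPerQMirna = 9, targetsPerAMirna = 1,
                 targetsDistribution = "fixed", seed = 1)
  expect_error(generateTruth(p), "shortfall")
})

test_that("noiseless planted pairs are perfectly anticorrelated", {
  p <- simParams(noiseSd = 0, donorSd = 0, refNoiseSd = 0,
                 targetsDistribution = "fixed", targetsPerQMirna = 5,
                 targetsPerAMirna = 1, seed = 2)
  study <- simulateStudy(p)
  ndct <- SummarizedExperiment::assay(negDeltaCt(mirnaCt(study)))
  expr <- SummarizedExperiment::assay(geneExpr(study))
  hsc <- colnames(ndct)
  pr <- truePairs(study)
  for (k in seq_len(min(5, nrow(pr)))) {
    r <- cor(ndct[pr$mirna_id[k], hsc], expr[pr$gene_id[k], hsc])
    expect_equal(r, -1, tolerance = 1e-12)
  }
})

test_that("null effect size gives fold changes near 1 and few calls", {
  p <- simParams(effectLog2 = 0, seed = 4)
  study <- simulateStudy(p)
  ndct <- negDeltaCt(mirnaCt(study))
  de <- classifyMirnas(ndct)
  keep <- !grepl("^miR-X", de$feature_id)  # planted-undetected rows aside
  expect_equal(mean(log2(de$fc_q_vs_a[keep])), 0, tolerance = 0.2)

  # null calibration across 20 seeds: <= 10% of features pass |FC|>=2, p<=.05
  hits <- 0; total <- 0
  for (s in 1:20) {
    st <- simulateStudy(simParams(effectLog2 = 0, nMirnaQ = 5, nMirnaA = 5,
                                  nGenesQ = 5, nGenesA = 5, nGenesBg = 0,
                                  nMirnaAbsent = 0, targetsPerQMirna = 2,
                                  targetsPerAMirna = 1,
                                  targetsDistribution = "fixed",
                                  seed = 100 + s))
    d <- classifyMirnas(negDeltaCt(mirnaCt(st)))
    pass <- (d$fc_q_vs_a >= 2 | d$fc_q_vs_a <= 0.5) &
      !is.na(d$p_value) & d$p_value <= 0.05
    hits <- hits + sum(pass); total <- total + length(pass)
  }
  expect_lte(hits / total, 0.10)
})

test_that("planted fold change is recovered within Monte-Carlo error", {
  p <- simParams(effectLog2 = 3, noiseSd = 0.25, nDonors = 4, seed = 1)
  study <- simulateStudy(p)
  ndct <- SummarizedExperiment::assay(negDeltaCt(mirnaCt(study)))
  sheet <- sampleSheet(study)
  q <- sheet$sample_id[sheet$cell_type == "HSC" &
                         sheet$state %in% "quiescent"]
  a <- sheet$sample_id[sheet$cell_type == "HSC" &
                         sheet$state %in% "activated"]
  qm <- truthMirnas(regulatoryTruth(study))
  qIds <- qm$mirna_id[qm$class == "q_associated"]
  lfc <- rowMeans(ndct[qIds, q]) - rowMeans(ndct[qIds, a])
  # per-sample var = noise^2 + donorSd^2; SE of the mean of 20 group contrasts
  se <- sqrt((0.25^2 + 0.3^2) * 2 / 4 / length(qIds))
  expect_lt(abs(mean(lfc) - 3), 3 * se + 1e-9)
})

test_that("prediction table respects degenerate and stochastic rates", {
  base <- list(targetsDistribution = "fixed", targetsPerQMirna = 5,
               targetsPerAMirna = 1, seed = 9)
  truth <- generateTruth(do.call(simParams, base))

  exact <- generatePredictionTable(
    truth, do.call(simParams, c(base, dbSensitivity = 1, dbFpr = 0,
                                dbNonsigCoverage = 0)))
  sig <- exact[exact$p_database < 0.05, c("mirna_id", "gene_id")]
  expect_setequal(paste(sig$mirna_id, sig$gene_id),
                  paste(truePairs(truth)$mirna_id, truePairs(truth)$gene_id))

  none <- generatePredictionTable(
    truth, do.call(simParams, c(base, dbSensitivity = 0)))
  key <- paste(none$mirna_id, none$gene_id)
  trueKey <- paste(truePairs(truth)$mirna_id, truePairs(truth)$gene_id)
  expect_true(all(none$p_database[key %in% trueKey] >= 0.05))

  # recount oracle at sensitivity 0.9: count via independent table scan
  p90 <- do.call(simParams, c(base[-4], list(seed = 21, dbSensitivity = 0.9)))
  truth90 <- generateTruth(p90)
  tab <- generatePredictionTable(truth90, p90)
  key <- paste(tab$mirna_id, tab$gene_id)
  trueKey <- paste(truePairs(truth90)$mirna_id, truePairs(truth90)$gene_id)
  nSigTrue <- sum(tab$p_database < 0.05 & key %in% trueKey)
  recount <- 0L
  for (i in seq_len(nrow(tab)))
    if (paste(tab$mirna_id[i], tab$gene_id[i]) %in% trueKey &&
        tab$p_database[i] < 0.05) recount <- recount + 1L
  expect_identical(nSigTrue, recount)
  expect_gt(nSigTrue / length(trueKey), 0.75)
  expect_lt(nSigTrue / length(trueKey), 1)
})

test_that("planted directions oppose between miRNA and target gene", {
  study <- simulateStudy(simParams(seed = 6))
  ndct <- SummarizedExperiment::assay(negDeltaCt(mirnaCt(study)))
  expr <- SummarizedExperiment::assay(geneExpr(study))
  sheet <- sampleSheet(study)
  q <- sheet$sample_id[sheet$cell_type == "HSC" &
                         sheet$state %in% "quiescent"]
  a <- sheet$sample_id[sheet$cell_type == "HSC" &
                         sheet$state %in% "activated"]
  pr <- truePairs(study)
  dM <- rowMeans(ndct[pr$mirna_id, q]) - rowMeans(ndct[pr$mirna_id, a])
  dG <- rowMeans(expr[pr$gene_id, q]) - rowMeans(expr[pr$gene_id, a])
  expect_true(all(sign(dM) != sign(dG)))
})
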