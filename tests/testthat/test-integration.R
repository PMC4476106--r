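deAll <- function(ids, kind) {
  data.frame(feature_id = ids, feature_kind = kind,
             class_label = "q_associated", stringsAsFactors = FALSE)
}

test_that("all-pairs Pearson matches closed forms and the cross-product
           contract", {
  mirna <- rbind(m1 = c(1, 2, 3, 4, 5, 6, 7, 8),
                 m2 = c(2, 1, 2, 1, 2, 1, 2, 1))
  gene <- rbind(g1 = -c(1, 2, 3, 4, 5, 6, 7, 8),
                g2 = c(8, 6, 7, 5, 4, 3, 1, 2))
  colnames(mirna) <- colnames(gene) <- paste0("s", 1:8)
  pairs <- pearsonAllPairs(mirna, gene,
                           deAll(rownames(mirna), "miRNA"),
                           deAll(rownames(gene), "gene"))
  expect_equal(nrow(pairs), 4)  # cross product of deregulated features

  p11 <- pairs[pairs$mirna_id == "m1" & pairs$gene_id == "g1", ]
  expect_equal(p11$pearson_r, -1)
  expect_equal(p11$cor_p, 0)

  orc <- pearsonOracle(mirna["m1", ], gene["g2", ])
  p12 <- pairs[pairs$mirna_id == "m1" & pairs$gene_id == "g2", ]
  expect_equal(p12$pearson_r, orc$r, tolerance = 1e-12)
  expect_equal(p12$cor_p, orc$p, tolerance = 1e-12)
  ct <- cor.test(mirna["m1", ], gene["g2", ])  # independent cross-check
  expect_equal(p12$pearson_r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(p12$cor_p, ct$p.value, tolerance = 1e-12)

  expect_error(pearsonAllPairs(mirna[, 1:2], gene[, 1:2],
                               deAll(rownames(mirna), "miRNA"),
                               deAll(rownames(gene), "gene")),
               "at least 3")
})

test_that("zero-variance features yield missing r excluded from the FDR
           family", {
  mirna <- rbind(m1 = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  gene <- rbind(g1 = c(4, 3, 2, 1))
  colnames(mirna) <- colnames(gene) <- paste0("s", 1:4)
  pairs <- pearsonAllPairs(mirna, gene, deAll(rownames(mirna), "miRNA"),
                           deAll(rownames(gene), "gene"))
  flat <- pairs[pairs$mirna_id == "flat", ]
  expect_true(is.na(flat$pearson_r) && is.na(flat$fdr))
  expect_false(anyNA(pairs$fdr[pairs$mirna_id == "m1"]))
})

test_that("BH adjustment matches hand-executed step-up cases", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.03), 0.03)            # m = 1 identity
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))  # ties stay tied
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up oracle on random vectors", {
  set.seed(2024)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("functional-pair selection requires all three conditions", {
  pairs <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m1"),
    gene_id = c("g1", "g2", "g3", "g4"),
    pearson_r = c(0.9, -0.8, -0.8, -0.8),
    cor_p = c(0.001, 0.2, 0.01, 0.01),
    fdr = c(0.001, 0.2, 0.01, 0.01))
  pred <- data.frame(mirna_id = c("m1", "m1", "m1"),
                     gene_id = c("g1", "g2", "g3"),
                     p_database = c(0.001, 0.001, 0.01))
  out <- selectFunctionalPairs(pairs, pred)
  expect_equal(out$selected, c(FALSE, FALSE, TRUE, FALSE))
  # g1: positive r; g2: FDR fail; g3: all pass; g4: absent from predictions
  expect_true(is.na(out$p_database[out$gene_id == "g4"]))
})

test_that("loosening selection cut-offs never deselects a pair", {
  study <- simulateStudy(simParams(seed = 31))
  res <- runPipeline(study)
  tight <- res$pairs$selected
  loose <- selectFunctionalPairs(res$pairs, predictionTable(study),
                                 fdrCut = 0.2, pdbCut = 0.2)$selected
  expect_true(all(loose[tight]))
  none <- selectFunctionalPairs(res$pairs, predictionTable(study),
                                fdrCut = 0)$selected
  expect_false(any(none))
})

test_that("integration recovers planted pairs on synthetic studies", {
  prec <- rec <- numeric(5)
  for (s in 1:5) {
    study <- simulateStudy(simParams(seed = 500 + s))
    ev <- runPipeline(study)$evaluation
    prec[s] <- ev$precision; rec[s] <- ev$recall
  }
  expect_gte(mean(rec), 0.5)
  expect_gte(mean(prec), 0.8)
})

test_that("null networks yield selected pairs within the nominal rates", {
  nSel <- nPredSig <- numeric(10)
  for (s in 1:10) {
    p <- simParams(effectLog2 = 0, targetsPerQMirna = 0, targetsPerAMirna = 0,
                   dbFpr = 0.05, nMirnaQ = 10, nMirnaA = 10,
                   nGenesQ = 30, nGenesA = 30, nGenesBg = 0,
                   nMirnaAbsent = 0, seed = 700 + s)
    study <- simulateStudy(p)
    res <- runPipeline(study)
    nSel[s] <- sum(res$pairs$selected)
    pred <- predictionTable(study)
    key <- paste(pred$mirna_id, pred$gene_id) %in%
      paste(res$pairs$mirna_id, res$pairs$gene_id)
    nPredSig[s] <- sum(pred$p_database < 0.05 & key)
  }
  expect_lte(mean(nSel), 0.05 * mean(nPredSig) + 1e-9)
})
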