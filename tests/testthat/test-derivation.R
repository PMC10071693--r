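test_that("IHC classes merge to a binary label, dropping indeterminate", {
  ann <- data.frame(sample_id = c("a", "b", "c"),
                    ihc_class = c("hot", "altered", "cold"))
  lab <- mergeIHCLabels(ann)
  expect_identical(unname(as.character(lab)),
                   c("inflamed", "inflamed", "cold"))
  expect_message(
    lab2 <- mergeIHCLabels(rbind(ann, data.frame(
      sample_id = "d", ihc_class = "indeterminate"))),
    "indeterminate")
  expect_length(lab2, 3)
  expect_error(suppressMessages(mergeIHCLabels(
    data.frame(sample_id = "x", ihc_class = "indeterminate"))),
    "no samples")
  # a CNS-like cohort: 29 cold + 9 altered -> 9 inflamed / 29 cold
  cns <- data.frame(sample_id = sprintf("c%02d", 1:38),
                    ihc_class = rep(c("cold", "altered"), c(29, 9)))
  expect_equal(as.vector(table(mergeIHCLabels(cns))), c(29L, 9L))
})

test_that("panel filtering keeps the intersection in matrix order", {
  m <- makeRandomMatrix(nGenes = 3, nSamples = 2, seed = 1)
  rownames(m) <- c("A", "B", "C")
  out <- filterPanelGenes(m, c("B", "C", "D"))
  expect_identical(rownames(out), c("B", "C"))
  expect_error(filterPanelGenes(m, c("X", "Y")), "no panel genes")
  # 766-gene synthetic panel fully contained in a 1000-gene matrix
  big <- makeRandomMatrix(nGenes = 1000, nSamples = 3, seed = 2)
  panel <- rownames(big)[seq_len(766)]
  expect_identical(rownames(filterPanelGenes(big, panel)), panel)
})

test_that("stratified split follows largest-remainder allocation", {
  labs <- setNames(rep(c("inflamed", "cold"), c(25, 44)),
                   sprintf("s%02d", 1:69))
  sp <- stratifiedSplit(labs, 0.5, seed = 3)
  expect_length(sp$trainIds, 34)
  expect_length(sp$testIds, 35)
  expect_equal(sum(labs[sp$trainIds] == "inflamed"), 12)
  expect_equal(sum(labs[sp$testIds] == "inflamed"), 13)
  expect_equal(sum(labs[sp$trainIds] == "cold"), 22)
  expect_setequal(c(sp$trainIds, sp$testIds), names(labs))

  # tiny balanced cohort: one of each class on each side
  small <- setNames(c("inflamed", "inflamed", "cold", "cold"),
                    letters[1:4])
  sp2 <- stratifiedSplit(small, 0.5, seed = 1)
  expect_equal(as.vector(table(small[sp2$trainIds])), c(1L, 1L))

  # seed determinism
  expect_identical(stratifiedSplit(labs, 0.5, seed = 7),
                   stratifiedSplit(labs, 0.5, seed = 7))
  expect_false(identical(stratifiedSplit(labs, 0.5, seed = 7),
                         stratifiedSplit(labs, 0.5, seed = 8)))
  expect_error(stratifiedSplit(setNames(c("a", "a", "b"), 1:3), 0.5, 1),
               "fewer than 2")
})

test_that("forest training separates a separable toy and is seeded", {
  # gene A high in every inflamed sample, zero elsewhere
  m <- matrix(0, nrow = 2, ncol = 20,
              dimnames = list(c("A", "B"), sprintf("s%02d", 1:20)))
  lab <- setNames(rep(c("inflamed", "cold"), each = 10), colnames(m))
  m["A", lab == "inflamed"] <- 50
  set.seed(1); m["B", ] <- runif(20, 0, 10)
  tr <- trainClassifier(m, lab, nTrees = 100, seed = 1)
  expect_identical(names(which.max(tr$importance)), "A")
  pred <- predict(tr$forest, t(m))
  expect_equal(mean(pred == lab), 1)
  expect_true(all(tr$importance >= 0))
  expect_length(tr$importance, 2)
  # determinism given seed
  tr2 <- trainClassifier(m, lab, nTrees = 100, seed = 1)
  expect_identical(tr$importance, tr2$importance)
  expect_error(trainClassifier(m, setNames(rep("cold", 20), colnames(m)),
                               seed = 1), "single class")
})

test_that("null labels yield no dominant importance", {
  # labels independent of features: max importance stays near the median
  ok <- 0L
  for (s in 1:20) {
    m <- makeRandomMatrix(nGenes = 20, nSamples = 60, seed = 5000 + s)
    lab <- setNames(rep(c("cold", "inflamed"), 30), colnames(m))
    tr <- trainClassifier(m, lab, nTrees = 500, seed = s)
    ok <- ok + (max(tr$importance) <= 3 * median(tr$importance))
  }
  expect_gte(ok, 19L)
})

test_that("signature extraction ranks by importance with lexicographic ties", {
  sig <- extractSignature(c(A = 0.5, B = 0.3, C = 0.3, D = 0.1), k = 2)
  expect_identical(signatureGenes(sig), c("A", "B"))
  expect_equal(rankScores(sig), c(0.5, 0.3))
  all4 <- extractSignature(c(B = 0.3, A = 0.5, D = 0.1, C = 0.3), k = 4)
  expect_identical(signatureGenes(all4), c("A", "B", "C", "D"))
  expect_error(extractSignature(c(A = 1), k = 2), "exceeds")
})

test_that("end-to-end derivation populates a consistent report", {
  coh <- simulateCohort(seed = 17)
  panel <- S4Vectors::metadata(coh)$panel
  rep <- deriveIPASS(coh, panel = panel, seed = 17)
  expect_s4_class(rep, "DerivationReport")
  expect_length(signatureGenes(rep), 15)
  expect_true(all(signatureGenes(rep) %in% panel))
  expect_length(c(rep@trainIds, rep@testIds), ncol(coh))
  expect_equal(nrow(importances(rep)), length(panel))
  # rerun with the same seed is identical
  rep2 <- deriveIPASS(coh, panel = panel, seed = 17)
  expect_equal(rep, rep2)
  # planted genes at default effects all rank in the top 30 of 766
  top30 <- importances(rep)$gene[1:30]
  expect_true(all(S4Vectors::metadata(coh)$informativeGenes %in% top30))
})

test_that("a noiseless, large-effect cohort is classified perfectly", {
  coh <- simulateCohort(nCold = 10, nAltered = 4, nHot = 2, nGenes = 120,
                        nPanel = 80, nInformative = 6, effectHot = 4,
                        effectAltered = 4, noiseSD = 0, seed = 23)
  rep <- deriveIPASS(coh, panel = S4Vectors::metadata(coh)$panel, k = 6,
                     nTrees = 200, seed = 23)
  expect_equal(testMetrics(rep)$accuracy, 1)
})

test_that("test samples never influence the extracted signature", {
  coh <- simulateCohort(nCold = 20, nAltered = 8, nHot = 4, nGenes = 200,
                        nPanel = 120, nInformative = 8, seed = 31)
  panel <- S4Vectors::metadata(coh)$panel
  rep <- deriveIPASS(coh, panel = panel, k = 8, nTrees = 200, seed = 31)
  # corrupt every test sample's expression; signature must not move
  m <- SummarizedExperiment::assay(coh, "tpm")
  m[, rep@testIds] <- m[, rep@testIds] * 10 + 3
  rep2 <- deriveIPASS(SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = m),
    colData = SummarizedExperiment::colData(coh)),
    panel = panel, k = 8, nTrees = 200, seed = 31)
  expect_identical(rep@trainIds, rep2@trainIds)
  expect_identical(signatureGenes(rep), signatureGenes(rep2))
  expect_equal(importances(rep), importances(rep2))
})
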