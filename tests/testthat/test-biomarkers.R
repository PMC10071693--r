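test_that("neoepitope filtering applies strict cut-offs and collapses by mutation", {
  row <- function(id, mut, wt, tpm)
    data.frame(mutation_id = id, hla_allele = "A*01:01", mut_ic50 = mut,
               wt_ic50 = wt, gene_tpm = tpm)
  expect_equal(filterNeoepitopes(row("m1", 300, 600, 2))$nNeoantigens, 1L)
  # all three boundaries are strict
  expect_equal(filterNeoepitopes(row("m1", 500, 600, 2))$nNeoantigens, 0L)
  expect_equal(filterNeoepitopes(row("m1", 300, 500, 2))$nNeoantigens, 0L)
  expect_equal(filterNeoepitopes(row("m1", 300, 600, 1))$nNeoantigens, 0L)
  # 3 passing epitopes for one mutation + 1 for another -> 2 neoantigens
  tab <- rbind(row("m1", 100, 700, 5), row("m1", 200, 800, 5),
               row("m1", 400, 600, 5), row("m2", 50, 900, 3))
  tab$hla_allele <- c("A*01:01", "B*07:02", "C*07:01", "A*01:01")
  res <- filterNeoepitopes(tab)
  expect_equal(nrow(res$passing), 4)
  expect_equal(res$nNeoantigens, 2L)
  expect_equal(filterNeoepitopes(tab[0, ])$nNeoantigens, 0L)
})

test_that("neoepitope filter matches a brute-force scan and is monotone", {
  set.seed(77)
  n <- 2000
  tab <- data.frame(
    mutation_id = sprintf("m%04d", sample(600, n, replace = TRUE)),
    hla_allele = sample(c("A*01:01", "B*07:02"), n, replace = TRUE),
    mut_ic50 = runif(n, 1, 1500), wt_ic50 = runif(n, 1, 1500),
    gene_tpm = runif(n, 0, 5))
  res <- filterNeoepitopes(tab)
  oracle <- neoepitopeOracle(tab)
  expect_equal(nrow(res$passing), sum(oracle$keep))
  expect_equal(unname(res$nNeoantigens), oracle$count)
  expect_lte(res$nNeoantigens, length(unique(tab$mutation_id)))
  # relaxing any cut-off never loses rows
  base <- nrow(res$passing)
  expect_gte(nrow(filterNeoepitopes(tab, mutCut = 800)$passing), base)
  expect_gte(nrow(filterNeoepitopes(tab, wtCut = 200)$passing), base)
  expect_gte(nrow(filterNeoepitopes(tab, tpmCut = 0.2)$passing), base)
})

test_that("PD-L1 IHC positivity is >= 1 percent, inclusive", {
  expect_identical(classifyPDL1(c(1, 0.9, 100, 0)),
                   c("positive", "negative", "positive", "negative"))
  expect_error(classifyPDL1(101), "percent")
  expect_error(classifyPDL1(-1), "percent")
})

test_that("PD-L1 IHC/RNA concordance cross-tabulates with a strict RNA cut", {
  tab <- pdl1Concordance(percent = rep(2, 4), tpm = rep(5, 4))
  expect_equal(unname(tab["positive", "high"]), 4L)
  expect_equal(sum(tab), 4L)
  tab2 <- pdl1Concordance(percent = 0.5, tpm = 4)
  expect_equal(unname(tab2["negative", "high"]), 1L)
  # boundary: tpm exactly at the cut is RNA-low
  expect_equal(unname(pdl1Concordance(2, 3)["positive", "low"]), 1L)
  # seeded random pairs match a brute-force scan
  set.seed(31)
  pc <- runif(200, 0, 5); tp <- runif(200, 0, 10)
  tab3 <- pdl1Concordance(pc, tp)
  expect_equal(unname(as.vector(tab3)),
               c(sum(pc >= 1 & tp > 3), sum(pc < 1 & tp > 3),
                 sum(pc >= 1 & tp <= 3), sum(pc < 1 & tp <= 3)))
})

test_that("archetype scoring standardises, assigns by max and flags ties", {
  set.seed(55)
  genes <- c(paste0("IRG", 1:4), paste0("IDG", 1:4))
  m <- matrix(2^rnorm(8 * 10, 3, 0.3) - 1, nrow = 8,
              dimnames = list(genes, paste0("s", 1:10)))
  # sample s1: all IR genes elevated ~ +3 SD in log space
  m[1:4, 1] <- 2^(log2(m[1:4, 1] + 1) + 3) - 1
  sets <- list(IR = paste0("IRG", 1:4), ID = paste0("IDG", 1:4))
  sc <- scoreArchetypes(m, sets)
  expect_identical(dim(sc), c(10L, 2L))
  asg <- assignArchetypes(sc)
  expect_identical(asg$archetype[asg$sample_id == "s1"], "IR")
  # z-score shift invariance: adding a constant in log space changes nothing
  m2 <- 2^(log2(m + 1) + 5) - 1
  asg2 <- assignArchetypes(scoreArchetypes(m2, sets))
  expect_identical(asg$archetype, asg2$archetype)
  # identical expression across samples -> degenerate cohort
  flat <- matrix(7, nrow = 8, ncol = 3, dimnames = list(genes, 1:3))
  expect_error(scoreArchetypes(flat, sets), "degenerate")
  # duplicated gene sets tie exactly; alphabetical break + flag
  expect_warning(
    asg3 <- assignArchetypes(scoreArchetypes(m, list(B = sets$IR,
                                                     A = sets$IR))),
    "tied")
  expect_true(all(asg3$archetype == "A"))
  expect_true(all(asg3$tie))
  expect_error(scoreArchetypes(m, list(IR = "NOTAGENE")), "IR")
})

test_that("clone summaries report counts and proportions that sum to one", {
  tab <- data.frame(sample_id = rep(c("s1", "s2"), c(2, 1)),
                    clone_id = c("c1", "c2", "c1"),
                    read_count = c(5, 5, 7))
  s <- summarizeClones(tab)
  expect_equal(unname(s$s1$proportions), c(0.5, 0.5))
  expect_equal(s$s2$proportions, c(c1 = 1))
  expect_equal(s$s1$n_clones, 2L)
  expect_equal(s$s1$total_reads, 10L)
  # seeded random table: proportions sum to 1 and match hand division
  set.seed(66)
  big <- data.frame(sample_id = rep(paste0("p", 1:5), each = 8),
                    clone_id = rep(paste0("c", 1:8), 5),
                    read_count = sample(1:500, 40, replace = TRUE))
  sb <- summarizeClones(big)
  for (p in names(sb)) {
    rows <- big[big$sample_id == p, ]
    expect_lt(abs(sum(sb[[p]]$proportions) - 1), 1e-12)
    expect_equal(unname(sb[[p]]$proportions),
                 rows$read_count / sum(rows$read_count))
  }
})
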