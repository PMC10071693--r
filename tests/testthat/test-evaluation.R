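test_that("confusion matrices cross-tabulate correctly", {
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  cm <- confusion2x2(pred, pred)
  expect_equal(as.vector(cm), c(4L, 0L, 0L, 6L))
  inv <- confusion2x2(!pred, pred)
  expect_equal(c(inv[1, 1], inv[2, 2]), c(0L, 0L))
  # seeded random labels match a brute-force pairwise count
  set.seed(12)
  p <- runif(50) > 0.5; t <- runif(50) > 0.5
  cm2 <- confusion2x2(p, t)
  expect_equal(as.vector(cm2),
               c(sum(p & t), sum(!p & t), sum(p & !t), sum(!p & !t)))
  # order invariance when named
  names(p) <- names(t) <- sprintf("s%02d", 1:50)
  perm <- sample(names(p))
  expect_equal(classificationMetrics(confusion2x2(p[perm], t)),
               classificationMetrics(cm2))
  expect_error(confusion2x2(setNames(p, paste0("x", 1:50)), t),
               "do not match")
})

test_that("metrics follow their defining ratios and flag zero denominators", {
  m <- classificationMetrics(tp = 21, fn = 4, fp = 6, tn = 46)
  expect_equal(m$sensitivity, 21 / 25)
  expect_equal(m$specificity, 46 / 52)
  expect_equal(m$ppv, 21 / 27)
  expect_equal(m$npv, 46 / 50)
  expect_equal(m$accuracy, 67 / 77)
  expect_equal(wholePercent(c(m$sensitivity, m$specificity, m$ppv, m$npv)),
               c(84L, 88L, 78L, 92L))
  perfect <- classificationMetrics(tp = 5, fn = 0, fp = 0, tn = 5)
  expect_true(all(unlist(perfect[1:5]) == 1))
  noPos <- classificationMetrics(tp = 0, fn = 2, fp = 0, tn = 8)
  expect_true(is.na(noPos$ppv))
  expect_identical(noPos$undefined, "ppv")
})

test_that("Fisher's exact test matches enumeration", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  set.seed(8)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0) next
    expect_equal(fisherExact2x2(tab), fisherOracle(tab), tolerance = 1e-10)
  }
  expect_error(fisherExact2x2(matrix(0, 2, 2)), "all-zero")
  expect_error(fisherExact2x2(matrix(c(1, -1, 1, 1), 2)), "non-negative")
})

test_that("Pearson correlation matches the closed form and is affine-invariant", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  r <- pearsonR(x, y)
  # closed-form oracle from raw sums
  rHand <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    sqrt((sum(x^2) - length(x) * mean(x)^2) *
         (sum(y^2) - length(y) * mean(y)^2))
  expect_equal(r$r, rHand, tolerance = 1e-12)
  expect_equal(pearsonR(x, x)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_equal(pearsonR(3 * x + 2, 0.5 * y - 1)$r, r$r, tolerance = 1e-12)
  expect_error(pearsonR(x, rep(1, 4)), "constant")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("the two-group decision flow picks the right test", {
  # under H0 of the three alpha = 0.05 gates (two Shapiro, one F) the
  # t-test fires with probability 0.95^3 ~ 0.857
  tSel <- 0L
  for (s in 1:100) {
    set.seed(s)
    res <- twoGroupCompare(rnorm(30), rnorm(30, 0.3))
    tSel <- tSel + (res$test == "t")
  }
  expect_gte(tSel, 80L)
  wSel <- 0L
  for (s in 1:100) {
    set.seed(s)
    res <- twoGroupCompare(rexp(30), rnorm(30, 1))
    wSel <- wSel + (res$test == "wilcoxon")
  }
  expect_gte(wSel, 90L)
  set.seed(2)
  a <- rnorm(25)
  expect_gt(twoGroupCompare(a, a)$p, 0.5)
  expect_error(twoGroupCompare(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("gene clustering finds the score-tracking block", {
  set.seed(44)
  n <- 40
  score <- sort(runif(n, -1, 1))
  tracking <- t(sapply(1:6, function(i) 2^(2 + 2 * score + rnorm(n, 0, 0.2)) - 1))
  anti <- t(sapply(1:6, function(i) 2^(2 - 2 * score + rnorm(n, 0, 0.2)) - 1))
  m <- pmax(rbind(tracking, anti), 0)
  dimnames(m) <- list(c(paste0("T", 1:6), paste0("A", 1:6)),
                      paste0("s", 1:n))
  names(score) <- colnames(m)
  cl <- clusterGenesVsScore(m, rownames(m), score, k = 2, seed = 1)
  expect_setequal(cl$bestGenes, paste0("T", 1:6))
  # determinism
  cl2 <- clusterGenesVsScore(m, rownames(m), score, k = 2, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)
  # k = number of genes -> singletons; best is the single top-correlated gene
  clAll <- clusterGenesVsScore(m, rownames(m), score, k = nrow(m), seed = 1)
  expect_length(clAll$bestGenes, 1)
  geneCor <- apply(log2(m + 1), 1, cor, score)
  expect_identical(clAll$bestGenes, names(which.max(geneCor)))
  expect_error(clusterGenesVsScore(m, rownames(m), score, k = 13), "k")
})
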