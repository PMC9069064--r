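test_that("probability combination is exact and sums to one", {
  expect_equal(unlist(combineProbabilities(1, 0)),
               c(p_pd = 0, p_sd = 0, p_pr = 1))
  expect_equal(unlist(combineProbabilities(0.3, 1)),
               c(p_pd = 0, p_sd = 1, p_pr = 0))
  expect_equal(unlist(combineProbabilities(0.6, 0.5)),
               c(p_pd = 0.2, p_sd = 0.5, p_pr = 0.3))
  expect_error(combineProbabilities(1.2, 0.5), "\\[0, 1\\]")
  set.seed(61)
  pr <- combineProbabilities(runif(1e4), runif(1e4))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
})

test_that("rank AUC matches the brute-force pair-count oracle", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0), nBoot = 100)$auc,
               0.75)
  expect_equal(rocAUC(4:1, c(1, 1, 0, 0), nBoot = 100)$auc, 1)
  expect_equal(rocAUC(rep(0.5, 10), rep(c(TRUE, FALSE), 5),
                      nBoot = 100)$auc, 0.5)
  set.seed(62)
  for (i in 1:10) {
    sc <- round(runif(20), 1)  # induces ties
    lab <- runif(20) > 0.5
    if (all(lab) || !any(lab)) next
    expect_equal(rocAUC(sc, lab, nBoot = 100)$auc, aucPairs(sc, lab))
  }
  expect_error(rocAUC(1:3, c(TRUE, TRUE, TRUE), nBoot = 100),
               "both classes")
})

test_that("bootstrap CI brackets the AUC and is seed-stable", {
  set.seed(63)
  sc <- c(rnorm(20, 1), rnorm(20))
  lab <- rep(c(TRUE, FALSE), each = 20)
  r1 <- rocAUC(sc, lab, nBoot = 500, seed = 4L)
  r2 <- rocAUC(sc, lab, nBoot = 500, seed = 4L)
  expect_identical(r1, r2)
  expect_lte(r1$ciLow, r1$auc)
  expect_gte(r1$ciHigh, r1$auc)
})

test_that("multi-omics fusion averages and renormalises", {
  p1 <- data.frame(sample_id = c("a", "b"), p_pd = c(0.2, 0.1),
                   p_sd = c(0.5, 0.2), p_pr = c(0.3, 0.7), predicted = "SD")
  p2 <- data.frame(sample_id = c("a", "b"), p_pd = c(0.4, 0.1),
                   p_sd = c(0.1, 0.2), p_pr = c(0.5, 0.7), predicted = "PR")
  expect_equal(fuseMultiomics(list(p1))[, c("p_pd", "p_sd", "p_pr")],
               p1[, c("p_pd", "p_sd", "p_pr")])
  same <- fuseMultiomics(list(p1, p1))
  expect_equal(same[, c("p_pd", "p_sd", "p_pr")],
               p1[, c("p_pd", "p_sd", "p_pr")])
  fused <- fuseMultiomics(list(p1, p2))
  expect_equal(unlist(fused[1, c("p_pd", "p_sd", "p_pr")]),
               c(p_pd = 0.3, p_sd = 0.3, p_pr = 0.4))
  expect_error(fuseMultiomics(list(p1, p2), weights = c(0, 0)), "weights")
  p3 <- p2; p3$sample_id <- c("b", "a")
  expect_error(fuseMultiomics(list(p1, p3)), "same samples")
})

test_that("feature selection recovers a perfectly separating feature", {
  set.seed(64)
  n <- 16L
  X <- matrix(rnorm(n * 201), n, 201,
              dimnames = list(sprintf("s%02d", 1:n),
                              c("signal", sprintf("noise%03d", 1:200))))
  y <- rep(c("PD", "PR"), each = n / 2)
  X[, "signal"] <- ifelse(y == "PR", 1, -1) + rnorm(n, 0, 0.05)
  sel <- cvFeatureSelect(X, y, seed = 3L)
  expect_equal(sel$feature[1L], "signal")
  expect_identical(sel, cvFeatureSelect(X, y, seed = 3L))  # deterministic
})

test_that("feature selection runs on a minimal smoke case", {
  X <- matrix(rnorm(4 * 6), 4, 6,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:6)))
  sel <- cvFeatureSelect(X, c("A", "A", "B", "B"), nFolds = 2L, nReps = 1L,
                         seed = 1L)
  expect_equal(nrow(sel), 6L)
  expect_setequal(sel$feature, colnames(X))
  expect_error(cvFeatureSelect(X, rep("A", 4)), "2 classes")
})

test_that("tiered training separates linearly separable classes", {
  set.seed(65)
  n <- 48L
  lab <- rep(c("PD", "SD", "PR"), each = n / 3)
  X <- matrix(rnorm(n * 40, 0, 0.2), n, 40,
              dimnames = list(sprintf("p%02d", 1:n), sprintf("f%02d", 1:40)))
  X[, 1] <- (lab == "PR") * 2
  X[, 2] <- (lab == "SD") * 2
  X[, 3] <- (lab == "PD") * 2
  tm <- trainTiered(X, lab, nReps = 30L, seed = 5L)
  predTrain <- predictTiered(tm, X[tm@trainingSampleIds, ])
  labTrain <- lab[match(tm@trainingSampleIds, rownames(X))]
  for (cl in c("PD", "SD", "PR")) {
    auc <- rocAUC(predTrain[[paste0("p_", tolower(cl))]], labTrain == cl,
                  nBoot = 100)$auc
    expect_equal(auc, 1)
  }
  # determinism end-to-end
  tm2 <- trainTiered(X, lab, nReps = 30L, seed = 5L)
  expect_identical(tm@featuresA, tm2@featuresA)
  expect_identical(tm@featuresB, tm2@featuresB)
  expect_equal(predictTiered(tm, X), predictTiered(tm2, X))
  # held-out predictions are class-probability vectors
  predTest <- predictTiered(tm, X[tm@testSampleIds, ])
  expect_true(all(abs(rowSums(predTest[, c("p_pd", "p_sd", "p_pr")]) - 1)
                  < 1e-9))
  # predicted class is invariant under feature column permutation
  perm <- sample(ncol(X))
  expect_equal(predictTiered(tm, X[, perm]), predictTiered(tm, X))
})

test_that("training-set structure follows the two-stage design", {
  set.seed(66)
  n <- 60L
  lab <- rep(c("PD", "SD", "PR"), times = c(30, 20, 10))
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("p%02d", 1:n), sprintf("f%02d", 1:20)))
  tm <- trainTiered(X, lab, nTrainPerClass = 8L, nReps = 5L, seed = 1L)
  labTr <- lab[match(tm@trainingSampleIds, rownames(X))]
  expect_equal(sum(labTr == "PR"), 8L)
  expect_equal(sum(labTr == "PD"), 8L)
  expect_equal(sum(labTr == "SD"), 16L)  # stage A's 16 are stage B's non-SD
  expect_length(intersect(tm@trainingSampleIds, tm@testSampleIds), 0L)
  expect_error(trainTiered(X, lab, nTrainPerClass = 11L, nReps = 2L),
               "class PR")
})

test_that("label-permuted training yields chance-level held-out AUC", {
  set.seed(67)
  aucs <- c()
  for (s in 1:6) {
    n <- 60L
    lab <- sample(rep(c("PD", "SD", "PR"), times = c(30, 20, 10)))
    X <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(sprintf("p%02d", 1:n), sprintf("f%02d", 1:30)))
    tm <- trainTiered(X, lab, nReps = 10L, seed = s)
    pred <- predictTiered(tm, X[tm@testSampleIds, ])
    labT <- lab[match(tm@testSampleIds, rownames(X))]
    for (cl in c("PD", "SD", "PR"))
      aucs <- c(aucs, rocAUC(pred[[paste0("p_", tolower(cl))]], labT == cl,
                             nBoot = 100, seed = s)$auc)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
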