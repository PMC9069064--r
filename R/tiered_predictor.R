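# Two-tiered random-forest response classifier: stage A separates PR from
# PD, stage B separates SD from non-SD; repeated cross-validated feature
# selection feeds each stage, and per-sample three-class probabilities come
# from a multiplicative combination of the two stage outputs.

#' @importFrom randomForest randomForest importance
NULL

# Stratified fold assignment; classes smaller than nFolds still spread one
# sample per fold, so degenerate folds (e.g. 1 sample per class with 16
# training samples in 8 folds) are legal.
.stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Repeated cross-validated feature selection
#'
#' Ranks features by their aggregated contribution over repeated stratified
#' cross-validation: in each repetition and fold, a small random forest is
#' grown on the in-fold samples over a random candidate-feature subset
#' (`ceiling(4 * sqrt(p))` features), its held-out fold accuracy is
#' recorded, and each candidate feature accrues
#' `importance x held-out accuracy` (`metric = "importance"`, the default)
#' or, alternatively, its selection frequency weighted by accuracy
#' (`metric = "frequency"`). Deterministic given `seed`.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (factor/character, exactly 2 classes).
#' @param nFolds folds per repetition (default 8; reduced automatically to
#'   the smaller class size when needed).
#' @param nReps repetitions (>= 1; default 200).
#' @param nTrees trees per selection forest (default 100).
#' @param metric `"importance"` or `"frequency"` contribution bookkeeping.
#' @param seed integer seed.
#' @return data.frame (`feature`, `score`, `rank`) sorted by decreasing
#'   score; ties broken by feature order.
#' @export
cvFeatureSelect <- function(X, y, nFolds = 8L, nReps = 200L, nTrees = 100L,
                            metric = c("importance", "frequency"),
                            seed = 1L) {
  metric <- match.arg(metric)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  if (nReps < 1L) stop("nReps must be >= 1")
  p <- ncol(X)
  nCand <- min(p, ceiling(4 * sqrt(p)))
  nFolds <- max(2L, min(nFolds, min(table(y)) * 2L, nrow(X)))
  score <- stats::setNames(numeric(p), colnames(X))
  .withSeed(seed, {
    for (rep in seq_len(nReps)) {
      fold <- .stratifiedFolds(y, nFolds)
      for (f in unique(fold)) {
        test <- fold == f
        yTrain <- y[!test]
        if (nlevels(droplevels(yTrain)) < 2L) next
        cand <- sample.int(p, nCand)
        rf <- randomForest::randomForest(
          X[!test, cand, drop = FALSE], yTrain, ntree = nTrees)
        pred <- stats::predict(rf, X[test, cand, drop = FALSE])
        acc <- mean(pred == y[test])
        contrib <- if (metric == "importance")
          randomForest::importance(rf)[, 1L] else 1
        score[cand] <- score[cand] + contrib * acc
      }
    }
  })
  ord <- order(-score, seq_len(p))
  data.frame(feature = colnames(X)[ord], score = unname(score[ord]),
             rank = seq_len(p), stringsAsFactors = FALSE)
}

# Out-of-fold AUC of a forest restricted to the top-k features, used to pick
# k on the selection grid. Small fixed CV inside the current RNG stream.
.oofAUC <- function(X, y, features, nFolds = 4L, nTrees = 100L) {
  nFolds <- max(2L, min(nFolds, min(table(y))))
  fold <- .stratifiedFolds(y, nFolds)
  scores <- rep(NA_real_, nrow(X))
  pos <- levels(y)[2L]
  for (f in unique(fold)) {
    test <- fold == f
    if (nlevels(droplevels(y[!test])) < 2L) next
    rf <- randomForest::randomForest(X[!test, features, drop = FALSE],
                                     y[!test], ntree = nTrees)
    scores[test] <- stats::predict(rf, X[test, features, drop = FALSE],
                                   type = "prob")[, pos]
  }
  ok <- !is.na(scores)
  if (length(unique(y[ok])) < 2L) return(NA_real_)
  .aucRank(scores[ok], y[ok] == pos)
}

# Mann-Whitney / rank formulation of the AUC, ties counted half.
.aucRank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted half, and a
#' stratified-bootstrap percentile 95% confidence interval.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) class labels; both classes required.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return list with `auc`, `ciLow`, `ciHigh`.
#' @examples
#' rocAUC(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE))$auc  # 0.75
#' @export
rocAUC <- function(scores, labels, nBoot = 2000L, seed = 1L) {
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) stop("missing scores or labels")
  auc <- .aucRank(scores, labels)
  posIdx <- which(labels); negIdx <- which(!labels)
  boot <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      ip <- sample(posIdx, length(posIdx), replace = TRUE)
      ineg <- sample(negIdx, length(negIdx), replace = TRUE)
      .aucRank(c(scores[ip], scores[ineg]),
               c(rep(TRUE, length(ip)), rep(FALSE, length(ineg))))
    }, 0)
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
  list(auc = auc, ciLow = ci[1L], ciHigh = ci[2L])
}

#' Combine the two stage probabilities into three classes
#'
#' Stage B gives the SD probability; stage A's PR-vs-PD probability splits
#' the non-SD mass: `p_sd = p_b_sd`, `p_pr = (1 - p_b_sd) * p_a_pr`,
#' `p_pd = (1 - p_b_sd) * (1 - p_a_pr)`. The three probabilities sum to 1
#' exactly.
#'
#' @param pAPr probability of PR from stage A, in \[0, 1\] (vectorised).
#' @param pBSd probability of SD from stage B, in \[0, 1\].
#' @return data.frame with columns `p_pd`, `p_sd`, `p_pr`.
#' @examples
#' combineProbabilities(0.6, 0.5)  # 0.2 / 0.5 / 0.3
#' @export
combineProbabilities <- function(pAPr, pBSd) {
  if (any(pAPr < 0 | pAPr > 1) || any(pBSd < 0 | pBSd > 1))
    stop("probabilities must lie in [0, 1]")
  data.frame(p_pd = (1 - pBSd) * (1 - pAPr),
             p_sd = pBSd,
             p_pr = (1 - pBSd) * pAPr)
}

#' Train the two-tiered random-forest response model
#'
#' Draws a class-stratified training set (`nTrainPerClass` PR and PD
#' patients for stage A; all stage-A training samples double as stage B's
#' non-SD class, joined by `2 * nTrainPerClass` SD patients), runs
#' [cvFeatureSelect()] separately per stage, picks the per-stage feature
#' count from `kGrid` by out-of-fold AUC (ties to the smaller k, capped at
#' `kCap`), and refits a final 500-tree forest per stage on its full
#' training data over the selected features.
#'
#' @param X samples x features matrix (rows named by sample id).
#' @param labels response labels in \{PD, SD, PR\}, aligned with rows of `X`.
#' @param nTrainPerClass PR/PD training count (default 8; SD gets twice
#'   this). An error names any class with too few samples.
#' @param nReps,nFolds,nTrees passed to [cvFeatureSelect()].
#' @param kGrid candidate selected-feature counts (default
#'   `c(5, 10, 20, 30, 50)`).
#' @param kCap upper bound on the selected k (default 30).
#' @param nTreesFinal trees in the final stage forests (default 500).
#' @param seed integer seed; identical inputs and seed give identical
#'   selected features and predictions.
#' @return A [TieredModel-class].
#' @export
trainTiered <- function(X, labels, nTrainPerClass = 8L, nReps = 200L,
                        nFolds = 8L, nTrees = 100L,
                        kGrid = c(5L, 10L, 20L, 30L, 50L), kCap = 30L,
                        nTreesFinal = 500L, seed = 1L) {
  stopifnot(is.matrix(X), !is.null(rownames(X)), !is.null(colnames(X)))
  labels <- as.character(labels)
  if (!all(labels %in% c("PD", "SD", "PR")))
    stop("labels must be PD, SD or PR")
  need <- c(PR = nTrainPerClass, PD = nTrainPerClass, SD = 2L * nTrainPerClass)
  for (cl in names(need)) {
    if (sum(labels == cl) < need[[cl]])
      stop(sprintf("class %s has %d samples but %d are required for training",
                   cl, sum(labels == cl), need[[cl]]))
  }
  kGrid <- sort(unique(pmin(kGrid, ncol(X), kCap)))

  train <- .withSeed(.subSeed(seed, 1L), {
    unlist(lapply(names(need), function(cl)
      sample(rownames(X)[labels == cl], need[[cl]])))
  })
  testIds <- setdiff(rownames(X), train)
  lab <- stats::setNames(labels, rownames(X))

  # stage A: PR vs PD on the 2 * nTrainPerClass PR/PD training samples
  idsA <- train[lab[train] %in% c("PD", "PR")]
  XA <- X[idsA, , drop = FALSE]
  yA <- factor(lab[idsA], levels = c("PD", "PR"))
  selA <- cvFeatureSelect(XA, yA, nFolds = nFolds, nReps = nReps,
                          nTrees = nTrees, seed = .subSeed(seed, 2L))
  # stage B: SD vs non-SD on all training samples
  XB <- X[train, , drop = FALSE]
  yB <- factor(ifelse(lab[train] == "SD", "SD", "nonSD"),
               levels = c("nonSD", "SD"))
  selB <- cvFeatureSelect(XB, yB, nFolds = nFolds, nReps = nReps,
                          nTrees = nTrees, seed = .subSeed(seed, 3L))

  pickK <- function(sel, Xt, yt, streamId) {
    .withSeed(.subSeed(seed, streamId), {
      aucs <- vapply(kGrid, function(k)
        .oofAUC(Xt, yt, sel$feature[seq_len(k)], nTrees = nTrees), 0)
      grid <- data.frame(k = kGrid, oofAUC = aucs)
      best <- kGrid[which.max(replace(aucs, is.na(aucs), -Inf))]
      list(k = best, grid = grid)
    })
  }
  kA <- pickK(selA, XA, yA, 4L)
  kB <- pickK(selB, XB, yB, 5L)
  featuresA <- selA$feature[seq_len(kA$k)]
  featuresB <- selB$feature[seq_len(kB$k)]

  fit <- .withSeed(.subSeed(seed, 6L), {
    list(a = randomForest::randomForest(XA[, featuresA, drop = FALSE], yA,
                                        ntree = nTreesFinal),
         b = randomForest::randomForest(XB[, featuresB, drop = FALSE], yB,
                                        ntree = nTreesFinal))
  })
  new("TieredModel", modelA = fit$a, modelB = fit$b,
      featuresA = featuresA, featuresB = featuresB,
      trainingSampleIds = train, testSampleIds = testIds,
      seed = as.integer(seed),
      selectionTrace = list(stageA = selA, stageB = selB,
                            kGridA = kA$grid, kGridB = kB$grid))
}

#' Predict three-class response probabilities
#'
#' Applies both stage forests of a [TieredModel-class] (class probability =
#' fraction of tree votes) and combines them with
#' [combineProbabilities()].
#'
#' @param model a TieredModel.
#' @param X samples x features matrix covering the model's features.
#' @return data.frame with `sample_id`, `p_pd`, `p_sd`, `p_pr` and
#'   `predicted` (argmax class).
#' @export
predictTiered <- function(model, X) {
  stopifnot(is(model, "TieredModel"), is.matrix(X))
  miss <- setdiff(c(model@featuresA, model@featuresB), colnames(X))
  if (length(miss)) stop("X is missing model features: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  pA <- stats::predict(model@modelA, X[, model@featuresA, drop = FALSE],
                       type = "prob")[, "PR"]
  pB <- stats::predict(model@modelB, X[, model@featuresB, drop = FALSE],
                       type = "prob")[, "SD"]
  pr <- combineProbabilities(pA, pB)
  cls <- c("PD", "SD", "PR")[max.col(pr, ties.method = "first")]
  cbind(data.frame(sample_id = rownames(X), stringsAsFactors = FALSE),
        pr, predicted = cls)
}

#' Fuse prediction results across data modalities
#'
#' Weighted arithmetic mean of class-probability vectors from models
#' trained on different feature sets (e.g. MGS, KO, tumour genetics),
#' renormalised per sample. Equal weights by default.
#'
#' @param results list of data.frames from [predictTiered()], covering the
#'   same samples in the same order.
#' @param weights non-negative weights, one per result (sum > 0).
#' @return data.frame in the [predictTiered()] layout.
#' @export
fuseMultiomics <- function(results, weights = NULL) {
  stopifnot(length(results) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(results))
  if (length(weights) != length(results) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  ids <- results[[1L]]$sample_id
  for (r in results)
    if (!identical(r$sample_id, ids))
      stop("all results must cover the same samples in the same order")
  cols <- c("p_pd", "p_sd", "p_pr")
  acc <- matrix(0, length(ids), 3L, dimnames = list(NULL, cols))
  for (i in seq_along(results))
    acc <- acc + weights[i] * as.matrix(results[[i]][, cols])
  acc <- acc / rowSums(acc)
  cls <- c("PD", "SD", "PR")[max.col(acc, ties.method = "first")]
  cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE),
        as.data.frame(acc), predicted = cls)
}

#' Baseline feature matrix for prediction
#'
#' Assembles the per-patient baseline (M0) feature table used by the tiered
#' predictor: MGS and/or KO relative abundances, optionally joined by
#' tumour-genetics columns (numeric TMB plus binary EGFR/ALK indicators
#' when present in the metadata).
#'
#' @param cohort an [ICTCohort-class].
#' @param features character subset of `c("mgs", "ko", "wes")`.
#' @param timepoint baseline visit label (default `"M0"`).
#' @return list with `X` (patients x features matrix, rows named by
#'   patient id) and `labels` (response per patient, FD excluded).
#' @export
baselineFeatures <- function(cohort, features = c("mgs", "ko"),
                             timepoint = "M0") {
  stopifnot(is(cohort, "ICTCohort"))
  features <- match.arg(features, c("mgs", "ko", "wes"), several.ok = TRUE)
  meta <- sampleMeta(cohort)
  sel <- meta$timepoint == timepoint & meta$response %in% c("PD", "SD", "PR")
  m <- meta[sel, ]
  blocks <- list()
  if ("mgs" %in% features)
    blocks$mgs <- mgsAbundance(cohort)[m$sample_id, , drop = FALSE]
  if ("ko" %in% features)
    blocks$ko <- koAbundance(cohort)[m$sample_id, , drop = FALSE]
  if ("wes" %in% features) {
    wes <- cbind(TMB = m$tmb)
    if ("egfr" %in% colnames(m)) wes <- cbind(wes, EGFR = as.numeric(m$egfr))
    if ("alk" %in% colnames(m)) wes <- cbind(wes, ALK = as.numeric(m$alk))
    rownames(wes) <- m$sample_id
    blocks$wes <- wes
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- m$patient_id
  list(X = X, labels = stats::setNames(m$response, m$patient_id))
}
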