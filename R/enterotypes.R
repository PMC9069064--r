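# Dirichlet-multinomial mixture (DMM) enterotyping of genus-level profiles.
# The mixture is fitted by EM with weighted Minka fixed-point updates of the
# Dirichlet parameters; model order is selected by Laplace-approximated
# evidence (BIC available as an alternative).

.ALPHA_MIN <- 1e-6
.ALPHA_MAX <- 1e6

#' Aggregate species abundances to genus-level counts
#'
#' Sums MGS relative abundances by genus, renormalises per sample,
#' multiplies by a pseudo-count sequencing depth and rounds half-to-even.
#' Rounding residue is removed from the largest genus so that no sample
#' exceeds `depth` counts.
#'
#' @param mgsAbund samples x MGS matrix or an [ICTCohort-class].
#' @param taxonomy data.frame with `mgs_id` and `genus` columns (taken from
#'   the cohort when one is given).
#' @param depth pseudo-count depth (>= 100; default 10000).
#' @return samples x genus integer count matrix.
#' @export
toGenusCounts <- function(mgsAbund, taxonomy = NULL, depth = 10000L) {
  if (is(mgsAbund, "ICTCohort")) {
    taxonomy <- taxonomyMap(mgsAbund)
    mgsAbund <- mgsAbundance(mgsAbund)
  }
  stopifnot(is.matrix(mgsAbund), is.data.frame(taxonomy))
  if (depth < 100) stop("depth must be >= 100")
  genus <- taxonomy$genus[match(colnames(mgsAbund), taxonomy$mgs_id)]
  if (anyNA(genus)) stop("taxonomy does not cover all MGS features")
  agg <- t(rowsum(t(mgsAbund), group = genus))
  agg <- agg / rowSums(agg)
  counts <- round(agg * depth)
  over <- rowSums(counts) - depth
  for (i in which(over > 0)) {
    j <- which.max(counts[i, ])
    counts[i, j] <- counts[i, j] - over[i]
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate Dirichlet-multinomial mixture counts
#'
#' Draws `n` count profiles at fixed depth from a K-component DMM: a
#' component per sample from `weights`, a composition from the component's
#' Dirichlet, counts from the multinomial.
#'
#' @param n number of samples.
#' @param alpha K x G matrix of positive Dirichlet parameters (a vector is
#'   treated as one component).
#' @param weights mixture proportions (default uniform).
#' @param depth counts per sample.
#' @param seed integer seed.
#' @return list with `counts` (n x G integer matrix) and `component`
#'   (true component index per sample).
#' @export
simulateDMMCounts <- function(n, alpha, weights = NULL, depth = 5000L,
                              seed = 1L) {
  if (is.vector(alpha)) alpha <- matrix(alpha, nrow = 1L)
  K <- nrow(alpha); G <- ncol(alpha)
  if (is.null(weights)) weights <- rep(1 / K, K)
  stopifnot(length(weights) == K, all(alpha > 0))
  .withSeed(seed, {
    comp <- sample.int(K, n, replace = TRUE, prob = weights)
    counts <- matrix(0L, n, G)
    for (i in seq_len(n)) {
      g <- stats::rgamma(G, shape = alpha[comp[i], ], rate = 1)
      p <- g / sum(g)
      counts[i, ] <- as.integer(stats::rmultinom(1L, depth, p))
    }
    colnames(counts) <- sprintf("g%02d", seq_len(G))
    list(counts = counts, component = comp)
  })
}

# Per-component DM log density for all samples. X: N x G counts, alpha: G,
# n: precomputed row sums. Includes the multinomial coefficient (constant
# across components).
.dmLogDensity <- function(X, alpha, logCoef, n) {
  A <- sum(alpha)
  la <- lgamma(X + rep(alpha, each = nrow(X)))
  as.numeric(la %*% rep(1, ncol(X))) - sum(lgamma(alpha)) +
    lgamma(A) - lgamma(n + A) + logCoef
}

# Weighted Minka fixed-point update of one component's alpha.
.minkaUpdate <- function(X, r, alpha, n, inner = 5L) {
  N <- nrow(X)
  sr <- sum(r)
  for (it in seq_len(inner)) {
    A <- sum(alpha)
    dg <- digamma(X + rep(alpha, each = N))
    num <- as.numeric(crossprod(r, dg)) - sr * digamma(alpha)
    den <- sum(r * (digamma(n + A) - digamma(A)))
    if (den <= 0) break
    alpha <- alpha * pmax(num, 0) / den
    alpha <- pmin(pmax(alpha, .ALPHA_MIN), .ALPHA_MAX)
  }
  alpha
}

# Initial responsibilities from k-means on proportion profiles.
.initResponsibilities <- function(P, K, seed) {
  N <- nrow(P)
  cl <- .withSeed(seed, {
    if (K == 1L) rep(1L, N)
    else tryCatch(stats::kmeans(P, centers = K, nstart = 3L)$cluster,
                  error = function(e) sample.int(K, N, replace = TRUE))
  })
  R <- matrix(0.1 / max(1L, K - 1L), N, K)
  R[cbind(seq_len(N), cl)] <- if (K == 1L) 1 else 0.9
  R / rowSums(R)
}

# Laplace-approximated log evidence. The Hessian of the log-likelihood in
# log(alpha) is approximated component-wise (responsibility-weighted,
# ignoring responsibility derivatives); each component block has the form
# diag(d) + c * 11', so its determinant comes from the matrix-determinant
# lemma in O(G). Mixture weights contribute a BIC-style (K-1)/2 log N term.
# Falls back to BIC when the curvature is not usable.
.laplaceEvidence <- function(X, fit) {
  K <- fit$K; G <- ncol(fit$alpha); N <- nrow(X)
  n <- rowSums(X)
  logDet <- 0
  for (k in seq_len(K)) {
    a <- fit$alpha[k, ]
    A <- sum(a)
    r <- fit$R[, k]
    cK <- sum(r * (trigamma(A) - trigamma(n + A)))
    d <- colSums(r * trigamma(sweep(X, 2L, a, "+"))) - sum(r) * trigamma(a)
    d <- pmin(d, -1e-10)
    lemma <- 1 - cK * sum(1 / d)
    if (!is.finite(lemma) || lemma <= 0) return(NA_real_)
    # block in log(alpha): diag(a) %*% (diag(d) + c 11') %*% diag(a)
    logDet <- logDet + 2 * sum(log(a)) + sum(log(-d)) + log(lemma)
  }
  dPar <- K * G
  fit$logLik + 0.5 * dPar * log(2 * pi) - 0.5 * logDet -
    0.5 * (K - 1) * log(N)
}

.bicEvidence <- function(X, fit) {
  dPar <- fit$K * ncol(fit$alpha) + (fit$K - 1)
  fit$logLik - 0.5 * dPar * log(nrow(X))
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Expectation-maximisation for a K-component DMM on genus-level counts.
#' The E-step computes posterior component memberships; the M-step updates
#' mixture weights and applies weighted Minka fixed-point iterations to each
#' component's Dirichlet parameters. The observed-data log-likelihood is
#' checked to be non-decreasing every iteration (within numerical
#' tolerance); the run stops when its relative change drops below `tol`.
#'
#' @param counts samples x genus non-negative integer matrix with positive
#'   row sums.
#' @param K number of components (>= 1).
#' @param seed integer seed (initialisation).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter maximum EM iterations (default 500); non-convergence
#'   returns the best fit flagged `converged = FALSE`.
#' @param criterion `"bic"` (default) or `"laplace"` model-selection score
#'   stored in `logEvidence`. The Laplace approximation is Hessian-based
#'   and becomes unreliable when a component captures few samples (its
#'   curvature block is near-singular), which at desk-scale cohort sizes
#'   underpenalises extra components; BIC is the robust default.
#' @return A [DMMFit-class].
#' @export
fitDMM <- function(counts, K, seed = 1L, tol = 1e-6, maxIter = 500L,
                   criterion = c("bic", "laplace")) {
  criterion <- match.arg(criterion)
  stopifnot(K >= 1L, is.matrix(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0)) stop("zero-sum count rows are not allowed")
  X <- counts
  storage.mode(X) <- "double"
  N <- nrow(X); G <- ncol(X)
  n <- rowSums(X)
  logCoef <- lgamma(n + 1) - rowSums(lgamma(X + 1))
  P <- X / n
  R <- .initResponsibilities(P, as.integer(K), seed)

  w <- colMeans(R)
  alpha <- matrix(0, K, G)
  for (k in seq_len(K)) {
    pk <- colSums(R[, k] * P) / sum(R[, k])
    alpha[k, ] <- pmax(pk, 1e-4) * G  # modest initial concentration
  }

  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step
    logF <- matrix(0, N, K)
    for (k in seq_len(K))
      logF[, k] <- .dmLogDensity(X, alpha[k, ], logCoef, n) + log(w[k])
    m <- logF[, 1L]
    if (K > 1L) for (k in 2:K) m <- pmax(m, logF[, k])
    lse <- m + log(rowSums(exp(logF - m)))
    llNew <- sum(lse)
    if (llNew < ll - 1e-6 * (1 + abs(ll)))
      warning("EM log-likelihood decreased; stopping at previous iterate")
    R <- exp(logF - lse)
    if (is.finite(ll) && abs(llNew - ll) <= tol * (1 + abs(ll))) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
    if (iter >= maxIter) break
    # M-step
    w <- pmax(colMeans(R), 1e-10)
    w <- w / sum(w)
    for (k in seq_len(K))
      alpha[k, ] <- .minkaUpdate(X, R[, k], alpha[k, ], n)
  }
  colnames(alpha) <- colnames(counts)
  fit <- list(K = as.integer(K), alpha = alpha, R = R, logLik = ll)
  ev <- if (criterion == "laplace") .laplaceEvidence(X, fit) else NA_real_
  if (!is.finite(ev)) ev <- .bicEvidence(X, fit)
  new("DMMFit", K = as.integer(K), weights = as.numeric(w), alpha = alpha,
      responsibilities = R, logLik = ll, logEvidence = ev,
      converged = converged, iterations = iter)
}

#' Select the number of enterotypes
#'
#' Fits the DMM at each candidate K with several random restarts (k-means
#' initialisations under different derived seeds), keeps the best
#' log-likelihood fit per K and returns the K with the highest model
#' evidence. K = 1 has a deterministic initialisation and is fitted once;
#' for K > 1 the restart loop stops early once two restarts have reproduced
#' the incumbent optimum (within likelihood tolerance).
#'
#' @param counts samples x genus count matrix.
#' @param kRange candidate component counts (default 1:5).
#' @param seed integer seed.
#' @param nRestarts restarts per K (default 5).
#' @param ... passed to [fitDMM()] (e.g. `criterion`, `tol`, `maxIter`).
#' @return list with `bestK`, `fit` (the winning [DMMFit-class]) and
#'   `evidence` (data.frame K, logLik, logEvidence).
#' @export
selectK <- function(counts, kRange = 1:5, seed = 1L, nRestarts = 5L, ...) {
  if (!length(kRange)) stop("kRange must be non-empty")
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    K <- kRange[i]
    best <- NULL
    dup <- 0L
    for (r in seq_len(if (K == 1L) 1L else nRestarts)) {
      f <- fitDMM(counts, K, seed = .subSeed(seed, K, r), ...)
      if (is.null(best) || f@logLik > best@logLik + 1e-6 * (1 + abs(f@logLik))) {
        if (!is.null(best) &&
            f@logLik > best@logLik + 1e-6 * (1 + abs(f@logLik))) dup <- 0L
        best <- f
      } else dup <- dup + 1L
      if (dup >= 2L) break
    }
    fits[[i]] <- best
  }
  ev <- data.frame(K = as.integer(kRange),
                   logLik = vapply(fits, function(f) f@logLik, 0),
                   logEvidence = vapply(fits, function(f) f@logEvidence, 0))
  bi <- which.max(ev$logEvidence)
  list(bestK = ev$K[bi], fit = fits[[bi]], evidence = ev)
}

#' Hard enterotype assignments and driver genera
#'
#' Maximum-posterior component per sample plus, per component, the genera
#' with the largest expected proportions (the "drivers").
#'
#' @param fit a [DMMFit-class].
#' @param topN driver genera reported per component (default 3).
#' @return list with `assignment` (integer per sample) and `drivers`
#'   (list of named numeric vectors of expected proportions).
#' @export
enterotypeAssignments <- function(fit, topN = 3L) {
  stopifnot(is(fit, "DMMFit"))
  assignment <- max.col(fit@responsibilities, ties.method = "first")
  drivers <- lapply(seq_len(fit@K), function(k) {
    p <- fit@alpha[k, ] / sum(fit@alpha[k, ])
    utils::head(sort(p, decreasing = TRUE), topN)
  })
  list(assignment = assignment, drivers = drivers)
}
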