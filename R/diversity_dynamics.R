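# Alpha/beta diversity per response group and timepoint, and a permutation
# spline test for longitudinal group comparison.

#' Shannon diversity index
#'
#' `H = -sum(q * log(q))` in nats over the renormalised vector
#' `q = p / sum(p)`, skipping zero entries. Bounded by `log(#nonzero)`.
#'
#' @param p non-negative abundance vector with positive sum.
#' @return Shannon index in nats.
#' @examples
#' shannonIndex(rep(1, 4))          # log(4)
#' shannonIndex(c(0.5, 0.3, 0.2))
#' @export
shannonIndex <- function(p) {
  if (any(p < 0) || anyNA(p)) stop("abundances must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("all-zero abundance vector")
  q <- p[p > 0] / s
  -sum(q * log(q))
}

#' Bray-Curtis dissimilarity
#'
#' `d = 1 - 2 * sum(pmin(p, q)) / (sum(p) + sum(q))`, symmetric, in
#' \[0, 1\], and invariant under joint rescaling of both vectors.
#'
#' @param p,q non-negative abundance vectors over the same features, each
#'   with positive sum.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' brayCurtis(c(0.7, 0.3, 0), c(0.2, 0.3, 0.5))  # 0.5
#' @export
brayCurtis <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  if (any(p < 0) || any(q < 0) || anyNA(p) || anyNA(q))
    stop("abundances must be non-negative")
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("all-zero abundance vector")
  1 - 2 * sum(pmin(p, q)) / (sp + sq)
}

#' Within-group beta-diversity dispersion at a timepoint
#'
#' All pairwise Bray-Curtis dissimilarities among the samples of one
#' response group at one visit: the quantity whose temporal trajectory
#' summarises how internally (dis)similar a group's gut microbiota is.
#'
#' @param abund samples x features abundance matrix or [ICTCohort-class]
#'   (MGS table used).
#' @param group response-group label.
#' @param timepoint visit label.
#' @param meta metadata data.frame (ignored for a cohort).
#' @return A list with `group`, `timepoint`, `week` and `values` (numeric
#'   vector of length n(n-1)/2; empty, with a warning, when fewer than two
#'   samples are available).
#' @export
groupDispersion <- function(abund, group, timepoint, meta = NULL) {
  if (is(abund, "ICTCohort")) {
    meta <- sampleMeta(abund)
    abund <- mgsAbundance(abund)
  }
  sel <- meta$response == group & meta$timepoint == timepoint
  ids <- meta$sample_id[sel]
  week <- if (any(sel)) meta$week[sel][1L] else NA_integer_
  if (length(ids) < 2L) {
    warning(sprintf("fewer than 2 samples for %s at %s", group, timepoint))
    return(list(group = group, timepoint = timepoint, week = week,
                values = numeric()))
  }
  m <- abund[ids, , drop = FALSE]
  n <- nrow(m)
  vals <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n)) {
      k <- k + 1L
      vals[k] <- brayCurtis(m[i, ], m[j, ])
    }
  list(group = group, timepoint = timepoint, week = week, values = vals)
}

# Local linear regression with tricube weights on a fixed grid. `span` is
# the fraction of points forming each neighbourhood (loess-style).
.localLinear <- function(x, y, grid, span = 0.75) {
  n <- length(x)
  k <- max(2L, min(n, floor(span * n)))
  vapply(grid, function(g) {
    d <- abs(x - g)
    h <- sort(d, partial = k)[k]
    if (h <= 0) h <- max(d)
    if (h <= 0) return(mean(y))
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    xm <- x[use] - g
    wm <- w[use]; ym <- y[use]
    sw <- sum(wm); sx <- sum(wm * xm); sxx <- sum(wm * xm^2)
    sy <- sum(wm * ym); sxy <- sum(wm * xm * ym)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-12 * max(sxx, 1)) sy / sw
    else (sxx * sy - sx * sxy) / det  # intercept at x = g
  }, 0)
}

#' Permutation spline test for longitudinal group difference
#'
#' Compares two groups' longitudinal trajectories: one tricube local-linear
#' smoother (span 0.75) is fitted per group over the overlapping week range,
#' the test statistic is the mean absolute difference between the two
#' smoothers on an evenly spaced grid, and its null distribution is built by
#' permuting group labels between whole patients (all of a patient's
#' observations move together, respecting repeated measures). The p-value
#' uses the add-one permutation convention and is therefore in (0, 1\].
#'
#' @param seriesA,seriesB data.frames with columns `patient`, `week`,
#'   `value`; each group needs observations at >= 3 distinct weeks.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed.
#' @param gridSize evaluation grid size (default 50).
#' @return A list with `statistic`, `p`, `grid`, `fitA`, `fitB`, `nPerm`.
#' @examples
#' a <- data.frame(patient = rep(1:6, each = 4), week = rep(c(0, 2, 4, 8), 6),
#'                 value = rnorm(24))
#' b <- a; b$patient <- b$patient + 100; b$value <- b$value + 2
#' permusplineTest(a, b, nPerm = 99, seed = 1)$p
#' @export
permusplineTest <- function(seriesA, seriesB, nPerm = 999L, seed = 1L,
                            gridSize = 50L) {
  for (s in list(seriesA, seriesB))
    stopifnot(all(c("patient", "week", "value") %in% colnames(s)))
  if (nPerm < 99L) stop("nPerm must be >= 99")
  if (length(unique(seriesA$week)) < 3L || length(unique(seriesB$week)) < 3L)
    stop("each group needs observations at >= 3 distinct weeks")
  lo <- max(min(seriesA$week), min(seriesB$week))
  hi <- min(max(seriesA$week), max(seriesB$week))
  if (hi <= lo) stop("no overlapping week range between the groups")
  grid <- seq(lo, hi, length.out = gridSize)

  statFun <- function(a, b) {
    fa <- .localLinear(a$week, a$value, grid)
    fb <- .localLinear(b$week, b$value, grid)
    mean(abs(fa - fb))
  }
  fitA <- .localLinear(seriesA$week, seriesA$value, grid)
  fitB <- .localLinear(seriesB$week, seriesB$value, grid)
  obs <- mean(abs(fitA - fitB))

  # pool observations, keyed by patient; permute patient-level labels
  pool <- rbind(
    data.frame(patient = as.character(seriesA$patient), week = seriesA$week,
               value = seriesA$value),
    data.frame(patient = as.character(seriesB$patient), week = seriesB$week,
               value = seriesB$value)
  )
  patients <- unique(pool$patient)
  nA <- length(unique(as.character(seriesA$patient)))
  exceed <- .withSeed(seed, {
    cnt <- 0L
    for (r in seq_len(nPerm)) {
      pa <- sample(patients, nA)
      inA <- pool$patient %in% pa
      st <- statFun(pool[inA, ], pool[!inA, ])
      if (st >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(statistic = obs, p = (1 + exceed) / (1 + nPerm), grid = grid,
       fitA = fitA, fitB = fitB, nPerm = as.integer(nPerm))
}

#' Per-group alpha-diversity series from a cohort
#'
#' Convenience wrapper computing the Shannon index of every sample and
#' returning a long data.frame suitable for [permusplineTest()] and
#' trajectory plots.
#'
#' @param cohort an [ICTCohort-class].
#' @param level `"mgs"` (default) or `"ko"`: which profile to use. (The
#'   study computed diversity on its gene catalogue; level choice is
#'   documented, not enforced.)
#' @return data.frame with columns `sample_id`, `patient`, `group`,
#'   `timepoint`, `week`, `value`.
#' @export
alphaDiversitySeries <- function(cohort, level = c("mgs", "ko")) {
  level <- match.arg(level)
  m <- if (level == "mgs") mgsAbundance(cohort) else koAbundance(cohort)
  meta <- sampleMeta(cohort)
  data.frame(sample_id = meta$sample_id, patient = meta$patient_id,
             group = meta$response, timepoint = meta$timepoint,
             week = meta$week,
             value = apply(m[meta$sample_id, , drop = FALSE], 1, shannonIndex),
             row.names = NULL)
}
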