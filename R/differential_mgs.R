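# BMI-adjusted per-species ANOVA across the PD/SD/PR response groups,
# Tukey HSD pairwise contrasts and enrichment labelling.

#' BMI-adjusted one-way ANOVA
#'
#' Tests for a response-group effect on a (transformed) abundance while
#' adjusting for body-mass index: the linear model `value ~ group + bmi` is
#' compared against the reduced model `value ~ bmi` by an extra-sum-of-
#' squares F test.
#'
#' @param values numeric per-sample response (e.g. log10 relative
#'   abundance).
#' @param groups factor or character group labels (>= 2 groups, each with
#'   >= 3 samples).
#' @param bmi numeric covariate, finite.
#' @return The F-test p-value, or `NA` (with a warning) for degenerate
#'   inputs (constant values, no residual degrees of freedom).
#' @export
bmiAdjustedAnova <- function(values, groups, bmi) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 3L)) stop("each group needs >= 3 samples")
  if (!all(is.finite(bmi))) stop("bmi must be finite")
  p <- .anovaFMany(matrix(values, ncol = 1L), groups, bmi)
  p[1L]
}

# Vectorised extra-sum-of-squares F test over the columns of Y for
# `y ~ group + bmi` vs `y ~ bmi`. Shared design across features makes this
# a pair of QR decompositions regardless of feature count.
.anovaFMany <- function(Y, groups, bmi) {
  groups <- droplevels(factor(groups))
  X1 <- stats::model.matrix(~ groups + bmi)
  X0 <- stats::model.matrix(~ bmi)
  q1 <- qr(X1); q0 <- qr(X0)
  r1 <- qr.resid(q1, Y); r0 <- qr.resid(q0, Y)
  rss1 <- colSums(r1^2); rss0 <- colSums(r0^2)
  df1 <- q1$rank - q0$rank
  df2 <- nrow(Y) - q1$rank
  out <- rep(NA_real_, ncol(Y))
  if (df2 <= 0L || df1 <= 0L) {
    warning("no residual degrees of freedom; returning NA")
    return(out)
  }
  tss <- colSums(scale(Y, scale = FALSE)^2)
  ok <- tss > 1e-12 * pmax(1, colMeans(Y)^2) & rss1 > 0
  constant <- !ok & tss <= 1e-12 * pmax(1, colMeans(Y)^2)
  if (any(constant)) {
    warning(sum(constant), " constant feature(s); returning NA")
  }
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  out[ok] <- stats::pf(Fstat[ok], df1, df2, lower.tail = FALSE)
  # perfect fits (rss1 == 0) with real variation: p -> 0
  perfect <- !ok & !constant
  out[perfect] <- 0
  out
}

#' Tukey honest-significant-difference pairwise p-values
#'
#' Family-adjusted studentized-range p-values for every group pair of a
#' one-way layout, via [stats::TukeyHSD()] on the underlying ANOVA fit.
#' Pairs involving a group with a single sample are reported `NA`.
#'
#' @param values numeric responses.
#' @param groups group labels (>= 2 groups with >= 2 samples each overall;
#'   singleton groups are tolerated but excluded pairwise).
#' @return Named numeric vector of adjusted p-values; names are
#'   `"A-B"` pairs as produced by `TukeyHSD` (order-symmetric).
#' @export
tukeyHSDPairs <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  sizes <- table(groups)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  p <- tk[, "p adj"]
  names(p) <- rownames(tk)
  singleton <- names(sizes)[sizes < 2L]
  if (length(singleton)) {
    pairs <- strsplit(names(p), "-", fixed = TRUE)
    bad <- vapply(pairs, function(pr) any(pr %in% singleton), TRUE)
    p[bad] <- NA_real_
  }
  p
}

#' Enrichment labelling of a differential species
#'
#' Assigns the group with the highest ("+") and lowest ("-") median
#' abundance of a species, unless the species occurs in too few samples of
#' every group to call a direction, in which case both labels are `NA`.
#' Median ties are broken by higher occurrence, then by the fixed group
#' order PR > SD > PD.
#'
#' @param medianAbund named numeric, per-group median relative abundance.
#' @param occurrence named numeric, per-group fraction of samples with
#'   nonzero abundance.
#' @param minOccurrence occurrence threshold; if no group reaches it the
#'   result is `(NA, NA)`.
#' @return list with `high` and `low` group labels (or `NA`).
#' @export
enrichmentLabel <- function(medianAbund, occurrence, minOccurrence = 0.2) {
  groups <- intersect(c("PR", "SD", "PD"), names(medianAbund))
  if (length(groups) < 3L) stop("three groups (PR, SD, PD) required")
  med <- medianAbund[groups]
  occ <- occurrence[groups]
  if (max(occ) < minOccurrence) return(list(high = NA_character_,
                                            low = NA_character_))
  ord <- order(-med, -occ, match(groups, c("PR", "SD", "PD")))
  list(high = groups[ord[1L]], low = groups[ord[length(groups)]])
}

#' BMI-adjusted differential-abundance screen over all species
#'
#' For every MGS: transforms its relative abundances (default
#' `log10(x + eps)` with `eps` half the smallest nonzero value of the
#' matrix), runs the BMI-adjusted ANOVA across PD/SD/PR, adjusts p-values by
#' Benjamini-Hochberg over all tested species, and, for the significant
#' ones, computes Tukey HSD pairwise contrasts and enrichment labels.
#' FD samples are excluded; the caller is expected to supply an
#' antibiotics-excluded view (see [validateCohort()]).
#'
#' @param cohort an [ICTCohort-class], or a samples x features matrix.
#' @param transform `"log10"` (default) or `"identity"`.
#' @param alpha significance level (default 0.05).
#' @param useQ call significance on BH q-values instead of raw p
#'   (default FALSE, mirroring a per-feature ANOVA screen; q-values are
#'   reported either way).
#' @param minOccurrence occurrence threshold for [enrichmentLabel()].
#' @param timepoint optional visit label to restrict the test to; default
#'   pools all longitudinal samples.
#' @param meta metadata data.frame when `cohort` is a matrix.
#' @return data.frame (one row per MGS, sorted by q then p) with columns
#'   `mgs_id`, `anova_p`, `bh_q`, `significant`, Tukey pairwise p columns
#'   `tukey_PR_SD`, `tukey_PR_PD`, `tukey_SD_PD`, enrichment labels
#'   `enrich_high`/`enrich_low` and per-group occurrence and median
#'   abundance columns.
#' @export
runDifferential <- function(cohort, transform = c("log10", "identity"),
                            alpha = 0.05, useQ = FALSE, minOccurrence = 0.2,
                            timepoint = NULL, meta = NULL) {
  transform <- match.arg(transform)
  if (is(cohort, "ICTCohort")) {
    meta <- sampleMeta(cohort)
    abund <- mgsAbundance(cohort)
  } else abund <- cohort
  stopifnot(is.matrix(abund), is.data.frame(meta))
  if (!nrow(abund) || !ncol(abund)) stop("empty abundance matrix")
  keep <- meta$response %in% c("PR", "SD", "PD")
  if (!is.null(timepoint)) keep <- keep & meta$timepoint == timepoint
  meta <- meta[keep, , drop = FALSE]
  abund <- abund[meta$sample_id, , drop = FALSE]
  groups <- factor(meta$response, levels = c("PR", "SD", "PD"))
  if (any(table(groups) < 3L)) stop("each of PR, SD, PD needs >= 3 samples")

  Y <- if (transform == "log10") {
    nz <- abund[abund > 0]
    eps <- if (length(nz)) min(nz) / 2 else 1e-12
    log10(abund + eps)
  } else abund
  p <- .anovaFMany(Y, groups, meta$bmi)
  q <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p) & (if (useQ) q else p) < alpha

  gl <- levels(groups)
  occ <- sapply(gl, function(g)
    colMeans(abund[groups == g, , drop = FALSE] > 0))
  med <- sapply(gl, function(g)
    apply(abund[groups == g, , drop = FALSE], 2, stats::median))

  n <- ncol(abund)
  tukey <- matrix(NA_real_, n, 3L,
                  dimnames = list(NULL, c("tukey_PR_SD", "tukey_PR_PD",
                                          "tukey_SD_PD")))
  high <- low <- rep(NA_character_, n)
  for (j in which(sig)) {
    tk <- tukeyHSDPairs(Y[, j], groups)
    tukey[j, "tukey_PR_SD"] <- .pickPair(tk, "PR", "SD")
    tukey[j, "tukey_PR_PD"] <- .pickPair(tk, "PR", "PD")
    tukey[j, "tukey_SD_PD"] <- .pickPair(tk, "SD", "PD")
    lab <- enrichmentLabel(med[j, ], occ[j, ], minOccurrence)
    high[j] <- lab$high
    low[j] <- lab$low
  }
  out <- data.frame(mgs_id = colnames(abund), anova_p = p, bh_q = q,
                    significant = sig, tukey, enrich_high = high,
                    enrich_low = low,
                    occ_PR = occ[, "PR"], occ_SD = occ[, "SD"],
                    occ_PD = occ[, "PD"],
                    median_PR = med[, "PR"], median_SD = med[, "SD"],
                    median_PD = med[, "PD"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$bh_q, out$anova_p), ]
}

.pickPair <- function(p, a, b) {
  i <- match(paste(a, b, sep = "-"), names(p))
  if (is.na(i)) i <- match(paste(b, a, sep = "-"), names(p))
  if (is.na(i)) NA_real_ else unname(p[i])
}
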