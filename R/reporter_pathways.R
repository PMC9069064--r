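# Signed, background-corrected reporter scores: pathway-level aggregation
# of per-KO differential z-scores between two response groups, standardised
# against a Monte-Carlo background of random same-size KO sets.

.Z_CAP <- 8  # |z| ceiling, guards against p-value underflow

#' Per-KO differential test between two response groups
#'
#' For every KO, a two-sided Wilcoxon rank-sum test (normal approximation
#' with tie correction) compares relative abundances between a designated
#' "better" and "worse" response group at one visit. The signed z-score is
#' `qnorm(1 - p/2)` carrying the sign of the median difference (a zero
#' median difference maps to +1), capped at +/- 8. A KO constant across
#' both groups scores `p = 1, z = 0`.
#'
#' @param koAbund samples x KO matrix or an [ICTCohort-class].
#' @param betterGroup,worseGroup response labels; positive z means enriched
#'   in `betterGroup`.
#' @param timepoint visit label (default `"M0"`).
#' @param meta metadata data.frame when a matrix is given.
#' @return data.frame with columns `ko_id`, `p`, `direction`, `z`.
#' @export
koDifferential <- function(koAbund, betterGroup, worseGroup,
                           timepoint = "M0", meta = NULL) {
  if (is(koAbund, "ICTCohort")) {
    meta <- sampleMeta(koAbund)
    koAbund <- koAbundance(koAbund)
  }
  selB <- meta$response == betterGroup & meta$timepoint == timepoint
  selW <- meta$response == worseGroup & meta$timepoint == timepoint
  if (sum(selB) < 3L || sum(selW) < 3L)
    stop(sprintf("need >= 3 samples per group at %s (got %d vs %d)",
                 timepoint, sum(selB), sum(selW)))
  B <- koAbund[meta$sample_id[selB], , drop = FALSE]
  W <- koAbund[meta$sample_id[selW], , drop = FALSE]
  nko <- ncol(koAbund)
  p <- numeric(nko); dir <- integer(nko)
  for (j in seq_len(nko)) {
    b <- B[, j]; w <- W[, j]
    if (max(c(b, w)) == min(c(b, w))) {
      p[j] <- 1; dir[j] <- 1L
      next
    }
    p[j] <- stats::wilcox.test(b, w, exact = FALSE)$p.value
    d <- stats::median(b) - stats::median(w)
    dir[j] <- if (d >= 0) 1L else -1L
  }
  p[is.na(p)] <- 1
  z <- pmin(stats::qnorm(1 - p / 2), .Z_CAP) * dir
  data.frame(ko_id = colnames(koAbund), p = p, direction = dir, z = z,
             stringsAsFactors = FALSE)
}

#' Background-corrected reporter scores per pathway
#'
#' Aggregates per-KO signed z-scores into pathway-level reporter scores:
#' a pathway with member scores `z1..zk` gets `raw_z = sum(z) / sqrt(k)`,
#' which is centred and scaled by the mean and standard deviation of the
#' same statistic over `nBackground` random draws of k KOs (without
#' replacement) from all scored KOs. Positive corrected scores mean
#' enrichment in the "better" group of the underlying contrast. Pathways
#' with no scored KO are dropped with a message. Backgrounds with (near)
#' zero spread return a corrected score of 0.
#'
#' @param koResults data.frame from [koDifferential()].
#' @param pathwayMap named list, pathway id -> KO ids.
#' @param nBackground Monte-Carlo background size (>= 100; default 1000).
#' @param seed integer seed for the background draws.
#' @param alpha,alphaStrict significance levels for the reported boolean
#'   flags (defaults 0.05 and 0.01).
#' @return data.frame with columns `pathway_id`, `k` (scored KOs used),
#'   `raw_z`, `corrected_z`, `significant_05`, `significant_01`.
#' @export
reporterScore <- function(koResults, pathwayMap, nBackground = 1000L,
                          seed = 1L, alpha = 0.05, alphaStrict = 0.01) {
  stopifnot(all(c("ko_id", "z") %in% colnames(koResults)))
  if (nBackground < 100L) stop("nBackground must be >= 100")
  z <- stats::setNames(koResults$z, koResults$ko_id)
  ks <- vapply(pathwayMap, function(m) sum(m %in% names(z)), 0L)
  dropped <- names(pathwayMap)[ks == 0L]
  if (length(dropped))
    message("dropping ", length(dropped), " pathway(s) with no scored KO")
  keep <- names(pathwayMap)[ks > 0L]
  if (!length(keep)) stop("no pathway has scored KOs")

  rawZ <- vapply(keep, function(pid) {
    zi <- z[intersect(pathwayMap[[pid]], names(z))]
    sum(zi) / sqrt(length(zi))
  }, 0)
  kk <- ks[keep]

  # background moments per distinct set size, one seeded stream
  moments <- .withSeed(seed, {
    sizes <- sort(unique(kk))
    res <- matrix(0, length(sizes), 2L,
                  dimnames = list(as.character(sizes), c("mu", "sigma")))
    for (s in sizes) {
      draws <- vapply(seq_len(nBackground), function(i)
        sum(sample(z, s)) / sqrt(s), 0)
      res[as.character(s), ] <- c(mean(draws), stats::sd(draws))
    }
    res
  })
  mu <- moments[as.character(kk), "mu"]
  sig <- moments[as.character(kk), "sigma"]
  corrected <- ifelse(sig > 1e-8, (rawZ - mu) / sig, 0)
  thr05 <- significanceThreshold(alpha)
  thr01 <- significanceThreshold(alphaStrict)
  data.frame(pathway_id = keep, k = as.integer(kk), raw_z = unname(rawZ),
             corrected_z = unname(corrected),
             significant_05 = abs(corrected) > thr05,
             significant_01 = abs(corrected) > thr01,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided normal significance threshold
#'
#' `qnorm(1 - alpha/2)`: the |z| cutoff at two-sided level `alpha`
#' (1.96 at 0.05, 2.576 at 0.01).
#'
#' @param alpha two-sided level in (0, 1).
#' @return The z cutoff.
#' @export
significanceThreshold <- function(alpha) {
  .assertScalarNumber(alpha, "alpha")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  stats::qnorm(1 - alpha / 2)
}

#' Cross-timepoint consistency of reporter scores
#'
#' Spearman rank correlation between two pathway score vectors (typically a
#' later visit against baseline M0), over their shared pathways.
#'
#' @param scoresT,scoresRef named numeric vectors of corrected reporter
#'   scores (names are pathway ids); >= 3 shared pathways required.
#' @return Spearman rho in \[-1, 1\].
#' @export
scoreConsistency <- function(scoresT, scoresRef) {
  shared <- intersect(names(scoresT), names(scoresRef))
  if (length(shared) < 3L) stop("need >= 3 shared pathways")
  stats::cor(scoresT[shared], scoresRef[shared], method = "spearman")
}

# Contrast orientation used throughout: first member is the "better" group.
.CONTRASTS <- list(c("PR", "SD"), c("PR", "PD"), c("SD", "PD"))

#' Full reporter-score table across contrasts and timepoints
#'
#' Runs [koDifferential()] + [reporterScore()] for the three oriented
#' response contrasts (PR over SD, PR over PD, SD over PD) at each requested
#' visit, and summarises cross-timepoint consistency of each contrast's
#' score vector against baseline.
#'
#' @param cohort an [ICTCohort-class].
#' @param timepoints visit labels (default all in the cohort metadata,
#'   baseline first).
#' @param nBackground,seed passed to [reporterScore()].
#' @param minPerGroup skip (with a message) contrast/timepoint cells where
#'   either group has fewer samples (default 3).
#' @return list with `scores` (long data.frame: pathway, contrast,
#'   timepoint, k, raw_z, corrected_z, significance flags) and
#'   `consistency` (data.frame: contrast, timepoint, rho vs baseline).
#' @export
reporterTable <- function(cohort, timepoints = NULL, nBackground = 1000L,
                          seed = 1L, minPerGroup = 3L) {
  stopifnot(is(cohort, "ICTCohort"))
  meta <- sampleMeta(cohort)
  ko <- koAbundance(cohort)
  if (is.null(timepoints))
    timepoints <- unique(meta$timepoint[order(meta$week)])
  pmap <- pathwayMap(cohort)
  rows <- list(); cons <- list()
  baseline <- list()
  for (tpt in timepoints) {
    for (ct in .CONTRASTS) {
      nb <- sum(meta$response == ct[1] & meta$timepoint == tpt)
      nw <- sum(meta$response == ct[2] & meta$timepoint == tpt)
      if (nb < minPerGroup || nw < minPerGroup) {
        message(sprintf("skipping %s>%s at %s (%d vs %d samples)",
                        ct[1], ct[2], tpt, nb, nw))
        next
      }
      kores <- koDifferential(ko, ct[1], ct[2], tpt, meta = meta)
      rs <- reporterScore(kores, pmap, nBackground = nBackground,
                          seed = .subSeed(seed, match(tpt, timepoints),
                                          match(ct[1], c("PR", "SD"))))
      key <- paste(ct[1], ct[2], sep = ">")
      rs$contrast <- key
      rs$timepoint <- tpt
      rows[[length(rows) + 1L]] <- rs
      vec <- stats::setNames(rs$corrected_z, rs$pathway_id)
      if (tpt == timepoints[1L]) baseline[[key]] <- vec
      else if (!is.null(baseline[[key]]))
        cons[[length(cons) + 1L]] <- data.frame(
          contrast = key, timepoint = tpt,
          rho = scoreConsistency(vec, baseline[[key]]),
          stringsAsFactors = FALSE)
    }
  }
  list(scores = do.call(rbind, rows),
       consistency = if (length(cons)) do.call(rbind, cons) else
         data.frame(contrast = character(), timepoint = character(),
                    rho = numeric()))
}
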