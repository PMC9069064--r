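test_that("significance thresholds are the two-sided normal quantiles", {
  expect_equal(significanceThreshold(0.05), 1.96, tolerance = 5e-3)
  expect_equal(significanceThreshold(0.01), 2.576, tolerance = 5e-4)
  expect_equal(significanceThreshold(1), 0)
  expect_error(significanceThreshold(0), "alpha")
})

test_that("KO differential test scores direction, separation and constants", {
  # complete separation at n = 10 per group gives |z| >= 3
  meta <- data.frame(sample_id = sprintf("s%02d", 1:20),
                     response = rep(c("PR", "PD"), each = 10),
                     timepoint = "M0")
  ko <- cbind(sep = c(seq(1, 2, length.out = 10) / 100,
                      seq(5, 6, length.out = 10) / 100),
              konst = rep(0.02, 20))
  rownames(ko) <- meta$sample_id
  res <- koDifferential(ko, "PR", "PD", "M0", meta = meta)
  expect_equal(res$z[res$ko_id == "konst"], 0)
  expect_equal(res$p[res$ko_id == "konst"], 1)
  zSep <- res$z[res$ko_id == "sep"]
  expect_lte(zSep, -3)  # enriched in PD, away from the better group
  # flipping the contrast negates z
  res2 <- koDifferential(ko, "PD", "PR", "M0", meta = meta)
  expect_equal(res2$z, -res$z)
  expect_error(koDifferential(ko, "PR", "PD", "W1", meta = meta), ">= 3 samples")
})

test_that("null KO z-scores are centred at zero", {
  set.seed(51)
  n <- 16
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     response = rep(c("PR", "PD"), each = n / 2),
                     timepoint = "M0")
  ko <- matrix(rexp(n * 500), n, 500,
               dimnames = list(meta$sample_id, sprintf("K%03d", 1:500)))
  ko <- ko / rowSums(ko)
  res <- koDifferential(ko, "PR", "PD", "M0", meta = meta)
  expect_lt(abs(mean(res$z)), 0.1)
})

test_that("reporter scores match an independent re-draw of the background", {
  set.seed(52)
  z <- rnorm(80)
  kores <- data.frame(ko_id = sprintf("K%03d", 1:80), p = NA, direction = 1,
                      z = z)
  pmap <- list(one = "K005", three = c("K010", "K020", "K030"))
  got <- reporterScore(kores, pmap, nBackground = 500L, seed = 9L)
  # independent brute-force replication of the seeded sampling scheme
  zN <- setNames(z, kores$ko_id)
  set.seed(9L)
  mu <- sig <- list()
  for (s in c(1L, 3L)) {
    draws <- vapply(seq_len(500L), function(i) sum(sample(zN, s)) / sqrt(s), 0)
    mu[[as.character(s)]] <- mean(draws)
    sig[[as.character(s)]] <- sd(draws)
  }
  expRaw <- c(one = zN[["K005"]],
              three = sum(zN[c("K010", "K020", "K030")]) / sqrt(3))
  expCorr <- (expRaw - unlist(mu)) / unlist(sig)
  expect_equal(got$raw_z, unname(expRaw), tolerance = 1e-12)
  expect_equal(got$corrected_z, unname(expCorr), tolerance = 1e-12)
})

test_that("degenerate all-zero scores give zero reporter scores", {
  kores <- data.frame(ko_id = sprintf("K%03d", 1:30), p = 1, direction = 1,
                      z = 0)
  pmap <- list(a = sprintf("K%03d", 1:5), b = sprintf("K%03d", 6:7))
  rs <- reporterScore(kores, pmap, nBackground = 200L, seed = 1L)
  expect_equal(rs$corrected_z, c(0, 0))
  expect_false(any(rs$significant_05))
})

test_that("pathways with no scored KO are dropped", {
  kores <- data.frame(ko_id = c("K1", "K2"), p = .5, direction = 1,
                      z = c(1, -1))
  pmap <- list(good = c("K1", "K2"), ghost = c("K9"))
  expect_message(rs <- reporterScore(kores, pmap, nBackground = 100L),
                 "dropping 1 pathway")
  expect_equal(rs$pathway_id, "good")
  expect_true(all(rs$significant_05 | !rs$significant_01))  # 01 implies 05
})

test_that("corrected scores are KO-label invariant and contrast-antisymmetric", {
  ch <- generateCohort(tinyConfig(seed = 53L, nPatients = 40L))
  chv <- subsetSamples(ch, validateCohort(ch)$validSamples)
  kr <- koDifferential(chv, "PR", "PD", "M0")
  rs <- reporterScore(kr, pathwayMap(ch), nBackground = 300L, seed = 2L)
  # relabel KOs consistently everywhere: identical scores
  relab <- setNames(sprintf("Q%05d", seq_len(nrow(kr))), kr$ko_id)
  kr2 <- transform(kr, ko_id = unname(relab[ko_id]))
  pmap2 <- lapply(pathwayMap(ch), function(m) unname(relab[m]))
  rs2 <- reporterScore(kr2, pmap2, nBackground = 300L, seed = 2L)
  expect_equal(rs2$corrected_z, rs$corrected_z, tolerance = 1e-12)
  # flipping better/worse negates every corrected score
  krF <- koDifferential(chv, "PD", "PR", "M0")
  rsF <- reporterScore(krF, pathwayMap(ch), nBackground = 300L, seed = 2L)
  expect_equal(rsF$raw_z, -rs$raw_z, tolerance = 1e-12)
  expect_equal(sign(rsF$corrected_z), -sign(rs$corrected_z))
})

test_that("planted pathways score above threshold toward PR", {
  hits <- 0L; n <- 15L
  for (s in seq_len(n)) {
    cfg <- cohortConfig(nMGS = 120L, nKO = 150L, nPathways = 12L,
                        pathwaySizeRange = c(10L, 10L),
                        nDifferentialMGS = 18L, mgsEffectSize = 1.0,
                        nDifferentialPathways = 2L, enterotypeCount = 1L,
                        seed = 600L + s)
    ch <- generateCohort(cfg)
    chv <- subsetSamples(ch, validateCohort(ch)$validSamples)
    kr <- koDifferential(chv, "PR", "PD", "M0")
    rs <- reporterScore(kr, pathwayMap(ch), nBackground = 500L, seed = s)
    planted <- cohortTruth(ch)$differentialPathways
    if (all(rs$corrected_z[rs$pathway_id %in% planted] > 1.96))
      hits <- hits + 1L
  }
  expect_gte(hits / n, 0.9)
})

test_that("score consistency is an exact Spearman correlation", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_equal(scoreConsistency(x, x), 1)
  expect_equal(scoreConsistency(x, rev(setNames(x, names(x)))), 1)
  y <- setNames(rev(unname(x)), names(x))
  expect_equal(scoreConsistency(x, y), -1)
  set.seed(54)
  v <- setNames(rnorm(5), letters[1:5])
  w <- setNames(rnorm(5), letters[1:5])
  expect_equal(scoreConsistency(v, w), spearmanOracle(v, w),
               tolerance = 1e-12)
  expect_error(scoreConsistency(x[1:2], x[1:2]), "shared pathways")
})

test_that("full reporter table covers contrasts and tracks baseline", {
  ch <- generateCohort(tinyConfig(seed = 55L, nPatients = 50L,
                                  dropoutRate = 0))
  chv <- subsetSamples(ch, validateCohort(ch)$validSamples)
  rt <- suppressMessages(reporterTable(chv, timepoints = c("M0", "M1"),
                                       nBackground = 200L, seed = 3L))
  expect_setequal(unique(rt$scores$contrast), c("PR>SD", "PR>PD", "SD>PD"))
  expect_true(all(rt$consistency$timepoint == "M1"))
  expect_true(all(abs(rt$consistency$rho) <= 1))
})
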