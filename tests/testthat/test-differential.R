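test_that("BMI-adjusted ANOVA matches an explicit sums-of-squares oracle", {
  set.seed(31)
  groups <- rep(c("PR", "SD", "PD"), each = 6)
  bmi <- rnorm(18, 23, 2)
  for (i in 1:10) {
    values <- rep(c(1, 1.5, 2), each = 6) + rnorm(18, 0, 0.8)
    expect_equal(bmiAdjustedAnova(values, groups, bmi),
                 anovaFOracle(values, groups, bmi), tolerance = 1e-10)
  }
})

test_that("BMI-adjusted ANOVA is calibrated when values depend only on BMI", {
  set.seed(32)
  groups <- rep(c("PR", "SD", "PD"), times = c(10, 15, 20))
  p <- replicate(800, {
    bmi <- rnorm(45, 23, 2)
    bmiAdjustedAnova(0.5 * bmi + rnorm(45), groups, bmi)
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("degenerate ANOVA inputs give NA or errors", {
  groups <- rep(c("PR", "SD", "PD"), each = 4)
  bmi <- rnorm(12)
  expect_warning(p <- bmiAdjustedAnova(rep(1, 12), groups, bmi), "constant")
  expect_true(is.na(p))
  expect_error(bmiAdjustedAnova(rnorm(6), rep(c("A", "B"), c(4, 2)),
                                rnorm(6)), ">= 3 samples")
  expect_error(bmiAdjustedAnova(rnorm(6), rep("A", 6), rnorm(6)),
               ">= 2 groups")
})

test_that("Tukey HSD pairwise p-values match a studentized-range oracle", {
  set.seed(33)
  groups <- rep(c("PD", "PR", "SD"), times = c(7, 5, 6))
  for (i in 1:8) {
    values <- rnorm(18) + rep(c(0, 0.5, 1), times = c(7, 5, 6))
    got <- tukeyHSDPairs(values, groups)
    oracle <- tukeyOracle(values, groups)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-6)
  }
  # means separated by ~10 pooled SDs: vanishing p
  sep <- tukeyHSDPairs(c(rnorm(5), rnorm(5) + 10, rnorm(5) + 20),
                       rep(c("A", "B", "C"), each = 5))
  expect_lt(max(sep), 1e-6)
  # singleton group pairs are NA
  single <- tukeyHSDPairs(c(1, 2, 3, 4, 10), c("A", "A", "B", "B", "C"))
  expect_true(all(is.na(single[grep("C", names(single))])))
})

test_that("Tukey p-values are >= their two-sample unadjusted counterparts", {
  set.seed(34)
  for (i in 1:10) {
    values <- rnorm(21) + rep(c(0, .4, .8), each = 7)
    groups <- rep(c("A", "B", "C"), each = 7)
    tk <- tukeyHSDPairs(values, groups)
    tAB <- t.test(values[groups == "A"], values[groups == "B"],
                  var.equal = TRUE)$p.value
    expect_gte(tk[["B-A"]] + 1e-10, tAB)
  }
})

test_that("two equal-mean groups give Tukey p near 1", {
  set.seed(35)
  v <- rnorm(20)
  p <- tukeyHSDPairs(c(v, v + 1e-9), rep(c("A", "B"), each = 20))
  expect_gte(unname(p["B-A"]), 0.99)
})

test_that("enrichment labelling follows occurrence gates and tie-breaks", {
  expect_equal(
    enrichmentLabel(c(PR = 1e-4, SD = 1e-6, PD = 0),
                    c(PR = .5, SD = .5, PD = .5)),
    list(high = "PR", low = "PD"))
  # too low occurrence in every group
  expect_equal(
    enrichmentLabel(c(PR = 1e-4, SD = 1e-6, PD = 0),
                    c(PR = 0.05, SD = 0.04, PD = 0.02), minOccurrence = 0.2),
    list(high = NA_character_, low = NA_character_))
  # exact median tie broken by higher occurrence
  expect_equal(
    enrichmentLabel(c(PR = 1e-4, SD = 1e-4, PD = 1e-6),
                    c(PR = .6, SD = .4, PD = .5))$high, "PR")
  expect_equal(
    enrichmentLabel(c(PR = 1e-4, SD = 1e-4, PD = 1e-6),
                    c(PR = .4, SD = .6, PD = .5))$high, "SD")
  # full tie falls back to fixed group order PR > SD > PD
  expect_equal(
    enrichmentLabel(c(PR = 1, SD = 1, PD = 1), c(PR = .5, SD = .5, PD = .5)),
    list(high = "PR", low = "PD"))
})

test_that("differential screen recovers planted species with correct labels", {
  ch <- generateCohort(tinyConfig(seed = 41L, nPatients = 60L, nMGS = 120L,
                                  nDifferentialMGS = 12L,
                                  mgsEffectSize = 1.5))
  chv <- subsetSamples(ch, validateCohort(ch)$validSamples)
  dt <- suppressWarnings(runDifferential(chv, useQ = TRUE))
  truth <- cohortTruth(ch)$differentialMGS
  disc <- dt$mgs_id[dt$significant]
  expect_gte(mean(truth$mgs_id %in% disc), 0.8)
  hit <- dt[dt$significant & dt$mgs_id %in% truth$mgs_id, ]
  agree <- hit$enrich_high ==
    truth$enriched_group[match(hit$mgs_id, truth$mgs_id)]
  expect_gte(mean(agree), 0.95)
  # q-values dominate p-values and are monotone in them
  ok <- !is.na(dt$anova_p)
  expect_true(all(dt$bh_q[ok] >= dt$anova_p[ok] - 1e-12))
  o <- order(dt$anova_p[ok])
  expect_true(all(diff(dt$bh_q[ok][o]) >= -1e-12))
})

test_that("patient-level community heterogeneity inflates the pooled test", {
  # enterotype structure makes longitudinal samples of a patient
  # correlated; pooling them breaks exchangeability and the per-feature
  # ANOVA becomes anti-conservative on enterotype-driver features, while
  # homogeneous cohorts stay calibrated (documented limitation)
  drivers <- c("Bacteroides", "Faecalibacterium", "Eubacterium",
               "Clostridium", "Prevotella")
  rates <- c(het = NA_real_, hom = NA_real_)
  for (mode in names(rates)) {
    pd <- c()
    for (s in 1:2) {
      ch <- generateCohort(nullConfig(
        seed = 1200L + s, nMGS = 250L, nPatients = 85L,
        enterotypeCount = if (mode == "het") 3L else 1L))
      dt <- suppressWarnings(
        runDifferential(subsetSamples(ch, validateCohort(ch)$validSamples)))
      tax <- taxonomyMap(ch)
      isDrv <- tax$genus[match(dt$mgs_id, tax$mgs_id)] %in% drivers
      pd <- c(pd, dt$anova_p[isDrv])
    }
    rates[mode] <- mean(pd < 0.05, na.rm = TRUE)
  }
  expect_gt(unname(rates["het"]), 2 * unname(rates["hom"]))  # clear inflation
  expect_gt(unname(rates["het"]), 0.12)
  expect_lt(unname(rates["hom"]), 0.10)  # calibrated without heterogeneity
})

test_that("differential screen rejects empty and undersized inputs", {
  expect_error(runDifferential(matrix(numeric(), 0, 0), meta = data.frame()),
               "empty")
  ch <- suppressWarnings(
    generateCohort(tinyConfig(seed = 42L, nPatients = 6L,
                              timepoints = c(M0 = 0L))))
  expect_error(suppressWarnings(runDifferential(ch)), ">= 3 samples")
})
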