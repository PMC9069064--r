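test_that("Shannon index matches closed forms and vegan", {
  expect_equal(shannonIndex(c(1, 0, 0)), 0)
  expect_equal(shannonIndex(rep(1, 4)), log(4))
  expect_equal(shannonIndex(c(0.5, 0.3, 0.2)), 1.029653, tolerance = 1e-6)
  expect_error(shannonIndex(c(0, 0)), "all-zero")
  set.seed(11)
  for (i in 1:20) {
    p <- runif(12) * rbinom(12, 1, 0.7)
    if (sum(p) == 0) p[1] <- 1
    expect_equal(shannonIndex(p),
                 unname(vegan::diversity(p, index = "shannon")),
                 tolerance = 1e-12)
    # invariant under feature permutation
    expect_equal(shannonIndex(p), shannonIndex(sample(p)))
  }
})

test_that("Bray-Curtis matches the formula, vegan, and its invariances", {
  expect_equal(brayCurtis(c(0.7, 0.3, 0), c(0.2, 0.3, 0.5)), 0.5)
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 0, 0), c(0, 1, 1)), 1)  # disjoint support
  expect_error(brayCurtis(1:3, 1:4), "length mismatch")
  set.seed(12)
  for (i in 1:20) {
    p <- runif(10); q <- runif(10)
    expect_equal(brayCurtis(p, q),
                 as.numeric(vegan::vegdist(rbind(p, q), "bray")),
                 tolerance = 1e-12)
    expect_equal(brayCurtis(p, q), brayCurtis(q, p))               # symmetry
    expect_equal(brayCurtis(3 * p, 3 * q), brayCurtis(p, q))       # scale
    d <- brayCurtis(p, q)
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("group dispersion enumerates all within-group pairs", {
  ch <- generateCohort(tinyConfig(seed = 5L))
  meta <- sampleMeta(ch)
  g <- names(which.max(table(meta$response[meta$timepoint == "M0"])))
  ds <- groupDispersion(ch, group = g, timepoint = "M0")
  n <- sum(meta$response == g & meta$timepoint == "M0")
  expect_length(ds$values, n * (n - 1) / 2)
  # exhaustive pairwise oracle
  m <- mgsAbundance(ch)[meta$sample_id[meta$response == g &
                                         meta$timepoint == "M0"], ]
  oracle <- as.numeric(vegan::vegdist(m, "bray"))
  expect_equal(sort(ds$values), sort(oracle), tolerance = 1e-12)
  # identical samples give zero; < 2 samples warns and returns empty
  ab <- rbind(s1 = c(.5, .5), s2 = c(.5, .5))
  colnames(ab) <- c("f1", "f2")
  meta2 <- data.frame(sample_id = c("s1", "s2"), response = "PR",
                      timepoint = "M0", week = 0L)
  expect_equal(groupDispersion(ab, "PR", "M0", meta = meta2)$values, 0)
  expect_warning(out <- groupDispersion(ab, "SD", "M0", meta = meta2),
                 "fewer than 2")
  expect_length(out$values, 0L)
})

test_that("alpha-diversity series aligns samples with metadata", {
  ch <- generateCohort(tinyConfig(seed = 6L))
  ad <- alphaDiversitySeries(ch)
  meta <- sampleMeta(ch)
  expect_identical(ad$sample_id, meta$sample_id)
  i <- which.max(ad$week)
  expect_equal(ad$value[i],
               shannonIndex(mgsAbundance(ch)[ad$sample_id[i], ]))
  expect_true(all(is.finite(ad$value)))
})

test_that("tricube local-linear smoother agrees with loess", {
  set.seed(3)
  x <- rep(c(0, 1, 2, 4, 8, 12, 16), each = 6)
  y <- sin(x / 5) + rnorm(length(x), 0, 0.3)
  grid <- seq(0, 16, length.out = 50)
  ours <- microICT:::.localLinear(x, y, grid, span = 0.75)
  ref <- predict(loess(y ~ x, span = 0.75, degree = 1, family = "gaussian",
                       control = loess.control(surface = "direct")),
                 data.frame(x = grid))
  expect_equal(ours, unname(ref), tolerance = 1e-8)
})

test_that("permutation spline test finds a planted offset and not its absence", {
  set.seed(21)
  weeks <- c(0, 1, 2, 4, 8, 12, 16)
  mk <- function(n, offset, idBase) {
    data.frame(patient = rep(idBase + seq_len(n), each = length(weeks)),
               week = rep(weeks, n),
               value = offset + rnorm(n * length(weeks), 0, 0.1))
  }
  a <- mk(20, 0, 0); b <- mk(20, 2, 100)
  res <- permusplineTest(a, b, nPerm = 999, seed = 1L)
  expect_lte(res$p, 0.01)
  expect_gt(res$statistic, 1.5)
  # a copy of the same series: statistic 0, p = 1
  same <- permusplineTest(a, transform(a, patient = patient + 500),
                          nPerm = 99, seed = 1L)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("permutation spline p-values are valid under the null", {
  set.seed(77)
  weeks <- c(0, 2, 4, 8, 12)
  rej <- 0L; n <- 150L
  for (r in seq_len(n)) {
    a <- data.frame(patient = rep(1:8, each = 5), week = rep(weeks, 8),
                    value = rnorm(40))
    b <- data.frame(patient = rep(101:108, each = 5), week = rep(weeks, 8),
                    value = rnorm(40))
    if (permusplineTest(a, b, nPerm = 99, seed = r)$p <= 0.05) rej <- rej + 1L
  }
  bound <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rej / n - 0.05), bound + 1e-12)
})

test_that("spline test input contracts are enforced", {
  a <- data.frame(patient = 1:4, week = c(0, 0, 1, 1), value = rnorm(4))
  b <- data.frame(patient = 5:8, week = c(0, 1, 2, 3), value = rnorm(4))
  expect_error(permusplineTest(a, b, nPerm = 99), "distinct weeks")
  a2 <- data.frame(patient = rep(1:3, each = 3), week = rep(0:2, 3),
                   value = rnorm(9))
  b2 <- data.frame(patient = rep(4:6, each = 3), week = rep(10:12, 3),
                   value = rnorm(9))
  expect_error(permusplineTest(a2, b2, nPerm = 99), "overlapping")
  expect_error(permusplineTest(a2, a2, nPerm = 10), "nPerm")
})
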