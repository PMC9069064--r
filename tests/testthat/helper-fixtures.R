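# Shared fixtures and independent oracles, built in code at test time.

# A small cohort configuration that keeps unit tests fast.
tinyConfig <- function(seed = 1L, ...) {
  args <- list(nPatients = 24L, nMGS = 40L, nKO = 60L, nPathways = 6L,
               nDifferentialMGS = 6L, mgsEffectSize = 1.5,
               nDifferentialPathways = 2L, enterotypeCount = 1L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohortConfig, args)
}

# Homogeneous null configuration: nothing planted, one community type.
nullConfig <- function(seed = 1L, ...) {
  tinyConfig(seed = seed, nDifferentialMGS = 0L, mgsEffectSize = 0,
             nDifferentialPathways = 0L, bmiConfounderStrength = 0, ...)
}

# Brute-force AUC oracle: concordant-pair count with ties at half weight.
aucPairs <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Hand product-limit estimator (events before censorings at tied times).
kmOracle <- function(times, events) {
  ut <- sort(unique(times[events]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    atRisk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / atRisk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# Observed-minus-expected log-rank oracle (two groups, 1 df).
logrankOracle <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  ut <- sort(unique(times[events]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    atRisk <- times >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1L)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Tukey-Kramer oracle from group means, pooled MSE and ptukey.
tukeyOracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- table(groups)
  mi <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum((values - mi[groups])^2) / df
  lv <- levels(groups)
  out <- c()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- abs(mi[j] - mi[i]) / se
    out[paste(lv[j], lv[i], sep = "-")] <-
      ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  out
}

# Explicit sums-of-squares F oracle for value ~ group + bmi vs value ~ bmi,
# via normal equations (a different route than the package's QR).
anovaFOracle <- function(values, groups, bmi) {
  G <- model.matrix(~ factor(groups))
  X1 <- cbind(G, bmi)
  X0 <- cbind(1, bmi)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% values)
    sum((values - X %*% b)^2)
  }
  r1 <- rss(X1); r0 <- rss(X0)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(values) - ncol(X1)
  f <- ((r0 - r1) / df1) / (r1 / df2)
  pf(f, df1, df2, lower.tail = FALSE)
}

# Spearman oracle: Pearson correlation of explicit ranks.
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
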