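# Internal helpers shared across modules.

# Deterministic sub-stream seed derivation. All randomness in the package
# flows from a single user seed; independent sub-streams (per patient, per
# purpose) are derived so that, e.g., dropout draws never perturb abundance
# draws. Result is always a valid 32-bit seed.
.subSeed <- function(seed, i, j = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 97531 +
    as.double(j) * 7919 + 12345
  as.integer(s %% 2147483629L + 1L)
}

# Evaluate `code` under a temporary RNG state, restoring the caller's state.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Largest-remainder (Hamilton) apportionment of n units to proportions.
# Deterministic; ties in remainders resolved by the order of `props`.
.apportion <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0), abs(sum(props) - 1) < 1e-9)
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    take <- ord[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# Canonical response-group order used for tie-breaking and reporting.
.GROUP_ORDER <- c("PR", "SD", "PD", "FD")
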