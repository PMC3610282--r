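# Independent brute-force oracles, deliberately written as plain double loops
# against the formulas, sharing no code with the package internals.

# kernel: log2(|x - y| / max(x, y) + 1), 0/0 -> 0
oracle_kernel <- function(x, y) {
  if (x == 0 && y == 0) return(0)
  log2(abs(x - y) / max(x, y) + 1)
}

# generalized estimator: naive double loop over cases and pairs
oracle_ibmd <- function(cases) {
  total <- 0
  npairs <- 0
  for (v in cases) {
    m <- length(v)
    if (m < 2) next
    for (j in seq_len(m - 1)) {
      for (k in (j + 1):m) {
        total <- total + oracle_kernel(v[[j]], v[[k]])
        npairs <- npairs + 1
      }
    }
  }
  total / npairs
}

# resample-loop bootstrap driven by the current RNG stream, recomputing the
# estimate from the raw observations of each replicate
oracle_bootstrap <- function(cases, n_boot, level = 0.95) {
  n <- length(cases)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b] <- oracle_ibmd(cases[idx])
  }
  alpha <- 1 - level
  unname(quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
}

# random ragged table on (0, 100], sizes 2..max_m
random_ragged <- function(n_cases, max_m = 5, min_m = 2) {
  cases <- lapply(seq_len(n_cases), function(i) {
    m <- sample(min_m:max_m, 1)
    runif(m, min = 1e-6, max = 100)
  })
  ratings_table(cases)
}

# self-seeding variant for tests that need a fixed table without touching
# the ambient stream order
random_ragged_seeded <- function(seed = 1, n_cases = 12, max_m = 5) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  random_ragged(n_cases, max_m = max_m)
}
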