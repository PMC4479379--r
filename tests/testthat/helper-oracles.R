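# Independent naive-loop oracles: deliberately scalar, formula-by-formula
# recomputations kept free of any package internals, used to cross-check the
# vectorized implementations.

oracle_spectrum_tally <- function(counts) {
  f <- integer(0)
  for (y in counts) {
    while (length(f) < y) f <- c(f, 0L)
    f[y] <- f[y] + 1L
  }
  f  # dense vector indexed by r
}

oracle_f <- function(fvec, r) if (r <= length(fvec)) fvec[r] else 0

oracle_chao1 <- function(fvec) {
  f1 <- oracle_f(fvec, 1); f2 <- oracle_f(fvec, 2)
  if (f1 == 0) return(0)
  if (f2 == 0) return(f1 * (f1 - 1) / (2 * (f2 + 1)))
  f1 * f1 / (2 * f2)
}

oracle_chao2 <- function(fvec) {
  f1 <- oracle_f(fvec, 1); f2 <- oracle_f(fvec, 2)
  f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_ichao1 <- function(fvec) {
  f1 <- oracle_f(fvec, 1); f2 <- oracle_f(fvec, 2)
  f3 <- oracle_f(fvec, 3); f4 <- oracle_f(fvec, 4)
  if (f1 == 0) return(0)
  base <- if (f2 == 0) f1 * (f1 - 1) / (2 * (f2 + 1)) else f1 * f1 / (2 * f2)
  corr <- if (f4 == 0) 0 else (f3 / (4 * f4)) * max(f1 - f2 * f3 / (2 * f4), 0)
  base + corr
}

oracle_medial <- function(fvec, N = NULL) {
  f1 <- oracle_f(fvec, 1); f2 <- oracle_f(fvec, 2)
  out <- f1 * (f1 - 1) / (f2 + 1)
  if (!is.null(N)) out <- out * (N - 1) / N
  out
}

oracle_pythagorean <- function(fvec, mean_type, degree, u) {
  f1 <- oracle_f(fvec, 1)
  if (f1 == 0) return(0)
  vals <- numeric(0)
  for (r in 2:degree) vals <- c(vals, oracle_f(fvec, r))
  c_val <- if (mean_type == "arithmetic") {
    s <- 0; for (v in vals) s <- s + v; s / length(vals)
  } else if (mean_type == "geometric") {
    if (any(vals == 0)) 0 else { s <- 0; for (v in vals) s <- s + log(v); exp(s / length(vals)) }
  } else {
    if (any(vals == 0)) 0 else { s <- 0; for (v in vals) s <- s + 1 / v; length(vals) / s }
  }
  if (c_val == 0) return(NA_real_)
  u * f1 * f1 / c_val
}

oracle_h6 <- function(fvec) oracle_pythagorean(fvec, "harmonic", 6, 6 / 10)

# Exhaustive enumeration of P(all genes detected) for a multinomial sample:
# iterates over every outcome sequence of length N (gene index per tag).
oracle_prob_all_detected <- function(p, N) {
  G <- length(p)
  if (N == 0) return(if (G >= 1) 0 else 1)
  total <- 0
  idx <- rep(1L, N)
  repeat {
    if (length(unique(idx)) == G) total <- total + prod(p[idx])
    j <- N
    while (j >= 1) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= G) break
      idx[j] <- 1L
      j <- j - 1L
    }
    if (j < 1) break
  }
  total
}

# Random sparse spectrum over r = 1..10 with occasional zeros at every order.
random_spectrum <- function() {
  f <- rpois(10, lambda = sample(c(0.7, 3, 20), 1))
  if (sum(f) == 0) f[sample(10, 1)] <- 1L
  freq_spectrum(r = which(f > 0), f = f[f > 0])
}

dense_f <- function(spec) {
  out <- numeric(max(spec$r))
  out[spec$r] <- spec$f
  out
}

# Small random count vector for round-trip style properties.
random_counts <- function(n_max = 30, y_max = 12) {
  n <- sample(n_max, 1)
  sample(y_max, n, replace = TRUE)
}

write_temp_counts <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
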