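## Parametric bootstrap machinery. A sample (or a complete reference) is
## treated as the truth: its empirical tag proportions y_i / N are the
## population abundances, its g detected genes play the role of G. Replicates
## drawn from that distribution have a known number of missing genes, which
## gives standard errors for any f0 estimator and a level playing field for
## comparing candidate estimators.

#' Bootstrap configuration
#'
#' @param B number of replicates (`>= 1`).
#' @param distribution `"multinomial"` (totals exactly `N_i`; equivalent to
#'   the non-parametric bootstrap) or `"poisson"` (independent counts with
#'   rates `N_i * p_i`).
#' @param n_min,n_max replicate depths are drawn uniformly on
#'   `[n_min, n_max]` by the selection harness (`1 <= n_min <= n_max`).
#'   Depths below about one million tags make all spectrum-based estimators
#'   erratic; the default floor reflects that.
#' @param seed master integer seed; per-replicate streams are derived from it
#'   so results are reproducible regardless of execution order.
#' @param drop_degenerate drop replicates where an estimator hit a zero
#'   denominator (counted and reported); when `FALSE` they enter as zero.
#' @param ci_method `"normal"` (f0_hat +/- 1.96 se, clamped at 0) or
#'   `"percentile"` (2.5% and 97.5% quantiles of the replicate estimates).
#' @return A list of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(B = 1000L, distribution = c("multinomial", "poisson"),
                             n_min = 1e6, n_max = 1e6, seed = 1L,
                             drop_degenerate = TRUE,
                             ci_method = c("normal", "percentile")) {
  distribution <- match.arg(distribution)
  ci_method <- match.arg(ci_method)
  if (B < 1) stop("bootstrap_config: B must be >= 1")
  if (n_min < 1 || n_min > n_max)
    stop("bootstrap_config: need 1 <= n_min <= n_max")
  structure(list(B = as.integer(B), distribution = distribution,
                 n_min = n_min, n_max = n_max, seed = as.integer(seed),
                 drop_degenerate = isTRUE(drop_degenerate),
                 ci_method = ci_method),
            class = "bootstrap_config")
}

# One deterministic sub-seed per replicate, derived from the master seed.
derive_replicate_seeds <- function(seed, B) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, B, replace = TRUE)
}

#' Draw one bootstrap replicate from a reference sample
#'
#' The reference count vector is treated as a complete description of the
#' population: gene `i` has probability `y_i / N`. A replicate of depth
#' `N_i` is drawn (multinomial or Poisson) and reduced to its frequency
#' spectrum; the realized number of missing genes is
#' `true_f0 = g_reference - g_replicate`.
#'
#' @param reference a [count_vector()].
#' @param N_i replicate depth (`>= 1`).
#' @param distribution `"multinomial"` or `"poisson"`.
#' @param seed optional integer seed (same seed, same draw).
#' @return List with `spectrum` (a [freq_spectrum()], or `NULL` if the draw
#'   detected nothing), `true_f0`, and `g` (genes detected in the replicate).
#' @export
bootstrap_sample <- function(reference, N_i,
                             distribution = c("multinomial", "poisson"),
                             seed = NULL) {
  stopifnot(inherits(reference, "count_vector"))
  distribution <- match.arg(distribution)
  if (length(N_i) != 1L || N_i < 1) stop("bootstrap_sample: N_i must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- reference$counts / reference$N
  y <- if (distribution == "multinomial") {
    drop(stats::rmultinom(1, size = N_i, prob = p))
  } else {
    stats::rpois(reference$g, lambda = N_i * p)
  }
  y <- y[y > 0]
  g_rep <- length(y)
  list(
    spectrum = if (g_rep > 0) spectrum_from_counts(y) else NULL,
    true_f0 = reference$g - g_rep,
    g = g_rep
  )
}

# Apply an estimator (function or name) to a replicate spectrum. Functions
# carrying attr "uses_truth" receive the replicate's true f0 as a second
# argument (oracle injection for harness self-tests).
apply_estimator <- function(fn, spectrum, true_f0) {
  if (is.character(fn)) fn <- estimator_by_name(fn)
  if (is.null(spectrum)) return(list(value = NA_real_, degenerate = TRUE))
  est <- if (isTRUE(attr(fn, "uses_truth"))) fn(spectrum, true_f0) else fn(spectrum)
  if (inherits(est, "richness_estimate"))
    list(value = est$f0_hat, degenerate = est$degenerate || is.na(est$f0_hat))
  else
    list(value = as.double(est), degenerate = is.na(est))
}

#' Bootstrap standard error and confidence interval for an estimate
#'
#' Runs `B` bootstrap replicates at the sample's own depth `N` from the
#' sample's empirical distribution, applies the estimator to each, and
#' measures the root mean squared deviation between the replicate estimates
#' and the replicate truths:
#' \deqn{se = \sqrt{\frac{1}{B} \sum_{i=1}^{B} (\hat f_{0i} - f_{0i})^2}}
#' The 95% interval is `f0_hat +/- 1.96 se` clamped at 0 (default), or the
#' percentile interval of the replicate estimates. Replicates where the
#' estimator was degenerate are dropped and counted (`n_degenerate`).
#'
#' @param sample a [count_vector()] (the observed sample).
#' @param estimator estimator name (see [estimator_by_name()]) or a function
#'   `freq_spectrum -> richness_estimate`.
#' @param config a [bootstrap_config()]; `n_min`/`n_max` are ignored here
#'   (replicates use the sample's own `N`).
#' @return A [richness_estimate()] with `se`, `ci_lower`, `ci_upper` filled,
#'   plus attribute `"n_degenerate"`.
#' @examples
#' \donttest{
#' pop <- make_population(200, "uniform")
#' s <- draw_sample(pop, 2000, seed = 1)$sample
#' estimate_se_bias_ci(s, "h6", bootstrap_config(B = 200, seed = 7))
#' }
#' @export
estimate_se_bias_ci <- function(sample, estimator, config = bootstrap_config()) {
  stopifnot(inherits(sample, "count_vector"),
            inherits(config, "bootstrap_config"))
  fn <- if (is.character(estimator)) estimator_by_name(estimator) else estimator
  point <- apply_estimator(fn, spectrum_from_counts(sample), NA_real_)
  seeds <- derive_replicate_seeds(config$seed, config$B)
  est_i <- true_i <- numeric(config$B)
  for (i in seq_len(config$B)) {
    rep_i <- bootstrap_sample(sample, sample$N, config$distribution,
                              seed = seeds[i])
    true_i[i] <- rep_i$true_f0
    est_i[i] <- apply_estimator(fn, rep_i$spectrum, rep_i$true_f0)$value
  }
  degen <- is.na(est_i)
  n_degen <- sum(degen)
  if (config$drop_degenerate) {
    keep <- !degen
  } else {
    est_i[degen] <- 0
    keep <- rep(TRUE, config$B)
  }
  if (!any(keep))
    stop("estimate_se_bias_ci: estimator degenerate in every replicate")
  se <- sqrt(mean((est_i[keep] - true_i[keep])^2))
  if (config$ci_method == "normal") {
    lo <- max(0, point$value - 1.96 * se)
    hi <- point$value + 1.96 * se
  } else {
    q <- stats::quantile(est_i[keep], c(0.025, 0.975), names = FALSE)
    lo <- max(0, q[1L]); hi <- q[2L]
  }
  name <- if (is.character(estimator)) estimator else "custom"
  out <- richness_estimate(name, point$value, g = sample$g, N = sample$N,
                           se = se, ci_lower = lo, ci_upper = hi,
                           degenerate = point$degenerate)
  attr(out, "n_degenerate") <- n_degen
  out
}

#' Score candidate estimators against known truth on a complete sample
#'
#' The estimator-selection harness. For each of `B` replicates a depth `N_i`
#' is drawn uniformly on `[n_min, n_max]`, a bootstrap sample is taken from
#' the complete reference, and every candidate estimator is applied. Each
#' estimator is scored by its standard error
#' `sqrt(mean((f0_hat_i - f0_i)^2))`, the squared Pearson correlation between
#' estimates and truths, and the spread of its signed errors. Degenerate
#' replicates are excluded per estimator (or zero-filled when
#' `drop_degenerate = FALSE`) and counted.
#'
#' @param complete a complete [count_vector()] reference (warns when
#'   `f1 > 0`: truth `G = g` is then only approximate).
#' @param estimators character vector of estimator names and/or a named list
#'   of estimator functions.
#' @param config a [bootstrap_config()].
#' @return A data frame of class `"evaluation_result"`, one row per
#'   estimator: `estimator`, `se`, `pct_se_chao1` (se as a percentage of
#'   Chao1's, `NA` if Chao1 absent), `r_squared`, `error_min`,
#'   `error_median`, `error_mean`, `error_max`, `n_degenerate`, `n_used`.
#' @export
run_selection_harness <- function(complete,
                                  estimators = c("chao1", "ichao1", "medial", "h6"),
                                  config = bootstrap_config()) {
  stopifnot(inherits(complete, "count_vector"),
            inherits(config, "bootstrap_config"))
  if (config$n_min > complete$N)
    stop("run_selection_harness: n_min exceeds the reference depth N")
  if (!is_complete(complete))
    warning("reference sample has f1 > 0; it is not complete and truth G = g is approximate")
  if (is.character(estimators)) estimators <- as.list(estimators)
  nm <- vapply(seq_along(estimators), function(k) {
    if (is.character(estimators[[k]])) estimators[[k]]
    else if (!is.null(names(estimators)) && nzchar(names(estimators)[k]))
      names(estimators)[k]
    else paste0("estimator", k)
  }, "")
  K <- length(estimators)
  seeds <- derive_replicate_seeds(config$seed, config$B)
  est_mat <- matrix(NA_real_, config$B, K)
  true_i <- numeric(config$B)
  for (i in seq_len(config$B)) {
    set.seed(seeds[i])
    N_i <- round(stats::runif(1, config$n_min, config$n_max))
    rep_i <- bootstrap_sample(complete, N_i, config$distribution)
    true_i[i] <- rep_i$true_f0
    for (k in seq_len(K))
      est_mat[i, k] <- apply_estimator(estimators[[k]], rep_i$spectrum,
                                       rep_i$true_f0)$value
  }
  rows <- lapply(seq_len(K), function(k) {
    est <- est_mat[, k]
    degen <- is.na(est)
    if (config$drop_degenerate) keep <- !degen
    else { est[degen] <- 0; keep <- rep(TRUE, config$B) }
    if (!any(keep))
      return(data.frame(estimator = nm[k], se = NA_real_, r_squared = NA_real_,
                        error_min = NA_real_, error_median = NA_real_,
                        error_mean = NA_real_, error_max = NA_real_,
                        n_degenerate = sum(degen), n_used = 0L))
    err <- est[keep] - true_i[keep]
    r2 <- if (stats::sd(est[keep]) > 0 && stats::sd(true_i[keep]) > 0)
      stats::cor(est[keep], true_i[keep])^2 else NA_real_
    data.frame(estimator = nm[k],
               se = sqrt(mean(err^2)),
               r_squared = r2,
               error_min = min(err), error_median = stats::median(err),
               error_mean = mean(err), error_max = max(err),
               n_degenerate = sum(degen), n_used = sum(keep))
  })
  out <- do.call(rbind, rows)
  if ("chao1" %in% out$estimator)
    out$pct_se_chao1 <- 100 * out$se / out$se[out$estimator == "chao1"]
  else out$pct_se_chao1 <- NA_real_
  out <- out[, c("estimator", "se", "pct_se_chao1", "r_squared", "error_min",
                 "error_median", "error_mean", "error_max", "n_degenerate",
                 "n_used")]
  class(out) <- c("evaluation_result", "data.frame")
  out
}

#' Probability that a sample detects every gene
#'
#' For a population with abundances `p` sampled at depth `N`, approximates
#' the probability that no gene is missed by treating gene detections as
#' independent: `prod(1 - (1 - p_i)^N)` (each factor is the exact marginal
#' detection probability under multinomial sampling; only the independence
#' across genes is approximate). The exact multinomial probability is
#' available by inclusion-exclusion for `G <= 12` as an oracle.
#'
#' @param population a [make_population()] object, or a bare probability
#'   vector summing to 1.
#' @param N sample depth (`>= 0`).
#' @param method `"approximate"` (any `G`) or `"exact"` (`G <= 12`).
#' @return Probability in `[0, 1]`.
#' @examples
#' prob_all_detected(c(0.5, 0.5), 2, method = "exact")  # 0.5
#' @export
prob_all_detected <- function(population, N, method = c("approximate", "exact")) {
  method <- match.arg(method)
  p <- if (inherits(population, "synthetic_population")) population$p
       else as.double(population)
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
    stop("prob_all_detected: p must be positive and sum to 1")
  if (length(N) != 1L || N < 0) stop("prob_all_detected: N must be >= 0")
  G <- length(p)
  if (N == 0) return(if (G >= 1) 0 else 1)
  if (method == "approximate") return(prod(1 - (1 - p)^N))
  if (G > 12) stop("prob_all_detected: exact method limited to G <= 12")
  # inclusion-exclusion over the set of missed genes
  total <- 0
  for (mask in 0:(2^G - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(G - 1))) > 0)
    total <- total + (-1)^length(idx) * (1 - sum(p[idx]))^N
  }
  min(max(total, 0), 1)
}
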