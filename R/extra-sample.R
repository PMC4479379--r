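## Extra sequencing depth planning. Given an estimate f0_hat of the genes a
## sample missed, how many additional tags m are needed so that a proportion
## psi of them is expected to be observed? Two closed forms are provided,
## both subject to the positivity condition f0_hat / (G_hat (1 - psi)) > 1:
## below it, the target proportion is already within reach of the current
## depth. Logarithms are natural.

new_extra_sample_estimate <- function(method, psi, m_extra, condition_met,
                                      degenerate = FALSE) {
  structure(list(method = method, psi = psi, m_extra = m_extra,
                 condition_met = condition_met, degenerate = degenerate),
            class = "extra_sample_estimate")
}

#' @export
print.extra_sample_estimate <- function(x, ...) {
  cat(sprintf("Extra sample (%s, psi = %g): ", x$method, x$psi))
  if (!x$condition_met)
    cat("target proportion already within reach of current depth\n")
  else if (is.na(x$m_extra))
    cat("undefined (degenerate spectrum)\n")
  else
    cat(format(round(x$m_extra), big.mark = ","), "additional tags\n")
  invisible(x)
}

#' Extra sample size via the Chao-style formula
#'
#' \deqn{m_\psi \approx N \frac{f_1}{2 f_2}
#'       \log\!\left(\frac{\hat f_0}{\hat G (1-\psi)}\right)}
#' with `G_hat = g + f0_hat`. Returns `m_extra = 0` for a complete sample
#' (`f1 = 0`); returns `condition_met = FALSE` with `m_extra = NA` when
#' `f0_hat / (G_hat (1 - psi)) <= 1`. `f0_hat` is typically the Chao-family
#' estimate, but any non-negative estimate is accepted.
#'
#' @param spec a [freq_spectrum()] or [count_vector()].
#' @param f0_hat estimated number of undetected genes (`>= 0`).
#' @param psi target proportion of the undetected genes, in `(0, 1)`.
#' @param N sample depth; defaults to the spectrum's `N`.
#' @return An `extra_sample_estimate`: list with `method`, `psi`, `m_extra`
#'   (tags), `condition_met`, `degenerate`.
#' @export
extra_sample_chao <- function(spec, f0_hat = NULL, psi = 0.95, N = NULL) {
  spec <- as_spectrum(spec)
  if (length(psi) != 1L || psi <= 0 || psi >= 1)
    stop("extra_sample_chao: psi must be in (0, 1)")
  if (is.null(N)) N <- spec$N
  if (N < 1) stop("extra_sample_chao: N must be >= 1")
  if (is.null(f0_hat)) f0_hat <- chao1(spec)$f0_hat
  if (is.na(f0_hat) || f0_hat < 0)
    stop("extra_sample_chao: f0_hat must be a non-negative number")
  f1 <- spectrum_f(spec, 1); f2 <- spectrum_f(spec, 2)
  if (f1 == 0)
    return(new_extra_sample_estimate("chao", psi, 0, condition_met = TRUE))
  G_hat <- spec$g + f0_hat
  ratio <- f0_hat / (G_hat * (1 - psi))
  if (ratio <= 1)
    return(new_extra_sample_estimate("chao", psi, NA_real_, condition_met = FALSE))
  if (f2 == 0)
    return(new_extra_sample_estimate("chao", psi, NA_real_, condition_met = TRUE,
                                     degenerate = TRUE))
  new_extra_sample_estimate("chao", psi,
                            N * (f1 / (2 * f2)) * log(ratio),
                            condition_met = TRUE)
}

#' Extra sample size via the h6-based formula
#'
#' \deqn{m'_\psi = N \frac{h_6}{f_1}
#'       \log\!\left(\frac{h_6}{\hat G (1-\psi)}\right)}
#' with `G_hat = g + h6`. The quotient `h6 / f1` in place of `f1 / (2 f2)`
#' gives markedly more accurate depth predictions for RNA-seq. Same
#' completeness and positivity-condition handling as [extra_sample_chao()].
#'
#' @inheritParams extra_sample_chao
#' @param h6_hat the h6 estimate of the undetected genes; computed from the
#'   spectrum when omitted.
#' @return An `extra_sample_estimate`.
#' @export
extra_sample_h6 <- function(spec, h6_hat = NULL, psi = 0.95, N = NULL) {
  spec <- as_spectrum(spec)
  if (length(psi) != 1L || psi <= 0 || psi >= 1)
    stop("extra_sample_h6: psi must be in (0, 1)")
  if (is.null(N)) N <- spec$N
  if (N < 1) stop("extra_sample_h6: N must be >= 1")
  f1 <- spectrum_f(spec, 1)
  if (is.null(h6_hat)) {
    est <- h6(spec)
    if (is.na(est$f0_hat))
      return(new_extra_sample_estimate("h6", psi, NA_real_,
                                       condition_met = TRUE, degenerate = TRUE))
    h6_hat <- est$f0_hat
  }
  if (is.na(h6_hat) || h6_hat < 0)
    stop("extra_sample_h6: h6_hat must be a non-negative number")
  if (f1 == 0) {
    if (h6_hat > 0)
      stop("extra_sample_h6: inconsistent input (f1 = 0 but h6_hat > 0)")
    return(new_extra_sample_estimate("h6", psi, 0, condition_met = TRUE))
  }
  if (h6_hat == 0)
    return(new_extra_sample_estimate("h6", psi, NA_real_, condition_met = FALSE))
  G_hat <- spec$g + h6_hat
  ratio <- h6_hat / (G_hat * (1 - psi))
  if (ratio <= 1)
    return(new_extra_sample_estimate("h6", psi, NA_real_, condition_met = FALSE))
  new_extra_sample_estimate("h6", psi,
                            N * (h6_hat / f1) * log(ratio),
                            condition_met = TRUE)
}

#' Expected number of detected genes at a given depth
#'
#' Under a known abundance vector `p`, the expected number of genes detected
#' by a depth-`N` sample is computed by Poissonization:
#' `sum(1 - exp(-N * p_i))`.
#'
#' @param population a [make_population()] object, a [count_vector()] (its
#'   empirical proportions are used), or a bare probability vector.
#' @param N depth in tags (`>= 0`).
#' @return Expected detected-gene count.
#' @export
expected_genes_at_depth <- function(population, N) {
  p <- if (inherits(population, "synthetic_population")) population$p
       else if (inherits(population, "count_vector"))
         population$counts / population$N
       else as.double(population)
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
    stop("expected_genes_at_depth: p must be positive and sum to 1")
  if (length(N) != 1L || N < 0) stop("expected_genes_at_depth: N must be >= 0")
  sum(1 - exp(-N * p))
}

#' Weighted squared error of an extra-sample prediction
#'
#' Scores a depth prediction by the squared gap between the predicted gene
#' total (`g + psi * f0_hat`) and the expected gene total actually reachable
#' at the predicted depth (`E[G | N + m]`), weighted by `1 / f0_hat^2`:
#' \deqn{\left(\frac{(g + \psi \hat f_0) - E[G \mid N + m_\psi]}
#'       {\hat f_0}\right)^2}
#'
#' @param predicted_gain_target the predicted gene total `g + psi * f0_hat`.
#' @param realized_expected_G the expected detected-gene count at depth
#'   `N + m` (see [expected_genes_at_depth()] or bootstrap averaging).
#' @param f0_hat the estimate the prediction was based on (`> 0`).
#' @return Non-negative weighted squared error.
#' @export
weighted_squared_error <- function(predicted_gain_target, realized_expected_G,
                                   f0_hat) {
  if (any(f0_hat <= 0))
    stop("weighted_squared_error: f0_hat must be > 0 (weight undefined)")
  ((predicted_gain_target - realized_expected_G) / f0_hat)^2
}

#' Compare extra-sample estimators on a complete reference
#'
#' Draws bootstrap samples of varying depth from a complete reference and,
#' for each sample, method and target proportion, predicts the extra depth
#' `m`, then scores the prediction by [weighted_squared_error()] against the
#' expected gene total at depth `N_i + m` under the reference distribution
#' (Poissonization). Method `"chao"` pairs the Chao-style depth formula with
#' the Chao1 estimate; method `"h6"` pairs the h6-based formula with the h6
#' estimate. Replicates where an estimate was degenerate, zero, or the
#' positivity condition failed are flagged and excluded from the error
#' summaries.
#'
#' @param complete a complete [count_vector()] reference.
#' @param psis target proportions, each in `(0, 1)`.
#' @param config a [bootstrap_config()]; replicate depths are uniform on
#'   `[n_min, n_max]`.
#' @param methods subset of `c("chao", "h6")`.
#' @return Data frame with one row per method x psi: `method`, `psi`,
#'   `mean_wse`, `median_wse`, `n_used`, `n_condition_failed`,
#'   `n_degenerate`.
#' @export
compare_extra_sample_estimators <- function(complete, psis = 0.95,
                                            config = bootstrap_config(),
                                            methods = c("chao", "h6")) {
  stopifnot(inherits(complete, "count_vector"),
            inherits(config, "bootstrap_config"))
  if (any(psis <= 0 | psis >= 1))
    stop("compare_extra_sample_estimators: each psi must be in (0, 1)")
  methods <- match.arg(methods, several.ok = TRUE)
  p_ref <- complete$counts / complete$N
  seeds <- derive_replicate_seeds(config$seed, config$B)
  grid <- expand.grid(method = methods, psi = psis,
                      stringsAsFactors = FALSE)
  wse <- matrix(NA_real_, config$B, nrow(grid))
  failed <- degen <- matrix(FALSE, config$B, nrow(grid))
  for (i in seq_len(config$B)) {
    set.seed(seeds[i])
    N_i <- round(stats::runif(1, config$n_min, config$n_max))
    rep_i <- bootstrap_sample(complete, N_i, config$distribution)
    if (is.null(rep_i$spectrum)) { degen[i, ] <- TRUE; next }
    sp <- rep_i$spectrum
    f0_chao <- chao1(sp)
    f0_h6 <- h6(sp)
    for (k in seq_len(nrow(grid))) {
      m_est <- if (grid$method[k] == "chao") {
        if (f0_chao$degenerate || is.na(f0_chao$f0_hat) || f0_chao$f0_hat <= 0) {
          degen[i, k] <- TRUE; next
        }
        extra_sample_chao(sp, f0_chao$f0_hat, grid$psi[k], N = N_i)
      } else {
        if (f0_h6$degenerate || is.na(f0_h6$f0_hat) || f0_h6$f0_hat <= 0) {
          degen[i, k] <- TRUE; next
        }
        extra_sample_h6(sp, f0_h6$f0_hat, grid$psi[k], N = N_i)
      }
      if (!m_est$condition_met) { failed[i, k] <- TRUE; next }
      if (is.na(m_est$m_extra)) { degen[i, k] <- TRUE; next }
      f0_used <- if (grid$method[k] == "chao") f0_chao$f0_hat else f0_h6$f0_hat
      predicted <- sp$g + grid$psi[k] * f0_used
      realized <- expected_genes_at_depth(p_ref, N_i + m_est$m_extra)
      wse[i, k] <- weighted_squared_error(predicted, realized, f0_used)
    }
  }
  out <- grid
  out$mean_wse <- colMeans(wse, na.rm = TRUE)
  out$median_wse <- apply(wse, 2, stats::median, na.rm = TRUE)
  out$n_used <- colSums(!is.na(wse))
  out$n_condition_failed <- colSums(failed)
  out$n_degenerate <- colSums(degen)
  out
}
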