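## Closed-form non-parametric estimators of f0, the number of expressed but
## undetected genes. All operate on the frequency spectrum alone; none uses
## gene identities. Zero denominators are flagged (`degenerate = TRUE`),
## never raised: these estimators have no finite expectation precisely
## because their denominators can be zero with positive probability.

as_spectrum <- function(x) {
  if (inherits(x, "count_vector")) return(spectrum_from_counts(x))
  if (inherits(x, "freq_spectrum")) return(x)
  if (is.numeric(x)) return(spectrum_from_counts(x))
  stop("expected a freq_spectrum or count_vector")
}

#' Construct a richness estimate object
#'
#' Container for an estimator's output: the estimated number of missing genes
#' `f0_hat`, the implied total `G_hat = g + f0_hat`, the percentage of
#' undetected genes `100 * f0_hat / G_hat`, and optional bootstrap standard
#' error and approximate 95% confidence bounds. `degenerate = TRUE` marks
#' estimates where a zero denominator was encountered; `f0_hat` is then `NA`
#' unless a documented fallback exists.
#'
#' @param estimator estimator name.
#' @param f0_hat estimated number of undetected genes (`NA` when degenerate
#'   with no fallback).
#' @param g number of genes detected in the sample.
#' @param N sample depth in tags (optional, carried for reporting).
#' @param se,ci_lower,ci_upper optional bootstrap standard error and 95% CI.
#' @param degenerate logical flag for zero-denominator cases.
#' @return An object of class `"richness_estimate"`.
#' @export
richness_estimate <- function(estimator, f0_hat, g, N = NA_real_,
                              se = NA_real_, ci_lower = NA_real_,
                              ci_upper = NA_real_, degenerate = FALSE) {
  stopifnot(is.na(f0_hat) || f0_hat >= 0, g >= 1)
  G_hat <- g + f0_hat
  structure(
    list(estimator = estimator, f0_hat = f0_hat, g = g, N = N,
         G_hat = G_hat,
         pct_missing = if (is.na(f0_hat)) NA_real_ else 100 * f0_hat / G_hat,
         se = se, ci_lower = ci_lower, ci_upper = ci_upper,
         degenerate = isTRUE(degenerate)),
    class = "richness_estimate"
  )
}

#' @export
print.richness_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%s estimate of undetected genes: f0_hat = %s (g = %s",
              x$estimator,
              if (is.na(x$f0_hat)) "NA (degenerate)" else
                format(round(x$f0_hat, digits), big.mark = ","),
              format(x$g, big.mark = ",")))
  if (!is.na(x$pct_missing))
    cat(sprintf(", %.1f%% of G_hat missing", x$pct_missing))
  cat(")\n")
  if (!is.na(x$se))
    cat(sprintf("  se = %.*f, 95%% CI [%.*f, %.*f]\n", digits, x$se,
                digits, x$ci_lower, digits, x$ci_upper))
  invisible(x)
}

#' Chao1 estimator of undetected genes
#'
#' The classical lower-bound estimator `f0_hat = f1^2 / (2 f2)`, built from
#' singletons and doubletons only. When `f2 = 0` but `f1 > 0` the estimate is
#' undefined; following standard ecological-software practice the
#' bias-corrected form `f1 (f1 - 1) / (2 (f2 + 1))` is returned instead, with
#' `degenerate = TRUE`. A complete sample (`f1 = 0`) yields 0.
#'
#' @param spec a [freq_spectrum()] or [count_vector()].
#' @return A [richness_estimate()].
#' @examples
#' chao1(freq_spectrum(1:2, c(3, 9)))$f0_hat  # 0.5
#' @export
chao1 <- function(spec) {
  spec <- as_spectrum(spec)
  f1 <- spectrum_f(spec, 1); f2 <- spectrum_f(spec, 2)
  if (f1 == 0) {
    est <- 0; degen <- FALSE
  } else if (f2 == 0) {
    est <- f1 * (f1 - 1) / (2 * (f2 + 1)); degen <- TRUE
  } else {
    est <- f1^2 / (2 * f2); degen <- FALSE
  }
  richness_estimate("chao1", est, g = spec$g, N = spec$N, degenerate = degen)
}

#' Bias-corrected Chao2 estimator
#'
#' `f0_hat = f1 (f1 - 1) / (2 (f2 + 1))`; always finite, never degenerate.
#'
#' @inheritParams chao1
#' @return A [richness_estimate()].
#' @export
chao2_corrected <- function(spec) {
  spec <- as_spectrum(spec)
  f1 <- spectrum_f(spec, 1); f2 <- spectrum_f(spec, 2)
  richness_estimate("chao2", f1 * (f1 - 1) / (2 * (f2 + 1)),
                    g = spec$g, N = spec$N)
}

#' iChao1 estimator of undetected genes
#'
#' Improved Chao1, adding information from `f3` and `f4`:
#' `f0_hat = f1^2/(2 f2) + (f3/(4 f4)) * max(f1 - f2 f3 / (2 f4), 0)`.
#' Zero denominators are handled term by term: `f2 = 0` with `f1 > 0` makes
#' the base term fall back to the bias-corrected Chao2 form, and `f4 = 0`
#' drops the correction term; both cases set `degenerate = TRUE`.
#'
#' @inheritParams chao1
#' @return A [richness_estimate()].
#' @export
ichao1 <- function(spec) {
  spec <- as_spectrum(spec)
  f1 <- spectrum_f(spec, 1); f2 <- spectrum_f(spec, 2)
  f3 <- spectrum_f(spec, 3); f4 <- spectrum_f(spec, 4)
  if (f1 == 0)
    return(richness_estimate("ichao1", 0, g = spec$g, N = spec$N))
  degen <- FALSE
  if (f2 == 0) {
    base <- f1 * (f1 - 1) / (2 * (f2 + 1)); degen <- TRUE
  } else base <- f1^2 / (2 * f2)
  if (f4 == 0) {
    corr <- if (f3 > 0) { degen <- TRUE; 0 } else 0
  } else {
    corr <- (f3 / (4 * f4)) * max(f1 - f2 * f3 / (2 * f4), 0)
  }
  richness_estimate("ichao1", base + corr, g = spec$g, N = spec$N,
                    degenerate = degen)
}

#' Medial estimator of undetected genes
#'
#' `f0_hat = ((N - 1)/N) * f1 (f1 - 1) / (f2 + 1)` (exact form), or the
#' approximate form without the `(N - 1)/N` factor — irrelevant at RNA-seq
#' depths of millions of tags and therefore the default.
#'
#' @inheritParams chao1
#' @param exact use the exact form with the `(N - 1)/N` factor.
#' @return A [richness_estimate()].
#' @export
medial <- function(spec, exact = FALSE) {
  spec <- as_spectrum(spec)
  f1 <- spectrum_f(spec, 1); f2 <- spectrum_f(spec, 2)
  est <- f1 * (f1 - 1) / (f2 + 1)
  if (exact) {
    if (is.na(spec$N) || spec$N < 1) stop("medial: exact form requires N >= 1")
    est <- est * (spec$N - 1) / spec$N
  }
  richness_estimate("medial", est, g = spec$g, N = spec$N)
}

#' Naive estimator: assume no genes were missed
#'
#' Returns `f0_hat = 0` for every sample — the implicit assumption of most
#' RNA-seq pipelines (`G = g`). Included as the baseline the other estimators
#' are measured against.
#'
#' @inheritParams chao1
#' @return A [richness_estimate()] with `f0_hat = 0`.
#' @export
naive_richness <- function(spec) {
  spec <- as_spectrum(spec)
  richness_estimate("naive", 0, g = spec$g, N = spec$N)
}

#' Pythagorean-mean estimator family
#'
#' The candidate family `f0_hat = u * f1^2 / c(f2, ..., f_degree)` where
#' `c()` is the arithmetic, geometric or harmonic mean of `f2` up to
#' `f_degree`. The search grid spans degrees 3..10 for each of the three
#' Pythagorean means; the selected member is [h6()] (harmonic, degree 6,
#' `u = 6/10`). When the required mean is zero or undefined (any `f_r = 0`
#' for the geometric/harmonic means, or all zero for the arithmetic), the
#' estimate is `NA` with `degenerate = TRUE` — no standard correction exists
#' for these forms.
#'
#' @inheritParams chao1
#' @param mean_type one of `"arithmetic"`, `"geometric"`, `"harmonic"`.
#' @param degree highest `f_r` used, integer in 3..10.
#' @param u positive scalar multiplier.
#' @return A [richness_estimate()].
#' @examples
#' sp <- freq_spectrum(1:3, c(4, 2, 6))
#' pythagorean_family(sp, "arithmetic", 3, 1)$f0_hat  # 4
#' @export
pythagorean_family <- function(spec, mean_type = c("harmonic", "arithmetic", "geometric"),
                               degree = 6L, u = 6 / 10) {
  spec <- as_spectrum(spec)
  mean_type <- match.arg(mean_type)
  if (length(degree) != 1L || degree < 3 || degree > 10 || degree != floor(degree))
    stop("pythagorean_family: degree must be an integer in 3..10")
  if (!is.numeric(u) || length(u) != 1L || u <= 0)
    stop("pythagorean_family: u must be a positive scalar")
  name <- paste0(substr(mean_type, 1, 1), degree)
  f1 <- spectrum_f(spec, 1)
  if (f1 == 0)
    return(richness_estimate(name, 0, g = spec$g, N = spec$N))
  fr <- spectrum_f(spec, 2:degree)
  c_val <- switch(mean_type,
    arithmetic = mean(fr),
    geometric  = if (any(fr == 0)) 0 else exp(mean(log(fr))),
    harmonic   = if (any(fr == 0)) 0 else length(fr) / sum(1 / fr)
  )
  if (!is.finite(c_val) || c_val == 0)
    return(richness_estimate(name, NA_real_, g = spec$g, N = spec$N,
                             degenerate = TRUE))
  richness_estimate(name, u * f1^2 / c_val, g = spec$g, N = spec$N)
}

#' The harmonic estimator of degree 6 (h6)
#'
#' The selected estimator of the number of undetected genes for RNA-seq:
#' \deqn{h_6 = \frac{6}{10} \frac{f_1^2}{H(f_2, \ldots, f_6)}, \qquad
#'       H(f_2, \ldots, f_6) = \frac{5}{\sum_{r=2}^{6} 1/f_r}}
#' i.e. the Pythagorean family member with the harmonic mean of `f2..f6` and
#' `u = 6/10` exactly. Deep RNA-seq samples have `f_2, ..., f_6 > 0` almost
#' always, so the degenerate case (any required `f_r = 0`, estimate `NA`) is
#' rare in practice. A complete sample (`f1 = 0`) yields 0.
#'
#' @inheritParams chao1
#' @return A [richness_estimate()].
#' @examples
#' sp <- freq_spectrum(1:6, c(3, 9, 27, 15, 23, 439))
#' h6(sp)$f0_hat  # 0.2814167
#' @export
h6 <- function(spec) {
  est <- pythagorean_family(as_spectrum(spec), "harmonic", degree = 6L, u = 6 / 10)
  est$estimator <- "h6"
  est
}

#' Good-Turing adjusted count
#'
#' The expected-frequency recurrence `r* = (r + 1) f_{r+1} / f_r`: the
#' adjusted relative frequency `r*/N` replaces the naive `r/N` for rare
#' classes when the true number of classes is unknown.
#'
#' @inheritParams chao1
#' @param r observed tag count (`f_r` must be positive).
#' @return The adjusted count `r*`.
#' @export
good_turing_adjusted_count <- function(spec, r) {
  spec <- as_spectrum(spec)
  stopifnot(length(r) == 1L, r >= 1)
  fr <- spectrum_f(spec, r)
  if (fr == 0)
    stop("good_turing_adjusted_count: undefined adjusted count (f_", r, " = 0)")
  (r + 1) * spectrum_f(spec, r + 1) / fr
}

#' Good's sample coverage
#'
#' `C = 1 - f1 / N`: the estimated probability that the next sampled tag maps
#' to an already-detected gene. A complete sample has coverage 1.
#'
#' @inheritParams chao1
#' @return Coverage in `[0, 1]`.
#' @export
good_coverage <- function(spec) {
  spec <- as_spectrum(spec)
  if (spec$N < 1) stop("good_coverage: N >= 1 required")
  1 - spectrum_f(spec, 1) / spec$N
}

#' Percentage of undetected genes
#'
#' `100 * f0_hat / (g + f0_hat)`: the estimated share of the true gene set
#' that the sample missed.
#'
#' @param f0_hat estimated number of undetected genes (`>= 0`).
#' @param g number of detected genes (`>= 1`).
#' @return Percentage in `[0, 100]`.
#' @examples
#' round(percent_undetected(4786, 34066))  # 12
#' @export
percent_undetected <- function(f0_hat, g) {
  stopifnot(all(f0_hat >= 0), all(g >= 1))
  100 * f0_hat / (g + f0_hat)
}

#' Look up an estimator function by name
#'
#' Accepted names: `"chao1"`, `"chao2"`, `"ichao1"`, `"medial"`, `"naive"`,
#' `"h6"`, or `"pythagorean:<mean>:<degree>:<u>"` (e.g.
#' `"pythagorean:harmonic:6:0.6"`).
#'
#' @param name estimator name.
#' @return A function `freq_spectrum -> richness_estimate`.
#' @export
estimator_by_name <- function(name) {
  if (grepl("^pythagorean:", name)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 4L)
      stop("estimator_by_name: expected pythagorean:<mean>:<degree>:<u>")
    mean_type <- parts[2L]
    degree <- as.integer(parts[3L]); u <- as.numeric(parts[4L])
    return(function(spec) pythagorean_family(spec, mean_type, degree, u))
  }
  switch(name,
    chao1 = chao1,
    chao2 = chao2_corrected,
    ichao1 = ichao1,
    medial = medial,
    naive = naive_richness,
    h6 = h6,
    stop("estimator_by_name: unknown estimator '", name, "'")
  )
}
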