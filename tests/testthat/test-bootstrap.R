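# Parametric bootstrap: draws, standard errors, the selection harness and
# detection probabilities.

test_that("bootstrap draws respect totals and saturate at large depth", {
  ref <- count_vector(c(1, 1))
  rep_big <- bootstrap_sample(ref, 1e6, "multinomial", seed = 1)
  expect_equal(rep_big$true_f0, 0)  # both genes essentially certain

  ref2 <- count_vector(c(5, 5))
  rep1 <- bootstrap_sample(ref2, 1, "multinomial", seed = 2)
  expect_equal(rep1$g, 1)           # one tag detects exactly one gene
  expect_equal(rep1$true_f0, 1)

  # multinomial totals are exact; poisson totals only in expectation
  set.seed(3)
  ref3 <- count_vector(c(10, 20, 30))
  for (i in 1:20) {
    r <- bootstrap_sample(ref3, 500, "multinomial")
    expect_equal(r$spectrum$N, 500)
  }
  pois_tot <- replicate(400, bootstrap_sample(ref3, 500, "poisson")$spectrum$N)
  expect_lt(abs(mean(pois_tot) - 500), 3 * sqrt(500 / 400))
})

test_that("two-gene missing probability matches the exact binomial", {
  # reference (5,5), N_i = 2: both tags hit one gene with prob 2 * (1/2)^2
  ref <- count_vector(c(5, 5))
  hits <- replicate(10000, bootstrap_sample(ref, 2, "multinomial")$true_f0)
  phat <- mean(hits == 1)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("same seed gives bit-identical draws and estimates", {
  ref <- count_vector(rpois(200, 20) + 1)
  a <- bootstrap_sample(ref, 1000, seed = 77)
  b <- bootstrap_sample(ref, 1000, seed = 77)
  expect_identical(a, b)

  cfg <- bootstrap_config(B = 50, seed = 9)
  e1 <- estimate_se_bias_ci(ref, "h6", cfg)
  e2 <- estimate_se_bias_ci(ref, "h6", cfg)
  expect_identical(e1$se, e2$se)
  expect_identical(e1$ci_lower, e2$ci_lower)
})

test_that("se is the root mean squared deviation from replicate truth", {
  ref <- count_vector(rep(2, 50))
  # oracle estimator that returns the replicate truth exactly: se must be 0
  perfect <- structure(function(sp, f0) richness_estimate("oracle", f0, g = sp$g),
                       uses_truth = TRUE)
  est <- estimate_se_bias_ci(ref, perfect, bootstrap_config(B = 30, seed = 4))
  expect_equal(est$se, 0)

  # the naive estimator's se must reproduce sqrt(mean(f0_i^2)) by hand
  cfg <- bootstrap_config(B = 40, seed = 5)
  est_n <- estimate_se_bias_ci(ref, "naive", cfg)
  seeds <- genemiss:::derive_replicate_seeds(5, 40)
  truths <- vapply(seq_len(40), function(i)
    bootstrap_sample(ref, ref$N, seed = seeds[i])$true_f0, 0)
  expect_equal(est_n$se, sqrt(mean(truths^2)))
  expect_gt(est_n$se, 0)
  expect_equal(est_n$ci_lower, 0)  # clamped at zero around f0_hat = 0
})

test_that("normal CI arithmetic and percentile option behave", {
  ref <- count_vector(rpois(300, 8) + 1)
  cfg <- bootstrap_config(B = 60, seed = 12)
  e <- estimate_se_bias_ci(ref, "chao1", cfg)
  expect_equal(e$ci_upper, e$f0_hat + 1.96 * e$se)
  expect_equal(e$ci_lower, max(0, e$f0_hat - 1.96 * e$se))
  p <- estimate_se_bias_ci(ref, "chao1",
                           bootstrap_config(B = 60, seed = 12,
                                            ci_method = "percentile"))
  expect_lte(p$ci_lower, p$ci_upper)
  expect_gte(p$ci_lower, 0)
})

test_that("the selection harness scores a perfect oracle as ideal", {
  pop <- make_population(300, "uniform")
  ref <- make_complete_reference(pop, target_N = 5000, seed = 6)
  perfect <- structure(function(sp, f0) f0, uses_truth = TRUE)
  cfg <- bootstrap_config(B = 80, n_min = 50, n_max = 2000, seed = 8)
  res <- run_selection_harness(ref, list(oracle = perfect, naive = "naive"),
                               cfg)
  expect_equal(res$se[res$estimator == "oracle"], 0)
  expect_equal(res$r_squared[res$estimator == "oracle"], 1)
  naive_row <- res[res$estimator == "naive", ]
  expect_gt(naive_row$se, 0)
  expect_lte(naive_row$error_min, naive_row$error_median)
  expect_lte(naive_row$error_median, naive_row$error_max)
})

test_that("harness validates depth bounds and warns on incomplete references", {
  ref <- count_vector(c(5, 5, 1))  # has a singleton
  expect_warning(
    run_selection_harness(ref, "naive",
                          bootstrap_config(B = 5, n_min = 2, n_max = 5, seed = 1)),
    "not complete")
  expect_error(
    run_selection_harness(count_vector(c(5, 5)), "naive",
                          bootstrap_config(B = 5, n_min = 100, n_max = 100)),
    "n_min exceeds")
})

test_that("degenerate replicates are dropped and counted per estimator", {
  # tiny reference: h6 needs f2..f6 > 0, essentially never true here
  ref <- count_vector(c(3, 4, 5))
  cfg <- bootstrap_config(B = 30, n_min = 3, n_max = 6, seed = 21)
  res <- run_selection_harness(ref, c("h6", "naive"), cfg)
  h6_row <- res[res$estimator == "h6", ]
  expect_gt(h6_row$n_degenerate, 0)
  expect_equal(h6_row$n_used + h6_row$n_degenerate, 30)
  expect_equal(res$n_degenerate[res$estimator == "naive"], 0)
})

test_that("expected true_f0 is non-increasing in depth", {
  pop <- make_population(100, "lognormal", sdlog = 1, seed = 31)
  ref <- make_complete_reference(pop, target_N = 1e4, seed = 32)
  depths <- c(100, 400, 1600, 6400)
  means <- vapply(depths, function(N) {
    mean(replicate(60, bootstrap_sample(ref, N)$true_f0))
  }, 0)
  expect_true(all(diff(means) <= 0))
})

test_that("detection probability: approximation, exact oracle and edge cases", {
  expect_equal(prob_all_detected(c(0.5, 0.5), 2, method = "exact"), 0.5)
  expect_equal(prob_all_detected(c(0.5, 0.5), 0), 0)
  expect_equal(prob_all_detected(1, 5), 1)
  expect_error(prob_all_detected(c(0.2, 0.2), 5), "sum to 1")

  # exact inclusion-exclusion agrees with exhaustive outcome enumeration
  set.seed(17)
  for (G in 2:3) for (N in c(2, 4)) {
    p <- runif(G); p <- p / sum(p)
    expect_equal(prob_all_detected(p, N, method = "exact"),
                 oracle_prob_all_detected(p, N), tolerance = 1e-10)
  }

  # independence approximation is close to exact for uniform p at N = 6
  for (G in 1:3) {
    p <- rep(1 / G, G)
    expect_lt(abs(prob_all_detected(p, 6) -
                  prob_all_detected(p, 6, method = "exact")), 0.02)
  }
})

test_that("h6 normal-approximation CIs cover the truth at moderate depth", {
  # known-truth loop: population -> sample -> CI; coverage should be near
  # nominal (loose bound, acknowledging the normal approximation)
  pop <- make_population(800, "lognormal", sdlog = 1.2, seed = 41)
  ref <- make_complete_reference(pop, target_N = 5e4, seed = 42)
  n_trials <- 40
  covered <- logical(n_trials)
  set.seed(43)
  trial_seeds <- sample.int(1e6, n_trials)
  for (t in seq_len(n_trials)) {
    dr <- draw_sample(pop, round(0.15 * ref$N), seed = trial_seeds[t])
    est <- estimate_se_bias_ci(dr$sample, "h6",
                               bootstrap_config(B = 150, seed = trial_seeds[t]))
    covered[t] <- !is.na(est$f0_hat) &&
      dr$true_f0 >= est$ci_lower && dr$true_f0 <= est$ci_upper
  }
  expect_gte(mean(covered), 0.85)
})
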