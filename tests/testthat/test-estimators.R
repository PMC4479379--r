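# Closed-form f0 estimators: worked values, degeneracy handling, and
# cross-checks against scalar-loop oracles.

worked_spectrum <- freq_spectrum(1:6, c(3, 9, 27, 15, 23, 439))

test_that("chao1 reproduces hand arithmetic and handles degeneracy", {
  expect_equal(chao1(worked_spectrum)$f0_hat, 0.5)
  expect_equal(chao1(freq_spectrum(1:2, c(4, 2)))$f0_hat, 4)
  expect_equal(chao1(freq_spectrum(2, 10))$f0_hat, 0)  # complete

  degen <- chao1(freq_spectrum(1, 4))  # f2 = 0, f1 > 0
  expect_true(degen$degenerate)
  expect_equal(degen$f0_hat, 4 * 3 / 2)  # bias-corrected fallback
})

test_that("chao2 bias-corrected form is always finite", {
  expect_equal(chao2_corrected(freq_spectrum(1:2, c(4, 2)))$f0_hat, 2)
  expect_equal(chao2_corrected(freq_spectrum(1, 1))$f0_hat, 0)
  expect_equal(chao2_corrected(freq_spectrum(1:2, c(3, 9)))$f0_hat, 0.3)
  expect_false(chao2_corrected(freq_spectrum(1, 50))$degenerate)
})

test_that("ichao1 adds a clamped correction term", {
  # correction clamps to zero: f1 - f2*f3/(2 f4) = 3 - 8.1 < 0
  expect_equal(ichao1(freq_spectrum(1:4, c(3, 9, 27, 15)))$f0_hat, 0.5)
  expect_equal(ichao1(freq_spectrum(1:4, c(10, 2, 2, 2)))$f0_hat, 27.25)
  expect_equal(ichao1(freq_spectrum(2:4, c(9, 27, 15)))$f0_hat, 0)
  # f4 = 0 with f3 > 0: correction dropped, flagged
  d <- ichao1(freq_spectrum(1:3, c(10, 2, 2)))
  expect_true(d$degenerate)
  expect_equal(d$f0_hat, 25)
})

test_that("medial has approximate and exact forms", {
  sp <- freq_spectrum(1:2, c(3, 9))
  expect_equal(medial(sp)$f0_hat, 0.6)
  # exact form at N = 1e6 (constructed via a high count to pad N)
  sp6 <- freq_spectrum(c(1, 2, 999979), c(3, 9, 1))
  expect_equal(sp6$N, 1e6)
  expect_equal(medial(sp6, exact = TRUE)$f0_hat, 0.6 * (1 - 1e-6))
  expect_equal(medial(freq_spectrum(2, 5))$f0_hat, 0)
})

test_that("the naive estimator is identically zero", {
  expect_equal(naive_richness(worked_spectrum)$f0_hat, 0)
  expect_equal(naive_richness(freq_spectrum(1, 1000))$f0_hat, 0)
})

test_that("pythagorean family evaluates all three means and flags zeros", {
  sp <- freq_spectrum(1:3, c(4, 2, 6))
  expect_equal(pythagorean_family(sp, "arithmetic", 3, 1)$f0_hat, 4)
  sp2 <- freq_spectrum(1:6, c(10, 5, 5, 5, 5, 5))
  expect_equal(pythagorean_family(sp2, "harmonic", 6, 0.6)$f0_hat, 12)
  expect_equal(pythagorean_family(sp2, "geometric", 6, 0.6)$f0_hat, 12)

  gap <- freq_spectrum(c(1, 2, 4), c(5, 3, 3))  # f3 = 0
  expect_true(is.na(pythagorean_family(gap, "harmonic", 6)$f0_hat))
  expect_true(pythagorean_family(gap, "harmonic", 6)$degenerate)
  # arithmetic mean tolerates interior zeros
  expect_false(pythagorean_family(gap, "arithmetic", 4)$degenerate)

  expect_error(pythagorean_family(sp, "harmonic", degree = 2), "degree")
  expect_error(pythagorean_family(sp, "harmonic", 6, u = -1), "u must be")
})

test_that("h6 reproduces the published worked value", {
  expect_equal(h6(worked_spectrum)$f0_hat, 0.2814167, tolerance = 1e-7 / 0.28)
  expect_equal(h6(freq_spectrum(1:6, c(10, 5, 5, 5, 5, 5)))$f0_hat, 12)
  expect_equal(h6(freq_spectrum(2, 3))$f0_hat, 0)
  expect_true(h6(freq_spectrum(1:5, c(3, 9, 27, 15, 23)))$degenerate)
})

test_that("h6 equals the pythagorean family member bit for bit", {
  set.seed(7)
  for (rep in 1:200) {
    sp <- random_spectrum()
    a <- h6(sp)$f0_hat
    b <- pythagorean_family(sp, "harmonic", 6L, 6 / 10)$f0_hat
    expect_identical(a, b)
  }
})

test_that("estimates depend only on the spectrum, not labels or order", {
  set.seed(13)
  y <- random_counts()
  perm <- sample(length(y))
  a <- count_vector(y, gene_ids = paste0("a", seq_along(y)))
  b <- count_vector(y[perm], gene_ids = paste0("zz", seq_along(y)))
  for (nm in c("chao1", "chao2", "ichao1", "medial", "h6", "naive")) {
    fn <- estimator_by_name(nm)
    expect_identical(fn(spectrum_from_counts(a))$f0_hat,
                     fn(spectrum_from_counts(b))$f0_hat, label = nm)
  }
})

test_that("every estimator returns exactly zero on complete spectra", {
  set.seed(99)
  for (rep in 1:50) {
    f <- rpois(9, 4)
    if (sum(f) == 0) f[1] <- 1
    sp <- freq_spectrum(r = 1 + which(f > 0), f = f[f > 0])  # r >= 2 only
    for (nm in c("chao1", "chao2", "ichao1", "medial", "h6", "naive")) {
      est <- estimator_by_name(nm)(sp)
      expect_identical(est$f0_hat, 0, label = nm)
      expect_false(est$degenerate, label = nm)
    }
    expect_equal(pythagorean_family(sp, "geometric", 8, 2)$f0_hat, 0)
  }
})

test_that("algebraic inequalities hold across random spectra", {
  set.seed(1234)
  for (rep in 1:300) {
    sp <- random_spectrum()
    c1 <- chao1(sp); i1 <- ichao1(sp); c2 <- chao2_corrected(sp)
    if (!c1$degenerate && !i1$degenerate)
      expect_gte(i1$f0_hat, c1$f0_hat)
    if (!c1$degenerate)
      expect_lte(c2$f0_hat, c1$f0_hat + 1e-12)
  }
})

test_that("vectorized estimators match scalar-loop oracles", {
  set.seed(555)
  for (rep in 1:300) {
    sp <- random_spectrum()
    fvec <- dense_f(sp)
    expect_equal(chao1(sp)$f0_hat, oracle_chao1(fvec), tolerance = 1e-12)
    expect_equal(chao2_corrected(sp)$f0_hat, oracle_chao2(fvec), tolerance = 1e-12)
    expect_equal(ichao1(sp)$f0_hat, oracle_ichao1(fvec), tolerance = 1e-12)
    expect_equal(medial(sp)$f0_hat, oracle_medial(fvec), tolerance = 1e-12)
    expect_equal(h6(sp)$f0_hat, oracle_h6(fvec), tolerance = 1e-12)
  }
})

test_that("good-turing adjusted counts follow the recurrence", {
  sp <- freq_spectrum(1:2, c(6, 3))
  expect_equal(good_turing_adjusted_count(sp, 1), 1)
  expect_equal(good_turing_adjusted_count(freq_spectrum(2, 4), 2), 0)
  expect_error(good_turing_adjusted_count(freq_spectrum(2, 4), 1),
               "undefined adjusted count")
})

test_that("good coverage is 1 - f1/N with the right extremes", {
  sp <- freq_spectrum(c(1, 5), c(5, 19))  # N = 100
  expect_equal(good_coverage(sp), 0.95)
  expect_equal(good_coverage(freq_spectrum(2, 4)), 1)
  expect_equal(good_coverage(freq_spectrum(1, 17)), 0)  # all singletons
})

test_that("percent undetected matches the reporting convention", {
  expect_equal(round(percent_undetected(4786, 34066)), 12)
  expect_equal(percent_undetected(0, 10), 0)
  expect_equal(percent_undetected(25, 75), 25)
})

test_that("estimator_by_name resolves names and the pythagorean syntax", {
  expect_identical(estimator_by_name("h6")(worked_spectrum)$f0_hat,
                   h6(worked_spectrum)$f0_hat)
  fn <- estimator_by_name("pythagorean:harmonic:6:0.6")
  expect_identical(fn(worked_spectrum)$f0_hat, h6(worked_spectrum)$f0_hat)
  expect_error(estimator_by_name("nope"), "unknown estimator")
  expect_error(estimator_by_name("pythagorean:harmonic"), "expected")
})
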