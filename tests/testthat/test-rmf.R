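# Independent oracle: solve alpha*D + beta*D^2 = -log(S) by root bracketing
# rather than the closed-form quadratic used by the package.
oracle_dose <- function(alpha, beta, s) {
  f <- function(d) alpha * d + beta * d^2 + log(s)
  uniroot(f, c(0, 1e4), tol = 1e-14)$root
}

test_that("per-cell DSB conversion is a plain genome-size scaling", {
  p1 <- rmf_params(genome_gbp = 1)
  expect_equal(dsb_per_cell(8.1, p1), 8.1)
  expect_equal(dsb_per_cell(0, p1), 0)
  p <- rmf_params(genome_gbp = 5.4)
  expect_equal(dsb_per_cell(get_spectrum("Co-60", 21), p), 8.1 * 5.4)
})

test_that("genome size calibrated on the reference alpha is a plausible
           hamster genome", {
  g <- calibrate_genome_size()
  expect_gt(g, 4)
  expect_lt(g, 7)
  # by construction the reference quality lands on the alpha-LET line
  p <- rmf_params(genome_gbp = g)
  zf <- frequency_mean_specific_energy(0.24, 8)
  a <- lq_alpha(8.1 * g, 1, p, zf)
  expect_equal(a, 0.0466 * 0.24 + 0.2412, tolerance = 1e-10)
})

test_that("rejoinable fraction sums the multiplicity histogram below j", {
  all2 <- data.frame(i = 2, expected_dsbs = 5)
  expect_equal(rejoinable_fraction(all2, 13), 1)
  split_hist <- data.frame(i = c(2, 20), expected_dsbs = c(90, 10))
  expect_equal(rejoinable_fraction(split_hist, 13), 0.9)
  expect_equal(rejoinable_fraction(split_hist, 2), 0)  # empty sum
  expect_error(rejoinable_fraction(data.frame(i = 2, expected_dsbs = 0), 13),
               "zero")
  expect_error(rejoinable_fraction(data.frame(i = 1, expected_dsbs = 1), 13),
               "i = 2")
  # f_R is non-decreasing in j
  h <- data.frame(i = 2:20, expected_dsbs = 0.5^(0:18))
  fr <- vapply(2:21, function(j) rejoinable_fraction(h, j), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("RMF alpha and beta match hand-evaluated values", {
  p <- rmf_params(theta = 0, kappa = 0, genome_gbp = 1)
  expect_equal(lq_alpha(50, 1, p, 0.02), 0)  # everything rejoined
  p <- rmf_params(genome_gbp = 1)  # theta 5.79e-3, kappa 5.59e-5
  expect_equal(lq_alpha(43.5, 1, p, 7.65e-4), 0.2520, tolerance = 5e-4)
  expect_equal(lq_beta(40, 1, p), 0.04472)
  expect_equal(lq_beta(80, 1, p), 4 * lq_beta(40, 1, p))  # quadratic
  # alpha rises as the rejoinable fraction falls (theta < 1)
  a <- vapply(seq(1, 0.9, by = -0.01),
              function(fr) lq_alpha(43.5, fr, p, 7.65e-4), numeric(1))
  expect_true(all(diff(a) > 0))
  # alpha and beta are non-decreasing in sigma
  sig <- seq(0, 80, by = 5)
  expect_true(all(diff(vapply(sig, function(s) lq_alpha(s, 0.99, p, 0.02),
                              numeric(1))) >= 0))
  expect_true(all(diff(vapply(sig, function(s) lq_beta(s, 0.99, p),
                              numeric(1))) >= 0))
})

test_that("survival and dose solvers invert each other", {
  lq <- lq_params(0.3, 0.03)
  expect_equal(survival_fraction(lq, 0), 1)
  d <- dose_for_survival(lq, 0.1)
  expect_equal(d, oracle_dose(0.3, 0.03, 0.1), tolerance = 1e-9)
  expect_equal(d, 5.0873, tolerance = 1e-4)
  expect_equal(survival_fraction(lq, 5.0877), 0.10, tolerance = 1e-3)
  # exponential and pure-quadratic limits
  expect_equal(dose_for_survival(lq_params(0.3, 0), 0.1), -log(0.1) / 0.3)
  expect_equal(dose_for_survival(lq_params(0, 0.03), 0.1),
               sqrt(-log(0.1) / 0.03))
  expect_equal(dose_for_survival(lq_params(0, 0.03), 0.1), 8.760,
               tolerance = 1e-4)
  expect_error(dose_for_survival(lq_params(0, 0), 0.1), "alpha = beta = 0")
  # survival monotone decreasing in dose
  s <- survival_fraction(lq, seq(0, 10, by = 0.5))
  expect_true(all(diff(s) < 0))
  # round-trip property over random triples
  set.seed(99)
  for (k in 1:200) {
    a <- runif(1, 0.01, 1); b <- runif(1, 0, 0.2); sv <- runif(1, 0.001, 0.99)
    lqk <- lq_params(a, b)
    expect_equal(survival_fraction(lqk, dose_for_survival(lqk, sv)), sv,
                 tolerance = 1e-10)
  }
})

test_that("RBE for DSB induction is a reference-normalised yield ratio", {
  expect_equal(rbe_dsb(10.8, 8.1), 1.3333, tolerance = 1e-4)
  expect_equal(round(rbe_dsb(10.8, 8.1), 1), 1.3)
  expect_equal(rbe_dsb(8.1, 8.1), 1)
  # printed one-decimal yields give 1.1 for the 10 kV quality even though
  # the published table prints 1.2 (unrounded internals behind the table)
  expect_equal(round(rbe_dsb(9.3, 8.1), 1), 1.1)
  expect_error(rbe_dsb(5, 0), "> 0")
})

test_that("survival RBE and OER follow from equal-effect doses", {
  ref <- lq_params(0.2524, 0.0485)
  expect_equal(rbe_survival(ref, ref), 1)
  expect_equal(rbe_survival(lq_params(0.6, 0), lq_params(0.3, 0)), 2)
  tst <- lq_params(0.5488, 0.0934)
  want <- oracle_dose(0.2524, 0.0485, 0.1) / oracle_dose(0.5488, 0.0934, 0.1)
  expect_equal(rbe_survival(tst, ref, 0.1), want, tolerance = 1e-9)
  expect_equal(want, 1.6823, tolerance = 1e-4)

  expect_equal(oer_dsb(8.1, 3.5), 2.3143, tolerance = 1e-4)
  expect_equal(round(oer_dsb(8.1, 3.5), 1), 2.3)
  expect_equal(oer_dsb(10.8, 4.9), 2.2041, tolerance = 1e-4)
  expect_equal(oer_dsb(4, 4), 1)
  expect_error(oer_dsb(4, 0), "> 0")

  aer <- lq_params(0.5488, 0.0934)
  hyp <- lq_params(0.3119, 0.0152)
  expect_equal(oer_survival(aer, aer), 1)
  expect_equal(oer_survival(lq_params(0.9, 0), lq_params(0.3, 0)), 3)
  want_oer <- oracle_dose(0.3119, 0.0152, 0.1) / oracle_dose(0.5488, 0.0934, 0.1)
  expect_equal(oer_survival(aer, hyp, 0.1), want_oer, tolerance = 1e-9)
  expect_equal(want_oer, 2.0357, tolerance = 1e-4)
  # hypoxic alpha, beta below aerobic implies OER >= 1
  expect_gte(oer_survival(aer, hyp), 1)
})

test_that("fraction-dose RBE has the right limit, value and monotonicity", {
  fp <- fractionation_params(alpha_ref = 0.2412, beta_ref = 0.0485,
                             lambda = 0.0466)
  expect_equal(rbe_fraction_dose(fp, 6.6, 0),
               (0.2412 + 0.0466 * 6.6) / 0.2412)
  expect_equal(rbe_fraction_dose(fp, 6.6, 2), 1.6208, tolerance = 1e-4)
  # continuous at D -> 0
  expect_equal(rbe_fraction_dose(fp, 6.6, 1e-9),
               rbe_fraction_dose(fp, 6.6, 0), tolerance = 1e-6)
  # strictly decreasing in dose at positive LET
  sweep <- rbe_fraction_dose(fp, 6.6, seq(0.25, 7, by = 0.25))
  expect_true(all(diff(sweep) < 0))
})

test_that("closed-form fraction-dose RBE agrees with the two-quality
           equal-effect derivation", {
  fp <- fractionation_params(0.2412, 0.0485, 0.0466)
  for (let in c(1, 2.7, 6.6)) {
    for (d in c(0.5, 2, 4.5, 7)) {
      lq_test <- lq_params(fp$alpha_ref + fp$lambda * let, fp$beta_ref)
      lq_ref <- lq_params(fp$alpha_ref, fp$beta_ref)
      s_at_d <- survival_fraction(lq_test, d)
      direct <- rbe_survival(lq_test, lq_ref, s_at_d)
      expect_equal(rbe_fraction_dose(fp, let, d), direct,
                   tolerance = 1e-8)
    }
  }
})

test_that("alpha-LET regression recovers exact lines and flags degeneracy", {
  let <- c(0.24, 2.7, 3.7, 5.6, 6.6)
  fit <- suppressWarnings(alpha_let_fit(let, 0.04 * let + 0.2))
  expect_equal(fit$slope, 0.04)
  expect_equal(fit$intercept, 0.2)
  expect_equal(fit$r_squared, 1)
  expect_error(alpha_let_fit(c(2, 2, 2), c(0.1, 0.2, 0.3)), "distinct")
})

test_that("low-energy bias arithmetic matches the published estimate", {
  b <- estimate_mcds_bias(24.9, 9.8, 0.09, 10.8)
  expect_equal(round(b$absolute, 1), 1.4)
  expect_equal(b$absolute, 1.359)
  expect_equal(round(b$relative_percent), 13)
  expect_equal(estimate_mcds_bias(24.9, 9.8, 0, 10.8)$absolute, 0)
  expect_equal(estimate_mcds_bias(5, 5, 0.09, 10.8)$relative_percent, 0)
  expect_error(estimate_mcds_bias(1, 1, 0.1, 0), "> 0")
})
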