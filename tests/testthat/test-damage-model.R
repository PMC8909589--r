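quick_config <- function(..., n_samples = 400, seed = 101) {
  simulation_config(..., n_samples = n_samples, seed = seed)
}

test_that("zero lesion rate yields an all-zero spectrum, not NaN", {
  sp <- simulate_damage_spectrum(quick_config(lesion_rate = 0))
  expect_true(sp$all_zero)
  expect_equal(unname(sp$yields), rep(0, 7))
  expect_equal(unname(sp$percentages), rep(0, 7))
  expect_equal(sp$total_dsb, 0)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  a <- simulate_damage_spectrum(quick_config())
  b <- simulate_damage_spectrum(quick_config())
  expect_identical(a$yields, b$yields)
  expect_identical(a$dsb_multiplicity, b$dsb_multiplicity)
  c <- simulate_damage_spectrum(simulation_config(n_samples = 400, seed = 102))
  expect_false(identical(a$yields, c$yields))
})

test_that("class percentages sum to 100 and totals match their components", {
  sp <- simulate_damage_spectrum(quick_config())
  expect_equal(sum(sp$percentages), 100, tolerance = 1e-10)
  expect_equal(sp$total_ssb, sum(sp$yields[c("SSB", "SSB+", "2SSB")]))
  expect_equal(sp$total_dsb, sum(sp$yields[c("DSB", "DSB+", "DSB++")]))
  expect_true(all(sp$yields >= 0))
  expect_true(all(sp$dsb_multiplicity$i >= 2))
})

test_that("doubling the lesion rate increases the DSB share of damage", {
  lo <- simulate_damage_spectrum(quick_config(lesion_rate = 600,
                                              n_samples = 600))
  hi <- simulate_damage_spectrum(quick_config(lesion_rate = 1200,
                                              n_samples = 600))
  frac <- function(sp) sp$total_dsb / sum(sp$yields)
  expect_gt(frac(hi), frac(lo))
})

test_that("yield SEM scales as one over the square root of n_samples", {
  s1 <- simulate_damage_spectrum(simulation_config(n_samples = 250,
                                                   seed = 7))
  s4 <- simulate_damage_spectrum(simulation_config(n_samples = 1000,
                                                   seed = 8))
  ratio <- s1$total_ssb_sem / s4$total_ssb_sem
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("oxygen modifier has the right limits and monotone shape", {
  expect_equal(oxygen_modifier(oxygen_model(21)), 1, tolerance = 1e-6)
  expect_equal(oxygen_modifier(oxygen_model(0)),
               oxygen_model(0)$plateau_fraction)
  m <- vapply(c(0.1, 2, 21), function(x) oxygen_modifier(oxygen_model(x)),
              numeric(1))
  expect_true(all(diff(m) > 0))
  expect_error(oxygen_model(-1), "o2_percent")
  # non-decreasing over a fine grid
  grid <- vapply(seq(0, 30, by = 0.5),
                 function(x) oxygen_modifier(oxygen_model(x)), numeric(1))
  expect_true(all(diff(grid) >= 0))
})

test_that("calibrated oxygen model matches the packaged SSB suppression", {
  mdl <- calibrate_oxygen_model()
  m <- function(x) oxygen_modifier(oxygen_model(x, mdl$plateau_fraction,
                                                mdl$k_half, mdl$hill))
  # per-quality aerobic-to-hypoxic total-SSB ratios span ~0.91-0.93 (2% O2)
  # and ~0.67-0.69 (0.1% O2); the fitted curve must sit inside those bands
  expect_gt(m(2), 0.90)
  expect_lt(m(2), 0.94)
  expect_gt(m(0.1), 0.66)
  expect_lt(m(0.1), 0.70)
})

test_that("total DSB yield drops monotonically with decreasing oxygen", {
  sims <- lapply(c(21, 2, 0.1), function(o2) {
    simulate_damage_spectrum(simulation_config(
      oxygen = oxygen_model(o2), n_samples = 500, seed = 31))
  })
  dsb <- vapply(sims, function(s) s$total_dsb, numeric(1))
  expect_true(all(diff(dsb) < 0))
  ssb <- vapply(sims, function(s) s$total_ssb, numeric(1))
  expect_true(all(diff(ssb) < 0))
})

test_that("calibration is a no-op with no free parameters and recovers a
           known configuration otherwise", {
  cfg0 <- simulation_config(lesion_rate = 700, segment_length_bp = 15000,
                            seed = 42, n_samples = 3000)
  expect_identical(calibrate_lesion_rates(get_spectrum("Co-60"), cfg0,
                                          free_params = character(0)),
                   cfg0)
  target <- simulate_damage_spectrum(cfg0)
  fit <- calibrate_lesion_rates(target, simulation_config(seed = 42),
                                n_samples = 400, maxit = 30)
  fit$n_samples <- 1500L
  fit$seed <- 4242L
  sp <- simulate_damage_spectrum(fit)
  expect_lt(abs(sp$total_ssb - target$total_ssb) / target$total_ssb, 0.05)
  expect_lt(abs(sp$total_dsb - target$total_dsb) / target$total_dsb, 0.05)
})

test_that("calibration refuses degenerate targets", {
  sp <- simulate_damage_spectrum(quick_config(lesion_rate = 0))
  expect_error(calibrate_lesion_rates(sp), "positive")
})
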