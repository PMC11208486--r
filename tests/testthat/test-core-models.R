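# Model-equation evaluation: closed-form values, limits, identities.

test_that("unfolding signal hits the baseline midpoint at c_U50", {
  # with flat baselines the midpoint is (alpha_F + alpha_U)/2
  p <- unfolding_params(0.8, 0, 1.0, 0, 2000, 15, 30)
  expect_equal(eval_unfolding_signal(p, 15), 0.9)

  # sloped baselines: hand arithmetic (0.82 + 1.04)/2
  p2 <- unfolding_params(0.8, 0.001, 1.0, 0.002, 1000, 20, 35)
  expect_equal(eval_unfolding_signal(p2, 20), 0.93)
})

test_that("unfolding signal approaches the pure baselines in the tails", {
  p <- unfolding_params(0.8, 0.001, 1.0, 0.002, 2500, 25, 35)
  cc_hi <- 90
  expect_equal(eval_unfolding_signal(p, cc_hi),
               p$alpha_U + p$beta_U * cc_hi, tolerance = 1e-9)
  f <- eval_fraction_unfolded(p, c(0, 90))
  expect_lt(f[1], 1e-6)
  expect_gt(f[2], 1 - 1e-6)
  expect_equal(eval_unfolding_signal(p, 0), p$alpha_F, tolerance = 1e-7)
})

test_that("unfolded fraction follows the logistic closed form", {
  p <- unfolding_params(0.8, 0, 1.0, 0, 1000, 10, 25)
  expect_equal(eval_fraction_unfolded(p, 10), 0.5)
  # choose the concentration where the exponent equals ln 3
  RT <- 8.314 * (25 + 273.15)
  c_ln3 <- 10 + log(3) * RT / 1000
  expect_equal(eval_fraction_unfolded(p, c_ln3), 0.75, tolerance = 1e-12)
  # degenerate flat model
  p0 <- unfolding_params(0.8, 0, 1.0, 0, 0, 10, 25)
  expect_equal(eval_fraction_unfolded(p0, c(0, 10, 50)), rep(0.5, 3))
})

test_that("unfolded fraction is monotone nondecreasing for m_folding > 0", {
  set.seed(11)
  grid <- seq(0, 60, by = 0.5)
  for (i in 1:20) {
    p <- unfolding_params(runif(1, 0.5, 1), runif(1, 0, 3e-3),
                          runif(1, 0.5, 1.5), runif(1, 0, 3e-3),
                          runif(1, 200, 5000), runif(1, 5, 50),
                          runif(1, 20, 60))
    expect_true(all(diff(eval_fraction_unfolded(p, grid)) >= 0))
  }
})

test_that("signal equals the mixture identity and matches the raw formula", {
  set.seed(12)
  grid <- seq(0, 45, by = 1.5)
  for (i in 1:10) {
    p <- unfolding_params(runif(1, 0.5, 1), runif(1, 0, 3e-3),
                          runif(1, 0.5, 1.5), runif(1, 0, 3e-3),
                          runif(1, 500, 3000), runif(1, 10, 35),
                          runif(1, 20, 60))
    f <- eval_fraction_unfolded(p, grid)
    mix <- (1 - f) * (p$alpha_F + p$beta_F * grid) +
      f * (p$alpha_U + p$beta_U * grid)
    expect_equal(eval_unfolding_signal(p, grid), mix, tolerance = 1e-12)
    expect_equal(eval_unfolding_signal(p, grid),
                 raw_unfolding_signal(p, grid), tolerance = 1e-10)
  }
})

test_that("evaluations stay finite for huge exponent arguments", {
  # m/(RT) * c up to ~1e4: raw exp() would overflow
  p <- unfolding_params(0.8, 0.001, 1.0, 0.002, 3e5, 10, 25)
  v <- eval_unfolding_signal(p, c(0, 10, 100))
  expect_true(all(is.finite(v)))
  expect_true(all(is.finite(eval_fraction_unfolded(p, c(0, 100)))))
  a <- activity_params(100, 50, 10, 5, 10, 3e5, 25)
  expect_true(all(is.finite(eval_activity(a, c(0, 10, 100)))))
})

test_that("activity model: logistic midpoint, Gaussian peak, and limits", {
  # xi = 0: pure decaying logistic, value nu/2 at c_A50
  a <- activity_params(0, 80, 10, 0, 18, 1500, 35)
  expect_equal(eval_activity(a, 18), 40)
  # limits: ~nu at c = 0 (c_A50 far away), ~0 far beyond c_A50
  expect_equal(eval_activity(a, 0), 80, tolerance = 1e-4)
  expect_lt(eval_activity(a, 100), 1e-6)
  # nu = 0: Gaussian peak xi/(sigma sqrt(2 pi))
  b <- activity_params(500, 0, 10, 12, 20, 1500, 35)
  expect_equal(eval_activity(b, 12), 500 / (10 * sqrt(2 * pi)),
               tolerance = 1e-12)
})

test_that("activity with xi = 0 is monotone nonincreasing for m > 0", {
  set.seed(13)
  grid <- seq(0, 60, by = 0.5)
  for (i in 1:10) {
    a <- activity_params(0, runif(1, 10, 200), runif(1, 10, 40),
                         runif(1, 0, 30), runif(1, 5, 40),
                         runif(1, 200, 4000), runif(1, 20, 50))
    expect_true(all(diff(eval_activity(a, grid)) <= 1e-12))
  }
})

test_that("free energy of folding is linear and zero at c_U50", {
  p <- unfolding_params(0.8, 0, 1.0, 0, 1000, 20, 25)
  expect_equal(free_energy_of_folding(p, 20), 0)
  expect_equal(free_energy_of_folding(p, 10), 10000)
  expect_lt(free_energy_of_folding(p, 30), 0)  # unfolded favoured above c_U50
  p0 <- unfolding_params(0.8, 0, 1.0, 0, 0, 20, 25)
  expect_equal(free_energy_of_folding(p0, c(0, 20, 80)), rep(0, 3))
})

test_that("parameter validation rejects out-of-bound and non-finite values", {
  expect_error(unfolding_params(-0.1, 0, 1, 0, 1000, 20, 25), ">= 0")
  expect_error(unfolding_params(0.8, 0, 1, 0, 1000, 120, 25), "<= 100")
  expect_error(unfolding_params(NaN, 0, 1, 0, 1000, 20, 25), "finite")
  expect_error(activity_params(10, 10, 5, 10, 10, 1000, 25), ">= 10")
  expect_error(activity_params(10, 10, 10, 110, 10, 1000, 25), "<= 100")
  p <- unfolding_params(0.8, 0, 1, 0, 1000, 20, 25)
  expect_error(eval_unfolding_signal(p, -1), ">= 0")
})

test_that("parameter sets round-trip through JSON with Celsius temperatures", {
  p <- unfolding_params(0.85, 5e-4, 1.05, 2e-3, 1500, 22.8, 35)
  js <- params_to_json(p)
  expect_match(as.character(js), "\"temperature_C\":35")
  expect_false(grepl("temperature_K", as.character(js)))
  p2 <- params_from_json(js)
  expect_equal(p2, p)

  a <- activity_params(800, 100, 12.1, 7.5, 19.6, 1500, 35)
  a2 <- params_from_json(params_to_json(a))
  expect_equal(a2, a)

  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, path)
  expect_equal(params_from_json(path), p)
})
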