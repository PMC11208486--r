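# Initial-rate extraction, normalization, and the activity-solvent fit.

test_that("initial rate follows the Lambert-Beer conversion chain", {
  # slope -0.001 A/s, eps 6220, l 0.5 cm, 0.01 mg/ml enzyme -> 1.93 U/mg
  tt <- seq(0, 240, by = 2)
  tr <- kinetic_trace("E1", "none", 0, 25, tt, 1 - 0.001 * tt,
                      enzyme_conc = 0.01, path_length = 0.5,
                      extinction_coeff = 6220)
  r <- initial_rate(tr)
  expect_equal(r$specific_activity, 0.001 / (6220 * 0.5) * 60 * 1e6 / 10,
               tolerance = 1e-12)
  expect_equal(r$specific_activity, 1.93, tolerance = 0.005)
  expect_false(r$increasing)
})

test_that("flat and increasing traces are handled", {
  tt <- seq(0, 240, by = 2)
  flat <- kinetic_trace("E1", "none", 0, 25, tt, rep(0.8, length(tt)),
                        0.01, 0.5)
  expect_equal(initial_rate(flat)$specific_activity, 0)
  up <- kinetic_trace("E1", "none", 0, 25, tt, 0.5 + 0.0005 * tt, 0.01, 0.5)
  r <- initial_rate(up)
  expect_true(r$increasing)
  expect_gt(r$specific_activity, 0)
})

test_that("exactly linear synthetic traces round-trip the generating rate", {
  set.seed(31)
  for (i in 1:5) {
    rate <- runif(1, 0.1, 20)
    tr <- generate_kinetic_trace(rate, enzyme_conc = runif(1, 0.005, 0.03))
    expect_equal(initial_rate(tr)$specific_activity, rate,
                 tolerance = 1e-9)
  }
})

test_that("rate scales linearly in slope and inversely in eps, l and enzyme", {
  base <- list(slope = 0.001, eps = 6220, l = 0.5, conc = 0.01)
  rate_of <- function(slope, eps, l, conc) {
    tt <- seq(0, 200, by = 2)
    tr <- kinetic_trace("E", "none", 0, 25, tt, 1 - slope * tt, conc, l, eps)
    initial_rate(tr)$specific_activity
  }
  r0 <- rate_of(base$slope, base$eps, base$l, base$conc)
  expect_equal(rate_of(2 * base$slope, base$eps, base$l, base$conc), 2 * r0,
               tolerance = 1e-9)
  expect_equal(rate_of(base$slope, 2 * base$eps, base$l, base$conc), r0 / 2,
               tolerance = 1e-9)
  expect_equal(rate_of(base$slope, base$eps, 2 * base$l, base$conc), r0 / 2,
               tolerance = 1e-9)
  expect_equal(rate_of(base$slope, base$eps, base$l, 2 * base$conc), r0 / 2,
               tolerance = 1e-9)
})

test_that("window selection excludes a curved late-time tail", {
  tr <- generate_kinetic_trace(5, enzyme_conc = 0.02, curvature = 1e-3,
                               curve_onset_frac = 0.5)
  r <- initial_rate(tr)
  expect_lte(r$window[["end_s"]], 150)   # curved tail excluded
  # R^2 >= 0.99 tolerates grazing the bend onset: ~few-percent slope bias
  expect_equal(r$specific_activity, 5, tolerance = 0.05)
  # a stricter linearity threshold pins the window to the linear phase
  strict <- initial_rate(tr, r_squared_min = 0.9999)
  expect_lte(strict$window[["end_s"]], 130)
  expect_equal(strict$specific_activity, 5, tolerance = 0.005)
})

test_that("relative activity normalizes to 100% and propagates SEM", {
  pts <- activity_points(c(0, 10), c(10, 12), sem = c(0.5, 1),
                         n_replicates = c(3, 3), temperature_C = 25)
  rel <- relative_activity(pts)
  ref <- which(rel$c_solv == 0)
  expect_equal(rel$rel_activity[ref], 100)
  i <- which(rel$c_solv == 10)
  expect_equal(rel$rel_activity[i], 120)
  expect_equal(rel$rel_sem[i], 120 * sqrt((1 / 12)^2 + (0.5 / 10)^2),
               tolerance = 1e-12)

  # zero SEMs propagate to zero
  pts0 <- activity_points(c(0, 10), c(10, 12), sem = c(0, 0),
                          temperature_C = 25)
  expect_equal(relative_activity(pts0)$rel_sem, c(0, 0))

  bad <- activity_points(c(0, 10), c(0, 12), temperature_C = 25)
  expect_error(relative_activity(bad), "must be > 0")
})

test_that("noise-free activity profiles return the generating midpoints", {
  # boosted profile
  truth <- activity_params(800, 100, 10, 7.5, 19.6, 1500, 35)
  pr <- generate_activity_profile(truth, default_grid)
  fit <- fit_activity_model(pr, options = fit_options(regularize = FALSE))
  expect_true(fit$converged)
  expect_equal(fit$params$c_A50, 19.6, tolerance = 0.2)
  expect_equal(fit$params$c_A_max, 7.5, tolerance = 0.2)

  # random draws: c_A50 and c_A_max within 1% relative
  set.seed(32)
  for (i in 1:4) {
    t2 <- activity_params(runif(1, 300, 1200), runif(1, 40, 150),
                          runif(1, 10, 15), runif(1, 5, 14),
                          runif(1, 15, 30), runif(1, 1000, 2500), 35)
    f2 <- fit_activity_model(generate_activity_profile(t2, default_grid),
                             options = fit_options(regularize = FALSE))
    expect_lt(abs(f2$params$c_A50 - t2$c_A50) / t2$c_A50, 0.01)
    expect_lt(abs(f2$params$c_A_max - t2$c_A_max) / t2$c_A_max, 0.01)
  }
})

test_that("without a generated boost the fitted Gaussian term stays negligible", {
  truth <- activity_params(0, 100, 12.1, 0, 14.9, 1500, 35)
  pr <- generate_activity_profile(truth, default_grid)
  fit <- fit_activity_model(pr, options = fit_options(regularize = FALSE))
  gauss_peak <- fit$params$xi / (fit$params$sigma * sqrt(2 * pi))
  expect_lt(gauss_peak, 0.02 * max(pr$specific_activity))
  expect_equal(fit$params$c_A50, 14.9, tolerance = 0.2)
})

test_that("regularization never lowers the achievable cost and barely moves c_A50", {
  truth <- activity_params(800, 100, 10, 7.5, 19.6, 1500, 35)
  pr <- generate_activity_profile(truth, default_grid)
  f_off <- fit_activity_model(pr, options = fit_options(regularize = FALSE))
  f_on <- fit_activity_model(pr, options = fit_options(regularize = TRUE))
  expect_lte(f_off$cost, f_on$cost)
  expect_lt(abs(f_on$params$c_A50 - f_off$params$c_A50), 0.5)
})

test_that("activity fit requires at least 6 points", {
  truth <- activity_params(0, 100, 12, 0, 15, 1500, 35)
  pr <- generate_activity_profile(truth, c(0, 10, 20, 30, 40))
  expect_error(fit_activity_model(pr), "at least 6")
})
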