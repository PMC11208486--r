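# Melting-temperature extraction, isothermal slicing, and the extended
# two-state unfolding fit.

test_that("inflection-point extractor recovers a known melt midpoint", {
  ramp <- generate_thermal_ramp(tm_C = 49.0)
  tm <- extract_tm(ramp)
  expect_equal(tm$tm_C, 49.0, tolerance = 0.25)
  expect_identical(tm$boundary, "none")
})

test_that("strictly linear signal gives no transition", {
  ramp <- generate_thermal_ramp(tm_C = 50, baseline_folded = c(0.5, 0.004),
                                baseline_unfolded = c(0.5, 0.004))
  expect_error(extract_tm(ramp), "no transition")
})

test_that("midpoint beyond the ramp end is boundary-flagged", {
  ramp <- generate_thermal_ramp(tm_C = 95)
  tm <- extract_tm(ramp)
  expect_identical(tm$boundary, "upper")
  expect_equal(tm$tm_C, 90)
  expect_match(tm$label, "^> 90")
})

test_that("Tm extraction is invariant to signal sign flip", {
  up <- generate_thermal_ramp(tm_C = 55.3)
  down <- generate_thermal_ramp(tm_C = 55.3, baseline_folded = c(1.05, 0),
                                baseline_unfolded = c(0.85, 0))
  expect_equal(extract_tm(up)$tm_C, extract_tm(down)$tm_C,
               tolerance = 1e-9)
})

test_that("isothermal slicing interpolates linearly and sorts by concentration", {
  concs <- c(20, 0, 10, 30, 5, 15, 25)
  tt <- seq(33.2, 36.8, by = 0.4)   # 35 degC lies between 34.8 and 35.2
  ramps <- lapply(concs, function(cs) {
    thermal_ramp("E1", "ethanol", cs, "ratio_350_330", tt,
                 0.9 + (tt - 34.8) * 0.05 + cs / 1000)
  })
  sl <- build_isothermal_slice(ramps, 35)
  expect_s3_class(sl, "isothermal_slice")
  expect_equal(sl$c_solv, sort(concs))
  # linear interpolation between 0.90 and 0.92 (plus the conc offset)
  expect_equal(sl$signal, 0.91 + sort(concs) / 1000, tolerance = 1e-12)
})

test_that("slicing rejects mixed conditions, duplicates and out-of-range temperatures", {
  tt <- seq(20, 90, by = 1)
  mk <- function(enz, cs) thermal_ramp(enz, "ethanol", cs, "ratio_350_330",
                                       tt, rep(1, length(tt)) + tt * 0)
  expect_error(build_isothermal_slice(list(mk("A", 0), mk("B", 5)), 35),
               "share enzyme")
  expect_error(build_isothermal_slice(list(mk("A", 5), mk("A", 5)), 35),
               "duplicate")
  expect_error(build_isothermal_slice(list(mk("A", 0), mk("A", 5)), 95),
               "outside ramp range")
})

test_that("noise-free slices return the generating c_U50 and m_folding", {
  truth <- nuisance_unfolding(22.8, 35)
  sl <- generate_isothermal_slice(truth, default_grid)
  fit <- fit_unfolding(sl)
  expect_true(fit$converged)
  expect_true(fit$analyzable)
  expect_equal(fit$params$c_U50, 22.8, tolerance = 0.1)
  expect_equal(fit$params$m_folding, 1500, tolerance = 1500 * 0.02)
})

test_that("all six parameters are recovered from random noise-free draws", {
  set.seed(21)
  for (i in 1:5) {
    aF <- runif(1, 0.7, 0.9); bF <- runif(1, 2e-4, 1e-3)
    aU <- aF + runif(1, 0.15, 0.3); bU <- runif(1, 1e-3, 3e-3)
    m <- runif(1, 1000, 3000); c50 <- runif(1, 12, 33)
    truth <- unfolding_params(aF, bF, aU, bU, m, c50, 35)
    fit <- fit_unfolding(generate_isothermal_slice(truth, default_grid))
    got <- unlist(fit$params[c("alpha_F", "beta_F", "alpha_U", "beta_U",
                               "m_folding", "c_U50")])
    want <- unlist(truth[c("alpha_F", "beta_F", "alpha_U", "beta_U",
                           "m_folding", "c_U50")])
    expect_lt(max(abs(got - want) / want), 0.01)
    expect_lt(abs(fit$params$c_U50 - c50), 0.1)
  }
})

test_that("median c_U50 error stays below 0.5 under 0.5%-amplitude noise", {
  truth <- nuisance_unfolding(20, 35)
  errs <- vapply(1:100, function(s) {
    sl <- generate_isothermal_slice(
      truth, default_grid,
      noise_spec(sd = 0.005, fraction_of_amplitude = TRUE, seed = s))
    abs(fit_unfolding(sl)$params$c_U50 - 20)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("flat signal is flagged not analyzable", {
  flat <- unfolding_params(0.9, 1e-3, 0.9, 1e-3, 1500, 20, 35)
  sl <- generate_isothermal_slice(flat, default_grid)
  fit <- fit_unfolding(sl)
  expect_false(fit$analyzable)
})

test_that("fitting is invariant to uniform signal scaling", {
  truth <- nuisance_unfolding(24, 30)
  sl <- generate_isothermal_slice(truth, default_grid)
  sl_scaled <- isothermal_slice(sl$enzyme, sl$solvent, sl$temperature_C,
                                sl$c_solv, sl$signal * 7.3)
  f1 <- fit_unfolding(sl)
  f2 <- fit_unfolding(sl_scaled)
  expect_equal(f2$params$c_U50, f1$params$c_U50, tolerance = 1e-3)
})

test_that("fitting requires at least 6 points", {
  truth <- nuisance_unfolding(20, 35)
  sl <- generate_isothermal_slice(truth, c(0, 10, 20, 30, 40))
  expect_error(fit_unfolding(sl), "at least 6")
})

test_that("c_U50-versus-temperature table is sorted and validated", {
  # published-style triple: DMF at 25/30/35 degC with c_U50 23/15/13
  cu <- c("35" = 13, "25" = 23, "30" = 15)
  fits <- lapply(names(cu), function(tC) {
    truth <- nuisance_unfolding(cu[[tC]], as.numeric(tC))
    fit_unfolding(generate_isothermal_slice(
      truth, default_grid, enzyme = "ChrOYE1", solvent = "DMF"))
  })
  tab <- cu50_vs_temperature(fits)
  expect_equal(tab$temperature_C, c(25, 30, 35))
  expect_equal(tab$c_U50, c(23, 15, 13), tolerance = 0.1)

  one <- cu50_vs_temperature(fits[1])
  expect_equal(nrow(one), 1L)
  expect_error(cu50_vs_temperature(list()), "non-empty")
})
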