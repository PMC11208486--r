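# Seeded synthetic-data generators with the models' statistical structure.
# Every generator is a pure function of (parameters, seed): the same call
# reproduces the same dataset bit for bit, and the generating truth travels
# with the object (attribute "true_params") so fitters can be tested against
# a known oracle.

#' Gaussian measurement-noise specification
#'
#' @param sd noise standard deviation; interpreted as absolute signal units
#'   unless `fraction_of_amplitude = TRUE`, in which case it is a fraction
#'   of the generating model's transition amplitude.
#' @param fraction_of_amplitude logical (default `FALSE`).
#' @param seed integer RNG seed, or `NULL` for noise-free/unseeded draws.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0, fraction_of_amplitude = FALSE, seed = NULL) {
  check_nonneg(sd, "sd")
  structure(list(kind = "gaussian", sd = sd,
                 fraction_of_amplitude = isTRUE(fraction_of_amplitude),
                 seed = seed),
            class = "noise_spec")
}

resolve_sd <- function(noise, amplitude) {
  if (noise$fraction_of_amplitude) noise$sd * abs(amplitude) else noise$sd
}

#' Simulate an isothermal unfolding slice
#'
#' Draws signal values from the extended two-state unfolding model on a
#' concentration grid and adds Gaussian noise. With `sd = 0` the points
#' lie exactly on the model curve. The transition amplitude used for
#' fraction-of-amplitude noise is the folded/unfolded baseline separation
#' at the midpoint, `|(alpha_U + beta_U c_U50) - (alpha_F + beta_F c_U50)|`.
#'
#' @param params an [unfolding_params()] generating truth.
#' @param c_grid concentration grid, percent (v/v); default 0-45 in 2.5
#'   steps (the experimental design of co-solvent activity screens).
#' @param noise a [noise_spec()].
#' @param enzyme,solvent labels for the simulated condition.
#' @return an [isothermal_slice()] with the truth in
#'   `attr(, "true_params")`.
#' @export
generate_isothermal_slice <- function(params, c_grid = seq(0, 45, by = 2.5),
                                      noise = noise_spec(),
                                      enzyme = "synthetic",
                                      solvent = "synthetic") {
  stopifnot(inherits(params, "unfolding_params"),
            inherits(noise, "noise_spec"))
  mu <- eval_unfolding_signal(params, c_grid)
  amp <- (params$alpha_U + params$beta_U * params$c_U50) -
    (params$alpha_F + params$beta_F * params$c_U50)
  sd_abs <- resolve_sd(noise, amp)
  sig <- if (sd_abs > 0) {
    with_seed(noise$seed, mu + rnorm(length(mu), sd = sd_abs))
  } else mu
  out <- isothermal_slice(enzyme, solvent, params$temperature_C,
                          c_grid, sig)
  attr(out, "true_params") <- params
  out
}

#' Simulate an activity profile
#'
#' Draws `n_replicates` activity measurements per concentration from the
#' activity-solvent model with Gaussian noise, and summarises each cell as
#' mean and standard error of the mean - the same aggregation applied to
#' experimental triplicates. For fraction-of-amplitude noise the amplitude
#' is the model's maximal activity over the grid.
#'
#' @param params an [activity_params()] generating truth.
#' @param c_grid concentration grid, percent (v/v).
#' @param noise a [noise_spec()].
#' @param n_replicates replicate draws per concentration (default 3).
#' @return an [activity_points()] data frame with the truth in
#'   `attr(, "true_params")`.
#' @export
generate_activity_profile <- function(params, c_grid = seq(0, 45, by = 2.5),
                                      noise = noise_spec(),
                                      n_replicates = 3L) {
  stopifnot(inherits(params, "activity_params"),
            inherits(noise, "noise_spec"), n_replicates >= 1L)
  mu <- eval_activity(params, c_grid)
  sd_abs <- resolve_sd(noise, max(mu))
  if (sd_abs > 0) {
    draws <- with_seed(noise$seed,
                       matrix(rnorm(length(mu) * n_replicates, mean = mu,
                                    sd = sd_abs),
                              nrow = length(mu)))
    draws[draws < 0] <- 0   # activities cannot be negative
    means <- rowMeans(draws)
    sems <- if (n_replicates >= 2L) {
      apply(draws, 1L, sd) / sqrt(n_replicates)
    } else rep(NA_real_, length(mu))
  } else {
    means <- mu
    sems <- rep(0, length(mu))
  }
  out <- activity_points(c_grid, means, sems,
                         rep(n_replicates, length(c_grid)),
                         temperature_C = params$temperature_C)
  attr(out, "true_params") <- params
  out
}

#' Simulate a thermal-ramp melt curve
#'
#' Generates a logistic-in-temperature melt curve with linear folded and
#' unfolded baselines on a uniform temperature grid (emulating a constant
#' heating rate). Midpoints outside the recorded range are deliberately
#' representable, to exercise boundary flagging in [extract_tm()]: `tm_C`
#' may lie anywhere in 20-120 degC. Setting `amplitude = 0` produces a
#' baseline-only curve with no transition.
#'
#' @param tm_C transition midpoint (degrees Celsius), in \[20, 120\].
#' @param transition_width_C logistic scale parameter of the transition
#'   (degrees Celsius, default 2).
#' @param t_range recorded temperature range (default `c(20, 90)`, the
#'   standard nanoDSF ramp).
#' @param step_C sampling step (default 0.5 degC).
#' @param baseline_folded,baseline_unfolded `c(intercept, slope)` of the
#'   two baselines in signal units (per degC for the slope).
#' @param noise a [noise_spec()] (absolute sd).
#' @param enzyme,solvent,c_solv,channel condition metadata.
#' @return a [thermal_ramp()] with `attr(, "true_tm")`.
#' @export
generate_thermal_ramp <- function(tm_C, transition_width_C = 2,
                                  t_range = c(20, 90), step_C = 0.5,
                                  baseline_folded = c(0.85, 0),
                                  baseline_unfolded = c(1.05, 0),
                                  noise = noise_spec(),
                                  enzyme = "synthetic",
                                  solvent = "none", c_solv = 0,
                                  channel = "ratio_350_330") {
  check_scalar(tm_C, "tm_C")
  if (tm_C < 20 || tm_C > 120)
    stop("'tm_C' must be in [20, 120] degC", call. = FALSE)
  check_scalar(transition_width_C, "transition_width_C")
  stopifnot(transition_width_C > 0, inherits(noise, "noise_spec"))
  tt <- seq(t_range[1L], t_range[2L], by = step_C)
  f <- plogis((tt - tm_C) / transition_width_C)
  mu <- (1 - f) * (baseline_folded[1L] + baseline_folded[2L] * tt) +
    f * (baseline_unfolded[1L] + baseline_unfolded[2L] * tt)
  amp <- (baseline_unfolded[1L] + baseline_unfolded[2L] * tm_C) -
    (baseline_folded[1L] + baseline_folded[2L] * tm_C)
  sd_abs <- resolve_sd(noise, amp)
  sig <- if (sd_abs > 0) {
    with_seed(noise$seed, mu + rnorm(length(mu), sd = sd_abs))
  } else mu
  out <- thermal_ramp(enzyme, solvent, c_solv, channel, tt, sig)
  attr(out, "true_tm") <- tm_C
  out
}

#' Simulate an NAD(P)H depletion kinetic trace
#'
#' Inverts the Lambert-Beer chain used by [initial_rate()]: a specific
#' activity (umol min^-1 mg^-1) becomes a molar consumption rate and an
#' absorbance slope, and the trace is linear in time apart from optional
#' late-time curvature (emulating substrate depletion) that the
#' linear-range selection must exclude.
#'
#' @param rate true specific initial activity (umol min^-1 mg^-1).
#' @param enzyme_conc enzyme concentration (mg ml^-1).
#' @param extinction_coeff molar extinction coefficient (M^-1 cm^-1,
#'   default 6220).
#' @param path_length optical path (cm, default 0.56).
#' @param duration_s trace duration (default 240 s).
#' @param step_s sampling interval (default 2 s).
#' @param a0 starting absorbance (default 1.0).
#' @param curvature quadratic bend (A s^-2) applied after
#'   `curve_onset_frac` of the trace; 0 keeps the trace exactly linear.
#' @param curve_onset_frac onset of the curvature as a fraction of the
#'   duration (default 0.6).
#' @param noise a [noise_spec()] (absolute sd in absorbance units).
#' @param enzyme,solvent,c_solv,temperature_C condition metadata.
#' @return a [kinetic_trace()] with `attr(, "true_rate")`.
#' @export
generate_kinetic_trace <- function(rate, enzyme_conc,
                                   extinction_coeff = 6220,
                                   path_length = 0.56,
                                   duration_s = 240, step_s = 2,
                                   a0 = 1.0, curvature = 0,
                                   curve_onset_frac = 0.6,
                                   noise = noise_spec(),
                                   enzyme = "synthetic",
                                   solvent = "none", c_solv = 0,
                                   temperature_C = 25) {
  check_nonneg(rate, "rate")
  stopifnot(inherits(noise, "noise_spec"))
  tt <- seq(0, duration_s, by = step_s)
  rate_molar <- rate * (enzyme_conc * 1000) / (60 * 1e6)   # mol L^-1 s^-1
  slope <- -rate_molar * extinction_coeff * path_length    # A s^-1
  mu <- a0 + slope * tt
  if (curvature != 0) {
    onset <- curve_onset_frac * duration_s
    mu <- mu + curvature * pmax(0, tt - onset)^2
  }
  sig <- if (noise$sd > 0) {
    with_seed(noise$seed, mu + rnorm(length(mu), sd = noise$sd))
  } else mu
  out <- kinetic_trace(enzyme, solvent, c_solv, temperature_C, tt, sig,
                       enzyme_conc, path_length, extinction_coeff)
  attr(out, "true_rate") <- rate
  out
}

#' Scenario specification for end-to-end simulation
#'
#' Describes a full simulated study of one enzyme/solvent pair: unfolding
#' and activity truths over a temperature grid, with the half-unfolding
#' concentration decreasing linearly in temperature (the behaviour
#' consistently observed experimentally: the hotter the sample, the less
#' co-solvent is needed to unfold it) and the activity-loss midpoint
#' tracking it.
#'
#' @param enzyme,solvent labels.
#' @param temperatures temperature grid (degC).
#' @param c_grid concentration grid, percent (v/v).
#' @param cu50_at_first `c_U50` at the first (lowest) temperature.
#' @param cu50_slope change of `c_U50` per degC (default -0.8).
#' @param m_folding shared proportionality constant (J mol^-1 per percent,
#'   default 1500).
#' @param baselines list with `alpha_F`, `beta_F`, `alpha_U`, `beta_U`.
#' @param activity list with `xi`, `nu`, `sigma`, `c_A_max_offset` and
#'   `c_A50_offset` (offsets relative to the temperature's `c_U50`).
#' @param noise_unfolding,noise_activity [noise_spec()]s.
#' @param n_replicates activity replicates per cell.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(enzyme = "ENZ1", solvent = "ethanol",
                          temperatures = c(25, 30, 35, 40, 45),
                          c_grid = seq(0, 45, by = 2.5),
                          cu50_at_first = 30, cu50_slope = -0.8,
                          m_folding = 1500,
                          baselines = list(alpha_F = 0.85, beta_F = 5e-4,
                                           alpha_U = 1.05, beta_U = 2e-3),
                          activity = list(xi = 800, nu = 100, sigma = 12,
                                          c_A_max_offset = -14,
                                          c_A50_offset = -2),
                          noise_unfolding = noise_spec(),
                          noise_activity = noise_spec(),
                          n_replicates = 3L) {
  stopifnot(length(temperatures) >= 1L, length(c_grid) >= 6L,
            n_replicates >= 1L)
  structure(list(enzyme = enzyme, solvent = solvent,
                 temperatures = sort(temperatures), c_grid = c_grid,
                 cu50_at_first = cu50_at_first, cu50_slope = cu50_slope,
                 m_folding = m_folding, baselines = baselines,
                 activity = activity,
                 noise_unfolding = noise_unfolding,
                 noise_activity = noise_activity,
                 n_replicates = as.integer(n_replicates)),
            class = "scenario_spec")
}

#' Generate all datasets of a scenario
#'
#' Expands a [scenario_spec()] into one isothermal slice and one activity
#' profile per temperature, each carrying its generating truth. Per-slice
#' seeds are derived deterministically from `seed` so the whole scenario
#' is reproducible from a single integer.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer master seed, or `NULL` for noise-free specs.
#' @return list with elements `slices` and `profiles` (both named by
#'   temperature) and `truth` (a data frame of per-temperature true
#'   parameters).
#' @export
generate_scenario <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  slices <- list()
  profiles <- list()
  truth <- data.frame()
  for (k in seq_along(spec$temperatures)) {
    tC <- spec$temperatures[k]
    cu50 <- spec$cu50_at_first +
      spec$cu50_slope * (tC - spec$temperatures[1L])
    cu50 <- min(max(cu50, 0), 100)
    up <- unfolding_params(spec$baselines$alpha_F, spec$baselines$beta_F,
                           spec$baselines$alpha_U, spec$baselines$beta_U,
                           spec$m_folding, cu50, tC)
    ca50 <- min(max(cu50 + spec$activity$c_A50_offset, 0), 100)
    camax <- min(max(cu50 + spec$activity$c_A_max_offset, 0), 100)
    ap <- activity_params(spec$activity$xi, spec$activity$nu,
                          spec$activity$sigma, camax, ca50,
                          spec$m_folding, tC)
    nu_spec <- spec$noise_unfolding
    na_spec <- spec$noise_activity
    if (!is.null(seed)) {
      nu_spec$seed <- seed + 2L * k
      na_spec$seed <- seed + 2L * k + 1L
    }
    key <- as.character(tC)
    slices[[key]] <- generate_isothermal_slice(
      up, spec$c_grid, nu_spec, enzyme = spec$enzyme,
      solvent = spec$solvent)
    profiles[[key]] <- generate_activity_profile(
      ap, spec$c_grid, na_spec, n_replicates = spec$n_replicates)
    truth <- rbind(truth, data.frame(
      temperature_C = tC, c_U50 = cu50, c_A50 = ca50, c_A_max = camax,
      m_folding = spec$m_folding))
  }
  list(slices = slices, profiles = profiles, truth = truth)
}
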