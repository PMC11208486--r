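# Specific initial activities from A340 kinetic traces, normalization, and
# the Gaussian-augmented activity-solvent model fit.

#' Specific initial activity from a kinetic trace
#'
#' Finds the linear part of an NAD(P)H depletion curve and converts its
#' slope into a specific initial activity via the Lambert-Beer law. The
#' linear range is selected by a deterministic sliding-window search: among
#' all contiguous windows of at least `min_window_frac` of the trace (and
#' at least 5 points) starting after `dead_time_s`, the longest window with
#' coefficient of determination `R^2 >= r_squared_min` wins; ties are
#' broken by the earliest start.
#'
#' The slope (A s^-1) becomes a molar rate `|slope| / (epsilon l)`
#' (mol L^-1 s^-1) and then a specific activity in umol min^-1 per mg
#' enzyme using the enzyme concentration of the well. A perfectly flat
#' trace is linear with slope zero and yields activity 0. An increasing
#' absorbance (positive slope) is chemically unexpected for a depletion
#' assay; it is flagged via `increasing = TRUE` while the magnitude is
#' still reported.
#'
#' @param trace a [kinetic_trace()].
#' @param r_squared_min linearity criterion (default 0.99).
#' @param min_window_frac minimum window length as a fraction of the trace
#'   (default 0.3).
#' @param dead_time_s observations before this time are ignored
#'   (default 0).
#' @return an object of class `initial_rate`: list with
#'   `specific_activity` (umol min^-1 mg^-1), `slope` (A s^-1),
#'   `r_squared`, `window` (start/end times), `increasing`.
#' @examples
#' tr <- generate_kinetic_trace(rate = 1.5, enzyme_conc = 0.02)
#' initial_rate(tr)$specific_activity
#' @export
initial_rate <- function(trace, r_squared_min = 0.99,
                         min_window_frac = 0.3, dead_time_s = 0) {
  stopifnot(inherits(trace, "kinetic_trace"))
  keep <- trace$times >= dead_time_s
  t <- trace$times[keep]
  y <- trace$a340[keep]
  n <- length(t)
  if (n < 5L)
    stop("fewer than 5 points in the candidate window", call. = FALSE)
  wmin <- max(5L, ceiling(min_window_frac * n))

  # prefix sums for O(1) per-window regression statistics
  Sx <- cumsum(c(0, t)); Sy <- cumsum(c(0, y))
  Sxx <- cumsum(c(0, t^2)); Sxy <- cumsum(c(0, t * y))
  Syy <- cumsum(c(0, y^2))
  win_stats <- function(i, j) {   # window [i, j], 1-based inclusive
    m <- j - i + 1
    sx <- Sx[j + 1] - Sx[i]; sy <- Sy[j + 1] - Sy[i]
    sxx <- Sxx[j + 1] - Sxx[i]; sxy <- Sxy[j + 1] - Sxy[i]
    syy <- Syy[j + 1] - Syy[i]
    vxx <- sxx - sx^2 / m
    vyy <- syy - sy^2 / m
    vxy <- sxy - sx * sy / m
    slope <- vxy / vxx
    r2 <- if (vyy <= .Machine$double.eps * max(1, syy)) 1 else vxy^2 / (vxx * vyy)
    list(slope = slope, r2 = r2)
  }

  found <- NULL
  for (len in seq(n, wmin)) {
    for (start in seq_len(n - len + 1L)) {
      st <- win_stats(start, start + len - 1L)
      if (st$r2 >= r_squared_min) {
        found <- c(st, list(i = start, j = start + len - 1L))
        break
      }
    }
    if (!is.null(found)) break
  }
  if (is.null(found))
    stop("no linear range: no window meets the linearity criterion",
         call. = FALSE)

  rate_molar <- abs(found$slope) /
    (trace$extinction_coeff * trace$path_length)      # mol L^-1 s^-1
  # umol min^-1 per mg enzyme: x60 s/min, x1e6 umol/mol, enzyme in mg L^-1
  specific <- rate_molar * 60 * 1e6 / (trace$enzyme_conc * 1000)
  structure(
    list(specific_activity = specific, slope = found$slope,
         r_squared = found$r2,
         window = c(start_s = t[found$i], end_s = t[found$j]),
         n_window = found$j - found$i + 1L,
         increasing = found$slope > 0),
    class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("Initial rate: %.4g umol/min/mg (slope %.3g A/s, R^2 %.4f, window %g-%g s)%s\n",
              x$specific_activity, x$slope, x$r_squared,
              x$window[["start_s"]], x$window[["end_s"]],
              if (x$increasing) " [absorbance increasing - flagged]" else ""))
  invisible(x)
}

#' Activity points at varied co-solvent concentration
#'
#' Assembles per-condition specific activities into the `data.frame`
#' consumed by [relative_activity()] and [fit_activity_model()].
#'
#' @param c_solv co-solvent concentrations, percent (v/v).
#' @param specific_activity mean specific activities
#'   (umol min^-1 mg^-1), `>= 0`.
#' @param sem standard errors of the mean (same units), `>= 0`; `NA`
#'   allowed for single measurements.
#' @param n_replicates replicate counts, `>= 1`.
#' @param temperature_C common reaction temperature.
#' @return a `data.frame` of class `activity_points`.
#' @export
activity_points <- function(c_solv, specific_activity,
                            sem = rep(0, length(c_solv)),
                            n_replicates = rep(1L, length(c_solv)),
                            temperature_C = NA_real_) {
  stopifnot(is.numeric(c_solv), is.numeric(specific_activity),
            length(specific_activity) == length(c_solv),
            length(sem) == length(c_solv),
            length(n_replicates) == length(c_solv))
  if (any(c_solv < 0)) stop("'c_solv' must be >= 0", call. = FALSE)
  if (any(specific_activity < 0))
    stop("'specific_activity' must be >= 0", call. = FALSE)
  if (any(sem < 0, na.rm = TRUE)) stop("'sem' must be >= 0", call. = FALSE)
  if (any(n_replicates < 1)) stop("'n_replicates' must be >= 1", call. = FALSE)
  out <- data.frame(c_solv = c_solv, temperature_C = temperature_C,
                    specific_activity = specific_activity,
                    sem = sem, n_replicates = as.integer(n_replicates))
  out <- out[order(out$c_solv), , drop = FALSE]
  class(out) <- c("activity_points", "data.frame")
  out
}

#' Relative activity with propagated uncertainty
#'
#' Normalizes a series of specific activities by the measurement without
#' co-solvent (the `c_solv = 0` point), setting it to 100 percent. Values
#' above 100 indicate activity boosted by the co-solvent. Uncertainties are
#' propagated by the Gaussian rule for a ratio:
#' `sem_rel = rel * sqrt((sem/a)^2 + (sem_ref/a_ref)^2)`.
#'
#' @param points an [activity_points()] data frame containing a
#'   `c_solv = 0` row with positive activity.
#' @return the input with added columns `rel_activity` (percent) and
#'   `rel_sem`.
#' @export
relative_activity <- function(points) {
  stopifnot(inherits(points, "activity_points"))
  ref_row <- which(points$c_solv == 0)
  if (length(ref_row) != 1L)
    stop("exactly one reference point at c_solv = 0 is required",
         call. = FALSE)
  a_ref <- points$specific_activity[ref_row]
  s_ref <- points$sem[ref_row]
  if (!is.finite(a_ref) || a_ref <= 0)
    stop("reference activity at c_solv = 0 must be > 0", call. = FALSE)
  a <- points$specific_activity
  s <- points$sem
  rel <- 100 * a / a_ref
  rel_sem <- ifelse(a > 0,
                    rel * sqrt((s / a)^2 + (s_ref / a_ref)^2),
                    100 * s / a_ref)
  points$rel_activity <- rel
  points$rel_sem <- rel_sem
  points
}

#' Fit the activity-solvent model to an activity profile
#'
#' Fits the six parameters of the Gaussian-augmented activity model
#' (`xi`, `nu`, `sigma`, `c_A_max`, `m_folding`, `c_A50`) to specific (or
#' relative) activities at varied co-solvent concentration and fixed
#' temperature. The cost is the residual sum of squares plus an L2 penalty
#' on the raw values of two weakly identified parameters,
#' `lambda_c_a_max * c_A_max^2 + lambda_xi * xi^2` (defaults 0.01 and
#' 0.001), which keeps the Gaussian term from wandering when no boost is
#' present; set `regularize = FALSE` in [fit_options()] for
#' parameter-recovery testing. Bounds: `xi, nu, c_A_max, c_A50 >= 0`,
#' `sigma >= 10`, `c_A_max, c_A50 <= 100`; `m_folding` is unbounded but
#' rescaled by `RT` over the concentration range before optimization.
#'
#' Initialization is deterministic: `c_A50` starts at the
#' `options$start_fracs` fractions of the largest concentration, `c_A_max`
#' at the concentration of maximal observed activity, `nu` at the activity
#' nearest `c = 0`, and `xi` at 0 and at
#' `(peak - baseline) sigma sqrt(2 pi)`; the lowest-cost solution wins.
#'
#' @param points an [activity_points()] data frame (at least 6
#'   concentrations) or a plain data frame with columns `c_solv` and
#'   `specific_activity`.
#' @param temperature_C reaction temperature; defaults to the points'
#'   temperature metadata.
#' @param options a [fit_options()] list.
#' @return an object of class `activity_fit`: list with `params`
#'   ([activity_params()]), `cost` (penalized), `rss`, `converged`,
#'   `n_points`.
#' @examples
#' truth <- activity_params(800, 100, 10, 7.5, 19.6, 1500, 35)
#' pr <- generate_activity_profile(truth, seq(0, 45, 2.5))
#' fit_activity_model(pr, options = fit_options(regularize = FALSE))$params$c_A50
#' @export
fit_activity_model <- function(points, temperature_C = NULL,
                               options = fit_options()) {
  stopifnot(is.data.frame(points), inherits(options, "fit_options"))
  if (is.null(temperature_C)) {
    temperature_C <- unique(points$temperature_C)
    temperature_C <- temperature_C[is.finite(temperature_C)]
    if (length(temperature_C) != 1L)
      stop("supply 'temperature_C' explicitly: points carry none or several",
           call. = FALSE)
  }
  cc <- points$c_solv
  a <- points$specific_activity
  n <- length(cc)
  if (n < 6L)
    stop("at least 6 concentration points are required for fitting",
         call. = FALSE)
  RT <- R_GAS * celsius_to_kelvin(temperature_C)
  crng <- max(cc) - min(cc)
  # only m_folding needs rescaling; the others are already O(1)-O(100)
  scale <- c(1, 1, 1, 1, RT / crng, 1)
  lam_cmax <- if (options$regularize) options$lambda_c_a_max else 0
  lam_xi <- if (options$regularize) options$lambda_xi else 0

  objective <- function(ts) {
    th <- ts * scale   # xi, nu, sigma, c_A_max, m, c_A50
    pred <- th[1L] * dnorm(cc, mean = th[4L], sd = th[3L]) +
      th[2L] * plogis(-th[5L] / RT * (cc - th[6L]))
    sum((pred - a)^2) + lam_cmax * th[4L]^2 + lam_xi * th[1L]^2
  }
  lower <- c(0, 0, 10, 0, -Inf, 0) / scale
  upper <- c(Inf, Inf, Inf, 100, Inf, 100) / scale

  nu0 <- max(a[which.min(cc)], 0)
  cmax0 <- cc[which.max(a)]
  sigma0 <- max(10, crng / 4)
  boost <- max(0, max(a) - nu0)
  xi_starts <- c(0, boost * sigma0 * sqrt(2 * pi))
  m0 <- 10 * RT / crng
  starts <- list()
  for (fr in options$start_fracs)
    for (xi0 in xi_starts)
      starts[[length(starts) + 1L]] <-
        c(xi0, nu0, sigma0, cmax0, m0, fr * max(cc)) / scale

  best <- multi_start_nlminb(starts, objective, lower, upper,
                             options$max_iter)
  if (is.null(best))
    stop("activity fit failed from every start", call. = FALSE)
  th <- best$par * scale
  th[3L] <- max(th[3L], 10)
  th[c(1L, 2L, 4L, 6L)] <- pmax(th[c(1L, 2L, 4L, 6L)], 0)
  th[c(4L, 6L)] <- pmin(th[c(4L, 6L)], 100)
  params <- activity_params(th[1L], th[2L], th[3L], th[4L], th[6L], th[5L],
                            temperature_C)
  rss <- sum((eval_activity(params, cc) - a)^2)
  structure(
    list(params = params, cost = best$objective, rss = rss,
         converged = best$convergence == 0L, n_points = n),
    class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf("Activity-solvent model fit at %.4g degC (%d points)\n",
              x$params$temperature_C, x$n_points))
  cat(sprintf("  c_A50 = %.3f, c_A_max = %.3f, sigma = %.3f %%(v/v); cost = %.4g\n",
              x$params$c_A50, x$params$c_A_max, x$params$sigma, x$cost))
  invisible(x)
}
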