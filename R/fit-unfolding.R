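# Bounded, scaled, multi-start least-squares fit of the extended two-state
# unfolding model to an isothermal slice.

#' Fit options for the unfolding and activity model fitters
#'
#' @param start_fracs fractions of the maximum observed concentration used
#'   as deterministic initial values for the transition midpoint
#'   (`c_U50` / `c_A50` multi-start grid).
#' @param analyzable_frac minimum fitted transition amplitude, as a fraction
#'   of the observed signal range, for an unfolding fit to be flagged
#'   analyzable (default 0.2).
#' @param regularize logical; apply the L2 penalty in the activity fit
#'   (default `TRUE`). Disable for parameter-recovery testing.
#' @param lambda_c_a_max,lambda_xi L2 penalty weights on the raw `c_A_max`
#'   and `xi` values (defaults 0.01 and 0.001).
#' @param max_iter iteration cap per optimizer start.
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(start_fracs = c(0.25, 0.5, 0.75),
                        analyzable_frac = 0.2,
                        regularize = TRUE,
                        lambda_c_a_max = 0.01,
                        lambda_xi = 0.001,
                        max_iter = 500L) {
  stopifnot(is.numeric(start_fracs), length(start_fracs) >= 1L,
            all(start_fracs > 0), all(start_fracs <= 1),
            is.numeric(analyzable_frac), analyzable_frac >= 0,
            is.logical(regularize),
            lambda_c_a_max >= 0, lambda_xi >= 0, max_iter >= 1)
  structure(list(start_fracs = start_fracs,
                 analyzable_frac = analyzable_frac,
                 regularize = isTRUE(regularize),
                 lambda_c_a_max = lambda_c_a_max,
                 lambda_xi = lambda_xi,
                 max_iter = as.integer(max_iter)),
            class = "fit_options")
}

# Run nlminb from a set of scaled starts; return the best (lowest objective,
# ties broken by first start).
multi_start_nlminb <- function(starts, objective, lower, upper, max_iter) {
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      nlminb(start = s, objective = objective, lower = lower, upper = upper,
             control = list(iter.max = max_iter, eval.max = 4L * max_iter)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  best
}

#' Fit the extended two-state unfolding model to an isothermal slice
#'
#' Minimizes the sum of squared residuals between the model signal and the
#' observed slice over the six model parameters (two linear baselines,
#' `m_folding` and `c_U50`) under the bounds: all six parameters `>= 0` and
#' `c_U50 <= 100` percent (v/v). Parameters are rescaled to order one
#' before optimization (intercepts by the observed signal range, slopes by
#' signal range over concentration range, `m_folding` by `RT` over
#' concentration range, `c_U50` by the concentration range) and unscaled on
#' output.
#'
#' Initialization is a deterministic multi-start: `c_U50` starts at the
#' fractions in `options$start_fracs` of the largest observed
#' concentration, baselines are initialized from the first and last two
#' points, and `m_folding` from a logistic-slope heuristic; the solution
#' with the lowest final cost wins, ties broken by the first start.
#'
#' A fit is flagged not analyzable when the fitted transition amplitude at
#' the midpoint, `|(alpha_U + beta_U c_U50) - (alpha_F + beta_F c_U50)|`,
#' is below `options$analyzable_frac` of the observed signal range - the
#' situation where the fluorescence reports too weakly on unfolding for
#' `c_U50` to mean anything. `c_U50` should only be used from fits with
#' `analyzable = TRUE`.
#'
#' @param slice an [isothermal_slice()] with at least 6 points.
#' @param options a [fit_options()] list.
#' @return an object of class `unfolding_fit`: list with `params`
#'   ([unfolding_params()]), `rss`, `converged`, `analyzable`, `n_points`.
#' @examples
#' truth <- unfolding_params(0.85, 5e-4, 1.05, 2e-3, 1500, 22.8, 35)
#' sl <- generate_isothermal_slice(truth, seq(0, 45, 2.5))
#' fit_unfolding(sl)$params$c_U50
#' @export
fit_unfolding <- function(slice, options = fit_options()) {
  stopifnot(inherits(slice, "isothermal_slice"),
            inherits(options, "fit_options"))
  cc <- slice$c_solv
  y <- slice$signal
  n <- length(cc)
  if (n < 6L)
    stop("at least 6 concentration points are required for fitting",
         call. = FALSE)
  RT <- R_GAS * celsius_to_kelvin(slice$temperature_C)
  crng <- max(cc) - min(cc)
  srng_obs <- max(y) - min(y)
  srng <- if (srng_obs > 0) srng_obs else 1
  scale <- c(srng, srng / crng, srng, srng / crng, RT / crng, crng)

  objective <- function(ts) {
    th <- ts * scale
    f <- plogis(th[5L] / RT * (cc - th[6L]))
    pred <- (1 - f) * (th[1L] + th[2L] * cc) + f * (th[3L] + th[4L] * cc)
    sum((pred - y)^2)
  }
  lower <- rep(0, 6L)
  upper <- c(rep(Inf, 5L), 100 / scale[6L])

  b_F <- max(0, (y[2L] - y[1L]) / (cc[2L] - cc[1L]))
  a_F <- max(0, y[1L] - b_F * cc[1L])
  b_U <- max(0, (y[n] - y[n - 1L]) / (cc[n] - cc[n - 1L]))
  a_U <- max(0, y[n] - b_U * cc[n])
  m0 <- 10 * RT / crng
  starts <- lapply(options$start_fracs, function(fr) {
    c(a_F, b_F, a_U, b_U, m0, fr * max(cc)) / scale
  })

  best <- multi_start_nlminb(starts, objective, lower, upper,
                             options$max_iter)
  if (is.null(best))
    stop("unfolding fit failed from every start", call. = FALSE)
  th <- pmin(pmax(best$par * scale, c(rep(0, 6L))), c(rep(Inf, 5L), 100))
  params <- unfolding_params(th[1L], th[2L], th[3L], th[4L], th[5L], th[6L],
                             slice$temperature_C)
  amp <- abs((th[3L] + th[4L] * th[6L]) - (th[1L] + th[2L] * th[6L]))
  converged <- best$convergence == 0L
  analyzable <- converged && srng_obs > 0 &&
    amp >= options$analyzable_frac * srng_obs
  structure(
    list(params = params, residual_sum_squares = best$objective,
         converged = converged, analyzable = analyzable, n_points = n,
         enzyme = slice$enzyme, solvent = slice$solvent),
    class = "unfolding_fit")
}

#' @export
print.unfolding_fit <- function(x, ...) {
  cat(sprintf("Two-state unfolding fit: %s / %s at %.4g degC (%d points)\n",
              x$enzyme, x$solvent, x$params$temperature_C, x$n_points))
  if (x$analyzable) {
    cat(sprintf("  c_U50 = %.3f %%(v/v), m_folding = %.4g J/mol/%%, RSS = %.3g\n",
                x$params$c_U50, x$params$m_folding, x$residual_sum_squares))
  } else {
    cat("  not analyzable: transition amplitude too small; c_U50 not reported\n")
  }
  invisible(x)
}

#' Half-unfolding concentration as a function of temperature
#'
#' Collects `c_U50` from a family of unfolding fits of the same
#' enzyme/solvent pair at different temperatures into a table sorted by
#' temperature. All fits must be converged and analyzable. No monotonicity
#' is enforced: the values are reported as observed, and the table feeds
#' [operating_window()].
#'
#' @param fits non-empty list of `unfolding_fit` objects.
#' @return a `data.frame` with columns `enzyme`, `solvent`,
#'   `temperature_C`, `c_U50`, sorted by temperature.
#' @export
cu50_vs_temperature <- function(fits) {
  if (!is.list(fits) || length(fits) == 0L ||
      !all(vapply(fits, inherits, logical(1), "unfolding_fit")))
    stop("'fits' must be a non-empty list of unfolding_fit objects",
         call. = FALSE)
  ok <- vapply(fits, function(f) f$converged && f$analyzable, logical(1))
  if (!all(ok))
    stop("all fits must be converged and analyzable; drop the others first",
         call. = FALSE)
  enz <- unique(vapply(fits, `[[`, character(1), "enzyme"))
  sol <- unique(vapply(fits, `[[`, character(1), "solvent"))
  if (length(enz) != 1L || length(sol) != 1L)
    stop("all fits must share enzyme and solvent", call. = FALSE)
  out <- data.frame(
    enzyme = enz, solvent = sol,
    temperature_C = vapply(fits, function(f) f$params$temperature_C,
                           numeric(1)),
    c_U50 = vapply(fits, function(f) f$params$c_U50, numeric(1)))
  out[order(out$temperature_C), , drop = FALSE]
}
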