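# Pure evaluation of the three model equations and derived quantities.
# All evaluations are vectorized over c_solv and overflow-safe: the logistic
# factor exp(x)/(1+exp(x)) is computed with stats::plogis, which evaluates
# the numerically stable branch for either sign of x.

check_conc <- function(c_solv) {
  if (!is.numeric(c_solv) || any(!is.finite(c_solv)))
    stop("'c_solv' must be finite numeric", call. = FALSE)
  if (any(c_solv < 0))
    stop("'c_solv' must be >= 0 percent (v/v)", call. = FALSE)
  invisible(c_solv)
}

#' Fraction of unfolded protein at a co-solvent concentration
#'
#' Evaluates the basic two-state model: the ratio of unfolded to total
#' protein follows a logistic law in co-solvent concentration,
#' `E / (1 + E)` with `E = exp(m_folding/(R T) (c - c_U50))`.
#' The fraction is exactly 0.5 at `c = c_U50` and is monotone
#' nondecreasing in concentration whenever `m_folding > 0`.
#'
#' @param params an [unfolding_params()] object.
#' @param c_solv co-solvent concentration(s), percent (v/v), `>= 0`.
#' @return numeric vector of unfolded fractions in \[0, 1\].
#' @export
eval_fraction_unfolded <- function(params, c_solv) {
  stopifnot(inherits(params, "unfolding_params"))
  check_conc(c_solv)
  x <- params$m_folding / (R_GAS * params$temperature_K) *
    (c_solv - params$c_U50)
  plogis(x)
}

#' Extended two-state unfolding signal
#'
#' Evaluates the extended two-state unfolding model: the observed
#' spectroscopic signal (e.g. the F350/330 fluorescence ratio) as a mixture
#' of linear folded and unfolded baselines weighted by the unfolded
#' fraction,
#' `(alpha_F + beta_F c + (alpha_U + beta_U c) E) / (1 + E)`.
#' It is evaluated in the algebraically identical mixture form
#' `(1 - f) (alpha_F + beta_F c) + f (alpha_U + beta_U c)` with
#' `f = E/(1+E)` computed on the stable branch, so the result is finite for
#' arbitrarily large exponent arguments.
#'
#' @inheritParams eval_fraction_unfolded
#' @return numeric vector of model signal values.
#' @export
eval_unfolding_signal <- function(params, c_solv) {
  f <- eval_fraction_unfolded(params, c_solv)
  (1 - f) * (params$alpha_F + params$beta_F * c_solv) +
    f * (params$alpha_U + params$beta_U * c_solv)
}

#' Activity-solvent model
#'
#' Evaluates the Gaussian-augmented activity model: a Gaussian boost term
#' centred at `c_A_max` with width `sigma`, plus a logistic decay term of
#' scale `nu` whose exponent carries a negative sign, so activity falls off
#' around `c_A50`:
#' `xi * dnorm(c, c_A_max, sigma) + nu * E'/(1+E')` with
#' `E' = exp(-(m_folding/(R T)) (c - c_A50))`.
#'
#' @param params an [activity_params()] object.
#' @param c_solv co-solvent concentration(s), percent (v/v), `>= 0`.
#' @return numeric vector of model activities (same units as `nu`).
#' @export
eval_activity <- function(params, c_solv) {
  stopifnot(inherits(params, "activity_params"))
  check_conc(c_solv)
  boost <- params$xi * dnorm(c_solv, mean = params$c_A_max, sd = params$sigma)
  x <- -params$m_folding / (R_GAS * params$temperature_K) *
    (c_solv - params$c_A50)
  boost + params$nu * plogis(x)
}

#' Free energy of folding at a co-solvent concentration
#'
#' In the two-state picture the free energy of folding varies linearly with
#' co-solvent concentration, `dG = m_folding (c_U50 - c)`. It is exactly
#' zero at the half-unfolding concentration; positive values mean the
#' folded state is favoured (below `c_U50` for `m_folding > 0`).
#'
#' @inheritParams eval_fraction_unfolded
#' @return free energy in J mol^-1.
#' @export
free_energy_of_folding <- function(params, c_solv) {
  stopifnot(inherits(params, "unfolding_params"))
  check_conc(c_solv)
  params$m_folding * (params$c_U50 - c_solv)
}
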