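#' Parameters of the extended two-state unfolding model
#'
#' Constructs a validated parameter set for the extended two-state model of
#' co-solvent induced unfolding. The model describes a spectroscopic signal
#' (typically the nanoDSF F350/330 ratio) as a population-weighted mixture of
#' a folded and an unfolded baseline, each linear in the co-solvent
#' concentration, with the unfolded population following a logistic law in
#' concentration whose midpoint is the half-unfolding concentration `c_U50`.
#'
#' @param alpha_F folded-baseline intercept (signal units).
#' @param beta_F folded-baseline slope (signal units per percent v/v).
#' @param alpha_U unfolded-baseline intercept (signal units).
#' @param beta_U unfolded-baseline slope (signal units per percent v/v).
#' @param m_folding proportionality constant linking co-solvent amount to the
#'   free energy of folding (J mol^-1 per percent v/v); the m-value of
#'   denaturation analysis.
#' @param c_U50 co-solvent concentration of half-unfolding (percent v/v),
#'   bounded to \[0, 100\].
#' @param temperature_C temperature of the isothermal slice (degrees Celsius).
#' @return an object of class `unfolding_params` (a named list that also
#'   stores `temperature_K`).
#' @seealso [eval_unfolding_signal()], [eval_fraction_unfolded()],
#'   [free_energy_of_folding()], [fit_unfolding()]
#' @examples
#' p <- unfolding_params(0.85, 5e-4, 1.05, 2e-3, 1500, 22.8, 35)
#' eval_fraction_unfolded(p, 22.8)  # exactly 0.5 at the midpoint
#' @export
unfolding_params <- function(alpha_F, beta_F, alpha_U, beta_U,
                             m_folding, c_U50, temperature_C) {
  check_nonneg(alpha_F, "alpha_F")
  check_nonneg(beta_F, "beta_F")
  check_nonneg(alpha_U, "alpha_U")
  check_nonneg(beta_U, "beta_U")
  check_nonneg(m_folding, "m_folding")
  check_nonneg(c_U50, "c_U50")
  if (c_U50 > 100)
    stop("'c_U50' must be <= 100 percent (v/v)", call. = FALSE)
  check_scalar(temperature_C, "temperature_C")
  temperature_K <- celsius_to_kelvin(temperature_C)
  if (temperature_K <= 0)
    stop("absolute temperature must be positive", call. = FALSE)
  structure(
    list(alpha_F = alpha_F, beta_F = beta_F,
         alpha_U = alpha_U, beta_U = beta_U,
         m_folding = m_folding, c_U50 = c_U50,
         temperature_C = temperature_C, temperature_K = temperature_K),
    class = "unfolding_params")
}

#' Parameters of the Gaussian-augmented activity-solvent model
#'
#' Constructs a validated parameter set for the activity-solvent model: a
#' Gaussian term describing the activity boost sometimes observed at low
#' co-solvent concentration, plus a decaying logistic term describing the
#' loss of activity as unfolding sets in. Note the logistic exponent carries
#' a negative sign, so the second term decreases with concentration.
#'
#' @param xi scale of the Gaussian boost term (activity units x percent v/v).
#' @param nu scale of the two-state term (activity units); the plateau
#'   activity at low co-solvent when no boost is present.
#' @param sigma width of the Gaussian term (percent v/v) - how narrow the
#'   tolerated concentration range is. A lower bound of 10 is enforced.
#' @param c_A_max concentration of maximal activity (percent v/v), in
#'   \[0, 100\].
#' @param c_A50 concentration of largest activity loss (percent v/v), in
#'   \[0, 100\].
#' @param m_folding proportionality constant (J mol^-1 per percent v/v); may
#'   be any finite value for this model.
#' @param temperature_C reaction temperature (degrees Celsius).
#' @return an object of class `activity_params`.
#' @seealso [eval_activity()], [fit_activity_model()]
#' @examples
#' p <- activity_params(800, 100, 10, 7.5, 19.6, 1500, 35)
#' eval_activity(p, c(0, 7.5, 19.6, 45))
#' @export
activity_params <- function(xi, nu, sigma, c_A_max, c_A50,
                            m_folding, temperature_C) {
  check_nonneg(xi, "xi")
  check_nonneg(nu, "nu")
  check_scalar(sigma, "sigma")
  if (sigma < 10)
    stop("'sigma' must be >= 10 percent (v/v)", call. = FALSE)
  check_nonneg(c_A_max, "c_A_max")
  if (c_A_max > 100) stop("'c_A_max' must be <= 100", call. = FALSE)
  check_nonneg(c_A50, "c_A50")
  if (c_A50 > 100) stop("'c_A50' must be <= 100", call. = FALSE)
  check_scalar(m_folding, "m_folding")
  check_scalar(temperature_C, "temperature_C")
  temperature_K <- celsius_to_kelvin(temperature_C)
  if (temperature_K <= 0)
    stop("absolute temperature must be positive", call. = FALSE)
  structure(
    list(xi = xi, nu = nu, sigma = sigma,
         c_A_max = c_A_max, c_A50 = c_A50, m_folding = m_folding,
         temperature_C = temperature_C, temperature_K = temperature_K),
    class = "activity_params")
}

#' @export
print.unfolding_params <- function(x, ...) {
  cat("Extended two-state unfolding model parameters\n")
  cat(sprintf("  c_U50 = %.3g %%(v/v) at %.4g degC; m_folding = %.4g J/mol/%%\n",
              x$c_U50, x$temperature_C, x$m_folding))
  cat(sprintf("  folded baseline:   %.4g + %.4g * c\n", x$alpha_F, x$beta_F))
  cat(sprintf("  unfolded baseline: %.4g + %.4g * c\n", x$alpha_U, x$beta_U))
  invisible(x)
}

#' @export
print.activity_params <- function(x, ...) {
  cat("Activity-solvent model parameters\n")
  cat(sprintf("  c_A50 = %.3g, c_A_max = %.3g, sigma = %.3g %%(v/v) at %.4g degC\n",
              x$c_A50, x$c_A_max, x$sigma, x$temperature_C))
  cat(sprintf("  xi = %.4g, nu = %.4g, m_folding = %.4g J/mol/%%\n",
              x$xi, x$nu, x$m_folding))
  invisible(x)
}

param_fields <- function(params) {
  keep <- setdiff(names(params), "temperature_K")
  params[keep]
}

#' Serialize a model parameter set to JSON
#'
#' Parameter sets are written as flat JSON objects with snake_case keys;
#' temperatures are serialized in degrees Celsius under `"temperature_C"`.
#'
#' @param params an `unfolding_params` or `activity_params` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @seealso [params_from_json()]
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, c("unfolding_params", "activity_params")))
  fields <- param_fields(params)
  fields$model <- if (inherits(params, "unfolding_params")) "unfolding" else "activity"
  js <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a model parameter set from JSON
#'
#' @param x a JSON string or path to a JSON file written by
#'   [params_to_json()].
#' @return an `unfolding_params` or `activity_params` object, validated on
#'   construction.
#' @export
params_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  model <- obj$model %||% if (!is.null(obj$c_U50)) "unfolding" else "activity"
  if (identical(model, "unfolding")) {
    unfolding_params(obj$alpha_F, obj$beta_F, obj$alpha_U, obj$beta_U,
                     obj$m_folding, obj$c_U50, obj$temperature_C)
  } else {
    activity_params(obj$xi, obj$nu, obj$sigma, obj$c_A_max, obj$c_A50,
                    obj$m_folding, obj$temperature_C)
  }
}
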