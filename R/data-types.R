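# Measurement containers: thermal ramps, isothermal slices, kinetic traces.

#' Thermal-ramp fluorescence curve
#'
#' A single melt curve: one enzyme/solvent/concentration condition heated
#' over a temperature gradient while a fluorescence signal is recorded
#' (the nanoDSF F350/330 ratio or single-channel FMN fluorescence).
#'
#' @param enzyme enzyme identifier.
#' @param solvent co-solvent identifier (use `"none"` for plain buffer).
#' @param c_solv co-solvent concentration, percent (v/v).
#' @param channel `"ratio_350_330"` or `"fmn_fluorescence"`.
#' @param temperature_C strictly increasing temperature series (degrees
#'   Celsius), at least 10 points.
#' @param signal fluorescence signal, same length as `temperature_C`.
#' @return an object of class `thermal_ramp`.
#' @seealso [extract_tm()], [build_isothermal_slice()], [read_ramps()]
#' @export
thermal_ramp <- function(enzyme, solvent, c_solv, channel,
                         temperature_C, signal) {
  stopifnot(is.character(enzyme), length(enzyme) == 1L,
            is.character(solvent), length(solvent) == 1L)
  check_nonneg(c_solv, "c_solv")
  channel <- match.arg(channel, c("ratio_350_330", "fmn_fluorescence"))
  if (!is.numeric(temperature_C) || length(temperature_C) < 10L)
    stop("'temperature_C' must be a numeric series of >= 10 points",
         call. = FALSE)
  if (any(diff(temperature_C) <= 0))
    stop("'temperature_C' must be strictly increasing", call. = FALSE)
  if (!is.numeric(signal) || length(signal) != length(temperature_C))
    stop("'signal' must be numeric and match 'temperature_C' in length",
         call. = FALSE)
  if (any(!is.finite(signal)))
    stop("'signal' must be finite", call. = FALSE)
  structure(
    list(enzyme = enzyme, solvent = solvent, c_solv = c_solv,
         channel = channel, temperature_C = temperature_C, signal = signal),
    class = "thermal_ramp")
}

#' @export
print.thermal_ramp <- function(x, ...) {
  cat(sprintf("Thermal ramp: %s / %s %g%% (v/v), %s, %d points %.4g-%.4g degC\n",
              x$enzyme, x$solvent, x$c_solv, x$channel,
              length(x$temperature_C),
              min(x$temperature_C), max(x$temperature_C)))
  invisible(x)
}

#' Isothermal unfolding slice
#'
#' Signal versus co-solvent concentration at one fixed temperature - the
#' input to the extended two-state unfolding fit. Usually constructed from
#' a family of thermal ramps with [build_isothermal_slice()] or simulated
#' with [generate_isothermal_slice()].
#'
#' @param enzyme,solvent condition identifiers.
#' @param temperature_C the slice temperature (degrees Celsius).
#' @param c_solv distinct, nonnegative co-solvent concentrations,
#'   percent (v/v).
#' @param signal signal values, same length as `c_solv`.
#' @return an object of class `isothermal_slice`, points sorted by
#'   concentration.
#' @export
isothermal_slice <- function(enzyme, solvent, temperature_C, c_solv, signal) {
  stopifnot(is.character(enzyme), length(enzyme) == 1L,
            is.character(solvent), length(solvent) == 1L)
  check_scalar(temperature_C, "temperature_C")
  if (!is.numeric(c_solv) || length(c_solv) < 2L)
    stop("need at least 2 concentration points", call. = FALSE)
  if (any(c_solv < 0))
    stop("'c_solv' must be >= 0", call. = FALSE)
  if (anyDuplicated(c_solv))
    stop("'c_solv' values must be distinct", call. = FALSE)
  if (!is.numeric(signal) || length(signal) != length(c_solv))
    stop("'signal' must match 'c_solv' in length", call. = FALSE)
  if (any(!is.finite(signal)))
    stop("'signal' must be finite", call. = FALSE)
  ord <- order(c_solv)
  structure(
    list(enzyme = enzyme, solvent = solvent, temperature_C = temperature_C,
         c_solv = c_solv[ord], signal = signal[ord]),
    class = "isothermal_slice")
}

#' @export
print.isothermal_slice <- function(x, ...) {
  cat(sprintf("Isothermal slice: %s / %s at %.4g degC, %d concentrations (%g-%g%% v/v)\n",
              x$enzyme, x$solvent, x$temperature_C, length(x$c_solv),
              min(x$c_solv), max(x$c_solv)))
  invisible(x)
}

#' Microplate kinetic trace
#'
#' Time course of absorbance at 340 nm during NAD(P)H depletion, with the
#' metadata needed to convert an absorbance slope into a specific initial
#' activity via the Lambert-Beer law.
#'
#' @param enzyme,solvent condition identifiers.
#' @param c_solv co-solvent concentration, percent (v/v).
#' @param temperature_C reaction temperature (degrees Celsius).
#' @param times strictly increasing time series (s).
#' @param a340 absorbance series, same length as `times`.
#' @param enzyme_conc enzyme concentration in the well (mg ml^-1), `> 0`.
#' @param path_length optical path length (cm), `> 0`. For microplates this
#'   depends on the fill volume; ~0.56 cm for a 200 ul well is a typical
#'   approximate value.
#' @param extinction_coeff molar extinction coefficient of NAD(P)H at
#'   340 nm (M^-1 cm^-1); defaults to the standard 6220.
#' @return an object of class `kinetic_trace`.
#' @seealso [initial_rate()], [read_traces()]
#' @export
kinetic_trace <- function(enzyme, solvent, c_solv, temperature_C,
                          times, a340, enzyme_conc, path_length,
                          extinction_coeff = 6220) {
  stopifnot(is.character(enzyme), length(enzyme) == 1L,
            is.character(solvent), length(solvent) == 1L)
  check_nonneg(c_solv, "c_solv")
  check_scalar(temperature_C, "temperature_C")
  if (!is.numeric(times) || length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!is.numeric(a340) || length(a340) != length(times) ||
      any(!is.finite(a340)))
    stop("'a340' must be finite numeric matching 'times'", call. = FALSE)
  check_scalar(enzyme_conc, "enzyme_conc")
  if (enzyme_conc <= 0) stop("'enzyme_conc' must be > 0", call. = FALSE)
  check_scalar(path_length, "path_length")
  if (path_length <= 0) stop("'path_length' must be > 0", call. = FALSE)
  check_scalar(extinction_coeff, "extinction_coeff")
  if (extinction_coeff <= 0)
    stop("'extinction_coeff' must be > 0", call. = FALSE)
  structure(
    list(enzyme = enzyme, solvent = solvent, c_solv = c_solv,
         temperature_C = temperature_C, times = times, a340 = a340,
         enzyme_conc = enzyme_conc, path_length = path_length,
         extinction_coeff = extinction_coeff),
    class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace: %s / %s %g%% (v/v) at %.4g degC, %d points over %.4g s\n",
              x$enzyme, x$solvent, x$c_solv, x$temperature_C,
              length(x$times), max(x$times) - min(x$times)))
  invisible(x)
}

#' Build an isothermal slice from a family of thermal ramps
#'
#' Reads the signal of every ramp at one fixed temperature (by linear
#' interpolation between the two adjacent ramp samples) and assembles the
#' (concentration, signal) pairs into an [isothermal_slice()]. All ramps
#' must share the enzyme, solvent and channel, and the requested
#' temperature must lie inside every ramp's recorded range.
#'
#' @param ramps list of [thermal_ramp()] objects at distinct co-solvent
#'   concentrations.
#' @param temperature_C the slice temperature (degrees Celsius).
#' @return an `isothermal_slice` with one point per ramp, sorted by
#'   concentration.
#' @export
build_isothermal_slice <- function(ramps, temperature_C) {
  if (!is.list(ramps) || length(ramps) == 0L ||
      !all(vapply(ramps, inherits, logical(1), "thermal_ramp")))
    stop("'ramps' must be a non-empty list of thermal_ramp objects",
         call. = FALSE)
  check_scalar(temperature_C, "temperature_C")
  enzymes <- vapply(ramps, `[[`, character(1), "enzyme")
  solvents <- vapply(ramps, `[[`, character(1), "solvent")
  channels <- vapply(ramps, `[[`, character(1), "channel")
  if (length(unique(enzymes)) != 1L || length(unique(solvents)) != 1L ||
      length(unique(channels)) != 1L)
    stop("all ramps must share enzyme, solvent and channel", call. = FALSE)
  concs <- vapply(ramps, `[[`, numeric(1), "c_solv")
  if (anyDuplicated(concs)) {
    dup <- concs[duplicated(concs)][1L]
    stop(sprintf("duplicate co-solvent concentration %g%% (v/v): ambiguous condition",
                 dup), call. = FALSE)
  }
  signal <- vapply(ramps, function(r) {
    if (temperature_C < min(r$temperature_C) ||
        temperature_C > max(r$temperature_C))
      stop(sprintf(
        "temperature %.4g degC outside ramp range for %s / %s %g%% (v/v)",
        temperature_C, r$enzyme, r$solvent, r$c_solv), call. = FALSE)
    approx(r$temperature_C, r$signal, xout = temperature_C)$y
  }, numeric(1))
  isothermal_slice(enzymes[1L], solvents[1L], temperature_C, concs, signal)
}
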