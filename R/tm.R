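# Melting-temperature extraction by inflection-point detection.

#' Extract the melting temperature from a thermal ramp
#'
#' Locates the inflection point of a melt curve as the temperature of the
#' maximum absolute first derivative of the (smoothed) signal with respect
#' to temperature. The signal is smoothed with a local quadratic
#' (Savitzky-Golay) filter before differencing, and the position of the
#' derivative peak is refined by a parabolic fit through the peak and its
#' neighbours when it lies in the interior of the ramp.
#'
#' The extraction is direction-agnostic: increasing and decreasing
#' transitions give the same inflection temperature because the absolute
#' derivative is used. Two degenerate outcomes are flagged rather than
#' silently reported:
#'
#' * if the derivative maximum falls on the first or last sample, the
#'   transition midpoint lies at or beyond the ramp boundary and the result
#'   carries `boundary = "lower"`/`"upper"` with a label such as
#'   `"> 90 degC"`; such values are bounds, not estimates;
#' * if no clear derivative peak exists (e.g. a strictly linear signal),
#'   the extraction aborts with a "no transition detected" error.
#'
#' @param ramp a [thermal_ramp()].
#' @param window odd Savitzky-Golay window length in samples (default 7);
#'   clamped to the ramp length.
#' @param poly_order polynomial order of the smoother (default 2).
#' @param min_peak_ratio transition-detection threshold: the maximum
#'   absolute derivative must exceed `min_peak_ratio` times its median
#'   (default 3).
#' @return an object of class `tm_estimate`: a list with `tm_C`,
#'   `boundary` (`"none"`, `"lower"` or `"upper"`), `label` (e.g.
#'   `"49.0 degC"` or `"> 90 degC"`) and `max_slope`.
#' @examples
#' ramp <- generate_thermal_ramp(tm_C = 49)
#' extract_tm(ramp)
#' @export
extract_tm <- function(ramp, window = 7L, poly_order = 2L,
                       min_peak_ratio = 3) {
  stopifnot(inherits(ramp, "thermal_ramp"))
  tt <- ramp$temperature_C
  y <- ramp$signal
  n <- length(y)
  w <- min(as.integer(window), if (n %% 2L == 0L) n - 1L else n)
  if (w %% 2L == 0L) w <- w - 1L
  w <- max(w, poly_order + 1L + (poly_order %% 2L))  # filter needs w > order
  sm <- signal::sgolayfilt(y, p = poly_order, n = w)
  # central-difference derivative on the (possibly nonuniform) grid
  d <- numeric(n)
  d[1L] <- (sm[2L] - sm[1L]) / (tt[2L] - tt[1L])
  d[n] <- (sm[n] - sm[n - 1L]) / (tt[n] - tt[n - 1L])
  d[2:(n - 1L)] <- (sm[3:n] - sm[1:(n - 2L)]) / (tt[3:n] - tt[1:(n - 2L)])
  ad <- abs(d)
  i <- which.max(ad)
  peak <- ad[i]
  med <- median(ad)
  if (!(peak > 0) || peak < min_peak_ratio * max(med, .Machine$double.eps))
    stop("no transition detected: derivative shows no clear peak",
         call. = FALSE)
  if (i == 1L || i == n) {
    boundary <- if (i == 1L) "lower" else "upper"
    tm <- tt[i]
    label <- sprintf("%s %.4g degC", if (i == 1L) "<" else ">", tm)
  } else {
    boundary <- "none"
    # parabolic refinement of the derivative peak
    num <- ad[i - 1L] - ad[i + 1L]
    den <- ad[i - 1L] - 2 * ad[i] + ad[i + 1L]
    tm <- if (abs(den) > .Machine$double.eps) {
      step <- (tt[i + 1L] - tt[i - 1L]) / 2
      tt[i] + 0.5 * num / den * step
    } else tt[i]
    label <- sprintf("%.4g degC", tm)
  }
  structure(
    list(tm_C = tm, boundary = boundary, label = label, max_slope = d[i]),
    class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("Melting temperature: %s%s\n", x$label,
              if (x$boundary != "none") " (boundary-flagged: bound, not estimate)" else ""))
  invisible(x)
}
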