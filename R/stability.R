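# Downstream stability comparisons: Tm shifts, rankings, operating windows,
# correlation, and replicate summaries.

#' Melting-temperature shift induced by a co-solvent
#'
#' Computes `delta_Tm = Tm(with solvent) - Tm(native)` and the normalized
#' form `delta_Tm / Tm(native)`, which for destabilizing co-solvents lies
#' between -1 and 0. Boundary-flagged melting temperatures (e.g. "> 90
#' degC") carry no usable numeric value and are rejected: exclude those
#' conditions instead.
#'
#' @param tm_with_solvent,tm_native melting temperatures in degrees
#'   Celsius, as numbers or [extract_tm()] results.
#' @return list with `delta_tm` (degC) and `relative` (dimensionless).
#' @export
delta_tm <- function(tm_with_solvent, tm_native) {
  as_tm <- function(x, name) {
    if (inherits(x, "tm_estimate")) {
      if (x$boundary != "none")
        stop(sprintf("'%s' is boundary-flagged (%s): exclude it from delta-Tm analysis",
                     name, x$label), call. = FALSE)
      x <- x$tm_C
    }
    check_scalar(x, name)
    x
  }
  tw <- as_tm(tm_with_solvent, "tm_with_solvent")
  tn <- as_tm(tm_native, "tm_native")
  d <- tw - tn
  rel <- d / tn
  if (d > 0)
    warning("positive delta-Tm: apparent stabilization by the co-solvent",
            call. = FALSE)
  list(delta_tm = d, relative = rel)
}

#' Per-enzyme stability table
#'
#' Assembles named stability measures into the enzymes-by-measures table
#' consumed by [rank_enzymes()] and [rank_divergence()]. Missing values are
#' explicit `NA`s, never silent zeros.
#'
#' @param enzyme character vector of enzyme identifiers (unique).
#' @param ... equal-length numeric vectors, one per measure (e.g.
#'   `tm_native`, `tm_at_10pct_ethanol`, `cu50_at_30C_ethanol`).
#' @return a `data.frame` of class `stability_table`.
#' @export
stability_table <- function(enzyme, ...) {
  stopifnot(is.character(enzyme), length(enzyme) >= 1L,
            !anyDuplicated(enzyme))
  measures <- list(...)
  if (length(measures) == 0L) stop("supply at least one measure", call. = FALSE)
  if (is.null(names(measures)) || any(names(measures) == ""))
    stop("all measures must be named", call. = FALSE)
  for (nm in names(measures)) {
    if (!is.numeric(measures[[nm]]) ||
        length(measures[[nm]]) != length(enzyme))
      stop(sprintf("measure '%s' must be numeric and match 'enzyme' in length",
                   nm), call. = FALSE)
  }
  out <- data.frame(enzyme = enzyme, measures, check.names = FALSE)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Rank enzymes by a stability measure
#'
#' Orders enzymes by a chosen measure, most stable (largest value) first,
#' and encodes ranks with plus symbols in the convention where the top
#' enzyme of `n` ranked gets `n` pluses, the second `n - 1`, down to one.
#' Ties share the average numeric rank and the symbol count of their best
#' position. Enzymes missing the measure are excluded from the ranking and
#' returned separately - never imputed.
#'
#' @param table a [stability_table()].
#' @param measure name of the measure column to rank by.
#' @return a `data.frame` with columns `enzyme`, `value`, `rank` (average
#'   rank, 1 = most stable) and `symbols`, sorted by rank; enzymes lacking
#'   the measure are in `attr(, "unranked")`.
#' @export
rank_enzymes <- function(table, measure) {
  stopifnot(inherits(table, "stability_table"),
            is.character(measure), length(measure) == 1L)
  available <- setdiff(names(table), "enzyme")
  if (!measure %in% available)
    stop(sprintf("unknown measure '%s'; available: %s",
                 measure, paste(available, collapse = ", ")), call. = FALSE)
  x <- table[[measure]]
  keep <- is.finite(x)
  if (sum(keep) < 2L)
    stop("measure must be present for at least 2 enzymes", call. = FALSE)
  vals <- x[keep]
  enz <- table$enzyme[keep]
  n <- length(vals)
  rk_avg <- rank(-vals, ties.method = "average")
  rk_min <- rank(-vals, ties.method = "min")
  symbols <- vapply(rk_min, function(r) paste(rep("+", n - r + 1L),
                                              collapse = " "),
                    character(1))
  out <- data.frame(enzyme = enz, value = vals, rank = rk_avg,
                    symbols = symbols)
  out <- out[order(out$rank, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unranked") <- table$enzyme[!keep]
  attr(out, "measure") <- measure
  out
}

#' Divergence between two stability rankings
#'
#' Compares the orderings an enzyme set receives under two different
#' stability measures (e.g. native melting temperature versus the
#' half-unfolding concentration in ethanol at 30 degC). Reports the
#' per-enzyme rank shift (`rank_a - rank_b`) and, for three or more shared
#' enzymes, the Spearman correlation of the two orders as a supporting
#' agreement statistic.
#'
#' @param table a [stability_table()].
#' @param measure_a,measure_b measure column names.
#' @return list with `shifts` (data frame: enzyme, rank_a, rank_b, shift)
#'   and `spearman` (`NA` when fewer than 3 shared enzymes).
#' @export
rank_divergence <- function(table, measure_a, measure_b) {
  stopifnot(inherits(table, "stability_table"))
  for (m in c(measure_a, measure_b))
    if (!m %in% names(table))
      stop(sprintf("unknown measure '%s'", m), call. = FALSE)
  keep <- is.finite(table[[measure_a]]) & is.finite(table[[measure_b]])
  a <- table[[measure_a]][keep]
  b <- table[[measure_b]][keep]
  enz <- table$enzyme[keep]
  if (length(enz) == 0L) stop("no shared enzymes with both measures", call. = FALSE)
  rank_a <- rank(-a, ties.method = "average")
  rank_b <- rank(-b, ties.method = "average")
  shifts <- data.frame(enzyme = enz, rank_a = rank_a, rank_b = rank_b,
                       shift = rank_a - rank_b)
  spearman <- if (length(enz) >= 3L) cor(a, b, method = "spearman") else NA_real_
  list(shifts = shifts, spearman = spearman)
}

#' Operating window from a half-unfolding-versus-temperature curve
#'
#' Builds the boundary of the region of suitable reaction conditions in
#' the (temperature, co-solvent concentration) plane: conditions below the
#' `c_U50`-versus-temperature curve leave the enzyme predominantly folded.
#'
#' @param boundary a data frame with columns `temperature_C` and `c_U50`
#'   (at least 2 rows, distinct temperatures), e.g. the output of
#'   [cu50_vs_temperature()].
#' @param enzyme,solvent optional identifiers (taken from `boundary`
#'   columns when present).
#' @return an object of class `operating_window`.
#' @export
operating_window <- function(boundary, enzyme = NULL, solvent = NULL) {
  stopifnot(is.data.frame(boundary),
            all(c("temperature_C", "c_U50") %in% names(boundary)))
  if (nrow(boundary) < 2L)
    stop("at least 2 boundary points are required for interpolation",
         call. = FALSE)
  if (anyDuplicated(boundary$temperature_C))
    stop("boundary temperatures must be distinct", call. = FALSE)
  ord <- order(boundary$temperature_C)
  structure(
    list(enzyme = enzyme %||% boundary$enzyme[1] %||% NA_character_,
         solvent = solvent %||% boundary$solvent[1] %||% NA_character_,
         temperature_C = boundary$temperature_C[ord],
         c_U50 = boundary$c_U50[ord]),
    class = "operating_window")
}

#' @export
print.operating_window <- function(x, ...) {
  cat(sprintf("Operating window: %s / %s, boundary over %.4g-%.4g degC (%d points)\n",
              x$enzyme, x$solvent, min(x$temperature_C),
              max(x$temperature_C), length(x$temperature_C)))
  invisible(x)
}

#' Test a reaction condition against an operating window
#'
#' Interpolates the `c_U50` boundary linearly at the query temperature and
#' classifies the condition: inside the window iff the queried co-solvent
#' concentration is strictly below the boundary (a point exactly on the
#' curve counts as outside). Temperatures outside the boundary's span are
#' an error unless `clamp = TRUE`, which holds the boundary constant at
#' its end values.
#'
#' @param window an [operating_window()].
#' @param temperature_C,c_solv the query condition.
#' @param clamp allow extrapolation by clamping to the span ends
#'   (default `FALSE`).
#' @return list with `inside` (logical), `margin` (boundary minus query
#'   concentration, percent v/v) and `threshold` (interpolated boundary).
#' @export
operating_window_contains <- function(window, temperature_C, c_solv,
                                      clamp = FALSE) {
  stopifnot(inherits(window, "operating_window"))
  check_scalar(temperature_C, "temperature_C")
  check_nonneg(c_solv, "c_solv")
  lo <- min(window$temperature_C); hi <- max(window$temperature_C)
  if (temperature_C < lo || temperature_C > hi) {
    if (!clamp)
      stop(sprintf("temperature %.4g degC outside the boundary span %.4g-%.4g degC",
                   temperature_C, lo, hi), call. = FALSE)
    temperature_C <- min(max(temperature_C, lo), hi)
  }
  threshold <- approx(window$temperature_C, window$c_U50,
                      xout = temperature_C)$y
  list(inside = c_solv < threshold, margin = threshold - c_solv,
       threshold = threshold)
}

#' Pearson correlation with pairwise missing-value handling
#'
#' Product-moment correlation of two equal-length series, dropping any
#' pair with a missing member (the number of complete pairs used is
#' reported). Used e.g. to relate the activity-loss midpoint `c_A50` to
#' the half-unfolding concentration `c_U50` across enzymes and
#' temperatures.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r` (coefficient in \[-1, 1\]) and `n_used`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in at least one series", call. = FALSE)
  list(r = cor(x, y, method = "pearson"), n_used = length(x))
}

#' Mean and standard error of the mean of replicates
#'
#' @param replicates numeric vector, `n >= 1`.
#' @return list with `mean`, `sem` (`NA` with `sem_defined = FALSE` for a
#'   single value) and `n`.
#' @export
mean_sem <- function(replicates) {
  stopifnot(is.numeric(replicates))
  replicates <- replicates[is.finite(replicates)]
  n <- length(replicates)
  if (n == 0L) stop("no finite replicate values", call. = FALSE)
  if (n == 1L)
    return(list(mean = replicates, sem = NA_real_, sem_defined = FALSE,
                n = 1L))
  list(mean = mean(replicates), sem = sd(replicates) / sqrt(n),
       sem_defined = TRUE, n = n)
}
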