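# Long-format CSV and JSON interchange. Long CSV is the canonical format:
# vendor nanoDSF and plate-reader exports vary too much to parse directly,
# so instrument data is assumed pre-converted to these documented schemas.
# Headers are exact, decimal separator ".", encoding UTF-8.

RAMP_COLS <- c("enzyme", "solvent", "conc_pct_vv", "channel",
               "temperature_C", "signal")
TRACE_COLS <- c("enzyme", "solvent", "conc_pct_vv", "temperature_C",
                "time_s", "a340", "enzyme_conc_mg_ml", "path_length_cm")
PROFILE_COLS <- c("enzyme", "solvent", "conc_pct_vv", "temperature_C",
                  "specific_activity", "sem", "n")

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & trimws(raw) != "" &
                   toupper(trimws(raw)) != "NA")
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at data line(s) %s",
                   path, col, paste(bad + 1L, collapse = ", ")),
           call. = FALSE)
    df[[col]] <- num
  }
  df
}

apply_filters <- function(df, solvent = NULL, enzyme = NULL) {
  if (!is.null(solvent)) df <- df[df$solvent %in% solvent, , drop = FALSE]
  if (!is.null(enzyme)) df <- df[df$enzyme %in% enzyme, , drop = FALSE]
  df
}

#' Read thermal ramps from long-format CSV
#'
#' Expects columns `enzyme, solvent, conc_pct_vv, channel, temperature_C,
#' signal`, one row per recorded temperature. Rows are grouped into one
#' [thermal_ramp()] per (enzyme, solvent, concentration, channel)
#' condition; duplicate temperatures within a condition are an error.
#'
#' @param path CSV file path.
#' @param solvent,enzyme optional filters (character vectors).
#' @return a list of `thermal_ramp` objects.
#' @seealso [write_ramps()]
#' @export
read_ramps <- function(path, solvent = NULL, enzyme = NULL) {
  df <- read_checked_csv(path, RAMP_COLS,
                         c("conc_pct_vv", "temperature_C", "signal"))
  df <- apply_filters(df, solvent, enzyme)
  if (nrow(df) == 0L)
    stop("no rows remaining after filtering", call. = FALSE)
  key <- interaction(df$enzyme, df$solvent, df$conc_pct_vv, df$channel,
                     drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$temperature_C), , drop = FALSE]
    if (anyDuplicated(g$temperature_C))
      stop(sprintf("duplicate temperature rows for %s / %s %g%% (v/v)",
                   g$enzyme[1L], g$solvent[1L], g$conc_pct_vv[1L]),
           call. = FALSE)
    thermal_ramp(g$enzyme[1L], g$solvent[1L], g$conc_pct_vv[1L],
                 g$channel[1L], g$temperature_C, g$signal)
  })
}

#' Write thermal ramps to long-format CSV
#'
#' @param ramps list of [thermal_ramp()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ramps <- function(ramps, path) {
  stopifnot(is.list(ramps),
            all(vapply(ramps, inherits, logical(1), "thermal_ramp")))
  rows <- do.call(rbind, lapply(ramps, function(r) {
    data.frame(enzyme = r$enzyme, solvent = r$solvent,
               conc_pct_vv = r$c_solv, channel = r$channel,
               temperature_C = r$temperature_C, signal = r$signal)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read kinetic traces from long-format CSV
#'
#' Expects columns `enzyme, solvent, conc_pct_vv, temperature_C, time_s,
#' a340, enzyme_conc_mg_ml, path_length_cm` and optionally
#' `extinction_coeff`; one row per time point, grouped per condition.
#'
#' @inheritParams read_ramps
#' @return a list of [kinetic_trace()] objects.
#' @export
read_traces <- function(path, solvent = NULL, enzyme = NULL) {
  df <- read_checked_csv(path, TRACE_COLS,
                         c("conc_pct_vv", "temperature_C", "time_s", "a340",
                           "enzyme_conc_mg_ml", "path_length_cm",
                           "extinction_coeff"))
  df <- apply_filters(df, solvent, enzyme)
  if (nrow(df) == 0L)
    stop("no rows remaining after filtering", call. = FALSE)
  key <- interaction(df$enzyme, df$solvent, df$conc_pct_vv,
                     df$temperature_C, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    if (anyDuplicated(g$time_s))
      stop(sprintf("duplicate time rows for %s / %s %g%% (v/v)",
                   g$enzyme[1L], g$solvent[1L], g$conc_pct_vv[1L]),
           call. = FALSE)
    eps <- if ("extinction_coeff" %in% names(g)) g$extinction_coeff[1L] else 6220
    kinetic_trace(g$enzyme[1L], g$solvent[1L], g$conc_pct_vv[1L],
                  g$temperature_C[1L], g$time_s, g$a340,
                  g$enzyme_conc_mg_ml[1L], g$path_length_cm[1L], eps)
  })
}

#' Write kinetic traces to long-format CSV
#'
#' @param traces list of [kinetic_trace()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(is.list(traces),
            all(vapply(traces, inherits, logical(1), "kinetic_trace")))
  rows <- do.call(rbind, lapply(traces, function(x) {
    data.frame(enzyme = x$enzyme, solvent = x$solvent,
               conc_pct_vv = x$c_solv, temperature_C = x$temperature_C,
               time_s = x$times, a340 = x$a340,
               enzyme_conc_mg_ml = x$enzyme_conc,
               path_length_cm = x$path_length,
               extinction_coeff = x$extinction_coeff)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity profile from CSV
#'
#' Expects columns `enzyme, solvent, conc_pct_vv, temperature_C,
#' specific_activity, sem, n`.
#'
#' @inheritParams read_ramps
#' @return a `data.frame` with those columns (numeric ones validated).
#' @export
read_profile <- function(path, solvent = NULL, enzyme = NULL) {
  df <- read_checked_csv(path, PROFILE_COLS,
                         c("conc_pct_vv", "temperature_C",
                           "specific_activity", "sem", "n"))
  df <- apply_filters(df, solvent, enzyme)
  if (nrow(df) == 0L)
    stop("no rows remaining after filtering", call. = FALSE)
  df
}

#' Write an activity profile to CSV
#'
#' Accepts either the `data.frame` schema of [read_profile()] or an
#' [activity_points()] object plus condition labels.
#'
#' @param profile data frame to write.
#' @param path output CSV path.
#' @param enzyme,solvent labels used when `profile` is an
#'   [activity_points()] object.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, enzyme = "unknown",
                          solvent = "unknown") {
  if (inherits(profile, "activity_points")) {
    profile <- data.frame(enzyme = enzyme, solvent = solvent,
                          conc_pct_vv = profile$c_solv,
                          temperature_C = profile$temperature_C,
                          specific_activity = profile$specific_activity,
                          sem = profile$sem, n = profile$n_replicates)
  }
  stopifnot(all(PROFILE_COLS %in% names(profile)))
  write.csv(profile[PROFILE_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fit results to JSON
#'
#' Unfolding fits are written as records `{enzyme, solvent, temperature_C,
#' c_u50, m_folding, alpha_f, beta_f, alpha_u, beta_u, rss, converged,
#' analyzable}`; activity fits as `{enzyme, solvent, temperature_C, xi, nu,
#' sigma, c_a_max, c_a50, m_folding, cost, converged}`.
#'
#' @param fits a list of `unfolding_fit` or `activity_fit` objects (one
#'   kind per file).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_fits()]
#' @export
write_fits <- function(fits, path) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  recs <- lapply(fits, function(f) {
    if (inherits(f, "unfolding_fit")) {
      p <- f$params
      list(kind = "unfolding", enzyme = f$enzyme, solvent = f$solvent,
           temperature_C = p$temperature_C, c_u50 = p$c_U50,
           m_folding = p$m_folding, alpha_f = p$alpha_F,
           beta_f = p$beta_F, alpha_u = p$alpha_U, beta_u = p$beta_U,
           rss = f$residual_sum_squares, converged = f$converged,
           analyzable = f$analyzable)
    } else if (inherits(f, "activity_fit")) {
      p <- f$params
      list(kind = "activity", enzyme = f$enzyme %||% NA,
           solvent = f$solvent %||% NA,
           temperature_C = p$temperature_C, xi = p$xi, nu = p$nu,
           sigma = p$sigma, c_a_max = p$c_A_max, c_a50 = p$c_A50,
           m_folding = p$m_folding, cost = f$cost, converged = f$converged)
    } else stop("'fits' must contain unfolding_fit or activity_fit objects",
                call. = FALSE)
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' Read fit records from JSON
#'
#' @param path JSON path written by [write_fits()].
#' @return a `data.frame`, one row per fit record.
#' @export
read_fits <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  jsonlite::fromJSON(path)
}

#' Write a stability table or ranking as TSV
#'
#' Missing measures are written as `NA`, never as zeros.
#'
#' @param x a [stability_table()], [rank_enzymes()] output or any data
#'   frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a stability table from TSV
#'
#' @param path TSV path with an `enzyme` column and one column per measure
#'   (`NA` marks a missing measure).
#' @return a [stability_table()].
#' @export
read_stability_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!"enzyme" %in% names(df))
    stop(sprintf("%s: missing column(s): enzyme", path), call. = FALSE)
  measures <- df[setdiff(names(df), "enzyme")]
  do.call(stability_table, c(list(enzyme = df$enzyme), as.list(measures)))
}
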