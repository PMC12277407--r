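# CSV schemas are fixed so that measurement files round-trip between the
# simulator, the estimators, and external tools.
UFD_CSV_COLS <- c("specimen_id", "group", "height_cm", "pressure_cmH2O",
                  "flow_ml_s", "diameter_mm")
JESUS_CSV_COLS <- c("specimen_id", "group", "pressure_unit", "p_atm_cmH2O",
                    "v_injected_ml", "p_gauge")
ESTIMATE_CSV_COLS <- c("specimen_id", "group", "method", "value", "intercept",
                       "r_squared", "slope_se", "n_points", "model")

#' Write measurement series to CSV
#'
#' One row per observation, with the specimen identity repeated.  The UFD
#' schema is `specimen_id,group,height_cm,pressure_cmH2O,flow_ml_s,diameter_mm`;
#' the Jesus schema is
#' `specimen_id,group,pressure_unit,p_atm_cmH2O,v_injected_ml,p_gauge`.
#'
#' @param series A single series or a list of series (all [ufd_series()] or
#'   all [jesus_series()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_measurement_csv <- function(series, path) {
  if (inherits(series, c("ufd_series", "jesus_series"))) series <- list(series)
  rows <- lapply(series, function(s) {
    obs <- s$observations
    if (inherits(s, "ufd_series")) {
      data.frame(specimen_id = s$specimen_id, group = s$group,
                 height_cm = obs$height, pressure_cmH2O = obs$pressure,
                 flow_ml_s = obs$flow, diameter_mm = obs$diameter,
                 stringsAsFactors = FALSE)
    } else if (inherits(s, "jesus_series")) {
      data.frame(specimen_id = s$specimen_id, group = s$group,
                 pressure_unit = s$pressure_unit, p_atm_cmH2O = s$p_atm,
                 v_injected_ml = obs$v_injected, p_gauge = obs$p_gauge,
                 stringsAsFactors = FALSE)
    } else {
      abort_input("`series` must contain ufd_series or jesus_series objects")
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read measurement series from CSV
#'
#' Parses and validates a measurement CSV written in the package's UFD or
#' Jesus schema, groups rows into per-specimen series, and enforces all
#' series invariants (monotone heights / injected volumes, positive
#' diameters, and so on), reporting the offending column, row, or specimen.
#'
#' @param path CSV file path.
#' @param kind `"ufd"` or `"jesus"`.
#' @return A list of [ufd_series()] or [jesus_series()] objects, in file
#'   order of first appearance.
#' @export
read_measurement_csv <- function(path, kind = c("ufd", "jesus")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- if (kind == "ufd") UFD_CSV_COLS else JESUS_CSV_COLS
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0L) {
    abort_input(sprintf("schema error in %s: missing column(s) %s",
                        path, paste(missing_cols, collapse = ", ")),
                class = "urocomp_schema_error")
  }
  check_col <- function(col, ok, what) {
    bad <- which(!ok(df[[col]]))
    if (length(bad) > 0L) {
      abort_input(sprintf("validation error in %s, column %s, row %d: %s",
                          path, col, bad[1], what))
    }
  }
  if (kind == "ufd") {
    check_col("height_cm", function(v) is.finite(v) & v >= 0, "height must be >= 0")
    check_col("flow_ml_s", function(v) is.finite(v) & v >= 0, "flow must be >= 0")
    check_col("diameter_mm", function(v) is.finite(v) & v > 0, "diameter must be > 0")
    check_col("pressure_cmH2O", function(v) is.finite(v) & v >= 0, "pressure must be >= 0")
  } else {
    check_col("v_injected_ml", function(v) is.finite(v) & v >= 0, "v_injected must be >= 0")
    check_col("p_gauge", function(v) is.finite(v) & v >= 0, "p_gauge must be >= 0")
  }
  ids <- unique(df$specimen_id)
  lapply(ids, function(id) {
    sub <- df[df$specimen_id == id, , drop = FALSE]
    res <- tryCatch({
      if (kind == "ufd") {
        ufd_series(id, sub$group[1], height = sub$height_cm,
                   pressure = sub$pressure_cmH2O, flow = sub$flow_ml_s,
                   diameter = sub$diameter_mm)
      } else {
        jesus_series(id, sub$group[1], v_injected = sub$v_injected_ml,
                     p_gauge = sub$p_gauge,
                     pressure_unit = sub$pressure_unit[1],
                     p_atm = sub$p_atm_cmH2O[1])
      }
    }, urocomp_invalid_input = function(e) {
      abort_input(sprintf("validation error for specimen %s in %s: %s",
                          id, path, conditionMessage(e)))
    })
    res
  })
}

#' Write compliance estimates to CSV
#'
#' Schema:
#' `specimen_id,group,method,value,intercept,r_squared,slope_se,n_points,model`.
#'
#' @param estimates A list of [compliance_estimate()] objects (or one).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (inherits(estimates, "compliance_estimate")) estimates <- list(estimates)
  df <- do.call(rbind, lapply(estimates, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read compliance estimates from CSV
#'
#' @param path CSV file in the schema of [write_estimates_csv()].
#' @return A tibble of estimates.
#' @export
read_estimates_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ESTIMATE_CSV_COLS, names(df))
  if (length(missing_cols) > 0L) {
    abort_input(sprintf("schema error in %s: missing column(s) %s",
                        path, paste(missing_cols, collapse = ", ")),
                class = "urocomp_schema_error")
  }
  tibble::as_tibble(df)
}
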