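#' Construct a non-invasive (UFD) measurement series
#'
#' One specimen's paired observations of container height, the hydrostatic
#' gauge pressure it exerts, urinary flow rate, and ultrasound-measured
#' anteroposterior urethral diameter.  The diameter-vs-flow slope of such a
#' series is the non-invasive compliance estimate.
#'
#' @param specimen_id Character label.
#' @param group `"control"` or `"TIP"`.
#' @param height Container heights above the urethra, cm; strictly
#'   increasing, at least 3.
#' @param pressure Hydrostatic gauge pressures, cmH2O.
#' @param flow Urinary flow rates, ml/s.
#' @param diameter Anteroposterior diameters, mm; strictly positive.
#'
#' @return An object of class `ufd_series`: a list with the identifying
#'   fields and an `observations` tibble.
#' @export
ufd_series <- function(specimen_id, group, height, pressure, flow, diameter) {
  n <- length(height)
  if (n < 3L) abort_input("a UFD series needs at least 3 observations")
  lens <- c(length(pressure), length(flow), length(diameter))
  if (any(lens != n)) abort_input("height, pressure, flow, diameter must have equal length")
  assert_increasing(height, "height")
  if (any(height < 0)) abort_input("heights must be non-negative")
  if (any(pressure < 0)) abort_input("pressures must be non-negative")
  if (any(flow < 0)) abort_input("flows must be non-negative")
  if (any(diameter <= 0)) abort_input("diameters must be positive")
  structure(
    list(
      specimen_id = as.character(specimen_id),
      group = match.arg(group, c("control", "TIP")),
      observations = tibble::tibble(
        height = as.numeric(height), pressure = as.numeric(pressure),
        flow = as.numeric(flow), diameter = as.numeric(diameter)
      )
    ),
    class = "ufd_series"
  )
}

#' @export
print.ufd_series <- function(x, ...) {
  cat(sprintf("<ufd_series> %s [%s], %d observations\n",
              x$specimen_id, x$group, nrow(x$observations)))
  print(x$observations, n = 5)
  invisible(x)
}

#' Construct an invasive air-injection (Jesus) measurement series
#'
#' One specimen's observations of cumulative injected air volume (at ambient
#' pressure) and the gauge pressure measured inside the sealed urethral
#' segment.  Cavity volumes are later reconstructed from these via Boyle's
#' law, and the volume-vs-pressure slope is the invasive compliance.
#'
#' @param specimen_id Character label.
#' @param group `"control"` or `"TIP"`.
#' @param v_injected Cumulative injected volumes, ml; strictly increasing,
#'   non-negative, at least 3 values.
#' @param p_gauge Gauge pressures in `pressure_unit`; non-negative.
#' @param pressure_unit `"cmH2O"` or `"PSI"`.
#' @param p_atm Ambient absolute pressure, cmH2O.
#'
#' @return An object of class `jesus_series`.
#' @export
jesus_series <- function(specimen_id, group, v_injected, p_gauge,
                         pressure_unit = c("cmH2O", "PSI"),
                         p_atm = 1033.2) {
  pressure_unit <- match.arg(pressure_unit)
  n <- length(v_injected)
  if (n < 3L) abort_input("a Jesus series needs at least 3 observations")
  if (length(p_gauge) != n) abort_input("v_injected and p_gauge must have equal length")
  assert_increasing(v_injected, "v_injected")
  if (any(v_injected < 0)) abort_input("v_injected must be non-negative")
  if (any(p_gauge < 0)) abort_input("p_gauge must be non-negative")
  assert_number(p_atm, "p_atm", lower = 0, strict = TRUE)
  structure(
    list(
      specimen_id = as.character(specimen_id),
      group = match.arg(group, c("control", "TIP")),
      pressure_unit = pressure_unit,
      p_atm = p_atm,
      observations = tibble::tibble(
        v_injected = as.numeric(v_injected), p_gauge = as.numeric(p_gauge)
      )
    ),
    class = "jesus_series"
  )
}

#' @export
print.jesus_series <- function(x, ...) {
  cat(sprintf("<jesus_series> %s [%s], %d observations, unit %s, p_atm %.1f cmH2O\n",
              x$specimen_id, x$group, nrow(x$observations),
              x$pressure_unit, x$p_atm))
  print(x$observations, n = 5)
  invisible(x)
}
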