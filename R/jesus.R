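#' Pressure unit conversions between PSI and cmH2O
#'
#' 1 PSI = 70.307 cmH2O at reference conditions (4 degrees C water column,
#' standard gravity).  The two functions are exact inverses.
#'
#' @param p Pressure value(s).
#' @return The converted pressure(s).
#' @export
#' @examples
#' psi_to_cmH2O(1)
#' cmH2O_to_psi(psi_to_cmH2O(0.37))
psi_to_cmH2O <- function(p) p * 70.307

#' @rdname psi_to_cmH2O
#' @export
cmH2O_to_psi <- function(p) p / 70.307

#' Reconstruct cavity volume from injected air and measured pressure
#'
#' Inverts the isothermal gas balance of the sealed segment: all the air in
#' the cavity (`v0` resting plus `v_injected`, both at ambient absolute
#' pressure `p_atm`) is compressed to absolute pressure `p_atm + p_gauge`,
#' so by Boyle's law the cavity volume is
#' \deqn{V = \frac{p_{atm}(v_0 + v_{inj} + v_{dead})}{p_{atm} + p_{gauge}} - v_{dead}.}
#' Any rigid dead space (catheter and tubing) shares the pressure but not
#' the compliance, so it is subtracted back out.
#'
#' @param v_injected Cumulative injected volume(s), ml.
#' @param p_gauge Gauge pressure(s) in `pressure_unit`.
#' @param v0 Resting cavity volume, ml.
#' @param p_atm Ambient absolute pressure, cmH2O.
#' @param pressure_unit Unit of `p_gauge`: `"cmH2O"` or `"PSI"`.
#' @param v_dead Rigid dead-space volume, ml (default 0).
#' @return A tibble with `p_gauge_cmH2O` and reconstructed `v_cavity` (ml).
#' @export
#' @examples
#' reconstruct_cavity_volume(1, 1033.2, v0 = 1, p_atm = 1033.2)
reconstruct_cavity_volume <- function(v_injected, p_gauge, v0,
                                      p_atm = 1033.2,
                                      pressure_unit = c("cmH2O", "PSI"),
                                      v_dead = 0) {
  pressure_unit <- match.arg(pressure_unit)
  assert_number(v0, "v0", lower = 0, strict = TRUE)
  assert_number(p_atm, "p_atm", lower = 0, strict = TRUE)
  assert_number(v_dead, "v_dead", lower = 0)
  if (any(v_injected < 0)) abort_input("`v_injected` must be non-negative")
  p_cm <- if (pressure_unit == "PSI") psi_to_cmH2O(p_gauge) else p_gauge
  if (any(p_atm + p_cm <= 0)) {
    abort_input("absolute pressure p_atm + p_gauge must be positive")
  }
  v <- p_atm * (v0 + v_dead + v_injected) / (p_atm + p_cm) - v_dead
  tibble::tibble(p_gauge_cmH2O = as.numeric(p_cm), v_cavity = as.numeric(v))
}

#' Estimate invasive urethral compliance (volume-vs-pressure slope)
#'
#' Reconstructs the cavity volume at every observation of an air-injection
#' series via [reconstruct_cavity_volume()], then fits ordinary least
#' squares of volume (ml) on gauge pressure (cmH2O, converted from PSI if
#' needed).  The slope is the volumetric compliance in ml/cmH2O.
#'
#' The resting cavity volume `v0` is not observable from the pressure trace
#' alone and must be supplied; for simulated data it is available from the
#' generating [tube_spec()].  Because volume enters the regression only
#' through the affine reconstruction, a mis-specified `v0` shifts the
#' intercept far more than the slope; [jesus_v0_sensitivity()] quantifies
#' the residual slope sensitivity.
#'
#' @param series A [jesus_series()].
#' @param v0 Resting cavity volume, ml.
#' @param model `"linear"` (default) or `"quadratic"`.
#' @param v_dead Rigid dead-space volume, ml.
#' @return A [compliance_estimate()] with `method = "Jesus"`.
#' @export
#' @examples
#' sp <- tube_spec("r1", "control", v0 = 1, c_vp = 0.05, noise_p = 0)
#' s <- simulate_jesus_series(sp, seq(0.5, 5, 0.5))
#' estimate_jesus_compliance(s, v0 = 1)
estimate_jesus_compliance <- function(series, v0,
                                      model = c("linear", "quadratic"),
                                      v_dead = 0) {
  stopifnot(inherits(series, "jesus_series"))
  obs <- series$observations
  rec <- reconstruct_cavity_volume(obs$v_injected, obs$p_gauge, v0 = v0,
                                   p_atm = series$p_atm,
                                   pressure_unit = series$pressure_unit,
                                   v_dead = v_dead)
  f <- fit_response_curve(rec$p_gauge_cmH2O, rec$v_cavity, match.arg(model))
  compliance_estimate(series$specimen_id, series$group, "Jesus",
                      value = f$slope, intercept = f$intercept,
                      r_squared = f$r_squared, slope_se = f$slope_se,
                      n_points = f$n_points, model = f$model)
}

#' Sensitivity of the invasive compliance estimate to the assumed v0
#'
#' Re-estimates the volume-vs-pressure slope over a grid of assumed resting
#' volumes, as a diagnostic for how strongly a mis-specified `v0`
#' propagates into the compliance value.
#'
#' @param series A [jesus_series()].
#' @param v0_grid Numeric vector of candidate resting volumes, ml.
#' @return A tibble with columns `v0` and `value`.
#' @export
jesus_v0_sensitivity <- function(series, v0_grid) {
  stopifnot(inherits(series, "jesus_series"))
  vals <- vapply(v0_grid, function(v0) {
    estimate_jesus_compliance(series, v0 = v0)$value
  }, numeric(1))
  tibble::tibble(v0 = as.numeric(v0_grid), value = vals)
}
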