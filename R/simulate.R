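#' Hydrostatic gauge pressure of a urine column
#'
#' Urine is treated as a unit-density water column, so a container held
#' `height` cm above the urethra exerts `height` cmH2O of gauge pressure.
#'
#' @param height Container height(s) above the urethra, cm; non-negative.
#' @return Gauge pressure(s), cmH2O.
#' @export
#' @examples
#' height_to_pressure(c(40, 100))
height_to_pressure <- function(height) {
  if (!is.numeric(height) || any(!is.finite(height))) {
    abort_input("`height` must be finite numeric")
  }
  if (any(height < 0)) abort_input("`height` must be non-negative")
  height * 1.0
}

#' Noise-free urinary flow at a given driving pressure
#'
#' Evaluates the linear pressure--flow relation `Q = q0 + b_qp * P`, floored
#' at zero (no retrograde flow).
#'
#' @param spec A [tube_spec()].
#' @param pressure Gauge pressure(s), cmH2O; non-negative.
#' @return Flow(s), ml/s.
#' @export
flow_from_pressure <- function(spec, pressure) {
  stopifnot(inherits(spec, "tube_spec"))
  if (any(pressure < 0)) abort_input("`pressure` must be non-negative")
  pmax(spec$q0 + spec$b_qp * pressure, 0)
}

#' Noise-free anteroposterior diameter at a given pressure
#'
#' Evaluates the elastic tube law `D = d0 + c_dp * P` (plus the optional
#' quadratic term `c_dp2 * P^2` when the spec enables it).
#'
#' @inheritParams flow_from_pressure
#' @return Diameter(s), mm.
#' @export
diameter_from_pressure <- function(spec, pressure) {
  stopifnot(inherits(spec, "tube_spec"))
  if (any(pressure < 0)) abort_input("`pressure` must be non-negative")
  spec$d0 + spec$c_dp * pressure + spec$c_dp2 * pressure^2
}

# Diameters are floored here rather than at zero: an ultrasound reading of a
# patent lumen is always positive.
.DIAMETER_EPS <- 1e-3

#' Simulate a non-invasive flow/diameter measurement series
#'
#' Generates one observation per container height: the hydrostatic pressure,
#' the flow from the linear pressure--flow relation plus Gaussian noise
#' (floored at 0), and the diameter from the tube law plus Gaussian noise
#' (floored at a small positive epsilon).  Deterministic given `spec$seed`.
#'
#' @param spec A [tube_spec()].
#' @param heights Container heights, cm; strictly increasing, non-negative.
#' @return A [ufd_series()].
#' @export
#' @examples
#' sp <- tube_spec("r1", "control", noise_d = 0, noise_q = 0)
#' simulate_ufd_series(sp, seq(40, 100, by = 20))
simulate_ufd_series <- function(spec, heights = seq(40, 100, by = 10)) {
  stopifnot(inherits(spec, "tube_spec"))
  assert_increasing(heights, "heights")
  p <- height_to_pressure(heights)
  n <- length(p)
  with_seed_or_not(spec$seed, {
    flow <- pmax(flow_from_pressure(spec, p) + stats::rnorm(n, 0, spec$noise_q), 0)
    diam <- pmax(diameter_from_pressure(spec, p) + stats::rnorm(n, 0, spec$noise_d),
                 .DIAMETER_EPS)
    ufd_series(spec$specimen_id, spec$group,
               height = heights, pressure = p, flow = flow, diameter = diam)
  })
}

#' Gauge pressure of a sealed elastic cavity after air injection
#'
#' The sealed 1-cm urethral segment holds `v0` ml of air at ambient absolute
#' pressure `p_atm`.  Injecting `v_injected` ml (measured at ambient
#' pressure) raises the gauge pressure `p` to the unique non-negative root
#' of the isothermal mass balance
#' \deqn{p_{atm} (v_0 + v_{inj}) = (p_{atm} + p)(v_0 + c_{vp} p),}
#' which couples Boyle's law for the trapped gas with the linear tube law
#' `V(p) = v0 + c_vp * p` for the cavity.  The root is computed in closed
#' form from the quadratic; `method = "bisection"` solves the same mass
#' balance numerically and exists as an independent cross-check.
#'
#' @param spec A [tube_spec()] (uses `v0`, `c_vp`).
#' @param v_injected Cumulative injected volume(s), ml; non-negative.
#' @param p_atm Ambient absolute pressure, cmH2O.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return Gauge pressure(s), cmH2O.
#' @export
#' @examples
#' sp <- tube_spec(v0 = 1, c_vp = 0.001)
#' gauge_pressure_after_injection(sp, 0.5, p_atm = 1000)
gauge_pressure_after_injection <- function(spec, v_injected, p_atm = 1033.2,
                                           method = c("closed_form", "bisection")) {
  stopifnot(inherits(spec, "tube_spec"))
  method <- match.arg(method)
  if (any(v_injected < 0)) abort_input("`v_injected` must be non-negative")
  assert_number(p_atm, "p_atm", lower = 0, strict = TRUE)
  v0 <- spec$v0; cvp <- spec$c_vp
  if (method == "bisection") {
    return(vapply(v_injected, function(vi) {
      if (vi == 0) return(0)
      f <- function(p) (p_atm + p) * (v0 + cvp * p) - p_atm * (v0 + vi)
      upper <- p_atm * vi / v0  # rigid-cavity pressure bounds the root above
      stats::uniroot(f, c(0, upper), tol = 1e-12 * max(1, upper))$root
    }, numeric(1)))
  }
  # c_vp p^2 + (v0 + c_vp p_atm) p - p_atm v_injected = 0
  b <- v0 + cvp * p_atm
  if (cvp == 0) return(p_atm * v_injected / v0)
  disc <- b^2 + 4 * cvp * p_atm * v_injected
  if (any(disc < 0)) {
    stop("internal consistency error: mass balance has no non-negative root")
  }
  (-b + sqrt(disc)) / (2 * cvp)
}

#' Simulate an invasive air-injection measurement series
#'
#' For each cumulative injection step, computes the noise-free gauge
#' pressure via [gauge_pressure_after_injection()], adds Gaussian
#' measurement noise (floored at 0), and converts to the requested pressure
#' unit.  Deterministic given `spec$seed`.
#'
#' @param spec A [tube_spec()].
#' @param injection_steps Cumulative injected volumes, ml; strictly
#'   increasing, non-negative.
#' @param p_atm Ambient absolute pressure, cmH2O.
#' @param pressure_unit `"cmH2O"` or `"PSI"` (the unit the gauge displays).
#' @return A [jesus_series()].
#' @export
simulate_jesus_series <- function(spec, injection_steps = seq(0.25, 10, by = 0.25),
                                  p_atm = 1033.2,
                                  pressure_unit = c("cmH2O", "PSI")) {
  stopifnot(inherits(spec, "tube_spec"))
  pressure_unit <- match.arg(pressure_unit)
  assert_increasing(injection_steps, "injection_steps")
  if (any(injection_steps < 0)) abort_input("injection steps must be non-negative")
  p_true <- gauge_pressure_after_injection(spec, injection_steps, p_atm)
  with_seed_or_not(spec$seed, {
    p_meas <- pmax(p_true + stats::rnorm(length(p_true), 0, spec$noise_p), 0)
    if (pressure_unit == "PSI") p_meas <- cmH2O_to_psi(p_meas)
    jesus_series(spec$specimen_id, spec$group,
                 v_injected = injection_steps, p_gauge = p_meas,
                 pressure_unit = pressure_unit, p_atm = p_atm)
  })
}

#' Simulate a paired two-group cohort
#'
#' Draws specimen-level true compliances log-normally around the group
#' medians (one shared latent tissue-elasticity factor per specimen scales
#' both the diameter compliance and the volumetric compliance), then
#' simulates a UFD series and a Jesus series for every specimen, as in a
#' self-controlled design where each urethra undergoes both assessments.
#'
#' @param cohort A [cohort_spec()].
#' @return A list with class `cohort_sim`: `specs` (list of [tube_spec()]
#'   with per-specimen true parameters), `ufd` (list of [ufd_series()]),
#'   `jesus` (list of [jesus_series()]), and `truth` (tibble of per-specimen
#'   ground-truth compliances).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_per_group = 4, seed = 7))
#' sim$truth
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_per_group
  groups <- rep(c("control", "TIP"), each = n)
  ids <- sprintf("%s_%02d", ifelse(groups == "control", "ctl", "tip"),
                 rep(seq_len(n), times = 2))
  # log-normal with median exp(mu) and CV^2 = exp(sigma^2) - 1
  sdlog <- sqrt(log(1 + cohort$between_specimen_cv^2))
  with_seed_or_not(cohort$seed, {
    factor_i <- stats::rlnorm(2 * n, meanlog = 0, sdlog = sdlog)
    # child seeds keep each specimen's series reproducible in isolation
    child_seeds <- sample.int(.Machine$integer.max, 2 * n)
    specs <- vector("list", 2 * n)
    ufd <- vector("list", 2 * n)
    jesus <- vector("list", 2 * n)
    for (i in seq_len(2 * n)) {
      g <- groups[i]
      cua_ufd_true <- cohort$group_median_ufd[[g]] * factor_i[i]
      c_vp_true <- cohort$group_median_jesus[[g]] * factor_i[i]
      specs[[i]] <- tube_spec(
        specimen_id = ids[i], group = g,
        d0 = cohort$d0, c_dp = cua_ufd_true * cohort$b_qp,
        b_qp = cohort$b_qp, q0 = cohort$q0,
        v0 = cohort$v0, c_vp = c_vp_true,
        noise_d = cohort$noise_d, noise_q = cohort$noise_q,
        noise_p = cohort$noise_p, seed = child_seeds[i]
      )
      ufd[[i]] <- simulate_ufd_series(specs[[i]], cohort$heights)
      jesus[[i]] <- simulate_jesus_series(specs[[i]], cohort$injection_steps,
                                          p_atm = cohort$p_atm)
    }
  })
  truth <- tibble::tibble(
    specimen_id = ids, group = groups,
    cua_ufd_true = vapply(specs, function(s) s$c_dp / s$b_qp, numeric(1)),
    c_vp_true = vapply(specs, function(s) s$c_vp, numeric(1))
  )
  structure(
    list(specs = specs, ufd = ufd, jesus = jesus, truth = truth,
         cohort = cohort),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d specimens (%d per group), seed %d\n",
              nrow(x$truth), x$cohort$n_per_group, x$cohort$seed))
  print(x$truth, n = 6)
  invisible(x)
}
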