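#' A fitted compliance value with diagnostics
#'
#' Container returned by [estimate_ufd_compliance()] and
#' [estimate_jesus_compliance()].  `value` is the fitted slope: mm s/ml for
#' the non-invasive method (`method = "UFD"`, diameter on flow) and
#' ml/cmH2O for the invasive method (`method = "Jesus"`, reconstructed
#' volume on gauge pressure).
#'
#' @param specimen_id,group Identity of the specimen.
#' @param method `"UFD"` or `"Jesus"`.
#' @param value Fitted compliance (slope).
#' @param intercept Fitted intercept from the same regression.
#' @param r_squared Coefficient of determination in `[0, 1]`.
#' @param slope_se Standard error of the slope.
#' @param n_points Number of observations in the fit.
#' @param model `"linear"` or `"quadratic"`.
#' @return An object of class `compliance_estimate`.
#' @export
compliance_estimate <- function(specimen_id, group, method, value, intercept,
                                r_squared, slope_se, n_points,
                                model = c("linear", "quadratic")) {
  method <- match.arg(method, c("UFD", "Jesus"))
  model <- match.arg(model)
  if (n_points < 3L) abort_input("a compliance estimate needs n_points >= 3")
  if (!is.finite(value)) abort_input("compliance value must be finite")
  if (r_squared < 0 || r_squared > 1) abort_input("r_squared must lie in [0, 1]")
  structure(
    list(specimen_id = as.character(specimen_id),
         group = match.arg(group, c("control", "TIP")),
         method = method, value = value, intercept = intercept,
         r_squared = r_squared, slope_se = slope_se,
         n_points = as.integer(n_points), model = model),
    class = "compliance_estimate"
  )
}

#' @export
print.compliance_estimate <- function(x, ...) {
  unit <- if (x$method == "UFD") "mm s/ml" else "ml/cmH2O"
  cat(sprintf("<compliance_estimate> %s [%s] %s: %.4g %s (SE %.3g, R2 %.3f, n %d, %s fit)\n",
              x$specimen_id, x$group, x$method, x$value, unit,
              x$slope_se, x$r_squared, x$n_points, x$model))
  invisible(x)
}

#' @export
as.data.frame.compliance_estimate <- function(x, ...) {
  data.frame(specimen_id = x$specimen_id, group = x$group, method = x$method,
             value = x$value, intercept = x$intercept,
             r_squared = x$r_squared, slope_se = x$slope_se,
             n_points = x$n_points, model = x$model,
             stringsAsFactors = FALSE)
}

# Shared OLS core for both estimators: y on x (+ x^2 for the quadratic
# model).  Returns the slope evaluated at the mean of x for the quadratic
# model, so that "compliance" is always a local derivative.
fit_response_curve <- function(x, y, model = c("linear", "quadratic")) {
  model <- match.arg(model)
  n <- length(x)
  if (n < 3L) abort_input("at least 3 observations are required")
  if (length(unique(x)) == 1L) {
    abort_input("all predictor values identical: design is degenerate",
                class = "urocomp_degenerate_design")
  }
  fit <- if (model == "linear") {
    stats::lm(y ~ x)
  } else {
    stats::lm(y ~ x + I(x^2))
  }
  cf <- stats::coef(fit)
  # zero-noise validation series are a supported input; the residual-scale
  # warning they trigger in summary.lm is expected, not actionable
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    # flat response: a physically meaningful rigid tube; R^2 is undefined,
    # report 0 by convention
    warning("response has zero variance; reporting R-squared = 0")
    r2 <- 0
  } else {
    r2 <- sm$r.squared
  }
  if (model == "linear") {
    slope <- unname(cf[2])
    slope_se <- sm$coefficients["x", "Std. Error"]
  } else {
    # derivative of the fitted parabola at the mean predictor
    slope <- unname(cf[2] + 2 * cf[3] * mean(x))
    V <- stats::vcov(fit)
    a <- c(0, 1, 2 * mean(x))
    slope_se <- sqrt(drop(t(a) %*% V %*% a))
  }
  list(intercept = unname(cf[1]), slope = slope, slope_se = slope_se,
       r_squared = min(max(r2, 0), 1), n_points = n, model = model, fit = fit)
}

#' Regress urethral diameter on urinary flow
#'
#' Ordinary least-squares fit of anteroposterior diameter (mm) on flow rate
#' (ml/s).  With `model = "linear"` the slope is the non-invasive
#' compliance; with `model = "quadratic"` a second-order term is added and
#' the reported slope is the derivative of the fitted curve at the mean
#' observed flow.
#'
#' @param series A [ufd_series()].
#' @param model `"linear"` (default) or `"quadratic"`.
#' @return A list with `intercept`, `slope`, `slope_se`, `r_squared`,
#'   `n_points`, `model`, and the underlying `lm` fit.
#' @export
fit_diameter_flow <- function(series, model = c("linear", "quadratic")) {
  stopifnot(inherits(series, "ufd_series"))
  obs <- series$observations
  fit_response_curve(obs$flow, obs$diameter, match.arg(model))
}

#' Estimate non-invasive urethral compliance (diameter-vs-flow slope)
#'
#' The non-invasive method replaces direct pressure measurement with flow:
#' because pressure and flow are linearly related, the slope of diameter on
#' flow carries the same elastic information as diameter on pressure.  This
#' returns that slope, in mm s/ml, with fit diagnostics.
#'
#' @inheritParams fit_diameter_flow
#' @return A [compliance_estimate()] with `method = "UFD"`.
#' @export
#' @examples
#' sp <- tube_spec("r1", "control", c_dp = 0.01, b_qp = 0.5,
#'                 noise_d = 0, noise_q = 0)
#' estimate_ufd_compliance(simulate_ufd_series(sp, seq(40, 100, 20)))
estimate_ufd_compliance <- function(series, model = c("linear", "quadratic")) {
  stopifnot(inherits(series, "ufd_series"))
  f <- fit_diameter_flow(series, model)
  compliance_estimate(series$specimen_id, series$group, "UFD",
                      value = f$slope, intercept = f$intercept,
                      r_squared = f$r_squared, slope_se = f$slope_se,
                      n_points = f$n_points, model = f$model)
}
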