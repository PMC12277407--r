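test_that("hydrostatic pressure is the identity map on column height", {
  expect_identical(height_to_pressure(c(0, 40, 100)), c(0, 40, 100))
  expect_error(height_to_pressure(-1), class = "urocomp_invalid_input")
})

test_that("noise-free flow and diameter follow the linear laws with flooring", {
  sp <- tube_spec(q0 = 0, b_qp = 0.5, d0 = 2.0, c_dp = 0.01)
  expect_equal(flow_from_pressure(sp, c(0, 40)), c(0, 20))
  expect_equal(diameter_from_pressure(sp, c(0, 40)), c(2.0, 2.4))
  # negative intercept floors at zero flow
  sp2 <- tube_spec(q0 = -10, b_qp = 0.1)
  expect_equal(flow_from_pressure(sp2, 50), 0)
  # rigid tube keeps its resting diameter
  sp3 <- tube_spec(d0 = 2.0, c_dp = 0)
  expect_equal(diameter_from_pressure(sp3, 100), 2.0)
})

test_that("simulated series reproduce the noise-free closed form and the seed", {
  sp <- tube_spec("r1", "control", d0 = 2.0, c_dp = 0.01, q0 = 0, b_qp = 0.5,
                  noise_d = 0, noise_q = 0, seed = 5)
  s <- simulate_ufd_series(sp, c(40, 60, 80, 100))
  expect_equal(s$observations$diameter, c(2.4, 2.6, 2.8, 3.0))
  expect_equal(s$observations$flow, c(20, 30, 40, 50))

  spn <- tube_spec("r1", "control", noise_d = 0.05, noise_q = 0.5, seed = 99)
  expect_identical(simulate_ufd_series(spn), simulate_ufd_series(spn))
  expect_error(simulate_ufd_series(spn, numeric(0)),
               class = "urocomp_invalid_input")
})

test_that("replicate noisy diameters average to the noise-free tube law", {
  heights <- c(40, 60, 80, 100)
  sp <- tube_spec("mc", "control", noise_d = 0.05, noise_q = 0, seed = NULL)
  truth <- diameter_from_pressure(sp, height_to_pressure(heights))
  n_rep <- 4000
  set.seed(2601)
  sims <- replicate(n_rep, simulate_ufd_series(sp, heights)$observations$diameter)
  se <- 0.05 / sqrt(n_rep)
  expect_true(all(abs(rowMeans(sims) - truth) < 3 * se))
})

test_that("injection pressure solves the sealed-cavity mass balance", {
  # rigid cavity: doubling the gas at constant volume doubles absolute pressure
  rigid <- tube_spec(v0 = 1, c_vp = 0)
  expect_equal(gauge_pressure_after_injection(rigid, 1, p_atm = 1033.2), 1033.2)
  expect_equal(gauge_pressure_after_injection(rigid, 0, p_atm = 1033.2), 0)
  # compliant cavity: positive root of c_vp p^2 + (v0 + c_vp p_atm) p - p_atm vi
  sp <- tube_spec(v0 = 1, c_vp = 0.001)
  p <- gauge_pressure_after_injection(sp, 0.5, p_atm = 1000)
  expect_equal(p, (-2 + sqrt(6)) / 0.002, tolerance = 1e-12)
  expect_equal(p, oracle_gauge_pressure(1, 0.001, 0.5, 1000), tolerance = 1e-10)
  expect_equal(p, gauge_pressure_after_injection(sp, 0.5, 1000, "bisection"),
               tolerance = 1e-10)
})

test_that("injection pressure is monotone in volume and in compliance", {
  sp <- tube_spec(v0 = 0.8, c_vp = 0.05)
  vi <- seq(0, 5, by = 0.5)
  p <- gauge_pressure_after_injection(sp, vi)
  expect_true(all(diff(p) > 0))
  cvps <- c(0, 0.01, 0.05, 0.2)
  p_at_2 <- vapply(cvps, function(cv) {
    gauge_pressure_after_injection(tube_spec(v0 = 0.8, c_vp = cv), 2)
  }, numeric(1))
  expect_true(all(diff(p_at_2) < 0))
})

test_that("invasive series respect the unit contract and the seed", {
  sp <- tube_spec("r2", "TIP", v0 = 1, c_vp = 0.001, noise_p = 0, seed = 4)
  steps <- c(0.25, 0.5, 0.75)
  s_cm <- simulate_jesus_series(sp, steps, p_atm = 1000, pressure_unit = "cmH2O")
  s_psi <- simulate_jesus_series(sp, steps, p_atm = 1000, pressure_unit = "PSI")
  expect_equal(s_cm$observations$p_gauge,
               gauge_pressure_after_injection(sp, steps, 1000))
  expect_equal(s_psi$observations$p_gauge,
               s_cm$observations$p_gauge / 70.307)
  spn <- tube_spec("r2", "TIP", noise_p = 2, seed = 12)
  expect_identical(simulate_jesus_series(spn), simulate_jesus_series(spn))
})

test_that("simulated observations always satisfy the physical invariants", {
  set.seed(77)
  for (i in 1:25) {
    sp <- tube_spec("p", "control",
                    d0 = runif(1, 0.5, 4), c_dp = runif(1, 0, 0.1),
                    b_qp = runif(1, 0.05, 1), q0 = runif(1, -5, 5),
                    v0 = runif(1, 0.2, 3), c_vp = runif(1, 0, 0.3),
                    noise_d = runif(1, 0, 0.5), noise_q = runif(1, 0, 3),
                    noise_p = runif(1, 0, 10), seed = NULL)
    u <- simulate_ufd_series(sp, sort(runif(5, 0, 120)) + 1:5 * 1e-6)
    j <- simulate_jesus_series(sp, cumsum(runif(5, 0.1, 1)))
    expect_true(all(u$observations$flow >= 0))
    expect_true(all(u$observations$diameter > 0))
    expect_true(all(j$observations$p_gauge >= 0))
  }
})

test_that("cohorts are balanced, paired, seeded, and hit the target medians", {
  co <- cohort_spec(n_per_group = 4, seed = 8)
  sim <- simulate_cohort(co)
  expect_length(sim$ufd, 8)
  expect_length(sim$jesus, 8)
  expect_equal(table(sim$truth$group), table(rep(c("TIP", "control"), each = 4)),
               ignore_attr = TRUE)
  expect_identical(vapply(sim$ufd, `[[`, "", "specimen_id"),
                   vapply(sim$jesus, `[[`, "", "specimen_id"))
  sim2 <- simulate_cohort(co)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$ufd[[3]]$observations, sim2$ufd[[3]]$observations)

  # degenerate cohort: no biological variation, no noise
  co0 <- cohort_spec(n_per_group = 3, between_specimen_cv = 0,
                     noise_d = 0, noise_q = 0, noise_p = 0, seed = 2)
  est0 <- suppressWarnings(estimate_cohort(simulate_cohort(co0)))
  ctl <- est0$ufd[est0$group == "control"]
  expect_true(max(abs(ctl - ctl[1])) < 1e-12)

  # log-normal median recovery of the ground-truth compliances
  cob <- cohort_spec(n_per_group = 100, between_specimen_cv = 0.1, seed = 31)
  simb <- simulate_cohort(cob)
  med <- tapply(simb$truth$cua_ufd_true, simb$truth$group, median)
  expect_equal(med[["control"]], 0.247, tolerance = 0.05)
  expect_equal(med[["TIP"]], 0.269, tolerance = 0.05)
})

test_that("noise-free simulation makes diameter affine in flow with slope c_dp/b_qp", {
  set.seed(13)
  for (i in 1:10) {
    sp <- tube_spec("aff", "control", d0 = runif(1, 1, 3),
                    c_dp = runif(1, 0.001, 0.1), b_qp = runif(1, 0.05, 1),
                    noise_d = 0, noise_q = 0, seed = NULL)
    s <- simulate_ufd_series(sp, seq(40, 100, by = 15))$observations
    slopes <- diff(s$diameter) / diff(s$flow)
    expect_equal(slopes, rep(sp$c_dp / sp$b_qp, length(slopes)),
                 tolerance = 1e-10)
  }
})
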