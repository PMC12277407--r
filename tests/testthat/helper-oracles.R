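# Independent oracles, implemented by brute force and kept deliberately
# different from the package's algorithms.

# Exact two-sided Mann-Whitney p by explicit enumeration of every subset of
# the combined sample that could have been "group x".
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(length(r), n1)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Lexicographic next-permutation (iterative), distinct from the package's
# recursive prefix-extension generator.
next_permutation <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

# Exact two-sided Spearman p: P(|rho_perm| >= |rho_obs|) over all n!
# permutations, rho computed pair by pair with cor() on ranks.
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  p <- seq_along(y)
  hits <- 0L; total <- 0L
  repeat {
    rho_p <- stats::cor(rx, ry[p])
    if (abs(rho_p) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
    total <- total + 1L
    p <- next_permutation(p)
    if (is.null(p)) break
  }
  hits / total
}

# OLS slope/intercept/SE from the normal equations, written out by hand.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept, slope_se = sqrt(s2 / sxx))
}

# Bisection solver for the sealed-cavity mass balance, independent of both
# package solvers (plain hand-rolled bisection, no uniroot).
oracle_gauge_pressure <- function(v0, c_vp, v_injected, p_atm) {
  if (v_injected == 0) return(0)
  f <- function(p) (p_atm + p) * (v0 + c_vp * p) - p_atm * (v0 + v_injected)
  lo <- 0; hi <- p_atm * v_injected / v0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Convenience: estimate both compliances for every specimen of a cohort.
estimate_cohort <- function(sim, v0 = NULL) {
  ufd <- vapply(sim$ufd, function(s) estimate_ufd_compliance(s)$value,
                numeric(1))
  jes <- mapply(function(s, sp) {
    estimate_jesus_compliance(s, v0 = if (is.null(v0)) sp$v0 else v0)$value
  }, sim$jesus, sim$specs)
  list(ufd = ufd, jesus = jes, group = sim$truth$group)
}
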