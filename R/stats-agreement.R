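#' Median and interquartile range
#'
#' Quantiles use the linear-interpolation convention between order
#' statistics (R's type 7, the common software default).  Reported IQRs
#' depend on this choice, so it is fixed and documented.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4))
median_iqr <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    abort_input("`values` must be a non-empty numeric vector")
  }
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# Exact null distribution of the rank-sum of group 1 under the permutation
# null, with midranks (so ties are handled), via the Streitberg-Roehmel
# shift algorithm.  Midranks doubled to integers; returns the count of
# subsets of size n1 attaining each doubled rank-sum.
rank_sum_distribution <- function(ranks2, n1) {
  total <- sum(ranks2)
  # f[k + 1, s + 1] = number of size-k subsets with doubled rank-sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- n1
    for (k in kmax:1L) {
      idx <- (r + 1L):(total + 1L)
      f[k + 1L, idx] <- f[k + 1L, idx] + f[k, idx - r]
    }
  }
  f[n1 + 1L, ]
}

#' Mann--Whitney (Wilcoxon rank-sum) test, exact for small samples
#'
#' Two-sided rank-sum test.  For combined sample size at most
#' `exact_limit` the p-value is exact under the permutation null, computed
#' from the full null distribution of the rank-sum (midranks, so ties are
#' permitted) via the Streitberg--Roehmel shift algorithm; above that a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.  The two-sided p is twice the smaller tail
#' probability, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest combined n for which the exact distribution
#'   is enumerated (default 20).
#' @return List with `statistic` (U for `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y, exact_limit = 20L) {
  if (length(x) < 1L || length(y) < 1L) abort_input("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    counts <- rank_sum_distribution(as.integer(round(2 * r)), n1)
    total <- sum(counts)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Compare two groups with normality-routed testing
#'
#' Runs Shapiro--Wilk on each group; when both p-values exceed
#' `normality_alpha` the groups are compared with a two-sided Student's
#' t-test and summarized as mean (SD), otherwise with the two-sided
#' Mann--Whitney test (exact for combined n of 20 or fewer) and summarized
#' as median (IQR).  The routing can be overridden with `test`.
#'
#' @param x,y Numeric samples, each of length at least 3 (required by the
#'   normality test).
#' @param groups Length-2 character vector of group labels.
#' @param normality_alpha Threshold on the Shapiro--Wilk p-values (default
#'   0.05, matching the conventional significance level).
#' @param test `"auto"` (default routing), or force `"mann_whitney"` /
#'   `"student_t"`.
#' @return A list of class `group_comparison`: `summaries` (tibble, one row
#'   per group with n, median/q1/q3, mean/sd, and Shapiro--Wilk p),
#'   `test_used`, and `p_value`.
#' @export
#' @examples
#' compare_groups(rnorm(8), rnorm(8, 1))
compare_groups <- function(x, y, groups = c("control", "TIP"),
                           normality_alpha = 0.05,
                           test = c("auto", "mann_whitney", "student_t")) {
  test <- match.arg(test)
  if (length(x) < 3L || length(y) < 3L) {
    abort_input("each group needs at least 3 observations",
                class = "urocomp_insufficient_data")
  }
  # shapiro.test errors on zero-variance input; such data is certainly not
  # Gaussian, so route it to the rank test
  sw_p <- vapply(list(x, y), function(v) {
    if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (test == "auto") {
    test_used <- if (all(sw_p > normality_alpha)) "student_t" else "mann_whitney"
  } else {
    test_used <- test
  }
  p_value <- if (test_used == "student_t") {
    stats::t.test(x, y, var.equal = TRUE)$p.value
  } else {
    mann_whitney(x, y)$p_value
  }
  summaries <- do.call(rbind, Map(function(v, g, swp) {
    mi <- median_iqr(v)
    tibble::tibble(group = g, n = length(v),
                   median = mi[["median"]], q1 = mi[["q1"]], q3 = mi[["q3"]],
                   mean = mean(v), sd = stats::sd(v), normality_p = swp)
  }, list(x, y), as.list(groups), as.list(sw_p)))
  structure(list(summaries = summaries, test_used = test_used,
                 p_value = p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, two-sided p = %.4g\n",
              x$test_used, x$p_value))
  print(x$summaries)
  invisible(x)
}

# All n! permutations of 1..n as a matrix, built by prefix extension.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perm_matrix(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, m * n, n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * m + 1L):(k * m)
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[p], m, n - 1L)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of midranks.  For n
#' at most `exact_limit` (default 9, covering typical n = 8 paired animal
#' cohorts) the two-sided p-value is exact: the full permutation
#' distribution of rho is enumerated and p = P(|rho_perm| >= |rho_obs|).
#' For larger n the usual t-approximation with n - 2 degrees of freedom is
#' used.
#'
#' @param x,y Paired numeric vectors of equal length, n >= 3.
#' @param exact_limit Largest n for which the permutation distribution is
#'   fully enumerated.
#' @return List with `rho`, `p_value`, `n`, and `method` (`"exact_permutation"`
#'   or `"t_approx"`).
#' @export
#' @examples
#' spearman_agreement(1:4, c(2, 1, 3, 4))
spearman_agreement <- function(x, y, exact_limit = 9L) {
  n <- length(x)
  if (length(y) != n) abort_input("`x` and `y` must have equal length")
  if (n < 3L) abort_input("at least 3 pairs are required")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort_input("ranks are constant in one variable; rho is undefined",
                class = "urocomp_degenerate_design")
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    # rho is monotone in the cross-sum S = sum(rx[perm] * ry) for fixed rank
    # multisets, but with ties the permuted rho must be computed per
    # permutation; vectorized as a matrix product over all n! permutations
    P <- perm_matrix(n)
    s <- as.vector(matrix(rx[P], nrow(P), n) %*% ry)
    rho_perm <- (s / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    method <- "t_approx"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Bland--Altman agreement analysis
#'
#' Computes paired differences `d = x - y`, the bias (mean difference),
#' and the limits of agreement `bias +/- z * SD(d)` with the sample SD
#' (n - 1 denominator).  When the two methods report on different scales,
#' `standardize = TRUE` z-scores each method first (a documented deviation
#' from the plain analysis; differences are then in SD units).
#'
#' @param x,y Paired measurements (convention: `x` = non-invasive UFD,
#'   `y` = invasive Jesus, so bias is UFD minus Jesus).
#' @param z Limit multiplier (default 1.96, the 95% normal range).
#' @param standardize Z-score each method before differencing.
#' @return A list of class `bland_altman`: `n_pairs`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `z`, and `table` (per-pair mean and difference,
#'   for plotting).
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(1.1, 2.1, 3.1))
bland_altman <- function(x, y, z = 1.96, standardize = FALSE) {
  n <- length(x)
  if (length(y) != n) abort_input("`x` and `y` must have equal length")
  if (n < 3L) abort_input("at least 3 pairs are required")
  assert_number(z, "z", lower = 0)
  if (standardize) {
    x <- as.vector(scale(x))
    y <- as.vector(scale(y))
  }
  d <- x - y
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(n_pairs = n, bias = bias, sd_diff = sd_d,
         loa_low = bias - z * sd_d, loa_high = bias + z * sd_d, z = z,
         standardized = standardize,
         table = tibble::tibble(mean = (x + y) / 2, difference = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d: bias %.4g, limits of agreement [%.4g, %.4g] (z = %.3g)\n",
    x$n_pairs, x$bias, x$loa_low, x$loa_high, x$z
  ))
  invisible(x)
}

#' Full method-agreement report (Spearman + Bland--Altman)
#'
#' Convenience wrapper pairing [spearman_agreement()] and [bland_altman()]
#' on the same paired measurements.
#'
#' @inheritParams bland_altman
#' @return A list of class `agreement_report` with `n_pairs`,
#'   `spearman_rho`, `spearman_p`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `z`, and the Bland--Altman `table`.
#' @export
method_agreement <- function(x, y, z = 1.96) {
  sp <- spearman_agreement(x, y)
  ba <- bland_altman(x, y, z = z)
  structure(
    list(n_pairs = ba$n_pairs, spearman_rho = sp$rho, spearman_p = sp$p_value,
         spearman_method = sp$method,
         bias = ba$bias, sd_diff = ba$sd_diff,
         loa_low = ba$loa_low, loa_high = ba$loa_high, z = ba$z,
         table = ba$table),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs\n", x$n_pairs))
  cat(sprintf("  Spearman rho = %.3f (p = %.4g, %s)\n",
              x$spearman_rho, x$spearman_p, x$spearman_method))
  cat(sprintf("  Bland-Altman bias = %.4g, limits [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Per-group sample size for a two-group equivalence design
#'
#' Chow's normal-approximation sample size for establishing equivalence of
#' two means within margin `delta`:
#' \deqn{n_2 = \left\lceil \frac{(z_{1-\alpha} + z_{1-\beta/2})^2 \sigma^2 (1 + 1/\kappa)}
#'   {(\delta - |\epsilon|)^2} \right\rceil}
#' where `epsilon` is the expected true difference, `sigma` the standard
#' deviation, `kappa` the allocation ratio n1/n2, and the result is floored
#' at 1.  `design = "paired"` drops the `(1 + 1/kappa)` factor, sizing the
#' number of within-subject pairs instead.
#'
#' @param diff Expected true difference between methods.
#' @param sd Standard deviation of the outcome.
#' @param alpha Significance level (each one-sided test of the equivalence
#'   pair is carried out at this level; `z_{1-alpha}` enters the formula).
#' @param power Target power, `1 - beta`.
#' @param margin Equivalence margin; must exceed `|diff|`.
#' @param ratio Allocation ratio `kappa = n1 / n2` (default 1).
#' @param design `"two_sample"` (default) or `"paired"`.
#' @return Integer sample size per group (or number of pairs).
#' @export
#' @examples
#' equivalence_sample_size(diff = 0.08, sd = 0.07, alpha = 0.05,
#'                         power = 0.9, margin = 0.2)
equivalence_sample_size <- function(diff, sd, alpha = 0.05, power = 0.9,
                                    margin, ratio = 1,
                                    design = c("two_sample", "paired")) {
  design <- match.arg(design)
  assert_number(sd, "sd", lower = 0, strict = TRUE)
  assert_number(alpha, "alpha", lower = 0, strict = TRUE)
  assert_number(power, "power", lower = 0, strict = TRUE)
  assert_number(ratio, "ratio", lower = 0, strict = TRUE)
  if (alpha >= 1 || power >= 1) abort_input("alpha and power must lie in (0, 1)")
  if (!is.finite(margin) && margin > 0) return(1L)
  if (margin <= abs(diff)) {
    abort_input("equivalence margin must exceed |diff|: design is infeasible",
                class = "urocomp_infeasible_design")
  }
  beta <- 1 - power
  z <- stats::qnorm(1 - alpha) + stats::qnorm(1 - beta / 2)
  alloc <- if (design == "two_sample") 1 + 1 / ratio else 1
  n <- z^2 * sd^2 * alloc / (margin - abs(diff))^2
  max(1L, as.integer(ceiling(n - 1e-12)))
}

#' Long-format table for paired-line plots
#'
#' Reshapes paired per-specimen values from two methods into (id, method,
#' value) rows, two per specimen, for within-subject line plots.
#'
#' @param x,y Paired values (method 1 and method 2).
#' @param ids Specimen identifiers.
#' @param methods Length-2 character vector of method labels.
#' @return A tibble with columns `specimen_id`, `method`, `value`.
#' @export
paired_lines_table <- function(x, y, ids, methods = c("UFD", "Jesus")) {
  n <- length(x)
  if (length(y) != n || length(ids) != n) {
    abort_input("`x`, `y` and `ids` must have equal length")
  }
  tibble::tibble(
    specimen_id = rep(as.character(ids), each = 2L),
    method = rep(methods, times = n),
    value = as.vector(rbind(x, y))
  )
}
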