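test_that("median and quartiles follow the linear-interpolation convention", {
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  expect_equal(median_iqr(c(3, 1, 2))[["median"]], 2)
  expect_error(median_iqr(numeric(0)), class = "urocomp_invalid_input")
})

test_that("exact Mann-Whitney reproduces hand-enumerable cases", {
  # complete separation of 3 vs 3: one split per tail out of C(6,3) = 20
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_identical(mann_whitney(c(1, 2, 3), c(4, 5, 6))$method, "exact")
  # identical samples carry no evidence
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(mann_whitney(x, x)$p_value, 1)
})

test_that("exact Mann-Whitney matches full enumeration, with and without ties", {
  set.seed(88)
  for (i in 1:40) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(1:6, n1, replace = TRUE)  # integer draws force frequent ties
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney approximation tracks the exact tail", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(15, 0.8)
  exact <- mann_whitney(x, y, exact_limit = 30)$p_value
  approx <- mann_whitney(x, y, exact_limit = 20)$p_value
  expect_identical(mann_whitney(x, y)$method, "normal_approx")
  expect_equal(approx, exact, tolerance = 0.25)
})

test_that("group comparison routes by Shapiro-Wilk normality", {
  set.seed(12)
  gx <- rnorm(12); gy <- rnorm(12, 0.5)
  cmp_norm <- compare_groups(gx, gy)
  expect_identical(cmp_norm$test_used, "student_t")
  ex <- rexp(12) ^ 3; ey <- rexp(12) ^ 3
  cmp_skew <- compare_groups(ex, ey)
  expect_identical(cmp_skew$test_used, "mann_whitney")
  # forced routing and summary content
  forced <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")
  expect_equal(forced$p_value, 0.1)
  expect_equal(forced$summaries$n, c(3, 3))
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)),
               class = "urocomp_insufficient_data")
})

test_that("the routed comparison holds its type-I error at the nominal level", {
  set.seed(314)
  n_rep <- 1000
  rejections <- sum(replicate(n_rep, {
    compare_groups(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  bounds <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})

test_that("Spearman rho and its exact permutation p are correct on small cases", {
  expect_equal(spearman_agreement(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  id4 <- spearman_agreement(1:4, 1:4)
  expect_equal(id4$rho, 1)
  expect_equal(id4$p_value, 2 / 24)
  expect_identical(id4$method, "exact_permutation")
  expect_error(spearman_agreement(1:3, 1:4), class = "urocomp_invalid_input")
})

test_that("exact Spearman p matches independent full enumeration for n <= 6", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    expect_equal(spearman_agreement(x, y)$p_value, oracle_spearman_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("noisy monotone pairs at n = 8 show strong rank correlation", {
  set.seed(23)
  x <- runif(8)
  y <- x + rnorm(8, 0, 0.02)
  expect_gt(spearman_agreement(x, y)$rho, 0.8)
})

test_that("Bland-Altman bias and limits follow their closed forms", {
  ba <- bland_altman(c(1, 2, 3), c(1.1, 2.1, 3.1))
  expect_equal(ba$bias, -0.1)
  expect_equal(ba$loa_low, -0.1)
  expect_equal(ba$loa_high, -0.1)
  x <- c(2.5, 3.1, 4.2, 5.0)
  same <- bland_altman(x, x)
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
  # limits always bracket the bias with width 2 z sd
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  ba2 <- bland_altman(a, b, z = 2.5)
  expect_lte(ba2$loa_low, ba2$bias)
  expect_gte(ba2$loa_high, ba2$bias)
  expect_equal(ba2$loa_high - ba2$loa_low, 2 * 2.5 * sd(a - b))
  expect_equal(nrow(ba2$table), 20)
})

test_that("equivalence sample size reproduces the published design and limits", {
  expect_identical(
    equivalence_sample_size(diff = 0.08, sd = 0.07, alpha = 0.05,
                            power = 0.9, margin = 0.2, ratio = 1),
    8L
  )
  expect_identical(
    equivalence_sample_size(diff = 0.08, sd = 0.07, alpha = 0.05,
                            power = 0.9, margin = 0.3, ratio = 1),
    3L
  )
  expect_identical(
    equivalence_sample_size(diff = 0, sd = 1, margin = Inf), 1L
  )
  expect_error(
    equivalence_sample_size(diff = 0.3, sd = 0.07, margin = 0.2),
    class = "urocomp_infeasible_design"
  )
})

test_that("equivalence sample size is monotone in its design inputs", {
  margins <- seq(0.12, 0.6, by = 0.04)
  n_margin <- vapply(margins, function(m) {
    equivalence_sample_size(diff = 0.05, sd = 0.1, margin = m)
  }, integer(1))
  expect_true(all(diff(n_margin) <= 0))
  sds <- seq(0.05, 0.4, by = 0.05)
  n_sd <- vapply(sds, function(s) {
    equivalence_sample_size(diff = 0.05, sd = s, margin = 0.2)
  }, integer(1))
  expect_true(all(diff(n_sd) >= 0))
  powers <- c(0.7, 0.8, 0.9, 0.95)
  n_pow <- vapply(powers, function(p) {
    equivalence_sample_size(diff = 0.05, sd = 0.1, power = p, margin = 0.2)
  }, integer(1))
  expect_true(all(diff(n_pow) >= 0))
  # paired design needs no between-group allocation factor
  expect_lt(
    equivalence_sample_size(diff = 0.08, sd = 0.07, margin = 0.2,
                            design = "paired"),
    equivalence_sample_size(diff = 0.08, sd = 0.07, margin = 0.2)
  )
})

test_that("paired-line tables are long, ordered, and label-preserving", {
  tbl <- paired_lines_table(c(0.25, 0.26), c(0.14, 0.18), c("r1", "r2"))
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$specimen_id, c("r1", "r1", "r2", "r2"))
  expect_equal(tbl$method, c("UFD", "Jesus", "UFD", "Jesus"))
  expect_equal(tbl$value, c(0.25, 0.14, 0.26, 0.18))
  empty <- paired_lines_table(numeric(0), numeric(0), character(0))
  expect_equal(nrow(empty), 0)
})

test_that("the combined agreement report carries both analyses consistently", {
  set.seed(9)
  x <- runif(10, 0.2, 0.3)
  y <- x - 0.1 + rnorm(10, 0, 0.01)
  rep <- method_agreement(x, y)
  expect_equal(rep$n_pairs, 10)
  expect_equal(rep$spearman_rho, spearman_agreement(x, y)$rho)
  expect_equal(rep$bias, mean(x - y))
  expect_equal(rep$loa_high - rep$loa_low, 2 * 1.96 * sd(x - y))
})
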