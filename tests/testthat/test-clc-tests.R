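test_that("the CLC statistic reproduces forced scalar cases", {
  # K = 1: everything is scalar, statistic = T^2
  r <- clc_statistic(1.7, matrix(1), matrix(1))
  expect_equal(r$statistic, 1.7^2)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, pchisq(1.7^2, 1, lower.tail = FALSE))
  # identity membership (L = K) collapses to the omnibus quadratic form
  set.seed(21)
  s <- rand_corr(4)
  tv <- rnorm(4)
  r <- clc_statistic(tv, s, diag(1, 4))
  expect_equal(r$statistic, drop(t(tv) %*% solve(s) %*% tv), tolerance = 1e-10)
  expect_equal(r$df, 4L)
})

test_that("the CLC statistic matches the brute-force matrix oracle", {
  # frozen 2-trait example
  s <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  r <- clc_statistic(c(2, 2), s, matrix(1, 2, 1))
  expect_equal(r$statistic, oracle_clc_stat(c(2, 2), s, matrix(1, 2, 1)),
               tolerance = 1e-12)
  expect_equal(r$df, 1L)
  # random memberships
  set.seed(22)
  for (i in 1:30) {
    K <- sample(2:8, 1)
    s <- rand_corr(K)
    tv <- rnorm(K, sd = 2)
    L <- sample(1:K, 1)
    cl <- c(seq_len(L), sample(seq_len(L), K - L, replace = TRUE))
    B <- oracle_membership(cl)
    expect_equal(clc_statistic(tv, s, B)$statistic,
                 oracle_clc_stat(tv, s, B), tolerance = 1e-8)
  }
  expect_error(clc_statistic(c(1, 2), diag(2), matrix(c(1, 2), 2, 1)), "0/1")
})

test_that("component p-values agree with per-cut CLC statistics", {
  set.seed(23)
  s <- rand_corr(6)
  tv <- rnorm(6)
  ps <- component_pvalues(tv, s)
  expect_length(ps, 6L)
  cuts <- all_cuts(s)
  for (L in 1:6) {
    expect_equal(ps[L], clc_statistic(tv, s, cuts[[L]])$p_value,
                 tolerance = 1e-9)
  }
  # K = 1 gives the single chi-square(1) p-value
  expect_equal(component_pvalues(2, matrix(1)),
               pchisq(4, 1, lower.tail = FALSE))
})

test_that("cauchy combination satisfies its algebraic identities", {
  # all p = 0.5 maps to exactly 0.5 (tan(0) = 0)
  expect_identical(cauchy_combine(rep(0.5, 7)), 0.5)
  # K = 1 is the identity on p
  for (p in c(1e-12, 0.01, 0.3, 0.77, 0.999)) {
    expect_equal(cauchy_combine(p), p, tolerance = 1e-9)
  }
  # frozen worked case: direct evaluation of the two displayed formulas
  p <- c(0.01, 0.5)
  expected <- 0.5 - atan(mean(tan((0.5 - p) * pi))) / pi
  expect_equal(cauchy_combine(p), expected, tolerance = 1e-12)
  # monotone: decreasing any p weakly decreases the combination
  expect_lt(cauchy_combine(c(0.005, 0.5)), cauchy_combine(c(0.01, 0.5)))
  # weights must be a probability vector
  expect_error(cauchy_combine(c(0.1, 0.2), weights = c(0.7, 0.7)), "sum to 1")
  expect_equal(cauchy_combine(c(0.01, 0.5), weights = c(1, 0)), 0.01,
               tolerance = 1e-9)
})

test_that("cauchy combination guards the boundary and extreme tails", {
  expect_warning(p0 <- cauchy_combine(c(0, 0.5)), "exactly 0")
  expect_gt(p0, 0)
  expect_warning(p1 <- cauchy_combine(c(1, 0.5)), "exactly 1")
  expect_lt(p1, 1)
  # tiny p survive without overflow and keep ACAT's tail identity:
  # combining K tiny equal p's returns approximately K * p / K = p
  p <- cauchy_combine(rep(1e-40, 4))
  expect_equal(p, 1e-40, tolerance = 1e-4)
})

test_that("ceCLC equals a straight-line reimplementation of the chain", {
  set.seed(24)
  for (i in 1:10) {
    K <- sample(c(3, 5, 9), 1)
    s <- rand_corr(K)
    tv <- rnorm(K, sd = 1.5)
    r <- ceclc_test(tv, s)
    expect_equal(r$p_value, oracle_ceclc_p(tv, s), tolerance = 1e-8)
    expect_length(r$component_p, K)
    expect_true(all(r$component_p > 0 & r$component_p <= 1))
  }
  # K = 1: identical to the chi-square(1) p-value of T^2
  r1 <- ceclc_test(2.3, matrix(1))
  expect_equal(r1$p_value, pchisq(2.3^2, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("ceCLC never touches the random-number generator", {
  set.seed(25)
  s <- rand_corr(8)
  tv <- rnorm(8)
  before <- .Random.seed
  invisible(ceclc_test(tv, s))
  invisible(component_pvalues(tv, s))
  invisible(cauchy_combine(c(0.01, 0.2, 0.9)))
  expect_identical(.Random.seed, before)
})

test_that("min-p CLC is reproducible and respects its estimator bounds", {
  set.seed(26)
  s <- rand_corr(4)
  tv <- rnorm(4)
  r1 <- clc_minp_test(tv, s, n_mc = 500, seed = 99)
  r2 <- clc_minp_test(tv, s, n_mc = 500, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, min(component_pvalues(tv, s)))
  expect_gte(r1$p_value, 1 / 501)
  expect_lte(r1$p_value, 1)
  # an observed min-p larger than every simulated minimum gives exactly 1
  r_null <- clc_minp_test(c(0, 0, 0, 0) + 1e-9, s, n_mc = 200, seed = 1)
  expect_equal(r_null$p_value, 1)
  expect_warning(clc_minp_test(tv, s, n_mc = 50, seed = 1), "coarse")
})

test_that("min-p CLC Monte-Carlo p is self-consistent across resolutions", {
  # 2 independent traits: a modest-mc run must agree with a 1e5-draw rerun
  set.seed(27)
  tv <- c(1.8, -0.6)
  s <- diag(2)
  p_small <- clc_minp_test(tv, s, n_mc = 2000, seed = 5)$p_value
  p_big <- clc_minp_test(tv, s, n_mc = 1e5, seed = 6)$p_value
  expect_lt(abs(p_small - p_big), 3 * sqrt(p_big * (1 - p_big) / 2000))
  # K = 1: min-p is the single chi-square p and MC must sit within
  # binomial error of it
  p1 <- pchisq(1.4^2, 1, lower.tail = FALSE)
  r1 <- clc_minp_test(1.4, matrix(1), n_mc = 1e4, seed = 7)
  expect_equal(r1$statistic, p1, tolerance = 1e-12)
  expect_lt(abs(r1$p_value - p1), 3 * sqrt(p1 * (1 - p1) / 1e4))
})

test_that("O'Brien and omnibus are exactly their CLC special cases", {
  set.seed(28)
  for (i in 1:1000) {
    K <- sample(2:6, 1)
    s <- rand_corr(K)
    tv <- rnorm(K)
    ob <- obrien_test(tv, s)
    om <- omnibus_test(tv, s)
    expect_identical(ob$statistic,
                     clc_statistic(tv, s, matrix(1L, K, 1L))$statistic)
    expect_identical(om$statistic,
                     clc_statistic(tv, s, diag(1L, K))$statistic)
  }
  # identity correlation closed forms
  tv <- c(1, 2, 3)
  expect_equal(obrien_test(tv, diag(3))$statistic, sum(tv)^2 / 3,
               tolerance = 1e-10)
  expect_equal(omnibus_test(tv, diag(3))$statistic, sum(tv^2),
               tolerance = 1e-10)
  expect_equal(obrien_test(2.2, matrix(1))$statistic, 2.2^2)
  expect_equal(omnibus_test(2.2, matrix(1))$statistic, 2.2^2)
})

test_that("ceCLC and min-p CLC rank null datasets concordantly", {
  # both aggregate the same p_L profile, so their p-values should be
  # strongly rank-correlated over null replicates
  spec <- factor_model_spec(model = 2, K = 10, N = 400, beta = 0)
  cfg <- experiment_config(spec, n_replicates = 300,
                           methods = c("ceclc", "clc"), mc_for_clc = 500,
                           seed = 31)
  res <- suppressWarnings(run_type1(cfg))
  pm <- res$p_values
  expect_gt(cor(pm[, "ceclc"], pm[, "clc"], method = "spearman"), 0.8)
})

test_that("broom and ggplot2 methods expose test results tidily", {
  set.seed(29)
  s <- rand_corr(5)
  tv <- rnorm(5)
  fit <- ceclc_test(tv, s)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$L, 1:5)
  expect_equal(td$p_value, unname(fit$component_p))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$method, "ceclc")
  expect_equal(gl$p_value, fit$p_value)
  expect_s3_class(autoplot(fit), "ggplot")
  om <- glance(omnibus_test(tv, s))
  expect_equal(om$df, 5L)
})
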