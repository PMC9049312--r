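test_that("score statistic matches the forced closed-form cases", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 0)
  # phenotype equal to the genotype vector forces T = sqrt(N)
  expect_equal(score_statistic(g, g), sqrt(length(g)))
  # phenotype orthogonal to the centered genotype forces T = 0
  y <- residuals(lm(rnorm(8) ~ g))
  expect_equal(score_statistic(g, y), 0, tolerance = 1e-12)
})

test_that("score statistic agrees with the two-loop arithmetic oracle", {
  g <- c(0, 1, 2, 1)
  y <- c(1.2, 0.7, 2.1, 1.0)
  expect_equal(score_statistic(g, y), oracle_score(g, y))
  # property: random small inputs
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    g <- rbinom(n, 2, 0.4)
    if (var(g) == 0) next
    y <- rnorm(n)
    expect_equal(score_statistic(g, y), oracle_score(g, y), tolerance = 1e-12)
  }
})

test_that("score statistic is location invariant and sign equivariant", {
  set.seed(7)
  g <- rbinom(40, 2, 0.3)
  y <- rnorm(40)
  t0 <- score_statistic(g, y)
  expect_equal(score_statistic(g + 3.7, y), t0, tolerance = 1e-10)
  expect_equal(score_statistic(g, y - 11.2), t0, tolerance = 1e-10)
  expect_equal(score_statistic(g, -y), -t0, tolerance = 1e-10)
  expect_equal(score_statistic(g, 2.5 * y), t0, tolerance = 1e-10)
})

test_that("constant genotype or phenotype raises a zero-variance error", {
  expect_error(score_statistic(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(score_statistic(rbinom(10, 2, 0.5), rep(2, 10)), "zero variance")
})

test_that("covariate adjustment residualizes via the normal equations", {
  g <- c(0, 1, 2, 1, 0)
  z <- matrix(1:5, ncol = 1)
  Y <- cbind(a = c(0.3, 1.1, 0.8, 1.9, 1.4))
  adj <- adjust_for_covariates(Y, g, z)
  # normal-equations oracle
  X <- cbind(1, z)
  beta_g <- solve(t(X) %*% X, t(X) %*% g)
  expect_equal(adj$genotypes, drop(g - X %*% beta_g), tolerance = 1e-12)
  beta_y <- solve(t(X) %*% X, t(X) %*% Y[, 1])
  expect_equal(unname(adj$phenotypes[, 1]), drop(Y[, 1] - X %*% beta_y),
               tolerance = 1e-12)
  expect_equal(mean(adj$genotypes), 0, tolerance = 1e-12)
  expect_equal(mean(adj$phenotypes[, 1]), 0, tolerance = 1e-12)
})

test_that("covariates orthogonal to the data leave only centering", {
  set.seed(1)
  n <- 24
  g <- rbinom(n, 2, 0.3)
  Y <- matrix(rnorm(2 * n), n, 2)
  z <- rnorm(n)
  z <- residuals(lm(z ~ cbind(g, Y)))  # orthogonal to g and Y after centering
  adj <- adjust_for_covariates(Y, g, matrix(z, ncol = 1))
  expect_equal(adj$genotypes, g - mean(g), tolerance = 1e-10)
  expect_equal(unname(adj$phenotypes), sweep(Y, 2, colMeans(Y)),
               tolerance = 1e-10)
})

test_that("degenerate covariate designs are rejected with named columns", {
  g <- rbinom(10, 2, 0.4)
  Y <- matrix(rnorm(10))
  Z <- cbind(x1 = rnorm(10), zero = 0)
  expect_error(adjust_for_covariates(Y, g, Z), "zero")
  expect_error(adjust_for_covariates(Y[1:3, , drop = FALSE], g[1:3],
                                     matrix(rnorm(6), 3, 2)), "too few samples")
})

test_that("score_summary returns T and the Pearson correlation of Y", {
  set.seed(3)
  n <- 60
  g <- rbinom(n, 2, 0.3)
  base <- rnorm(n)
  Y <- cbind(a = base + rnorm(n, sd = 0.5), b = rnorm(n), c = rnorm(n))
  s <- score_summary(Y, g)
  expect_s3_class(s, "score_summary")
  expect_equal(unname(s$t_stat),
               apply(Y, 2, function(y) oracle_score(g, y)) |> unname(),
               tolerance = 1e-12)
  expect_equal(s$sigma_hat["a", "b"], oracle_pearson(Y[, "a"], Y[, "b"]),
               tolerance = 1e-12)
  expect_equal(diag(s$sigma_hat), c(a = 1, b = 1, c = 1))
  expect_equal(s$sigma_hat, t(s$sigma_hat))
  expect_true(all(eigen(s$sigma_hat, only.values = TRUE)$values > -1e-10))
  # K = 1 collapses to the trivial correlation
  expect_equal(unname(score_summary(Y[, 1, drop = FALSE], g)$sigma_hat),
               matrix(1))
})

test_that("T and sigma_hat are invariant to trait location and positive scale", {
  set.seed(4)
  g <- rbinom(50, 2, 0.25)
  Y <- matrix(rnorm(150), 50, 3)
  s0 <- score_summary(Y, g)
  Y2 <- Y
  Y2[, 2] <- 5.5 + Y[, 2]
  Y2[, 3] <- 3 * Y[, 3]
  s2 <- score_summary(Y2, g)
  expect_equal(s2$t_stat, s0$t_stat, tolerance = 1e-10)
  expect_equal(s2$sigma_hat, s0$sigma_hat, tolerance = 1e-10)
})

test_that("duplicated traits give a unit off-diagonal (ridge handles inversion)", {
  set.seed(5)
  g <- rbinom(40, 2, 0.3)
  y <- rnorm(40)
  s <- score_summary(cbind(y, y), g)
  expect_equal(unname(s$sigma_hat[1, 2]), 1, tolerance = 1e-12)
  # downstream tests still produce finite p-values after the ridge
  expect_warning(res <- ceclc_test(s$t_stat, s$sigma_hat), "ridge")
  expect_true(is.finite(res$p_value))
  expect_true(all(is.finite(res$component_p)))
})

test_that("score statistics are null-calibrated and approximately normal", {
  set.seed(11)
  n_rep <- 2000
  N <- 1000
  K <- 5
  tmat <- matrix(NA_real_, n_rep, K)
  for (r in seq_len(n_rep)) {
    g <- rbinom(N, 2, 0.3)
    Y <- matrix(rnorm(N * K), N, K)
    tmat[r, ] <- ceclc:::.score_vector(Y, g)
  }
  v <- apply(tmat, 2, var)
  expect_true(all(v > 0.9 & v < 1.1))
  expect_gt(shapiro.test(tmat[, 1])$p.value, 0.001)
})

test_that("sign alignment flips negative-correlation traits only", {
  set.seed(6)
  base <- rnorm(100)
  Y <- sapply(1:4, function(i) base + rnorm(100, sd = 0.7))
  r0 <- cor(Y)
  a0 <- align_signs(Y)
  expect_false(any(a0$flipped))
  expect_equal(a0$phenotypes, Y)
  # flip two known-positive columns; alignment must restore them
  Yf <- Y
  Yf[, c(2, 4)] <- -Yf[, c(2, 4)]
  a <- align_signs(Yf)
  expect_equal(which(a$flipped), c(2L, 4L))
  expect_equal(cor(a$phenotypes), r0, tolerance = 1e-12)
  expect_true(all(cor(a$phenotypes[, 1], a$phenotypes) >= 0))
  expect_error(align_signs(Y[, 1, drop = FALSE]), "at least two")
})
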