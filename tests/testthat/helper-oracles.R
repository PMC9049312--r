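# Independent oracles: deliberately naive implementations of the displayed
# formulas, kept free of the package's internal code paths.

# two-loop score statistic U / sqrt(V)
oracle_score <- function(g, y) {
  n <- length(g)
  gb <- mean(g)
  yb <- mean(y)
  U <- 0
  for (i in seq_len(n)) U <- U + y[i] * (g[i] - gb)
  ssy <- 0
  ssg <- 0
  for (i in seq_len(n)) {
    ssy <- ssy + (y[i] - yb)^2
    ssg <- ssg + (g[i] - gb)^2
  }
  U / sqrt(ssy * ssg / n)
}

# brute-force Pearson correlation of two columns
oracle_pearson <- function(x, y) {
  n <- length(x)
  xm <- mean(x); ym <- mean(y)
  num <- sum((x - xm) * (y - ym))
  num / sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

# the displayed CLC quadratic form, evaluated literally with solve()
oracle_clc_stat <- function(tvec, sigma, B) {
  W <- t(B) %*% solve(sigma)
  wt <- W %*% tvec
  drop(t(wt) %*% solve(W %*% sigma %*% t(W)) %*% wt)
}

# membership matrix from a plain cutree partition
oracle_membership <- function(cl) {
  L <- max(cl)
  B <- matrix(0, length(cl), L)
  B[cbind(seq_along(cl), cl)] <- 1
  B
}

# straight-line reimplementation of the whole ceCLC chain
oracle_ceclc_p <- function(tvec, sigma, linkage = "average") {
  K <- length(tvec)
  hc <- stats::hclust(stats::as.dist(1 - sigma), method = linkage)
  ps <- vapply(seq_len(K), function(L) {
    cl <- if (L == K) seq_len(K) else stats::cutree(hc, k = L)
    stat <- oracle_clc_stat(tvec, sigma, oracle_membership(cl))
    stats::pchisq(stat, df = L, lower.tail = FALSE)
  }, numeric(1))
  stat <- mean(tan((0.5 - ps) * pi))
  0.5 - atan(stat) / pi
}

# a random well-conditioned correlation matrix
rand_corr <- function(K, n = K + 20) {
  stats::cor(matrix(stats::rnorm(n * K), n, K))
}

# partition sets at one cut, independent of column labelling
partition_sets <- function(B) {
  cl <- apply(B, 1L, which.max)
  unname(lapply(split(seq_along(cl), cl), sort))
}
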