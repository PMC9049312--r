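#' @keywords internal
new_mt_test <- function(method, statistic, df, p_value, component_p = NULL,
                        mc_replicates = NULL) {
  structure(
    list(method = method, statistic = statistic, df = df, p_value = p_value,
         component_p = component_p, mc_replicates = mc_replicates),
    class = "mt_test")
}

#' Clustered linear combination chi-square statistic
#'
#' Evaluates the CLC test statistic
#' \eqn{T_{CLC}^L = (WT)^T (W \hat\Sigma W^T)^{-1} (WT)} with
#' \eqn{W = B^T \hat\Sigma^{-1}}, which combines the per-trait score
#' statistics linearly within each cluster and quadratically across the L
#' clusters. Under no association it follows a chi-square distribution with
#' L degrees of freedom.
#'
#' A near-singular `sigma_hat` (e.g. duplicated traits) is regularized by
#' adding a ridge of `1e-8` to its diagonal, with a warning.
#'
#' @param t_stat Length-K vector of per-trait score statistics.
#' @param sigma_hat K x K trait correlation matrix estimating the null
#'   covariance of `t_stat`.
#' @param B K x L 0/1 membership matrix assigning each trait to one cluster
#'   (see [cut_tree()]).
#' @return An object of class `mt_test` with fields `method`, `statistic`,
#'   `df` (= L), and `p_value` (upper chi-square tail).
#' @examples
#' clc_statistic(c(2, 2), diag(2), matrix(1, 2, 1))
#' @export
clc_statistic <- function(t_stat, sigma_hat, B) {
  K <- length(t_stat)
  .assert_square_corr(sigma_hat)
  B <- as.matrix(B)
  if (nrow(sigma_hat) != K || nrow(B) != K) {
    abort("`t_stat`, `sigma_hat` and `B` disagree on the number of traits")
  }
  if (!all(B %in% c(0, 1)) || any(rowSums(B) != 1) || any(colSums(B) < 1)) {
    abort("`B` must be 0/1 with one cluster per trait and no empty cluster")
  }
  L <- ncol(B)
  Rchol <- .chol_prec(sigma_hat)
  sinv <- chol2inv(Rchol)
  W <- crossprod(B, sinv)
  wt <- W %*% t_stat
  M <- W %*% sigma_hat %*% t(W)
  stat <- drop(crossprod(wt, solve(M, wt)))
  new_mt_test("clc", stat, L, pchisq(stat, df = L, lower.tail = FALSE))
}

#' CLC p-values for every number of clusters
#'
#' Clusters the traits hierarchically on `1 - sigma_hat`, computes the CLC
#' chi-square statistic for each cut L = 1..K, and returns the vector of
#' upper-tail p-values \eqn{p_1, \dots, p_K}. This is the p-value profile
#' that both the ceCLC Cauchy combination and the min-p CLC aggregate.
#'
#' @inheritParams clc_statistic
#' @inheritParams build_tree
#' @param warn_ridge Warn when a ridge is applied to `sigma_hat`? Set to
#'   `FALSE` inside high-volume simulation loops.
#' @return Numeric vector of length K; element L is the p-value of the
#'   L-cluster statistic against chi-square with L degrees of freedom.
#' @export
component_pvalues <- function(t_stat, sigma_hat,
                              linkage = c("average", "complete", "single"),
                              warn_ridge = TRUE) {
  linkage <- match.arg(linkage)
  K <- length(t_stat)
  .assert_square_corr(sigma_hat)
  if (nrow(sigma_hat) != K) abort("`sigma_hat` must be K x K")
  Rchol <- .chol_prec(sigma_hat, warn = warn_ridge)
  sinv <- chol2inv(Rchol)
  cl <- .cut_matrix(sigma_hat, linkage)
  stats <- .clc_profile_cpp(matrix(t_stat, nrow = 1L), sinv, cl)[1L, ]
  pchisq(stats, df = seq_len(K), lower.tail = FALSE)
}

#' Cauchy combination of (possibly dependent) p-values
#'
#' Aggregates p-values by the ACAT rule: each p is transformed to a
#' standard Cauchy variate \eqn{\tan\{(0.5 - p)\pi\}}, the transforms are
#' averaged with the given weights, and the combined p-value is the upper
#' Cauchy tail of the average. The heavy Cauchy tail makes the combination
#' insensitive to dependence among the inputs.
#'
#' For p below `1e-15` the transform is replaced by the asymptotically
#' exact tail form \eqn{1/(p\pi)} to avoid overflow. Boundary inputs are
#' nudged inward with a warning: p = 0 becomes `1e-300`, p = 1 becomes
#' `1 - 1e-15`.
#'
#' @param p Vector of p-values in (0, 1).
#' @param weights Optional non-negative weights summing to 1; equal weights
#'   by default.
#' @return The combined p-value (a single number in (0, 1)).
#' @examples
#' cauchy_combine(c(0.01, 0.5))
#' @export
cauchy_combine <- function(p, weights = NULL) {
  if (length(p) == 0L) abort("no p-values to combine")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warn("p-value of exactly 0 replaced by 1e-300")
    p[p == 0] <- 1e-300
  }
  if (any(p == 1)) {
    warn("p-value of exactly 1 replaced by 1 - 1e-15")
    p[p == 1] <- 1 - 1e-15
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(p), length(p))
  } else {
    if (length(weights) != length(p) || any(weights < 0)) {
      abort("`weights` must be non-negative and match `p` in length")
    }
    if (abs(sum(weights) - 1) > 1e-8) abort("`weights` must sum to 1")
  }
  stat <- sum(weights * .cauchy_transform(p))
  pcauchy(stat, lower.tail = FALSE)
}

# tan((0.5 - p) * pi) with the small-p tail guard 1/(p * pi)
.cauchy_transform <- function(p) {
  out <- numeric(length(p))
  tiny <- p < 1e-15
  out[tiny] <- 1 / (p[tiny] * pi)
  out[!tiny] <- tan((0.5 - p[!tiny]) * pi)
  out
}

#' The ceCLC test: Cauchy-combined clustered linear combinations
#'
#' The computationally efficient CLC test. The CLC p-value profile
#' \eqn{p_1, \dots, p_K} over all cluster counts is combined with equal
#' weights into \eqn{T_{ceCLC} = \frac{1}{K}\sum_L \tan\{(0.5 - p_L)\pi\}},
#' whose null distribution is approximately standard Cauchy, so the
#' p-value is the closed form \eqn{0.5 - \arctan(T_{ceCLC})/\pi}. No
#' Monte-Carlo simulation is involved anywhere.
#'
#' @inheritParams component_pvalues
#' @return An `mt_test` with `method = "ceclc"`, the Cauchy statistic, its
#'   closed-form `p_value`, and the profile `component_p`.
#' @examples
#' s <- score_summary(matrix(rnorm(500), 100, 5), rbinom(100, 2, 0.3))
#' ceclc_test(s$t_stat, s$sigma_hat)
#' @export
ceclc_test <- function(t_stat, sigma_hat,
                       linkage = c("average", "complete", "single"),
                       warn_ridge = TRUE) {
  ps <- component_pvalues(t_stat, sigma_hat, linkage, warn_ridge = warn_ridge)
  K <- length(ps)
  stat <- mean(.cauchy_transform(ps))
  new_mt_test("ceclc", stat, NA_integer_,
              pcauchy(stat, lower.tail = FALSE), component_p = ps)
}

#' The original min-p CLC test with a Monte-Carlo null
#'
#' The reference test that ceCLC accelerates: the observed statistic is
#' \eqn{\min_L p_L}, which has no closed-form null distribution, so its
#' p-value is estimated by simulation. Null score vectors are drawn from
#' \eqn{MVN(0, \hat\Sigma)} and the min-p statistic is recomputed for each
#' draw using the same membership matrices as the observed data (the
#' clustering depends only on \eqn{\hat\Sigma}, which is fixed across
#' draws). The add-one estimator \eqn{(1 + \#\{t' \le t^*\})/(n_{mc} + 1)}
#' keeps the p-value strictly positive.
#'
#' @inheritParams component_pvalues
#' @param n_mc Number of Monte-Carlo null draws (values below 100 trigger a
#'   granularity warning).
#' @param seed Optional seed making the draw reproducible.
#' @return An `mt_test` with `method = "clc"`, `statistic` = min p_L, the
#'   Monte-Carlo `p_value`, `component_p`, and `mc_replicates`.
#' @export
clc_minp_test <- function(t_stat, sigma_hat, n_mc = 1000, seed = NULL,
                          linkage = c("average", "complete", "single"),
                          warn_ridge = TRUE) {
  linkage <- match.arg(linkage)
  n_mc <- as.integer(n_mc)
  if (n_mc < 1L) abort("`n_mc` must be positive")
  if (n_mc < 100L) {
    warn(sprintf("n_mc = %d gives a coarse p-value (granularity 1/%d)",
                 n_mc, n_mc + 1L))
  }
  K <- length(t_stat)
  .assert_square_corr(sigma_hat)
  Rchol <- .chol_prec(sigma_hat, warn = warn_ridge)
  sinv <- chol2inv(Rchol)
  cl <- .cut_matrix(sigma_hat, linkage)
  obs_stats <- .clc_profile_cpp(matrix(t_stat, nrow = 1L), sinv, cl)[1L, ]
  obs_p <- pchisq(obs_stats, df = seq_len(K), lower.tail = FALSE)
  t_star <- min(obs_p)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(rnorm(n_mc * K), n_mc, K) %*% Rchol
  null_stats <- .clc_profile_cpp(draws, sinv, cl)
  null_p <- pchisq(null_stats, df = rep(seq_len(K), each = n_mc),
                   lower.tail = FALSE)
  dim(null_p) <- dim(null_stats)
  null_min <- apply(null_p, 1L, min)
  p_mc <- (1 + sum(null_min <= t_star)) / (n_mc + 1)
  new_mt_test("clc", t_star, NA_integer_, p_mc, component_p = obs_p,
              mc_replicates = n_mc)
}

#' O'Brien linear combination test
#'
#' Combines the per-trait score statistics in a single optimal linear
#' combination, here realized as the one-cluster special case of the CLC
#' statistic (B a column of ones), giving a chi-square statistic with 1
#' degree of freedom. Powerful when all effects point the same way,
#' sensitive to sign heterogeneity.
#'
#' @inheritParams clc_statistic
#' @return An `mt_test` with `method = "obrien"` and `df = 1`.
#' @export
obrien_test <- function(t_stat, sigma_hat) {
  out <- clc_statistic(t_stat, sigma_hat, matrix(1L, length(t_stat), 1L))
  out$method <- "obrien"
  out
}

#' Omnibus chi-square test
#'
#' The no-clustering joint test \eqn{T^T \hat\Sigma^{-1} T \sim \chi^2_K},
#' equivalently the CLC statistic with identity membership (every trait its
#' own cluster).
#'
#' @inheritParams clc_statistic
#' @return An `mt_test` with `method = "omnibus"` and `df = K`.
#' @export
omnibus_test <- function(t_stat, sigma_hat) {
  out <- clc_statistic(t_stat, sigma_hat, diag(1L, length(t_stat)))
  out$method <- "omnibus"
  out
}

#' @export
print.mt_test <- function(x, ...) {
  cat("<mt_test> method: ", x$method, "\n", sep = "")
  cat("  statistic = ", format(x$statistic, digits = 6),
      if (!is.na(x$df %||% NA)) paste0("  (df = ", x$df, ")"),
      "\n  p-value   = ", format(x$p_value, digits = 6), "\n", sep = "")
  if (!is.null(x$component_p)) {
    cat("  component p-values (L = 1..", length(x$component_p), "):\n", sep = "")
    print(signif(x$component_p, 4))
  }
  if (!is.null(x$mc_replicates)) {
    cat("  Monte-Carlo replicates: ", x$mc_replicates, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the per-cluster-count p-value profile of a test
#'
#' @param x An `mt_test`.
#' @param ... Unused.
#' @return A tibble with one row per cluster count L (or a single row when
#'   the method has no profile), with columns `L` and `p_value`.
#' @method tidy mt_test
#' @export
tidy.mt_test <- function(x, ...) {
  if (is.null(x$component_p)) {
    return(tibble::tibble(L = x$df, p_value = x$p_value))
  }
  tibble::tibble(L = seq_along(x$component_p), p_value = x$component_p)
}

#' One-row summary of a multi-trait test
#'
#' @param x An `mt_test`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `mc_replicates`.
#' @method glance mt_test
#' @export
glance.mt_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    df = if (is.null(x$df)) NA_integer_ else x$df,
    p_value = x$p_value,
    mc_replicates = if (is.null(x$mc_replicates)) NA_integer_ else x$mc_replicates
  )
}

#' Plot the p-value profile of a multi-trait test
#'
#' @param object An `mt_test` carrying component p-values.
#' @param ... Unused.
#' @return A ggplot of -log10(p_L) against the number of clusters L.
#' @method autoplot mt_test
#' @export
autoplot.mt_test <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$L, y = -log10(.data$p_value))) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters (L)",
                  y = expression(-log[10](p[L])),
                  title = paste0(object$method, " p-value profile"),
                  subtitle = paste0("combined p = ",
                                    format(object$p_value, digits = 4))) +
    ggplot2::theme_minimal()
}
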