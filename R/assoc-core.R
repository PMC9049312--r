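#' Per-trait score statistic for genetic association
#'
#' Computes the score statistic \eqn{T = U/\sqrt{V}} for one phenotype
#' against one genotype vector, where \eqn{U = \sum_i y_i (g_i - \bar g)} and
#' \eqn{V = \frac{1}{n}\sum_i (y_i - \bar y)^2 \sum_i (g_i - \bar g)^2}.
#' Under no association \eqn{T} is approximately standard normal, for
#' quantitative phenotypes and for binary phenotypes coded 0/1 alike.
#'
#' @param genotypes Numeric vector: minor-allele counts in \{0, 1, 2\}, or
#'   real-valued residuals after covariate adjustment.
#' @param phenotype Numeric vector of the same length: one trait (binary
#'   traits coded 0/1), or its covariate-adjusted residuals.
#' @return A single numeric score statistic.
#' @examples
#' g <- c(0, 1, 2, 1, 0, 2)
#' score_statistic(g, g + rnorm(6, sd = 0.1))
#' @export
score_statistic <- function(genotypes, phenotype) {
  if (length(genotypes) != length(phenotype)) {
    abort("`genotypes` and `phenotype` must have the same length")
  }
  if (anyNA(genotypes) || anyNA(phenotype)) {
    abort("missing values; drop incomplete rows before testing")
  }
  drop(.score_vector(matrix(phenotype, ncol = 1L), genotypes))
}

#' Residualize genotypes and phenotypes on covariates
#'
#' Replaces the genotype vector and every phenotype column by the residuals
#' of an ordinary least-squares fit on an intercept plus the covariates, so
#' that downstream score statistics are covariate-adjusted. Binary
#' phenotypes are residualized with the same linear fit.
#'
#' @param phenotypes Numeric matrix (N x K) of phenotypes.
#' @param genotypes Numeric vector of length N.
#' @param covariates Numeric matrix (N x p), p >= 1.
#' @return A list with elements `phenotypes` and `genotypes`, each replaced
#'   by mean-zero residuals.
#' @export
adjust_for_covariates <- function(phenotypes, genotypes, covariates) {
  phenotypes <- as.matrix(phenotypes)
  covariates <- as.matrix(covariates)
  n <- length(genotypes)
  p <- ncol(covariates)
  if (nrow(phenotypes) != n || nrow(covariates) != n) {
    abort("phenotypes, genotypes and covariates must agree on the number of samples")
  }
  if (p < 1L) abort("at least one covariate column is required")
  if (n <= p + 1L) {
    abort(sprintf("too few samples (N = %d) for %d covariates plus an intercept", n, p))
  }
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    if (is.null(dropped)) dropped <- qx$pivot[-seq_len(qx$rank)]
    abort(paste0("covariate design is rank-deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  resid_of <- function(y) y - X %*% qr.coef(qx, y)
  list(
    phenotypes = apply(phenotypes, 2L, function(y) drop(resid_of(y))),
    genotypes = drop(resid_of(genotypes))
  )
}

#' Score statistics and trait correlation for one variant
#'
#' The entry point of the per-variant analysis: computes the length-K score
#' vector \eqn{T} and estimates its null covariance by the Pearson sample
#' correlation matrix of the phenotypes. If covariates are supplied, both
#' genotypes and phenotypes are first replaced by their linear-model
#' residuals (and the correlation is computed on the residualized traits).
#'
#' @param phenotypes Numeric matrix (N x K); binary traits coded 0/1.
#'   Column names, when present, label the traits.
#' @param genotypes Numeric vector of length N.
#' @param covariates Optional numeric matrix (N x p).
#' @return An object of class `score_summary`: a list with `t_stat`
#'   (length-K score vector), `sigma_hat` (K x K sample correlation matrix)
#'   and `n` (sample size).
#' @examples
#' Y <- matrix(rnorm(300), 100, 3)
#' g <- rbinom(100, 2, 0.3)
#' score_summary(Y, g)
#' @export
score_summary <- function(phenotypes, genotypes, covariates = NULL) {
  phenotypes <- as.matrix(phenotypes)
  n <- nrow(phenotypes)
  if (length(genotypes) != n) {
    abort("`genotypes` length must equal the number of phenotype rows")
  }
  if (n < 3L) abort("at least 3 samples are required")
  if (anyNA(phenotypes) || anyNA(genotypes) ||
      (!is.null(covariates) && anyNA(covariates))) {
    abort("missing values; drop incomplete rows before analysis (complete-case)")
  }
  if (!is.null(covariates)) {
    adj <- adjust_for_covariates(phenotypes, genotypes, covariates)
    phenotypes <- adj$phenotypes
    genotypes <- adj$genotypes
  }
  out <- list(
    t_stat = .score_vector(phenotypes, genotypes),
    sigma_hat = .fast_cor(phenotypes),
    n = n
  )
  names(out$t_stat) <- colnames(phenotypes)
  dimnames(out$sigma_hat) <- list(colnames(phenotypes), colnames(phenotypes))
  structure(out, class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat("<score_summary> ", length(x$t_stat), " traits, N = ", x$n, "\n", sep = "")
  cat("score statistics:\n")
  print(round(x$t_stat, 4))
  invisible(x)
}

#' Flip trait signs toward positive correlation with a reference trait
#'
#' Multiplies by -1 every phenotype column whose Pearson correlation with
#' the chosen reference column is negative. This is a pragmatic automatic
#' stand-in for sign conventions usually set by prior knowledge (e.g.
#' flipping lung-function traits so all disease-severity correlations are
#' positive); it guarantees non-negative correlation with the reference
#' only, not between all pairs.
#'
#' @param phenotypes Numeric matrix (N x K), K >= 2.
#' @param reference Column index (or name) of the reference trait.
#' @return A list with `phenotypes` (signs aligned) and `flipped`, a logical
#'   length-K vector marking the columns that were negated.
#' @export
align_signs <- function(phenotypes, reference = 1L) {
  phenotypes <- as.matrix(phenotypes)
  K <- ncol(phenotypes)
  if (K < 2L) abort("sign alignment needs at least two traits")
  if (is.character(reference)) reference <- match(reference, colnames(phenotypes))
  if (is.na(reference) || reference < 1L || reference > K) {
    abort("`reference` does not name a phenotype column")
  }
  r <- drop(cor(phenotypes[, reference], phenotypes))
  flipped <- r < 0
  phenotypes[, flipped] <- -phenotypes[, flipped, drop = FALSE]
  list(phenotypes = phenotypes, flipped = flipped)
}
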