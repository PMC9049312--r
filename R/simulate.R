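#' Specify one factor-model simulation scenario
#'
#' Defines the generating model for a cohort of N unrelated individuals
#' with one common variant and K correlated phenotypes
#' \deqn{Y = \lambda G + c \gamma f + \sqrt{1 - c^2}\,\varepsilon,}
#' where `G` is the minor-allele count drawn under Hardy-Weinberg
#' equilibrium at the given MAF, `f` is an R-vector of latent factors with
#' covariance \eqn{(1-\rho)I + \rho J}, \eqn{\gamma} is the K x R loading
#' matrix and the residuals are i.i.d. standard normal. Under the null
#' (`beta = 0`) each trait is standard normal with within-factor
#' correlation \eqn{c^2} and between-factor correlation \eqn{\rho c^2}.
#'
#' Four effect layouts are supported (see [build_effects()]): model 1 has a
#' single factor with effects on every trait growing linearly; model 2 has
#' two factors with only the second affected; models 3 and 4 have five
#' factors with two resp. four affected, including sign flips and
#' within-block gradients.
#'
#' @param model Effect layout, 1 to 4.
#' @param K Number of traits (even for model 2; divisible by 5 for models
#'   3-4). Default 20 traits.
#' @param beta Effect-size scalar; 0 gives the null scenario.
#' @param c Factor loading constant in \[0, 1); default 0.5, so the
#'   within-factor trait correlation is 0.25.
#' @param rho Between-factor correlation in \[0, 1); default 0.6.
#' @param maf Minor-allele frequency in (0, 0.5\]; default 0.3.
#' @param N Sample size; default 1000.
#' @param binary_mask Logical length-K vector marking traits to dichotomize
#'   by the liability-threshold rule (see [dichotomize()]); defaults to all
#'   quantitative. The helper [mixed_mask()] builds the half-and-half mask.
#' @param seed Optional RNG seed stored with the spec and used by
#'   [gen_phenotypes()].
#' @return A `factor_model_spec` list with the validated fields plus the
#'   derived number of factors `R`.
#' @examples
#' factor_model_spec(model = 2, K = 10, beta = 0.1)
#' @export
factor_model_spec <- function(model = 1, K = 20, beta = 0, c = 0.5, rho = 0.6,
                              maf = 0.3, N = 1000, binary_mask = NULL,
                              seed = NULL) {
  if (!model %in% 1:4) abort("`model` must be 1, 2, 3 or 4")
  R <- c(1L, 2L, 5L, 5L)[model]
  if (model >= 2 && K %% R != 0) {
    abort(sprintf("model %d needs K divisible by %d (got K = %d)", model, R, K))
  }
  if (K < 1L) abort("`K` must be at least 1")
  if (c < 0 || c >= 1) abort("`c` must lie in [0, 1)")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1)")
  if (maf <= 0 || maf > 0.5) abort("`maf` must lie in (0, 0.5]")
  if (N < 1L) abort("`N` must be positive")
  if (is.null(binary_mask)) binary_mask <- rep(FALSE, K)
  if (length(binary_mask) != K || !is.logical(binary_mask)) {
    abort("`binary_mask` must be a logical vector of length K")
  }
  structure(
    list(model = as.integer(model), K = as.integer(K), R = R, beta = beta,
         c = c, rho = rho, maf = maf, N = as.integer(N),
         binary_mask = binary_mask, seed = seed),
    class = "factor_model_spec")
}

#' @export
print.factor_model_spec <- function(x, ...) {
  cat(sprintf(
    "<factor_model_spec> model %d: K = %d traits (%d binary), R = %d factors\n",
    x$model, x$K, sum(x$binary_mask), x$R))
  cat(sprintf("  beta = %g, c = %g, rho = %g, MAF = %g, N = %d\n",
              x$beta, x$c, x$rho, x$maf, x$N))
  invisible(x)
}

#' Mask selecting half the traits as binary
#'
#' @param K Total number of traits (even).
#' @param half Which half is dichotomized; the second by default.
#' @return Logical vector of length K.
#' @export
mixed_mask <- function(K, half = c("second", "first")) {
  half <- match.arg(half)
  if (K %% 2 != 0) abort("`K` must be even for a half-and-half trait mix")
  m <- rep(FALSE, K)
  if (half == "second") m[(K / 2 + 1):K] <- TRUE else m[1:(K / 2)] <- TRUE
  m
}

#' Genotypes under Hardy-Weinberg equilibrium
#'
#' Draws minor-allele counts in \{0, 1, 2\} with probabilities
#' \eqn{((1-q)^2, 2q(1-q), q^2)} at minor-allele frequency q, i.e.
#' Binomial(2, q) per individual.
#'
#' @param N Number of individuals.
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param seed Optional RNG seed.
#' @return Integer vector of length N.
#' @export
gen_genotypes <- function(N, maf, seed = NULL) {
  if (maf <= 0 || maf > 0.5) abort("`maf` must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  rbinom(N, 2L, maf)
}

#' Genetic effect sizes and factor loadings of a scenario
#'
#' Builds the effect vector \eqn{\lambda} and the block-diagonal loading
#' matrix \eqn{\gamma} for the four effect layouts. With block size
#' k = K/R:
#' * model 1: \eqn{\lambda = \beta (1, 2, \dots, K)}, one factor loading all
#'   traits;
#' * model 2: K/2 zeros then K/2 entries \eqn{\beta}, two factors;
#' * model 3: three null blocks, a block of \eqn{-\beta}, and a graded block
#'   \eqn{\frac{2\beta}{k+1}(1, \dots, k)}, five factors;
#' * model 4: a null block, \eqn{+\beta} and \eqn{-\beta} blocks, and graded
#'   blocks \eqn{\mp\frac{2\beta}{k+1}(1, \dots, k)}, five factors.
#'
#' @param spec A [factor_model_spec()].
#' @return A list with `lambda` (length K) and `gamma` (K x R 0/1 matrix).
#' @export
build_effects <- function(spec) {
  stopifnot(inherits(spec, "factor_model_spec"))
  K <- spec$K; b <- spec$beta; R <- spec$R
  k <- K %/% R
  lambda <- switch(spec$model,
    b * seq_len(K),
    c(rep(0, k), rep(b, k)),
    c(rep(0, 3 * k), rep(-b, k), 2 * b / (k + 1) * seq_len(k)),
    c(rep(0, k), rep(b, k), rep(-b, k),
      -2 * b / (k + 1) * seq_len(k), 2 * b / (k + 1) * seq_len(k))
  )
  gamma <- matrix(0, K, R)
  for (r in seq_len(R)) gamma[((r - 1) * k + 1):(r * k), r] <- 1
  list(lambda = lambda, gamma = gamma)
}

#' Correlated latent factors
#'
#' Draws N i.i.d. rows from \eqn{MVN(0, (1-\rho)I + \rho J)}, J the all-ones
#' matrix, giving unit-variance factors with pairwise correlation rho.
#'
#' @param N Number of rows (individuals).
#' @param R Number of factors.
#' @param rho Between-factor correlation in \[0, 1).
#' @param seed Optional RNG seed.
#' @return An N x R matrix.
#' @export
gen_factors <- function(N, R, rho, seed = NULL) {
  if (R < 1L) abort("`R` must be at least 1")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(N * R), N, R)
  if (R == 1L || rho == 0) return(Z)
  sigma <- (1 - rho) * diag(R) + rho
  Z %*% chol(sigma)
}

#' Simulate genotypes and quantitative phenotypes from a scenario
#'
#' Composes [gen_genotypes()], [build_effects()] and [gen_factors()] and
#' adds the residual noise \eqn{\sqrt{1 - c^2}\,\varepsilon}. Draw order is
#' genotypes, factors, residuals, so outputs are bit-reproducible given the
#' spec's seed. Traits are left quantitative here; apply [dichotomize()]
#' (or use [simulate_cohort()]) for the binary-trait mix.
#'
#' @param spec A [factor_model_spec()].
#' @param seed RNG seed; defaults to the spec's own.
#' @return A list with `genotypes` (length N) and `phenotypes` (N x K).
#' @export
gen_phenotypes <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "factor_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  g <- gen_genotypes(spec$N, spec$maf)
  eff <- build_effects(spec)
  f <- gen_factors(spec$N, spec$R, spec$rho)
  Y <- tcrossprod(g, eff$lambda) +
    spec$c * tcrossprod(f, eff$gamma) +
    sqrt(1 - spec$c^2) * matrix(rnorm(spec$N * spec$K), spec$N, spec$K)
  colnames(Y) <- paste0("trait", seq_len(spec$K))
  list(genotypes = g, phenotypes = Y)
}

#' Liability-threshold dichotomization of selected traits
#'
#' Converts masked quantitative traits to 0/1 disease status: an individual
#' is affected when the trait is at least one standard deviation beyond the
#' trait's sample mean (above it for `tail = "upper"`, the default; below
#' for `"lower"` -- the two are equidistributed for symmetric traits). For
#' a normal trait the affected fraction is \eqn{\Phi(-1) \approx 0.159}.
#'
#' @param phenotypes Numeric N x K matrix.
#' @param binary_mask Logical length-K vector of columns to dichotomize.
#' @param tail Which tail defines "affected".
#' @return The matrix with masked columns replaced by 0/1.
#' @export
dichotomize <- function(phenotypes, binary_mask, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  phenotypes <- as.matrix(phenotypes)
  if (length(binary_mask) != ncol(phenotypes) || !is.logical(binary_mask)) {
    abort("`binary_mask` must be a logical vector with one flag per trait")
  }
  for (j in which(binary_mask)) {
    y <- phenotypes[, j]
    s <- sd(y)
    if (s == 0) abort(sprintf("cannot dichotomize constant column %d", j))
    m <- mean(y)
    phenotypes[, j] <- if (tail == "upper") {
      as.numeric(y >= m + s)
    } else {
      as.numeric(y <= m - s)
    }
  }
  phenotypes
}

#' Simulate a cohort as a tibble
#'
#' Runs the full generator for one scenario -- genotypes, factor-model
#' phenotypes, liability-threshold dichotomization per the spec's
#' `binary_mask` -- and returns a tidy table ready for [multi_trait_test()]
#' or for writing with [readr::write_tsv()].
#'
#' @param spec A [factor_model_spec()].
#' @param seed RNG seed; defaults to the spec's own.
#' @return A tibble with `sample_id`, `genotype`, and one column per trait.
#' @examples
#' simulate_cohort(factor_model_spec(model = 1, K = 4, N = 50, seed = 1))
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  dat <- gen_phenotypes(spec, seed = seed)
  Y <- dichotomize(dat$phenotypes, spec$binary_mask)
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("S%0*d", nchar(spec$N), seq_len(spec$N)),
      genotype = dat$genotypes),
    tibble::as_tibble(Y)
  )
}
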