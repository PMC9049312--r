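# Internal numerical helpers shared by the testing and experiment code.

# Pearson correlation via crossprod; ~2x faster than stats::cor on the
# dense, complete matrices used in the simulation loops.
.fast_cor <- function(Y) {
  Z <- sweep(Y, 2L, colMeans(Y), check.margin = FALSE)
  C <- crossprod(Z)
  d <- sqrt(diag(C))
  if (any(d == 0)) {
    abort(paste0("zero variance in phenotype column(s): ",
                 paste(which(d == 0), collapse = ", ")))
  }
  C / tcrossprod(d)
}

# Upper Cholesky factor of sigma, adding a ridge eps * I when sigma is
# singular or near-singular (squared diagonal ratio of the factor used as a
# cheap reciprocal-condition proxy).
.chol_prec <- function(sigma, ridge = 1e-8, warn = TRUE) {
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(R)) {
    d <- diag(R)
    ok <- (min(d) / max(d))^2 > 1e-12
  }
  if (!ok) {
    if (warn) {
      warn(sprintf(
        "trait correlation matrix is singular or near-singular; adding ridge %g to its diagonal",
        ridge))
    }
    R <- chol(sigma + diag(ridge, nrow(sigma)))
    attr(R, "ridged") <- TRUE
  }
  R
}

# Vector of per-trait score statistics T_k = U_k / sqrt(V_k) for a phenotype
# matrix against one genotype vector. Assumes complete data.
.score_vector <- function(Y, g) {
  n <- length(g)
  gc <- g - mean(g)
  ssg <- sum(gc^2)
  if (ssg == 0) abort("zero variance: genotype vector is constant")
  U <- as.vector(crossprod(Y, gc))
  ssy <- colSums(Y^2) - n * colMeans(Y)^2
  if (any(ssy <= 0)) {
    abort(paste0("zero variance in phenotype column(s): ",
                 paste(which(ssy <= 0), collapse = ", ")))
  }
  U / sqrt(ssy * ssg / n)
}

# K x K integer matrix of nested cluster assignments: column L is the
# partition with L clusters from one hierarchical tree.
.cut_matrix <- function(sigma, linkage = "average") {
  K <- nrow(sigma)
  if (K == 1L) return(matrix(1L, 1L, 1L))
  hc <- hclust(as.dist(1 - sigma), method = linkage)
  cl <- cutree(hc, k = seq_len(K))
  storage.mode(cl) <- "integer"
  cl
}

# Per-replicate RNG streams (L'Ecuyer-CMRG) keyed by (seed, replicate index),
# so experiment results do not depend on the worker count. Restores the
# caller's RNG state on exit.
.with_rep_streams <- function(n, seed, workers, fn) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  streams <- vector("list", n)
  s <- get(".Random.seed", globalenv(), inherits = FALSE)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  run_one <- function(i) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    fn(i)
  }
  if (workers > 1L) {
    parallel::mclapply(seq_len(n), run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n), run_one)
  }
}

.assert_square_corr <- function(sigma, arg = "sigma_hat", tol = 1e-8) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    abort(sprintf("`%s` must be a square matrix", arg))
  }
  if (max(abs(sigma - t(sigma))) > tol) {
    abort(sprintf("`%s` must be symmetric", arg))
  }
  if (max(abs(diag(sigma) - 1)) > tol) {
    abort(sprintf("`%s` must have a unit diagonal", arg))
  }
  invisible(sigma)
}
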