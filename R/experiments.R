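# Type-I-error and power experiment drivers over the factor-model simulator.

#' Configuration of a simulation experiment
#'
#' Bundles one generating scenario with the replication and evaluation
#' settings of a type-I-error or power run.
#'
#' @param spec A [factor_model_spec()]; use `beta = 0` for type-I error.
#' @param n_replicates Number of simulated datasets.
#' @param alpha_levels Nominal significance levels to evaluate.
#' @param methods Tests to run each replicate: any of `"ceclc"`, `"clc"`
#'   (min-p with Monte-Carlo null), `"obrien"`, `"omnibus"`.
#' @param mc_for_clc Monte-Carlo draws per replicate for the min-p CLC.
#' @param seed Master seed; each replicate gets its own L'Ecuyer-CMRG
#'   substream derived from it, so results do not depend on `workers`.
#' @param workers Number of forked workers (1 = serial).
#' @param linkage Clustering linkage passed through the pipeline.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(spec, n_replicates = 10000,
                              alpha_levels = 0.05, methods = "ceclc",
                              mc_for_clc = 1000, seed = 1, workers = 1,
                              linkage = c("average", "complete", "single")) {
  stopifnot(inherits(spec, "factor_model_spec"))
  methods <- match.arg(methods, c("ceclc", "clc", "obrien", "omnibus"),
                       several.ok = TRUE)
  if (any(alpha_levels <= 0 | alpha_levels >= 1)) {
    abort("`alpha_levels` must lie in (0, 1)")
  }
  if (n_replicates < 1L) abort("`n_replicates` must be positive")
  structure(
    list(spec = spec, n_replicates = as.integer(n_replicates),
         alpha_levels = alpha_levels, methods = methods,
         mc_for_clc = as.integer(mc_for_clc), seed = as.integer(seed),
         workers = as.integer(workers), linkage = match.arg(linkage)),
    class = "experiment_config")
}

# One replicate: simulate under `spec` from the current RNG stream, run the
# shared score/cluster/profile pipeline once, and read every requested
# method's p-value off it.
.rep_pvalues <- function(spec, methods, mc_for_clc, linkage) {
  dat <- gen_phenotypes(spec, seed = NULL)
  Y <- if (any(spec$binary_mask)) {
    dichotomize(dat$phenotypes, spec$binary_mask)
  } else {
    dat$phenotypes
  }
  tk <- .score_vector(Y, dat$genotypes)
  K <- length(tk)
  R <- .fast_cor(Y)
  Rchol <- .chol_prec(R, warn = FALSE)
  sinv <- chol2inv(Rchol)
  cl <- .cut_matrix(R, linkage)
  stats <- .clc_profile_cpp(matrix(tk, nrow = 1L), sinv, cl)[1L, ]
  ps <- pchisq(stats, df = seq_len(K), lower.tail = FALSE)
  out <- setNames(numeric(length(methods)), methods)
  for (m in methods) {
    out[[m]] <- switch(m,
      ceclc = pcauchy(mean(.cauchy_transform(ps)), lower.tail = FALSE),
      obrien = ps[1L],      # L = 1 cut is the single all-traits cluster
      omnibus = ps[K],      # L = K cut is the identity membership
      clc = {
        draws <- matrix(rnorm(mc_for_clc * K), mc_for_clc, K) %*% Rchol
        null_stats <- .clc_profile_cpp(draws, sinv, cl)
        null_p <- pchisq(null_stats, df = rep(seq_len(K), each = mc_for_clc),
                         lower.tail = FALSE)
        dim(null_p) <- dim(null_stats)
        (1 + sum(apply(null_p, 1L, min) <= min(ps))) / (mc_for_clc + 1)
      })
  }
  out
}

.run_experiment <- function(config, kind) {
  t0 <- proc.time()[["elapsed"]]
  n <- config$n_replicates
  res <- .with_rep_streams(n, config$seed, config$workers, function(i) {
    tryCatch(
      .rep_pvalues(config$spec, config$methods, config$mc_for_clc,
                   config$linkage),
      error = function(e) {
        setNames(rep(NA_real_, length(config$methods)), config$methods)
      })
  })
  pmat <- do.call(rbind, res)
  failed <- rowSums(is.na(pmat)) > 0
  n_failed <- sum(failed)
  if (n_failed > 0) {
    inform(sprintf("%d of %d replicates failed and were excluded", n_failed, n))
    if (n_failed / n > 0.001) {
      abort("more than 0.1% of replicates failed; aborting the experiment")
    }
    pmat <- pmat[!failed, , drop = FALSE]
  }
  n_ok <- nrow(pmat)
  grid <- tidyr::expand_grid(method = config$methods,
                             alpha = config$alpha_levels)
  results <- dplyr::mutate(grid,
    n_replicates = n_ok,
    rejections = purrr::map2_int(.data$method, .data$alpha,
      function(m, a) sum(pmat[, m] <= a)),
    estimate = .data$rejections / n_ok,
    ratio = .data$estimate / .data$alpha,
    ci_low = purrr::map2_dbl(.data$alpha, n_ok,
      function(a, n) ci_for_ratio(a, n)[["low"]]),
    ci_high = purrr::map2_dbl(.data$alpha, n_ok,
      function(a, n) ci_for_ratio(a, n)[["high"]]),
    within_ci = .data$ratio >= .data$ci_low & .data$ratio <= .data$ci_high
  )
  structure(
    list(results = results, kind = kind, config = config,
         n_failed = n_failed, p_values = pmat,
         runtime = proc.time()[["elapsed"]] - t0),
    class = "mt_experiment")
}

#' Empirical type-I-error rates under the null
#'
#' Simulates `n_replicates` datasets under the null scenario of the config
#' (which must have `beta = 0`), runs the full pipeline -- genotype and
#' phenotype generation, score statistics, sample correlation, clustering,
#' the requested tests -- on each, and reports per (method, alpha) the
#' rejection count, the ratio of the empirical rate to the nominal level,
#' and whether that ratio falls inside the analytic 95% CI of
#' [ci_for_ratio()]. A well-calibrated test gives ratios near 1.
#'
#' @param config An [experiment_config()] with a null (`beta = 0`) spec.
#' @return An `mt_experiment`; [tidy()] extracts the per-cell tibble.
#' @export
run_type1 <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$spec$beta != 0) {
    abort("type-I-error runs need a null spec (beta = 0)")
  }
  if (config$n_replicates < 1000) {
    warn(paste0("fewer than 1000 replicates: empirical rates at small alpha ",
                "will be dominated by granularity"))
  }
  .run_experiment(config, kind = "type1")
}

#' Empirical power under an alternative scenario
#'
#' As [run_type1()] but for `beta > 0`: the `estimate` column is the power
#' at each nominal level (default 0.05).
#'
#' @param config An [experiment_config()] with `beta > 0`.
#' @param allow_null Permit `beta = 0` (then power should equal alpha);
#'   off by default to catch misconfigured runs.
#' @return An `mt_experiment`.
#' @export
run_power <- function(config, allow_null = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$spec$beta <= 0 && !allow_null) {
    abort("power runs need an alternative spec (beta > 0)")
  }
  .run_experiment(config, kind = "power")
}

#' Analytic 95% CI for the type-I-error ratio
#'
#' The 95% binomial confidence interval for the ratio of an empirical
#' type-I-error rate to its nominal level alpha, when the rate is estimated
#' from n independent replicates of a calibrated test:
#' \eqn{1 \mp 1.96 \sqrt{\alpha(1-\alpha)/n} / \alpha}, rounded to 4
#' decimals for display.
#'
#' @param alpha Nominal significance level in (0, 1).
#' @param n_replicates Number of replicates.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' ci_for_ratio(0.001, 1e6)  # (0.9381, 1.0619)
#' @export
ci_for_ratio <- function(alpha, n_replicates) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (n_replicates < 1) abort("`n_replicates` must be positive")
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_replicates) / alpha
  c(low = round(1 - half, 4), high = round(1 + half, 4))
}

#' @export
print.mt_experiment <- function(x, ...) {
  cat(sprintf("<mt_experiment> %s: model %d, K = %d, N = %d, %d replicates (%.1fs)\n",
              x$kind, x$config$spec$model, x$config$spec$K, x$config$spec$N,
              x$config$n_replicates, x$runtime))
  print(x$results)
  invisible(x)
}

#' Per-cell results of an experiment
#'
#' @param x An `mt_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per (method, alpha): rejection counts,
#'   empirical rate, rate/alpha ratio and its analytic 95% CI.
#' @method tidy mt_experiment
#' @export
tidy.mt_experiment <- function(x, ...) x$results

#' One-row summary of an experiment
#'
#' @param x An `mt_experiment`.
#' @param ... Unused.
#' @return A one-row tibble of scenario and run metadata.
#' @method glance mt_experiment
#' @export
glance.mt_experiment <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, model = x$config$spec$model, K = x$config$spec$K,
    N = x$config$spec$N, beta = x$config$spec$beta,
    n_replicates = x$config$n_replicates, n_failed = x$n_failed,
    seed = x$config$seed, runtime = x$runtime)
}

#' Plot an experiment's calibration or power
#'
#' Type-I-error runs show the rate/alpha ratio with its analytic 95% CI
#' band; power runs show the rejection rate.
#'
#' @param object An `mt_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mt_experiment
#' @export
autoplot.mt_experiment <- function(object, ...) {
  d <- dplyr::mutate(object$results, alpha = factor(.data$alpha))
  if (object$kind == "type1") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$ratio,
                                    colour = .data$alpha)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             width = 0.2, colour = "grey70") +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(y = "type-I-error rate / alpha", x = NULL,
                    title = "Type-I-error calibration") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$estimate,
                                    fill = .data$alpha)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "power", x = NULL, title = "Empirical power") +
      ggplot2::theme_minimal()
  }
}

#' Render experiment results as a flat table
#'
#' Collects one or more experiments into a grid with one row per
#' (model, N, alpha, method) cell, the estimate and ratio, and a flag
#' marking ratios outside their analytic 95% CI; serialized as TSV or a
#' markdown table.
#'
#' @param results An `mt_experiment` or a list of them.
#' @param format `"tsv"` (machine-readable, round-trips through
#'   [parse_rendered_table()]) or `"markdown"`.
#' @return A single string.
#' @export
render_table <- function(results, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  if (inherits(results, "mt_experiment")) results <- list(results)
  grid <- purrr::map_dfr(results, function(x) {
    dplyr::mutate(tidy(x),
                  model = x$config$spec$model, N = x$config$spec$N,
                  .before = 1L)
  })
  grid <- dplyr::select(grid, "model", "N", "alpha", "method", "n_replicates",
                        "rejections", "estimate", "ratio", "within_ci")
  if (format == "tsv") return(readr::format_tsv(grid))
  header <- paste0("| ", paste(names(grid), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(grid)), collapse = "|"), "|")
  rows <- apply(grid, 1L, function(r) {
    paste0("| ", paste(trimws(format(r, digits = 6)), collapse = " | "), " |")
  })
  paste(c(header, rule, rows), collapse = "\n")
}

#' Parse a TSV table rendered by [render_table()]
#'
#' @param text A TSV string.
#' @return The tibble it encodes.
#' @export
parse_rendered_table <- function(text) {
  readr::read_tsv(I(text), show_col_types = FALSE)
}
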