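#' Test variants against multiple phenotypes jointly
#'
#' The data-frame-first entry point: joins phenotype, genotype and optional
#' covariate tables on their sample-ID column (keeping the phenotype file's
#' order and dropping incomplete rows), then for each variant column runs
#' the requested joint association tests on the shared score-statistic and
#' correlation summary.
#'
#' @param pheno Tibble/data frame: `sample_id` plus one column per trait
#'   (binary traits coded 0/1), as from [read_phenotypes()].
#' @param geno Tibble: `sample_id` plus one dosage column (0/1/2 or
#'   residualized real values) per variant, as from [read_genotypes()].
#' @param covar Optional tibble: `sample_id` plus covariate columns; when
#'   present, genotypes and phenotypes are residualized on them first.
#' @param methods Tests to run: any of `"ceclc"`, `"clc"`, `"obrien"`,
#'   `"omnibus"`.
#' @param linkage Clustering linkage for the CLC family.
#' @param n_mc Monte-Carlo draws for the min-p CLC null.
#' @param seed Seed for the min-p CLC draws.
#' @param align Align trait signs to the first trait with [align_signs()]
#'   before testing (off by default; sign conventions are usually set by
#'   prior knowledge).
#' @return A tibble with one row per variant x method: `variant`, `method`,
#'   `statistic`, `df`, `p_value`, and the per-L profile as a `component_p`
#'   list-column ([write_results()] flattens it).
#' @examples
#' cohort <- simulate_cohort(factor_model_spec(K = 4, N = 200, seed = 7))
#' pheno <- dplyr::select(cohort, sample_id, dplyr::starts_with("trait"))
#' geno <- dplyr::select(cohort, sample_id, snp1 = genotype)
#' multi_trait_test(pheno, geno, methods = c("ceclc", "omnibus"))
#' @export
multi_trait_test <- function(pheno, geno, covar = NULL,
                             methods = "ceclc",
                             linkage = c("average", "complete", "single"),
                             n_mc = 1000, seed = NULL, align = FALSE) {
  linkage <- match.arg(linkage)
  methods <- match.arg(methods, c("ceclc", "clc", "obrien", "omnibus"),
                       several.ok = TRUE)
  pheno <- tibble::as_tibble(pheno)
  geno <- tibble::as_tibble(geno)
  if (!"sample_id" %in% names(pheno)) names(pheno)[1L] <- "sample_id"
  if (!"sample_id" %in% names(geno)) names(geno)[1L] <- "sample_id"
  if (!is.null(covar)) {
    covar <- tibble::as_tibble(covar)
    if (!"sample_id" %in% names(covar)) names(covar)[1L] <- "sample_id"
  }
  trait_cols <- setdiff(names(pheno), "sample_id")
  variant_cols <- setdiff(names(geno), "sample_id")
  covar_cols <- if (is.null(covar)) character() else setdiff(names(covar), "sample_id")
  dat <- .assemble_input(pheno, geno, covar)
  Y <- as.matrix(dat[trait_cols])
  Z <- if (length(covar_cols)) as.matrix(dat[covar_cols]) else NULL
  if (align) Y <- align_signs(Y)$phenotypes
  purrr::map_dfr(variant_cols, function(v) {
    s <- score_summary(Y, dat[[v]], covariates = Z)
    purrr::map_dfr(methods, function(m) {
      fit <- switch(m,
        ceclc = ceclc_test(s$t_stat, s$sigma_hat, linkage),
        clc = clc_minp_test(s$t_stat, s$sigma_hat, n_mc = n_mc, seed = seed,
                            linkage = linkage),
        obrien = obrien_test(s$t_stat, s$sigma_hat),
        omnibus = omnibus_test(s$t_stat, s$sigma_hat))
      tibble::tibble(
        variant = v, method = m, statistic = fit$statistic,
        df = if (is.null(fit$df)) NA_integer_ else as.integer(fit$df),
        p_value = fit$p_value,
        component_p = list(fit$component_p))
    })
  })
}
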