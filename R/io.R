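# Delimited-text and VCF input. All tables are keyed by a sample-ID first
# column; matrices are joined on sample ID in the phenotype file's order.

.read_delim_auto <- function(file) {
  if (grepl("\\.csv$", file, ignore.case = TRUE)) {
    readr::read_csv(file, show_col_types = FALSE)
  } else {
    readr::read_tsv(file, show_col_types = FALSE)
  }
}

#' Read a phenotype table
#'
#' TSV or CSV with a header row; first column is the sample ID, remaining
#' columns are traits (binary traits coded 0/1).
#'
#' @param file Path to the file.
#' @return A tibble whose first column is renamed `sample_id`.
#' @export
read_phenotypes <- function(file) {
  d <- .read_delim_auto(file)
  if (ncol(d) < 2L) abort("phenotype file needs a sample-ID column plus traits")
  names(d)[1L] <- "sample_id"
  d
}

#' Read a genotype table
#'
#' Either a delimited text table (sample ID plus one column of 0/1/2
#' minor-allele counts per variant) or, for `.vcf`/`.vcf.gz` paths, a VCF
#' handled by [read_vcf_genotypes()].
#'
#' @param file Path to the file.
#' @return A tibble: `sample_id` plus one dosage column per variant.
#' @export
read_genotypes <- function(file) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", file, ignore.case = TRUE)) {
    return(read_vcf_genotypes(file))
  }
  d <- .read_delim_auto(file)
  if (ncol(d) < 2L) abort("genotype file needs a sample-ID column plus dosages")
  names(d)[1L] <- "sample_id"
  d
}

#' @rdname read_phenotypes
#' @export
read_covariates <- function(file) {
  d <- .read_delim_auto(file)
  if (ncol(d) < 2L) abort("covariate file needs a sample-ID column plus covariates")
  names(d)[1L] <- "sample_id"
  d
}

#' Minor-allele dosages from a VCF
#'
#' Reads biallelic sites from a VCF (via the VariantAnnotation package) and
#' converts each genotype call to a minor-allele count: ALT-allele dosage,
#' flipped to REF dosage at sites where ALT is the major allele. Sites with
#' more than one ALT allele are skipped with a warning. Missing calls
#' become `NA` and are later dropped by the complete-case join.
#'
#' @param file Path to a VCF (optionally bgzipped).
#' @return A tibble: `sample_id` plus one dosage column per variant, named
#'   by the VCF ID (or `chr:pos` when the ID is missing).
#' @export
read_vcf_genotypes <- function(file) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("reading VCF genotypes requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(file)
  n_alt <- lengths(VariantAnnotation::alt(vcf))
  if (any(n_alt != 1L)) {
    warn(sprintf("skipping %d multi-allelic site(s)", sum(n_alt != 1L)))
    vcf <- vcf[n_alt == 1L]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) abort("VCF has no GT field")
  dose <- function(x) {
    ifelse(grepl("\\.", x), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  D <- apply(gt, 2L, dose)
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(gt), dimnames = dimnames(gt))
  # dosage of the minor allele: flip sites where ALT is the major allele
  af <- rowMeans(D, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  D[flip, ] <- 2 - D[flip, , drop = FALSE]
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("var", seq_len(nrow(gt)))
  out <- tibble::as_tibble(t(D), .name_repair = "minimal")
  names(out) <- ids
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(gt)), out)
}

# Join phenotype / genotype / covariate tibbles on sample_id, keeping the
# phenotype order, and drop incomplete rows with a logged count.
.assemble_input <- function(pheno, geno, covar = NULL) {
  stopifnot("sample_id" %in% names(pheno), "sample_id" %in% names(geno))
  d <- dplyr::inner_join(pheno, geno, by = "sample_id",
                         suffix = c("", ".geno"))
  if (!is.null(covar)) {
    d <- dplyr::inner_join(d, covar, by = "sample_id", suffix = c("", ".covar"))
  }
  keep <- complete.cases(d)
  if (any(!keep)) {
    inform(sprintf("dropped %d incomplete row(s) (complete-case analysis)",
                   sum(!keep)))
    d <- d[keep, , drop = FALSE]
  }
  d
}

#' Write multi-trait test results as TSV
#'
#' Expands the `component_p` list-column into `p_L1..p_LK` columns so the
#' output is a flat table: one row per variant and method.
#'
#' @param results A tibble from [multi_trait_test()].
#' @param file Output path.
#' @return The written tibble, invisibly.
#' @export
write_results <- function(results, file) {
  flat <- results
  if ("component_p" %in% names(flat)) {
    comp <- purrr::map(flat$component_p, function(p) {
      if (is.null(p)) return(tibble::tibble())
      tibble::as_tibble(setNames(as.list(p), paste0("p_L", seq_along(p))))
    })
    flat <- dplyr::bind_cols(dplyr::select(flat, -"component_p"),
                             dplyr::bind_rows(comp))
  }
  readr::write_tsv(flat, file)
  invisible(flat)
}
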