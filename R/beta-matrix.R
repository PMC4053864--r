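#' Beta-value tables
#'
#' Throughout the package a *beta table* is a tibble whose first column,
#' `cpg_id`, holds CpG identifiers (e.g. Illumina `"cg02228185"`) and whose
#' remaining columns hold per-sample methylation fractions in `[0, 1]`, one
#' column per sample. `NA` marks a missing measurement; missing values are
#' never imputed silently.
#'
#' `validate_beta()` checks the invariants (unique CpG and sample ids, all
#' non-missing values inside `[0, 1]`) and returns the table invisibly;
#' `beta_to_matrix()` converts to a numeric matrix with CpG rownames for
#' linear algebra, and `matrix_to_beta()` converts back.
#'
#' @param beta A beta table (tibble, first column `cpg_id`).
#' @param m A numeric matrix, CpG rows x sample columns, with dimnames.
#'
#' @return `validate_beta()` returns `beta` invisibly (or errors);
#'   `beta_to_matrix()` a numeric matrix; `matrix_to_beta()` a tibble.
#'
#' @examples
#' b <- tibble::tibble(cpg_id = c("cg1", "cg2"), S1 = c(0.1, 0.5), S2 = c(0.9, 0.3))
#' validate_beta(b)
#' beta_to_matrix(b)
#' @export
validate_beta <- function(beta) {
  if (!is.data.frame(beta) || ncol(beta) < 2L) {
    abort("`beta` must be a data frame with a `cpg_id` column and at least one sample column.")
  }
  if (names(beta)[1] != "cpg_id") {
    abort("The first column of a beta table must be named `cpg_id`.")
  }
  ids <- beta$cpg_id
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated CpG ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  samp <- names(beta)[-1]
  if (anyDuplicated(samp)) {
    abort(paste0("Duplicated sample ids: ", paste(unique(samp[duplicated(samp)]), collapse = ", ")))
  }
  vals <- as.matrix(beta[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("All sample columns of a beta table must be numeric.")
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1))
  if (length(bad) > 0L) {
    abort(sprintf(
      "%d beta value(s) outside [0, 1]; first offender %.6g (CpG %s).",
      length(bad), vals[bad[1]], ids[(bad[1] - 1L) %% nrow(vals) + 1L]
    ))
  }
  invisible(beta)
}

#' @rdname validate_beta
#' @export
beta_to_matrix <- function(beta) {
  validate_beta(beta)
  m <- as.matrix(beta[, -1, drop = FALSE])
  rownames(m) <- beta$cpg_id
  m
}

#' @rdname validate_beta
#' @export
matrix_to_beta <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(cpg_id = rownames(m)), out)
  validate_beta(out)
  out
}

#' Validate a sample metadata table
#'
#' A sample table has one row per sample: a unique `sample_id`, a finite
#' non-negative `age_years`, optionally `sex` (`"male"`, `"female"`,
#' `"unknown"`) and any number of extra covariate columns (numeric or
#' categorical), e.g. `bmi`, `alcohol_g_per_day`, `n_children_category`.
#'
#' @param samples A data frame with at least `sample_id` and `age_years`.
#' @return `samples` as a tibble, invisibly validated.
#' @export
validate_samples <- function(samples) {
  if (!is.data.frame(samples)) abort("`samples` must be a data frame.")
  need <- setdiff(c("sample_id", "age_years"), names(samples))
  if (length(need) > 0L) {
    abort(paste0("Sample table is missing mandatory column(s): ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("`sample_id` values must be unique.")
  age <- samples$age_years
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    abort("`age_years` must be finite, numeric and >= 0 for every sample.")
  }
  if ("sex" %in% names(samples)) {
    bad <- setdiff(unique(stats::na.omit(samples$sex)), c("male", "female", "unknown"))
    if (length(bad) > 0L) {
      abort(paste0("`sex` must be one of male/female/unknown; found: ", paste(bad, collapse = ", ")))
    }
  }
  tibble::as_tibble(samples)
}

#' Restrict a beta table and a sample table to their common samples
#'
#' Both inputs are restricted, in identical order (order of appearance in
#' the beta table), to the intersection of their sample ids. Errors when the
#' intersection is empty. The operation is idempotent.
#'
#' @param beta A beta table (see [validate_beta()]).
#' @param samples A sample table (see [validate_samples()]).
#' @return A list with elements `beta` and `samples`, aligned.
#' @examples
#' b <- tibble::tibble(cpg_id = "cg1", A = 0.1, B = 0.2, C = 0.3)
#' s <- tibble::tibble(sample_id = c("B", "C", "D"), age_years = c(30, 40, 50))
#' align_samples(b, s)
#' @export
align_samples <- function(beta, samples) {
  validate_beta(beta)
  samples <- validate_samples(samples)
  common <- intersect(names(beta)[-1], samples$sample_id)
  if (length(common) == 0L) abort("Beta table and sample table share no sample ids.")
  beta_out <- beta[, c("cpg_id", common), drop = FALSE]
  samples_out <- samples[match(common, samples$sample_id), , drop = FALSE]
  list(beta = beta_out, samples = samples_out)
}
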