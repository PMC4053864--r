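#' Correlate every CpG's methylation with donor age
#'
#' Pearson correlation of each CpG's beta values with chronological age,
#' computed pairwise-complete (samples missing a CpG's value are dropped
#' for that CpG only — the natural choice when pooling multi-study
#' matrices). CpGs with fewer than 3 usable samples or zero beta variance
#' get a missing correlation and `defined = FALSE`; they are never
#' selected.
#'
#' @param beta A beta table.
#' @param samples A sample table; aligned to the beta table's samples
#'   internally.
#' @param min_samples Minimum complete pairs required to report an `r`
#'   (default 3).
#' @return A tibble with one row per CpG: `cpg_id`, `r`, `n_used`,
#'   `direction` (`"hyper"` for positive r, `"hypo"` for negative),
#'   `defined`.
#' @export
correlate_with_age <- function(beta, samples, min_samples = 3L) {
  al <- align_samples(beta, samples)
  m <- beta_to_matrix(al$beta)
  age <- al$samples$age_years
  if (ncol(m) < min_samples) abort(sprintf("Need at least %d overlapping samples.", min_samples))
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    ok <- !is.na(x)
    n_used <- sum(ok)
    r <- if (n_used >= min_samples && sd(x[ok]) > 0 && sd(age[ok]) > 0) {
      cor(x[ok], age[ok])
    } else {
      NA_real_
    }
    tibble::tibble(cpg_id = rownames(m)[i], r = r, n_used = n_used)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      direction = dplyr::case_when(is.na(.data$r) ~ NA_character_,
                                   .data$r > 0 ~ "hyper",
                                   .data$r < 0 ~ "hypo",
                                   TRUE ~ "none"),
      defined = !is.na(.data$r)
    )
}

#' Select age-related CpGs by a correlation cutoff
#'
#' Keeps CpGs with absolute correlation strictly greater than the
#' threshold (the screening rule r above 0.85 or below -0.85 that defines
#' an AR-CpG), sorted by descending absolute r. Undefined correlations are
#' excluded.
#'
#' @param correlations Output of [correlate_with_age()].
#' @param threshold Absolute-correlation cutoff in `(0, 1)`; default 0.85.
#' @return An `ar_cpg_set`: the selected rows as a tibble, with attributes
#'   `threshold`, `n_hypo` and `n_hyper` (also shown by [glance()]).
#' @export
select_ar_cpgs <- function(correlations, threshold = 0.85) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.")
  }
  sel <- correlations |>
    dplyr::filter(.data$defined, abs(.data$r) > threshold) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)))
  out <- tibble::new_tibble(sel, class = "ar_cpg_set")
  attr(out, "threshold") <- threshold
  attr(out, "n_hypo") <- sum(sel$direction == "hypo")
  attr(out, "n_hyper") <- sum(sel$direction == "hyper")
  out
}

#' Keep the most variable half of an AR-CpG set
#'
#' The pre-filter applied before subset search: computes each member CpG's
#' interquartile range of beta values and keeps members whose IQR is
#' strictly above the median IQR over the set. For an even-sized set this
#' keeps exactly half (102 candidate AR-CpGs reduce to 51). If strict
#' filtering would leave fewer than 2 CpGs (e.g. all IQRs equal), the rule
#' falls back to `>=` the median so the result stays usable.
#'
#' @param beta A beta table containing the set's CpGs.
#' @param set An `ar_cpg_set` (or any tibble with `cpg_id`), >= 2 members.
#' @return The filtered set as a tibble with an added `iqr` column,
#'   ordering preserved.
#' @export
filter_by_variability <- function(beta, set) {
  if (nrow(set) < 2L) abort("Variability filtering needs a set of at least 2 CpGs.")
  m <- beta_to_matrix(beta)
  miss <- setdiff(set$cpg_id, rownames(m))
  if (length(miss) > 0L) {
    abort(paste0("CpGs absent from the beta table: ", paste(head(miss, 5), collapse = ", ")))
  }
  iqr <- apply(m[set$cpg_id, , drop = FALSE], 1, stats::IQR, na.rm = TRUE)
  med <- median(iqr)
  keep <- iqr > med
  if (sum(keep) < 2L) keep <- iqr >= med
  out <- set[keep, , drop = FALSE]
  out$iqr <- unname(iqr[keep])
  tibble::as_tibble(out)
}

#' @export
glance.ar_cpg_set <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x),
    n_hypo = attr(x, "n_hypo"),
    n_hyper = attr(x, "n_hyper"),
    threshold = attr(x, "threshold")
  )
}

#' @export
print.ar_cpg_set <- function(x, ...) {
  cat(sprintf("<ar_cpg_set> %d CpGs with |r| > %.3g (%d hypo, %d hyper)\n",
              nrow(x), attr(x, "threshold"), attr(x, "n_hypo"), attr(x, "n_hyper")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
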