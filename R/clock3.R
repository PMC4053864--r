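#' The three-CpG pyrosequencing clock
#'
#' Constructor for a three-CpG linear age model over the pyrosequencing
#' markers alpha (cg02228185, *ASPA*), beta (cg25809905, *ITGA2B*) and
#' gamma (the CpG directly upstream of cg17861230 in *PDE4C*, which shows
#' the stronger age correlation in pyrosequencing assays). Called with no
#' arguments it returns the published coefficients, stored exactly as
#' printed:
#'
#' \deqn{\widehat{age} = 38.0 - 26.4\,\alpha - 23.7\,\beta + 164.7\,\gamma}
#'
#' The printed equation is the public contract of the clock (it is also
#' what the original online calculator evaluates), so no re-derived extra
#' digits are introduced.
#'
#' @param intercept Intercept in years.
#' @param w_alpha,w_beta,w_gamma Weights in years per unit methylation
#'   fraction.
#' @param provenance Free-text training description.
#' @return An object of class `three_cpg_model` with fields `intercept`,
#'   `coefficients` (named `alpha`, `beta`, `gamma`), `markers` and
#'   `provenance`.
#' @examples
#' three_cpg_model() # the published clock
#' @export
three_cpg_model <- function(intercept = 38.0, w_alpha = -26.4,
                            w_beta = -23.7, w_gamma = 164.7,
                            provenance = "published pyrosequencing clock") {
  vals <- c(intercept, w_alpha, w_beta, w_gamma)
  if (!all(is.finite(vals))) abort("All clock coefficients must be finite.")
  structure(
    list(
      intercept = intercept,
      coefficients = c(alpha = w_alpha, beta = w_beta, gamma = w_gamma),
      markers = c(alpha = "cg02228185 (ASPA)", beta = "cg25809905 (ITGA2B)",
                  gamma = "CpG upstream of cg17861230 (PDE4C)"),
      provenance = provenance
    ),
    class = "three_cpg_model"
  )
}

#' Predict age with the published three-CpG equation
#'
#' Evaluates `38.0 - 26.4*alpha - 23.7*beta + 164.7*gamma` exactly, with no
#' clipping: negative predicted ages are meaningful (pluripotent cells, for
#' instance, come out below zero).
#'
#' @param alpha,beta,gamma Methylation fractions in `[0, 1]` (vectors
#'   recycle in parallel). Percent values must be divided by 100 upstream,
#'   e.g. via [read_pyro_table()] with `unit = "percent"`.
#' @param model A `three_cpg_model`; defaults to the published
#'   coefficients.
#' @return Predicted age(s) in years.
#' @examples
#' predict_age_published(0, 0, 0)        # 38.0
#' predict_age_published(0.5, 0.5, 0.5)  # 95.3
#' @export
predict_age_published <- function(alpha, beta, gamma, model = three_cpg_model()) {
  for (v in list(alpha = alpha, beta = beta, gamma = gamma)) {
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort("Methylation fractions must lie in [0, 1]; convert percent inputs first.")
    }
  }
  model$intercept + model$coefficients[["alpha"]] * alpha +
    model$coefficients[["beta"]] * beta + model$coefficients[["gamma"]] * gamma
}

#' Predict ages for a pyrosequencing table
#'
#' Applies a three-CpG clock to each row of a pyro table; when a sample
#' table with chronological ages is supplied, signed deviations and
#' aggregate error metrics are attached as for [predict_ages()].
#'
#' @param pyro A pyro table (`sample_id`, `alpha`, `beta`, `gamma`), see
#'   [read_pyro_table()].
#' @param samples Optional sample table with `age_years`.
#' @param model A `three_cpg_model` (published coefficients by default).
#' @return A `prediction_report` tibble: `sample_id`, `predicted_age`, and
#'   with ages also `age_years` and `deviation`; aggregate MAD/RMSE/R² via
#'   [glance()].
#' @export
predict_clock3 <- function(pyro, samples = NULL, model = three_cpg_model()) {
  pyro <- validate_pyro(pyro)
  pred <- predict_age_published(pyro$alpha, pyro$beta, pyro$gamma, model = model)
  build_prediction_report(pyro$sample_id, pred, samples)
}

#' Refit a three-CpG clock from pyrosequencing training data
#'
#' Ordinary least squares of chronological age on the three marker
#' fractions, the same model family as the published equation but with
#' coefficients estimated from the supplied training table.
#'
#' @param pyro A pyro table.
#' @param samples A sample table supplying `age_years`.
#' @return A `three_cpg_model` with fresh coefficients and provenance.
#' @export
fit_three_cpg_model <- function(pyro, samples) {
  pyro <- validate_pyro(pyro)
  samples <- validate_samples(samples)
  d <- dplyr::inner_join(pyro, samples[, c("sample_id", "age_years")], by = "sample_id")
  d <- d[stats::complete.cases(d[, c("alpha", "beta", "gamma", "age_years")]), ]
  if (nrow(d) < 5L) abort("Need at least 5 complete samples to fit a three-CpG clock.")
  if (sd(d$age_years) == 0) {
    return(three_cpg_model(
      intercept = d$age_years[1], w_alpha = 0, w_beta = 0, w_gamma = 0,
      provenance = sprintf("refit on %d samples (constant age)", nrow(d))
    ))
  }
  X <- cbind(1, d$alpha, d$beta, d$gamma)
  qr_x <- qr(X)
  if (qr_x$rank < 4L) abort("Collinear pyrosequencing markers: cannot fit a unique model.")
  cf <- qr.coef(qr_x, d$age_years)
  three_cpg_model(
    intercept = cf[1], w_alpha = cf[2], w_beta = cf[3], w_gamma = cf[4],
    provenance = sprintf("OLS refit on %d pyrosequencing samples", nrow(d))
  )
}

#' Epigenetic age deviation (age acceleration)
#'
#' `predicted - chronological`, signed: positive means the sample appears
#' epigenetically older than its chronological age.
#'
#' @param predicted,chronological Ages in years (vectors recycle).
#' @return Deviation in years.
#' @examples
#' age_deviation(60, 50) # +10
#' @export
age_deviation <- function(predicted, chronological) {
  if (any(!is.finite(predicted)) || any(!is.finite(chronological))) {
    abort("Predicted and chronological ages must be finite.")
  }
  predicted - chronological
}

#' Compare age deviation between donor groups
#'
#' Summarises the signed deviation per group and compares each group with
#' the reference by a two-sided Wilcoxon rank-sum test. This is a
#' descriptive comparison of deviation distributions (e.g. aplastic anemia
#' or dyskeratosis congenita patients vs healthy donors); it does not claim
#' a specific parametric model.
#'
#' @param report A `prediction_report` containing `sample_id` and
#'   `deviation`.
#' @param groups A data frame with `sample_id` and a `group` column.
#' @param reference Name of the reference group (default `"healthy"`).
#' @return A tibble: `group`, `n`, `median_deviation`, `p_value` (NA for
#'   the reference row).
#' @export
compare_deviation_groups <- function(report, groups, reference = "healthy") {
  if (!"deviation" %in% names(report)) {
    abort("`report` must contain a `deviation` column (supply chronological ages when predicting).")
  }
  d <- dplyr::inner_join(
    tibble::as_tibble(report)[, c("sample_id", "deviation")],
    tibble::as_tibble(groups)[, c("sample_id", "group")],
    by = "sample_id"
  )
  if (!reference %in% d$group) abort(sprintf("Reference group '%s' not present.", reference))
  ref_dev <- d$deviation[d$group == reference]
  d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_deviation = median(.data$deviation),
      p_value = if (.data$group[1] == reference) NA_real_ else
        suppressWarnings(stats::wilcox.test(.data$deviation, ref_dev)$p.value),
      .groups = "drop"
    )
}

#' @export
print.three_cpg_model <- function(x, ...) {
  cat("<three_cpg_model>\n")
  cat(sprintf("  predicted age = %.6g %+.6g*alpha %+.6g*beta %+.6g*gamma\n",
              x$intercept, x$coefficients[["alpha"]], x$coefficients[["beta"]],
              x$coefficients[["gamma"]]))
  cat("  markers:", paste(x$markers, collapse = "; "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
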