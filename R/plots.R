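#' Plot methods
#'
#' `autoplot()` methods for the package's result objects, all returning
#' ggplot objects ready for further theming.
#'
#' * `prediction_report`: predicted vs chronological age with the identity
#'   line and the MAD/RMSE/R² annotation.
#' * `subset_search`: test MAD of the RFE subsets against the
#'   full-candidate baseline, per split ratio.
#' * `frequency_ranking`: per-CpG occurrence frequency among retained
#'   subsets, with the signature cutoff marked.
#'
#' @param object A result object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name methclock-autoplot
NULL

#' @rdname methclock-autoplot
#' @export
autoplot.prediction_report <- function(object, ...) {
  if (!"age_years" %in% names(object)) {
    abort("This report has no chronological ages; nothing to plot against.")
  }
  g <- glance(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$age_years, y = .data$predicted_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Chronological age (years)", y = "Predicted age (years)",
      title = "Epigenetic age prediction",
      subtitle = sprintf("MAD %.2f yr | RMSE %.2f yr | R² %.3f",
                         g$mad_years, g$rmse_years, g$r_squared)
    )
}

#' @rdname methclock-autoplot
#' @export
autoplot.subset_search <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("test_mad", "baseline_test_mad"),
                        names_to = "model", values_to = "mad") |>
    dplyr::mutate(model = ifelse(.data$model == "test_mad",
                                 sprintf("%d-CpG subset", attr(object, "k")),
                                 "all candidates"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$split_ratio), y = .data$mad,
                                  fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "Training split ratio", y = "Test MAD (years)",
                  fill = NULL, title = "Subset search performance")
}

#' @rdname methclock-autoplot
#' @export
autoplot.frequency_ranking <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$cpg_id <- factor(d$cpg_id, levels = rev(d$cpg_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$cpg_id)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "freq_threshold"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Frequency in retained subsets", y = NULL,
                  title = "AR-CpG occurrence frequency",
                  subtitle = sprintf("%d retained subsets", attr(object, "n_retained")))
}
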