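#' Fit a telomere-length age model
#'
#' Telomere length declines roughly linearly with age, so a linear
#' regression on healthy donors gives a (coarse) age predictor. The default
#' fits the biology-forward direction, `length ~ age`, and inverts the line
#' for prediction; `direction = "age_on_length"` regresses age on length
#' directly instead (the two give different least-squares answers on noisy
#' data, and both are offered).
#'
#' @param telomeres A telomere table (see [read_telomere_table()]).
#' @param samples A sample table supplying `age_years`.
#' @param cell_type Which cell population to use (default `"granulocyte"`).
#' @param group Donor group to fit on (default `"healthy"`).
#' @param direction `"length_on_age"` (default) or `"age_on_length"`.
#' @return A `telomere_age_model`: `intercept_kb`, `slope_kb_per_year`
#'   (expected negative), `direction`, `n`.
#' @export
fit_telomere_model <- function(telomeres, samples, cell_type = "granulocyte",
                               group = "healthy",
                               direction = c("length_on_age", "age_on_length")) {
  direction <- match.arg(direction)
  telomeres <- validate_telomeres(telomeres)
  samples <- validate_samples(samples)
  d <- telomeres |>
    dplyr::filter(.data$cell_type == !!cell_type, .data$group == !!group) |>
    dplyr::inner_join(samples[, c("sample_id", "age_years")], by = "sample_id")
  if (nrow(d) < 3L) abort("Need at least 3 matching healthy samples of the requested cell type.")
  if (sd(d$age_years) == 0) abort("Ages are constant; no regression possible.")
  if (direction == "length_on_age") {
    fit <- lm(telomere_length_kb ~ age_years, data = d)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
  } else {
    fit <- lm(age_years ~ telomere_length_kb, data = d)
    b <- unname(coef(fit)[2])
    if (b == 0) abort("Zero slope: age is not predictable from telomere length.")
    # Re-express as length = intercept + slope * age so both directions
    # share one representation; prediction inverts it again.
    slope <- 1 / b
    intercept <- -unname(coef(fit)[1]) / b
  }
  if (abs(slope) < .Machine$double.eps^0.5) {
    abort("Zero slope: age is not predictable from telomere length.")
  }
  structure(list(intercept_kb = intercept, slope_kb_per_year = slope,
                 direction = direction, n = nrow(d)),
            class = "telomere_age_model")
}

#' Predict age from telomere length
#'
#' Inverts the fitted attrition line: `age = (length - intercept) / slope`,
#' unclipped.
#'
#' @param model A `telomere_age_model`.
#' @param length_kb Telomere length(s) in kilobases.
#' @return Predicted age(s) in years.
#' @examples
#' m <- structure(list(intercept_kb = 10, slope_kb_per_year = -0.039,
#'                     direction = "length_on_age", n = NA),
#'                class = "telomere_age_model")
#' predict_age_from_telomere(m, 8.05) # 50
#' @export
predict_age_from_telomere <- function(model, length_kb) {
  if (!inherits(model, "telomere_age_model")) abort("`model` must be a telomere_age_model.")
  (length_kb - model$intercept_kb) / model$slope_kb_per_year
}

#' Associate age deviation with a clinical or lifestyle covariate
#'
#' Univariate linear regression with the signed deviation of predicted
#' from chronological age as the dependent variable and the covariate as
#' the independent variable. Ordered categories (factor or character) are
#' coded to consecutive integers (e.g. number-of-children categories 0, 1,
#' 2, >=3 become 0..3); logicals to 0/1. Reports the slope (years of
#' deviation per covariate unit), its standard error, the classical
#' two-sided t-test p-value and the complete-case count; optionally the
#' same model per sex stratum. P-values are reported raw, per covariate —
#' this is an exploratory screen, not a corrected family of tests.
#'
#' @param deviations A data frame with `sample_id` and `deviation` (years),
#'   e.g. a `prediction_report`.
#' @param samples A sample table carrying the covariate column.
#' @param covariate Name of the covariate column in `samples`.
#' @param stratify_by_sex Also fit separate models for `"male"` and
#'   `"female"` strata (requires a `sex` column).
#' @return A tibble: `covariate`, `stratum` (`"all"`, `"male"`,
#'   `"female"`), `slope`, `se`, `p_value`, `n`.
#' @export
associate_deviation <- function(deviations, samples, covariate,
                                stratify_by_sex = FALSE) {
  samples <- validate_samples(samples)
  if (!"deviation" %in% names(deviations)) abort("`deviations` must contain a `deviation` column.")
  if (!covariate %in% names(samples)) {
    abort(sprintf("Covariate '%s' not found in the sample table.", covariate))
  }
  d <- dplyr::inner_join(tibble::as_tibble(deviations)[, c("sample_id", "deviation")],
                         samples, by = "sample_id")
  x <- d[[covariate]]
  if (is.character(x) || is.factor(x)) x <- as.integer(factor(x)) - 1L
  if (is.logical(x)) x <- as.integer(x)
  d$..x <- as.numeric(x)
  fit_one <- function(dd, stratum) {
    dd <- dd[stats::complete.cases(dd[, c("deviation", "..x")]), ]
    if (nrow(dd) < 3L) {
      abort(sprintf("Fewer than 3 complete cases for covariate '%s' (stratum %s).",
                    covariate, stratum))
    }
    if (sd(dd$..x) == 0) {
      abort(sprintf("Covariate '%s' is constant (stratum %s); no association estimable.",
                    covariate, stratum))
    }
    sm <- summary(lm(deviation ~ ..x, data = dd))$coefficients
    tibble::tibble(covariate = covariate, stratum = stratum,
                   slope = sm[2, 1], se = sm[2, 2], p_value = sm[2, 4],
                   n = nrow(dd))
  }
  out <- fit_one(d, "all")
  if (stratify_by_sex) {
    if (!"sex" %in% names(d)) abort("`stratify_by_sex = TRUE` requires a `sex` column.")
    for (s in c("male", "female")) {
      out <- dplyr::bind_rows(out, fit_one(d[d$sex %in% s, , drop = FALSE], s))
    }
  }
  out
}

#' Binary (Shannon) entropy of a methylation fraction
#'
#' `H(b) = -(b log2 b + (1-b) log2 (1-b))` in bits, with the convention
#' `0 * log2(0) = 0`. Epigenetic drift pushes CpGs towards 50%
#' methylation, i.e. towards the entropy maximum of 1 bit; fully
#' methylated or unmethylated sites carry 0 bits.
#'
#' @param beta Methylation fraction(s) in `[0, 1]`.
#' @return Entropy in bits, same length as `beta`.
#' @examples
#' methylation_entropy(c(0, 0.5, 1)) # 0, 1, 0
#' @export
methylation_entropy <- function(beta) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    abort("`beta` must lie in [0, 1].")
  }
  term <- function(p) ifelse(p == 0, 0, p * log2(p))
  -(term(beta) + term(1 - beta))
}

#' @export
tidy.telomere_age_model <- function(x, ...) {
  tibble::tibble(term = c("intercept_kb", "slope_kb_per_year"),
                 estimate = c(x$intercept_kb, x$slope_kb_per_year))
}

#' @export
glance.telomere_age_model <- function(x, ...) {
  tibble::tibble(intercept_kb = x$intercept_kb,
                 slope_kb_per_year = x$slope_kb_per_year,
                 attrition_bp_per_year = -1000 * x$slope_kb_per_year,
                 direction = x$direction, n = x$n)
}

#' @export
print.telomere_age_model <- function(x, ...) {
  cat(sprintf("<telomere_age_model> length = %.4g kb %+.4g kb/yr * age (%s, n = %s)\n",
              x$intercept_kb, x$slope_kb_per_year, x$direction, x$n))
  invisible(x)
}
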