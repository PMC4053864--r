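new_linear_age_model <- function(intercept, coefficients, provenance = "") {
  structure(
    list(intercept = unname(intercept),
         coefficients = coefficients,
         provenance = provenance),
    class = "linear_age_model"
  )
}

#' Fit a multivariate linear age predictor
#'
#' Ordinary least squares of chronological age on the beta values of the
#' chosen CpGs — the workhorse of every clock in this package. No
#' regularisation by default (a plain multivariate linear model); a ridge
#' penalty is available for designs where the marker count approaches the
#' sample count. Missing betas abort the fit unless per-CpG mean imputation
#' is explicitly requested (and then it is announced, never silent).
#'
#' @param beta A beta table.
#' @param samples A sample table with `age_years`.
#' @param cpgs Character vector of CpG ids to use; `NULL` means all rows of
#'   `beta`.
#' @param impute If `TRUE`, missing betas are replaced by the CpG's mean
#'   over the training samples (reported via a message).
#' @param ridge_lambda Optional non-negative ridge penalty (0 = plain OLS).
#' @return A `linear_age_model`: `intercept` (years), `coefficients`
#'   (named, years per unit beta fraction), `provenance`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(
#'   n_samples = 30, age_range = c(0, 80),
#'   ar_cpgs = tibble::tibble(cpg_id = "cg_a", intercept = 0.1, slope = 0.005),
#'   seed = 1
#' ))
#' fit_age_model(sim$beta, sim$samples) # weight 200, intercept -20
#' @export
fit_age_model <- function(beta, samples, cpgs = NULL, impute = FALSE,
                          ridge_lambda = 0) {
  al <- align_samples(beta, samples)
  m <- beta_to_matrix(al$beta)
  if (!is.null(cpgs)) {
    miss <- setdiff(cpgs, rownames(m))
    if (length(miss) > 0L) {
      abort(paste0("Requested CpGs absent from the beta table: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    m <- m[cpgs, , drop = FALSE]
  }
  m <- impute_or_abort(m, impute)
  age <- al$samples$age_years
  p <- nrow(m)
  n <- ncol(m)
  if (n <= p + 1L) {
    abort(sprintf("Need more than %d samples to fit %d CpG weights plus an intercept (have %d).",
                  p + 1L, p, n))
  }
  if (sd(age) == 0) {
    return(new_linear_age_model(age[1], setNames(rep(0, p), rownames(m)),
                                provenance = sprintf("constant-age fit on %d samples", n)))
  }
  X <- cbind(`(Intercept)` = 1, t(m))
  if (ridge_lambda > 0) {
    # Penalise only the CpG weights, never the intercept.
    D <- diag(c(0, rep(sqrt(ridge_lambda), p)))
    Xa <- rbind(X, D)
    ya <- c(age, rep(0, p + 1L))
    cf <- qr.coef(qr(Xa), ya)
  } else {
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      abort("Rank-deficient design (duplicated or collinear CpG rows); cannot fit a unique model.")
    }
    cf <- qr.coef(qr_x, age)
  }
  new_linear_age_model(
    cf[1], cf[-1],
    provenance = sprintf("OLS fit: %d CpGs, %d samples%s", p, n,
                         if (ridge_lambda > 0) sprintf(", ridge lambda %g", ridge_lambda) else "")
  )
}

impute_or_abort <- function(m, impute) {
  if (!anyNA(m)) return(m)
  if (!impute) {
    abort("Beta values contain missing entries; pass `impute = TRUE` for per-CpG mean imputation.")
  }
  n_miss <- sum(is.na(m))
  for (i in seq_len(nrow(m))) {
    na_i <- is.na(m[i, ])
    if (any(na_i)) {
      mu <- mean(m[i, !na_i])
      if (!is.finite(mu)) abort(sprintf("CpG %s has no observed values to impute from.", rownames(m)[i]))
      m[i, na_i] <- mu
    }
  }
  message(sprintf("Imputed %d missing beta value(s) by per-CpG training means.", n_miss))
  m
}

#' Predict donor ages from a beta table
#'
#' `predicted = intercept + sum(weight * beta)` per sample, never clipped:
#' negative predictions carry information (reprogrammed pluripotent cells
#' land below zero). When a sample table with chronological ages is given,
#' deviations and aggregate MAD/RMSE/R² are attached.
#'
#' @param model A `linear_age_model` (or `three_cpg_model` coerced via its
#'   alpha/beta/gamma coefficients being matched by name).
#' @param beta A beta table containing every CpG the model uses.
#' @param samples Optional sample table with `age_years`.
#' @param impute Mean-impute missing betas (per CpG) before predicting.
#' @return A `prediction_report` tibble: `sample_id`, `predicted_age`,
#'   plus `age_years` and `deviation` when ages are available. Aggregate
#'   metrics via [glance()].
#' @export
predict_ages <- function(model, beta, samples = NULL, impute = FALSE) {
  if (!inherits(model, "linear_age_model")) abort("`model` must be a linear_age_model.")
  m <- beta_to_matrix(beta)
  need <- names(model$coefficients)
  miss <- setdiff(need, rownames(m))
  if (length(miss) > 0L) {
    abort(paste0("Beta table is missing model CpGs: ", paste(head(miss, 5), collapse = ", ")))
  }
  m <- impute_or_abort(m[need, , drop = FALSE], impute)
  pred <- model$intercept + as.numeric(crossprod(m, model$coefficients))
  build_prediction_report(colnames(m), pred, samples)
}

build_prediction_report <- function(sample_ids, predicted, samples = NULL) {
  out <- tibble::tibble(sample_id = sample_ids, predicted_age = predicted)
  metrics <- NULL
  if (!is.null(samples)) {
    samples <- validate_samples(samples)
    out <- dplyr::left_join(out, samples[, c("sample_id", "age_years")], by = "sample_id")
    out$deviation <- out$predicted_age - out$age_years
    ok <- !is.na(out$age_years)
    if (sum(ok) >= 2L) {
      metrics <- compute_metrics(out$predicted_age[ok], out$age_years[ok])
    }
  }
  out <- tibble::new_tibble(out, class = "prediction_report")
  attr(out, "metrics") <- metrics
  out
}

#' Prediction error metrics
#'
#' MAD is the mean absolute deviation of predicted from actual age, RMSE
#' the root mean square error, both in years. `r_squared` is the squared
#' Pearson correlation between predicted and actual age — deliberately not
#' `1 - SSE/SST`, so that a prediction with a systematic linear offset
#' (as seen when transferring a clock across array platforms) still scores
#' by its correlation. With zero variance in the actual ages `r_squared`
#' is undefined and reported as `NA`.
#'
#' @param predicted,actual Numeric vectors of equal length >= 2, years.
#' @return A one-row tibble: `mad_years`, `rmse_years`, `r_squared`.
#' @examples
#' compute_metrics(c(10, 20), c(12, 26)) # mad 4, rmse sqrt(20)
#' @export
compute_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) abort("`predicted` and `actual` must have equal length.")
  if (length(actual) < 2L) abort("Need at least 2 pairs to compute metrics.")
  err <- predicted - actual
  r2 <- if (sd(actual) > 0 && sd(predicted) > 0) cor(predicted, actual)^2 else NA_real_
  tibble::tibble(
    mad_years = mean(abs(err)),
    rmse_years = sqrt(mean(err^2)),
    r_squared = r2
  )
}

#' Leave-one-out cross-validation of a linear age model
#'
#' Each sample is predicted by the model fitted on all other samples. The
#' held-out predictions are obtained through the exact hat-matrix identity
#' for linear least squares (loo residual = residual / (1 - leverage)),
#' which is algebraically identical to refitting n times but runs in a
#' single decomposition.
#'
#' @inheritParams fit_age_model
#' @return A `prediction_report` over the held-out predictions, with
#'   MAD/RMSE/R² via [glance()].
#' @export
loocv <- function(beta, samples, cpgs = NULL, impute = FALSE) {
  al <- align_samples(beta, samples)
  m <- beta_to_matrix(al$beta)
  if (!is.null(cpgs)) m <- m[cpgs, , drop = FALSE]
  m <- impute_or_abort(m, impute)
  age <- al$samples$age_years
  p <- nrow(m)
  n <- ncol(m)
  if (n <= p + 2L) {
    abort(sprintf("LOOCV needs more than %d samples for %d CpGs (have %d).", p + 2L, p, n))
  }
  X <- cbind(1, t(m))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) abort("Rank-deficient design; cannot run LOOCV.")
  fitted <- qr.fitted(qr_x, age)
  Q <- qr.Q(qr_x)
  h <- rowSums(Q^2)
  if (any(h >= 1 - 1e-12)) {
    abort("A sample has leverage 1 (it is not predictable from the others).")
  }
  loo_pred <- age - (age - fitted) / (1 - h)
  build_prediction_report(colnames(m), loo_pred, al$samples)
}

#' Refit an age model on the markers a platform actually measures
#'
#' When moving a clock between array platforms some training CpGs are not
#' assayed (e.g. 99 of 102 markers on a newer chip); applying the old
#' weights then shows a systematic offset. This refits the model from
#' scratch, restricted to the intersection of the requested markers and
#' the beta table's CpGs, and records the dropped markers in the
#' provenance.
#'
#' @inheritParams fit_age_model
#' @param available_cpgs Character vector of markers the target platform
#'   provides.
#' @return A `linear_age_model` trained on the intersection.
#' @export
refit_on_marker_subset <- function(beta, samples, available_cpgs, impute = FALSE) {
  if (length(available_cpgs) == 0L) abort("`available_cpgs` must be non-empty.")
  present <- intersect(available_cpgs, beta$cpg_id)
  if (length(present) == 0L) {
    abort("None of the requested markers is present in the beta table.")
  }
  dropped <- setdiff(available_cpgs, present)
  model <- fit_age_model(beta, samples, cpgs = present, impute = impute)
  model$provenance <- paste0(
    model$provenance,
    sprintf("; marker-subset refit (%d of %d requested markers%s)",
            length(present), length(available_cpgs),
            if (length(dropped) > 0)
              paste0("; dropped: ", paste(dropped, collapse = ", ")) else "")
  )
  model
}

#' @export
tidy.linear_age_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.linear_age_model <- function(x, ...) {
  tibble::tibble(n_markers = length(x$coefficients),
                 intercept = x$intercept,
                 provenance = x$provenance)
}

#' @export
tidy.three_cpg_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    marker = c(NA_character_, unname(x$markers))
  )
}

#' @export
tidy.prediction_report <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.prediction_report <- function(x, ...) {
  m <- attr(x, "metrics")
  if (is.null(m)) {
    return(tibble::tibble(n = nrow(x), mad_years = NA_real_,
                          rmse_years = NA_real_, r_squared = NA_real_))
  }
  dplyr::bind_cols(tibble::tibble(n = nrow(x)), m)
}

#' @export
print.linear_age_model <- function(x, ...) {
  cat(sprintf("<linear_age_model> intercept %.4g yr, %d CpG weights\n",
              x$intercept, length(x$coefficients)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d samples\n", nrow(x)))
  m <- attr(x, "metrics")
  if (!is.null(m)) {
    cat(sprintf("  MAD %.3g yr | RMSE %.3g yr | R^2 %.3g\n",
                m$mad_years, m$rmse_years, m$r_squared))
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
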