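# Shared fixture builders and independent oracles. Everything is generated
# in code; no fixture files.

# A tiny beta table with explicit values.
toy_beta <- function(values, cpg_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cpg_ids %||% rownames(m) %||% sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  matrix_to_beta(m)
}

toy_samples <- function(ages, sample_ids = NULL, ...) {
  tibble::tibble(sample_id = sample_ids %||% sprintf("S%02d", seq_along(ages)),
                 age_years = ages, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook sum-formula Pearson correlation, independent of stats::cor.
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Brute-force leave-one-out oracle: refit with lm() for every held-out sample.
loocv_oracle <- function(beta, samples) {
  m <- beta_to_matrix(beta)
  age <- samples$age_years[match(colnames(m), samples$sample_id)]
  vapply(seq_len(ncol(m)), function(i) {
    d <- data.frame(age = age[-i], t(m[, -i, drop = FALSE]))
    fit <- lm(age ~ ., data = d)
    unname(predict(fit, newdata = data.frame(t(m[, i, drop = FALSE]))))
  }, numeric(1))
}

# A cohort with two CpGs carrying all the age signal plus pure-noise CpGs,
# for feature-selection oracle tests.
planted_pair_instance <- function(n = 40, n_noise = 10, noise_sd = 0.005, seed = 1) {
  withr::with_seed(seed, {
    age <- runif(n, 0, 80)
    m <- rbind(
      sig_a = pmin(pmax(0.15 + 0.004 * age + rnorm(n, sd = noise_sd), 0), 1),
      sig_b = pmin(pmax(0.90 - 0.003 * age + rnorm(n, sd = noise_sd), 0), 1),
      matrix(pmin(pmax(0.5 + rnorm(n_noise * n, sd = 0.05), 0), 1),
             nrow = n_noise, dimnames = list(sprintf("noise%02d", seq_len(n_noise)), NULL))
    )
    colnames(m) <- sprintf("S%03d", seq_len(n))
    list(beta = matrix_to_beta(m), samples = toy_samples(age, colnames(m)))
  })
}

# Exhaustive size-k subset scoring on a fixed train/test split: fit each
# subset by lm() on the training samples, score by MAD on the test samples.
exhaustive_best_subset <- function(beta, samples, train_idx, k = 2) {
  m <- beta_to_matrix(beta)
  age <- samples$age_years
  test_idx <- setdiff(seq_len(ncol(m)), train_idx)
  subsets <- combn(rownames(m), k, simplify = FALSE)
  mads <- vapply(subsets, function(s) {
    d_train <- data.frame(age = age[train_idx], t(m[s, train_idx, drop = FALSE]))
    fit <- lm(age ~ ., data = d_train)
    pred <- predict(fit, newdata = data.frame(t(m[s, test_idx, drop = FALSE])))
    mean(abs(pred - age[test_idx]))
  }, numeric(1))
  list(subset = sort(subsets[[which.min(mads)]]), mad = min(mads), all_mads = mads)
}
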