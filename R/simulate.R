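#' Specify a synthetic methylation cohort
#'
#' Describes a cohort with planted age-related CpGs among background CpGs,
#' mirroring the statistical structure an epigenetic clock assumes: beta
#' values that drift linearly with donor age, bounded in `[0, 1]`, with
#' additive Gaussian measurement noise clipped at the boundaries.
#'
#' @param n_samples Number of donors (>= 2).
#' @param age_range Numeric length-2, `c(min_years, max_years)` with
#'   `min < max`; ages are drawn uniformly (or stratified, see
#'   [simulate_cohort()]).
#' @param ar_cpgs Tibble of planted age-related CpGs with columns `cpg_id`,
#'   `intercept` (beta fraction at age 0) and `slope` (beta units per year;
#'   sign gives the direction, positive = hypermethylated with age). The
#'   noise-free trajectory `intercept + slope * age` must stay inside
#'   `[0, 1]` over the whole age range.
#' @param n_background Number of non-age-related CpGs (constant level plus
#'   noise).
#' @param noise_sd Standard deviation (beta units) of the additive Gaussian
#'   noise; >= 0.
#' @param seed Integer seed; one global seed drives an independent derived
#'   stream per operation so each stage is reproducible on its own.
#' @return A `cohort_spec` object (validated list).
#' @export
cohort_spec <- function(n_samples, age_range, ar_cpgs, n_background = 0L,
                        noise_sd = 0, seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 2) abort("`n_samples` must be >= 2.")
  if (length(age_range) != 2L || !(age_range[1] < age_range[2])) {
    abort("`age_range` must be c(min, max) with min < max.")
  }
  if (any(age_range < 0)) abort("`age_range` must be non-negative.")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_background < 0) abort("`n_background` must be >= 0.")
  ar_cpgs <- tibble::as_tibble(ar_cpgs)
  need <- setdiff(c("cpg_id", "intercept", "slope"), names(ar_cpgs))
  if (length(need) > 0L) {
    abort(paste0("`ar_cpgs` is missing column(s): ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ar_cpgs$cpg_id)) abort("Planted CpG ids must be unique.")
  lo <- ar_cpgs$intercept + ar_cpgs$slope * age_range[1]
  hi <- ar_cpgs$intercept + ar_cpgs$slope * age_range[2]
  if (any(pmin(lo, hi) < 0) || any(pmax(lo, hi) > 1)) {
    abort("Every planted trajectory intercept + slope * age must stay inside [0, 1] over `age_range`.")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
      ar_cpgs = ar_cpgs, n_background = as.integer(n_background),
      noise_sd = as.numeric(noise_sd), seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Deterministic per-operation sub-stream: Weyl-style mix kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Simulate a methylation cohort
#'
#' Draws donor ages uniformly over the spec's age range (or stratified with
#' equal counts per 6-year bin, echoing how population cohorts are sampled
#' by age category), then sets each planted CpG to
#' `clip(intercept + slope * age + noise, 0, 1)` and each background CpG to
#' `clip(level + noise, 0, 1)` with a constant per-CpG level. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param stratify_ages If `TRUE`, ages are stratified into 6-year bins
#'   with equal counts per bin instead of plain uniform sampling.
#' @return A list with `beta` (beta table) and `samples` (sample table with
#'   `sample_id`, `age_years`).
#' @examples
#' spec <- cohort_spec(
#'   n_samples = 10, age_range = c(0, 80),
#'   ar_cpgs = tibble::tibble(cpg_id = "cg_up", intercept = 0.1, slope = 0.005),
#'   n_background = 3, noise_sd = 0, seed = 7
#' )
#' sim <- simulate_cohort(spec)
#' @export
simulate_cohort <- function(spec, stratify_ages = FALSE) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec object.")
  n <- spec$n_samples
  ages <- withr::with_seed(derive_seed(spec$seed, 1L), {
    if (stratify_ages) draw_stratified_ages(n, spec$age_range) else
      runif(n, spec$age_range[1], spec$age_range[2])
  })
  sample_ids <- sprintf("S%04d", seq_len(n))
  n_ar <- nrow(spec$ar_cpgs)
  planted <- if (n_ar > 0) {
    outer(seq_len(n_ar), seq_len(n), function(i, j) {
      spec$ar_cpgs$intercept[i] + spec$ar_cpgs$slope[i] * ages[j]
    })
  } else {
    matrix(numeric(0), nrow = 0, ncol = n)
  }
  bg_levels <- withr::with_seed(derive_seed(spec$seed, 2L),
                                runif(spec$n_background, 0.05, 0.95))
  background <- matrix(rep(bg_levels, times = n), nrow = spec$n_background, ncol = n)
  m <- rbind(planted, background)
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(derive_seed(spec$seed, 3L),
                              matrix(rnorm(length(m), sd = spec$noise_sd), nrow = nrow(m)))
    m <- m + noise
  }
  m <- pmin(pmax(m, 0), 1)
  rownames(m) <- c(spec$ar_cpgs$cpg_id, sprintf("bg%04d", seq_len(spec$n_background)))
  colnames(m) <- sample_ids
  list(
    beta = matrix_to_beta(m),
    samples = tibble::tibble(sample_id = sample_ids, age_years = ages)
  )
}

draw_stratified_ages <- function(n, age_range, bin_width = 6) {
  breaks <- seq(age_range[1], age_range[2], by = bin_width)
  if (breaks[length(breaks)] < age_range[2]) breaks <- c(breaks, age_range[2])
  n_bins <- length(breaks) - 1L
  bin <- rep(seq_len(n_bins), length.out = n)
  runif(n, breaks[bin], breaks[bin + 1L])
}

# Biological baseline trajectories for the two hypomethylated pyro markers;
# scatter gives the design matrix full rank, the feasibility window keeps
# the solved gamma inside [0, 1].
.pyro_alpha_base <- function(age) 0.90 - 0.002 * age
.pyro_beta_base <- function(age) 0.80 - 0.0015 * age

#' Simulate pyrosequencing triplets consistent with the published clock
#'
#' For each sample, draws alpha (*ASPA*) and beta (*ITGA2B*) fractions from
#' declining baseline curves with independent biological scatter, then
#' solves gamma (*PDE4C*) from the published three-CpG equation so that the
#' noise-free triplet predicts the sample's chronological age exactly.
#' Measurement noise is then added and values clipped to `[0, 1]`.
#'
#' The beta draw is clamped into the window that keeps the solved gamma in
#' `[0, 1]`; an error is raised only when that window is empty, i.e. the
#' age is not representable with all three fractions in `[0, 1]` (at
#' alpha = beta = 0 the maximum representable age is 38.0 + 164.7 = 202.7).
#'
#' @param samples A sample table with `sample_id` and `age_years`.
#' @param noise_sd Standard deviation of Gaussian measurement noise added
#'   to all three fractions (beta units).
#' @param seed Integer seed.
#' @return A pyro table: `sample_id`, `alpha`, `beta`, `gamma`.
#' @examples
#' s <- tibble::tibble(sample_id = c("a", "b"), age_years = c(25, 60))
#' p <- simulate_pyro(s, noise_sd = 0, seed = 1)
#' predict_age_published(p$alpha, p$beta, p$gamma)  # 25, 60
#' @export
simulate_pyro <- function(samples, noise_sd = 0, seed = 1L) {
  samples <- validate_samples(samples)
  cf <- three_cpg_model()
  n <- nrow(samples)
  withr::with_seed(derive_seed(seed, 11L), {
    age <- samples$age_years
    alpha <- clip01(.pyro_alpha_base(age) + rnorm(n, sd = 0.05))
    # gamma = (age - intercept - w_alpha*alpha - w_beta*beta) / w_gamma must
    # lie in [0, 1]; with w_beta < 0 < w_gamma that bounds the beta fraction:
    wa <- cf$coefficients[["alpha"]]
    wb <- cf$coefficients[["beta"]]
    wg <- cf$coefficients[["gamma"]]
    b_min <- (cf$intercept + wa * alpha - age) / (-wb) # gamma >= 0
    b_max <- b_min + wg / (-wb)                        # gamma <= 1
    lo <- pmax(0, b_min)
    hi <- pmin(1, b_max)
    if (any(lo > hi)) {
      bad <- which(lo > hi)[1]
      abort(sprintf(
        "Age %.1f is not representable with all three methylation fractions in [0, 1].",
        age[bad]
      ))
    }
    beta <- pmin(pmax(.pyro_beta_base(age) + rnorm(n, sd = 0.05), lo), hi)
    gamma <- (age - cf$intercept - wa * alpha - wb * beta) / wg
    if (noise_sd > 0) {
      alpha <- clip01(alpha + rnorm(n, sd = noise_sd))
      beta <- clip01(beta + rnorm(n, sd = noise_sd))
      gamma <- clip01(gamma + rnorm(n, sd = noise_sd))
    }
    tibble::tibble(sample_id = samples$sample_id, alpha = alpha,
                   beta = beta, gamma = gamma)
  })
}

#' Simulate telomere lengths with linear age attrition
#'
#' Telomere length declines roughly linearly with donor age — about 39 bp
#' per year in granulocytes — so lengths are generated as
#' `baseline_kb - attrition_bp_per_year/1000 * age + noise`, floored at a
#' small positive constant (flow-FISH never reports non-positive lengths).
#'
#' @param samples A sample table with ages.
#' @param baseline_kb Mean length at age 0, kilobases; must exceed the
#'   total expected attrition over the cohort's age range.
#' @param attrition_bp_per_year Attrition rate, base pairs per year
#'   (default 39).
#' @param noise_sd_kb Gaussian noise SD in kb.
#' @param seed Integer seed.
#' @param cell_type,group Constant annotations for the generated records.
#' @param floor_kb Minimum reported length.
#' @return A telomere table: `sample_id`, `telomere_length_kb`,
#'   `cell_type`, `group`.
#' @export
simulate_telomeres <- function(samples, baseline_kb = 10,
                               attrition_bp_per_year = 39,
                               noise_sd_kb = 0, seed = 1L,
                               cell_type = "granulocyte", group = "healthy",
                               floor_kb = 0.1) {
  samples <- validate_samples(samples)
  slope_kb <- attrition_bp_per_year / 1000
  if (baseline_kb - slope_kb * max(samples$age_years) <= 0) {
    abort("`baseline_kb` implies non-positive expected lengths over this age range.")
  }
  n <- nrow(samples)
  len <- withr::with_seed(derive_seed(seed, 21L), {
    baseline_kb - slope_kb * samples$age_years +
      if (noise_sd_kb > 0) rnorm(n, sd = noise_sd_kb) else 0
  })
  tibble::tibble(
    sample_id = samples$sample_id,
    telomere_length_kb = pmax(len, floor_kb),
    cell_type = cell_type, group = group
  )
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d samples, ages %.4g-%.4g yr, %d planted AR-CpGs, %d background CpGs, noise_sd %.4g, seed %d\n",
    x$n_samples, x$age_range[1], x$age_range[2], nrow(x$ar_cpgs),
    x$n_background, x$noise_sd, x$seed
  ))
  invisible(x)
}
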