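test_that("fitting a single noise-free CpG inverts the planted affine map", {
  spec <- cohort_spec(30, c(0, 100),
                      tibble::tibble(cpg_id = "cg_a", intercept = 0.1, slope = 0.005),
                      noise_sd = 0, seed = 1)
  sim <- simulate_cohort(spec)
  model <- fit_age_model(sim$beta, sim$samples)
  # beta = 0.1 + 0.005 * age  =>  age = -20 + 200 * beta
  expect_equal(unname(model$coefficients["cg_a"]), 200, tolerance = 1e-8)
  expect_equal(model$intercept, -20, tolerance = 1e-6)
})

test_that("degenerate designs are caught", {
  ages <- c(30, 30, 30, 30, 30)
  b <- toy_beta(rbind(cg1 = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  m <- fit_age_model(b, toy_samples(ages))
  expect_equal(m$intercept, 30)
  expect_equal(unname(m$coefficients), 0)
  # duplicated CpG rows are rank deficient
  b2 <- toy_beta(rbind(cg1 = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       cg2 = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_error(fit_age_model(b2, toy_samples(c(10, 20, 30, 40, 50))), "Rank-deficient")
  # too few samples for the marker count
  expect_error(fit_age_model(toy_beta(matrix(runif(6), 3, 2)), toy_samples(c(1, 2))),
               "more than")
})

test_that("prediction is affine, unclipped and reports metrics", {
  zero <- methclock:::new_linear_age_model(38.0, c(cg1 = 0))
  b <- toy_beta(rbind(cg1 = c(0.1, 0.8, 0.5)))
  r <- predict_ages(zero, b)
  expect_equal(r$predicted_age, rep(38.0, 3))
  # negative predictions are meaningful and kept
  neg <- methclock:::new_linear_age_model(38.0, c(cg1 = -26.4, cg2 = -23.7))
  b2 <- toy_beta(rbind(cg1 = 1, cg2 = 1))
  expect_equal(predict_ages(neg, b2)$predicted_age, -12.1)
  # metrics appear once chronological ages are supplied
  model <- methclock:::new_linear_age_model(0, c(cg1 = 100))
  b3 <- toy_beta(rbind(cg1 = c(0.1, 0.3, 0.6)))
  rep3 <- predict_ages(model, b3, toy_samples(c(10, 30, 60)))
  expect_equal(rep3$deviation, rep(0, 3))
  expect_equal(glance(rep3)$mad_years, 0)
  expect_error(predict_ages(model, toy_beta(rbind(other = 0.5))), "missing model CpGs")
})

test_that("prediction is linear in the beta matrix (convex combinations)", {
  withr::with_seed(31, {
    model <- methclock:::new_linear_age_model(5, c(a = 40, b = -60, c = 120))
    m1 <- matrix(runif(15), 3, 5, dimnames = list(c("a", "b", "c"), sprintf("S%d", 1:5)))
    m2 <- matrix(runif(15), 3, 5, dimnames = list(c("a", "b", "c"), sprintf("S%d", 1:5)))
  })
  lam <- 0.3
  mix <- matrix_to_beta(lam * m1 + (1 - lam) * m2)
  p_mix <- predict_ages(model, mix)$predicted_age
  p1 <- predict_ages(model, matrix_to_beta(m1))$predicted_age
  p2 <- predict_ages(model, matrix_to_beta(m2))$predicted_age
  expect_equal(p_mix, lam * p1 + (1 - lam) * p2)
})

test_that("error metrics follow their definitions", {
  expect_equal(compute_metrics(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(mad_years = 0, rmse_years = 0, r_squared = 1))
  off <- compute_metrics(c(12, 22, 32), c(10, 20, 30))
  expect_equal(off$mad_years, 2)
  expect_equal(off$rmse_years, 2)
  expect_equal(off$r_squared, 1)
  two <- compute_metrics(c(10, 20), c(12, 26))
  expect_equal(two$mad_years, 4)
  expect_equal(two$rmse_years, sqrt((4 + 36) / 2))
  expect_error(compute_metrics(1:3, 1:2), "equal length")
  # undefined R^2 under zero variance in the actual ages
  expect_true(is.na(compute_metrics(c(1, 2), c(5, 5))$r_squared))
})

test_that("MAD never exceeds RMSE and they vanish together", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(2:40, 1)
      m <- compute_metrics(rnorm(n, 50, 20), rnorm(n, 50, 20))
      expect_lte(m$mad_years, m$rmse_years + 1e-12)
    }
  })
})

test_that("hat-matrix LOOCV equals the brute-force refit oracle", {
  withr::with_seed(55, {
    for (i in 1:5) {
      n <- sample(8:30, 1)
      p <- sample(1:3, 1)
      spec <- cohort_spec(n, c(0, 80), default_planted_cpgs(p, 0.004),
                          n_background = 1, noise_sd = 0.05,
                          seed = sample.int(10000, 1))
      sim <- simulate_cohort(spec)
      lp <- loocv(sim$beta, sim$samples)
      expect_equal(lp$predicted_age, loocv_oracle(sim$beta, sim$samples),
                   tolerance = 1e-9)
    }
  })
  # and on exact linear structure held-out predictions are exact
  exact <- simulate_cohort(cohort_spec(15, c(0, 80), default_planted_cpgs(1, 0.004),
                                       noise_sd = 0, seed = 2))
  expect_lt(glance(loocv(exact$beta, exact$samples))$mad_years, 1e-6)
})

test_that("marker-subset refitting matches a direct fit on the intersection", {
  spec <- cohort_spec(80, c(0, 78), default_planted_cpgs(6, 0.004),
                      n_background = 4, noise_sd = 0.02, seed = 44)
  sim <- simulate_cohort(spec)
  all_cpgs <- sim$beta$cpg_id
  full <- fit_age_model(sim$beta, sim$samples)
  same <- refit_on_marker_subset(sim$beta, sim$samples, all_cpgs)
  expect_equal(same$coefficients, full$coefficients)
  expect_equal(same$intercept, full$intercept)
  # dropping markers the platform lacks is recorded and changes the fit
  avail <- c(setdiff(all_cpgs, c("ar001", "ar002")), "cg_not_on_chip")
  sub <- refit_on_marker_subset(sim$beta, sim$samples, avail)
  expect_false("ar001" %in% names(sub$coefficients))
  expect_match(sub$provenance, "cg_not_on_chip")
  expect_error(refit_on_marker_subset(sim$beta, sim$samples, "cg_nowhere"),
               "None of the requested markers")
})

test_that("missing betas abort unless imputation is explicitly requested", {
  spec <- cohort_spec(40, c(0, 78), default_planted_cpgs(2, 0.004),
                      noise_sd = 0.02, seed = 3)
  sim <- simulate_cohort(spec)
  sim$beta$S0001[1] <- NA
  expect_error(fit_age_model(sim$beta, sim$samples), "impute")
  expect_message(m <- fit_age_model(sim$beta, sim$samples, impute = TRUE), "Imputed 1")
  expect_length(m$coefficients, 2)
})

test_that("noisy-cohort LOOCV error stays near the noise floor", {
  # 10 planted CpGs, noise_sd 0.02: the per-CpG age-equivalent noise is
  # 0.02/0.004 = 5 yr; pooling 10 markers brings the floor near
  # 5/sqrt(10) = 1.6 yr. Check MAD < 3x that bound.
  spec <- cohort_spec(300, c(0, 78), default_planted_cpgs(10, 0.004),
                      noise_sd = 0.02, seed = 77)
  sim <- simulate_cohort(spec)
  mad <- glance(loocv(sim$beta, sim$samples))$mad_years
  expect_lt(mad, 3 * 5 / sqrt(10))
  expect_gt(mad, 0.1)
})
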