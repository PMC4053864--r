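test_that("RFE discards an uninformative CpG and keeps the signal carriers", {
  # five CpGs carry the age signal (independent jitter keeps them from
  # being mutually collinear); one more is pure noise
  withr::with_seed(13, {
    age <- runif(40, 0, 80)
    jit <- function() rnorm(40, sd = 0.01)
    m <- rbind(
      s1 = 0.10 + 0.004 * age + jit(), s2 = 0.90 - 0.004 * age + jit(),
      s3 = 0.20 + 0.003 * age + jit(), s4 = 0.80 - 0.003 * age + jit(),
      s5 = 0.15 + 0.005 * age + jit(),
      junk = runif(40, 0.3, 0.7)
    )
    colnames(m) <- sprintf("S%02d", 1:40)
  })
  sel <- rfe_select(matrix_to_beta(m), toy_samples(age, colnames(m)), k = 5)
  expect_setequal(as.character(sel), c("s1", "s2", "s3", "s4", "s5"))
  expect_equal(attr(sel, "elimination_order"), "junk")
  # k equal to the candidate count is the identity
  all6 <- rfe_select(matrix_to_beta(m), toy_samples(age, colnames(m)), k = 6)
  expect_setequal(as.character(all6), rownames(m))
  expect_error(rfe_select(matrix_to_beta(m), toy_samples(age, colnames(m)), k = 7),
               "k = 7")
})

test_that("per-split RFE subsets score in the top quartile of exhaustive subsets", {
  inst <- planted_pair_instance(n = 40, n_noise = 8, seed = 101)
  withr::with_seed(7, train_idx <- sort(sample.int(40, 24)))
  b_train <- inst$beta[, c(1, 1 + train_idx)]
  s_train <- inst$samples[train_idx, ]
  sel <- sort(as.character(rfe_select(b_train, s_train, k = 2)))
  ex <- exhaustive_best_subset(inst$beta, inst$samples, train_idx, k = 2)
  subsets <- combn(inst$beta$cpg_id, 2, simplify = FALSE)
  sel_mad <- ex$all_mads[vapply(subsets, function(s) setequal(s, sel), logical(1))]
  expect_lte(sel_mad, quantile(ex$all_mads, 0.25))
})

test_that("run_search is reproducible and invariant to CpG row order", {
  inst <- planted_pair_instance(n = 36, n_noise = 6, seed = 5)
  plan <- split_plan(ratios = 0.6, n_iterations = 3, seed = 9)
  res1 <- run_search(inst$beta, inst$samples, inst$beta$cpg_id, plan, k = 2)
  expect_equal(nrow(res1), 3L)
  res2 <- run_search(inst$beta, inst$samples, inst$beta$cpg_id, plan, k = 2)
  expect_identical(tibble::as_tibble(res1), tibble::as_tibble(res2))
  shuffled <- inst$beta[rev(seq_len(nrow(inst$beta))), ]
  res3 <- run_search(shuffled, inst$samples, shuffled$cpg_id, plan, k = 2)
  expect_equal(res3$selected_cpgs, res1$selected_cpgs)
  expect_equal(res3$test_mad, res1$test_mad)
  # a single-cell plan yields exactly one result row
  one <- run_search(inst$beta, inst$samples, inst$beta$cpg_id,
                    split_plan(ratios = 0.5, n_iterations = 1, seed = 1), k = 2)
  expect_equal(nrow(one), 1L)
})

test_that("splits too small for the baseline fit are refused", {
  inst <- planted_pair_instance(n = 20, n_noise = 10, seed = 2)
  expect_error(
    run_search(inst$beta, inst$samples, inst$beta$cpg_id,
               split_plan(ratios = 0.3, n_iterations = 1, seed = 1), k = 2),
    "training samples"
  )
})

test_that("frequency ranking counts occurrences among retained subsets only", {
  mk <- function(cpgs, mad, base) {
    tibble::tibble(split_ratio = 0.5, iteration = 1L,
                   selected_cpgs = list(sort(cpgs)), test_mad = mad,
                   baseline_test_mad = base)
  }
  one <- tibble::new_tibble(mk(c("a", "b", "c", "d", "e"), 2, 5), class = "subset_search")
  r1 <- filter_and_rank(one)
  expect_equal(attr(r1, "n_retained"), 1L)
  expect_true(all(r1$frequency == 1))
  expect_setequal(signature_cpgs(r1), c("a", "b", "c", "d", "e"))
  # two retained subsets sharing exactly one CpG
  two <- tibble::new_tibble(
    dplyr::bind_rows(mk(c("a", "b"), 2, 5), mk(c("a", "c"), 3, 5)),
    class = "subset_search"
  )
  r2 <- filter_and_rank(two)
  expect_equal(r2$frequency[r2$cpg_id == "a"], 1.0)
  expect_equal(r2$frequency[r2$cpg_id == "b"], 0.5)
  expect_setequal(signature_cpgs(r2), "a") # strict > 0.5
  # nothing beats the baseline: warn, empty signature
  bad <- tibble::new_tibble(mk(c("a", "b"), 9, 5), class = "subset_search")
  expect_warning(r3 <- filter_and_rank(bad), "No subset")
  expect_length(signature_cpgs(r3), 0)
})

test_that("the baseline filter only shrinks the retained list", {
  inst <- planted_pair_instance(n = 40, n_noise = 6, seed = 3)
  res <- run_search(inst$beta, inst$samples, inst$beta$cpg_id,
                    split_plan(ratios = c(0.5, 0.7), n_iterations = 4, seed = 21), k = 2)
  rk <- filter_and_rank(res)
  expect_lte(attr(rk, "n_retained"), nrow(res))
  # per-split pairing is the alternative baseline mode
  rk2 <- filter_and_rank(res, baseline = "per_split")
  expect_lte(attr(rk2, "n_retained"), nrow(res))
})

test_that("the end-to-end pipeline recovers a planted 5-CpG signature", {
  spec <- cohort_spec(120, c(0, 78), default_planted_cpgs(5, 0.005),
                      n_background = 40, noise_sd = 0.02, seed = 61)
  sim <- simulate_cohort(spec)
  res <- end_to_end_signature(sim$beta, sim$samples,
                              plan = split_plan(ratios = 0.6, n_iterations = 5, seed = 8))
  expect_setequal(res$signature, sprintf("ar%03d", 1:5))
  expect_true(any(grepl("Variability filter skipped", res$log)))
  # byte-identical ranking across runs
  res2 <- end_to_end_signature(sim$beta, sim$samples,
                               plan = split_plan(ratios = 0.6, n_iterations = 5, seed = 8))
  expect_identical(tibble::as_tibble(res$ranking), tibble::as_tibble(res2$ranking))
})

test_that("a cohort without age signal reports an empty signature", {
  spec <- cohort_spec(60, c(0, 78), default_planted_cpgs(0), n_background = 30,
                      noise_sd = 0.05, seed = 15)
  sim <- simulate_cohort(spec)
  res <- end_to_end_signature(sim$beta, sim$samples)
  expect_length(res$signature, 0)
  expect_true(any(grepl("No CpG passed", res$log)))
})

test_that("the variability pre-filter halves large candidate pools before search", {
  spec <- cohort_spec(150, c(0, 78), default_planted_cpgs(12, 0.005),
                      n_background = 30, noise_sd = 0.01, seed = 33)
  sim <- simulate_cohort(spec)
  res <- end_to_end_signature(sim$beta, sim$samples,
                              plan = split_plan(ratios = 0.6, n_iterations = 3, seed = 2))
  expect_equal(nrow(res$ar_set), 12L)
  expect_equal(nrow(res$candidates), 6L) # strictly-above-median keeps half
  expect_true(all(res$candidates$cpg_id %in% res$ar_set$cpg_id))
})
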