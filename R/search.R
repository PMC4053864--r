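#' Plan the iterative train/test splits of the signature search
#'
#' @param ratios Training fractions, each strictly in `(0, 1)`. Default
#'   `c(0.2, 0.4, 0.6, 0.8)` spans sparse to generous training sets.
#' @param n_iterations Random splits per ratio (>= 1), default 25.
#' @param seed Integer master seed; each `(ratio, iteration)` cell gets an
#'   independent derived stream so runs reproduce cell-by-cell.
#' @return A `split_plan` object.
#' @export
split_plan <- function(ratios = c(0.2, 0.4, 0.6, 0.8), n_iterations = 25L, seed = 1L) {
  if (any(ratios <= 0 | ratios >= 1)) abort("`ratios` must lie strictly between 0 and 1.")
  if (n_iterations < 1L) abort("`n_iterations` must be >= 1.")
  structure(list(ratios = as.numeric(ratios), n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Recursive feature elimination to a fixed CpG count
#'
#' Fits the linear age model on the remaining CpGs, scores each CpG by its
#' standardized coefficient (|weight| times the CpG's training standard
#' deviation — plain |weight| would confound the beta scale), removes the
#' least important, and repeats until `k` CpGs remain. One CpG is dropped
#' per step once 20 or fewer remain; above that the lowest-scoring 10% go
#' per step. Aliased (collinear) CpGs get importance zero, so one of a
#' collinear pair is eliminated first, with a message.
#'
#' @param beta A beta table of candidate CpGs (training samples only).
#' @param samples A sample table with ages for the training samples.
#' @param k Target signature size (default 5).
#' @return Character vector of the `k` retained CpG ids, with the
#'   elimination order (first-eliminated first) in attribute
#'   `"elimination_order"`.
#' @export
rfe_select <- function(beta, samples, k = 5L) {
  al <- align_samples(beta, samples)
  m <- beta_to_matrix(al$beta)
  if (anyNA(m)) abort("RFE requires complete beta values; impute or filter first.")
  age <- al$samples$age_years
  if (nrow(m) < k) abort(sprintf("Only %d candidate CpGs but k = %d.", nrow(m), k))
  remaining <- rownames(m)
  eliminated <- character(0)
  while (length(remaining) > k) {
    X <- cbind(1, t(m[remaining, , drop = FALSE]))
    if (ncol(X) > nrow(X)) {
      abort(sprintf("Training set too small (%d samples) to fit %d CpGs during elimination.",
                    nrow(X), length(remaining)))
    }
    cf <- qr.coef(qr(X), age)[-1]
    aliased <- is.na(cf)
    if (any(aliased)) {
      message(sprintf("Dropping collinear CpG(s) during elimination: %s",
                      paste(remaining[aliased], collapse = ", ")))
      cf[aliased] <- 0
    }
    sds <- apply(m[remaining, , drop = FALSE], 1, sd)
    importance <- abs(cf) * sds
    n_drop <- if (length(remaining) <= 20L) 1L else
      min(max(1L, floor(length(remaining) * 0.1)), length(remaining) - k)
    drop_idx <- order(importance)[seq_len(n_drop)]
    eliminated <- c(eliminated, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  structure(remaining, elimination_order = eliminated)
}

#' Run the iterative split / RFE subset search
#'
#' For every `(ratio, iteration)` cell of the plan: draw a random split
#' with `ratio` of the samples as training set, run [rfe_select()] on the
#' training side, fit the k-CpG subset model *and* the full-candidate-set
#' baseline model on the same training samples, and evaluate both by MAD
#' on the held-out test samples. Reproducible from the plan's seed.
#'
#' @param beta A beta table.
#' @param samples A sample table.
#' @param candidates Character vector of candidate CpG ids (typically the
#'   variability-filtered AR-CpG set), or a tibble with `cpg_id`.
#' @param plan A [split_plan()].
#' @param k Subset size handed to RFE (default 5).
#' @return A `subset_search` tibble, one row per cell: `split_ratio`,
#'   `iteration`, `selected_cpgs` (list column of character vectors),
#'   `test_mad`, `baseline_test_mad`.
#' @export
run_search <- function(beta, samples, candidates, plan = split_plan(), k = 5L) {
  if (is.data.frame(candidates)) candidates <- candidates$cpg_id
  al <- align_samples(beta[beta$cpg_id %in% candidates, , drop = FALSE], samples)
  m <- beta_to_matrix(al$beta)
  age_tbl <- al$samples
  n <- nrow(age_tbl)
  cells <- tidyr::expand_grid(split_ratio = plan$ratios,
                              iteration = seq_len(plan$n_iterations))
  results <- purrr::pmap(cells, function(split_ratio, iteration) {
    cell_index <- match(split_ratio, plan$ratios) * 10000L + iteration
    withr::with_seed(derive_seed(plan$seed, cell_index), {
      n_train <- round(split_ratio * n)
      p <- nrow(m)
      if (n_train <= p + 1L || n_train >= n) {
        abort(sprintf(
          "Split ratio %.2f leaves %d training samples; need > %d for the %d-CpG baseline fit and >= 1 test sample.",
          split_ratio, n_train, p + 1L, p
        ))
      }
      train_idx <- sort(sample.int(n, n_train))
      test_idx <- setdiff(seq_len(n), train_idx)
      b_train <- al$beta[, c(1L, 1L + train_idx), drop = FALSE]
      b_test <- al$beta[, c(1L, 1L + test_idx), drop = FALSE]
      s_train <- age_tbl[train_idx, ]
      s_test <- age_tbl[test_idx, ]
      subset_cpgs <- rfe_select(b_train, s_train, k = k)
      subset_model <- fit_age_model(b_train, s_train, cpgs = as.character(subset_cpgs))
      baseline_model <- fit_age_model(b_train, s_train)
      test_mad <- glance(predict_ages(subset_model, b_test, s_test))$mad_years
      baseline_mad <- glance(predict_ages(baseline_model, b_test, s_test))$mad_years
      tibble::tibble(
        split_ratio = split_ratio, iteration = iteration,
        selected_cpgs = list(sort(as.character(subset_cpgs))),
        test_mad = test_mad, baseline_test_mad = baseline_mad
      )
    })
  })
  out <- tibble::new_tibble(dplyr::bind_rows(results), class = "subset_search")
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- plan$seed
  out
}

#' Filter subsets by the baseline and rank CpGs by occurrence frequency
#'
#' Retains only those search results whose subset test MAD beats the
#' baseline — by default the mean of the full-candidate-set test MAD over
#' *all* cells (`"global_mean"`); `"per_split"` instead requires each
#' subset to beat its own split's baseline. Among the retained subsets,
#' each CpG's frequency of occurrence is computed; CpGs occurring in
#' strictly more than `freq_threshold` (default 0.5, i.e. "more than 50%")
#' of the retained subsets form the final signature.
#'
#' @param results A `subset_search` tibble from [run_search()].
#' @param freq_threshold Occurrence-fraction cutoff; strictly exceeded.
#' @param baseline `"global_mean"` or `"per_split"`.
#' @return A `frequency_ranking` tibble (`cpg_id`, `frequency`, sorted
#'   descending) with attributes `n_retained`, `baseline_mean`,
#'   `signature` (character vector, also via [signature_cpgs()]).
#' @export
filter_and_rank <- function(results, freq_threshold = 0.5,
                            baseline = c("global_mean", "per_split")) {
  baseline <- match.arg(baseline)
  if (nrow(results) == 0L) abort("`results` is empty.")
  baseline_mean <- mean(results$baseline_test_mad)
  retained <- if (baseline == "global_mean") {
    results[results$test_mad < baseline_mean, , drop = FALSE]
  } else {
    results[results$test_mad < results$baseline_test_mad, , drop = FALSE]
  }
  if (nrow(retained) == 0L) {
    warn("No subset performed better than the baseline; the ranking is empty.")
  }
  counts <- table(unlist(retained$selected_cpgs))
  ranking <- tibble::tibble(
    cpg_id = as.character(names(counts) %||% character(0)),
    frequency = as.numeric(counts) / max(nrow(retained), 1L)
  ) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$cpg_id)
  out <- tibble::new_tibble(ranking, class = "frequency_ranking")
  attr(out, "n_retained") <- nrow(retained)
  attr(out, "baseline_mean") <- baseline_mean
  attr(out, "signature") <- ranking$cpg_id[ranking$frequency > freq_threshold]
  attr(out, "freq_threshold") <- freq_threshold
  out
}

#' @rdname filter_and_rank
#' @param ranking A `frequency_ranking`.
#' @export
signature_cpgs <- function(ranking) attr(ranking, "signature")

#' Full signature-selection pipeline
#'
#' Composes the whole discovery chain: age correlation screen
#' ([select_ar_cpgs()]), variability pre-filter
#' ([filter_by_variability()]), iterative split/RFE search
#' ([run_search()]) and baseline filtering with frequency ranking
#' ([filter_and_rank()]). The variability filter is only applied while the
#' filtered pool still holds at least `k` CpGs (RFE needs `k` candidates);
#' with a pool already at signature size the filter is skipped and that is
#' logged.
#'
#' If the correlation screen selects nothing (a cohort with no age
#' signal), the pipeline stops early and returns an empty signature with
#' an explanatory log instead of erroring.
#'
#' @inheritParams run_search
#' @param r_threshold Absolute-correlation cutoff for the AR screen.
#' @param variability_filter Apply the IQR pre-filter (default `TRUE`).
#' @param freq_threshold Occurrence cutoff for the final signature.
#' @param baseline Baseline mode, see [filter_and_rank()].
#' @return A `signature_result` list: `correlations`, `ar_set`,
#'   `candidates`, `results`, `ranking`, `signature` (character vector,
#'   possibly empty) and `log` (character, full provenance).
#' @export
end_to_end_signature <- function(beta, samples, r_threshold = 0.85,
                                 variability_filter = TRUE,
                                 plan = split_plan(), k = 5L,
                                 freq_threshold = 0.5,
                                 baseline = "global_mean") {
  log <- character(0)
  say <- function(...) sprintf(...)
  correlations <- correlate_with_age(beta, samples)
  ar_set <- select_ar_cpgs(correlations, threshold = r_threshold)
  log <- c(log, say("AR screen: %d of %d CpGs with |r| > %g (%d hypo, %d hyper)",
                    nrow(ar_set), nrow(correlations), r_threshold,
                    attr(ar_set, "n_hypo"), attr(ar_set, "n_hyper")))
  if (nrow(ar_set) == 0L) {
    log <- c(log, "No CpG passed the age-correlation screen; empty signature.")
    return(structure(list(correlations = correlations, ar_set = ar_set,
                          candidates = ar_set, results = NULL, ranking = NULL,
                          signature = character(0), log = log),
                     class = "signature_result"))
  }
  candidates <- ar_set
  if (variability_filter && nrow(ar_set) >= 2L) {
    filtered <- filter_by_variability(beta, ar_set)
    if (nrow(filtered) >= k) {
      candidates <- filtered
      log <- c(log, say("Variability filter: kept %d of %d CpGs above the median IQR",
                        nrow(filtered), nrow(ar_set)))
    } else {
      log <- c(log, say("Variability filter skipped: it would leave %d CpGs, fewer than k = %d",
                        nrow(filtered), k))
    }
  }
  if (nrow(candidates) < k) {
    abort(sprintf("Only %d candidate CpGs passed screening but k = %d.", nrow(candidates), k))
  }
  results <- run_search(beta, samples, candidates, plan = plan, k = k)
  log <- c(log, say("Search: %d cells (%s ratios x %d iterations), seed %d",
                    nrow(results), paste(plan$ratios, collapse = "/"),
                    plan$n_iterations, plan$seed))
  ranking <- filter_and_rank(results, freq_threshold = freq_threshold,
                             baseline = baseline)
  sig <- signature_cpgs(ranking)
  log <- c(log, say("Ranking: %d retained subsets (baseline mean MAD %.3g yr); signature of %d CpGs: %s",
                    attr(ranking, "n_retained"), attr(ranking, "baseline_mean"),
                    length(sig), paste(sig, collapse = ", ")))
  structure(
    list(correlations = correlations, ar_set = ar_set, candidates = candidates,
         results = results, ranking = ranking, signature = sig, log = log),
    class = "signature_result"
  )
}

#' @export
print.signature_result <- function(x, ...) {
  cat("<signature_result>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' @export
glance.subset_search <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    k = attr(x, "k"),
    mean_test_mad = mean(x$test_mad),
    mean_baseline_mad = mean(x$baseline_test_mad)
  )
}
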