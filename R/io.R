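#' Read a beta-value matrix from CSV or TSV
#'
#' Expects the layout of BeadChip or pyrosequencing exports: the first
#' column holds CpG ids, the header row holds sample ids, and every other
#' cell is a methylation value or a missing token (empty cell or `"NA"`).
#' Lines starting with `#` are treated as comments (the package's own
#' writers put provenance there).
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by file extension), `"csv"` or `"tsv"`.
#' @param percent If `TRUE` the file stores percent methylation; values are
#'   divided by 100 before validation. Internally betas are always
#'   fractions in `[0, 1]` — the published clock coefficients are only
#'   dimensionally sensible on that scale.
#' @param missing Character vector of tokens read as missing.
#' @return A validated beta table (see [validate_beta()]).
#' @export
read_beta_matrix <- function(path, dialect = c("auto", "csv", "tsv"),
                             percent = FALSE, missing = c("", "NA")) {
  dialect <- match.arg(dialect)
  raw <- read_delim_table(path, dialect, missing)
  if (ncol(raw) < 2L) abort("Beta matrix file must have a CpG-id column plus sample columns.")
  names(raw)[1] <- "cpg_id"
  raw$cpg_id <- as.character(raw$cpg_id)
  for (j in seq(2L, ncol(raw))) {
    v <- raw[[j]]
    if (is.character(v)) {
      v[v %in% missing] <- NA_character_
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0L) {
        abort(sprintf("Non-numeric cell '%s' in column '%s' does not match a missing token.",
                      v[bad[1]], names(raw)[j]))
      }
      v <- num
    }
    raw[[j]] <- if (percent) v / 100 else as.numeric(v)
  }
  validate_beta(raw)
  raw
}

#' Write a beta table to CSV
#'
#' @param beta A beta table.
#' @param path Output path.
#' @param provenance Optional character vector written as `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, provenance = NULL) {
  validate_beta(beta)
  write_csv_atomic(beta, path, provenance)
}

#' Read a sample metadata table
#'
#' The header must contain `sample_id` and `age_years`; any extra column is
#' kept as a covariate. Validation rejects duplicate ids and negative or
#' non-finite ages.
#'
#' @inheritParams read_beta_matrix
#' @return A validated sample table.
#' @export
read_sample_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- read_delim_table(path, dialect, c("", "NA"))
  validate_samples(raw)
}

#' Read a pyrosequencing result table for the three signature CpGs
#'
#' Columns: `sample_id`, `alpha` (cg02228185, *ASPA*), `beta` (cg25809905,
#' *ITGA2B*), `gamma` (the CpG upstream of cg17861230 in *PDE4C*).
#' Pyrosequencing software reports percent methylation; pass
#' `unit = "percent"` to divide by 100 on read. After normalisation all
#' three values must lie in `[0, 1]`.
#'
#' @inheritParams read_beta_matrix
#' @param unit `"fraction"` or `"percent"`.
#' @return A tibble with columns `sample_id`, `alpha`, `beta`, `gamma`.
#' @export
read_pyro_table <- function(path, dialect = c("auto", "csv", "tsv"),
                            unit = c("fraction", "percent")) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  raw <- read_delim_table(path, dialect, c("", "NA"))
  validate_pyro(raw, unit = unit)
}

validate_pyro <- function(pyro, unit = "fraction") {
  need <- setdiff(c("sample_id", "alpha", "beta", "gamma"), names(pyro))
  if (length(need) > 0L) {
    abort(paste0("Pyro table is missing column(s): ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(pyro$sample_id)) abort("`sample_id` values must be unique.")
  for (col in c("alpha", "beta", "gamma")) {
    v <- as.numeric(pyro[[col]])
    if (unit == "percent") v <- v / 100
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort(sprintf("`%s` has values outside [0, 1] after unit normalisation.", col))
    }
    pyro[[col]] <- v
  }
  tibble::as_tibble(pyro)
}

#' Read a telomere-length table
#'
#' Columns: `sample_id`, `telomere_length_kb` (positive, kilobases, e.g.
#' from flow-FISH), optionally `cell_type` (`granulocyte` or `lymphocyte`)
#' and `group` (`healthy`, `AA`, `DKC`). Missing `cell_type`/`group`
#' default to `granulocyte`/`healthy`.
#'
#' @inheritParams read_beta_matrix
#' @return A validated tibble.
#' @export
read_telomere_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- read_delim_table(path, dialect, c("", "NA"))
  validate_telomeres(raw)
}

validate_telomeres <- function(tel) {
  need <- setdiff(c("sample_id", "telomere_length_kb"), names(tel))
  if (length(need) > 0L) {
    abort(paste0("Telomere table is missing column(s): ", paste(need, collapse = ", ")))
  }
  len <- as.numeric(tel$telomere_length_kb)
  if (any(!is.finite(len)) || any(len <= 0)) {
    abort("`telomere_length_kb` must be finite and > 0.")
  }
  tel$telomere_length_kb <- len
  if (!"cell_type" %in% names(tel)) tel$cell_type <- "granulocyte"
  if (!"group" %in% names(tel)) tel$group <- "healthy"
  bad_ct <- setdiff(unique(tel$cell_type), c("granulocyte", "lymphocyte"))
  if (length(bad_ct) > 0L) {
    abort(paste0("`cell_type` must be granulocyte or lymphocyte; found: ",
                 paste(bad_ct, collapse = ", ")))
  }
  bad_g <- setdiff(unique(tel$group), c("healthy", "AA", "DKC"))
  if (length(bad_g) > 0L) {
    abort(paste0("`group` must be one of healthy/AA/DKC; found: ", paste(bad_g, collapse = ", ")))
  }
  tibble::as_tibble(tel)
}

# Format version for serialized models; bump on layout changes.
.model_format <- "methclock-model"
.model_version <- 1L

#' Serialize and restore linear age models
#'
#' Models are written as versioned JSON with every coefficient encoded as a
#' full-precision decimal string, so a write/read round-trip preserves the
#' intercept and every weight bit-exactly across platforms.
#'
#' @param model A model from [fit_age_model()] or [three_cpg_model()].
#' @param path File path for the JSON document.
#' @return `write_age_model()` returns `path` invisibly; `read_age_model()`
#'   returns the restored model object.
#' @examples
#' m <- three_cpg_model()
#' f <- tempfile(fileext = ".json")
#' write_age_model(m, f)
#' identical(read_age_model(f)$intercept, 38.0)
#' @export
write_age_model <- function(model, path) {
  if (!inherits(model, c("linear_age_model", "three_cpg_model"))) {
    abort("`model` must be a linear_age_model or three_cpg_model.")
  }
  doc <- list(
    format = .model_format,
    version = .model_version,
    class = class(model)[1],
    intercept = num_to_decimal(model$intercept),
    coefficients = as.list(vapply(model$coefficients, num_to_decimal, character(1))),
    provenance = model$provenance %||% ""
  )
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path), error = function(e) {
    abort(paste0("Cannot parse model file '", path, "': ", conditionMessage(e)))
  })
  if (!identical(doc$format, .model_format)) {
    abort("Not a methclock model file (missing or wrong `format` field).")
  }
  if (!identical(as.integer(doc$version), .model_version)) {
    abort(sprintf("Unknown model file version %s.", deparse(doc$version)))
  }
  coefs <- vapply(doc$coefficients, function(x) as.numeric(x), numeric(1))
  if (length(coefs) == 0L) coefs <- setNames(numeric(0), character(0))
  cls <- doc$class %||% "linear_age_model"
  if (identical(cls, "three_cpg_model")) {
    three_cpg_model(
      intercept = as.numeric(doc$intercept),
      w_alpha = coefs[["alpha"]], w_beta = coefs[["beta"]], w_gamma = coefs[["gamma"]],
      provenance = doc$provenance %||% ""
    )
  } else {
    new_linear_age_model(as.numeric(doc$intercept), coefs, doc$provenance %||% "")
  }
}

# Full-precision decimal encoding: 17 significant digits round-trips any
# IEEE-754 double exactly through as.numeric().
num_to_decimal <- function(x) sprintf("%.17g", x)

read_delim_table <- function(path, dialect, missing) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  out <- reader(path, na = missing, comment = "#", show_col_types = FALSE,
                progress = FALSE, name_repair = "minimal")
  nm <- names(out)
  if (any(nm == "" | is.na(nm))) abort("Malformed header: empty column name.")
  out
}

# Atomic CSV write with optional '#' provenance header; readers skip '#'.
write_csv_atomic <- function(x, path, provenance = NULL) {
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, open = "w", encoding = "UTF-8")
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  close(con)
  readr::write_csv(x, tmp, append = !is.null(provenance),
                   col_names = TRUE, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
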