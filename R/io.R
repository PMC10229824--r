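## Plain-text interchange: CSV waveforms / covariate tables (full double
## precision via "%.17g") and JSON records for configurations and fits.

.fmt_num <- function(x) sprintf("%.17g", x)

.write_table_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write / read an ERP pair as CSV
#'
#' Columns `time_ms`, `MCN`, `vlPAG`; `n_trials` is carried in a `#` header
#' comment. Doubles are serialized at full precision.
#'
#' @param erp An [erp_pair()].
#' @param path Output CSV path.
#' @return `write_erp_csv`: the path, invisibly. `read_erp_csv`: an
#'   [erp_pair()].
#' @export
write_erp_csv <- function(erp, path) {
  stopifnot(inherits(erp, "erp_pair"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_trials: %s", format(erp$n_trials)), con)
  df <- data.frame(time_ms = erp$time_ms,
                   MCN = erp$amplitude["MCN", ],
                   vlPAG = erp$amplitude["vlPAG", ])
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, .fmt_num), sep = ",")), con)
  invisible(path)
}

#' @rdname write_erp_csv
#' @export
read_erp_csv <- function(path) {
  first <- readLines(path, n = 1)
  n_trials <- NA_integer_
  if (startsWith(first, "#")) {
    v <- sub("^# n_trials:\\s*", "", first)
    n_trials <- suppressWarnings(as.integer(v))
  }
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "numeric")
  erp_pair(df$time_ms, rbind(MCN = df$MCN, vlPAG = df$vlPAG),
           n_trials = n_trials)
}

#' Write / read a cohort dataset
#'
#' Serializes a [generate_cohort()] result to a directory: `covariates.csv`,
#' `truth.csv` (the generating latent strengths, full precision),
#' `config.json`, and one `erp_<key>.csv` per subject x block (the
#' trial-averaged observed ERP). The round trip is lossless for the
#' covariate and ground-truth tables.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort`: `dir`, invisibly. `read_cohort`: a list with
#'   `config`, `covariates`, `truth` and `erps`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_table_exact(cohort$covariates, file.path(dir, "covariates.csv"))
  .write_table_exact(cohort$truth, file.path(dir, "truth.csv"))
  cfg <- unclass(cohort$config)
  cfg$variant_id <- cohort$variant_id
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (key in names(cohort$erps))
    write_erp_csv(cohort$erps[[key]], file.path(dir, paste0("erp_", key, ".csv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  files <- sort(list.files(dir, pattern = "^erp_.*\\.csv$", full.names = TRUE))
  erps <- lapply(files, read_erp_csv)
  names(erps) <- sub("^erp_(.*)\\.csv$", "\\1", basename(files))
  list(config = cfg, covariates = covariates, truth = truth, erps = erps)
}

#' Write / read a first-level fit record
#'
#' JSON record with the named posterior mean and covariance, noise
#' hyperparameter, free energy, trace and fitted waveforms.
#'
#' @param fit A `dcm_fit`.
#' @param path Output JSON path.
#' @return `write_fit_json`: the path, invisibly. `read_fit_json`: a
#'   `dcm_fit`-like list usable by [fit_peb()] and [evidence_matrix()].
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dcm_fit"))
  rec <- list(
    variant_id = fit$variant_id,
    free_energy = fit$free_energy,
    converged = fit$converged,
    iterations = fit$iterations,
    lambda = fit$lambda,
    trace = fit$trace,
    posterior = list(names = fit$posterior$names,
                     mean = unname(fit$posterior$mean),
                     cov = fit$posterior$cov,
                     prior_sd = unname(fit$posterior$prior_sd)),
    fitted = list(time_ms = fit$fitted$time_ms,
                  amplitude = fit$fitted$amplitude)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$posterior$mean <- stats::setNames(rec$posterior$mean,
                                        rec$posterior$names)
  rec$posterior$cov <- as.matrix(rec$posterior$cov)
  if (!is.null(rec$posterior$prior_sd))
    rec$posterior$prior_sd <- stats::setNames(rec$posterior$prior_sd,
                                              rec$posterior$names)
  class(rec) <- "dcm_fit"
  rec
}
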