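#' Read a steady-state dataset from CSV
#'
#' Reads an RFC-4180 CSV with a header row into the steady-state schema
#' (`intensity_percent`, `ligand_nM`, and `calcium_au` or `bound_mfi`, plus
#' an optional `replicate`). Published source-data spreadsheets with other
#' column headers are mapped via `col_map` rather than hand-edited.
#'
#' @param path CSV file path.
#' @param readout `"calcium"` or `"binding"`.
#' @param col_map Optional named character vector mapping schema names to
#'   file column names, e.g.
#'   `c(intensity_percent = "Intensity", calcium_au = "Ca")`.
#' @return A validated tibble in the corresponding schema.
#' @export
read_steady_state_csv <- function(path, readout = c("calcium", "binding"),
                                  col_map = NULL) {
  readout <- match.arg(readout)
  value_col <- if (readout == "calcium") "calcium_au" else "bound_mfi"
  df <- .read_mapped_csv(path, c("intensity_percent", "ligand_nM", value_col),
                         col_map)
  bundle <- list(df)
  names(bundle) <- readout
  .validate_bundle(bundle)[[readout]]
}

#' Read a pulse-kinetics dataset from CSV
#'
#' @inheritParams read_steady_state_csv
#' @return A validated tibble with columns `duration_s`, `intensity_percent`,
#'   `ligand_nM`, `calcium_au` (plus `replicate` if present).
#' @export
read_kinetics_csv <- function(path, col_map = NULL) {
  df <- .read_mapped_csv(path, c("duration_s", "intensity_percent",
                                 "ligand_nM", "calcium_au"), col_map)
  .validate_bundle(list(kinetics = df))$kinetics
}

.read_mapped_csv <- function(path, required, col_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      src <- col_map[[schema_name]]
      if (!src %in% names(df))
        stop("column '", src, "' (mapped to '", schema_name,
             "') not found in ", path)
      names(df)[names(df) == src] <- schema_name
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write a dataset bundle as CSV files
#'
#' Writes `calcium.csv`, `binding.csv`, `kinetics.csv` (whichever are
#' present) into `dir` using the package's interchange schemas.
#'
#' @param bundle Named list as produced by [generate_dataset_bundle()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset_bundle <- function(bundle, dir) {
  bundle <- .validate_bundle(bundle)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle))
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset_bundle()]
#'
#' @param dir Directory containing `calcium.csv` / `binding.csv` /
#'   `kinetics.csv` (any subset).
#' @return A named list of validated tibbles.
#' @export
read_dataset_bundle <- function(dir) {
  out <- list()
  f <- file.path(dir, "calcium.csv")
  if (file.exists(f)) out$calcium <- read_steady_state_csv(f, "calcium")
  f <- file.path(dir, "binding.csv")
  if (file.exists(f)) out$binding <- read_steady_state_csv(f, "binding")
  f <- file.path(dir, "kinetics.csv")
  if (file.exists(f)) out$kinetics <- read_kinetics_csv(f)
  if (length(out) == 0) stop("no dataset CSVs found in ", dir)
  out
}

#' Write a JSON fit report
#'
#' Serializes estimates, log-likelihoods, test results and profile CI into a
#' single JSON report for provenance.
#'
#' @param fit A `kpr_fit` object.
#' @param lrt Optional `kpr_lrt` object.
#' @param profile Optional `kpr_profile` object.
#' @param path Output JSON path.
#' @return The report list, invisibly.
#' @export
write_fit_report <- function(fit, path, lrt = NULL, profile = NULL) {
  stopifnot(inherits(fit, "kpr_fit"))
  report <- list(
    package_version = as.character(utils::packageVersion("optoKPR")),
    variant = fit$variant, error_model = fit$error_model,
    estimates = as.list(fit$estimates),
    s_bind = fit$s_bind, sigma_hat = as.list(fit$sigma_hat),
    logLik = fit$logLik, convergence = fit$convergence,
    n_starts = fit$n_starts, seed = fit$seed, n_obs = as.list(fit$n_obs))
  if (!is.null(lrt))
    report$lrt <- list(statistic = lrt$statistic, p_value = lrt$p_value,
                       p_value_chisq1 = lrt$p_value_chisq1, df = lrt$df,
                       logLik_null = lrt$fit_null$logLik)
  if (!is.null(profile))
    report$profile <- list(tau_hat = profile$tau_hat,
                           ci = as.list(profile$ci),
                           conf_level = profile$conf_level,
                           threshold = profile$threshold)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
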