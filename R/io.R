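#' Read a count regression data set from CSV
#'
#' Reads a delimited file with a header row, checks that the designated
#' response column holds non-negative integer counts and that all remaining
#' columns are numeric covariates.
#'
#' @param path CSV file path.
#' @param response Name of the response column.
#' @return A tibble with the response column first, covariates after, and
#'   the response name attached as attribute `response`.
#' @export
read_count_data <- function(path, response = "y") {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  if (!response %in% names(dat)) {
    stop("response column `", response, "` not found in ", path, call. = FALSE)
  }
  y <- dat[[response]]
  if (!is.numeric(y) || any(y < 0) || any(y != floor(y))) {
    stop("response column must hold non-negative integer counts",
         call. = FALSE)
  }
  covs <- dat[setdiff(names(dat), response)]
  bad <- names(covs)[!vapply(covs, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric covariate column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::bind_cols(dat[response], covs)
  attr(out, "response") <- response
  out
}

#' Write a machine-readable fit report
#'
#' Writes the coefficient table (CSV, full precision) and a JSON sidecar of
#' fit-level summaries and metadata.
#'
#' @param fit A `pmql_fit` or `pmql_shrinkage` object.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; produces `<stem>_coefficients.csv` and
#'   `<stem>_summary.json`.
#' @param meta Optional named list merged into the JSON sidecar (e.g. the
#'   seed and resolved configuration of a pipeline run).
#' @return Invisibly, the two file paths.
#' @export
write_fit_report <- function(fit, dir = ".", stem = "pmql_fit", meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coef_path <- file.path(dir, paste0(stem, "_coefficients.csv"))
  json_path <- file.path(dir, paste0(stem, "_summary.json"))
  readr::write_csv(tidy(fit), coef_path)
  summ <- c(
    as.list(glance(fit)),
    list(package = "pmqlreg",
         version = as.character(utils::packageVersion("pmqlreg")),
         written = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    meta
  )
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(coefficients = coef_path, summary = json_path))
}
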