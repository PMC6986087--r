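RESULT_SCHEMA_VERSION <- "costsel-1"

# auto-detect comma vs tab from the first line
detect_delim <- function(path) {
  line <- readLines(path, n = 1)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read a feature table or a cost table from delimited text
#'
#' `read_feature_data()` reads a samples-by-features table with a header row
#' of feature ids; the response may be a named column of the same file or a
#' separate single-column file. `read_costs()` reads a two-column
#' `(feature, cost)` table (header optional) into a named cost vector.
#' The delimiter is auto-detected among comma and tab unless given.
#'
#' @param path File path.
#' @param response Optional response column name (validated to be 0/1).
#' @param delim `","`, `"\t"`, or `NULL` to auto-detect.
#' @return `read_feature_data()`: a tibble. `read_costs()`: a named numeric
#'   vector.
#' @export
read_feature_data <- function(path, response = NULL, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (anyDuplicated(names(out))) abort("feature ids in the header must be unique")
  if (!is.null(response)) response_vector(out, response)
  out
}

#' @rdname read_feature_data
#' @export
read_costs <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  first <- strsplit(readLines(path, n = 1), delim, fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  tab <- readr::read_delim(path, delim = delim, col_names = has_header,
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort("cost file needs two columns: feature id, cost")
  costs <- setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  if (any(!is.finite(costs) | costs <= 0)) {
    abort("cost file contains non-positive or non-numeric costs")
  }
  costs
}

#' Serialise results to disk
#'
#' Selection results are written as JSON (schema version, method label,
#' selected member ids, total cost, budget, AIC, feasibility, evaluation
#' count, and the score trace); benchmark tables as CSV with a schema
#' version comment-free header. `read_result()` restores the JSON form as a
#' plain list.
#'
#' @param x A [selection_result] or a [run_benchmark()] tibble.
#' @param path Output path (`.json` for selections, `.csv` for tables).
#' @return `write_result()` invisibly returns `path`.
#' @export
write_result <- function(x, path) {
  if (inherits(x, "selection_result")) {
    payload <- list(
      schema_version = RESULT_SCHEMA_VERSION,
      method = x$method,
      selected = as.list(x$selected),
      total_cost = x$total_cost,
      budget = x$budget,
      aic = x$aic,
      feasible = x$feasible,
      n_evaluations = x$n_evaluations,
      trace = x$trace
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  } else if (is.data.frame(x)) {
    readr::write_csv(dplyr::mutate(x, schema_version = RESULT_SCHEMA_VERSION,
                                   .before = 1), path, progress = FALSE)
  } else {
    abort("write_result handles selection_result objects and data frames")
  }
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (grepl("\\.json$", path)) {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    out$selected <- as.character(out$selected)
    out$trace <- as_tibble(out$trace)
    out
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Serialise a setting specification
#'
#' Round-trips a [setting_spec()] through JSON so simulation conditions can
#' be stored next to their results.
#'
#' @param spec A [setting_spec()].
#' @param path File path.
#' @return `read_setting()` returns the restored `setting_spec`.
#' @export
write_setting <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_setting
#' @export
read_setting <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  # rebuild through the constructor so defaults fill fields stored as null
  vals <- Filter(Negate(is.null), vals)
  do.call(setting_spec, c(list(vals$label), vals[names(vals) != "label"]))
}
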