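# Shared I/O: response tables in, profile tables and reports out, run
# manifests. All files are UTF-8, comma-delimited, period decimal separator;
# outputs are byte-stable given identical inputs.

#' Read a respondent response table
#'
#' Reads a delimited (CSV) file with a header of item ids and one respondent
#' per row; blank cells are missing. Columns not matching any item id are
#' kept but reported with a warning; non-numeric cells are logged as
#' row-level issues and read as missing. Comma decimal separators are
#' rejected with a clear error (files must use the period).
#'
#' @param path CSV file path.
#' @param instrument a `semas_instrument` used to resolve item columns.
#' @return data frame with `respondent_id` and numeric item columns; parsing
#'   issues in the `issues` attribute.
#' @export
read_responses <- function(path, instrument) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"))
  if (!"respondent_id" %in% names(raw)) {
    stop("response file '", path, "' lacks a respondent_id column",
         call. = FALSE)
  }
  dups <- unique(raw$respondent_id[duplicated(raw$respondent_id)])
  if (length(dups)) {
    stop("duplicate respondent_id in '", path, "': ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), c("respondent_id", instrument$items$item_id))
  if (length(unknown)) {
    warning("unknown column(s) in '", path, "': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  issues <- character()
  for (col in setdiff(names(raw), "respondent_id")) {
    v <- raw[[col]]
    comma <- !is.na(v) & grepl("^-?[0-9]+,[0-9]+$", v)
    if (any(comma)) {
      stop("column '", col, "' in '", path, "' uses a comma decimal ",
           "separator (e.g. '", v[comma][1], "'); use the period",
           call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      issues <- c(issues, paste0(col, " row ", which(bad), ": unparseable '",
                                 v[bad], "'"))
    }
    raw[[col]] <- num
  }
  attr(raw, "issues") <- issues
  raw
}

fmt_ratio <- function(x) ifelse(is.na(x), "N.A.", sprintf("%.3f", x))

#' Write a scored profile table
#'
#' Fixed column order, fixed numeric formatting (integer sums, burden to one
#' decimal), byte-stable across runs on identical input.
#'
#' @param profiles a `semas_profiles` table from [score_cohort()].
#' @param path output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  out <- as.data.frame(profiles)
  for (col in names(out)) {
    if (col == "burden_sum") {
      out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.1f", out[[col]]))
    } else if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%d", as.integer(out[[col]])))
    } else {
      out[[col]] <- ifelse(is.na(out[[col]]), "", out[[col]])
    }
  }
  write_csv_stable(out, path)
}

#' Read back a written profile table
#'
#' @param path CSV path written by [write_profiles()].
#' @return data frame with numeric sum/count columns.
#' @export
read_profiles <- function(path) {
  utils::read.csv(path, check.names = FALSE, na.strings = "",
                  stringsAsFactors = FALSE)
}

#' Write a validation report as CSV
#'
#' One row per characteristic (columns: characteristic, n, ppv, npv, alpha,
#' corr, corr_method, p), followed by the three coping-style rows. Ratios
#' are formatted to 3 decimals; undefined values print as `N.A.`. An empty
#' report writes the header only.
#'
#' @param report a `semas_validation_report`.
#' @param path output CSV path.
#' @export
write_report <- function(report, path) {
  rows <- report$rows
  style <- report$coping_styles
  tab <- data.frame(
    characteristic = c(rows$characteristic,
                       if (nrow(style)) paste0("coping_", style$style)),
    n = c(rows$n, style$n),
    ppv = fmt_ratio(c(rows$ppv, rep(NA, nrow(style)))),
    npv = fmt_ratio(c(rows$npv, rep(NA, nrow(style)))),
    alpha = fmt_ratio(c(rows$alpha, style$alpha)),
    corr = fmt_ratio(c(rows$corr, style$corr)),
    corr_method = ifelse(is.na(c(rows$corr_method, style$corr_method)), "N.A.",
                         c(rows$corr_method, style$corr_method)),
    p = fmt_ratio(c(rows$corr_p, style$corr_p)),
    stringsAsFactors = FALSE)
  write_csv_stable(tab, path)
}

#' Write the regression block of a validation report as CSV
#'
#' @param report a `semas_validation_report` with a regression block.
#' @param path output CSV path.
#' @export
write_regression <- function(report, path) {
  reg <- report$regression
  if (is.null(reg)) {
    tab <- data.frame(term = character(), beta = character(),
                      se_beta = character(), std_beta = character(),
                      p = character(), stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      term = c("intercept", reg$coefficients$term,
               "r_squared", "n"),
      beta = c(sprintf("%.2f", reg$intercept),
               sprintf("%.2f", reg$coefficients$beta),
               sprintf("%.3f", reg$r_squared), sprintf("%d", reg$n)),
      se_beta = c("", sprintf("%.2f", reg$coefficients$se_beta), "", ""),
      std_beta = c("", sprintf("%.2f", reg$coefficients$std_beta), "", ""),
      p = c(fmt_ratio(reg$intercept_p), fmt_ratio(reg$coefficients$p_value),
            "", ""),
      stringsAsFactors = FALSE)
  }
  write_csv_stable(tab, path)
}

# byte-stable CSV: LF line endings, no quoting unless needed, no row names
write_csv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "")
  invisible(path)
}

#' Write a run manifest
#'
#' Every output directory gets exactly one `manifest.json` recording the
#' command, content digests (MD5) of the input files, the instrument name
#' and schema version, the seed (if any), the package version and a
#' timestamp — enough to reproduce the run.
#'
#' @param dir output directory.
#' @param command the command name.
#' @param inputs named character vector of input file paths.
#' @param instrument the `semas_instrument` used (optional).
#' @param seed seed used, or `NULL`.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(dir, command, inputs = character(),
                           instrument = NULL, seed = NULL) {
  digests <- if (length(inputs)) {
    as.list(stats::setNames(unname(tools::md5sum(unlist(inputs))),
                            names(inputs) %||% basename(unlist(inputs))))
  } else {
    list()
  }
  manifest <- list(
    command = command,
    input_digests = digests,
    instrument = if (!is.null(instrument)) {
      list(name = instrument$name,
           schema_version = instrument$schema_version)
    },
    seed = seed,
    tool_version = as.character(utils::packageVersion("semas")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(manifest)
}
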