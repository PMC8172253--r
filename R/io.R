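# Reading trial tables and writing analysis results.

grade_levels <- c("Grade E" = 1, "Grade D" = 2, "Grade C" = 3, "Grade B" = 4,
                  "Non-responder" = 5,
                  "E" = 1, "D" = 2, "C" = 3, "B" = 4, "A" = 5, "NR" = 5)

#' Read a per-patient trial table
#'
#' Reads a delimited file with the trial columns (`treat`, `y10`, `y20`,
#' `Y1`, `Y2`, `Y3`, `Y4`), optionally renaming file columns via
#' `column_map`. The ordinal column may be coded as integers 1-5 (1 = best
#' grade, 5 = worst/non-responder category) or as grade labels
#' (`"Grade E"`..`"Grade B"`, `"Non-responder"`, or the short forms
#' `"E"`..`"B"`, `"A"`/`"NR"` for the top category). A column named `T` is
#' accepted as the treatment indicator. Validation failures report the
#' offending rows.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical names
#'   to file column names, e.g. `c(treat = "arm", Y1 = "pga_change")`.
#' @param delim field delimiter (default `","`).
#' @return a validated tibble.
#' @export
read_trial_table <- function(path, column_map = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(raw))
    if (length(miss) > 0) {
      stop("read_trial_table: mapped column(s) not in file: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  if (!"treat" %in% names(raw) && "T" %in% names(raw)) {
    names(raw)[names(raw) == "T"] <- "treat"
  }
  miss <- setdiff(trial_cols, names(raw))
  if (length(miss) > 0) {
    stop("read_trial_table: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.character(raw$Y3)) {
    code <- grade_levels[trimws(raw$Y3)]
    if (anyNA(code)) {
      stop("read_trial_table: unrecognised ordinal label in row(s) ",
           paste(head(which(is.na(code)), 5L), collapse = ", "),
           call. = FALSE)
    }
    raw$Y3 <- unname(code)
  }
  for (cl in trial_cols) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !all(is.na(v))) {
        stop("read_trial_table: non-numeric value in `", cl, "`, row(s) ",
             paste(head(which(is.na(conv) & !is.na(v)), 5L), collapse = ", "),
             call. = FALSE)
      }
      raw[[cl]] <- conv
    }
  }
  validate_trial_data(raw[, trial_cols])
}

#' Write analysis results
#'
#' Effect estimates and other tabular results are written as CSV; lists (or
#' any result object with a [tidy()] method) can be written as JSON with
#' provenance (package version and any seed attribute).
#'
#' @param results a tibble, an `lv_effect`, `lv_bootstrap` or
#'   `lv_scenario_result`, or a plain list.
#' @param path output path; `.json` selects JSON, anything else CSV.
#' @param seed optional seed to record in JSON provenance.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NULL) {
  if (inherits(results, c("lv_effect", "lv_bootstrap",
                          "lv_scenario_result"))) {
    tab <- tidy(results)
  } else if (is.data.frame(results)) {
    tab <- results
  } else {
    tab <- NULL
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      results = if (is.null(tab)) results else tab,
      provenance = list(
        package = "lvcomposite",
        version = as.character(utils::packageVersion("lvcomposite")),
        seed = seed))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    if (is.null(tab)) {
      stop("write_results: only tabular results can be written as CSV",
           call. = FALSE)
    }
    readr::write_csv(tab, path)
  }
  invisible(path)
}
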