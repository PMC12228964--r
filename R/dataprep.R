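#' Read a delimited repeated-measures table
#'
#' Reads a comma-separated (`.csv`) or tab-delimited (`.txt`/`.tsv`) table with
#' a header row. The literal token `"NA"` (case-sensitive) and empty cells are
#' treated as missing; numeric-looking columns are parsed as numbers and column
#' names are preserved verbatim.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`. When `NULL` (default) it is inferred from
#'   the file extension: `.csv` is comma-separated, `.txt` and `.tsv` are
#'   tab-delimited.
#' @return A `data.frame` with one row per input record. Missing cells are `NA`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,a", "1,2", "2,NA"), tf)
#' read_traj_table(tf)
#' @export
read_traj_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': file does not exist", call. = FALSE)
  }
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      csv = "csv",
      txt = ,
      tsv = "tsv",
      stop("cannot infer dialect from extension '.", ext,
           "'; pass dialect = \"csv\" or \"tsv\"", call. = FALSE)
    )
  }
  dialect <- match.arg(dialect, c("csv", "tsv"))
  sep <- if (dialect == "csv") "," else "\t"

  # pre-check field counts so a ragged row is reported with its line number
  nf <- utils::count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) > 0L && any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged table: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L], call. = FALSE)
  }

  out <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           na.strings = c("NA", ""), check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           blank.lines.skip = TRUE)
  out
}

#' Describe a wide repeated-measures layout
#'
#' A wide layout has one row per individual, with one age column and one
#' outcome column per measurement occasion. `wide_spec()` records which columns
#' play which role and what the long-format columns should be called.
#'
#' @param subject Name of the subject-identifier column.
#' @param ages Character vector of age/time column names, one per occasion, in
#'   occasion order.
#' @param outcomes Character vector of outcome column names, matched
#'   pairwise with `ages`.
#' @param occasion_name,outcome_name,age_name Names for the occasion, outcome
#'   and age columns of the long dataset (defaults `"time_point"`, `"score"`,
#'   `"age"`).
#' @param occasion_labels Optional vector of occasion labels (defaults to
#'   `1:k` in column order).
#' @return An object of class `"wide_spec"`.
#' @export
wide_spec <- function(subject, ages, outcomes,
                      occasion_name = "time_point", outcome_name = "score",
                      age_name = "age", occasion_labels = NULL) {
  spec <- list(subject = as.character(subject),
               ages = as.character(ages),
               outcomes = as.character(outcomes),
               occasion_name = occasion_name,
               outcome_name = outcome_name,
               age_name = age_name,
               occasion_labels = occasion_labels)
  class(spec) <- "wide_spec"
  spec
}

#' Validate a wide layout against a table
#'
#' Checks that a [wide_spec()] is usable on `data`: equal numbers of age and
#' outcome columns, all named columns present, no duplicated subject
#' identifiers (wide format promises one row per individual), and no name
#' collisions among the new long-format column names. Issues are returned as
#' data, never raised.
#'
#' @param data A data frame as returned by [read_traj_table()].
#' @param spec A [wide_spec()].
#' @return Character vector of human-readable issues; empty if valid.
#' @export
validate_wide_spec <- function(data, spec) {
  issues <- character(0)
  if (length(spec$ages) != length(spec$outcomes)) {
    issues <- c(issues, sprintf(
      "unequal number of occasions and outcomes: %d age columns but %d outcome columns",
      length(spec$ages), length(spec$outcomes)))
  }
  if (length(spec$ages) < 2L) {
    issues <- c(issues, "at least 2 occasions are required")
  }
  needed <- unique(c(spec$subject, spec$ages, spec$outcomes))
  absent <- setdiff(needed, names(data))
  for (col in absent) {
    issues <- c(issues, sprintf("column '%s' not found in the data", col))
  }
  if (spec$subject %in% names(data)) {
    ids <- data[[spec$subject]]
    if (anyDuplicated(ids[!is.na(ids)])) {
      issues <- c(issues,
        "duplicate subject identifiers in wide data (expected one row per individual)")
    }
  }
  newnames <- c(spec$occasion_name, spec$outcome_name, spec$age_name)
  if (anyDuplicated(c(spec$subject, newnames))) {
    issues <- c(issues,
      "occasion, outcome, age and subject column names must be mutually distinct")
  }
  if (!is.null(spec$occasion_labels) &&
      length(spec$occasion_labels) != length(spec$ages)) {
    issues <- c(issues, "occasion_labels must have one label per occasion")
  }
  issues
}

#' Reshape wide repeated measures to long format
#'
#' Converts one-row-per-individual data to one-row-per-occasion format for
#' multilevel growth-curve modelling. Occasion `j` takes its age from
#' `spec$ages[j]` and its outcome from `spec$outcomes[j]`. Rows where both age
#' and outcome are missing are retained (they are dropped later, at fit time).
#' Columns that are not part of the repeated block are carried through as
#' subject-level covariates.
#'
#' @param data Wide data frame.
#' @param spec A [wide_spec()]; must validate cleanly
#'   (see [validate_wide_spec()]).
#' @return A long data frame with columns `subject`, occasion, age and outcome
#'   (named per the spec), then any carried covariates.
#' @export
reshape_wide_to_long <- function(data, spec) {
  issues <- validate_wide_spec(data, spec)
  if (length(issues) > 0L) {
    stop("invalid wide specification:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  k <- length(spec$ages)
  n <- nrow(data)
  labels <- spec$occasion_labels
  if (is.null(labels)) labels <- seq_len(k)
  carry <- setdiff(names(data), c(spec$subject, spec$ages, spec$outcomes))

  idx <- rep(seq_len(n), each = k)      # subject-major order: all occasions per subject
  occ <- rep(seq_len(k), times = n)
  long <- data.frame(data[idx, spec$subject, drop = FALSE], row.names = NULL,
                     check.names = FALSE)
  long[[spec$occasion_name]] <- labels[occ]
  age_mat <- as.matrix(data[spec$ages])
  out_mat <- as.matrix(data[spec$outcomes])
  long[[spec$age_name]] <- age_mat[cbind(idx, occ)]
  long[[spec$outcome_name]] <- out_mat[cbind(idx, occ)]
  for (col in carry) long[[col]] <- data[[col]][idx]
  long
}

#' Per-occasion descriptive statistics
#'
#' Computes, for each occasion, the number of non-missing outcomes, mean,
#' standard deviation, median and interquartile range of the outcome, and the
#' mean observed age. Quartiles use linear interpolation between order
#' statistics (R's default "type 7" rule). Occasions with no non-missing
#' outcome yield `n = 0` with `NA` statistics.
#'
#' @param data Long data frame.
#' @param outcome,occasion,time Column names of the outcome, occasion label and
#'   age/time variables.
#' @return A data frame with one row per occasion (in first-appearance order of
#'   sorted occasion labels), columns `occasion`, `n`, `mean`, `sd`, `median`,
#'   `iqr`, `mean_time`.
#' @export
describe_by_occasion <- function(data, outcome, occasion, time) {
  stopifnot(nrow(data) > 0L)
  for (col in c(outcome, occasion, time)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in the data", call. = FALSE)
    }
  }
  occs <- data[[occasion]]
  levs <- sort(unique(occs[!is.na(occs)]))
  rows <- lapply(levs, function(l) {
    y <- data[[outcome]][!is.na(occs) & occs == l]
    t <- data[[time]][!is.na(occs) & occs == l]
    y_obs <- y[!is.na(y)]
    n <- length(y_obs)
    data.frame(
      occasion = l,
      n = n,
      mean = if (n > 0) mean(y_obs) else NA_real_,
      sd = if (n > 1) stats::sd(y_obs) else NA_real_,
      median = if (n > 0) stats::median(y_obs) else NA_real_,
      iqr = if (n > 0) stats::IQR(y_obs, type = 7) else NA_real_,
      mean_time = if (any(!is.na(t))) mean(t, na.rm = TRUE) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# shortest decimal representation that parses back to the same double
.format_real <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.15g", x[ok])
  for (fmt in c("%.16g", "%.17g")) {
    bad <- ok & !is.na(out) & suppressWarnings(as.numeric(out)) != x
    bad[is.na(bad)] <- FALSE
    if (!any(bad)) break
    out[bad] <- sprintf(fmt, x[bad])
  }
  out
}

#' Write a long dataset as CSV
#'
#' Writes the table with a header row, missing cells as the literal `"NA"`,
#' and no row names. Real columns are written with the shortest decimal
#' representation that parses back to the identical double, so
#' [read_traj_table()] recovers the same content exactly.
#'
#' @param data Long data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_long <- function(data, path) {
  out <- data
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- .format_real(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = TRUE)
  invisible(path)
}
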