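#' @importFrom utils read.csv write.csv
NULL

# canonical column order; population and shares_sample_with are optional on read
.ct_required <- c("study_id", "n", "indicator_name", "polarity",
                  "r_pa_re", "r_pa_mh", "r_re_mh")
.ct_optional <- c("population", "shares_sample_with")
.ct_columns  <- c(.ct_required, .ct_optional)
.polarities  <- c("positive", "negative")

#' Construct a coding table
#'
#' A coding table holds one row per independent sample of a three-variable
#' correlation meta-analysis: physical activity (X), resilience (M), and a
#' mental-health indicator (Y), with the three pairwise Pearson correlations
#' and the sample size. Rows coded from the same underlying subjects are
#' linked through `shares_sample_with` so that subject totals are not
#' double-counted.
#'
#' @param records data frame with columns `study_id`, `n`, `indicator_name`,
#'   `polarity` (`"positive"` or `"negative"`), `r_pa_re`, `r_pa_mh`,
#'   `r_re_mh`, and optionally `population` and `shares_sample_with`.
#' @param provenance free-text note on where the rows come from.
#' @return object of class `coding_table` (a data frame).
#' @export
coding_table <- function(records, provenance = "") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.ct_required, names(records))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (opt in .ct_optional)
    if (!opt %in% names(records)) records[[opt]] <- NA_character_
  records <- records[, .ct_columns, drop = FALSE]
  records$study_id <- as.character(records$study_id)
  records$shares_sample_with <- as.character(records$shares_sample_with)
  records$population <- as.character(records$population)
  if (anyDuplicated(records$study_id))
    stop("duplicate study_id: ",
         paste(unique(records$study_id[duplicated(records$study_id)]),
               collapse = ", "))
  rownames(records) <- NULL
  structure(records,
            provenance = provenance,
            class = c("coding_table", "data.frame"))
}

# per-row invariant check; returns character vector of problems (empty if ok)
.validate_record <- function(row) {
  probs <- character(0)
  if (!is.finite(row$n) || row$n != round(row$n) || row$n < 4)
    probs <- c(probs, sprintf("n = %s must be an integer >= 4", row$n))
  for (rc in c("r_pa_re", "r_pa_mh", "r_re_mh")) {
    r <- row[[rc]]
    if (!is.finite(r) || abs(r) >= 1)
      probs <- c(probs, sprintf("%s = %s not strictly inside (-1, 1)", rc, r))
  }
  if (!row$polarity %in% .polarities)
    probs <- c(probs, sprintf("polarity '%s' not one of %s", row$polarity,
                              paste(.polarities, collapse = "/")))
  probs
}

#' Read a study coding table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row carrying the
#' canonical column names (`study_id`, `n`, `indicator_name`, `polarity`,
#' `r_pa_re`, `r_pa_mh`, `r_re_mh`, optionally `population`,
#' `shares_sample_with`). Each row must satisfy: `n >= 4` (so the Fisher-z
#' sampling variance 1/(n-3) is finite and positive), all three correlations
#' strictly inside (-1, 1), and a valid polarity.
#'
#' @param path path to the CSV file.
#' @param strict if `TRUE` (default) any invariant violation is an error;
#'   if `FALSE`, offending rows are dropped with a warning.
#' @return a [coding_table()].
#' @export
read_coding_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE,
                  fileEncoding = "UTF-8")
  missing_cols <- setdiff(.ct_required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("coding table at ", path, " has a valid header but no rows")
    empty <- as.data.frame(setNames(
      c(list(character(0), integer(0), character(0), character(0)),
        rep(list(numeric(0)), 3), rep(list(character(0)), 2)),
      .ct_columns))
    return(coding_table(empty, provenance = path))
  }
  for (col in c("n", "r_pa_re", "r_pa_mh", "r_re_mh")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & nzchar(trimws(raw[[col]])))
    if (length(bad) > 0)
      stop("non-numeric ", col, " in row(s): ", paste(bad, collapse = ", "))
    if (anyNA(vals))
      stop("empty ", col, " in row(s): ", paste(which(is.na(vals)), collapse = ", "))
    raw[[col]] <- vals
  }
  for (opt in .ct_optional) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
    raw[[opt]][!nzchar(trimws(raw[[opt]]))] <- NA_character_
  }
  bad_rows <- integer(0)
  for (i in seq_len(nrow(raw))) {
    probs <- .validate_record(raw[i, ])
    if (length(probs) > 0) {
      msg <- sprintf("row %d (%s): %s", i, raw$study_id[i],
                     paste(probs, collapse = "; "))
      if (strict) stop(msg) else {
        warning("dropping ", msg)
        bad_rows <- c(bad_rows, i)
      }
    }
  }
  if (length(bad_rows) > 0) raw <- raw[-bad_rows, , drop = FALSE]
  coding_table(raw, provenance = path)
}

#' Write a coding table to CSV
#'
#' Inverse of [read_coding_table()]: read-write-read round-trips are the
#' identity on all fields.
#'
#' @param table a [coding_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coding_table <- function(table, path) {
  stopifnot(inherits(table, "coding_table"))
  out <- as.data.frame(table)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a coding table by indicator polarity
#'
#' The two analysis strata pool positive indicators of mental health
#' (well-being, life satisfaction) and negative indicators (depression,
#' anxiety, negative affect) separately; this extracts one stratum,
#' preserving the original row order.
#'
#' @param table a [coding_table()].
#' @param polarity `"positive"` or `"negative"`.
#' @param exclude_ids study_id values to drop from the stratum (e.g. to
#'   match an analysis that folded overlapping samples together).
#' @return a [coding_table()] with the matching rows.
#' @export
subset_by_polarity <- function(table, polarity, exclude_ids = character(0)) {
  stopifnot(inherits(table, "coding_table"))
  polarity <- match.arg(polarity, .polarities)
  keep <- table$polarity == polarity & !(table$study_id %in% exclude_ids)
  coding_table(as.data.frame(table)[keep, , drop = FALSE],
               provenance = attr(table, "provenance"))
}

#' Count unique subjects in a coding table
#'
#' Sums sample sizes over rows, counting each `shares_sample_with` group of
#' rows (sub-samples coded from the same subjects) once.
#'
#' @param table a [coding_table()].
#' @return integer total of unique subjects.
#' @export
unique_subjects <- function(table) {
  stopifnot(inherits(table, "coding_table"))
  if (nrow(table) == 0) return(0L)
  # resolve each row to a group root by following shares_sample_with links
  root <- table$study_id
  link <- table$shares_sample_with
  names(link) <- table$study_id
  for (i in seq_along(root)) {
    seen <- character(0)
    while (!is.na(link[root[i]]) && link[root[i]] %in% table$study_id &&
           !root[i] %in% seen) {
      seen <- c(seen, root[i])
      root[i] <- link[root[i]]
    }
  }
  as.integer(sum(tapply(table$n, root, max)))
}

#' Packaged study table: physical activity, resilience, and mental health
#'
#' The coded study table shipped with the package: 16 independent samples
#' from 15 published reports (17,043 unique subjects; two rows are
#' sub-samples of the same cohort, linked via `shares_sample_with`), each
#' supplying the three pairwise correlations among physical activity,
#' resilience, and a positive or negative mental-health indicator.
#' Correlations are stored exactly as published, including mixed precision.
#'
#' @return a [coding_table()] with 16 records.
#' @export
pa_resilience_studies <- function() {
  path <- system.file("extdata", "pa_resilience_mh_studies.csv",
                      package = "metapath", mustWork = TRUE)
  read_coding_table(path)
}

#' @export
print.coding_table <- function(x, ...) {
  cat(sprintf("Coding table: %d record(s), %d unique subject(s)\n",
              nrow(x), unique_subjects(x)))
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("provenance:", attr(x, "provenance"), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
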