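# Cohort container and delimited-text I/O.

COHORT_RAW_COLS <- c("id", "site", "sex", "age", "genotype", "rle_count",
                     "cha_score", "dep", "bsi_dep", "bsi_anx")

#' Construct a cohort table
#'
#' A cohort is an ordinary data frame with one row per subject, raw columns
#' `id`, `site`, `sex`, `age`, `genotype`, `rle_count`, `cha_score`, `dep`,
#' `bsi_dep`, `bsi_anx` and (after [derive_variables()]) the derived
#' category columns. Subject ids must be unique; subsetting never mutates
#' records.
#'
#' @param x A data frame with at least the raw columns.
#' @return The validated data frame with class `cohort` prepended.
#' @export
as_cohort <- function(x) {
  if (!is.data.frame(x)) stop_validation("cohort must be a data frame")
  missing_cols <- setdiff(COHORT_RAW_COLS, names(x))
  if (length(missing_cols))
    stop_validation("cohort is missing columns: ",
                    paste(missing_cols, collapse = ", "))
  if (anyDuplicated(x$id)) stop_validation("subject ids must be unique")
  ok <- is.na(x$genotype) | tolower(x$genotype) %in% c("ss", "sl", "ls", "ll")
  if (!all(ok)) stop_validation("invalid genotype tokens in cohort")
  class(x) <- unique(c("cohort", class(x)))
  x
}

#' Select a subgroup of a cohort
#'
#' Filters rows by derived-category values, e.g.
#' `cohort_subset(ch, rle_cat = "high", age_group = "young")`. Records are
#' copied, never mutated; `NA` in a filtering column drops the row.
#'
#' @param cohort A cohort table.
#' @param ... Named filters: column = allowed value(s).
#' @return The filtered cohort.
#' @export
cohort_subset <- function(cohort, ...) {
  filters <- list(...)
  keep <- rep(TRUE, nrow(cohort))
  for (nm in names(filters)) {
    if (!nm %in% names(cohort))
      stop_validation("unknown cohort column: ", nm)
    col <- cohort[[nm]]
    keep <- keep & !is.na(col) & as.character(col) %in%
      as.character(filters[[nm]])
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a cohort from delimited text
#'
#' Accepts tab- or comma-separated text with a header row. Missing values
#' may be empty fields or `NA`. Genotypes are matched case-insensitively
#' against `ss`/`sl`/`ll`. Derived columns are recomputed on read.
#'
#' @param path File path.
#' @param sep Field separator; default tab, use "," for CSV.
#' @return A cohort table with derived variables attached.
#' @export
read_cohort <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  df$genotype <- ifelse(is.na(df$genotype), NA_character_,
                        tolower(df$genotype))
  derive_variables(df)
}

#' Write a cohort as tab-separated text
#'
#' Writes the raw columns (and any derived columns present) with a header
#' row; missing values are written as `NA`.
#'
#' @param cohort A cohort table.
#' @param path Output file path.
#' @param sep Field separator; default tab.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = "\t") {
  utils::write.table(cohort, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects, %d columns\n", nrow(x), ncol(x)))
  NextMethod()
}
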