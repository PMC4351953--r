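# Derived-variable rules of the cohort data model: BSI weighted scoring,
# all categorizations, additive genotype coding. Every rule is total on its
# valid domain, deterministic, and propagates missingness (no imputation).

#' BSI weighted score from item responses
#'
#' The Brief Symptom Inventory subscales are scored as the sum of completed
#' item scores divided by the number of items completed, so partially
#' answered subscales still yield a score on the 0-4 scale. With no
#' completed items the score is missing.
#'
#' @param items Integer item responses in 0-4; `NA` marks a skipped item.
#'   Either a vector (one subject) or a matrix with one row per subject.
#' @return A score in [0,4] (or a vector of them for matrix input); `NA`
#'   where no item was completed.
#' @examples
#' weighted_bsi_score(c(1, 2, 3, NA))  # 2
#' @export
weighted_bsi_score <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    m <- as.matrix(items)
    bad <- !is.na(m) & (m < 0 | m > 4)
    if (any(bad)) stop_validation("BSI item scores must lie in 0-4")
    k <- rowSums(!is.na(m))
    out <- ifelse(k == 0, NA_real_, rowSums(m, na.rm = TRUE) / k)
    return(as.numeric(out))
  }
  x <- as.numeric(items)
  if (any(!is.na(x) & (x < 0 | x > 4)))
    stop_validation("BSI item scores must lie in 0-4")
  if (all(is.na(x))) return(NA_real_)
  mean(x, na.rm = TRUE)
}

#' Categorize a BSI score into severity bands
#'
#' Low is below 1, moderate is 1 to below 2, severe is 2 to 4; boundaries
#' belong to the upper band (a score of exactly 1 is moderate, exactly 2 is
#' severe).
#'
#' @param score Numeric score(s) in [0,4]; `NA` allowed.
#' @return Factor with levels `low`, `moderate`, `severe`.
#' @export
categorize_bsi <- function(score) {
  x <- as.numeric(score)
  if (any(!is.na(x) & (x < 0 | x > 4)))
    stop_validation("BSI score out of range [0,4]")
  cut_to_factor(x, c(1, 2), c("low", "moderate", "severe"))
}

#' Categorize a recent-negative-life-event count
#'
#' Low is 0-1 events in the past year, medium exactly 2, high 3 or more.
#'
#' @param count Nonnegative integer count(s); `NA` allowed.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
categorize_rle <- function(count) {
  x <- as.numeric(count)
  if (any(!is.na(x) & x < 0)) stop_validation("RLE count must be >= 0")
  cut_to_factor(x, c(2, 3), c("low", "medium", "high"))
}

#' Categorize a childhood-adversity score
#'
#' Low is a summed score of 0-3, medium 4-6, high 7 or more.
#'
#' @param score Nonnegative integer score(s); `NA` allowed.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
categorize_cha <- function(score) {
  x <- as.numeric(score)
  if (any(!is.na(x) & x < 0)) stop_validation("CHA score must be >= 0")
  cut_to_factor(x, c(4, 7), c("low", "medium", "high"))
}

# Shared piecewise-constant mapper: breaks are lower bounds of the upper
# bands, so values on a boundary land in the upper band.
#' @keywords internal
cut_to_factor <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks) + 1L
  factor(labels[idx], levels = labels)
}

#' Age stratum assignment
#'
#' The two age strata split at 30 years; the boundary belongs to the
#' younger stratum (30 or below is `young`, above 30 is `old`).
#'
#' @param age Age(s) in years; `NA` allowed.
#' @return Factor with levels `young`, `old`.
#' @export
assign_age_group <- function(age) {
  x <- as.numeric(age)
  factor(ifelse(x <= 30, "young", "old"), levels = c("young", "old"))
}

#' Additive genotype coding
#'
#' Codes each genotype by its count of s (minor) alleles: ll is 0, sl is 1,
#' ss is 2. The additive regression models test this single 0/1/2 term.
#'
#' @param genotype Character vector of genotypes `ss`, `sl`, `ll`
#'   (case-insensitive; `ls` accepted for `sl`); `NA` allowed.
#' @return Integer vector in 0/1/2.
#' @export
additive_code <- function(genotype) {
  g <- tolower(as.character(genotype))
  g[g == "ls"] <- "sl"
  codes <- c(ll = 0L, sl = 1L, ss = 2L)
  bad <- !is.na(g) & !g %in% names(codes)
  if (any(bad))
    stop_validation("unknown genotype token: ",
                    paste(unique(g[bad]), collapse = ", "))
  unname(codes[g])
}

#' Attach all derived variables to a cohort table
#'
#' Recomputes `rle_cat`, `cha_cat`, `bsi_dep_cat`, `bsi_anx_cat`,
#' `age_group` and the additive genotype code `g_additive` from the raw
#' columns. Derived values are pure functions of the raw fields; a missing
#' raw field yields a missing derived field.
#'
#' @param cohort A cohort data frame with the raw columns (`genotype`,
#'   `age`, `rle_count`, `cha_score`, `bsi_dep`, `bsi_anx`).
#' @return The cohort with derived columns added/refreshed, class `cohort`.
#' @export
derive_variables <- function(cohort) {
  cohort$rle_cat <- categorize_rle(cohort$rle_count)
  cohort$cha_cat <- categorize_cha(cohort$cha_score)
  cohort$bsi_dep_cat <- categorize_bsi(cohort$bsi_dep)
  cohort$bsi_anx_cat <- categorize_bsi(cohort$bsi_anx)
  cohort$age_group <- assign_age_group(cohort$age)
  cohort$g_additive <- additive_code(cohort$genotype)
  as_cohort(cohort)
}
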