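# Genotype-level QC: Hardy-Weinberg equilibrium, between-site genotype
# comparison, and the population summary table.

#' Genotype counts
#'
#' @param n_ss,n_sl,n_ll Nonnegative counts of the three genotypes.
#' @return A `genotype_counts` object.
#' @export
genotype_counts <- function(n_ss, n_sl, n_ll) {
  n <- c(ss = n_ss, sl = n_sl, ll = n_ll)
  if (any(is.na(n)) || any(n < 0) || any(n != floor(n)))
    stop_validation("genotype counts must be nonnegative integers")
  if (sum(n) == 0) stop_validation("genotype counts are all zero")
  structure(as.list(n), class = "genotype_counts")
}

#' @keywords internal
count_genotypes <- function(cohort) {
  g <- tolower(cohort$genotype)
  genotype_counts(sum(g == "ss", na.rm = TRUE),
                  sum(g %in% c("sl", "ls"), na.rm = TRUE),
                  sum(g == "ll", na.rm = TRUE))
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness of fit of the observed
#' genotype counts against the Hardy-Weinberg proportions p^2, 2pq, q^2
#' implied by the observed allele frequency. This is the standard
#' asymptotic genotype-QC test for a biallelic locus; with the cohort sizes
#' used here the asymptotic approximation is adequate and no exact test is
#' offered.
#'
#' @param counts A [genotype_counts()] object, or a cohort table (counts
#'   are extracted from its `genotype` column).
#' @return List with `chi_square`, `p`, `df` (= 1) and the fitted
#'   s-allele frequency `s_freq`.
#' @examples
#' hwe_test(genotype_counts(438, 1138, 782))
#' @export
hwe_test <- function(counts) {
  if (inherits(counts, "cohort") || is.data.frame(counts))
    counts <- count_genotypes(counts)
  if (!inherits(counts, "genotype_counts"))
    counts <- do.call(genotype_counts, as.list(unname(unlist(counts))))
  obs <- c(counts$ss, counts$sl, counts$ll)
  n <- sum(obs)
  p <- (2 * counts$ss + counts$sl) / (2 * n)
  q <- 1 - p
  expd <- n * c(p^2, 2 * p * q, q^2)
  if (p %in% c(0, 1)) {
    # monomorphic: trivially consistent with HWE
    return(list(chi_square = 0, p = 1, df = 1L, s_freq = p))
  }
  chi <- sum((obs - expd)^2 / expd)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       df = 1L, s_freq = p)
}

#' Population summary table
#'
#' Per-variable counts with integer-rounded percentages (denominator: the
#' nonmissing values of that variable; percentages rounded half-up) and
#' mean with standard error of the mean for continuous variables —
#' the layout of a study population-description table.
#'
#' @param cohort A cohort table (derived variables are recomputed if
#'   absent).
#' @return A data frame with columns `variable`, `statistic`, `count`,
#'   `percent`, `mean`, `sem`.
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort) == 0) stop_validation("cohort is empty")
  if (!"g_additive" %in% names(cohort)) cohort <- derive_variables(cohort)
  rows <- list()
  add_cat <- function(variable, values, levels) {
    values <- factor(as.character(values), levels = levels)
    tab <- table(values)
    denom <- sum(tab)
    for (lv in levels) {
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, statistic = lv,
        count = as.integer(tab[[lv]]),
        percent = if (denom > 0)
          round_half_up(100 * tab[[lv]] / denom) else NA_real_,
        mean = NA_real_, sem = NA_real_)
    }
  }
  add_cont <- function(variable, x) {
    x <- x[!is.na(x)]
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, statistic = "mean",
      count = length(x), percent = NA_real_,
      mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
  }
  add_cat("sex", cohort$sex, c("male", "female"))
  add_cat("dep", cohort$dep, c("no", "yes"))
  add_cont("rle_count", cohort$rle_count)
  add_cat("rle_cat", cohort$rle_cat, c("low", "medium", "high"))
  add_cont("cha_score", cohort$cha_score)
  add_cat("cha_cat", cohort$cha_cat, c("low", "medium", "high"))
  add_cont("age", cohort$age)
  add_cat("age_group", cohort$age_group, c("young", "old"))
  add_cont("bsi_dep", cohort$bsi_dep)
  add_cat("bsi_dep_cat", cohort$bsi_dep_cat, c("low", "moderate", "severe"))
  add_cont("bsi_anx", cohort$bsi_anx)
  add_cat("bsi_anx_cat", cohort$bsi_anx_cat, c("low", "moderate", "severe"))
  add_cat("genotype", tolower(cohort$genotype), c("ss", "sl", "ll"))
  do.call(rbind, rows)
}

#' Compare genotype distributions between two cohorts
#'
#' Logistic regression of cohort membership on the additive genotype code,
#' mirroring the additive-model site-comparison test used to justify
#' pooling recruitment sites.
#'
#' @param cohort_a,cohort_b Cohort tables with genotypes.
#' @return A `regression_result` row for the additive term (see
#'   [fit_model()]).
#' @export
compare_genotype_distributions <- function(cohort_a, cohort_b) {
  if (nrow(cohort_a) == 0 || nrow(cohort_b) == 0)
    stop_validation("both cohorts must be nonempty")
  g <- c(additive_code(cohort_a$genotype), additive_code(cohort_b$genotype))
  y <- c(rep(0L, nrow(cohort_a)), rep(1L, nrow(cohort_b)))
  keep <- !is.na(g)
  fit <- stats::glm(y[keep] ~ g[keep], family = stats::binomial())
  summarize_glm_term(fit, term_index = 2L, term = "g_additive",
                     logistic = TRUE, n_used = sum(keep))
}
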