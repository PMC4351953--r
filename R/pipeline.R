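# End-to-end orchestration: QC -> population summary -> association model
# matrix -> Bayesian stratified analyses -> consolidated report.

#' Analysis configuration for a full study run
#'
#' @param input Optional path to a cohort file (read with
#'   [read_cohort()]); if `NULL`, a cohort is generated from `sim`.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param stages Which stages to run, a subset of
#'   `c("qc", "summary", "assoc", "bayes")`.
#' @param n_perm Permutations for the p-value follow-up of nominally
#'   significant cells.
#' @param perm_threshold Permutation p-values are computed only for cells
#'   with asymptotic p below this (matching the practice of permuting only
#'   nominally significant results); set to 1 to permute everything, 0 to
#'   disable.
#' @param ess,max_parents,n_draws,min_stratum_n Bayesian-track settings,
#'   see [enumerate_model_posterior()], [bayesian_or()] and
#'   [stratified_relevance_grid()].
#' @param bonferroni_tests Optional user-declared number of tests; when
#'   given, the report annotates the Bonferroni-corrected threshold
#'   `0.05 / bonferroni_tests` next to the nominal 0.05 (no correction is
#'   applied to the results themselves).
#' @param seed Root seed; every stochastic stage derives its own stream
#'   from it.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, sim = sim_config(),
                            stages = c("qc", "summary", "assoc", "bayes"),
                            n_perm = 200, perm_threshold = 0.05,
                            ess = 1, max_parents = 2, n_draws = 4000,
                            min_stratum_n = 20, bonferroni_tests = NULL,
                            seed = 1L) {
  stages <- match.arg(stages, c("qc", "summary", "assoc", "bayes"),
                      several.ok = TRUE)
  if (is.null(seed)) stop_config("seed is mandatory")
  structure(list(input = input, sim = sim, stages = stages,
                 n_perm = n_perm, perm_threshold = perm_threshold,
                 ess = ess, max_parents = max_parents, n_draws = n_draws,
                 min_stratum_n = min_stratum_n,
                 bonferroni_tests = bonferroni_tests, seed = seed),
            class = "analysis_config")
}

#' @keywords internal
try_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           value = conditionMessage(e)))
  if (res$ok) report[[name]] <- res$value
  else report$failures[[name]] <- res$value
  report
}

# The shipped association model matrix: three outcomes x four model
# families x three age strata, skipping the anxiety-covariate family for
# the anxiety outcome (it cannot be its own covariate).
#' @keywords internal
assoc_model_matrix <- function(cohort, n_perm, perm_threshold, seed) {
  outcomes <- c("DEP", "BSI_DEP", "BSI_ANX")
  strata <- list(all = list(), young = list(age_group = "young"),
                 old = list(age_group = "old"))
  families <- list(
    main = list(environment = "none", interaction = FALSE,
                anx_covariate = FALSE),
    GxRLE = list(environment = "RLE", interaction = TRUE,
                 anx_covariate = FALSE),
    GxRLE_anxcov = list(environment = "RLE", interaction = TRUE,
                        anx_covariate = TRUE),
    GxCHA = list(environment = "CHA", interaction = TRUE,
                 anx_covariate = FALSE))
  rows <- list()
  for (oc in outcomes) for (fam in names(families)) {
    if (oc == "BSI_ANX" && fam == "GxRLE_anxcov") next
    for (st in names(strata)) {
      f <- families[[fam]]
      spec <- model_spec(outcome = oc, environment = f$environment,
                         interaction = f$interaction,
                         anx_covariate = f$anx_covariate,
                         subgroup = strata[[st]])
      res <- tryCatch(fit_model(cohort, spec), error = function(e) NULL)
      if (is.null(res)) next
      if (!is.na(res$p) && res$p < perm_threshold && n_perm >= 1) {
        pseed <- derive_seed(seed, paste(oc, fam, st))
        res <- tryCatch({
          if (f$interaction)
            permutation_p_interaction(cohort, spec, n_perm, pseed)
          else permutation_p_main(cohort, spec, n_perm, pseed)
        }, error = function(e) res)
      }
      res$outcome <- oc; res$model <- fam; res$stratum <- st
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("outcome", "model", "stratum", "term", "estimate", "or_value",
          "se", "l95", "u95", "stat", "p", "p_perm", "n_used",
          "converged", "note")]
}

# Genotype-by-RLE interaction on the BSI depression score within
# childhood-adversity strata (the stress-sensitization design).
#' @keywords internal
gxrle_by_cha <- function(cohort) {
  strata <- list(cha_low = list(cha_cat = "low"),
                 cha_medhigh = list(cha_cat = c("medium", "high")))
  rows <- list()
  for (oc in c("DEP", "BSI_DEP")) for (st in names(strata)) {
    spec <- model_spec(outcome = oc, environment = "RLE",
                       interaction = TRUE, subgroup = strata[[st]])
    res <- tryCatch(fit_model(cohort, spec), error = function(e) NULL)
    if (is.null(res)) next
    res$outcome <- oc; res$model <- "GxRLE"; res$stratum <- st
    rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full two-track study analysis
#'
#' Executes, in order and as selected by `config$stages`: cohort loading
#' or generation with derived variables; genotype QC (Hardy-Weinberg
#' equilibrium in the whole cohort and within site and
#' lifetime-depression subcohorts, plus the between-site genotype
#' comparison); the population summary table; the frequentist association
#' model matrix (genotype main effects, genotype-by-RLE interaction with
#' and without the anxiety covariate, genotype-by-CHA interaction, each in
#' the full cohort and the two age strata, with permutation p-values for
#' nominally significant cells, plus the genotype-by-RLE interaction
#' within childhood-adversity strata); and the Bayesian stratified
#' relevance and odds-ratio analyses (per RLE stratum for the three
#' phenotypes, per age stratum for anxiety, and the multivariate-phenotype
#' grid over RLE x CHA x age). A failed stage is recorded in
#' `$failures` and does not stop independent stages.
#'
#' @param config An [analysis_config()].
#' @return A `study_report` list with elements `cohort`, `qc`, `summary`,
#'   `assoc`, `assoc_by_cha`, `bayes`, `failures` and `provenance`.
#' @export
run_study <- function(config) {
  if (!inherits(config, "analysis_config"))
    stop_validation("config must be an analysis_config")
  report <- structure(list(failures = list()), class = "study_report")

  cohort <- if (!is.null(config$input)) read_cohort(config$input)
  else generate_cohort(config$sim,
                       seed = derive_seed(config$seed, "cohort"))
  report$cohort <- cohort

  if ("qc" %in% config$stages) {
    report <- try_stage(report, "qc", {
      by_site <- lapply(split(cohort, cohort$site), hwe_test)
      by_dep <- lapply(split(cohort, cohort$dep), hwe_test)
      sites <- split(cohort, cohort$site)
      cmp <- if (length(sites) == 2)
        compare_genotype_distributions(sites[[1]], sites[[2]]) else NULL
      list(hwe_total = hwe_test(cohort), hwe_by_site = by_site,
           hwe_by_dep = by_dep, site_comparison = cmp)
    })
  }
  if ("summary" %in% config$stages)
    report <- try_stage(report, "summary", cohort_summary(cohort))
  if ("assoc" %in% config$stages) {
    report <- try_stage(report, "assoc", assoc_model_matrix(
      cohort, config$n_perm, config$perm_threshold,
      derive_seed(config$seed, "assoc")))
    report <- try_stage(report, "assoc_by_cha", gxrle_by_cha(cohort))
  }
  if ("bayes" %in% config$stages) {
    bseed <- derive_seed(config$seed, "bayes")
    report <- try_stage(report, "bayes", {
      rle_strata <- list(rle_cat = c("low", "medium", "high"))
      by_rle <- list(
        dep = stratified_relevance_grid(
          cohort, rle_strata, targets = "dep",
          or_spec = list(target = "dep", target_category = "yes",
                         reference_category = "no"),
          max_parents = config$max_parents, ess = config$ess,
          n_draws = config$n_draws, min_n = config$min_stratum_n,
          seed = derive_seed(bseed, "dep")),
        bsi_dep = stratified_relevance_grid(
          cohort, rle_strata, targets = "bsi_dep_cat",
          or_spec = list(target = "bsi_dep_cat",
                         target_category = "severe",
                         reference_category = "low"),
          max_parents = config$max_parents, ess = config$ess,
          n_draws = config$n_draws, min_n = config$min_stratum_n,
          seed = derive_seed(bseed, "bsi_dep")),
        bsi_anx = stratified_relevance_grid(
          cohort, rle_strata, targets = "bsi_anx_cat",
          or_spec = list(target = "bsi_anx_cat",
                         target_category = "severe",
                         reference_category = "low"),
          max_parents = config$max_parents, ess = config$ess,
          n_draws = config$n_draws, min_n = config$min_stratum_n,
          seed = derive_seed(bseed, "bsi_anx")))
      anx_by_age <- stratified_relevance_grid(
        cohort, list(age_group = c("young", "old")),
        targets = "bsi_anx_cat",
        or_spec = list(target = "bsi_anx_cat", target_category = "severe",
                       reference_category = "low"),
        max_parents = config$max_parents, ess = config$ess,
        n_draws = config$n_draws, min_n = config$min_stratum_n,
        seed = derive_seed(bseed, "anx_age"))
      multivariate <- stratified_relevance_grid(
        cohort,
        list(rle_cat = c("low", "medium", "high"),
             cha_cat = list(low = "low", medhigh = c("medium", "high")),
             age_group = c("young", "old")),
        targets = c("dep", "bsi_dep_cat", "bsi_anx_cat"),
        max_parents = config$max_parents, ess = config$ess,
        n_draws = 0, min_n = config$min_stratum_n,
        seed = derive_seed(bseed, "multi"))
      list(by_rle = by_rle, anx_by_age = anx_by_age,
           multivariate = multivariate)
    })
  }
  report$provenance <- list(
    seed = config$seed, stages = config$stages,
    n_perm = config$n_perm, ess = config$ess,
    max_parents = config$max_parents, n_draws = config$n_draws,
    alpha_nominal = 0.05,
    alpha_bonferroni = if (!is.null(config$bonferroni_tests))
      0.05 / config$bonferroni_tests else NA_real_,
    package_version = as.character(utils::packageVersion("gxebayes")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  cat(sprintf("  cohort: %d subjects\n", nrow(x$cohort)))
  if (!is.null(x$qc))
    cat(sprintf("  QC: HWE chi2 = %.3f, p = %.3f\n",
                x$qc$hwe_total$chi_square, x$qc$hwe_total$p))
  if (!is.null(x$assoc))
    cat(sprintf("  assoc: %d model cells (%d nominally significant)\n",
                nrow(x$assoc), sum(x$assoc$p < 0.05, na.rm = TRUE)))
  if (!is.null(x$bayes))
    cat(sprintf("  bayes: %d RLE-stratified grids + multivariate grid\n",
                length(x$bayes$by_rle)))
  if (length(x$failures))
    cat("  failed stages:", paste(names(x$failures), collapse = ", "),
        "\n")
  invisible(x)
}

#' Positive likelihood ratios of a binary outcome by exposure group
#'
#' For each exposure group, LR+ = P(group | outcome yes) /
#' P(group | outcome no), computed from the group-by-outcome contingency
#' table. A zero denominator cell triggers a continuity-corrected fallback
#' (0.5 added to every cell), flagged in the result.
#'
#' @param cohort A cohort table.
#' @param outcome Name of a binary (`yes`/`no`) cohort column; default
#'   `dep`.
#' @param exposure Name of a categorical cohort column; default `rle_cat`.
#' @return Data frame with `group`, `n_case`, `n_control`, `lr_plus`,
#'   `corrected`.
#' @export
likelihood_ratio_by_exposure <- function(cohort, outcome = "dep",
                                         exposure = "rle_cat") {
  if (!"g_additive" %in% names(cohort)) cohort <- derive_variables(cohort)
  y <- cohort[[outcome]]
  g <- cohort[[exposure]]
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(factor(g[keep]))
  if (!length(y)) stop_validation("no complete cases")
  if (!all(y %in% c("yes", "no")))
    stop_validation("outcome must be binary yes/no")
  tab <- table(g, factor(y, levels = c("no", "yes")))
  corrected <- any(tab == 0) || any(colSums(tab) == 0)
  if (corrected) tab <- tab + 0.5
  p_case <- tab[, "yes"] / sum(tab[, "yes"])
  p_ctrl <- tab[, "no"] / sum(tab[, "no"])
  data.frame(group = rownames(tab),
             n_case = as.numeric(tab[, "yes"]),
             n_control = as.numeric(tab[, "no"]),
             lr_plus = as.numeric(p_case / p_ctrl),
             corrected = corrected, row.names = NULL)
}
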