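# Bayesian relevance track, part 3: stratified subgroup analyses.

#' @keywords internal
expand_strata <- function(stratify_by) {
  # each element: character vector of levels, or a named list whose
  # entries are level groups (e.g. list(low = "low",
  # medhigh = c("medium", "high")))
  lab <- lapply(stratify_by, function(x) {
    if (is.list(x)) names(x) else as.character(x)
  })
  grid <- expand.grid(lab, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  values <- lapply(seq_len(nrow(grid)), function(i) {
    vals <- list()
    for (v in names(stratify_by)) {
      x <- stratify_by[[v]]
      vals[[v]] <- if (is.list(x)) x[[grid[i, v]]] else grid[i, v]
    }
    vals
  })
  list(labels = grid, values = values)
}

#' Stratified relevance and odds-ratio grid
#'
#' Runs the discretize / enumerate / relevance pipeline independently in
#' each stratum of the cohort (strata defined by recent-life-event
#' category, childhood-adversity category and/or age group, possibly with
#' merged levels) and reports the posterior probability of strong
#' relevance of the chosen predictor per stratum, optionally together
#' with a Bayesian odds-ratio posterior per stratum. Empty or undersized
#' strata are reported as missing cells, not failures.
#'
#' @param cohort A cohort table.
#' @param stratify_by Named list defining the strata, e.g.
#'   `list(rle_cat = c("low", "medium", "high"))` or
#'   `list(rle_cat = c("low", "medium", "high"),
#'   cha_cat = list(low = "low", medhigh = c("medium", "high")),
#'   age_group = c("young", "old"))`.
#' @param targets Target variable name(s) in the discretized space;
#'   several targets give the multivariate (union) relevance reading.
#' @param predictor Predictor whose relevance is reported.
#' @param candidates Candidate predictors for the enumeration; sex and
#'   age group are included by default so model averaging handles them.
#' @param max_parents,ess Passed to [enumerate_model_posterior()].
#' @param or_spec Optional odds-ratio request: a list with `target`,
#'   `target_category`, `reference_category` and optionally
#'   `genotype_level` (default `"ss"`), evaluated per stratum via
#'   [bayesian_or()].
#' @param n_draws Monte-Carlo draws per odds-ratio posterior.
#' @param min_n Smallest complete-case stratum size analyzed.
#' @param seed Integer seed; per-stratum streams are derived from it.
#' @return A `relevance_grid` data frame: one row per stratum with the
#'   stratum labels, `n`, `pr` (relevance posterior), `prior_pr`
#'   (structure-prior baseline) and, when requested, `or_median`,
#'   `or_l95`, `or_u95`, `or_inclusion`. The full `or_posterior` objects
#'   are attached as attribute `"or"`.
#' @export
stratified_relevance_grid <- function(cohort,
                                      stratify_by = list(
                                        rle_cat = c("low", "medium",
                                                    "high")),
                                      targets = "dep",
                                      predictor = "genotype",
                                      candidates = c("genotype", "sex",
                                                     "age_group"),
                                      max_parents = 2, ess = 1,
                                      or_spec = NULL, n_draws = 4000,
                                      min_n = 20, seed = 1L) {
  if (!"g_additive" %in% names(cohort)) cohort <- derive_variables(cohort)
  strata <- expand_strata(stratify_by)
  vars <- unique(c(targets, candidates))
  prior_pr <- prior_inclusion_probability(length(candidates), max_parents)
  rows <- list(); ors <- list()
  for (i in seq_len(nrow(strata$labels))) {
    labs <- strata$labels[i, , drop = FALSE]
    label <- paste(names(labs), unlist(labs), sep = "=", collapse = ",")
    sub <- do.call(cohort_subset, c(list(cohort), strata$values[[i]]))
    row <- cbind(labs, data.frame(n = NA_integer_, pr = NA_real_,
                                  prior_pr = prior_pr,
                                  note = NA_character_))
    dd <- tryCatch(discretize_cohort(sub, variables = vars,
                                     subgroup_label = label),
                   error = function(e) NULL)
    if (is.null(dd) || nrow(dd) < min_n) {
      row$note <- "stratum empty or below min_n"
      rows[[i]] <- row
      next
    }
    post <- enumerate_model_posterior(dd, targets, candidates,
                                      max_parents = max_parents, ess = ess)
    row$n <- nrow(dd)
    row$pr <- relevance_posterior(post, predictor)
    if (!is.null(or_spec)) {
      orp <- tryCatch(bayesian_or(
        dd, post, target = or_spec$target,
        target_category = or_spec$target_category,
        reference_category = or_spec$reference_category,
        genotype_var = predictor,
        genotype_level = or_spec$genotype_level %||% "ss",
        n_draws = n_draws, seed = derive_seed(seed, label)),
        error = function(e) NULL)
      if (!is.null(orp)) {
        row$or_median <- orp$median
        row$or_l95 <- orp$ci[1]
        row$or_u95 <- orp$ci[2]
        row$or_inclusion <- orp$inclusion_prob
        ors[[label]] <- orp
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad rows missing OR columns
    if (!is.null(or_spec))
      for (cn in c("or_median", "or_l95", "or_u95", "or_inclusion"))
        if (!cn %in% names(r)) r[[cn]] <- NA_real_
    r
  }))
  rownames(out) <- NULL
  structure(out, class = c("relevance_grid", "data.frame"),
            or = if (length(ors)) ors else NULL,
            targets = targets, predictor = predictor)
}

#' @export
print.relevance_grid <- function(x, ...) {
  cat(sprintf("Relevance grid: Pr(%s strongly relevant for %s)\n",
              attr(x, "predictor"),
              paste(attr(x, "targets"), collapse = "+")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
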