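# Bayesian relevance track, part 1: discretization, Dirichlet-multinomial
# structure scoring, exhaustive parent-set posteriors, and relevance
# probabilities.
#
# The model class averaged over is the set of parent sets of the declared
# target(s) drawn from a fixed candidate-predictor list. When predictors
# are exogenous (roots) and targets are sinks — the situation here, where
# genotype, sex, age and exposure predict phenotypes — parent-set
# membership coincides with Markov-blanket (strong-relevance) membership,
# so exhaustive enumeration over parent sets replaces sampling over DAGs.

#' Discretize a cohort for the Bayesian analyses
#'
#' Maps the cohort onto the categorical variables the relevance analysis
#' operates on: genotype (ll/sl/ss), sex, the two-level age stratum,
#' low/medium/high recent-life-event and childhood-adversity categories,
#' lifetime depression (no/yes), and the low/moderate/severe bands of the
#' two BSI scores. Rows with a missing value in any selected variable are
#' dropped (complete-case per analysis).
#'
#' @param cohort A cohort table.
#' @param variables Character vector of variables to keep, from
#'   `genotype`, `sex`, `age_group`, `rle_cat`, `cha_cat`, `dep`,
#'   `bsi_dep_cat`, `bsi_anx_cat`, `pheno_multi`.
#' @param composite Add `pheno_multi`, a two-level composite phenotype that
#'   is `affected` when the subject reports lifetime depression or scores
#'   in the severe band of either BSI subscale. One of the two supported
#'   readings of a combined multivariate phenotype (the other being a
#'   joint multi-target analysis; see [relevance_posterior()]).
#' @param subgroup_label Provenance label stored on the result.
#' @return A data frame of factors with class `discrete_dataset` and
#'   attributes `n` and `subgroup`.
#' @export
discretize_cohort <- function(cohort,
                              variables = c("genotype", "sex", "age_group",
                                            "rle_cat", "dep"),
                              composite = FALSE,
                              subgroup_label = "all") {
  if (!"g_additive" %in% names(cohort)) cohort <- derive_variables(cohort)
  pool <- data.frame(
    genotype = factor(tolower(cohort$genotype), levels = c("ll", "sl", "ss")),
    sex = factor(cohort$sex, levels = c("male", "female")),
    age_group = cohort$age_group,
    rle_cat = cohort$rle_cat,
    cha_cat = cohort$cha_cat,
    dep = factor(cohort$dep, levels = c("no", "yes")),
    bsi_dep_cat = cohort$bsi_dep_cat,
    bsi_anx_cat = cohort$bsi_anx_cat)
  if (composite || "pheno_multi" %in% variables) {
    affected <- cohort$dep == "yes" | cohort$bsi_dep_cat == "severe" |
      cohort$bsi_anx_cat == "severe"
    pool$pheno_multi <- factor(ifelse(affected, "affected", "unaffected"),
                               levels = c("unaffected", "affected"))
    variables <- union(variables, "pheno_multi")
  }
  unknown <- setdiff(variables, names(pool))
  if (length(unknown))
    stop_validation("unknown variables: ", paste(unknown, collapse = ", "))
  out <- pool[, variables, drop = FALSE]
  keep <- stats::complete.cases(out)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop_validation("no complete cases for the selected variables")
  rownames(out) <- NULL
  structure(out, class = c("discrete_dataset", "data.frame"),
            n = nrow(out), subgroup = subgroup_label)
}

#' Dirichlet-multinomial score of one parent set
#'
#' Log marginal likelihood of the target variable given a candidate parent
#' set under the Bayesian-Dirichlet score with a uniform equivalent-sample
#' -size prior: with q parent configurations and r target categories the
#' hyperparameters are `alpha_jk = ess / (q * r)`, and the score is
#' `sum_j [ log Gamma(alpha_j) - log Gamma(alpha_j + N_j) +
#' sum_k ( log Gamma(alpha_jk + N_jk) - log Gamma(alpha_jk) ) ]`
#' with `alpha_j = ess / q`. Unobserved parent configurations contribute
#' zero.
#'
#' @param data A [discretize_cohort()] dataset.
#' @param target Name of the target variable.
#' @param parents Character vector of parent variable names (possibly
#'   empty).
#' @param ess Equivalent sample size of the parameter prior; must be > 0.
#' @return The log marginal likelihood (a single number).
#' @export
score_parent_set <- function(data, target, parents = character(), ess = 1) {
  if (!is.numeric(ess) || ess <= 0) stop_validation("ess must be > 0")
  if (target %in% parents)
    stop_validation("target cannot be its own parent")
  for (v in c(target, parents))
    if (!v %in% names(data)) stop_validation("unknown variable: ", v)
  tcol <- data[[target]]
  r <- nlevels(tcol)
  if (length(parents) == 0) {
    q <- 1L
    N <- matrix(table(tcol), nrow = 1)
  } else {
    q <- prod(vapply(parents, function(v) nlevels(data[[v]]), 1L))
    j <- interaction(data[parents], drop = FALSE, lex.order = TRUE)
    N <- as.matrix(table(j, tcol))
  }
  a_jk <- ess / (q * r)
  a_j <- ess / q
  Nj <- rowSums(N)
  sum(lgamma(a_j) - lgamma(a_j + Nj)) +
    sum(lgamma(a_jk + N) - lgamma(a_jk))
}

#' @keywords internal
all_parent_sets <- function(candidates, max_parents) {
  sets <- list(character())
  for (k in seq_len(min(max_parents, length(candidates)))) {
    cmb <- utils::combn(candidates, k, simplify = FALSE)
    sets <- c(sets, cmb)
  }
  sets
}

#' Exhaustive model posterior over parent sets
#'
#' Enumerates every parent subset of the candidate predictors up to
#' `max_parents` for each target, scores each with
#' [score_parent_set()], combines with the structure prior (uniform over
#' admissible sets by default) and normalizes with log-sum-exp. With
#' several targets the posterior factorizes over targets, each with its
#' own enumeration.
#'
#' @param data A [discretize_cohort()] dataset.
#' @param targets Character vector of target variable names.
#' @param candidates Candidate predictors (must not contain a target);
#'   at most 12, since enumeration is exhaustive.
#' @param max_parents Largest parent-set size considered.
#' @param ess Equivalent sample size passed to the score.
#' @param structure_prior `"uniform"` over admissible sets (default) or a
#'   numeric vector of log prior weights, one per enumerated set.
#' @return A `model_posterior`: for each target a data frame of
#'   `parent_set` (list column), `log_score`, `weight` (normalized, sums
#'   to 1).
#' @export
enumerate_model_posterior <- function(data, targets, candidates,
                                      max_parents = 4, ess = 1,
                                      structure_prior = "uniform") {
  if (any(targets %in% candidates))
    stop_validation("candidates must not contain a target")
  if (length(candidates) > 12)
    stop_validation("exhaustive enumeration supports at most 12 candidates")
  sets <- all_parent_sets(candidates, max_parents)
  log_prior <- if (identical(structure_prior, "uniform"))
    rep(-log(length(sets)), length(sets))
  else {
    if (length(structure_prior) != length(sets))
      stop_validation("structure_prior must have one weight per model")
    structure_prior - log_sum_exp(structure_prior)
  }
  per_target <- lapply(targets, function(tg) {
    ls_ <- vapply(sets, function(s) score_parent_set(data, tg, s, ess), 0)
    lp <- ls_ + log_prior
    w <- exp(lp - log_sum_exp(lp))
    df <- data.frame(log_score = ls_, weight = w)
    df$parent_set <- sets
    df
  })
  names(per_target) <- targets
  structure(list(per_target = per_target, targets = targets,
                 candidates = candidates, max_parents = max_parents,
                 ess = ess, n = attr(data, "n") %||% nrow(data),
                 subgroup = attr(data, "subgroup") %||% "all"),
            class = "model_posterior")
}

#' Posterior probability of strong relevance
#'
#' The posterior probability that a predictor belongs to the parent set of
#' the target — the model-averaged operationalization of strong relevance.
#' With several targets the default reading is the union: the probability
#' the predictor is a parent of at least one target (the factorized
#' posterior makes this `1 - prod_t (1 - Pr_t)`); `combine = "each"`
#' returns the per-target probabilities.
#'
#' @param posterior A [enumerate_model_posterior()] result.
#' @param predictor Name of the candidate predictor.
#' @param combine `"union"` (default) or `"each"`.
#' @return A probability in [0,1], or a named vector for `"each"`.
#' @export
relevance_posterior <- function(posterior, predictor, combine = "union") {
  if (!predictor %in% posterior$candidates)
    stop_validation("unknown predictor: ", predictor)
  incl <- vapply(posterior$per_target, function(pt) {
    sum(pt$weight[vapply(pt$parent_set, function(s) predictor %in% s,
                         TRUE)])
  }, 0)
  if (identical(combine, "each")) return(incl)
  1 - prod(1 - incl)
}

#' Prior inclusion probability of a predictor
#'
#' The structure-prior baseline against which a relevance posterior is
#' judged: under the uniform prior over parent sets of size at most
#' `max_parents` from `k` candidates, the fraction of sets containing any
#' given predictor.
#'
#' @param n_candidates Number of candidate predictors.
#' @param max_parents Largest parent-set size.
#' @return A probability in [0,1].
#' @export
prior_inclusion_probability <- function(n_candidates, max_parents) {
  sizes <- 0:min(max_parents, n_candidates)
  total <- sum(choose(n_candidates, sizes))
  containing <- sum(choose(n_candidates - 1, sizes[sizes > 0] - 1))
  containing / total
}

#' @export
print.model_posterior <- function(x, ...) {
  cat(sprintf(
    "Model posterior: %d target(s), %d candidates, max %d parents, n = %d\n",
    length(x$targets), length(x$candidates), x$max_parents, x$n))
  for (tg in x$targets) {
    pt <- x$per_target[[tg]]
    top <- order(pt$weight, decreasing = TRUE)[seq_len(min(3, nrow(pt)))]
    cat(sprintf("  %s: top sets %s\n", tg,
                paste(vapply(top, function(i) sprintf(
                  "{%s} %.3f", paste(pt$parent_set[[i]], collapse = ","),
                  pt$weight[i]), ""), collapse = "; ")))
  }
  invisible(x)
}
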