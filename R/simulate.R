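# Synthetic-cohort generator. Marginals emulate the motivating study
# population; effect sizes are injected on the scales the regression and
# relevance analyses estimate, so recovery is directly checkable.

# Within-category count distributions. Only the three category proportions
# are externally constrained; the within-category split is chosen once so
# the overall means land near the study's reported means (RLE ~1.21,
# CHA ~3.29) and is not configurable.
RLE_WITHIN <- list(low = c(`0` = 0.493, `1` = 0.507),
                   medium = c(`2` = 1),
                   high = c(`3` = 0.6, `4` = 0.3, `5` = 0.1))
CHA_WITHIN <- list(low = c(`0` = 0.22, `1` = 0.28, `2` = 0.20, `3` = 0.30),
                   medium = c(`4` = 1 / 3, `5` = 1 / 3, `6` = 1 / 3),
                   high = c(`7` = 0.4, `8` = 0.3, `9` = 0.2, `10` = 0.1))

#' @keywords internal
count_probs <- function(within, category_props) {
  values <- as.integer(unlist(lapply(within, names), use.names = FALSE))
  probs <- unlist(mapply(function(w, p) unname(w) * p, within,
                         category_props, SIMPLIFY = FALSE),
                  use.names = FALSE)
  list(values = values, probs = probs)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configuration's marginal structure and effect
#' sizes: genotypes in Hardy-Weinberg proportions at the configured
#' s-allele frequency; recent-life-event and childhood-adversity counts
#' whose low/medium/high category proportions match the config in
#' expectation; lifetime depression from a logistic model with additive
#' genotype, exposure-category and genotype-by-exposure terms plus a
#' latent-anxiety comorbidity term; and correlated censored-normal BSI
#' depression/anxiety scores on the 0-4 scale shifted by their own linear
#' predictors. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A cohort table (see [as_cohort()]) with derived variables.
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) config$seed <- seed
  n <- as.integer(config$n_subjects)
  with_seed(config$seed, {
    genotype <- sample(c("ss", "sl", "ll"), n, replace = TRUE,
                       prob = c(config$s_allele_freq^2,
                                2 * config$s_allele_freq *
                                  (1 - config$s_allele_freq),
                                (1 - config$s_allele_freq)^2))
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(config$female_prop, 1 - config$female_prop))
    site <- sample(names(config$site_props), n, replace = TRUE,
                   prob = config$site_props)
    age <- config$age_range[1] + diff(config$age_range) *
      stats::rbeta(n, config$age_shape[1], config$age_shape[2])

    rle_p <- count_probs(RLE_WITHIN, config$rle_category_props)
    rle_count <- sample(rle_p$values, n, TRUE, prob = rle_p$probs)
    cha_p <- count_probs(CHA_WITHIN, config$cha_category_props)
    cha_score <- sample(cha_p$values, n, TRUE, prob = cha_p$probs)

    g <- additive_code(genotype)
    e <- as.integer(categorize_rle(rle_count)) - 1L  # ordinal 0/1/2

    # correlated latent residuals for the two BSI scores
    z_dep <- stats::rnorm(n)
    z_anx <- config$phenotype_corr * z_dep +
      sqrt(1 - config$phenotype_corr^2) * stats::rnorm(n)

    anx_latent <- config$bsi_anx_base + config$beta_G_anx * g +
      config$beta_E_anx * e + config$beta_GxE_anx * g * e +
      config$noise_sd_bsi * z_anx
    dep_latent <- config$bsi_dep_base + config$beta_G_bsi_dep * g +
      config$beta_E_bsi_dep * e + config$beta_GxE_bsi_dep * g * e +
      config$noise_sd_bsi * z_dep
    bsi_anx <- pmin(pmax(anx_latent, 0), 4)
    bsi_dep <- pmin(pmax(dep_latent, 0), 4)

    # theoretical centring of the anxiety latent keeps the depression
    # intercept calibration independent of the comorbidity channel
    e_mean <- sum(c(0, 1, 2) * config$rle_category_props)
    g_mean <- 2 * config$s_allele_freq
    anx_expect <- config$bsi_anx_base + config$beta_G_anx * g_mean +
      config$beta_E_anx * e_mean + config$beta_GxE_anx * g_mean * e_mean
    lp <- config$dep_baseline_logit + config$beta_G_dep * g +
      config$beta_E_dep * e + config$beta_GxE_dep * g * e +
      config$beta_anx_dep * (anx_latent - anx_expect)
    dep <- ifelse(stats::runif(n) < stats::plogis(lp), "yes", "no")

    derive_variables(data.frame(
      id = sprintf("S%06d", seq_len(n)), site = site, sex = sex, age = age,
      genotype = genotype, rle_count = rle_count, cha_score = cha_score,
      dep = dep, bsi_dep = bsi_dep, bsi_anx = bsi_anx,
      stringsAsFactors = FALSE))
  })
}

#' Generate a null cohort (no genotype effects)
#'
#' Identical to [generate_cohort()] with every genotype-effect coefficient
#' forced to zero; exposures and phenotypes keep their marginal structure.
#' Used for type-I-error calibration of the association tests and as the
#' no-signal baseline for the relevance analyses.
#'
#' @inheritParams generate_cohort
#' @return A cohort table.
#' @export
generate_null_cohort <- function(config, seed = NULL) {
  for (nm in c("beta_G_dep", "beta_GxE_dep", "beta_G_anx", "beta_GxE_anx",
               "beta_G_bsi_dep", "beta_GxE_bsi_dep"))
    config[[nm]] <- 0
  generate_cohort(config, seed = seed)
}
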