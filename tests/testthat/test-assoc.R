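# Frequentist track: fits against independent oracles, permutation
# schemes against brute force, and the mediation contrast.

test_that("saturated logistic fit equals the cross-product odds ratio", {
  # 2x2 table: exposed 20 yes / 10 no, unexposed 10 yes / 20 no
  ch <- data.frame(
    id = 1:60, site = "a", sex = "female", age = 30,
    genotype = rep(c("sl", "ll"), each = 30),
    rle_count = 0, cha_score = 0,
    dep = c(rep("yes", 20), rep("no", 10), rep("yes", 10), rep("no", 20)),
    bsi_dep = 0, bsi_anx = 0)
  r <- fit_model(as_cohort(ch),
                 model_spec("DEP", covariates = character(0)))
  expect_equal(r$or_value, 4.0, tolerance = 1e-6)
  expect_equal(r$estimate, log(4), tolerance = 1e-6)
  expect_equal(r$n_used, 60)
})

test_that("noiseless linear relation is fitted exactly", {
  ch <- make_toy_cohort(90, seed = 11)
  ch$bsi_dep <- 2 * ch$g_additive
  r <- suppressWarnings(  # lm warns on an essentially perfect fit
    fit_model(ch, model_spec("BSI_DEP", covariates = character(0))))
  expect_equal(r$estimate, 2.0, tolerance = 1e-8)
  expect_lt(r$se, 1e-6)
})

test_that("fits agree with hand-rolled IRLS / normal-equation oracles", {
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 80
    ch <- as.data.frame(make_toy_cohort(n, seed = 2000 + s))
    ch$dep <- ifelse(runif(n) < plogis(-0.3 + 0.4 * ch$g_additive), "yes",
                     "no")
    ch$bsi_dep <- pmin(pmax(1 + 0.3 * ch$g_additive + rnorm(n, 0, 0.5),
                            0), 4)
    ch <- derive_variables(ch)
    X <- cbind(1, g = ch$g_additive, sex = as.integer(ch$sex == "female"),
               age = ch$age)

    rl <- fit_model(ch, model_spec("DEP"))
    ol <- oracle_irls_logistic(X, as.integer(ch$dep == "yes"))
    expect_equal(rl$estimate, ol$coef[2], tolerance = 1e-6)
    expect_equal(rl$se, ol$se[2], tolerance = 1e-6)

    rg <- fit_model(ch, model_spec("BSI_DEP"))
    og <- oracle_lm(X, ch$bsi_dep)
    expect_equal(rg$estimate, og$coef[2], tolerance = 1e-8)
    expect_equal(rg$se, og$se[2], tolerance = 1e-8)
  }
})

test_that("degenerate model inputs are rejected or flagged", {
  ch <- make_toy_cohort(50, seed = 12)
  ch$dep <- "yes"
  expect_error(fit_model(ch, model_spec("DEP")), "constant")
  ch2 <- make_toy_cohort(50, seed = 13)
  ch2$genotype <- "ll"
  ch2 <- derive_variables(ch2)
  expect_error(fit_model(ch2, model_spec("DEP")), "focal")
  # complete separation is flagged, not silently reported
  ch3 <- make_toy_cohort(80, seed = 14)
  ch3$dep <- ifelse(ch3$g_additive >= 1, "yes", "no")
  r <- fit_model(ch3, model_spec("DEP", covariates = character(0)))
  expect_false(r$converged)
  expect_match(r$note, "separation")
})

test_that("outcome-permutation p matches exhaustive enumeration", {
  set.seed(42)
  n <- 7
  ch <- as.data.frame(make_toy_cohort(n, seed = 15))
  ch$bsi_dep <- round(runif(n, 0, 4), 2)
  ch <- derive_variables(ch)
  spec <- model_spec("BSI_DEP", covariates = character(0))
  # exhaustive permutation p over all 7! orderings: for simple linear
  # regression |t| is monotone in |cor|, so compare correlations
  x <- ch$g_additive
  y <- ch$bsi_dep
  r_obs <- abs(cor(x, y))
  rs <- vapply(all_perms(n), function(p) abs(cor(x, y[p])), 0)
  p_exh <- mean(rs >= r_obs - 1e-12)
  r <- permutation_p_main(ch, spec, n_perm = 2000, seed = 77,
                          min_cases = 5)
  tol <- 3 * sqrt(p_exh * (1 - p_exh) / 2000) + 1 / 2001
  expect_lt(abs(r$p_perm - p_exh), tol)
})

test_that("overwhelming effects reach the permutation floor", {
  ch <- make_toy_cohort(80, seed = 16)
  set.seed(1)
  ch$bsi_dep <- pmin(pmax(2 * ch$g_additive + rnorm(80, 0, 0.1), 0), 4)
  ch <- derive_variables(ch)
  r <- permutation_p_main(ch, model_spec("BSI_DEP"), n_perm = 499,
                          seed = 5)
  expect_equal(r$p_perm, 1 / 500)
  expect_error(permutation_p_main(ch, model_spec("BSI_DEP"), n_perm = 0),
               "n_perm")
})

test_that("residual permutation of the interaction is calibrated", {
  # reduced-scale type-I check; the full calibration runs in acceptance
  hits <- 0L
  n_reps <- 150
  for (r in seq_len(n_reps)) {
    ch <- generate_null_cohort(sim_config(n_subjects = 300,
                                          seed = 5000 + r))
    p <- tryCatch(
      permutation_p_interaction(ch,
                                model_spec("DEP", "RLE",
                                           interaction = TRUE),
                                n_perm = 79, seed = r)$p_perm,
      error = function(e) NA_real_)
    if (!is.na(p) && p <= 0.05) hits <- hits + 1L
  }
  rate <- hits / n_reps
  expect_lt(abs(rate - 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / n_reps))
  expect_error(
    permutation_p_interaction(make_toy_cohort(50), model_spec("DEP")),
    "interaction")
})

test_that("anxiety covariate attenuates a mediated genotype effect", {
  # genotype reaches depression only through the anxiety latent
  cfg <- sim_config(n_subjects = 6000, beta_G_dep = 0, beta_GxE_dep = 0,
                    beta_G_anx = 0.5, beta_anx_dep = 0.8, seed = 61)
  ch <- generate_cohort(cfg)
  m <- mediation_contrast(ch, model_spec("DEP"),
                          model_spec("DEP", anx_covariate = TRUE))
  expect_lt(m$attenuation_ratio, 0.7)

  # anxiety unrelated to genotype and outcome: no attenuation
  cfg0 <- sim_config(n_subjects = 6000, beta_G_dep = 0.4,
                     beta_G_anx = 0, beta_GxE_anx = 0, beta_anx_dep = 0,
                     phenotype_corr = 0, seed = 62)
  ch0 <- generate_cohort(cfg0)
  m0 <- mediation_contrast(ch0, model_spec("DEP"),
                           model_spec("DEP", anx_covariate = TRUE))
  expect_equal(m0$attenuation_ratio, 1, tolerance = 0.15)

  # all anxiety scores missing: the adjusted model cannot be fitted
  chm <- ch0
  chm$bsi_anx <- NA_real_
  expect_error(mediation_contrast(derive_variables(as.data.frame(chm)),
                                  model_spec("DEP"),
                                  model_spec("DEP",
                                             anx_covariate = TRUE)))
  # specs must differ only in the anxiety covariate
  expect_error(mediation_contrast(ch0, model_spec("DEP"),
                                  model_spec("BSI_DEP",
                                             anx_covariate = TRUE)),
               "differ")
})

test_that("p_perm is invariant to subject ordering", {
  ch <- make_toy_cohort(120, seed = 17)
  spec <- model_spec("BSI_DEP")
  r1 <- permutation_p_main(ch, spec, n_perm = 200, seed = 9)
  perm <- sample(nrow(ch))
  ch2 <- ch[perm, ]
  ch2$id <- ch$id  # keep ids unique/valid after reordering
  r2 <- permutation_p_main(as_cohort(ch2), spec, n_perm = 200, seed = 9)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-10)
  # permutation p-values agree within Monte-Carlo error
  expect_lt(abs(r1$p_perm - r2$p_perm),
            3 * sqrt(0.25 / 200) + 1 / 201)
})
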