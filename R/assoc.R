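# Frequentist association track: additive-model regressions with
# covariates, focal-term Wald tests, and permutation p-values.

#' Regression model specification
#'
#' Describes one cell of the association model matrix: the outcome
#' (lifetime depression fitted by logistic regression; the two BSI scores
#' by linear regression), an additive genotype term, an optional
#' environment term (recent life events or childhood adversity, coded
#' ordinally 0/1/2 over the low/medium/high categories by default), an
#' optional single-df genotype-by-environment interaction, covariates
#' (sex and age always, BSI anxiety on request), and an optional subgroup
#' filter.
#'
#' @param outcome One of `"DEP"`, `"BSI_DEP"`, `"BSI_ANX"`.
#' @param environment One of `"none"`, `"RLE"`, `"CHA"`.
#' @param interaction Logical; include the genotype-by-environment
#'   interaction (requires an environment term). The interaction is then
#'   the focal term.
#' @param anx_covariate Logical; add the BSI anxiety score as a covariate
#'   (the mediation model). Not allowed when the outcome is `BSI_ANX`.
#' @param covariates Baseline covariates; sex and age by default, as in all
#'   models of the motivating analysis.
#' @param env_coding `"ordinal"` (single 0/1/2 term; default) or `"dummy"`
#'   (two indicator columns, interaction with the medium/high indicators).
#' @param subgroup Named list of derived-category filters, e.g.
#'   `list(age_group = "young")` or `list(cha_cat = c("medium", "high"))`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome = c("DEP", "BSI_DEP", "BSI_ANX"),
                       environment = c("none", "RLE", "CHA"),
                       interaction = FALSE,
                       anx_covariate = FALSE,
                       covariates = c("sex", "age"),
                       env_coding = c("ordinal", "dummy"),
                       subgroup = list()) {
  outcome <- match.arg(gsub("-", "_", toupper(outcome[1])),
                       c("DEP", "BSI_DEP", "BSI_ANX"))
  environment <- match.arg(toupper(environment[1]), c("NONE", "RLE", "CHA"))
  environment <- c(NONE = "none", RLE = "RLE", CHA = "CHA")[[environment]]
  env_coding <- match.arg(env_coding)
  if (interaction && environment == "none")
    stop_validation("an interaction model requires an environment term")
  if (anx_covariate && outcome == "BSI_ANX")
    stop_validation("the outcome cannot also be a covariate")
  structure(list(outcome = outcome, environment = environment,
                 interaction = isTRUE(interaction),
                 anx_covariate = isTRUE(anx_covariate),
                 covariates = covariates, env_coding = env_coding,
                 subgroup = subgroup),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rhs <- c("g", if (x$environment != "none") tolower(x$environment),
           if (x$interaction) paste0("g:", tolower(x$environment)),
           x$covariates, if (x$anx_covariate) "bsi_anx")
  cat(sprintf("%s ~ %s%s\n", x$outcome, paste(rhs, collapse = " + "),
              if (length(x$subgroup))
                paste0("  [", paste(names(x$subgroup),
                                    vapply(x$subgroup, paste,
                                           "", collapse = "/"),
                                    sep = "=", collapse = ", "), "]")
              else ""))
  invisible(x)
}

# Build the complete-case response/design pair for a spec. Returns y,
# design matrix X (with intercept), the focal column name, and bookkeeping.
#' @keywords internal
build_model_frame <- function(cohort, spec) {
  if (!"g_additive" %in% names(cohort)) cohort <- derive_variables(cohort)
  if (length(spec$subgroup))
    cohort <- do.call(cohort_subset, c(list(cohort), spec$subgroup))

  ycol <- switch(spec$outcome, DEP = "dep", BSI_DEP = "bsi_dep",
                 BSI_ANX = "bsi_anx")
  logistic <- spec$outcome == "DEP"
  y <- cohort[[ycol]]
  if (logistic) y <- ifelse(is.na(y), NA, as.integer(y == "yes"))

  cols <- list(g = cohort$g_additive)
  if ("sex" %in% spec$covariates)
    cols$sex <- ifelse(is.na(cohort$sex), NA,
                       as.integer(cohort$sex == "female"))
  if ("age" %in% spec$covariates) cols$age <- cohort$age
  if (spec$anx_covariate) cols$bsi_anx <- cohort$bsi_anx

  focal <- "g"
  if (spec$environment != "none") {
    ecat <- if (spec$environment == "RLE") cohort$rle_cat else cohort$cha_cat
    ecode <- as.integer(ecat) - 1L
    if (spec$env_coding == "ordinal") {
      cols$env <- ecode
      if (spec$interaction) {
        cols$gxe <- cohort$g_additive * ecode
        focal <- "gxe"
      }
    } else {
      cols$env_med <- as.integer(ecode == 1L)
      cols$env_high <- as.integer(ecode == 2L)
      if (spec$interaction) {
        cols$gxe_med <- cohort$g_additive * cols$env_med
        cols$gxe_high <- cohort$g_additive * cols$env_high
        focal <- "gxe_high"
      }
    }
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  cc <- stats::complete.cases(cbind(y, X))
  list(y = y[cc], X = X[cc, , drop = FALSE], focal = focal,
       logistic = logistic, n_used = sum(cc))
}

#' @keywords internal
regression_result <- function(term, estimate, se, stat, p, logistic, n_used,
                              p_perm = NA_real_, converged = TRUE,
                              note = NA_character_) {
  structure(data.frame(
    term = term, estimate = estimate,
    or_value = if (logistic) exp(estimate) else NA_real_,
    se = se,
    l95 = if (logistic) exp(estimate - 1.96 * se) else estimate - 1.96 * se,
    u95 = if (logistic) exp(estimate + 1.96 * se) else estimate + 1.96 * se,
    stat = stat, p = p, p_perm = p_perm, n_used = n_used,
    converged = converged, note = note, stringsAsFactors = FALSE),
    class = c("regression_result", "data.frame"))
}

#' @keywords internal
summarize_glm_term <- function(fit, term_index, term, logistic, n_used) {
  cf <- stats::coef(summary(fit))
  est <- cf[term_index, 1]
  se <- cf[term_index, 2]
  stat <- cf[term_index, 3]
  p <- cf[term_index, 4]
  converged <- if (logistic) isTRUE(fit$converged) else TRUE
  note <- NA_character_
  if (!converged || (logistic && (abs(est) > 15 || se > 100))) {
    converged <- FALSE
    note <- "nonconvergence or separation; estimates unreliable"
  }
  regression_result(term, est, se, stat, p, logistic, n_used,
                    converged = converged, note = note)
}

# Wald statistic of column `focal` from a design-matrix fit; the fast path
# used inside permutation loops.
#' @keywords internal
fit_stat <- function(X, y, focal, logistic) {
  j <- match(focal, colnames(X))
  if (logistic) {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    p <- ncol(X)
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- chol2inv(R)
    fit$coefficients[j] / sqrt(cov[j, j])
  } else {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (length(y) - fit$rank)
    R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- chol2inv(R) * sigma2
    jj <- match(focal, colnames(X)[fit$qr$pivot])
    fit$coefficients[j] / sqrt(cov[jj, jj])
  }
}

#' Fit one association model and test its focal term
#'
#' Complete-case maximum-likelihood fit (logistic for lifetime depression,
#' least squares for the BSI scores) of the model described by `spec`,
#' returning the Wald test of the focal term: the genotype-by-environment
#' interaction when `spec$interaction` is set, otherwise the additive
#' genotype main effect. Confidence bounds are the normal-approximation
#' estimate +/- 1.96 SE, exponentiated to an odds-ratio scale for logistic
#' models.
#'
#' @param cohort A cohort table.
#' @param spec A [model_spec()].
#' @param min_cases Smallest admissible complete-case count (default 10);
#'   lower it only for toy worked examples.
#' @return A `regression_result` data-frame row with columns `term`,
#'   `estimate`, `or_value`, `se`, `l95`, `u95`, `stat`, `p`, `p_perm`
#'   (filled by the permutation helpers), `n_used`, `converged`, `note`.
#' @export
fit_model <- function(cohort, spec, min_cases = 10) {
  fr <- build_model_frame(cohort, spec)
  if (fr$n_used < min_cases)
    stop_validation("fewer than ", min_cases,
                    " complete cases for this model")
  if (length(unique(fr$y)) < 2)
    stop_validation("outcome is constant in the analysis subset")
  if (length(unique(fr$X[, fr$focal])) < 2)
    stop_validation("focal term is constant in the analysis subset")
  df <- data.frame(.y = fr$y, fr$X[, -1, drop = FALSE], check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(
    sprintf("`%s`", setdiff(colnames(fr$X), "(Intercept)")),
    collapse = " + ")))
  fit <- if (fr$logistic)
    suppressWarnings(stats::glm(
      fml, data = df, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  else stats::lm(fml, data = df)
  idx <- match(sprintf("`%s`", fr$focal), names(stats::coef(fit)))
  if (is.na(idx)) idx <- match(fr$focal, names(stats::coef(fit)))
  summarize_glm_term(fit, idx, fr$focal, fr$logistic, fr$n_used)
}

#' Permutation p-value for a main-effect term
#'
#' Permutes the outcome across subjects (all covariates stay attached to
#' their subjects), refits, and compares absolute focal-term Wald
#' statistics, with the add-one correction
#' `(1 + #{|stat_perm| >= |stat_obs|}) / (n_perm + 1)` so the p-value is
#' never zero.
#'
#' @param cohort A cohort table.
#' @param spec A [model_spec()]; the focal term is tested.
#' @param n_perm Number of permutations (the motivating analysis used
#'   1000).
#' @param seed Integer seed for the permutation stream.
#' @param min_cases Passed to [fit_model()].
#' @return The [fit_model()] result with `p_perm` filled in.
#' @export
permutation_p_main <- function(cohort, spec, n_perm = 1000, seed = 1L,
                               min_cases = 10) {
  if (n_perm < 1) stop_validation("n_perm must be >= 1")
  res <- fit_model(cohort, spec, min_cases = min_cases)
  fr <- build_model_frame(cohort, spec)
  obs <- abs(res$stat)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(fit_stat(fr$X, sample(fr$y), fr$focal, fr$logistic)) >= obs
    }, logical(1)))
  })
  res$p_perm <- (1 + exceed) / (n_perm + 1)
  res
}

#' Residual-permutation p-value for an interaction covariate
#'
#' Permutation test for a single covariate of a generalized linear model
#' that keeps the other covariates intact: the interaction column is
#' regressed (least squares) on all other design columns, its residuals
#' are permuted, the permuted residual vector replaces the tested column,
#' the model is refitted and absolute Wald statistics are compared as in
#' [permutation_p_main()]. This preserves the null relationship between
#' the outcome and the non-focal covariates, which naive outcome
#' permutation would destroy for an interaction term.
#'
#' @inheritParams permutation_p_main
#' @return The [fit_model()] result with `p_perm` filled in.
#' @export
permutation_p_interaction <- function(cohort, spec, n_perm = 1000,
                                      seed = 1L) {
  if (!isTRUE(spec$interaction))
    stop_validation("spec must be an interaction model")
  if (n_perm < 1) stop_validation("n_perm must be >= 1")
  res <- fit_model(cohort, spec)
  fr <- build_model_frame(cohort, spec)
  jf <- match(fr$focal, colnames(fr$X))
  Xother <- fr$X[, -jf, drop = FALSE]
  r <- stats::lm.fit(Xother, fr$X[, jf])$residuals
  # observed statistic on the residualized covariate (equivalent test)
  obs <- abs(fit_stat(cbind(Xother, .r = r), fr$y, ".r", fr$logistic))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      Xp <- cbind(Xother, .r = sample(r))
      abs(fit_stat(Xp, fr$y, ".r", fr$logistic)) >= obs
    }, logical(1)))
  })
  res$p_perm <- (1 + exceed) / (n_perm + 1)
  res
}

#' Attenuation of a focal effect by the anxiety covariate
#'
#' Fits the same model with and without the BSI anxiety covariate and
#' reports both focal-term results plus the attenuation ratio
#' (estimate with anxiety / estimate without). A ratio well below 1 is the
#' signature of partial mediation of the focal effect through anxiety.
#'
#' @param cohort A cohort table.
#' @param spec_without_anx,spec_with_anx Two [model_spec()]s identical
#'   except for `anx_covariate`.
#' @return List with `without`, `with` (regression results) and
#'   `attenuation_ratio`.
#' @export
mediation_contrast <- function(cohort, spec_without_anx, spec_with_anx) {
  a <- spec_without_anx; b <- spec_with_anx
  a$anx_covariate <- b$anx_covariate <- NULL
  if (!identical(unclass(a), unclass(b)))
    stop_validation("specs must differ only in the anxiety covariate")
  if (isTRUE(spec_without_anx$anx_covariate) ||
      !isTRUE(spec_with_anx$anx_covariate))
    stop_validation("spec_with_anx must add the anxiety covariate")
  without <- fit_model(cohort, spec_without_anx)
  with_ <- fit_model(cohort, spec_with_anx)
  list(without = without, with = with_,
       attenuation_ratio = with_$estimate / without$estimate)
}
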