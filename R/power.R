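# Simulation-based power estimation for the association models.

#' Monte-Carlo power of a focal-term test
#'
#' Repeatedly generates cohorts from `config`, fits `spec`, and reports
#' the fraction of replicates whose focal-term asymptotic p-value falls
#' below `alpha`, with an exact binomial confidence interval. Under a null
#' configuration this estimates the test's size.
#'
#' @param config A [sim_config()]; its effect sizes define the alternative.
#' @param spec A [model_spec()].
#' @param alpha Significance threshold, in (0,1).
#' @param n_reps Number of replicates.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return List with `power`, `ci` (95 percent Clopper-Pearson), `n_reps`,
#'   `n_subjects`, `alpha`.
#' @export
estimate_power <- function(config, spec, alpha = 0.05, n_reps = 200,
                           seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must lie in (0,1)")
  if (n_reps < 1) stop_validation("n_reps must be >= 1")
  hits <- 0L
  for (r in seq_len(n_reps)) {
    ch <- generate_cohort(config, seed = derive_seed(seed, paste0("rep", r)))
    p <- tryCatch(fit_model(ch, spec)$p, error = function(e) NA_real_)
    if (!is.na(p) && p < alpha) hits <- hits + 1L
  }
  ci <- as.numeric(stats::binom.test(hits, n_reps)$conf.int)
  list(power = hits / n_reps, ci = ci, n_reps = n_reps,
       n_subjects = as.integer(config$n_subjects), alpha = alpha)
}

#' Smallest sample size reaching a target power
#'
#' Bisection over `n_subjects` on the Monte-Carlo power curve. Because the
#' power estimate is noisy the answer is approximate; increase `n_reps`
#' for a sharper bracket.
#'
#' @inheritParams estimate_power
#' @param target_power Desired power, e.g. 0.9.
#' @param n_range Integer bracket (low, high) to search within.
#' @return List with `n_required`, the final bracket, and the power
#'   estimate at `n_required`.
#' @export
required_sample_size <- function(config, spec, target_power = 0.9,
                                 alpha = 0.05, n_reps = 100,
                                 n_range = c(200, 20000), seed = 1L) {
  lo <- as.integer(n_range[1]); hi <- as.integer(n_range[2])
  pw <- function(n, tag) {
    cfg <- config; cfg$n_subjects <- n
    estimate_power(cfg, spec, alpha, n_reps,
                   seed = derive_seed(seed, tag))$power
  }
  if (pw(hi, "hi") < target_power)
    return(list(n_required = NA_integer_, bracket = c(lo, hi),
                power_at_n = NA_real_,
                note = "target power not reached at upper bracket"))
  power_at <- NA_real_
  while (hi - lo > max(50, 0.05 * lo)) {
    mid <- as.integer((lo + hi) / 2)
    p <- pw(mid, paste0("mid", mid))
    if (p >= target_power) { hi <- mid; power_at <- p } else lo <- mid
  }
  list(n_required = hi, bracket = c(lo, hi), power_at_n = power_at)
}
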