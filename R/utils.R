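# Internal helpers shared across modules.

#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Round half away from zero (Table-style integer percentages), unlike
# base round()'s banker's rounding.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a child seed from a root seed and a stage label, staying inside
# 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate `expr` with a private RNG stream seeded by `seed`; the caller's
# global RNG state is untouched.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_config <- function(...) {
  stop(structure(class = c("gxe_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
stop_validation <- function(...) {
  stop(structure(class = c("gxe_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
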