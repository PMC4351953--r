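# Independent oracles used to validate the package's fits and scores.
# These re-derive each quantity from first principles and share no code
# with the implementation paths they check.

# Logistic regression by hand-rolled iteratively reweighted least squares.
oracle_irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    WX <- X * w
    beta_new <- solve(t(X) %*% WX, t(WX) %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  covb <- solve(t(X) %*% (X * (mu * (1 - mu))))
  list(coef = as.vector(beta), se = unname(sqrt(diag(covb))))
}

# Least squares via the normal equations.
oracle_lm <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - ncol(X))
  list(coef = as.vector(beta), se = unname(sqrt(diag(XtXi) * sigma2)))
}

# Dirichlet-multinomial local score by explicit loops over a q x r count
# matrix (rows: parent configurations, incl. all-zero rows).
oracle_bd_score <- function(N, ess) {
  q <- nrow(N); r <- ncol(N)
  a_jk <- ess / (q * r); a_j <- ess / q
  s <- 0
  for (j in seq_len(q)) {
    s <- s + lgamma(a_j) - lgamma(a_j + sum(N[j, ]))
    for (k in seq_len(r)) s <- s + lgamma(a_jk + N[j, k]) - lgamma(a_jk)
  }
  s
}

# Count matrix for target given parents, enumerating ALL parent-level
# combinations (not only observed ones), built independently of the
# implementation's interaction()-based path.
oracle_count_matrix <- function(data, target, parents) {
  r <- nlevels(data[[target]])
  if (length(parents) == 0) {
    return(matrix(tabulate(as.integer(data[[target]]), r), nrow = 1))
  }
  lev <- lapply(parents, function(v) levels(data[[v]]))
  grid <- expand.grid(rev(lev), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(parents)), drop = FALSE]
  names(grid) <- parents
  N <- matrix(0, nrow(grid), r)
  for (j in seq_len(nrow(grid))) {
    sel <- rep(TRUE, nrow(data))
    for (v in parents) sel <- sel & data[[v]] == grid[j, v]
    if (any(sel)) N[j, ] <- tabulate(as.integer(data[[target]][sel]), r)
  }
  N
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# A tiny deterministic cohort exercising every variable.
make_toy_cohort <- function(n = 40, seed = 99) {
  gxebayes::generate_cohort(gxebayes::sim_config(n_subjects = n,
                                                 seed = seed))
}

# Random small discrete dataset for score-oracle comparisons.
rand_discrete_data <- function(n_rows, n_vars, cards) {
  df <- as.data.frame(lapply(seq_len(n_vars), function(i) {
    factor(sample(letters[seq_len(cards[i])], n_rows, replace = TRUE),
           levels = letters[seq_len(cards[i])])
  }))
  names(df) <- paste0("v", seq_len(n_vars))
  df
}
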