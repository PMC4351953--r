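# Bayesian relevance track: Dirichlet-multinomial scores against a
# brute-force oracle, exhaustive posteriors, relevance probabilities and
# odds-ratio posteriors.

dset <- function(...) {
  # build a discrete dataset directly from named factor columns
  df <- data.frame(..., stringsAsFactors = FALSE)
  df[] <- lapply(df, function(x) if (is.factor(x)) x else factor(x))
  structure(df, class = c("discrete_dataset", "data.frame"),
            n = nrow(df), subgroup = "test")
}

test_that("empty-parent score matches the Beta-binomial closed form", {
  d <- dset(y = factor(c("a", "a", "a", "b"), levels = c("a", "b")))
  got <- score_parent_set(d, "y", character(), ess = 1)
  want <- lgamma(1) - lgamma(1 + 4) +
    (lgamma(0.5 + 3) - lgamma(0.5)) + (lgamma(0.5 + 1) - lgamma(0.5))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(score_parent_set(d, "y", "y"), "parent")
  expect_error(score_parent_set(d, "y", character(), ess = 0), "ess")
})

test_that("a constant parent column leaves the score unchanged", {
  d <- dset(y = c("a", "b", "a", "b", "b"),
            k = factor(rep("only", 5)))
  expect_equal(score_parent_set(d, "y", "k"),
               score_parent_set(d, "y", character()), tolerance = 1e-12)
})

test_that("per-row score approaches the entropy limit under duplication", {
  set.seed(33)
  base <- rand_discrete_data(40, 2, c(2, 3))
  dup <- function(k) {
    d <- base[rep(seq_len(nrow(base)), k), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  per_row <- vapply(c(1, 2, 4, 8), function(k)
    score_parent_set(dup(k), "v1", "v2") / (40 * k), 0)
  # empirical conditional entropy of v1 given v2 (nats, negated)
  N <- table(base$v2, base$v1)
  H <- -sum(N / 40 * log(sweep(N, 1, rowSums(N), "/")), na.rm = TRUE)
  expect_true(all(diff(per_row) > 0))
  expect_true(all(abs(per_row + H) == sort(abs(per_row + H),
                                           decreasing = TRUE)))
})

test_that("score matches the brute-force Gamma-product oracle", {
  set.seed(44)
  for (rep in 1:20) {
    nv <- sample(2:4, 1)
    cards <- sample(2:4, nv, replace = TRUE)
    d <- rand_discrete_data(sample(10:50, 1), nv, cards)
    target <- "v1"
    parents <- setdiff(names(d), target)
    parents <- sample(parents, sample(0:length(parents), 1))
    ess <- sample(c(0.5, 1, 4), 1)
    got <- score_parent_set(d, target, parents, ess)
    want <- oracle_bd_score(oracle_count_matrix(d, target, parents), ess)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("posterior enumeration covers all subsets and normalizes", {
  d <- dset(y = c("a", "b"), A = c("x", "y"), B = c("x", "x"))
  post <- enumerate_model_posterior(d, "y", c("A", "B"), max_parents = 2)
  expect_equal(nrow(post$per_target$y), 4L)
  expect_equal(sum(post$per_target$y$weight), 1, tolerance = 1e-12)
  expect_error(enumerate_model_posterior(d, "y", c("A", "y")),
               "candidates")
})

test_that("with no data the posterior equals the structure prior", {
  d0 <- dset(y = factor(character(), levels = c("a", "b")),
             A = factor(character(), levels = c("x", "y")),
             B = factor(character(), levels = c("x", "y")))
  post <- enumerate_model_posterior(d0, "y", c("A", "B"), max_parents = 2)
  expect_equal(post$per_target$y$weight, rep(0.25, 4), tolerance = 1e-12)
  # uniform posterior over {0,{A},{B},{A,B}} gives Pr(A) = 1/2
  expect_equal(relevance_posterior(post, "A"), 0.5, tolerance = 1e-12)
})

test_that("relevance separates signal from noise and matches summation", {
  set.seed(55)
  n <- 500
  y <- factor(sample(c("a", "b"), n, TRUE))
  A <- factor(ifelse(runif(n) < 0.9, as.character(y),
                     sample(c("a", "b"), n, TRUE)))
  B <- factor(sample(c("x", "y"), n, TRUE))
  d <- dset(y = y, A = A, B = B)
  post <- enumerate_model_posterior(d, "y", c("A", "B"), max_parents = 2)
  prA <- relevance_posterior(post, "A")
  prB <- relevance_posterior(post, "B")
  expect_gt(prA, 0.99)
  expect_lt(prB, 0.1)
  # exact agreement with explicit summation over the listed model set
  pt <- post$per_target$y
  manual <- sum(pt$weight[vapply(pt$parent_set,
                                 function(s) "A" %in% s, TRUE)])
  expect_identical(prA, manual)
  expect_error(relevance_posterior(post, "Z"), "unknown")
  # predictor confined out of the model space has zero relevance
  post0 <- enumerate_model_posterior(d, "y", c("A", "B"), max_parents = 0)
  expect_equal(relevance_posterior(post0, "A"), 0)
})

test_that("posterior is invariant to candidate order and row shuffling", {
  set.seed(66)
  d <- rand_discrete_data(80, 3, c(2, 3, 2))
  p1 <- enumerate_model_posterior(d, "v1", c("v2", "v3"))
  p2 <- enumerate_model_posterior(d[sample(80), , drop = FALSE], "v1",
                                  c("v3", "v2"))
  expect_equal(relevance_posterior(p1, "v2"), relevance_posterior(p2, "v2"),
               tolerance = 1e-12)
  expect_equal(relevance_posterior(p1, "v3"), relevance_posterior(p2, "v3"),
               tolerance = 1e-12)
})

test_that("basis-versus-basis odds ratio degenerates to one", {
  ch <- make_toy_cohort(300, seed = 18)
  dd <- discretize_cohort(ch, c("genotype", "sex", "dep"))
  post <- enumerate_model_posterior(dd, "dep", c("genotype", "sex"))
  orp <- bayesian_or(dd, post, "dep", "yes", "no",
                     genotype_level = "ll", n_draws = 500, seed = 1)
  expect_true(all(orp$draws == 1))
  expect_equal(orp$ci, c(1, 1))
})

test_that("an empty-parent posterior yields the unit atom", {
  ch <- make_toy_cohort(300, seed = 19)
  dd <- discretize_cohort(ch, c("genotype", "sex", "dep"))
  post <- enumerate_model_posterior(dd, "dep", c("genotype", "sex"),
                                    max_parents = 0)
  orp <- bayesian_or(dd, post, "dep", "yes", "no", n_draws = 500,
                     seed = 2)
  expect_true(all(orp$draws == 1))
  expect_equal(orp$inclusion_prob, 0)
})

test_that("forced genotype model matches a direct Dirichlet oracle", {
  # 2x2: genotype ss/ll versus a binary target with strong association
  set.seed(77)
  n <- 400
  g <- factor(sample(c("ll", "ss"), n, TRUE), levels = c("ll", "ss"))
  y <- factor(ifelse(runif(n) < ifelse(g == "ss", 0.7, 0.3), "yes", "no"),
              levels = c("no", "yes"))
  d <- dset(genotype = g, dep = y)
  post <- enumerate_model_posterior(d, "dep", "genotype", max_parents = 1)
  post$per_target$dep$weight <- c(0, 1)  # force genotype as sole parent
  orp <- bayesian_or(d, post, "dep", "yes", "no", n_draws = 20000,
                     seed = 3)
  # oracle: naive Dirichlet sampling of the 2x2 row probabilities with
  # the same prior mass ess/(q*r) = 1/4 per cell
  N <- table(g, y)
  a <- 1 / 4
  set.seed(99)
  m <- 20000
  th_ss_yes <- rgamma(m, a + N["ss", "yes"])
  th_ss_no <- rgamma(m, a + N["ss", "no"])
  th_ll_yes <- rgamma(m, a + N["ll", "yes"])
  th_ll_no <- rgamma(m, a + N["ll", "no"])
  or_oracle <- (th_ss_yes / th_ss_no) / (th_ll_yes / th_ll_no)
  expect_equal(median(orp$draws), median(or_oracle), tolerance = 0.05)
  expect_equal(quantile(orp$draws, 0.9), quantile(or_oracle, 0.9),
               tolerance = 0.08, ignore_attr = TRUE)
})

test_that("mixed posteriors show the unit atom plus a shifted mode", {
  set.seed(89)
  n <- 220
  g3 <- factor(sample(c("ll", "sl", "ss"), n, TRUE),
               levels = c("ll", "sl", "ss"))
  pr <- c(ll = 0.3, sl = 0.42, ss = 0.62)[as.character(g3)]
  y <- factor(ifelse(runif(n) < pr, "yes", "no"), levels = c("no", "yes"))
  s <- factor(sample(c("male", "female"), n, TRUE))
  d <- dset(genotype = g3, sex = s, dep = y)
  post <- enumerate_model_posterior(d, "dep", c("genotype", "sex"))
  incl <- relevance_posterior(post, "genotype")
  # choose a dataset size where the posterior genuinely mixes
  expect_true(incl > 0.05 && incl < 0.95)
  orp <- bayesian_or(d, post, "dep", "yes", "no", n_draws = 20000,
                     seed = 4)
  expect_gt(orp$atom_mass, 0.02)
  expect_gt(median(orp$draws[orp$draws != 1]), 1)
  # model-inclusion probability equals the fraction of non-unit draws
  expect_equal(1 - orp$atom_mass, incl,
               tolerance = 3 * sqrt(incl * (1 - incl) / 20000) + 1e-3)
})

test_that("relevance is consistent as the sample grows", {
  prs <- sapply(c(100, 1000, 10000), function(n) {
    set.seed(n + 7)
    y <- factor(sample(c("a", "b"), n, TRUE))
    A <- factor(ifelse(runif(n) < 0.8, as.character(y),
                       sample(c("a", "b"), n, TRUE)))
    B <- factor(sample(c("x", "y"), n, TRUE))
    d <- dset(y = y, A = A, B = B)
    post <- enumerate_model_posterior(d, "y", c("A", "B"))
    c(A = relevance_posterior(post, "A"),
      B = relevance_posterior(post, "B"))
  })
  expect_true(all(diff(prs["A", ]) >= 0) || prs["A", 3] > 0.999)
  expect_gt(prs["A", 3], 0.999)
  baseline <- prior_inclusion_probability(2, 4)
  expect_lt(prs["B", 3], baseline)
})
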