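# Mk likelihood, fitting and marginal ancestral states.

test_that("transition probability rows sum to 1 and P(0) is the identity", {
  set.seed(3)
  for (i in 1:20) {
    P <- mk_transition_prob(runif(1, 0, 5), runif(1, 0, 5), rexp(1))
    expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  expect_identical(mk_transition_prob(0.3, 0.7, 0), diag(2))
  expect_identical(mk_transition_prob(0, 0, 2.5), diag(2))
})

test_that("degenerate likelihoods take their closed-form values", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  # zero-length branches force the root to carry both tip states
  expect_equal(mk_loglik(tr, c(A = 1, B = 1), 0.4, 0.9, root = "flat"),
               log(0.5), tolerance = 1e-12)
  # frozen process, root fixed at the observed state: probability 1
  tr2 <- toy_tree4()
  y0 <- c(A = 0, B = 0, C = 0, D = 0)
  expect_equal(mk_loglik(tr2, y0, 0, 0, root = "fixed", root_state = 0),
               0, tolerance = 1e-12)
})

test_that("pruning equals the exhaustive enumeration oracle", {
  tr <- ape::read.tree(text = "((A:0.6,B:1.3):0.8,(C:0.3,D:2.1):0.5);")
  y <- c(A = 1, B = 0, C = 0, D = 1)
  ll <- mk_loglik(tr, y, 0.7, 0.25)
  expect_equal(ll, log(oracle_mk_lik(tr, y, 0.7, 0.25)), tolerance = 1e-10)
})

test_that("likelihood is invariant to tip ordering", {
  tr <- random_tree(12, seed = 21)
  set.seed(1)
  y <- setNames(rbinom(12, 1, 0.4), tr$tip.label)
  ll1 <- mk_loglik(tr, y, 0.2, 0.6)
  ll2 <- mk_loglik(tr, y[sample(names(y))], 0.2, 0.6)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("ER is the equal-rates restriction of ARD", {
  tr <- rescale_tree_depth(simulate_bd_tree(80, 1, 0, seed = 31), 100)
  for (s in 1:3) {
    y <- simulate_mk_trait(tr, 0.01, 0.03, seed = 40 + s)$trait
    if (length(unique(y)) < 2) next
    er <- fit_mk(tr, y, "ER")
    ard <- fit_mk(tr, y, "ARD")
    expect_lte(er$loglik, ard$loglik + 1e-6)
  }
})

test_that("likelihood-ratio test follows the chi-squared reference", {
  tr <- rescale_tree_depth(simulate_bd_tree(60, 1, 0, seed = 9), 100)
  y <- simulate_mk_trait(tr, 0.02, 0.02, seed = 2)$trait
  er <- fit_mk(tr, y, "ER")
  expect_equal(lrt_er_vs_ard(er, structure(
    list(model = "ARD", loglik = er$loglik, n_tips = er$n_tips),
    class = "mk_fit"))$p, 1)
  fake_er <- structure(list(model = "ER", loglik = -100, n_tips = 60),
                       class = "mk_fit")
  fake_ard <- structure(list(model = "ARD", loglik = -95, n_tips = 60),
                        class = "mk_fit")
  res <- lrt_er_vs_ard(fake_er, fake_ard)
  expect_equal(res$statistic, 10)
  expect_equal(res$p, 1.565402e-3, tolerance = 1e-6)
  bad_ard <- structure(list(model = "ARD", loglik = -101, n_tips = 60),
                       class = "mk_fit")
  expect_error(lrt_er_vs_ard(fake_er, bad_ard), "optimizer")
})

test_that("monomorphic traits are flagged, not silently fitted", {
  tr <- toy_tree4()
  y <- c(A = 0, B = 0, C = 0, D = 0)
  expect_warning(f <- fit_mk(tr, y, "ER"), "monomorphic")
  expect_true(f$boundary)
})

test_that("marginal ancestral states match brute-force Bayes", {
  tr <- ape::read.tree(text = "((A:0.9,B:0.4):0.7,C:1.5);")
  y <- c(A = 1, B = 1, C = 0)
  fit <- structure(list(q01 = 0.3, q10 = 0.5, root = "flat",
                        root_state = 0L), class = "mk_fit")
  m <- marginal_asr(tr, y, fit)
  expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-10)
  oracle <- oracle_marginals(tr, y, 0.3, 0.5)
  got <- m[(ape::Ntip(tr) + 1):nrow(m), "p1"]
  expect_equal(unname(got), oracle, tolerance = 1e-10)
})

test_that("marginal states respect hard limits", {
  tr <- toy_tree4()
  y0 <- c(A = 0, B = 0, C = 0, D = 0)
  fit0 <- structure(list(q01 = 0, q10 = 0, root = "flat", root_state = 0L),
                    class = "mk_fit")
  m <- marginal_asr(tr, y0, fit0)
  expect_equal(unname(m[, "p1"]), rep(0, nrow(m)))

  # a cherry of two state-1 tips on short branches under slow rates
  tr2 <- ape::read.tree(text = "((A:0.05,B:0.05):1,(C:1,D:1):0.1);")
  y2 <- c(A = 1, B = 1, C = 0, D = 0)
  fit2 <- structure(list(q01 = 0.05, q10 = 0.05, root = "flat",
                         root_state = 0L), class = "mk_fit")
  m2 <- marginal_asr(tr2, y2, fit2)
  cherry_parent <- ape::getMRCA(tr2, c("A", "B"))
  expect_gt(m2[cherry_parent, "p1"], 0.95)
})

test_that("ARD fitting detects the empirical gain/loss asymmetry", {
  # rare-gain / frequent-loss regime: ARD should beat ER in most datasets
  hits <- 0L
  n_rep <- 12L
  for (s in seq_len(n_rep)) {
    tr <- rescale_tree_depth(simulate_bd_tree(400, 1, 0, seed = 100 + s), 100)
    y <- simulate_mk_trait(tr, 0.005, 0.071, seed = 200 + s)$trait
    if (length(unique(y)) < 2) next
    p <- lrt_er_vs_ard(fit_mk(tr, y, "ER"), fit_mk(tr, y, "ARD"))$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_rep, 0.75)
})
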