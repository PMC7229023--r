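# Synthetic-data generators: determinism, distributional ground truth.

test_that("birth-death trees meet their structural contract", {
  t3 <- simulate_bd_tree(3, 1, 0, seed = 1)
  expect_equal(ape::Ntip(t3), 3)
  expect_equal(t3$Nnode, 2)
  expect_true(ape::is.ultrametric(t3, tol = 1e-8))

  t50 <- simulate_bd_tree(50, 1, 0.3, seed = 2)
  expect_equal(ape::Ntip(t50), 50)
  expect_true(ape::is.ultrametric(t50, tol = 1e-8))
  expect_true(all(t50$edge.length >= 0))

  expect_identical(ape::write.tree(simulate_bd_tree(20, 1, 0.1, seed = 7)),
                   ape::write.tree(simulate_bd_tree(20, 1, 0.1, seed = 7)))
  expect_error(simulate_bd_tree(10, 1, 1, seed = 1), "birth > death")
})

test_that("pure-birth depth matches the Yule expectation", {
  n <- 20; b <- 1
  expected <- sum(1 / (b * (2:n)))
  depths <- vapply(1:200, function(s) {
    max(ape::node.depth.edgelength(simulate_bd_tree(n, b, 0, seed = 1000 + s)))
  }, numeric(1))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 4 * se)
})

test_that("Mk trait simulation is exact at its limits", {
  tr <- toy_tree4()
  s0 <- simulate_mk_trait(tr, 0, 0, root = 1, seed = 3)
  expect_true(all(s0$trait == 1))
  expect_equal(s0$history$n01 + s0$history$n10, 0L)

  # long independent branches reach the symmetric stationary mass
  star <- ape::stree(1000, "star")
  star$edge.length <- rep(50, 1000)
  s1 <- simulate_mk_trait(star, 0.5, 0.5, root = 0, seed = 4)
  p <- mean(s1$trait)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("simulated histories recount their own transitions", {
  tr <- rescale_tree_depth(simulate_bd_tree(60, 1, 0, seed = 5), 100)
  sim <- simulate_mk_trait(tr, 0.01, 0.05, seed = 6)
  seg <- sim$history$edge
  n01 <- sum(vapply(unique(seg$edge), function(i) {
    s <- seg$state[seg$edge == i]; sum(diff(s) == 1)
  }, numeric(1)))
  n10 <- sum(vapply(unique(seg$edge), function(i) {
    s <- seg$state[seg$edge == i]; sum(diff(s) == -1)
  }, numeric(1)))
  expect_equal(sim$history$n01, n01)
  expect_equal(sim$history$n10, n10)
  # dwell times tile the branches
  lens <- ape::reorder.phylo(tr, "postorder")$edge.length
  agg <- tapply(seg$dwell, seg$edge, sum)
  expect_lt(max(abs(agg - lens[as.integer(names(agg))])), 1e-9)
})

test_that("the rare-gain regime yields low prevalence", {
  tr <- rescale_tree_depth(simulate_bd_tree(800, 1, 0.2, seed = 7), 100)
  prev <- mean(simulate_mk_trait(tr, 0.005, 0.071, seed = 8)$trait)
  expect_lt(prev, 0.25)
})

test_that("threshold traits hit their prevalence exactly and reproduce", {
  tr <- rescale_tree_depth(simulate_bd_tree(100, 1, 0, seed = 9), 100)
  y <- simulate_threshold_trait(tr, 0.5, seed = 10)
  expect_equal(sum(y), 50)
  expect_identical(y, simulate_threshold_trait(tr, 0.5, seed = 10))
  expect_error(simulate_threshold_trait(tr, 1.2, seed = 1), "prevalence")
})

test_that("covariate simulation honours its null limits", {
  star <- ape::stree(2000, "star")
  star$edge.length <- rep(1, 2000)
  star$tip.label <- paste0("t", 1:2000)
  ds <- simulate_covariates_and_response(star, c(x = 0), signal = 0,
                                         intercept = -2, resid_sd = 0,
                                         seed = 11)
  p_hat <- mean(ds$y)
  p0 <- plogis(-2)
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / 2000))
  expect_identical(attr(ds, "beta_true"), c(x = 0))
})

test_that("raster fields achieve the requested cross-correlation", {
  nm <- c("uv_b", "tmin", "tmax", "precip")
  cc <- diag(4); dimnames(cc) <- list(nm, nm)
  rs0 <- synth_rasters(extent = 100, cell = 1, corr_length = 5,
                       cross_corr = cc, seed = 12)
  c_off <- cor(as.vector(rs0$uv_b$values), as.vector(rs0$tmax$values))
  expect_lt(abs(c_off), 0.1)

  cc2 <- cc; cc2["uv_b", "tmax"] <- cc2["tmax", "uv_b"] <- 0.8
  rs1 <- synth_rasters(extent = 100, cell = 1, corr_length = 5,
                       cross_corr = cc2, seed = 13)
  expect_lt(abs(cor(as.vector(rs1$uv_b$values),
                    as.vector(rs1$tmax$values)) - 0.8), 0.1)
  bad <- cc; bad["uv_b", "tmin"] <- bad["tmin", "uv_b"] <- 1.5
  expect_error(synth_rasters(cross_corr = bad, seed = 1), "semi-definite")
})

test_that("short correlation lengths remove spatial autocorrelation", {
  nm <- c("uv_b", "tmin", "tmax", "precip")
  cc <- diag(4); dimnames(cc) <- list(nm, nm)
  rs <- synth_rasters(extent = 60, cell = 1, corr_length = 1e-6,
                      cross_corr = cc, seed = 14)
  m <- rs$uv_b$values
  lag1 <- cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  expect_lt(abs(lag1), 0.15)
})

test_that("occurrence sampling follows the suitability surface", {
  pm <- matrix(0, 10, 10); pm[4, 7] <- 1
  suit <- raster_grid(pm, 0, 0, 1, "s")
  occ <- synth_occurrences(suit, 50, seed = 15)
  idx <- melanomap:::.cell_index(suit, occ$lon, occ$lat)
  expect_true(all(idx == idx[1]))

  unif <- raster_grid(matrix(1, 10, 10), 0, 0, 1, "s")
  occ2 <- synth_occurrences(unif, 10000, seed = 16)
  counts <- tabulate(melanomap:::.cell_index(unif, occ2$lon, occ2$lat), 100)
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
  expect_error(synth_occurrences(raster_grid(matrix(0, 5, 5), 0, 0, 1),
                                 10, seed = 1), "all zero")
})

test_that("the assembled world is reproducible and carries ground truth", {
  w1 <- synth_world(n_tips = 120, seed = 17)
  w2 <- synth_world(n_tips = 120, seed = 17)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  expect_identical(w1$trait, w2$trait)
  expect_identical(w1$occurrences$lon, w2$occurrences$lon)
  expect_equal(w1$q_true, c(q01 = 0.005, q10 = 0.071))
  expect_true(all(c("tree", "trait", "history", "dataset", "rasters",
                    "suitability_true", "occurrences") %in% names(w1)))
})
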