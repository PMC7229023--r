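# Maximum-entropy niche model: rasters, thinning, Gibbs fitting,
# prediction, contributions, response curves and difference maps.

flat_raster <- function(v, n = 20, name = "x") {
  raster_grid(matrix(v, n, n), 0, 0, 1, name = name)
}

test_that("ESRI ASCII grids round-trip including nodata", {
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  g <- raster_grid(m, -10, 40, 0.5, name = "uv_b", units = "kJ m-2 day-1")
  tmp <- tempfile(fileext = ".asc")
  write_ascii_grid(g, tmp)
  g2 <- read_ascii_grid(tmp, name = "uv_b")
  expect_equal(g2$values, g$values, tolerance = 1e-7)
  expect_equal(g2$cellsize, 0.5)
  expect_equal(g2$xmin, -10)
})

test_that("thinning respects the cap, keeps small samples, is idempotent", {
  set.seed(4)
  occ <- occurrence_set(
    species = c(rep("few", 3), rep("many", 500)),
    lon = c(runif(3, 0, 10), runif(500, 0, 1.5)),
    lat = c(runif(3, 0, 10), runif(500, 0, 1.5)))
  th <- thin_occurrences(occ, grid_deg = 2, cap_per_species = 50, seed = 1)
  cnt <- table(th$species)
  expect_equal(unname(cnt[["few"]]), 3)       # below cap: all kept
  expect_equal(unname(cnt[["many"]]), 50)     # single cell: cap binds
  # property: per-species count never exceeds min(cap, raw)
  raw <- table(occ$species)
  expect_true(all(cnt <= pmin(raw[names(cnt)], 50)))
  # idempotence under the stratified-first rule
  th2 <- thin_occurrences(th, grid_deg = 2, cap_per_species = 50, seed = 99)
  expect_equal(th$lon, th2$lon)
  expect_equal(th$lat, th2$lat)
  expect_error(thin_occurrences(occ[0, ], 2, 50, seed = 1), "empty")
})

test_that("stratification spreads retained records across cells", {
  set.seed(9)
  # 90 points in one cell, 10 spread over 10 other cells; cap 20 must keep
  # all 10 sparse cells and fill the rest from the dense cell
  occ <- occurrence_set(
    species = "sp",
    lon = c(runif(90, 0, 1.8), seq(2.5, 20.5, by = 2)),
    lat = c(runif(90, 0, 1.8), rep(0.5, 10)))
  th <- thin_occurrences(occ, grid_deg = 2, cap_per_species = 20, seed = 2)
  expect_equal(nrow(th), 20)
  expect_equal(sum(th$lon > 2), 10)
})

test_that("constant rasters give the uniform model with zero gain", {
  occ <- occurrence_set("sp", runif(40, 0, 20), runif(40, 0, 20))
  rs <- list(flat_raster(3, name = "a"), flat_raster(7, name = "b"))
  m <- fit_maxent(occ, rs, reg = 1)
  expect_true(all(m$lambda == 0))
  expect_equal(m$gain, 0)
  expect_equal(sum(m$prob), 1, tolerance = 1e-9)
  s <- predict_suitability(m, rs)
  expect_equal(max(s$values) - min(s$values), 0)
})

test_that("reg = 0 on a binary feature solves the moment condition", {
  set.seed(11)
  bin <- raster_grid(matrix(rbinom(400, 1, 0.4), 20, 20), 0, 0, 1, "bin")
  suit <- raster_grid(ifelse(bin$values == 1, 0.8, 0.2), 0, 0, 1, "s")
  occ <- synth_occurrences(suit, 600, seed = 12)
  m <- fit_maxent(occ, list(bin), reg = 0, features = "linear")
  f <- as.vector(bin$values)
  mu <- mean(f[melanomap:::.cell_index(bin, occ$lon, occ$lat)])
  lam_star <- uniroot(function(l) sum(f * exp(l * f)) / sum(exp(l * f)) - mu,
                      c(-50, 50), tol = 1e-12)$root
  expect_equal(unname(m$lambda[1]), lam_star, tolerance = 1e-4)
})

test_that("cell probabilities sum to one and the L1 path shrinks weights", {
  set.seed(13)
  rs <- synth_rasters(extent = 20, cell = 1, corr_length = 3,
                      cross_corr = {
                        cc <- diag(2)
                        dimnames(cc) <- list(c("uv_b", "tmax"),
                                             c("uv_b", "tmax"))
                        cc
                      }, seed = 14)
  uv <- rs$uv_b$values
  uvs <- (uv - min(uv)) / (max(uv) - min(uv))
  occ <- synth_occurrences(raster_grid(exp(uvs), 0, 0, 1, "s"), 500,
                           seed = 15)
  prev <- Inf
  for (reg in c(0.01, 0.5, 2, 8)) {
    m <- fit_maxent(occ, rs, reg = reg, features = "linear")
    expect_equal(sum(m$prob), 1, tolerance = 1e-9)
    tot <- sum(abs(m$lambda))
    expect_lte(tot, prev + 1e-8)
    prev <- tot
  }
})

test_that("variable contributions isolate the informative layer", {
  set.seed(16)
  inf <- raster_grid(matrix(runif(400), 20, 20), 0, 0, 1, "signal")
  con1 <- flat_raster(5, name = "const1")
  suit <- raster_grid(exp(2 * inf$values), 0, 0, 1, "s")
  occ <- synth_occurrences(suit, 800, seed = 17)
  m <- fit_maxent(occ, list(inf, con1), reg = 0.1)
  vc <- variable_contribution(m)
  expect_equal(sum(vc$contribution), 100, tolerance = 0.1)
  expect_equal(sum(vc$permutation_importance), 100, tolerance = 0.1)
  expect_equal(vc$contribution[vc$variable == "signal"], 100,
               tolerance = 0.1)
})

test_that("duplicated variables share the single variable's contribution", {
  set.seed(18)
  base <- matrix(runif(400), 20, 20)
  r1 <- raster_grid(base, 0, 0, 1, "v")
  occ <- synth_occurrences(raster_grid(exp(2 * base), 0, 0, 1, "s"), 1500,
                           seed = 19)
  m_single <- fit_maxent(occ, list(r1), reg = 0.1)
  vc1 <- variable_contribution(m_single)
  dup <- list(raster_grid(base, 0, 0, 1, "va"),
              raster_grid(base, 0, 0, 1, "vb"))
  m_dup <- fit_maxent(occ, dup, reg = 0.1)
  vc2 <- variable_contribution(m_dup)
  expect_equal(sum(vc2$contribution), vc1$contribution[1], tolerance = 1)
})

test_that("background subsampling approximates the full-background fit", {
  set.seed(31)
  r <- raster_grid(matrix(runif(1600), 40, 40), 0, 0, 1, "uv_b")
  occ <- synth_occurrences(raster_grid(exp(2 * r$values), 0, 0, 1, "s"),
                           2000, seed = 32)
  full <- fit_maxent(occ, list(r), reg = 0.01, features = "linear")
  sub <- fit_maxent(occ, list(r), reg = 0.01, features = "linear",
                    bg_subsample = 800, bg_seed = 2)
  expect_equal(length(sub$prob), 800)
  expect_lt(abs(unname(sub$lambda[1]) - unname(full$lambda[1])), 0.25)
})

test_that("suitability is a monotone transform of the Gibbs density", {
  set.seed(21)
  r <- raster_grid(matrix(runif(400, 10, 30), 20, 20), 0, 0, 1, "tmax")
  occ <- synth_occurrences(raster_grid(exp((r$values - 10) / 10),
                                       0, 0, 1, "s"), 400, seed = 22)
  m <- fit_maxent(occ, list(r), reg = 0.1)
  s <- predict_suitability(m, list(r))
  expect_true(all(s$values >= 0 & s$values <= 1))
  eta <- melanomap:::.build_features(
    cbind(tmax = as.vector(r$values)), m$ranges, m$features) %*% m$lambda
  expect_equal(rank(as.vector(s$values)), rank(as.vector(eta)))
  expect_error(predict_suitability(m, list(flat_raster(1, name = "other"))),
               "match")
})

test_that("response curves reflect the fitted feature shape", {
  set.seed(23)
  r <- raster_grid(matrix(runif(900), 30, 30), 0, 0, 1, "uv_b")
  # interior optimum at scaled value 0.5
  suit <- raster_grid(exp(4 * r$values - 4 * r$values^2), 0, 0, 1, "s")
  occ <- synth_occurrences(suit, 3000, seed = 24)
  m <- fit_maxent(occ, list(r), reg = 0.01)
  rc <- response_curve(m, "uv_b", grid = 201)
  opt <- rc$value[which.max(rc$suitability)]
  expect_lt(abs(opt - 0.5), 0.1)
  expect_error(response_curve(m, "nope"), "unknown variable")

  # a positive linear-only model yields a monotone curve; zero weights flat
  m_lin <- fit_maxent(occ, list(r), reg = 0.05, features = "linear")
  rc_lin <- response_curve(m_lin, "uv_b", grid = 50)
  if (m_lin$lambda[1] > 0) {
    expect_true(all(diff(rc_lin$suitability) >= -1e-12))
  }
  m0 <- m
  m0$lambda[] <- 0
  rc0 <- response_curve(m0, "uv_b", grid = 20)
  expect_lt(max(rc0$suitability) - min(rc0$suitability), 1e-12)
})

test_that("difference maps and relative diversity behave definitionally", {
  pred <- raster_grid(matrix(runif(100, 0, 40), 10, 10), 0, 0, 1, "tmax")
  rel <- pred$values / max(pred$values)
  suit <- raster_grid(rel, 0, 0, 1, "suitability")
  dm <- difference_map(suit, pred)
  expect_equal(max(abs(dm$values)), 0)

  suit1 <- raster_grid(matrix(1, 10, 10), 0, 0, 1, "s")
  pred0 <- raster_grid(matrix(c(40, rep(1e-9, 99)), 10, 10), 0, 0, 1, "p")
  dm2 <- difference_map(suit1, pred0)
  expect_equal(max(dm2$values), 1, tolerance = 1e-6)
  expect_true(all(dm2$values >= -1 & dm2$values <= 1))
  # definitional antisymmetry: s - rel(p) = -(rel(p) - s)
  expect_equal(dm2$values, -(pred0$values / max(pred0$values) - suit1$values))
  expect_error(difference_map(suit1, raster_grid(matrix(-1, 10, 10),
                                                 0, 0, 1, "n")), "positive")

  div <- raster_grid(matrix(c(0, 5, 10, 2), 2, 2), 0, 0, 1, "richness")
  rd <- relative_diversity(div)
  expect_equal(max(rd$values), 1)
  expect_equal(rd$values[1, 1], 0)
  div2 <- div; div2$values <- div$values * 2
  expect_equal(relative_diversity(div2)$values, rd$values)
  expect_error(relative_diversity(raster_grid(matrix(0, 2, 2), 0, 0, 1)),
               "all-zero")
})
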