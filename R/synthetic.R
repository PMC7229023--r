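# Synthetic-data generators with known ground truth: birth-death trees,
# Mk traits with their full generating histories, threshold (liability)
# traits, covariates with tunable phylogenetic signal and known logit
# effects, spatially autocorrelated and cross-correlated rasters, and
# occurrences sampled from a known suitability surface with optional
# spatial sampling bias. Every generator is deterministic under its seed.

#' Simulate a birth-death tree conditioned on a tip count
#'
#' Forward Gillespie simulation from a crown pair of lineages: waiting
#' times are exponential with total rate `k (birth + death)`, events are
#' speciations with probability `birth / (birth + death)`. Simulation runs
#' until `n_tips` extant lineages exist (restarting on extinction, i.e.
#' conditioning on survival), then all pendant branches are extended by
#' the waiting time to the next (not realized) event, so for a pure-birth
#' process the expected crown depth is `sum_{k=2..n} 1 / (birth * k)`.
#' Extinct lineages are pruned; the returned tree is ultrametric.
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth Speciation rate (> death).
#' @param death Extinction rate (>= 0).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_bd_tree <- function(n_tips, birth, death = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!(birth > death) || death < 0) {
    stop("need birth > death >= 0", call. = FALSE)
  }
  if (n_tips < 3) stop("n_tips must be >= 3", call. = FALSE)
  set.seed(as.integer(seed))
  repeat {
    # node table: parent, birth time; alive lineages indexed into it
    parent <- c(NA_integer_, 1L, 1L)
    btime <- c(0, 0, 0)
    alive <- c(2L, 3L)
    t_now <- 0
    ok <- TRUE
    while (length(alive) < n_tips) {
      kk <- length(alive)
      t_now <- t_now + stats::rexp(1, kk * (birth + death))
      if (stats::runif(1) < birth / (birth + death)) {
        i <- alive[sample.int(kk, 1)]
        id <- length(parent) + c(1L, 2L)
        parent <- c(parent, i, i)
        btime <- c(btime, t_now, t_now)
        alive <- c(setdiff(alive, i), id)
      } else {
        dead <- alive[sample.int(kk, 1)]
        alive <- setdiff(alive, dead)
        if (length(alive) < 2) { ok <- FALSE; break }
      }
    }
    if (ok) break
  }
  t_stop <- t_now + stats::rexp(1, n_tips * (birth + death))

  # keep only lineages ancestral to an extant tip, splice unary nodes
  n_all <- length(parent)
  has_ext <- logical(n_all)
  has_ext[alive] <- TRUE
  for (i in n_all:2) if (has_ext[i]) has_ext[parent[i]] <- TRUE
  # children lists among surviving lineages
  kids <- vector("list", n_all)
  for (i in 2:n_all) if (has_ext[i]) kids[[parent[i]]] <- c(kids[[parent[i]]], i)

  tip_ids <- alive
  ntip <- length(tip_ids)
  tip_no <- integer(n_all); tip_no[tip_ids] <- seq_len(ntip)
  edges <- list(); lens <- numeric(0)
  node_no <- integer(n_all)
  next_node <- ntip + 1L

  # recursive splice starting from the root (id 1)
  splice <- function(i) {
    # follow unary chains
    while (!tip_no[i] && length(kids[[i]]) == 1L) i <- kids[[i]][1]
    i
  }
  assign_nodes <- function(i) {
    i <- splice(i)
    if (tip_no[i]) return(list(no = tip_no[i], time = t_stop))
    my_no <- next_node; next_node <<- next_node + 1L
    for (ch in kids[[i]]) {
      res <- assign_nodes(ch)
      edges[[length(edges) + 1L]] <<- c(my_no, res$no)
      lens[length(lens) + 1L] <<- res$time - btime[ch]
    }
    list(no = my_no, time = btime[kids[[i]][1]])
  }
  # wrap recursion in a loop-safe environment (trees can be deep)
  old_exp <- getOption("expressions")
  options(expressions = 500000)
  on.exit(options(expressions = old_exp))
  root_res <- assign_nodes(1L)

  tree <- structure(list(
    edge = do.call(rbind, edges),
    edge.length = lens,
    Nnode = next_node - ntip - 1L,
    tip.label = paste0("t", seq_len(ntip))
  ), class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_tree(tree)
  tree
}

#' Rescale a tree to a target root-to-tip depth
#'
#' @param tree A `phylo` object.
#' @param depth Target maximum root-to-tip path length.
#' @return The rescaled tree.
#' @export
rescale_tree_depth <- function(tree, depth) {
  d0 <- max(ape::node.depth.edgelength(tree))
  if (d0 <= 0) stop("tree has zero depth", call. = FALSE)
  tree$edge.length <- tree$edge.length * (depth / d0)
  tree
}

#' Simulate a binary Mk trait with its full character history
#'
#' Exact Gillespie simulation of the two-state Markov process down every
#' branch from a given root state. Returns both the tip states and the
#' complete generating history (per-edge state segments and true gain/loss
#' counts), in the same layout that [sample_histories()] produces, so
#' mapped counts can be checked against the truth.
#'
#' @param tree A `phylo` object.
#' @param q01,q10 Gain/loss rates (>= 0).
#' @param root Root state (0/1).
#' @param seed Integer seed.
#' @return List with `trait` (named 0/1 vector) and `history` (list with
#'   `edge` segments, `node_state`, `n01`, `n10`).
#' @export
simulate_mk_trait <- function(tree, q01, q10, root = 0L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0", call. = FALSE)
  validate_tree(tree)
  set.seed(as.integer(seed))
  po <- ape::reorder.phylo(tree, "postorder")
  pa <- po$edge[, 1]; ch <- po$edge[, 2]; len <- po$edge.length
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  st <- integer(nn)
  st[ntip + 1L] <- as.integer(root)
  segs <- vector("list", length(pa))
  n01 <- 0L; n10 <- 0L
  for (i in rev(seq_along(pa))) {        # preorder
    path <- .ctmc_forward(st[pa[i]], len[i], q01, q10)
    st[ch[i]] <- path[nrow(path), "state"]
    if (nrow(path) > 1L) {
      tr <- diff(path[, "state"])
      n01 <- n01 + sum(tr == 1L)
      n10 <- n10 + sum(tr == -1L)
    }
    segs[[i]] <- data.frame(edge = i, parent = pa[i], child = ch[i],
                            state = path[, "state"], dwell = path[, "dwell"])
  }
  trait <- stats::setNames(st[seq_len(ntip)], tree$tip.label)
  list(trait = trait,
       history = list(edge = do.call(rbind, segs), node_state = st,
                      n01 = n01, n10 = n10))
}

#' Simulate a threshold (liability) trait
#'
#' A unit-rate Brownian liability is evolved along the tree and thresholded
#' so that exactly `round(prevalence * n)` tips score 1 (ties broken by
#' rank). This is the Brownian-conserved null of the D statistic.
#'
#' @param tree A `phylo` object.
#' @param prevalence Target fraction of state-1 tips, strictly in (0, 1).
#' @param seed Integer seed.
#' @return Named 0/1 vector over the tips.
#' @export
simulate_threshold_trait <- function(tree, prevalence, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  liab <- .bm_tips(tree)
  k <- max(1L, min(length(liab) - 1L, round(prevalence * length(liab))))
  stats::setNames(.threshold_at_count(liab, k), tree$tip.label)
}

#' Simulate covariates and a binary response with known effects
#'
#' Each covariate mixes a Brownian component on the tree with independent
#' noise: `x = sqrt(signal) * z_phylo + sqrt(1 - signal) * z_iid`, both
#' standardized, so `signal` in `[0, 1]` is the fraction of covariate
#' variance with phylogenetic structure. The response is Bernoulli with
#' `logit p = intercept + X beta_true + resid_sd * z_phylo_resid`, a
#' tree-structured residual liability. Ground truth is attached as
#' attributes.
#'
#' @param tree A `phylo` object.
#' @param beta_true Named numeric vector of true logit effects; names
#'   become covariate columns.
#' @param signal Phylogenetic-signal mixing fraction in `[0, 1]`.
#' @param intercept Logit intercept (default -3, ~5% baseline prevalence,
#'   the empirical regime for rare concealed-skin traits).
#' @param resid_sd Standard deviation of the phylogenetic residual
#'   liability (default 0.5).
#' @param seed Integer seed.
#' @return Data frame (`species`, `y`, covariates) with attributes
#'   `beta_true`, `intercept`, `signal`, `resid_sd`.
#' @export
simulate_covariates_and_response <- function(tree, beta_true, signal = 0.5,
                                             intercept = -3, resid_sd = 0.5,
                                             seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (signal < 0 || signal > 1) stop("signal must be in [0, 1]",
                                     call. = FALSE)
  if (any(!is.finite(beta_true))) stop("beta_true must be finite",
                                       call. = FALSE)
  validate_tree(tree)
  set.seed(as.integer(seed))
  n <- ape::Ntip(tree)
  p <- length(beta_true)
  if (is.null(names(beta_true))) names(beta_true) <- paste0("x", seq_len(p))
  X <- vapply(seq_len(p), function(j) {
    zp <- standardize(.bm_tips(tree))
    zi <- stats::rnorm(n)
    standardize(sqrt(signal) * zp + sqrt(1 - signal) * zi)
  }, numeric(n))
  colnames(X) <- names(beta_true)
  resid <- if (resid_sd > 0) resid_sd * standardize(.bm_tips(tree)) else 0
  eta <- intercept + drop(X %*% beta_true) + resid
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  out <- data.frame(species = tree$tip.label, y = y, X,
                    stringsAsFactors = FALSE)
  attr(out, "beta_true") <- beta_true
  attr(out, "intercept") <- intercept
  attr(out, "signal") <- signal
  attr(out, "resid_sd") <- resid_sd
  out
}

# separable Gaussian smoothing of a matrix with reflecting edges
.smooth_grid <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_cells))
  kern <- stats::dnorm(-half:half, sd = sigma_cells)
  kern <- kern / sum(kern)
  pad_conv <- function(v) {
    vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1L]))
    stats::convolve(vp, rev(kern), type = "filter")
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

# plausible unit rescalings for the standard variable names
.raster_units <- list(
  uv_b   = list(mean = 4000, sd = 1200, units = "kJ m-2 day-1", floor = 0),
  tmin   = list(mean = 5,    sd = 10,  units = "degC", floor = -Inf),
  tmax   = list(mean = 25,   sd = 8,   units = "degC", floor = -Inf),
  precip = list(mean = 1200, sd = 600, units = "mm", floor = 0)
)

#' Generate co-registered autocorrelated environmental rasters
#'
#' Seeded Gaussian white noise per variable is smoothed to the requested
#' spatial correlation length and linearly mixed (Cholesky of
#' `cross_corr`) to achieve the requested inter-variable correlations --
#' emulating, e.g., the collinearity between UV radiance and temperature.
#' Fields are rescaled to plausible units by variable name (`uv_b`,
#' `tmin`, `tmax`, `precip`; unknown names stay standardized).
#'
#' @param extent Extent in degrees (square grid from (0, 0)).
#' @param cell Cell size in degrees.
#' @param corr_length Spatial correlation length in degrees.
#' @param cross_corr Positive semi-definite correlation matrix; its
#'   row/col names are the variable names (default: identity over
#'   `uv_b`, `tmin`, `tmax`, `precip`).
#' @param seed Integer seed.
#' @return Named list of `raster_grid`s.
#' @export
synth_rasters <- function(extent = 40, cell = 1, corr_length = 5,
                          cross_corr = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(cross_corr)) {
    cross_corr <- diag(4)
    dimnames(cross_corr) <- list(names(.raster_units), names(.raster_units))
  }
  ch <- tryCatch(chol(cross_corr), error = function(e) NULL)
  if (is.null(ch)) stop("cross_corr is not positive semi-definite",
                        call. = FALSE)
  vars <- rownames(cross_corr)
  if (is.null(vars)) vars <- paste0("v", seq_len(nrow(cross_corr)))
  set.seed(as.integer(seed))
  n <- max(2L, round(extent / cell))
  fields <- lapply(seq_along(vars), function(j) {
    f <- .smooth_grid(matrix(stats::rnorm(n * n), n, n), corr_length / cell)
    (f - mean(f)) / stats::sd(f)
  })
  Z <- vapply(fields, as.vector, numeric(n * n))
  # empirical whitening so the sample cross-correlation matches the target
  Z <- scale(Z)
  Z <- Z %*% solve(chol(stats::cov(Z)))
  Y <- Z %*% ch                          # columns get cross_corr structure
  out <- list()
  for (j in seq_along(vars)) {
    v <- vars[j]
    u <- .raster_units[[v]]
    x <- Y[, j]
    if (!is.null(u)) {
      x <- pmax(u$mean + u$sd * x, u$floor)
      units <- u$units
    } else units <- "z"
    out[[v]] <- raster_grid(matrix(x, n, n), 0, 0, cell, name = v,
                            units = units)
  }
  out
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn with probability proportional to
#' `suitability * bias` (bias defaults to uniform; a bias raster emulates
#' collector-density artefacts that thinning must mitigate); points are
#' jittered uniformly within their cell.
#'
#' @param suitability `raster_grid` with values in `[0, 1]`.
#' @param n Number of points.
#' @param bias Optional co-registered `raster_grid` of non-negative
#'   sampling weights.
#' @param species Species label(s) recycled over the points.
#' @param seed Integer seed.
#' @return An `occurrence_set` tagged `"raw"`.
#' @export
synth_occurrences <- function(suitability, n, bias = NULL,
                              species = "black_pseudospecies", seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  w <- as.vector(suitability$values)
  if (!is.null(bias)) {
    .check_coregistered(list(suitability, bias))
    w <- w * as.vector(bias$values)
  }
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("suitability (x bias) is all zero", call. = FALSE)
  set.seed(as.integer(seed))
  nr <- nrow(suitability$values)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  cs <- suitability$cellsize
  lon <- suitability$xmin + (col - 1L) * cs + stats::runif(n) * cs
  lat <- suitability$ymin + (nr - row) * cs + stats::runif(n) * cs
  occurrence_set(rep_len(species, n), lon, lat, provenance = "raw",
                 seed = as.integer(seed))
}

#' Build a per-specimen trait table from simulated components
#'
#' Converts a simulated binary trait and covariate set into the
#' per-specimen trait-table layout consumed by
#' [build_analysis_dataset()] and [descriptive_counts()]: one male and one
#' female record per species for the given region, raw-unit covariates
#' (standardized simulated covariates are mapped back through the inverse
#' of the log/standardize transforms the dataset builder applies), and
#' synthetic genus/family labels grouping consecutive tips.
#'
#' @param tree `phylo` the trait was simulated on.
#' @param trait Named 0/1 vector over the tips.
#' @param dataset Optional output of [simulate_covariates_and_response()];
#'   numeric covariates named `uv_b` / `mass_g` are exponentiated into
#'   plausible raw units, others passed through.
#' @param region `"head"` or `"venter"`.
#' @param genus_size,family_size Tips per genus, genera per family.
#' @return A trait table data frame.
#' @export
synth_trait_table <- function(tree, trait, dataset = NULL, region = "head",
                              genus_size = 3, family_size = 5) {
  sp <- tree$tip.label
  n <- length(sp)
  gi <- (seq_len(n) - 1) %/% genus_size + 1
  fi <- (gi - 1) %/% family_size + 1
  base <- data.frame(
    species = sp,
    region = region,
    skin = ifelse(trait[sp] == 1, "black", "non-black"),
    genus = paste0("g", gi), family = paste0("f", fi),
    stringsAsFactors = FALSE
  )
  if (!is.null(dataset)) {
    d <- dataset[match(sp, dataset$species), , drop = FALSE]
    for (v in setdiff(names(d), c("species", "y"))) {
      if (!is.numeric(d[[v]])) next
      base[[v]] <- switch(v,
        uv_b   = exp(d[[v]] * 0.4 + 8.3),      # ~4000 kJ m-2 day-1 scale
        mass_g = exp(d[[v]] * 1.2 + 5.5),      # ~250 g scale
        bald   = as.integer(d[[v]] > 1),
        d[[v]])
    }
  }
  rbind(transform(base, sex = "M"), transform(base, sex = "F"))
}

#' Assemble a full synthetic study world
#'
#' The default (`preset = "empirical"`) mirrors the empirical regime of
#' the concealed black-skin study: a birth-death tree rescaled to depth
#' 100, rare-gain/frequent-loss Mk rates (0.005 / 0.071 per unit depth,
#' giving ~5-7% trait prevalence), covariates with known logit effects,
#' four autocorrelated rasters with a 0.7 UV-temperature correlation, and
#' occurrences over an exponential UV-driven suitability surface. Every
#' component stores its ground truth.
#'
#' @param n_tips Tips in the tree (default 2000).
#' @param seed Integer master seed; sub-seeds are derived deterministically.
#' @param preset Currently `"empirical"`.
#' @return List: `tree`, `trait`, `history`, `q_true`, `dataset`
#'   (covariates + response), `rasters`, `suitability_true`, `occurrences`,
#'   `seeds`.
#' @export
synth_world <- function(n_tips = 2000, seed, preset = "empirical") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  preset <- match.arg(preset)
  seeds <- as.integer(seed) + c(tree = 101L, trait = 211L, covar = 307L,
                                raster = 401L, occ = 503L)
  tree <- rescale_tree_depth(
    simulate_bd_tree(n_tips, birth = 1, death = 0.2, seed = seeds["tree"]),
    100)
  q_true <- c(q01 = 0.005, q10 = 0.071)
  sim <- simulate_mk_trait(tree, q_true["q01"], q_true["q10"], root = 0L,
                           seed = seeds["trait"])
  beta_true <- c(uv_b = 1, mass_g = 0, bald = 0.8)
  ds <- simulate_covariates_and_response(tree, beta_true, signal = 0.5,
                                         seed = seeds["covar"])
  cc <- diag(4)
  dimnames(cc) <- list(names(.raster_units), names(.raster_units))
  cc["uv_b", "tmax"] <- cc["tmax", "uv_b"] <- 0.7
  rasters <- synth_rasters(extent = 40, cell = 1, corr_length = 5,
                           cross_corr = cc, seed = seeds["raster"])
  uv <- rasters$uv_b$values
  uvs <- (uv - min(uv)) / (max(uv) - min(uv))
  suit <- raster_grid(exp(2 * uvs) / max(exp(2 * uvs)),
                      rasters$uv_b$xmin, rasters$uv_b$ymin,
                      rasters$uv_b$cellsize, name = "true_suitability",
                      units = "relative")
  occ <- synth_occurrences(suit, n = 2500, seed = seeds["occ"])
  list(tree = tree, trait = sim$trait, history = sim$history,
       q_true = q_true, dataset = ds, beta_true = beta_true,
       rasters = rasters, suitability_true = suit, occurrences = occ,
       seeds = seeds)
}
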