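# Maximum-entropy trait-distribution modelling: a lightweight lon/lat
# raster container with ESRI ASCII grid I/O, grid-based occurrence
# thinning, an L1-regularized Gibbs model over background cells fitted by
# coordinate descent (tracking per-iteration gain for the variable
# contribution table), cloglog suitability prediction, response curves,
# and difference maps against normalized predictors.

#' Construct a regular lon/lat raster grid
#'
#' @param values Numeric matrix; row 1 is the northernmost row, columns run
#'   west to east. `NA` marks nodata.
#' @param xmin,ymin Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell size in degrees (square cells).
#' @param name Variable name.
#' @param units Units string (e.g. `"kJ m-2 day-1"`).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymin, cellsize, name = "layer",
                        units = "") {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, name = name, units = units),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid '%s' [%s]: %d rows x %d cols, cell %g deg, origin (%g, %g)\n",
              x$name, x$units, nrow(x$values), ncol(x$values), x$cellsize,
              x$xmin, x$ymin))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  range %.4g .. %.4g, %d nodata cells\n",
                             min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Read / write an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value` header followed by rows from
#' north to south).
#'
#' @param path File path.
#' @param name,units Metadata attached on read.
#' @return A `raster_grid` (read) or `path` invisibly (write).
#' @export
read_ascii_grid <- function(path, name = basename(path), units = "") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, name, units)
}

#' @rdname read_ascii_grid
#' @param grid A `raster_grid` to write.
#' @export
write_ascii_grid <- function(grid, path) {
  m <- grid$values
  m[is.na(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid$values)),
    paste("nrows", nrow(grid$values)),
    paste("xllcorner", format(grid$xmin, digits = 12)),
    paste("yllcorner", format(grid$ymin, digits = 12)),
    paste("cellsize", format(grid$cellsize, digits = 12)),
    paste("NODATA_value", -9999)
  ), con)
  utils::write.table(format(m, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.check_coregistered <- function(rasters) {
  ref <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!identical(dim(r$values), dim(ref$values)) ||
        abs(r$xmin - ref$xmin) > 1e-9 || abs(r$ymin - ref$ymin) > 1e-9 ||
        abs(r$cellsize - ref$cellsize) > 1e-9) {
      stop("rasters are not co-registered ('", r$name, "' vs '", ref$name,
           "')", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# row/col (row 1 = north) and linear cell index for lon/lat points
.cell_index <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xmin) / grid$cellsize) + 1L
  row_s <- floor((lat - grid$ymin) / grid$cellsize) + 1L  # from south
  row <- nr - row_s + 1L
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  idx <- ifelse(ok, (col - 1L) * nr + row, NA_integer_)
  idx
}

#' Construct an occurrence set
#'
#' @param species Character vector of species identifiers.
#' @param lon,lat Coordinates in degrees.
#' @param provenance `"raw"` or `"thinned"`.
#' @param seed Seed recorded for thinned sets.
#' @return A data frame of class `occurrence_set`.
#' @export
occurrence_set <- function(species, lon, lat, provenance = "raw",
                           seed = NA_integer_) {
  d <- data.frame(species = as.character(species), lon = lon, lat = lat,
                  stringsAsFactors = FALSE)
  structure(d, class = c("occurrence_set", "data.frame"),
            provenance = provenance, seed = seed)
}

#' Thin occurrences on a spatial grid
#'
#' Collector-density bias correction: per species, occurrences are bucketed
#' into `grid_deg` x `grid_deg` cells and at most `cap_per_species` records
#' are kept, sampling stratified across occupied cells first (round-robin,
#' one per cell per round, cell order and within-cell order seeded) and
#' then within cells. Species with fewer records than the cap keep them
#' all. Thinning is idempotent: re-thinning a thinned set with the same
#' parameters returns the same set.
#'
#' @param occ An `occurrence_set`.
#' @param grid_deg Cell size in degrees (default 2).
#' @param cap_per_species Maximum records per species (default 50).
#' @param seed Integer seed.
#' @return A thinned `occurrence_set` (rows sorted by species, lon, lat).
#' @export
thin_occurrences <- function(occ, grid_deg = 2, cap_per_species = 50, seed) {
  if (!nrow(occ)) stop("empty occurrence set", call. = FALSE)
  if (grid_deg <= 0 || cap_per_species < 1) {
    stop("grid_deg must be > 0 and cap_per_species >= 1", call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  cell <- paste(floor((occ$lon + 180) / grid_deg),
                floor((occ$lat + 90) / grid_deg))
  keep <- unlist(lapply(split(seq_len(nrow(occ)), occ$species), function(ix) {
    if (length(ix) <= cap_per_species) return(ix)
    by_cell <- split(ix, cell[ix])
    by_cell <- lapply(by_cell, function(v) if (length(v) > 1) sample(v) else v)
    by_cell <- sample(by_cell)
    chosen <- integer(0)
    round_i <- 1L
    while (length(chosen) < cap_per_species) {
      for (v in by_cell) {
        if (length(v) >= round_i) {
          chosen <- c(chosen, v[round_i])
          if (length(chosen) == cap_per_species) break
        }
      }
      round_i <- round_i + 1L
    }
    chosen
  }), use.names = FALSE)
  out <- occ[keep, , drop = FALSE]
  out <- out[order(out$species, out$lon, out$lat), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("occurrence_set", "data.frame"),
            provenance = "thinned", seed = as.integer(seed))
}

# feature matrix over a set of cell values; linear + quadratic per
# variable, min-max scaled by the background range
.build_features <- function(env, ranges, features) {
  cols <- list()
  for (v in colnames(env)) {
    r <- ranges[[v]]
    x <- if (r[2] > r[1]) (env[, v] - r[1]) / (r[2] - r[1]) else env[, v] * 0
    if ("linear" %in% features) cols[[paste0(v, ":linear")]] <- x
    if ("quadratic" %in% features) cols[[paste0(v, ":quadratic")]] <- x^2
  }
  do.call(cbind, cols)
}

#' Fit a maximum-entropy trait-distribution model
#'
#' Presence-background model: the trait distribution over background cells
#' is the Gibbs distribution `p(cell) = exp(f(cell)' lambda) / Z` whose
#' weights minimize the negative mean log-likelihood of the presence cells
#' plus an L1 penalty `reg * sum(r_j |lambda_j|)`, where `r_j` is the
#' presence-sample standard error of feature `j`'s mean (so `reg` is a
#' unitless multiplier and regularization relaxes as presences accumulate).
#' Features are linear and quadratic transforms of each environmental
#' layer, min-max scaled over the background. The convex problem is solved by greedy coordinate
#' descent with soft thresholding (the classic sequential maxent update),
#' recording per-iteration gain so contributions can be attributed to
#' variables; iteration stops when the largest KKT violation falls below
#' `tol` (default 1e-6).
#'
#' @param occ An `occurrence_set` (all species pooled as one
#'   pseudo-species; thin per species first, then concatenate).
#' @param rasters List of co-registered `raster_grid` layers.
#' @param reg Non-negative L1 regularization strength (default 1).
#' @param features Feature classes, subset of `c("linear", "quadratic")`.
#' @param tol Convergence tolerance on the KKT violation.
#' @param max_iter Iteration cap.
#' @param bg_subsample Optional cap on the number of background cells; by
#'   default every valid cell is background (desk-scale grids need no
#'   subsample). When set below the valid-cell count, that many cells are
#'   drawn without replacement using `bg_seed`. Presence features are kept
#'   separately, so subsampling only adds Monte-Carlo noise to the
#'   background normalizer.
#' @param bg_seed Seed for the background subsample (default 1).
#' @return Object of class `maxent_model`: `lambda`, feature metadata,
#'   background feature matrix, presence indices, `training_log`
#'   (iteration, feature, gain), `entropy`, `gain`.
#' @export
fit_maxent <- function(occ, rasters, reg = 1.0,
                       features = c("linear", "quadratic"),
                       tol = 1e-6, max_iter = 10000,
                       bg_subsample = NULL, bg_seed = 1L) {
  .check_coregistered(rasters)
  features <- match.arg(features, several.ok = TRUE)
  env_full <- vapply(rasters, function(r) as.vector(r$values),
                     numeric(length(rasters[[1]]$values)))
  colnames(env_full) <- vapply(rasters, `[[`, character(1), "name")
  if (any(!is.finite(env_full) & !is.na(env_full))) {
    stop("non-finite raster values", call. = FALSE)
  }
  valid <- stats::complete.cases(env_full)
  if (!any(valid)) stop("no valid background cells", call. = FALSE)
  env <- env_full[valid, , drop = FALSE]
  cell_of_valid <- which(valid)

  idx_full <- .cell_index(rasters[[1]], occ$lon, occ$lat)
  pres_full <- idx_full[!is.na(idx_full) & idx_full %in% cell_of_valid]
  if (!length(pres_full)) {
    stop("no presence records fall on valid raster cells", call. = FALSE)
  }
  env_pres <- env_full[pres_full, , drop = FALSE]

  if (!is.null(bg_subsample) && bg_subsample < length(cell_of_valid)) {
    set.seed(as.integer(bg_seed))
    keep <- sort(sample(cell_of_valid, bg_subsample))
    env <- env_full[keep, , drop = FALSE]
    cell_of_valid <- keep
  }

  ranges <- lapply(colnames(env), function(v) range(env[, v]))
  names(ranges) <- colnames(env)
  FF <- .build_features(env, ranges, features)
  FF_pres <- .build_features(env_pres, ranges, features)
  k <- ncol(FF)
  mu_hat <- colMeans(FF_pres)

  # per-feature penalty scaled by the presence-sample standard error of the
  # feature mean (the reference tool's scheme), so `reg` is a unitless
  # multiplier and the penalty vanishes as the presence sample grows
  sd_pres <- apply(FF_pres, 2, stats::sd)
  reg_j <- reg * pmax(sd_pres, 1e-6) / sqrt(nrow(FF_pres))

  nb <- nrow(FF)
  lambda <- numeric(k)
  eta <- numeric(nb)
  pnll <- function(lambda, eta) {
    logZ <- log(sum(exp(eta - max(eta)))) + max(eta)
    -sum(lambda * mu_hat) + logZ + sum(reg_j * abs(lambda))
  }
  cur <- pnll(lambda, eta)
  nll0 <- cur
  log_rows <- list()
  for (it in seq_len(max_iter)) {
    w <- exp(eta - max(eta)); w <- w / sum(w)
    m1 <- drop(w %*% FF)
    g <- m1 - mu_hat                     # gradient of smooth part
    viol <- ifelse(lambda == 0, pmax(abs(g) - reg_j, 0),
                   abs(g + reg_j * sign(lambda)))
    if (max(viol) < tol) break
    j <- which.max(viol)
    m2 <- drop(w %*% (FF[, j]^2))
    d2 <- max(m2 - m1[j]^2, 1e-12)       # curvature (model variance)
    z <- lambda[j] - g[j] / d2
    new_lj <- sign(z) * max(abs(z) - reg_j[j] / d2, 0)
    step <- new_lj - lambda[j]
    # backtracking on the penalized objective
    repeat {
      cand <- lambda; cand[j] <- lambda[j] + step
      eta_c <- eta + step * FF[, j]
      val <- pnll(cand, eta_c)
      if (val <= cur + 1e-12 || abs(step) < 1e-14) break
      step <- step / 2
    }
    gain_delta <- cur - val
    lambda[j] <- lambda[j] + step
    eta <- eta + step * FF[, j]
    cur <- val
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(iter = it, feature = colnames(FF)[j],
                 variable = sub(":.*$", "", colnames(FF)[j]),
                 gain = gain_delta)
  }
  w <- exp(eta - max(eta)); w <- w / sum(w)
  names(lambda) <- colnames(FF)
  structure(list(
    lambda = lambda, features = features, ranges = ranges,
    variables = colnames(env), reg = reg,
    bg_features = FF, bg_cells = cell_of_valid, prob = w,
    pres_features = FF_pres, n_presence = nrow(FF_pres),
    mu_hat = mu_hat,
    training_log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(iter = integer(0), feature = character(0),
                 variable = character(0), gain = numeric(0)),
    gain = nll0 - cur,
    entropy = -sum(w * log(pmax(w, 1e-300))),
    grid = rasters[[1]][c("xmin", "ymin", "cellsize")],
    dim = dim(rasters[[1]]$values),
    converged = it < max_iter
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d presences, %d background cells, reg = %g\n",
              x$n_presence, length(x$prob), x$reg))
  cat(sprintf("  regularized gain %.4f, entropy %.4f\n", x$gain, x$entropy))
  nz <- x$lambda[x$lambda != 0]
  if (length(nz)) {
    cat("  non-zero weights:\n")
    for (nm in names(nz)) cat(sprintf("    %-24s % .4f\n", nm, nz[nm]))
  } else cat("  all weights zero (uniform model)\n")
  invisible(x)
}

#' Predict trait suitability over the training grid
#'
#' Cell suitability is the cloglog transform of the normalized Gibbs
#' density: `1 - exp(-exp(H) * p(cell))` with `H` the entropy of the cell
#' distribution, a monotone map of the raw density into `[0, 1]`.
#'
#' @param model A `maxent_model`.
#' @param rasters The co-registered environmental layers (must carry the
#'   training variable names).
#' @return A `raster_grid` of suitabilities.
#' @export
predict_suitability <- function(model, rasters) {
  .check_coregistered(rasters)
  nms <- vapply(rasters, `[[`, character(1), "name")
  if (!setequal(nms, model$variables)) {
    stop("raster variables do not match the trained model (",
         paste(model$variables, collapse = ", "), ")", call. = FALSE)
  }
  rasters <- rasters[match(model$variables, nms)]
  env <- vapply(rasters, function(r) as.vector(r$values),
                numeric(length(rasters[[1]]$values)))
  colnames(env) <- model$variables
  valid <- stats::complete.cases(env)
  FF <- .build_features(env[valid, , drop = FALSE], model$ranges,
                        model$features)
  eta <- drop(FF %*% model$lambda)
  logZ <- log(sum(exp(eta - max(eta)))) + max(eta)
  raw <- exp(eta - logZ)
  s <- 1 - exp(-exp(model$entropy) * raw)
  out <- rep(NA_real_, nrow(env))
  out[valid] <- s
  raster_grid(matrix(out, model$dim[1], model$dim[2]),
              model$grid$xmin, model$grid$ymin, model$grid$cellsize,
              name = "suitability", units = "probability")
}

#' Variable contribution table
#'
#' Primary column: percentage of the accumulated per-iteration training
#' gain attributed to each variable (the variable whose feature was updated
#' at each coordinate-descent iteration). Secondary column: permutation
#' importance -- the increase in training negative log-likelihood when the
#' variable's values are permuted jointly across presence and background
#' samples (seeded), normalized to percentages. Each column sums to 100.
#'
#' @param model A trained `maxent_model`.
#' @return Data frame with `variable`, `contribution`, `permutation_importance`.
#' @export
variable_contribution <- function(model) {
  if (is.null(model$training_log)) stop("untrained model", call. = FALSE)
  gains <- vapply(model$variables, function(v) {
    sum(model$training_log$gain[model$training_log$variable == v])
  }, numeric(1))
  gains <- pmax(gains, 0)
  contr <- if (sum(gains) > 0) 100 * gains / sum(gains) else
    rep(100 / length(gains), length(gains))

  nll_at <- function(FFp, FFb) {
    eta_b <- drop(FFb %*% model$lambda)
    logZ <- log(sum(exp(eta_b - max(eta_b)))) + max(eta_b)
    -mean(drop(FFp %*% model$lambda)) + logZ
  }
  scaled_value <- function(FF, v) {
    if ("linear" %in% model$features) {
      FF[, paste0(v, ":linear")]
    } else {
      sqrt(pmax(FF[, paste0(v, ":quadratic")], 0))
    }
  }
  base <- nll_at(model$pres_features, model$bg_features)
  n_p <- nrow(model$pres_features)
  set.seed(1L)
  drop_j <- vapply(model$variables, function(v) {
    xs <- c(scaled_value(model$pres_features, v),
            scaled_value(model$bg_features, v))
    xs <- xs[sample(length(xs))]
    FFp <- model$pres_features
    FFb <- model$bg_features
    if ("linear" %in% model$features) {
      FFp[, paste0(v, ":linear")] <- xs[seq_len(n_p)]
      FFb[, paste0(v, ":linear")] <- xs[-seq_len(n_p)]
    }
    if ("quadratic" %in% model$features) {
      FFp[, paste0(v, ":quadratic")] <- xs[seq_len(n_p)]^2
      FFb[, paste0(v, ":quadratic")] <- xs[-seq_len(n_p)]^2
    }
    max(nll_at(FFp, FFb) - base, 0)
  }, numeric(1))
  pimp <- if (sum(drop_j) > 0) 100 * drop_j / sum(drop_j) else
    rep(100 / length(drop_j), length(drop_j))
  data.frame(variable = model$variables, contribution = contr,
             permutation_importance = pimp, row.names = NULL)
}

#' Marginal response curve for one variable
#'
#' Varies the target variable over its observed background range while
#' holding all other variables at their background means, and reports the
#' cloglog suitability at each grid point.
#'
#' @param model A `maxent_model`.
#' @param variable Variable name.
#' @param grid Number of evaluation points (default 100).
#' @return Data frame with `value` (original units) and `suitability`.
#' @export
response_curve <- function(model, variable, grid = 100) {
  if (!variable %in% model$variables) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  r <- model$ranges[[variable]]
  xs <- seq(r[1], r[2], length.out = grid)
  # background means on the original scale, reconstructed from features
  mean_env <- vapply(model$variables, function(v) {
    rv <- model$ranges[[v]]
    sc <- if ("linear" %in% model$features) {
      mean(model$bg_features[, paste0(v, ":linear")])
    } else {
      mean(sqrt(pmax(model$bg_features[, paste0(v, ":quadratic")], 0)))
    }
    rv[1] + sc * (rv[2] - rv[1])
  }, numeric(1))
  env <- matrix(rep(mean_env, each = grid), nrow = grid)
  colnames(env) <- model$variables
  env[, variable] <- xs
  FF <- .build_features(env, model$ranges, model$features)
  eta <- drop(FF %*% model$lambda)
  eta_bg <- drop(model$bg_features %*% model$lambda)
  logZ <- log(sum(exp(eta_bg - max(eta_bg)))) + max(eta_bg)
  raw <- exp(eta - logZ)
  data.frame(value = xs, suitability = 1 - exp(-exp(model$entropy) * raw))
}

#' Difference map between suitability and a normalized predictor
#'
#' Per-cell suitability minus the predictor normalized by its global
#' maximum (`predictor / max(predictor)`); values near 0 indicate a good
#' fit between predictor and predicted trait probability. Range `[-1, 1]`.
#'
#' @param suitability,predictor Co-registered `raster_grid`s.
#' @return A `raster_grid` named `"<suitability> - rel_<predictor>"`.
#' @export
difference_map <- function(suitability, predictor) {
  .check_coregistered(list(suitability, predictor))
  mx <- max(predictor$values, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    stop("predictor maximum must be positive", call. = FALSE)
  }
  raster_grid(suitability$values - predictor$values / mx,
              suitability$xmin, suitability$ymin, suitability$cellsize,
              name = paste0(suitability$name, " - rel_", predictor$name),
              units = "difference")
}

#' Relative diversity raster
#'
#' Normalizes a non-negative diversity (richness) raster by its global
#' maximum, giving values in `[0, 1]`.
#'
#' @param diversity A `raster_grid` of non-negative counts.
#' @return A `raster_grid` in `[0, 1]`.
#' @export
relative_diversity <- function(diversity) {
  v <- diversity$values
  if (any(v < 0, na.rm = TRUE)) stop("diversity must be non-negative",
                                     call. = FALSE)
  mx <- max(v, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) stop("all-zero diversity raster",
                                      call. = FALSE)
  raster_grid(v / mx, diversity$xmin, diversity$ymin, diversity$cellsize,
              name = paste0("rel_", diversity$name), units = "fraction")
}
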