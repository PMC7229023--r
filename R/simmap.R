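# Stochastic character mapping: sample full trait histories conditional on
# tip data under a fitted Mk model, count gains/losses, and summarize maps
# into per-edge posterior occupancy (density maps).

# forward CTMC path on one branch from state `a` over time `t`;
# returns matrix of (state, dwell) segments
.ctmc_forward <- function(a, t, q01, q10) {
  states <- integer(0); dwell <- numeric(0)
  s <- a; rem <- t
  repeat {
    rate <- if (s == 0L) q01 else q10
    w <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (w >= rem) {
      states <- c(states, s); dwell <- c(dwell, rem)
      break
    }
    states <- c(states, s); dwell <- c(dwell, w)
    rem <- rem - w
    s <- 1L - s
  }
  cbind(state = states, dwell = dwell)
}

# endpoint-conditioned path via uniformization (exact; used when rejection
# sampling of the forward process fails to hit the required endpoint)
.ctmc_bridge_unif <- function(a, b, t, q01, q10) {
  omega <- max(q01, q10)
  if (omega == 0 || t == 0) {
    if (a != b) stop("impossible bridge under zero rates", call. = FALSE)
    return(cbind(state = a, dwell = t))
  }
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  R <- diag(2) + Q / omega
  nmax <- max(10L, stats::qpois(1 - 1e-12, omega * t) + 10L)
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1]] <- diag(2)
  for (k in seq_len(nmax)) Rpow[[k + 1]] <- Rpow[[k]] %*% R
  wts <- vapply(0:nmax, function(n) {
    stats::dpois(n, omega * t) * Rpow[[n + 1]][a + 1L, b + 1L]
  }, numeric(1))
  if (sum(wts) <= 0) stop("bridge weight underflow", call. = FALSE)
  n <- sample.int(nmax + 1L, 1L, prob = wts) - 1L
  if (n == 0L) return(cbind(state = a, dwell = t))
  jumps <- sort(stats::runif(n, 0, t))
  seq_states <- integer(n + 1L); seq_states[1] <- a; seq_states[n + 1L] <- b
  if (n > 1L) {
    for (k in 2:n) {
      prev <- seq_states[k - 1L]
      pr <- vapply(0:1, function(x) {
        R[prev + 1L, x + 1L] * Rpow[[n - k + 2L]][x + 1L, b + 1L]
      }, numeric(1))
      seq_states[k] <- sample.int(2L, 1L, prob = pr) - 1L
    }
  }
  bounds <- c(0, jumps, t)
  keep <- c(TRUE, diff(seq_states) != 0L)   # collapse virtual jumps
  st <- seq_states[keep]
  cut <- c(bounds[c(keep, TRUE)])
  cbind(state = st, dwell = diff(cut))
}

# endpoint-conditioned path: rejection sampling with uniformization fallback
.ctmc_bridge <- function(a, b, t, q01, q10, max_reject = 100L) {
  if (t == 0) {
    if (a != b) stop("endpoint mismatch on zero-length branch", call. = FALSE)
    return(cbind(state = a, dwell = 0))
  }
  for (i in seq_len(max_reject)) {
    path <- .ctmc_forward(a, t, q01, q10)
    if (path[nrow(path), "state"] == b) return(path)
  }
  .ctmc_bridge_unif(a, b, t, q01, q10)
}

#' Sample stochastic character maps
#'
#' Draws full character histories (state intervals along every branch) from
#' their joint posterior given the tip data and a fitted Mk model
#' (empirical Bayes: rates fixed at their ML estimates). Node states are
#' sampled exactly from the joint conditional distribution -- the root from
#' its marginal posterior, then each child conditionally on its parent --
#' and within-branch paths are endpoint-conditioned CTMC bridges (rejection
#' sampling with a uniformization fallback, so sampling cannot fail).
#'
#' @inheritParams mk_loglik
#' @param fit A converged `mk_fit`.
#' @param n_maps Number of histories to sample (>= 1).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A list of class `character_history_set`; each element has
#'   `edge` (data frame: edge index, parent, child, segment state, dwell),
#'   `node_state`, and counts `n01` (gains), `n10` (losses).
#' @export
sample_histories <- function(tree, y, fit, n_maps, seed) {
  validate_tree(tree)
  if (n_maps < 1) stop("n_maps must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  prep <- .mk_prepare(tree, y)
  q01 <- fit$q01; q10 <- fit$q10
  prior <- .mk_root_prior(fit$root, q01, q10, fit$root_state)
  down <- .mk_prune(prep, q01, q10, prior)
  if (!is.finite(down$loglik)) stop("data impossible under fit", call. = FALSE)

  n_edges <- length(prep$parent)
  Plist <- lapply(seq_len(n_edges), function(i) {
    mk_transition_prob(q01, q10, prep$len[i])
  })

  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    nn <- prep$ntip + prep$nnode
    st <- integer(nn)
    pr_root <- prior * down$L[prep$root, ]
    st[prep$root] <- sample.int(2L, 1L, prob = pr_root) - 1L
    for (i in rev(seq_len(n_edges))) {     # preorder
      pa <- prep$parent[i]; ch <- prep$child[i]
      pr <- Plist[[i]][st[pa] + 1L, ] * down$L[ch, ]
      st[ch] <- sample.int(2L, 1L, prob = pr) - 1L
    }
    segs <- vector("list", n_edges)
    n01 <- 0L; n10 <- 0L
    for (i in seq_len(n_edges)) {
      path <- .ctmc_bridge(st[prep$parent[i]], st[prep$child[i]],
                           prep$len[i], q01, q10)
      ns <- nrow(path)
      if (ns > 1L) {
        tr <- diff(path[, "state"])
        n01 <- n01 + sum(tr == 1L)
        n10 <- n10 + sum(tr == -1L)
      }
      segs[[i]] <- data.frame(edge = i, parent = prep$parent[i],
                              child = prep$child[i],
                              state = path[, "state"], dwell = path[, "dwell"])
    }
    maps[[m]] <- list(edge = do.call(rbind, segs), node_state = st,
                      n01 = n01, n10 = n10)
  }
  structure(maps, class = "character_history_set",
            tree = tree, seed = as.integer(seed),
            edge_parent = prep$parent, edge_child = prep$child,
            edge_len = prep$len)
}

# state at the midpoint of edge i in one history
.state_at_midpoint <- function(map, i, half_len) {
  seg <- map$edge[map$edge$edge == i, , drop = FALSE]
  cum <- cumsum(seg$dwell)
  if (length(cum) == 1L || half_len <= 0) return(seg$state[1])
  seg$state[which(cum >= half_len - 1e-12)[1]]
}

#' Summarize a set of stochastic maps
#'
#' Gain/loss count distributions across maps plus the per-edge posterior
#' probability of occupying state 1 (evaluated at the edge midpoint) --
#' the density map underlying figures of repeated trait origins.
#'
#' @param maps A `character_history_set` from [sample_histories()].
#' @return A list of class `map_summary`: `n_maps`, data frame `gains` /
#'   `losses` statistics (mean, median, min, max), vectors `n01`, `n10`,
#'   and `edge_p1` (per-edge state-1 probability).
#' @export
summarize_maps <- function(maps) {
  if (!length(maps)) stop("empty map list", call. = FALSE)
  n01 <- vapply(maps, `[[`, integer(1), "n01")
  n10 <- vapply(maps, `[[`, integer(1), "n10")
  lens <- attr(maps, "edge_len")
  n_edges <- length(lens)
  edge_p1 <- vapply(seq_len(n_edges), function(i) {
    mean(vapply(maps, .state_at_midpoint, numeric(1), i = i,
                half_len = lens[i] / 2))
  }, numeric(1))
  stat <- function(x) c(mean = mean(x), median = stats::median(x),
                        min = min(x), max = max(x))
  structure(list(
    n_maps = length(maps),
    gains = stat(n01), losses = stat(n10),
    n01 = n01, n10 = n10,
    edge_p1 = edge_p1,
    edge_parent = attr(maps, "edge_parent"),
    edge_child = attr(maps, "edge_child")
  ), class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("Stochastic map summary over %d histories\n", x$n_maps))
  cat(sprintf("  gains  (0->1): median %g, mean %.2f [%g, %g]\n",
              x$gains["median"], x$gains["mean"], x$gains["min"],
              x$gains["max"]))
  cat(sprintf("  losses (1->0): median %g, mean %.2f [%g, %g]\n",
              x$losses["median"], x$losses["mean"], x$losses["min"],
              x$losses["max"]))
  invisible(x)
}

#' Export a density map as annotated Newick text
#'
#' Serializes the density map as plain text: the Newick tree followed by
#' one comment line per edge (`# edge <parent>-><child> p1=<occupancy>`,
#' edges in postorder, node numbers in ape convention), so the per-branch
#' posterior occupancy can be re-joined to the topology by any reader.
#'
#' @param summary A `map_summary`.
#' @param tree The tree the maps were sampled on.
#' @param path Optional output file.
#' @return The annotated text, invisibly.
#' @export
density_map_newick <- function(summary, tree, path = NULL) {
  tab <- paste(sprintf("# edge %d->%d p1=%.4f", summary$edge_parent,
                       summary$edge_child, summary$edge_p1),
               collapse = "\n")
  out <- paste0(ape::write.tree(tree), "\n", tab, "\n")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
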