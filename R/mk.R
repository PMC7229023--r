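# Two-state Mk machinery: closed-form transition probabilities,
# Felsenstein-pruning likelihood, ER/ARD maximum-likelihood fits,
# likelihood-ratio model selection and marginal ancestral states.

#' Two-state Mk transition probability matrix
#'
#' Closed form for the continuous-time two-state Markov chain with gain
#' rate `q01` (0 to 1) and loss rate `q10` (1 to 0). With `s = q01 + q10`,
#' `P(0->1, t) = (q01/s) (1 - exp(-s t))` and rows sum to 1; a zero-length
#' branch gives the identity exactly.
#'
#' @param q01,q10 Non-negative transition rates per unit branch length.
#' @param t Non-negative branch length.
#' @return A 2x2 matrix with rows/cols in state order (0, 1).
#' @export
mk_transition_prob <- function(q01, q10, t) {
  if (q01 < 0 || q10 < 0 || t < 0) stop("rates and time must be >= 0",
                                        call. = FALSE)
  s <- q01 + q10
  if (s == 0 || t == 0) return(diag(2))
  e <- exp(-s * t)
  p01 <- (q01 / s) * (1 - e)
  p10 <- (q10 / s) * (1 - e)
  matrix(c(1 - p01, p10, p01, 1 - p10), 2, 2)
}

# postorder edge cache reused across likelihood evaluations on one tree
.mk_prepare <- function(tree, y) {
  y <- .align_trait(tree, y)
  po <- ape::reorder.phylo(tree, "postorder")
  list(
    ntip   = ape::Ntip(tree),
    nnode  = tree$Nnode,
    root   = ape::Ntip(tree) + 1L,
    parent = po$edge[, 1],
    child  = po$edge[, 2],
    len    = po$edge.length,
    y      = y
  )
}

.mk_root_prior <- function(root, q01, q10, root_state = 0L) {
  switch(root,
    flat = c(0.5, 0.5),
    stationary = {
      s <- q01 + q10
      if (s == 0) c(0.5, 0.5) else c(q10 / s, q01 / s)
    },
    fixed = if (root_state == 0L) c(1, 0) else c(0, 1),
    stop("unknown root treatment '", root, "'", call. = FALSE)
  )
}

# pruning pass; returns per-node partial likelihoods (conditional on the
# data below each node), per-node log scale factors, and the total loglik
.mk_prune <- function(prep, q01, q10, prior) {
  nn <- prep$ntip + prep$nnode
  L <- matrix(1, nn, 2)
  L[cbind(seq_len(prep$ntip), prep$y + 1L)] <- 1
  L[cbind(seq_len(prep$ntip), 2L - prep$y)] <- 0
  lsc <- numeric(nn)
  s <- q01 + q10
  for (i in seq_along(prep$parent)) {
    ch <- prep$child[i]; pa <- prep$parent[i]; t <- prep$len[i]
    if (s == 0 || t == 0) {
      v0 <- L[ch, 1]; v1 <- L[ch, 2]
    } else {
      e <- exp(-s * t)
      p01 <- (q01 / s) * (1 - e)
      p10 <- (q10 / s) * (1 - e)
      v0 <- (1 - p01) * L[ch, 1] + p01 * L[ch, 2]
      v1 <- p10 * L[ch, 1] + (1 - p10) * L[ch, 2]
    }
    L[pa, 1] <- L[pa, 1] * v0
    L[pa, 2] <- L[pa, 2] * v1
    lsc[pa] <- lsc[pa] + lsc[ch]
    f <- L[pa, 1] + L[pa, 2]
    if (f > 0 && f < 1e-30) {           # rescale to avoid underflow
      L[pa, ] <- L[pa, ] / f
      lsc[pa] <- lsc[pa] + log(f)
    }
  }
  lik <- prior[1] * L[prep$root, 1] + prior[2] * L[prep$root, 2]
  ll <- if (lik <= 0) -Inf else log(lik) + lsc[prep$root]
  list(L = L, lsc = lsc, loglik = ll)
}

#' Mk log-likelihood of binary tip data
#'
#' Probability of the observed tip states under the two-state Mk process,
#' computed by Felsenstein's pruning algorithm with numerical rescaling.
#' The root is weighted by a flat prior by default; stationary and
#' fixed-state treatments are available.
#'
#' @param tree A `phylo` object (polytomies are handled natively by the
#'   pruning pass).
#' @param y Named binary (0/1) vector over the tree tips.
#' @param q01,q10 Non-negative gain/loss rates.
#' @param root Root-state treatment: `"flat"` (default), `"stationary"` or
#'   `"fixed"`.
#' @param root_state Root state (0/1) when `root = "fixed"`.
#' @return The log-likelihood (a non-positive real for proper data).
#' @export
mk_loglik <- function(tree, y, q01, q10,
                      root = c("flat", "stationary", "fixed"),
                      root_state = 0L) {
  root <- match.arg(root)
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0", call. = FALSE)
  validate_tree(tree)
  prep <- .mk_prepare(tree, y)
  prior <- .mk_root_prior(root, q01, q10, root_state)
  .mk_prune(prep, q01, q10, prior)$loglik
}

#' Maximum-likelihood fit of the two-state Mk model
#'
#' Fits gain/loss rates by maximizing the pruning likelihood, under either
#' the equal-rates (`ER`, one free rate) or all-rates-different (`ARD`)
#' model. Rates are optimized on the log scale with multiple starting
#' points spanning 1e-4 to 1 expected transitions per unit tree depth;
#' the ARD fit additionally starts from the ER optimum so the ARD
#' likelihood can never fall below the ER one. A monomorphic trait is not
#' a silent success: the fit is returned with `boundary = TRUE`.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` or `"ARD"`.
#' @param n_starts Number of multi-start initial values (minimum 5).
#' @return An object of class `mk_fit`: rates, model class, log-likelihood,
#'   convergence and boundary flags, root treatment.
#' @export
fit_mk <- function(tree, y, model = c("ARD", "ER"),
                   root = c("flat", "stationary", "fixed"),
                   root_state = 0L, n_starts = 5) {
  model <- match.arg(model)
  root <- match.arg(root)
  n_starts <- max(5L, as.integer(n_starts))
  validate_tree(tree)
  prep <- .mk_prepare(tree, y)

  boundary <- length(unique(prep$y)) < 2L
  if (boundary) {
    warning("trait is monomorphic; rate estimates lie on the boundary",
            call. = FALSE)
  }

  depth <- max(ape::node.depth.edgelength(tree))
  if (depth <= 0) stop("tree has zero depth", call. = FALSE)
  base_rates <- 10^seq(-4, 0, length.out = n_starts) / depth

  nll <- function(lp) {
    q <- exp(lp)
    if (model == "ER") q <- c(q, q)
    prior <- .mk_root_prior(root, q[1], q[2], root_state)
    ll <- .mk_prune(prep, q[1], q[2], prior)$loglik
    if (!is.finite(ll)) 1e12 else -ll
  }

  best <- NULL
  if (model == "ER") {
    for (r in base_rates) {
      o <- stats::optim(log(r), nll, method = "Brent",
                        lower = log(1e-9 / depth), upper = log(1e4 / depth),
                        control = list(reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    q01 <- q10 <- exp(best$par)
  } else {
    starts <- lapply(base_rates, function(r) log(c(r, r)))
    # asymmetric starts plus the ER optimum as a safeguard
    starts <- c(starts,
                list(log(c(base_rates[2], base_rates[n_starts])),
                     log(c(base_rates[n_starts], base_rates[2]))))
    er <- fit_mk(tree, y, model = "ER", root = root, root_state = root_state,
                 n_starts = n_starts)
    starts <- c(starts, list(log(c(max(er$q01, 1e-12), max(er$q10, 1e-12)))))
    for (s0 in starts) {
      o <- stats::optim(s0, nll, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 2000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    q <- exp(best$par)
    q01 <- q[1]; q10 <- q[2]
  }

  structure(list(
    q01 = q01, q10 = q10, model = model,
    loglik = -best$value,
    converged = (best$convergence == 0),
    boundary = boundary,
    root = root, root_state = root_state,
    n_tips = prep$ntip
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk %s fit (%d tips, root prior: %s)\n", x$model, x$n_tips,
              x$root))
  cat(sprintf("  gain rate q01 = %.6g\n  loss rate q10 = %.6g\n",
              x$q01, x$q10))
  cat(sprintf("  log-likelihood = %.4f%s%s\n", x$loglik,
              if (!x$converged) " (NOT converged)" else "",
              if (x$boundary) " (boundary: monomorphic trait)" else ""))
  invisible(x)
}

#' Likelihood-ratio test of ER against ARD
#'
#' The equal-rates model is the one-parameter restriction `q01 = q10` of
#' the two-parameter all-rates-different model, so twice the log-likelihood
#' difference is referred to a chi-squared distribution with 1 degree of
#' freedom.
#'
#' @param fit_er,fit_ard `mk_fit` objects from the same tree and data.
#' @param tol Tolerance for a slightly negative statistic due to optimizer
#'   round-off (clamped to 0).
#' @return A list with `statistic`, `df` (1) and `p`.
#' @export
lrt_er_vs_ard <- function(fit_er, fit_ard, tol = 1e-6) {
  if (fit_er$model != "ER" || fit_ard$model != "ARD") {
    stop("arguments must be an ER fit and an ARD fit", call. = FALSE)
  }
  if (fit_er$n_tips != fit_ard$n_tips) {
    stop("fits come from different data", call. = FALSE)
  }
  stat <- 2 * (fit_ard$loglik - fit_er$loglik)
  if (stat < -tol) {
    stop("ARD log-likelihood below ER beyond tolerance: optimizer failure",
         call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Marginal ancestral state probabilities
#'
#' For every internal node, the posterior probability of each state given
#' all tip data, combining the postorder (pruning) pass with a preorder
#' pass. Probabilities at each node sum to 1.
#'
#' @inheritParams mk_loglik
#' @param fit An `mk_fit` (its rates and root treatment are used).
#' @return A matrix (rows = nodes in ape numbering, tips included) with
#'   columns `p0`, `p1`.
#' @export
marginal_asr <- function(tree, y, fit) {
  validate_tree(tree)
  prep <- .mk_prepare(tree, y)
  q01 <- fit$q01; q10 <- fit$q10
  prior <- .mk_root_prior(fit$root, q01, q10, fit$root_state)
  down <- .mk_prune(prep, q01, q10, prior)
  if (!is.finite(down$loglik)) stop("data impossible under fit", call. = FALSE)

  nn <- prep$ntip + prep$nnode
  U <- matrix(0, nn, 2)        # "above" partials, rescaled per node
  U[prep$root, ] <- prior
  kids <- split(seq_along(prep$parent), prep$parent)

  # preorder = reverse postorder over edges
  for (i in rev(seq_along(prep$parent))) {
    pa <- prep$parent[i]; ch <- prep$child[i]; t <- prep$len[i]
    P_ch <- mk_transition_prob(q01, q10, t)
    sibs <- setdiff(prep$child[kids[[as.character(pa)]]], ch)
    a <- U[pa, ]
    for (sb in sibs) {
      ti <- prep$len[match(sb, prep$child)]
      Ps <- mk_transition_prob(q01, q10, ti)
      a <- a * as.vector(Ps %*% down$L[sb, ])
    }
    u <- as.vector(a %*% P_ch)
    f <- sum(u)
    U[ch, ] <- if (f > 0) u / f else u
  }

  post <- down$L * U
  post <- post / rowSums(post)
  colnames(post) <- c("p0", "p1")
  post
}
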