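# Phylogenetic logistic regression: a latent-liability logistic model with
# tree-structured random effects (strength alpha), fitted by penalized
# maximum likelihood (Firth-type adjustment) with a Laplace approximation
# over the latent field, plus a likelihood-based R-squared and a model
# screen ranked by AIC.

# phylogenetic correlation matrix: shared-path covariance scaled to unit
# diagonal, tips in tree order
phylo_corr <- function(tree) {
  V <- ape::vcv(tree)
  stats::cov2cor(V)
}

.bernoulli_ll <- function(y, eta) {
  sum(y * eta - log1p(exp(eta)))
}

# Firth-adjusted IRLS for ordinary logistic regression (alpha = 0 limit);
# step-halving on the penalized objective keeps separated data convergent
.firth_logistic <- function(X, y, penalty = TRUE, maxit = 200, tol = 1e-12) {
  p <- ncol(X)
  beta <- numeric(p)
  obj <- function(beta) {
    eta <- drop(X %*% beta)
    o <- .bernoulli_ll(y, eta)
    if (penalty) {
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      o <- o + 0.5 * as.numeric(
        determinant(t(X * w) %*% X, logarithm = TRUE)$modulus)
    }
    o
  }
  cur <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtW <- t(X * w)
    I_mat <- XtW %*% X
    ystar <- y
    if (penalty) {
      Xw <- X * sqrt(w)
      h <- rowSums((Xw %*% solve(I_mat)) * Xw)
      ystar <- y + h * (0.5 - mu)
    }
    score <- drop(t(X) %*% (ystar - mu))
    step <- solve(I_mat, score)
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      new <- obj(beta_new)
      if (new >= cur - 1e-10 || lam < 1e-4 || !penalty) break
      lam <- lam / 2
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    cur <- new
    if (moved < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  I_mat <- t(X * w) %*% X
  list(beta = beta, eta = eta, loglik = .bernoulli_ll(y, eta),
       vcov = solve(I_mat), converged = it < maxit, b = numeric(length(y)))
}

# joint penalized Newton fit of (beta, b) at fixed alpha > 0
.pglm_inner <- function(X, y, Cinv, alpha, penalty = TRUE,
                        maxit = 200, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  K <- Cinv / alpha
  beta <- numeric(p); b <- numeric(n)
  obj <- function(beta, b) {
    eta <- drop(X %*% beta) + b
    o <- .bernoulli_ll(y, eta) - 0.5 * drop(b %*% (K %*% b))
    if (penalty) {
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      o <- o + 0.5 * determinant(t(X * w) %*% X, logarithm = TRUE)$modulus
    }
    o
  }
  cur <- obj(beta, b)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + b
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    ystar <- y
    if (penalty) {
      I_beta <- t(X * w) %*% X
      Xw <- X * sqrt(w)
      h <- rowSums((Xw %*% solve(I_beta)) * Xw)
      ystar <- y + h * (0.5 - mu)
    }
    r <- ystar - mu
    score <- c(drop(t(X) %*% r), r - drop(K %*% b))
    H <- rbind(cbind(t(X * w) %*% X, t(X * w)),
               cbind(X * w, diag(w, n) + K))
    step <- solve(H, score)
    lam <- 1
    repeat {
      beta_new <- beta + lam * step[seq_len(p)]
      b_new <- b + lam * step[p + seq_len(n)]
      new <- obj(beta_new, b_new)
      if (new >= cur - 1e-8 || lam < 1e-4) break
      lam <- lam / 2
    }
    moved <- max(abs(c(beta_new - beta, b_new - b)))
    beta <- beta_new; b <- b_new; cur <- new
    if (moved < tol) break
  }
  eta <- drop(X %*% beta) + b
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  list(beta = beta, b = b, eta = eta, w = w, K = K,
       converged = it < maxit)
}

# Laplace-approximate marginal log-likelihood (unpenalized) at a fitted mode
.pglm_marginal_ll <- function(fit, X, y, C, alpha) {
  eta <- fit$eta
  if (alpha == 0) return(.bernoulli_ll(y, eta))
  quad <- 0.5 * drop(fit$b %*% (fit$K %*% fit$b))
  n <- length(y)
  ld <- determinant(diag(n) + alpha * (C * rep(fit$w, each = n)), # aC %*% diag(w)
                    logarithm = TRUE)$modulus
  .bernoulli_ll(y, eta) - quad - 0.5 * as.numeric(ld)
}

#' Phylogenetic logistic regression
#'
#' Regresses a binary species trait on standardized covariates while
#' accounting for phylogenetic non-independence through a latent liability:
#' `logit P(y_i = 1) = x_i' beta + b_i`, with `b ~ N(0, alpha * C)` where
#' `C` is the tree's shared-path correlation matrix (off-diagonal entries
#' decay with phylogenetic distance) and `alpha >= 0` measures the strength
#' of the tree-structured correlation. Estimation is by penalized maximum
#' likelihood -- a Firth-type adjustment keeps estimates finite under
#' complete separation -- with a Laplace approximation over the latent
#' field; `alpha` is chosen by maximizing the Laplace marginal likelihood
#' (the boundary `alpha = 0`, ordinary logistic regression, is always a
#' candidate). On a star phylogeny there is no shared history (`C` is the
#' identity) and the phylogenetic component is unidentifiable from binary
#' data, so `alpha` is fixed at 0 and the fit reduces to (Firth) logistic
#' regression.
#'
#' @param dataset Data frame with a binary `y` column and covariate
#'   columns (see [build_analysis_dataset()]); one row per species in tree
#'   tip order or carrying a `species` column matched against the tips.
#' @param tree A `phylo` object.
#' @param covariates Character vector of covariate columns; default: every
#'   numeric column except `y`.
#' @param penalty `"firth"` (default) or `"none"`.
#' @param alpha `NULL` to estimate, or a fixed non-negative value.
#' @return Object of class `pglm_fit`: `coefficients` table (estimate, SE,
#'   z, p), `alpha`, `loglik` (Laplace marginal), `n`, `converged`,
#'   `separation` flag.
#' @export
fit_phylogistic <- function(dataset, tree, covariates = NULL,
                            penalty = c("firth", "none"), alpha = NULL) {
  penalty <- match.arg(penalty)
  use_pen <- penalty == "firth"
  validate_tree(tree)

  if ("species" %in% names(dataset)) {
    miss <- setdiff(dataset$species, tree$tip.label)
    if (length(miss)) {
      stop("species not in tree: ", paste(utils::head(miss, 5),
           collapse = ", "), call. = FALSE)
    }
    tree <- ape::keep.tip(tree, dataset$species)
    dataset <- dataset[match(tree$tip.label, dataset$species), , drop = FALSE]
  } else if (nrow(dataset) != ape::Ntip(tree)) {
    stop("dataset rows must match tree tips (or supply a species column)",
         call. = FALSE)
  }

  y <- dataset$y
  if (is.null(y) || !all(y %in% c(0, 1))) {
    stop("dataset must contain a binary 'y' column", call. = FALSE)
  }
  if (length(unique(y)) < 2L) stop("response has a single class", call. = FALSE)

  if (is.null(covariates)) {
    covariates <- setdiff(names(dataset)[vapply(dataset, is.numeric,
                                                logical(1))], "y")
  }
  miss <- setdiff(covariates, names(dataset))
  if (length(miss)) stop("covariates absent from dataset: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dataset[, covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular covariate matrix; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  C <- phylo_corr(tree)
  n <- nrow(X); p <- ncol(X)
  star_like <- max(abs(C[upper.tri(C)])) < 1e-10

  fit_at <- function(a) {
    if (a == 0) {
      f <- .firth_logistic(X, y, penalty = use_pen)
      list(fit = f, ll = .bernoulli_ll(y, f$eta))
    } else {
      f <- .pglm_inner(X, y, Cinv, a, penalty = use_pen)
      list(fit = f, ll = .pglm_marginal_ll(f, X, y, C, a))
    }
  }

  if (star_like || identical(alpha, 0)) {
    alpha_hat <- 0
    Cinv <- NULL
    best <- fit_at(0)
  } else {
    Cinv <- solve(C + diag(1e-10, n))
    if (!is.null(alpha)) {
      alpha_hat <- alpha
      best <- fit_at(alpha)
    } else {
      base <- fit_at(0)
      opt <- stats::optimize(function(la) fit_at(exp(la))$ll,
                             interval = c(log(1e-3), log(50)), maximum = TRUE,
                             tol = 1e-3)
      if (opt$objective > base$ll + 1e-6) {
        alpha_hat <- exp(opt$maximum)
        best <- fit_at(alpha_hat)
      } else {
        alpha_hat <- 0
        best <- base
      }
    }
  }

  f <- best$fit
  w <- if (alpha_hat == 0) {
    mu <- stats::plogis(f$eta); pmax(mu * (1 - mu), 1e-12)
  } else f$w
  if (alpha_hat == 0) {
    vc <- f$vcov
  } else {
    XtWX <- t(X * w) %*% X
    A <- solve(diag(w, n) + f$K, X * w)      # (W + K)^{-1} W X
    vc <- solve(XtWX - t(X * w) %*% A)
  }
  se <- sqrt(diag(vc))
  z <- f$beta / se
  coef_tab <- data.frame(
    term = colnames(X), estimate = f$beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), row.names = NULL
  )

  # complete separation along the fitted direction: the linear predictor
  # perfectly orders the classes (Firth keeps such fits finite)
  eta_fix <- drop(X %*% f$beta)
  sep <- length(unique(y)) == 2 && ncol(X) > 1 &&
    min(eta_fix[y == 1]) >= max(eta_fix[y == 0])

  structure(list(
    coefficients = coef_tab, alpha = alpha_hat,
    loglik = best$ll, n = n, vcov = vc,
    converged = f$converged,
    separation = sep || max(abs(f$beta)) > 10,
    penalty = penalty, covariates = covariates
  ), class = "pglm_fit")
}

#' @export
print.pglm_fit <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic logistic regression (n = %d, alpha = %.4g, logLik = %.3f)\n",
    x$n, x$alpha, x$loglik))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), se = signif(se, 4),
                  z = signif(z, 3), p = signif(p, 3)), row.names = FALSE)
  if (x$separation) cat("note: possible complete separation (penalized fit)\n")
  invisible(x)
}

#' Likelihood-based R-squared for nested fits
#'
#' `R2 = 1 - exp(-(2/n) (ll_full - ll_null))`, clamped to `[0, 1)`.
#'
#' @param fit_full,fit_null `pglm_fit` objects on the same data, null
#'   nested in full. For a clean comparison fit the null with `alpha`
#'   fixed at the full model's estimate.
#' @param tol Tolerance for `ll_full < ll_null` before erroring (default
#'   0.25). Log-likelihoods are Laplace approximations evaluated at
#'   Firth-penalized modes, so a full model whose extra covariates are
#'   uninformative can sit as much as a few tenths below the null; such
#'   deficits clamp to R-squared 0, while larger ones indicate non-nested
#'   fits or optimizer failure.
#' @return R-squared in `[0, 1)`.
#' @export
r2_lik <- function(fit_full, fit_null, tol = 0.25) {
  if (fit_full$n != fit_null$n) stop("fits are not on the same data",
                                     call. = FALSE)
  dll <- fit_full$loglik - fit_null$loglik
  if (dll < -tol) stop("full model log-likelihood below null: not nested ",
                       "or optimizer failure", call. = FALSE)
  dll <- max(dll, 0)
  min(1 - exp(-(2 / fit_full$n) * dll), 1 - 1e-12)
}

#' Screen covariate sets for predicting the trait
#'
#' Fits each covariate set by [fit_phylogistic()], computes AIC on the
#' (penalized) likelihood and the likelihood R-squared against the
#' intercept-only null, and ranks by AIC (ties broken by declaration
#' order). When `clade` names a logical/binary column of the dataset, the
#' screen is additionally run on each partition (e.g. passerines vs
#' non-passerines).
#'
#' @param dataset,tree As in [fit_phylogistic()].
#' @param covariate_sets Named list of character vectors.
#' @param clade Optional name of a 0/1 partition column.
#' @return Data frame ranked by AIC within each partition, with columns
#'   `partition`, `set`, `k`, `loglik`, `aic`, `r2`, `rank`.
#' @export
model_screen <- function(dataset, tree, covariate_sets, clade = NULL) {
  if (!length(covariate_sets)) stop("need at least one covariate set",
                                    call. = FALSE)
  if (is.null(names(covariate_sets))) {
    names(covariate_sets) <- paste0("set", seq_along(covariate_sets))
  }
  parts <- list(all = rep(TRUE, nrow(dataset)))
  if (!is.null(clade)) {
    if (!clade %in% names(dataset)) stop("clade column '", clade,
                                         "' absent from dataset",
                                         call. = FALSE)
    parts <- c(parts, stats::setNames(
      list(dataset[[clade]] == 1, dataset[[clade]] == 0),
      paste0(clade, c("=1", "=0"))))
  }
  out <- list()
  for (pn in names(parts)) {
    ds <- dataset[parts[[pn]], , drop = FALSE]
    tr <- if ("species" %in% names(ds)) ape::keep.tip(tree, ds$species) else tree
    rows <- lapply(seq_along(covariate_sets), function(i) {
      cs <- covariate_sets[[i]]
      miss <- setdiff(cs, names(ds))
      if (length(miss)) stop("covariate absent from dataset: ",
                             paste(miss, collapse = ", "), call. = FALSE)
      f <- fit_phylogistic(ds, tr, covariates = cs)
      # null at the same alpha so the R-squared comparison is nested
      null_fit <- fit_phylogistic(ds, tr, covariates = character(0),
                                  alpha = f$alpha)
      k <- length(cs) + 1L + as.integer(f$alpha > 0)
      data.frame(partition = pn, set = names(covariate_sets)[i], k = k,
                 loglik = f$loglik, aic = -2 * f$loglik + 2 * k,
                 r2 = r2_lik(f, null_fit), declared = i)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$aic, tab$declared), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    out[[pn]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$declared <- NULL
  res
}
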