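# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's own code paths: transition probabilities come from a
# matrix exponential, likelihoods from exhaustive enumeration over
# internal-node states, marginals from brute-force Bayes.

# matrix-exponential transition probabilities (independent of the
# closed form used inside the package)
oracle_P <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  as.matrix(Matrix::expm(Q * t))
}

# exhaustive-enumeration Mk likelihood: sum over all internal-state
# assignments of products of transition probabilities
oracle_mk_lik <- function(tree, y, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  root <- ntip + 1L
  Pcache <- lapply(seq_len(nrow(tree$edge)), function(i) {
    oracle_P(q01, q10, tree$edge.length[i])
  })
  grid <- as.matrix(expand.grid(rep(list(0:1), nn)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- c(as.integer(y[tree$tip.label]), as.integer(grid[r, ]))
    pr <- prior[st[root] + 1L]
    for (i in seq_len(nrow(tree$edge))) {
      pr <- pr * Pcache[[i]][st[tree$edge[i, 1]] + 1L,
                             st[tree$edge[i, 2]] + 1L]
    }
    tot <- tot + pr
  }
  tot
}

# brute-force marginal posterior P(state = 1) for every node
oracle_marginals <- function(tree, y, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  root <- ntip + 1L
  Pcache <- lapply(seq_len(nrow(tree$edge)), function(i) {
    oracle_P(q01, q10, tree$edge.length[i])
  })
  grid <- as.matrix(expand.grid(rep(list(0:1), nn)))
  joint <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    st <- c(as.integer(y[tree$tip.label]), as.integer(grid[r, ]))
    pr <- prior[st[root] + 1L]
    for (i in seq_len(nrow(tree$edge))) {
      pr <- pr * Pcache[[i]][st[tree$edge[i, 1]] + 1L,
                             st[tree$edge[i, 2]] + 1L]
    }
    joint[r] <- pr
  }
  joint <- joint / sum(joint)
  vapply(seq_len(nn), function(k) sum(joint[grid[, k] == 1]), numeric(1))
}

# random bifurcating tree with exponential branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# tiny per-specimen trait table used across dataset tests
toy_trait_table <- function() {
  data.frame(
    species = c("A", "A", "B", "C", "D", "D"),
    sex     = c("M", "F", "F", "M", "M", "F"),
    region  = "head",
    skin    = c("black", "non-black", "non-black", "non-black",
                "non-black", "black"),
    feather = c("white", "white", "brown", "black", "brown", "brown"),
    mass_g  = c(100, 110, 250, 50, 500, 480),
    uv_b    = c(4000, 4100, 2000, 3000, 5000, 5100),
    genus   = c("g1", "g1", "g1", "g2", "g3", "g3"),
    family  = c("f1", "f1", "f1", "f1", "f2", "f2"),
    stringsAsFactors = FALSE
  )
}

toy_tree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}
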