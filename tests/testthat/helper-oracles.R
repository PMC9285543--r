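# Independent oracles used across the suite. These deliberately use direct
# matrix inversion / closed forms, never the package's own fast paths.

# Generalized least squares closed form (X' C^-1 X)^-1 X' C^-1 y.
gls_oracle <- function(x, y, C) {
  X <- cbind(1, x)
  Ci <- solve(C)
  drop(solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y))
}

# Brute-force multivariate normal log density by direct inversion and
# determinant.
mvn_logdens_brute <- function(y, mu, S) {
  r <- y - mu
  n <- length(y)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  drop(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(S) %*% r))
}

# Root-to-tip path lengths of every tip, by walking edges (independent of
# ape's node.depth.edgelength).
tip_depths_brute <- function(tree) {
  ntip <- ape::Ntip(tree)
  depths <- numeric(ntip)
  for (i in seq_len(ntip)) {
    d <- 0
    node <- i
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      d <- d + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    depths[i] <- d
  }
  stats::setNames(depths, tree$tip.label)
}

# A random tree with a few internal branches collapsed to zero.
random_zero_branch_tree <- function(n_tips, n_zero = 2, seed = 1) {
  tree <- simulate_tree(n_tips, seed = seed)
  internal <- which(tree$edge[, 2] > ape::Ntip(tree) &
                      tree$edge[, 1] != ape::Ntip(tree) + 1L)
  set.seed(seed)
  zap <- sample(internal, min(n_zero, length(internal)))
  # push the removed time down into child edges so depths stay sensible
  for (e in zap) {
    child <- tree$edge[e, 2]
    kids <- which(tree$edge[, 1] == child)
    tree$edge.length[kids] <- tree$edge.length[kids] + tree$edge.length[e]
    tree$edge.length[e] <- 0
  }
  tree
}

fast_config <- function(seed = 1, chains = 1) {
  ppm_config(iterations = 600, burnin = 150, thin = 1, chains = chains,
             seed = seed)
}
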