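# Independent oracles and small fixtures used across the test files.

# a reproducible, non-trivial model
fixture_model <- function(seed = 1, magnitude = 0.5, gc = 0.5,
                          alpha = 0.8) {
  m <- perturb_model(synthetic_base_model(gc), magnitude, seed = seed,
                     name = sprintf("fix%d", seed))
  m$alpha <- alpha
  m
}

# convert this package's pair storage (row-major lower triangle) to
# phangorn's Q vector (column-major lower triangle)
phangorn_Q <- function(R) {
  M <- matrix(0, 20, 20)
  k <- 0
  for (i in 2:20) {
    for (j in 1:(i - 1)) {
      k <- k + 1
      M[i, j] <- M[j, i] <- R[k]
    }
  }
  M[lower.tri(M)]
}

# phangorn log-likelihood with a custom Q (independent oracle for the
# pruning engine)
phangorn_loglik <- function(msa, tree, model, k = 1, shape = 1,
                            inv = 0) {
  pd <- phangorn::phyDat(msa$seq, type = "AA")
  fit <- phangorn::pml(tree, pd, bf = model$pi, Q = phangorn_Q(model$R),
                       k = k, shape = shape, inv = inv)
  fit$logLik
}

# brute-force pruning oracle on a small alphabet: enumerates every
# assignment of states to internal nodes. Q is ns x ns; msa_codes is an
# integer matrix (ntip x nsites, 1-based states).
enumerate_loglik <- function(tree, Q, pi, msa_codes, rate = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ns <- length(pi)
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1]
  internals <- (ntip + 1):nnode
  e <- eigen(Q)
  Plist <- lapply(seq_len(nrow(tr$edge)), function(i) {
    P <- Re(e$vectors %*% diag(exp(e$values * tr$edge.length[i] * rate)) %*%
              solve(e$vectors))
    pmax(P, 0)
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(internals))))
  loglik <- 0
  for (site in seq_len(ncol(msa_codes))) {
    state <- integer(nnode)
    state[seq_len(ntip)] <- msa_codes[, site]
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      state[internals] <- grid[g, ]
      term <- pi[state[root]]
      for (i in seq_len(nrow(tr$edge))) {
        term <- term * Plist[[i]][state[tr$edge[i, 1]], state[tr$edge[i, 2]]]
      }
      lik <- lik + term
    }
    loglik <- loglik + log(lik)
  }
  loglik
}

# run the package's compiled pruning core on an arbitrary-size alphabet
plik_direct <- function(tree, Q, pi, msa_codes, rate = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  eig <- protspace:::.eigen_q(Q, pi)
  res <- protspace:::cpp_plik(
    tr$edge, tr$edge.length, length(tr$tip.label),
    t(msa_codes) - 1L, rep(1, ncol(msa_codes)),
    eig$U, eig$lambda, eig$Uinv, pi,
    rate, 1, 0, rep(-2L, ncol(msa_codes)), FALSE)
  res$loglik
}

# brute-force minimum-cost perfect matching over all permutations
brute_matching <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# brute-force matching split distance for small binary trees
brute_msd <- function(t1, t2) {
  leaves <- sort(t1$tip.label)
  s1 <- protspace:::.tree_splits(t1, leaves)
  s2 <- protspace:::.tree_splits(t2, leaves)
  n <- length(leaves)
  ham <- outer(seq_len(nrow(s1)), seq_len(nrow(s2)),
               Vectorize(function(i, j) sum(s1[i, ] != s2[j, ])))
  brute_matching(pmin(ham, n - ham))
}

# reference gamma bin means by adaptive quadrature
quadrature_gamma_rates <- function(alpha, k) {
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  vapply(seq_len(k), function(i) {
    k * stats::integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                         q[i], q[i + 1], rel.tol = 1e-12)$value
  }, numeric(1))
}
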