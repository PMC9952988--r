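# Model space: Euclidean distances among normalized exchangeability
# vectors, neighbor-joining trees of models, matching split distance
# between trees, and the random-tree null test.

#' Euclidean distance between two models
#'
#' Both exchangeability vectors are normalized to sum to one and the
#' Euclidean norm of their difference is returned. Frequencies do not
#' enter the distance (set `include_frequencies = TRUE` to append them
#' for exploration).
#'
#' @param m1,m2 [substitution_model()] objects.
#' @param include_frequencies append the frequency vectors to the
#'   compared vectors (default FALSE).
#' @return Non-negative numeric distance.
#' @export
#' @examples
#' b <- synthetic_base_model()
#' model_distance(b, b)  # 0
model_distance <- function(m1, m2, include_frequencies = FALSE) {
  stopifnot(inherits(m1, "substitution_model"),
            inherits(m2, "substitution_model"))
  v1 <- normalize_exchangeabilities(m1$R)
  v2 <- normalize_exchangeabilities(m2$R)
  if (include_frequencies) {
    v1 <- c(v1, m1$pi)
    v2 <- c(v2, m2$pi)
  }
  sqrt(sum((v1 - v2)^2))
}

#' Pairwise distance matrix over a set of models
#'
#' @param models named list of [substitution_model()] objects (names
#'   default to each model's own name).
#' @param include_frequencies see [model_distance()].
#' @return A symmetric matrix with zero diagonal and model names as
#'   dimnames, of class `model_distance_matrix`.
#' @export
model_distance_matrix <- function(models, include_frequencies = FALSE) {
  stopifnot(length(models) >= 2L)
  nm <- names(models)
  if (is.null(nm)) nm <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("model names must be unique")
  n <- length(models)
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <-
        model_distance(models[[i]], models[[j]], include_frequencies)
    }
  }
  class(D) <- c("model_distance_matrix", "matrix")
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou–Nei agglomeration: repeatedly joins the pair minimizing the
#' rate-corrected criterion `(n-2) d_ij - R_i - R_j`; ties are broken
#' deterministically by lexicographic order of the pair's labels. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' adjacent sister branch, preserving path lengths. Applied to exactly
#' additive distances it recovers the generating tree.
#'
#' @param D symmetric numeric matrix with labels as dimnames (e.g. a
#'   `model_distance_matrix`), at least 3 x 3.
#' @return An ape `phylo` (unrooted).
#' @export
neighbor_joining <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 items")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("m", seq_len(n))

  # active cluster -> phylo node id; tips 1..n, internals n+1 ...
  node <- seq_len(n)
  names(node) <- labels
  edges <- NULL      # rows: parent, child, length
  nextnode <- n + 1L
  act <- labels

  repeat {
    r <- length(act)
    if (r == 3L) break
    Dm <- D[act, act]
    R <- rowSums(Dm)
    qmat <- (r - 2) * Dm - outer(R, R, "+")
    diag(qmat) <- Inf
    # deterministic tie-break: smallest Q, then lexicographic pair label
    best <- which(qmat <= min(qmat) + 1e-12, arr.ind = TRUE)
    pair_lab <- apply(best, 1, function(ij) {
      paste(sort(c(act[ij[1]], act[ij[2]])), collapse = "\r")
    })
    pick <- best[order(pair_lab)[1L], ]
    i <- act[pick[1L]]; j <- act[pick[2L]]
    vi <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- Dm[i, j] - vi
    # clamp negatives, transferring length to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    u <- nextnode; nextnode <- nextnode + 1L
    edges <- rbind(edges, c(u, node[i], vi), c(u, node[j], vj))
    newlab <- paste0("&", u)
    duk <- (D[i, act] + D[j, act] - D[i, j]) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- newlab
    D[newlab, act] <- D[act, newlab] <- duk
    D[newlab, newlab] <- 0
    act <- c(setdiff(act, c(i, j)), newlab)
    node[newlab] <- u
  }

  # final 3-point join
  a <- act[1L]; b <- act[2L]; c3 <- act[3L]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  vc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  u <- nextnode
  edges <- rbind(edges,
                 c(u, node[a], max(va, 0)),
                 c(u, node[b], max(vb, 0)),
                 c(u, node[c3], max(vc, 0)))

  # renumber internals so the root-most is n+1 (ape convention is tips
  # 1..n then internals; any consistent numbering works for phylo)
  emat <- edges[, 1:2, drop = FALSE]
  internal_ids <- sort(unique(emat[emat > n]))
  remap <- integer(max(emat))
  remap[seq_len(n)] <- seq_len(n)
  remap[internal_ids] <- n + rev(seq_along(internal_ids))
  emat[] <- remap[emat]
  storage.mode(emat) <- "integer"
  tr <- structure(list(edge = emat,
                       edge.length = edges[, 3L],
                       tip.label = labels,
                       Nnode = length(internal_ids)),
                  class = "phylo")
  ape::reorder.phylo(tr, "postorder")
}

# nontrivial splits of an unrooted binary tree as a logical matrix
# (rows = splits, columns = leaves in `leaf_order`)
.tree_splits <- function(tree, leaf_order) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  below <- matrix(FALSE, max(tr$edge), n)
  below[cbind(seq_len(n), match(tree$tip.label, leaf_order))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  internal <- tr$edge[, 2L] > n
  sp <- below[tr$edge[internal, 2L], , drop = FALSE]
  keep <- rowSums(sp) >= 2 & rowSums(sp) <= n - 2
  sp[keep, , drop = FALSE]
}

# Hungarian algorithm (shortest augmenting paths with potentials);
# cost is an n x n matrix, returns the minimum total assignment cost
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)        # predecessor column on the augmenting path
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L                # virtual start column
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      sel <- used
      u[p[sel]] <- u[p[sel]] + delta
      v[sel] <- v[sel] - delta
      minv[!sel] <- minv[!sel] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  sum(cost[cbind(p[seq_len(n)], seq_len(n))])
}

#' Matching split distance between two binary trees
#'
#' Collects the nontrivial bipartitions of each (unrooted, binary) tree as
#' leaf-membership indicator vectors, scores a pair of splits by the
#' smaller of their Hamming distance and its complement, and returns the
#' cost of the minimum-weight perfect matching between the two split sets
#' (both of size n-3), found with the Hungarian algorithm. Branch lengths
#' are ignored. This is a metric on binary topologies: it is zero exactly
#' for identical topologies.
#'
#' @param t1,t2 ape `phylo` trees on the same leaf set, fully resolved.
#' @return Integer distance.
#' @export
#' @examples
#' a <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' b <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
#' matching_split_distance(a, b)  # 2
matching_split_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  leaves <- sort(t1$tip.label)
  if (!identical(sort(t2$tip.label), leaves))
    stop("trees must share an identical leaf set")
  n <- length(leaves)
  if (!ape::is.binary(ape::unroot(t1)) || !ape::is.binary(ape::unroot(t2)))
    stop("matching split distance is defined here for binary trees only")
  s1 <- .tree_splits(t1, leaves)
  s2 <- .tree_splits(t2, leaves)
  if (nrow(s1) != nrow(s2))
    stop("internal error: unequal split counts for binary trees")
  if (nrow(s1) == 0L) return(0L)
  # pairwise costs: min(hamming, n - hamming)
  X1 <- s1 * 1; X2 <- s2 * 1
  agree <- X1 %*% t(X2) + (1 - X1) %*% t(1 - X2)
  ham <- n - agree
  cost <- pmin(ham, n - ham)
  as.integer(round(.hungarian(cost)))
}

#' Random-tree null test for tree congruence
#'
#' Tests whether an observed tree is closer to a reference tree than
#' expected by chance: draws `n_random` topologies uniformly from all
#' labeled binary topologies on the same leaf set, computes the matching
#' split distance of each to the reference, and reports the empirical
#' one-sided p-value `(1 + #{null <= observed}) / (n_random + 1)`.
#'
#' @param reference,observed ape `phylo` trees on the same leaf set.
#' @param n_random number of null draws.
#' @param seed optional integer seed.
#' @return An object of class `null_test_result`: list with `observed`
#'   (distance), `null_sample`, `n_random`, `p_value`, `histogram`
#'   (counts by distance, bins labeled by bin minimum).
#' @export
random_tree_null <- function(reference, observed, n_random = 1000L,
                             seed = NULL) {
  stopifnot(inherits(reference, "phylo"), inherits(observed, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  obs <- matching_split_distance(reference, observed)
  labs <- reference$tip.label
  null_sample <- vapply(seq_len(n_random), function(i) {
    rt <- generate_random_topology(length(labs), labels = sample(labs))
    matching_split_distance(reference, rt)
  }, integer(1))
  p <- (1 + sum(null_sample <= obs)) / (n_random + 1)
  breaks <- seq(0L, max(c(null_sample, obs)) + 5L, by = 5L)
  h <- table(cut(null_sample, c(breaks, Inf), right = FALSE,
                 labels = breaks))
  structure(list(observed = obs, null_sample = null_sample,
                 n_random = as.integer(n_random), p_value = p,
                 histogram = h),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat("random-tree null test:\n  observed matching distance:",
      x$observed, "\n  null range: [", min(x$null_sample), ",",
      max(x$null_sample), "] over", x$n_random, "draws\n",
      " empirical p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
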