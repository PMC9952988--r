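test_that("model distances are normalized Euclidean distances on REs", {
  m <- fixture_model(seed = 1)
  expect_identical(model_distance(m, m), 0)
  # invariance to rescaling of exchangeabilities
  m2 <- m
  m2$R <- 37 * m$R
  expect_equal(model_distance(m, m2), 0)
  # +delta on one pair, -delta on another: distance delta * sqrt(2)
  v <- normalize_exchangeabilities(rep(1, 190))
  delta <- 1e-3
  w <- v
  w[3] <- w[3] + delta
  w[10] <- w[10] - delta
  ma <- substitution_model("a", v, rep(0.05, 20))
  mb <- substitution_model("b", w, rep(0.05, 20))
  expect_equal(model_distance(ma, mb), delta * sqrt(2),
               tolerance = 1e-12)
  # frequencies do not enter by default
  mc <- substitution_model("c", v, codon_frequencies(0.7))
  expect_equal(model_distance(ma, mc), 0)
  expect_gt(model_distance(ma, mc, include_frequencies = TRUE), 0)

  D <- model_distance_matrix(list(a = ma, b = mb, c = mc))
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("neighbor joining solves additive distances exactly", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  # topology AB|CD
  expect_equal(matching_split_distance(
    tr, parse_newick("((A:1,B:1):1,(C:1,D:1):1);")), 0L)
  # exact branch lengths A:1 B:2 C:3 D:4 internal:1
  tip_len <- tr$edge.length[match(seq_len(4), tr$edge[, 2])]
  expect_equal(tip_len[match(LETTERS[1:4], tr$tip.label)], c(1, 2, 3, 4),
               tolerance = 1e-12)
  expect_equal(tr$edge.length[tr$edge[, 2] > 4], 1, tolerance = 1e-12)

  # three items: closed-form three-point solution
  D3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(D3)
  len <- t3$edge.length[match(1:3, t3$edge[, 2])]
  names(len) <- t3$tip.label[1:3]
  expect_equal(unname(len[c("a", "b", "c")]), c(0, 2, 3))

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric|at least 3")
})

test_that("neighbor joining matches an independent implementation", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    X <- matrix(runif(n * 3), n)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("m", 1:n), paste0("m", 1:n))
    mine <- neighbor_joining(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(mine, ape::unroot(ref)), 0)
  }
})

test_that("group-structured model sets yield the group bipartition", {
  base <- synthetic_base_model(0.5)
  hits <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    g1 <- lapply(1:4, function(j)
      perturb_model(perturb_model(base, 1.5, seed = 7000 + i,
                                  name = "g1"),
                    0.3, seed = 100 * i + j,
                    name = paste0("a", j)))
    g2 <- lapply(1:4, function(j)
      perturb_model(perturb_model(base, 1.5, seed = 8000 + i,
                                  name = "g2"),
                    0.3, seed = 200 * i + j,
                    name = paste0("b", j)))
    D <- model_distance_matrix(c(g1, g2))
    tr <- neighbor_joining(D)
    want <- rownames(unclass(D))[1:4]
    splits <- protspace:::.tree_splits(tr, sort(tr$tip.label))
    found <- any(apply(splits, 1, function(s) {
      side <- sort(tr$tip.label)[s]
      setequal(side, want) || setequal(side, setdiff(rownames(unclass(D)),
                                                     want))
    }))
    hits <- hits + found
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("matching split distance equals brute force and is a metric", {
  a <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  b <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_identical(matching_split_distance(a, a), 0L)
  expect_identical(matching_split_distance(a, b), 2L)

  # brute-force matching oracle on 6-leaf trees
  set.seed(13)
  for (i in 1:15) {
    t1 <- generate_random_topology(6, labels = LETTERS[1:6])
    t2 <- generate_random_topology(6, labels = LETTERS[1:6])
    expect_identical(matching_split_distance(t1, t2),
                     as.integer(brute_msd(t1, t2)))
  }

  # exhaustive metric check over all 15 five-leaf topologies
  all5 <- phangorn::allTrees(5, rooted = FALSE,
                             tip.label = letters[1:5])
  M <- outer(seq_along(all5), seq_along(all5),
             Vectorize(function(i, j)
               matching_split_distance(all5[[i]], all5[[j]])))
  expect_true(all(M == t(M)))
  expect_true(all(diag(M) == 0))
  expect_true(all(M[upper.tri(M)] > 0))  # identity of indiscernibles
  for (i in 1:15) {
    for (j in 1:15) {
      expect_true(all(M[i, j] <= M[i, ] + M[, j]))
    }
  }

  # sampled triangle inequality at n = 8
  set.seed(14)
  t8 <- replicate(12, generate_random_topology(8), simplify = FALSE)
  M8 <- outer(1:12, 1:12, Vectorize(function(i, j)
    matching_split_distance(t8[[i]], t8[[j]])))
  for (i in 1:12) {
    for (j in 1:12) {
      expect_true(all(M8[i, j] <= M8[i, ] + M8[, j]))
    }
  }

  expect_error(matching_split_distance(a, parse_newick("((A:1,B:1):1,(C:1,E:1):1);")),
               "leaf set")
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,(D:1,E:1):1,F:1);")
  expect_error(matching_split_distance(poly, generate_random_topology(
    6, seed = 1, labels = LETTERS[1:6])), "binary")
})

test_that("hungarian assignment matches exhaustive search", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    cost <- matrix(sample(0:12, n * n, replace = TRUE), n)
    expect_equal(protspace:::.hungarian(cost), brute_matching(cost))
  }
})

test_that("random-tree null test reports sane results", {
  ref <- generate_random_topology(10, seed = 71)
  # observed equal to the reference: minimum distance, smallest p
  res <- random_tree_null(ref, ref, n_random = 99, seed = 72)
  expect_identical(res$observed, 0L)
  expect_equal(res$p_value, 1 / 100)
  expect_length(res$null_sample, 99L)
  # determinism
  res2 <- random_tree_null(ref, ref, n_random = 99, seed = 72)
  expect_identical(res$null_sample, res2$null_sample)
  # a typical random observed tree is not significant
  obs <- generate_random_topology(10, seed = 73,
                                  labels = ref$tip.label)
  res3 <- random_tree_null(ref, obs, n_random = 199, seed = 74)
  expect_gt(res3$p_value, 0.01)
})
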