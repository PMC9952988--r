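test_that("Newick parsing validates and round-trips", {
  tr <- parse_newick("((A:1,B:2):1,C:3);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  rt <- parse_newick(write_newick(tr))
  expect_equal(sort(rt$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_warning(parse_newick("((A,B),C);"), "no branch lengths")
  expect_error(parse_newick("((A:1,A:1):1,C:1);"), "duplicate")
})

test_that("discrete gamma categories match the quadrature oracle", {
  # near-infinite shape concentrates all rates at 1
  r <- discrete_gamma_rates(1e4, 4)
  expect_true(all(abs(r$rates - 1) < 0.05))
  expect_identical(discrete_gamma_rates(2, 1)$rates, 1)
  for (alpha in c(0.3, 1, 2.7)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(r$rates, quadrature_gamma_rates(alpha, 4),
                 tolerance = 1e-6)
    expect_true(all(diff(r$rates) > 0))
    expect_equal(sum(r$rates * r$weights), 1, tolerance = 1e-9)
  }
  # invariant class keeps the overall mean rate at one
  r <- discrete_gamma_rates(0.7, 4, p_inv = 0.3)
  expect_equal(sum(r$rates * r$weights) + 0 * r$p_inv, 1,
               tolerance = 1e-9)
  expect_error(discrete_gamma_rates(-1, 4), "alpha")
})

test_that("transition probabilities: identity, closed form, ergodic limit", {
  m <- substitution_model("u", rep(1, 190), rep(0.05, 20))
  Q <- build_rate_matrix(m$R, m$pi)
  expect_equal(transition_probabilities(Q, 0, pi = m$pi), diag(20),
               tolerance = 1e-12, ignore_attr = TRUE)
  # 20-state equal-rates closed form P_ii(t) = 1/20 + (19/20) e^(-20 t/19)
  P <- transition_probabilities(Q, 0.95, pi = m$pi)
  expect_equal(unname(diag(P)),
               rep(1 / 20 + (19 / 20) * exp(-20 * 0.95 / 19), 20),
               tolerance = 1e-10)
  expect_true(all(P >= 0 & P <= 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # long branches decay to the equilibrium frequencies
  m2 <- fixture_model(seed = 2)
  P2 <- transition_probabilities(build_rate_matrix(m2$R, m2$pi), 500,
                                 pi = m2$pi)
  expect_lt(max(abs(sweep(P2, 2, m2$pi))), 1e-6)
  expect_error(transition_probabilities(Q, -1, pi = m$pi), ">= 0")
})

test_that("Chapman-Kolmogorov holds for seeded random models", {
  set.seed(7)
  for (i in 1:3) {
    m <- fixture_model(seed = i, magnitude = 1)
    Q <- build_rate_matrix(m$R, m$pi)
    t1 <- runif(1, 0.05, 1)
    t2 <- runif(1, 0.05, 1)
    P <- transition_probabilities(Q, t1, pi = m$pi) %*%
      transition_probabilities(Q, t2, pi = m$pi)
    expect_equal(P, transition_probabilities(Q, t1 + t2, pi = m$pi),
                 tolerance = 1e-8)
  }
})

test_that("pruning matches closed forms and an independent implementation", {
  m <- fixture_model(seed = 4, magnitude = 0.6)
  # two taxa, one site: lnL = log(pi_x P_xy(t))
  msa <- protein_msa(c(a = "F", b = "Y"))
  tr <- ape::read.tree(text = "(a:0.4,b:0.3);")
  P <- transition_probabilities(build_rate_matrix(m$R, m$pi), 0.7,
                                pi = m$pi)
  expect_equal(msa_log_likelihood(msa, tr, m,
                                  discrete_gamma_rates(1, 1)),
               log(m$pi["F"] * P["F", "Y"]),
               ignore_attr = TRUE, tolerance = 1e-10)

  # independent oracle (phangorn) on a larger alignment, with gamma and +I
  tr6 <- generate_random_topology(6, seed = 11)
  msa6 <- simulate_msa(tr6, m, 180, rates = discrete_gamma_rates(0.8, 4),
                       seed = 12)
  expect_equal(msa_log_likelihood(msa6, tr6, m,
                                  discrete_gamma_rates(0.8, 4)),
               phangorn_loglik(msa6, tr6, m, k = 4, shape = 0.8),
               tolerance = 1e-8)
  expect_equal(msa_log_likelihood(msa6, tr6, m,
                                  discrete_gamma_rates(0.8, 4,
                                                       p_inv = 0.25)),
               phangorn_loglik(msa6, tr6, m, k = 4, shape = 0.8,
                               inv = 0.25),
               tolerance = 1e-8)
})

test_that("pruning agrees with exhaustive enumeration on a small alphabet", {
  # same compiled code path, 4-state alphabet, brute force over all
  # internal-node state assignments
  set.seed(31)
  tr <- ape::unroot(ape::rtree(4))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
  pi <- c(0.1, 0.2, 0.3, 0.4)
  R <- rexp(6)
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- R
  S <- S + t(S)
  Q <- S * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  codes <- matrix(sample.int(4, 4 * 6, replace = TRUE), nrow = 4)
  expect_equal(plik_direct(tr, Q, pi, codes),
               enumerate_loglik(tr, Q, pi, codes),
               tolerance = 1e-10)
})

test_that("site independence, missing data, rooting and degenerate edges", {
  m <- fixture_model(seed = 5)
  tr <- generate_random_topology(6, seed = 21)
  msa <- simulate_msa(tr, m, 120, rates = discrete_gamma_rates(1, 4),
                      seed = 22)
  r4 <- discrete_gamma_rates(1, 4)
  lnl <- msa_log_likelihood(msa, tr, m, r4)

  # duplicated columns double the log-likelihood (site independence,
  # and pattern compression does not change the result)
  dbl <- protein_msa(cbind(msa$seq, msa$seq), id = "dbl")
  expect_equal(msa_log_likelihood(dbl, tr, m, r4), 2 * lnl,
               tolerance = 1e-8)

  # pulley principle: likelihood invariant to the virtual root
  for (node in unique(tr$edge[, 1])) {
    rooted <- ape::root(tr, node = node, resolve.root = FALSE)
    expect_equal(msa_log_likelihood(msa, rooted, m, r4), lnl,
                 tolerance = 1e-8)
  }

  # a zero-length pendant edge on a duplicated label changes nothing:
  # instead test an internal zero-length branch directly
  tr0 <- tr
  internal <- which(tr0$edge[, 2] > length(tr0$tip.label))[1]
  tr_split <- tr0
  tr_split$edge.length[internal] <- 0
  tr_ref <- tr0
  tr_ref$edge.length[internal] <- 1e-12
  expect_equal(msa_log_likelihood(msa, tr_split, m, r4),
               msa_log_likelihood(msa, tr_ref, m, r4), tolerance = 1e-6)

  # gap and ambiguity columns contribute partial likelihood one:
  # an all-gap column leaves the likelihood unchanged
  gap <- msa
  gapcol <- matrix("-", msa$n_taxa, 1)
  gap <- protein_msa(cbind(msa$seq, gapcol), id = "gap")
  expect_equal(msa_log_likelihood(gap, tr, m, r4), lnl, tolerance = 1e-8)

  # p_inv = 0 equals the plain gamma likelihood
  expect_equal(msa_log_likelihood(msa, tr, m,
                                  discrete_gamma_rates(1, 4, p_inv = 0)),
               lnl, tolerance = 1e-12)

  # label mismatch is an input error
  bad <- msa
  rownames(bad$seq)[1] <- "zz"
  expect_error(msa_log_likelihood(bad, tr, m, r4), "labels")
})

test_that("BIC arithmetic and equal-dimension ranking", {
  expect_equal(bic(-1000, 10, 100), 10 * log(100) + 2000)
  expect_equal(bic(-50, 0, 10), 100)
  # same k on the same data: BIC ranking equals likelihood ranking
  lnls <- c(-120.7, -119.2, -140.1)
  expect_identical(order(bic(lnls, 25, 300)), order(-lnls))
  expect_error(bic(-1, 2, 0), "n_sites")
})

test_that("branch-length optimization recovers simulated lengths", {
  m <- fixture_model(seed = 6, magnitude = 0.3)
  tr <- generate_random_topology(8, seed = 23, depth_scale = 0.15)
  msa <- simulate_msa(tr, m, 2000, rates = discrete_gamma_rates(0.8, 4),
                      seed = 24)
  fit <- optimize_branch_lengths_and_rates(msa, tr, m, k = 4)
  trp <- ape::reorder.phylo(tr, "postorder")
  key <- function(t) paste(t$edge[, 1], t$edge[, 2])
  est <- fit$tree$edge.length[match(key(trp), key(fit$tree))]
  expect_gt(cor(trp$edge.length, est), 0.9)
  expect_true(all(est >= 1e-8 & est <= 20))
  expect_true(fit$alpha >= 0.05 && fit$alpha <= 100)
  expect_equal(fit$bic,
               fit$k_free_parameters * log(fit$n_sites) - 2 * fit$lnL,
               tolerance = 1e-6)
  # restarting at the optimum stays put
  fit2 <- optimize_branch_lengths_and_rates(msa, fit$tree, m, k = 4,
                                            alpha = fit$alpha)
  expect_lt(abs(fit2$lnL - fit$lnL), 1e-3)

  # identical sequences drive the branch to its lower bound
  same <- protein_msa(c(a = strrep("ARNDC", 20), b = strrep("ARNDC", 20)))
  tr2 <- ape::read.tree(text = "(a:0.2,b:0.2);")
  f0 <- optimize_branch_lengths_and_rates(same, tr2, m,
                                          optimize_alpha = FALSE, k = 1)
  expect_lt(sum(f0$tree$edge.length), 1e-6)
})
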