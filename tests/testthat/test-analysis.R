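test_that("group means average normalized REs and frequencies", {
  m1 <- fixture_model(seed = 1)
  m2 <- fixture_model(seed = 2)
  g <- group_mean_model(list(m1, m2))
  v1 <- normalize_exchangeabilities(m1$R)
  v2 <- normalize_exchangeabilities(m2$R)
  expect_equal(g$R, (v1 + v2) / 2, tolerance = 1e-12)
  expect_equal(g$pi, (m1$pi + m2$pi) / 2, tolerance = 1e-12)
  # identical inputs reproduce the model; order does not matter
  expect_equal(group_mean_model(list(m1, m1))$R,
               normalize_exchangeabilities(m1$R), tolerance = 1e-12)
  expect_equal(group_mean_model(list(m2, m1))$R, g$R, tolerance = 1e-12)
  expect_error(group_mean_model(list()), "non-empty")
})

test_that("RE difference ranking is antisymmetric with zero sum", {
  m1 <- fixture_model(seed = 3)
  m2 <- fixture_model(seed = 4)
  tab <- rank_re_differences(list(m1), list(m2))
  expect_identical(sort(tab$rank), 1:190)
  expect_true(all(diff(tab$difference[order(tab$rank)]) >= 0))
  expect_equal(sum(tab$difference), 0, tolerance = 1e-12)

  # identical groups: all differences zero, ranks by label order
  t0 <- rank_re_differences(list(m1), list(m1))
  expect_true(all(t0$difference == 0))
  expect_identical(t0$pair, sort(aa_pair_names()))

  # elevating only F-Y in group B puts it at rank 190
  base <- synthetic_base_model(0.5)
  up <- perturb_model(base, 0, name = "up")
  up$R[aa_pair_index("F-Y")] <- up$R[aa_pair_index("F-Y")] * 8
  up$R <- normalize_exchangeabilities(up$R)
  tb <- rank_re_differences(list(base), list(up))
  expect_identical(tb$pair[tb$rank == 190], "Y-F")

  # swapping the groups maps rank r to 191 - r (tie-free input)
  swapped <- rank_re_differences(list(m2), list(m1))
  expect_identical(
    tab$rank[match(swapped$pair, tab$pair)] + swapped$rank,
    rep(191L, 190))

  out <- outlier_re_pairs(tb, 3)
  expect_identical(out$top$pair[3], "Y-F")
  expect_identical(nrow(out$bottom), 3L)
  p95 <- outlier_re_pairs(tb, 95)
  expect_identical(nrow(p95$top) + nrow(p95$bottom), 190L)
  expect_error(outlier_re_pairs(tb, 96), "1..95")
})

test_that("frequency classes partition unity and regress exactly", {
  # uniform frequencies: f_GARP 0.20, f_FYMINK 0.30, f_other 0.50
  u <- substitution_model("u", rep(1, 190), rep(0.05, 20))
  fs <- frequency_class_summary(list(u, u), gc = c(40, 60))
  expect_equal(fs$per_model$f_garp, c(0.2, 0.2))
  expect_equal(fs$per_model$f_fymink, c(0.3, 0.3))
  expect_equal(fs$per_model$f_other, c(0.5, 0.5))

  # constructed exact line: slope and r^2 recovered to machine precision
  gc <- c(35, 45, 55, 65)
  models <- lapply(gc, function(g) {
    target <- 0.005 * g + 0.1
    pi <- rep((1 - target) / 16, 20)
    names(pi) <- AA_ALPHABET
    pi[c("G", "A", "R", "P")] <- target / 4
    substitution_model(paste0("gc", g), rep(1, 190), pi)
  })
  fs2 <- suppressWarnings(frequency_class_summary(models, gc))
  reg <- fs2$regressions[fs2$regressions$class == "f_garp", ]
  expect_equal(reg$slope, 0.005, tolerance = 1e-9)
  expect_equal(reg$intercept, 0.1, tolerance = 1e-9)
  expect_equal(reg$r_squared, 1, tolerance = 1e-9)
  expect_true(all(abs(fs2$per_model$f_garp + fs2$per_model$f_fymink +
                        fs2$per_model$f_other - 1) < 1e-9))
  # r^2 equals the squared Pearson correlation
  fm <- fs2$per_model
  reg2 <- fs2$regressions[fs2$regressions$class == "f_fymink", ]
  expect_equal(reg2$r_squared, cor(fm$gc, fm$f_fymink)^2,
               tolerance = 1e-9)
  expect_warning(frequency_class_summary(models[1], gc[1]), ">= 2")
})

test_that("synthetic GC-driven frequencies show the expected class trends", {
  gc <- seq(30, 70, by = 5)
  models <- lapply(gc, function(g)
    substitution_model(paste0("m", g), grantham_exchangeabilities(),
                       codon_frequencies(g / 100)))
  fs <- frequency_class_summary(models, gc)
  sl <- fs$regressions
  expect_gt(sl$slope[sl$class == "f_garp"], 0)
  expect_lt(sl$slope[sl$class == "f_fymink"], 0)
  expect_gt(sl$r_squared[sl$class == "f_garp"], 0.9)

  # OLS recovers a known linear map within 2 standard errors (>= 95%)
  set.seed(20)
  hits <- 0L
  for (i in 1:40) {
    x <- runif(12, 30, 70)
    y <- 0.004 * x + 0.05 + rnorm(12, 0, 0.01)
    fit <- lm(y ~ x)
    ci <- coef(fit)[2] + c(-2, 2) * summary(fit)$coefficients[2, 2]
    hits <- hits + (0.004 >= ci[1] && 0.004 <= ci[2])
  }
  expect_gte(hits / 40, 0.9)
})

test_that("spearman correlation matches independent references", {
  # monotone transform gives rho = 1; reversal negates it
  expect_equal(spearman_correlation(1:3, c(1, 4, 9))$rho, 1)
  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  set.seed(8)
  x <- rnorm(15)
  y <- rnorm(15)
  s <- spearman_correlation(x, y)
  expect_equal(s$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman_correlation(x, -y)$rho, -s$rho,
               tolerance = 1e-12)
  # tie-free closed form: 1 - 6 sum d^2 / (n (n^2-1))
  d <- rank(x) - rank(y)
  expect_equal(s$rho, 1 - 6 * sum(d^2) / (15 * (15^2 - 1)),
               tolerance = 1e-12)
  # p-value agrees with the t-approximation reference
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  expect_equal(s$p_value, unname(ct$p.value), tolerance = 1e-9)
  # ties handled by average ranks
  xt <- c(1, 1, 2, 3, 3, 4)
  yt <- c(2, 1, 2, 5, 4, 4)
  expect_equal(spearman_correlation(xt, yt)$rho,
               cor(xt, yt, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("acidic to basic ratios follow the frequency definition", {
  expect_equal(acidic_basic_ratio(rep(0.05, 20)), 2 / 3)
  pi <- rep(0.05, 20)
  names(pi) <- AA_ALPHABET
  pi[c("D", "E")] <- 0.1
  pi[c("R", "K", "H")] <- 0.05
  pi <- pi / sum(pi)
  expect_equal(acidic_basic_ratio(pi), 0.2 / 0.15, tolerance = 1e-9)
  # joint rescaling of the involved residues leaves the ratio unchanged
  pi2 <- pi
  pi2[c("D", "E", "R", "K", "H")] <- pi2[c("D", "E", "R", "K", "H")] * 2
  expect_equal(acidic_basic_ratio(pi2 / sum(pi2)),
               acidic_basic_ratio(pi), tolerance = 1e-9)
  # histidine exclusion widens the ratio
  expect_gt(acidic_basic_ratio(pi, include_histidine = FALSE),
            acidic_basic_ratio(pi))
})
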