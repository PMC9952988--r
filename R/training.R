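# Joint estimation of a clade-specific GTR20(+I)+Gamma model from many
# alignments, each on its own tree: neighbor-joining trees from pairwise
# maximum-likelihood distances, then quasi-Newton maximization of the
# summed log-likelihood over shared exchangeabilities and frequencies
# (analytic gradients), with per-alignment gamma shapes profiled out.

#' Training configuration
#'
#' @param initial_model optional [substitution_model()] to start from;
#'   default is uniform exchangeabilities with pooled observed
#'   frequencies.
#' @param max_outer maximum alternations of tree re-estimation and shared
#'   model optimization (>= 1).
#' @param tol stop when the total log-likelihood improves by less than
#'   this between outer iterations.
#' @param use_pinv estimate a shared invariant-site proportion.
#' @param k number of gamma categories.
#' @param shared_alpha a single gamma shape across alignments instead of
#'   one per alignment.
#' @param maxit_bfgs quasi-Newton iteration cap per optimization round.
#' @return An object of class `training_config`.
#' @export
training_config <- function(initial_model = NULL, max_outer = 2L,
                            tol = 0.1, use_pinv = FALSE, k = 4L,
                            shared_alpha = FALSE, maxit_bfgs = 100L) {
  if (max_outer < 1L) stop("max_outer must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  structure(list(initial_model = initial_model,
                 max_outer = as.integer(max_outer), tol = tol,
                 use_pinv = use_pinv, k = as.integer(k),
                 shared_alpha = shared_alpha,
                 maxit_bfgs = as.integer(maxit_bfgs)),
            class = "training_config")
}

# ML distance between two encoded sequences (0-based, -1 missing) under a
# fixed model; returns the optimized branch length in [1e-8, 10]
.pair_ml_distance <- function(xi, yi, eig, rates, cap = 10) {
  ok <- xi >= 0L & yi >= 0L
  if (!any(ok)) return(list(d = cap, saturated = TRUE))
  N <- table(factor(xi[ok], levels = 0:19), factor(yi[ok], levels = 0:19))
  N <- unclass(N)
  if (all(N[row(N) != col(N)] == 0))
    return(list(d = 1e-8, saturated = FALSE))
  pinv <- rates$p_inv
  nll <- function(lt) {
    t <- exp(lt)
    M <- matrix(0, 20, 20)
    for (c in seq_along(rates$rates)) {
      M <- M + rates$weights[c] *
        (eig$U %*% (exp(eig$lambda * t * rates$rates[c]) * eig$Uinv))
    }
    L <- eig$pi * M
    if (pinv > 0) diag(L) <- diag(L) + pinv * eig$pi
    L[L < 1e-300] <- 1e-300
    -sum(N * log(L))
  }
  o <- stats::optimize(nll, interval = log(c(1e-8, cap)), tol = 1e-6)
  d <- exp(o$minimum)
  saturated <- d > cap * 0.98
  list(d = if (saturated) cap else d, saturated = saturated)
}

#' Estimate a tree for one alignment under a given model
#'
#' Topology from neighbor-joining on pairwise maximum-likelihood
#' distances (1-D likelihood optimization per sequence pair under the
#' model), followed by joint branch-length (and optionally gamma shape)
#' optimization on the fixed topology. Saturated pairs are capped at
#' distance 10 with a warning; NJ branch lengths below `1e-8` are raised
#' to that floor before optimization.
#'
#' @param msa a [protein_msa()] (>= 2 sequences; a pair yields the
#'   trivial two-leaf tree).
#' @param model a [substitution_model()].
#' @param optimize_alpha optimize the gamma shape during branch-length
#'   fitting.
#' @param k gamma categories.
#' @return An ape `phylo` with an attribute `fit` holding the
#'   `fit_result` of the final branch-length optimization (NULL for two
#'   taxa).
#' @export
estimate_msa_tree <- function(msa, model, optimize_alpha = TRUE, k = 4L) {
  stopifnot(inherits(msa, "protein_msa"),
            inherits(model, "substitution_model"))
  eig <- .model_eigen(model)
  rates <- .model_rates(model, k)
  code <- matrix(.encode_residues(msa$seq), nrow = msa$n_taxa)
  n <- msa$n_taxa
  labs <- rownames(msa$seq)

  if (n == 2L) {
    p <- .pair_ml_distance(code[1, ], code[2, ], eig, rates)
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                        labs[1], p$d / 2,
                                        labs[2], p$d / 2))
    return(tr)
  }

  D <- matrix(0, n, n, dimnames = list(labs, labs))
  n_sat <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- .pair_ml_distance(code[i, ], code[j, ], eig, rates)
      D[i, j] <- D[j, i] <- p$d
      n_sat <- n_sat + p$saturated
    }
  }
  if (n_sat > 0L)
    warning(n_sat, " saturated pair distance(s) capped at 10 in '",
            msa$id, "'")
  tr <- neighbor_joining(D)  # n = 3 yields the unique unrooted topology
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  fit <- optimize_branch_lengths_and_rates(msa, tr, model,
                                           optimize_alpha = optimize_alpha,
                                           k = k, max_rounds = 5L)
  out <- fit$tree
  attr(out, "fit") <- fit
  out
}

# pooled observed frequencies over several alignments
.pooled_frequencies <- function(msas) {
  counts <- numeric(20)
  for (m in msas) {
    code <- .encode_residues(m$seq)
    code <- code[code >= 0]
    counts <- counts + tabulate(code + 1L, nbins = 20L)
  }
  f <- pmax(counts / sum(counts), 1e-6)
  f / sum(f)
}

# shared-model objective/gradient machinery ---------------------------------

.theta_from_model <- function(model) {
  r <- pmax(model$R, 1e-12)
  r <- r / r[1]                       # reference pair A-R fixed at 1
  z <- log(model$pi / model$pi[20])   # additive log-ratio vs V
  c(log(r[-1]), z[1:19])
}

.model_from_theta <- function(theta, name = "shared") {
  r <- exp(c(0, theta[1:189]))
  z <- c(theta[190:208], 0)
  pi <- exp(z - max(z))
  pi <- pi / sum(pi)
  list(R = r, pi = pi)
}

# dlnL/d(theta) from the compiled C (= dlnL/dQ) and direct-frequency terms
.theta_gradient <- function(theta, Csum, dpisum) {
  par <- .model_from_theta(theta)
  r <- par$R; pi <- par$pi
  idx <- .pair_indices()
  a <- idx[, 1]; b <- idx[, 2]
  mu <- 2 * sum(pi[a] * pi[b] * r)
  S <- matrix(0, 20, 20)
  S[idx] <- r; S <- S + t(S)          # symmetric exchangeability matrix
  Q <- S * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  Q <- Q / mu
  sC <- sum(Csum * Q)
  dC <- diag(Csum)
  # exchangeabilities (log scale, reference entry dropped)
  g_r <- (pi[b] * (Csum[cbind(a, b)] - dC[a]) +
          pi[a] * (Csum[cbind(b, a)] - dC[b]) -
          2 * pi[a] * pi[b] * sC) / mu
  g_logr <- g_r * r
  # frequencies: rate-matrix path + direct root/invariant term
  g_pi <- dpisum
  for (cc in 1:20) {
    i <- setdiff(1:20, cc)
    dmu <- 2 * sum(S[cc, i] * pi[i])
    g_pi[cc] <- g_pi[cc] +
      (sum(S[i, cc] * (Csum[i, cc] - dC[i])) - dmu * sC) / mu
  }
  g_z <- pi * (g_pi - sum(pi * g_pi))
  c(g_logr[-1], g_z[1:19])
}

#' Optimize shared model parameters over many alignments
#'
#' Maximizes the summed log-likelihood over the 189 free log
#' exchangeabilities (reference pair A-R fixed at 1) and 19 free
#' log-ratio frequencies, holding each alignment's tree fixed, with the
#' per-alignment gamma shape (and optional shared invariant proportion)
#' profiled out by 1-D optimization between quasi-Newton rounds.
#' Gradients of the likelihood with respect to the rate-matrix
#' parameters are analytic.
#'
#' @param msas list of [protein_msa()].
#' @param trees list of ape `phylo`, aligned 1:1 with `msas`.
#' @param config a [training_config()].
#' @param alphas optional starting gamma shapes (recycled).
#' @return An object of class `trained_model`: list with `model` (the
#'   fitted [substitution_model()], REs normalized to sum 1),
#'   `total_lnL`, `per_msa` (data frame: id, lnL, alpha), `trees`,
#'   `p_inv`, `trace`.
#' @export
optimize_shared_model <- function(msas, trees, config = training_config(),
                                  alphas = NULL) {
  stopifnot(length(msas) == length(trees), length(msas) >= 1L)
  nm <- length(msas)
  pds <- lapply(seq_len(nm), function(i) .plik_data(msas[[i]], trees[[i]]))
  init <- config$initial_model
  if (is.null(init)) {
    init <- substitution_model("init", rep(1, 190),
                               .pooled_frequencies(msas), alpha = 1)
  }
  if (is.null(alphas))
    alphas <- rep(if (is.null(init$alpha)) 1 else init$alpha, nm)
  alphas <- rep_len(alphas, nm)
  p_inv <- if (config$use_pinv) {
    if (is.null(init$p_inv)) 0.05 else init$p_inv
  } else 0

  theta <- .theta_from_model(init)

  eval_model <- function(theta) {
    par <- .model_from_theta(theta)
    Q <- {
      S <- matrix(0, 20, 20)
      S[.pair_indices()] <- par$R
      S <- S + t(S)
      Q <- S * rep(par$pi, each = 20)
      diag(Q) <- -rowSums(Q)
      Q / (-sum(par$pi * diag(Q)))
    }
    c(.eigen_q(Q, par$pi), list(pi = par$pi))
  }

  lnL_all <- function(theta, alphas, p_inv, want_grad = FALSE) {
    eig <- eval_model(theta)
    tot <- 0
    Csum <- matrix(0, 20, 20)
    dpisum <- numeric(20)
    per <- numeric(nm)
    for (i in seq_len(nm)) {
      r <- discrete_gamma_rates(alphas[i], config$k, p_inv = p_inv)
      res <- .plik_call(pds[[i]], eig, r, want_grad = want_grad)
      per[i] <- res$loglik
      tot <- tot + res$loglik
      if (want_grad) {
        Csum <- Csum + res$C
        dpisum <- dpisum + res$dpi
      }
    }
    out <- list(total = tot, per = per)
    if (want_grad) out$grad <- .theta_gradient(theta, Csum, dpisum)
    out
  }

  opt_alphas <- function(theta, alphas, p_inv) {
    eig <- eval_model(theta)
    one <- function(i) {
      o <- stats::optimize(function(la) {
        r <- discrete_gamma_rates(exp(la), config$k, p_inv = p_inv)
        -.plik_call(pds[[i]], eig, r)$loglik
      }, interval = log(c(0.05, 100)), tol = 1e-3)
      exp(o$minimum)
    }
    if (config$shared_alpha) {
      o <- stats::optimize(function(la) {
        r <- discrete_gamma_rates(exp(la), config$k, p_inv = p_inv)
        -sum(vapply(pds, function(pd)
          .plik_call(pd, eig, r)$loglik, numeric(1)))
      }, interval = log(c(0.05, 100)), tol = 1e-3)
      rep(exp(o$minimum), nm)
    } else {
      vapply(seq_len(nm), one, numeric(1))
    }
  }

  start <- lnL_all(theta, alphas, p_inv)
  if (!is.finite(start$total)) {
    warning("non-finite likelihood at start; falling back to uniform model")
    theta <- .theta_from_model(
      substitution_model("uniform", rep(1, 190),
                         .pooled_frequencies(msas)))
    start <- lnL_all(theta, alphas, p_inv)
  }
  trace <- start$total

  for (round in 1:2) {
    if (config$use_pinv) {
      # profile p_inv with the gamma shapes re-optimized at every value:
      # +I and +G are strongly confounded, so coordinate-wise alternation
      # crawls along the ridge instead of crossing it
      op <- stats::optimize(function(p)
        -lnL_all(theta, opt_alphas(theta, alphas, p), p)$total,
        interval = c(0, 0.75), tol = 1e-3)
      p_inv <- op$minimum
    }
    alphas <- opt_alphas(theta, alphas, p_inv)
    fn <- function(th) {
      v <- -lnL_all(th, alphas, p_inv)$total
      if (!is.finite(v)) 1e12 else v   # guard underflow in line searches
    }
    gr <- function(th) {
      g <- -lnL_all(th, alphas, p_inv, want_grad = TRUE)$grad
      if (any(!is.finite(g))) rep(0, length(g)) else g
    }
    o <- stats::optim(theta, fn = fn, gr = gr,
                      method = "L-BFGS-B",
                      lower = -15, upper = 15,
                      control = list(maxit = config$maxit_bfgs,
                                     factr = 1e7))
    theta <- o$par
    cur <- -o$value
    trace <- c(trace, cur)
    if (length(trace) >= 2 &&
        cur - trace[length(trace) - 1] < config$tol) break
  }
  alphas <- opt_alphas(theta, alphas, p_inv)
  final <- lnL_all(theta, alphas, p_inv)
  trace <- c(trace, final$total)
  trace <- cummax(trace)  # guard against 1-D profiling tolerance jitter

  par <- .model_from_theta(theta)
  model <- substitution_model("shared",
                              normalize_exchangeabilities(par$R),
                              par$pi,
                              alpha = stats::median(alphas),
                              p_inv = if (config$use_pinv) p_inv else NULL)
  structure(list(model = model, total_lnL = final$total,
                 per_msa = data.frame(
                   id = vapply(msas, function(m) m$id, character(1)),
                   lnL = final$per, alpha = alphas),
                 trees = trees, p_inv = p_inv, trace = trace),
            class = "trained_model")
}

#' Train a clade-specific model from a set of alignments
#'
#' Alternates per-alignment tree estimation under the current model
#' ([estimate_msa_tree()]) with shared model optimization
#' ([optimize_shared_model()]) until the total log-likelihood improves by
#' less than `config$tol` or `config$max_outer` alternations have run.
#' A re-estimated tree is only accepted for an alignment when it does not
#' decrease that alignment's likelihood, so the training trace is
#' monotone.
#'
#' @param msas list of [protein_msa()] (>= 2 recommended; a single
#'   alignment trains with a warning).
#' @param config a [training_config()].
#' @return A `trained_model` (see [optimize_shared_model()]) with an
#'   `outer_trace` of total log-likelihoods.
#' @export
train_clade_model <- function(msas, config = training_config()) {
  if (length(msas) == 0L) stop("msas must be non-empty")
  if (length(msas) == 1L)
    warning("training on a single alignment; estimates will be noisy")
  model <- config$initial_model
  if (is.null(model)) {
    model <- substitution_model("init", rep(1, 190),
                                .pooled_frequencies(msas), alpha = 1)
  }
  trees <- vector("list", length(msas))
  fit <- NULL
  outer_trace <- numeric(0)
  alphas <- NULL
  for (iter in seq_len(config$max_outer)) {
    cur <- model
    if (!is.null(alphas)) cur$alpha <- stats::median(alphas)
    for (i in seq_along(msas)) {
      cand <- estimate_msa_tree(msas[[i]], cur, k = config$k)
      keep <- TRUE
      if (!is.null(trees[[i]])) {
        new_lnL <- attr(cand, "fit")$lnL
        old_lnL <- msa_log_likelihood(
          msas[[i]], trees[[i]], cur,
          discrete_gamma_rates(if (is.null(alphas)) 1 else alphas[i],
                               config$k))
        keep <- is.null(new_lnL) || new_lnL >= old_lnL
      }
      if (keep) trees[[i]] <- cand
    }
    fit <- optimize_shared_model(msas, trees, config = .config_with(
      config, initial_model = model), alphas = alphas)
    alphas <- fit$per_msa$alpha
    model <- fit$model
    outer_trace <- c(outer_trace, fit$total_lnL)
    if (iter >= 2L &&
        outer_trace[iter] - outer_trace[iter - 1L] < config$tol) break
  }
  fit$outer_trace <- outer_trace
  fit
}

.config_with <- function(config, initial_model) {
  config$initial_model <- initial_model
  config
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model '", x$model$name, "': ",
      nrow(x$per_msa), " alignments, total lnL = ",
      format(x$total_lnL, digits = 10), "\n", sep = "")
  invisible(x)
}
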