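# Likelihood engine: eigendecomposition of the reversible rate matrix,
# transition probabilities, Felsenstein pruning (compiled core), and
# fixed-topology optimization of branch lengths and rate heterogeneity.

# Symmetrized eigendecomposition of a reversible Q:
# B = D Q D^-1 with D = diag(sqrt(pi)) is symmetric, so the decomposition
# is numerically stable and the eigenvalues are real.
.eigen_q <- function(Q, pi) {
  ns <- length(pi)
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sp,
       lambda = e$values,
       Uinv = t(e$vectors) * rep(sp, each = ns))
}

.model_eigen <- function(model) {
  Q <- build_rate_matrix(model$R, model$pi, floor_zeros = TRUE)
  c(.eigen_q(Q, model$pi), list(Q = Q, pi = model$pi))
}

#' Transition probability matrix
#'
#' Computes `P(t) = exp(Q * t * rate)` for a reversible rate matrix via
#' the symmetrized eigendecomposition. Rows sum to one and `P(0)` is the
#' identity.
#'
#' @param Q a 20x20 rate matrix from [build_rate_matrix()] (or a
#'   `substitution_model`).
#' @param t branch length (expected substitutions per site), `>= 0`.
#' @param rate rate-category multiplier, `>= 0`.
#' @param pi equilibrium frequencies; recovered from `Q`'s stationary
#'   vector if omitted.
#' @return A 20x20 probability matrix.
#' @export
#' @examples
#' m <- substitution_model("u", rep(1, 190), rep(0.05, 20))
#' P <- transition_probabilities(build_rate_matrix(m), 0.95)
#' P[1, 1]  # 1/20 + (19/20) * exp(-20 * 0.95 / 19)
transition_probabilities <- function(Q, t, rate = 1, pi = NULL) {
  if (inherits(Q, "substitution_model")) {
    pi <- Q$pi
    Q <- build_rate_matrix(Q$R, Q$pi)
  }
  if (!is.finite(t) || t < 0) stop("branch length must be >= 0")
  if (!is.finite(rate) || rate < 0) stop("rate must be >= 0")
  if (is.null(pi)) {
    # stationary distribution: left eigenvector of Q for eigenvalue 0
    e <- eigen(t(Q))
    pi <- abs(Re(e$vectors[, which.min(abs(e$values))]))
    pi <- pi / sum(pi)
  }
  e <- .eigen_q(Q, pi)
  P <- e$U %*% (exp(e$lambda * t * rate) * e$Uinv)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Prepare the per-MSA data passed to the compiled pruning core.
.plik_data <- function(msa, tree) {
  pat <- .msa_patterns(msa)
  if (!all(pat$labels %in% tree$tip.label))
    stop("alignment labels missing from tree: ",
         paste(setdiff(pat$labels, tree$tip.label), collapse = ", "))
  if (!all(tree$tip.label %in% pat$labels))
    stop("tree leaves missing from alignment: ",
         paste(setdiff(tree$tip.label, pat$labels), collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  # order pattern columns by the tree's tip numbering
  ord <- match(tr$tip.label, pat$labels)
  list(edge = tr$edge,
       elen = tr$edge.length,
       ntip = length(tr$tip.label),
       tipstate = pat$tipstate[, ord, drop = FALSE],
       weights = pat$weights,
       conststate = pat$conststate,
       tree = tr)
}

.plik_call <- function(pd, eig, rates, want_grad = FALSE, elen = NULL) {
  cpp_plik(pd$edge, if (is.null(elen)) pd$elen else elen,
           pd$ntip, pd$tipstate, pd$weights,
           eig$U, eig$lambda, eig$Uinv, eig$pi,
           rates$rates, rates$weights, rates$p_inv,
           pd$conststate, want_grad)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over the (unrooted) tree under a GTR20 model with
#' discrete-gamma rate categories and an optional invariant-site class.
#' Site patterns are compressed before evaluation; gaps and ambiguity
#' codes contribute a partial likelihood of one over all states.
#'
#' @param msa a [protein_msa()].
#' @param tree an ape `phylo` with branch lengths; leaf set must match the
#'   alignment labels.
#' @param model a [substitution_model()].
#' @param rates a [discrete_gamma_rates()] object; defaults to the model's
#'   own `alpha`/`p_inv` (single rate if the model has no `alpha`).
#' @return The log-likelihood (numeric scalar).
#' @export
msa_log_likelihood <- function(msa, tree, model, rates = NULL) {
  stopifnot(inherits(msa, "protein_msa"), inherits(tree, "phylo"),
            inherits(model, "substitution_model"))
  if (is.null(rates)) rates <- .model_rates(model)
  pd <- .plik_data(msa, tree)
  eig <- .model_eigen(model)
  .plik_call(pd, eig, rates)$loglik
}

#' Bayesian information criterion
#'
#' @param lnL log-likelihood.
#' @param k number of free parameters (>= 0).
#' @param n_sites number of alignment sites (>= 1).
#' @return `k * log(n_sites) - 2 * lnL`.
#' @export
#' @examples
#' bic(-1000, 10, 100)
bic <- function(lnL, k, n_sites) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (k < 0) stop("k must be >= 0")
  k * log(n_sites) - 2 * lnL
}

#' Optimize branch lengths and rate heterogeneity on a fixed topology
#'
#' Maximizes the log-likelihood over branch lengths (jointly, quasi-Newton
#' on log lengths with analytic gradients) interleaved with 1-D golden
#' section/Brent optimization of the gamma shape `alpha` and, optionally,
#' the invariant-site proportion `p_inv`. The topology is never changed.
#' Branch lengths are constrained to `[1e-8, 20]` and `alpha` to
#' `[0.05, 100]`; iteration stops when the round-to-round improvement
#' drops below `tol` (default 1e-4) or after `max_rounds` rounds.
#'
#' @param msa a [protein_msa()].
#' @param tree starting tree (topology fixed, lengths used as start).
#' @param model a [substitution_model()]; its `R` and `pi` are held fixed.
#' @param optimize_alpha optimize the gamma shape? (default TRUE)
#' @param optimize_pinv optimize the invariant proportion? (default FALSE)
#' @param k number of gamma categories.
#' @param alpha starting shape (model's `alpha`, else 1).
#' @param p_inv starting invariant proportion (model's `p_inv`, else 0).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_rounds maximum optimization rounds.
#' @return An object of class `fit_result`: list with `lnL`, `tree`
#'   (optimized lengths), `alpha`, `p_inv`, `k_free_parameters`,
#'   `n_sites`, `bic`, `trace`.
#' @export
optimize_branch_lengths_and_rates <- function(msa, tree, model,
                                              optimize_alpha = TRUE,
                                              optimize_pinv = FALSE,
                                              k = 4L,
                                              alpha = NULL, p_inv = NULL,
                                              tol = 1e-4,
                                              max_rounds = 200L) {
  stopifnot(inherits(msa, "protein_msa"), inherits(tree, "phylo"))
  if (is.null(alpha)) alpha <- if (is.null(model$alpha)) 1 else model$alpha
  if (is.null(p_inv)) p_inv <- if (is.null(model$p_inv)) 0 else model$p_inv
  pd <- .plik_data(msa, tree)
  pd$elen <- pmin(pmax(pd$elen, 1e-8), 20)
  eig <- .model_eigen(model)

  lik_at <- function(elen, a, p) {
    r <- discrete_gamma_rates(a, k, p_inv = p)
    .plik_call(pd, eig, r, elen = elen)$loglik
  }

  opt_branches <- function(elen, a, p) {
    r <- discrete_gamma_rates(a, k, p_inv = p)
    fn <- function(lt) {
      -.plik_call(pd, eig, r, elen = exp(lt))$loglik
    }
    gr <- function(lt) {
      res <- .plik_call(pd, eig, r, want_grad = TRUE, elen = exp(lt))
      -res$dt * exp(lt)   # chain rule for log lengths
    }
    o <- stats::optim(log(elen), fn, gr, method = "L-BFGS-B",
                      lower = log(1e-8), upper = log(20),
                      control = list(maxit = 100L))
    if (!is.finite(o$value))
      stop("branch-length optimization produced a non-finite likelihood")
    exp(o$par)
  }

  lnL <- lik_at(pd$elen, alpha, p_inv)
  if (!is.finite(lnL))
    stop("non-finite starting likelihood for '", msa$id, "'")
  trace <- lnL
  for (round in seq_len(max_rounds)) {
    pd$elen <- opt_branches(pd$elen, alpha, p_inv)
    if (optimize_alpha) {
      oa <- stats::optimize(function(la) -lik_at(pd$elen, exp(la), p_inv),
                            interval = log(c(0.05, 100)), tol = 1e-3)
      alpha <- exp(oa$minimum)
    }
    if (optimize_pinv) {
      op <- stats::optimize(function(p) -lik_at(pd$elen, alpha, p),
                            interval = c(0, 0.9), tol = 1e-4)
      p_inv <- op$minimum
    }
    new <- lik_at(pd$elen, alpha, p_inv)
    trace <- c(trace, new)
    if (new - lnL < tol) { lnL <- max(lnL, new); break }
    lnL <- new
  }

  out_tree <- pd$tree
  out_tree$edge.length <- pd$elen
  kfree <- nrow(pd$tree$edge) + 1L + 19L + if (optimize_pinv) 1L else 0L
  structure(list(lnL = lnL, tree = out_tree, alpha = alpha,
                 p_inv = p_inv,
                 k_free_parameters = kfree,
                 n_sites = msa$n_sites,
                 bic = bic(lnL, kfree, msa$n_sites),
                 trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: lnL =", format(x$lnL, digits = 8),
      " alpha =", format(x$alpha, digits = 4),
      if (x$p_inv > 0) paste(" p_inv =", format(x$p_inv, digits = 3)) else "",
      "\n  k =", x$k_free_parameters, " n =", x$n_sites,
      " BIC =", format(x$bic, digits = 8), "\n")
  invisible(x)
}
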