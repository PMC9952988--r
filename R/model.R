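#' Construct a time-reversible amino-acid substitution model
#'
#' A `substitution_model` bundles the 190 relative exchangeabilities (REs)
#' of the 20-state general time-reversible (GTR) model, the equilibrium
#' frequencies, and optional among-site rate-heterogeneity parameters
#' (gamma shape `alpha`, invariant-site proportion `p_inv`). The
#' instantaneous rate of change from residue X to residue Y is
#' `r_XY * pi_Y`; see [build_rate_matrix()].
#'
#' @param name non-empty model identifier.
#' @param R numeric vector of 190 non-negative exchangeabilities in
#'   lower-triangle row-major order (see [aa_pair_names()]).
#' @param pi numeric vector of 20 positive equilibrium frequencies summing
#'   to 1 (renormalized if within 1e-3 of 1).
#' @param alpha optional positive gamma shape.
#' @param p_inv optional invariant-site proportion in `[0, 1)`.
#' @return An object of class `substitution_model`.
#' @export
#' @examples
#' m <- substitution_model("uniform", rep(1, 190), rep(0.05, 20))
#' m
substitution_model <- function(name, R, pi, alpha = NULL, p_inv = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("model name must be a non-empty string")
  R <- as.numeric(R)
  pi <- as.numeric(pi)
  if (length(R) != .N_PAIRS)
    stop("R must have exactly 190 entries, got ", length(R))
  if (any(!is.finite(R)) || any(R < 0))
    stop("exchangeabilities must be finite and non-negative")
  if (all(R == 0))
    stop("degenerate model: all exchangeabilities are zero")
  if (length(pi) != 20L)
    stop("pi must have exactly 20 entries, got ", length(pi))
  if (any(!is.finite(pi)) || any(pi <= 0))
    stop("frequencies must be finite and strictly positive")
  s <- sum(pi)
  if (abs(s - 1) > 1e-3)
    stop("frequencies sum to ", format(s), ", not 1")
  pi <- pi / s
  if (!is.null(alpha)) {
    alpha <- as.numeric(alpha)
    if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
      stop("alpha must be a positive number")
  }
  if (!is.null(p_inv)) {
    p_inv <- as.numeric(p_inv)
    if (length(p_inv) != 1L || !is.finite(p_inv) || p_inv < 0 || p_inv >= 1)
      stop("p_inv must lie in [0, 1)")
  }
  names(R) <- aa_pair_names()
  names(pi) <- AA_ALPHABET
  structure(list(name = name, R = R, pi = pi,
                 alpha = alpha, p_inv = p_inv),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("GTR20 substitution model '", x$name, "'\n", sep = "")
  Rn <- normalize_exchangeabilities(x$R)
  top <- order(Rn, decreasing = TRUE)[1:5]
  cat("  top exchangeabilities:",
      paste(sprintf("%s=%.4f", names(x$R)[top], Rn[top]), collapse = ", "),
      "\n")
  cat("  frequency range: [", format(min(x$pi), digits = 3), ", ",
      format(max(x$pi), digits = 3), "]\n", sep = "")
  if (!is.null(x$alpha)) cat("  gamma shape alpha:", format(x$alpha), "\n")
  if (!is.null(x$p_inv)) cat("  invariant proportion:", format(x$p_inv), "\n")
  invisible(x)
}

#' Normalize exchangeabilities to sum to one
#'
#' Model comparisons in this package are carried out on exchangeability
#' vectors rescaled to unit sum, which removes the arbitrary overall scale
#' of the GTR parameterization.
#'
#' @param R numeric vector of 190 non-negative values (or a
#'   `substitution_model`, whose `R` is extracted).
#' @return Numeric vector of 190 values summing to 1.
#' @export
normalize_exchangeabilities <- function(R) {
  if (inherits(R, "substitution_model")) R <- R$R
  R <- as.numeric(R)
  if (length(R) != .N_PAIRS) stop("R must have 190 entries")
  if (any(R < 0)) stop("exchangeabilities must be non-negative")
  s <- sum(R)
  if (s <= 0) stop("degenerate input: exchangeabilities sum to zero")
  out <- R / s
  names(out) <- aa_pair_names()
  out
}

#' Build the normalized instantaneous rate matrix
#'
#' Assembles the 20x20 GTR rate matrix `Q` with off-diagonal entries
#' `Q[i, j] = r_ij * pi_j`, diagonal entries set so rows sum to zero, and
#' the whole matrix rescaled to a mean rate of one
#' (`-sum(pi * diag(Q)) == 1`) so that branch lengths are expected
#' substitutions per site. Zero exchangeabilities are floored at `1e-8`
#' (with a message) to keep the chain irreducible for likelihood work.
#'
#' @param R exchangeability vector (190) or a `substitution_model`.
#' @param pi frequency vector (20); ignored when `R` is a model.
#' @param floor_zeros floor zero exchangeabilities at 1e-8 (default TRUE).
#' @return A 20x20 numeric matrix with residue dimnames.
#' @export
#' @examples
#' Q <- build_rate_matrix(rep(1, 190), rep(0.05, 20))
#' all.equal(-sum(diag(Q) * 0.05), 1)
build_rate_matrix <- function(R, pi = NULL, floor_zeros = TRUE) {
  if (inherits(R, "substitution_model")) {
    pi <- R$pi
    R <- R$R
  }
  R <- as.numeric(R)
  pi <- as.numeric(pi)
  if (length(R) != .N_PAIRS || length(pi) != 20L)
    stop("need 190 exchangeabilities and 20 frequencies")
  if (all(R == 0)) stop("degenerate input: all exchangeabilities are zero")
  if (floor_zeros && any(R < 1e-8)) {
    message("flooring ", sum(R < 1e-8), " zero/tiny exchangeabilities at 1e-8")
    R[R < 1e-8] <- 1e-8
  }
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- .pair_to_lowertri(R)
  S <- S + t(S)
  Q <- S * rep(pi, each = 20)   # Q[i, j] = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  Q
}

# reorder a pair-storage vector (row-major lower triangle) into R's
# column-major lower.tri order, and back
.pair_to_lowertri <- function(R) {
  idx <- .pair_indices()
  M <- matrix(0, 20, 20)
  M[idx] <- R
  M[lower.tri(M)]
}

.lowertri_to_pair <- function(lt) {
  M <- matrix(0, 20, 20)
  M[lower.tri(M)] <- lt
  idx <- .pair_indices()
  M[idx]
}

#' Count free parameters of standard model classes
#'
#' The 20-state GTR model has 190 exchangeabilities (one fixed by scale)
#' plus 19 free frequencies: 208 free parameters. The unrestricted 20-state
#' model has 380 directed rates (one fixed by scale) plus 19 frequencies:
#' 398. The 4-state nucleotide GTR has 5 + 3 = 8.
#'
#' @param model_class one of `"GTR20"`, `"UNREST20"`, `"GTR4"`.
#' @return Integer number of free parameters.
#' @export
#' @examples
#' count_free_parameters("GTR20")   # 208
#' count_free_parameters("UNREST20") # 398
count_free_parameters <- function(model_class) {
  if (!is.character(model_class) || length(model_class) != 1L)
    stop("model_class must be a single string")
  switch(model_class,
    GTR20    = 190L - 1L + 19L,
    UNREST20 = 380L - 1L + 19L,
    GTR4     = 6L - 1L + 3L,
    stop("unknown model class: ", model_class)
  )
}
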