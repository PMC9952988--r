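# Analyses of what drives model differences: group means and ranked RE
# differences, amino-acid class frequencies against genomic GC content,
# Spearman correlation, and acidic:basic frequency ratios.

#' Average a group of models
#'
#' Arithmetic mean of the normalized exchangeability vectors (renormalized,
#' a no-op since each summand sums to 1) and of the frequency vectors.
#'
#' @param models non-empty list of [substitution_model()] objects.
#' @param name name for the mean model.
#' @return A [substitution_model()].
#' @export
group_mean_model <- function(models, name = "group_mean") {
  if (length(models) == 0L) stop("models must be non-empty")
  stopifnot(all(vapply(models, inherits, logical(1),
                       "substitution_model")))
  Rm <- rowMeans(vapply(models,
                        function(m) normalize_exchangeabilities(m$R),
                        numeric(190)))
  pim <- rowMeans(vapply(models, function(m) m$pi, numeric(20)))
  substitution_model(name, normalize_exchangeabilities(Rm),
                     pim / sum(pim))
}

#' Ranked exchangeability differences between two model groups
#'
#' Computes, per residue pair, `mean(group B) - mean(group A)` on
#' normalized exchangeabilities, and ranks the 190 differences in
#' ascending order: rank 1 is the pair most elevated in group A, rank 190
#' the pair most elevated in group B. Ties are broken by lexicographic
#' pair label. Because both group means are normalized, the differences
#' sum to zero.
#'
#' @param groupA,groupB non-empty lists of [substitution_model()].
#' @return A data frame of class `re_difference_table` with columns
#'   `pair`, `difference`, `rank`, ordered by rank.
#' @export
rank_re_differences <- function(groupA, groupB) {
  mA <- group_mean_model(groupA)
  mB <- group_mean_model(groupB)
  diff <- normalize_exchangeabilities(mB$R) -
    normalize_exchangeabilities(mA$R)
  pair <- aa_pair_names()
  ord <- order(diff, pair)
  out <- data.frame(pair = pair[ord], difference = diff[ord],
                    rank = seq_len(190L), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("re_difference_table", "data.frame")
  out
}

#' Extreme pairs of an RE-difference table
#'
#' @param table an [rank_re_differences()] result.
#' @param n_top how many pairs from each end (1..95).
#' @return List with data frames `bottom` (ranks 1..n_top, most elevated
#'   in group A) and `top` (ranks 191-n_top..190, most elevated in
#'   group B).
#' @export
outlier_re_pairs <- function(table, n_top = 3L) {
  stopifnot(inherits(table, "re_difference_table"))
  if (n_top < 1L || n_top > 95L) stop("n_top must be in 1..95")
  tab <- table[order(table$rank), ]
  list(bottom = tab[seq_len(n_top), ],
       top = tab[seq(191L - n_top, 190L), ])
}

# residue classes by codon GC content
.GARP <- c("G", "A", "R", "P")
.FYMINK <- c("F", "Y", "M", "I", "N", "K")

#' Amino-acid class frequencies versus genomic GC content
#'
#' For each model, sums the equilibrium frequencies of the GARP residues
#' (GC-rich codons), the FYMINK residues (GC-poor codons) and the
#' remainder, then regresses each class sum on genomic GC% by ordinary
#' least squares.
#'
#' @param models list of [substitution_model()].
#' @param gc numeric vector of genomic GC values (percent), one per
#'   model.
#' @return An object of class `frequency_class_summary`: list with
#'   `per_model` (data frame: model, gc, f_garp, f_fymink, f_other) and
#'   `regressions` (data frame per class: slope, intercept, r_squared),
#'   the latter NULL with a warning when fewer than 2 models are given.
#' @export
frequency_class_summary <- function(models, gc) {
  if (length(gc) != length(models))
    stop("gc must align with models")
  if (any(!is.finite(gc))) stop("gc values must be finite")
  per <- data.frame(
    model = vapply(models, function(m) m$name, character(1)),
    gc = gc,
    f_garp = vapply(models, function(m) sum(m$pi[.GARP]), numeric(1)),
    f_fymink = vapply(models, function(m) sum(m$pi[.FYMINK]), numeric(1)))
  per$f_other <- 1 - per$f_garp - per$f_fymink
  regressions <- NULL
  if (length(models) < 2L) {
    warning("need >= 2 models for class regressions; skipped")
  } else {
    regressions <- do.call(rbind, lapply(
      c(f_garp = "f_garp", f_fymink = "f_fymink", f_other = "f_other"),
      function(cl) {
        fit <- stats::lm(per[[cl]] ~ gc, data = per)
        data.frame(class = cl,
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r_squared = summary(fit)$r.squared)
      }))
    rownames(regressions) <- NULL
  }
  structure(list(per_model = per, regressions = regressions),
            class = "frequency_class_summary")
}

#' @export
print.frequency_class_summary <- function(x, ...) {
  cat("frequency_class_summary over", nrow(x$per_model), "models\n")
  if (!is.null(x$regressions)) print(x$regressions)
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of the (average-tie) ranks; the
#' two-sided p-value uses the t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_correlation(1:5, c(2, 1, 4, 3, 5))
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined for a constant vector")
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = p, n = n)
}

#' Acidic to basic residue ratio
#'
#' `(pi_D + pi_E) / (pi_R + pi_K + pi_H)` from a model's equilibrium
#' frequencies. Histidine counts as basic by default; set
#' `include_histidine = FALSE` to restrict the denominator to R and K.
#'
#' @param pi frequency vector of length 20 (or a `substitution_model`).
#' @param include_histidine include H in the basic class (default TRUE).
#' @return Numeric ratio.
#' @export
#' @examples
#' acidic_basic_ratio(rep(0.05, 20))  # 2/3
acidic_basic_ratio <- function(pi, include_histidine = TRUE) {
  if (inherits(pi, "substitution_model")) pi <- pi$pi
  if (length(pi) != 20L) stop("pi must have 20 entries")
  names(pi) <- AA_ALPHABET
  basic <- if (include_histidine) c("R", "K", "H") else c("R", "K")
  sum(pi[c("D", "E")]) / sum(pi[basic])
}
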