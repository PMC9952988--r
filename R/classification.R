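# Model-fit classification: best-fitting model per alignment by BIC, and
# recall at the precise (clade) and domain levels.

#' Bundle candidate models with their metadata
#'
#' @param models named list of [substitution_model()] objects.
#' @param clade character vector of clade ids, one per model.
#' @param domain character vector of domain labels (`"bacteria"`,
#'   `"archaea"`, `"eukaryote"`, or `"universal"` for models without a
#'   clade of origin).
#' @param family model family label (e.g. `"generalized"`,
#'   `"ribosomal"`, `"published"`); recycled.
#' @return An object of class `candidate_set`.
#' @export
candidate_set <- function(models, clade, domain,
                          family = "generalized") {
  nm <- names(models)
  if (is.null(nm)) nm <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("candidate model names must be unique")
  if (length(clade) != length(models) || length(domain) != length(models))
    stop("clade and domain must align with models")
  ok <- domain %in% c("bacteria", "archaea", "eukaryote", "universal")
  if (!all(ok)) stop("unknown domain label(s): ",
                     paste(unique(domain[!ok]), collapse = ", "))
  structure(list(models = stats::setNames(models, nm),
                 info = data.frame(name = nm, clade = clade,
                                   domain = domain,
                                   family = rep_len(family, length(models)),
                                   stringsAsFactors = FALSE)),
            class = "candidate_set")
}

#' Best-fitting model for one alignment
#'
#' Follows the single-tree protocol: (1) estimate one tree for the
#' alignment under a reference model combined with the alignment's
#' empirical frequencies (+F) and 4-category gamma rates; (2) for each
#' candidate, keep that topology, swap in the candidate's
#' exchangeabilities (still +F), re-optimize branch lengths and the gamma
#' shape, and score with BIC; (3) return the candidate minimizing BIC.
#' All candidates share the same number of free parameters, so the BIC
#' ranking equals the likelihood ranking. Ties (BIC within 1e-6) keep the
#' first candidate and set the tie flag.
#'
#' @param msa a [protein_msa()] with >= 3 sequences.
#' @param candidates a [candidate_set()].
#' @param reference_model model used for the initial tree search;
#'   defaults to the pooled average of the candidates
#'   ([group_mean_model()]).
#' @param k gamma categories.
#' @return An object of class `classification_result`: list with
#'   `msa_id`, `best`, `tie`, `scores` (data frame: name, lnL, bic).
#' @export
best_fit_model <- function(msa, candidates, reference_model = NULL,
                           k = 4L) {
  stopifnot(inherits(msa, "protein_msa"),
            inherits(candidates, "candidate_set"))
  if (length(candidates$models) < 1L) stop("need at least one candidate")
  if (msa$n_taxa < 3L) stop("classification needs >= 3 sequences")
  if (is.null(reference_model))
    reference_model <- group_mean_model(candidates$models,
                                        name = "reference")
  empf <- empirical_frequencies(msa)
  ref_f <- substitution_model(reference_model$name, reference_model$R,
                              empf, alpha = reference_model$alpha)
  tree <- estimate_msa_tree(msa, ref_f, k = k)
  ref_fit <- attr(tree, "fit")

  nms <- names(candidates$models)
  lnL <- numeric(length(nms))
  bics <- numeric(length(nms))
  ok <- logical(length(nms))
  kfree <- NA_integer_
  for (i in seq_along(nms)) {
    cand <- candidates$models[[i]]
    m <- tryCatch(
      substitution_model(cand$name, cand$R, empf, alpha = cand$alpha),
      error = function(e) NULL)
    if (is.null(m)) {
      warning("skipping invalid candidate '", nms[i], "'")
      lnL[i] <- -Inf
      bics[i] <- Inf
      next
    }
    fit <- optimize_branch_lengths_and_rates(
      msa, tree, m, optimize_alpha = TRUE, k = k,
      alpha = if (is.null(ref_fit)) 1 else ref_fit$alpha,
      max_rounds = 3L)
    lnL[i] <- fit$lnL
    bics[i] <- fit$bic
    kfree <- fit$k_free_parameters
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no valid candidate could be scored")
  best <- which.min(bics)
  tie <- sum(abs(bics - bics[best]) < 1e-6) > 1L
  structure(list(msa_id = msa$id,
                 best = nms[best],
                 tie = tie,
                 scores = data.frame(msa_id = msa$id, model = nms,
                                     lnL = lnL,
                                     k = kfree, n_sites = msa$n_sites,
                                     bic = bics,
                                     stringsAsFactors = FALSE)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification of '", x$msa_id, "': best = ", x$best,
      if (x$tie) " (tie)" else "", "\n", sep = "")
  invisible(x)
}

#' Classify many alignments
#'
#' @param msas list of [protein_msa()].
#' @param candidates a [candidate_set()].
#' @param truth optional data frame with columns `msa_id`, `clade`,
#'   `domain` giving each alignment's origin (e.g. a synthetic dataset
#'   manifest); attached to the results for [compute_recall()].
#' @param ... passed to [best_fit_model()].
#' @return List of `classification_result` with attribute `truth`.
#' @export
classify_msas <- function(msas, candidates, truth = NULL, ...) {
  res <- lapply(msas, best_fit_model, candidates = candidates, ...)
  attr(res, "truth") <- truth
  res
}

#' Flatten classification results into a score table
#'
#' One row per (alignment, candidate): msa id, model name, lnL, number of
#' free parameters, sites, and BIC — the shape used for on-disk TSV
#' output via [utils::write.table()].
#'
#' @param results list of `classification_result`.
#' @return A data frame.
#' @export
classification_table <- function(results) {
  out <- do.call(rbind, lapply(results, function(r) {
    s <- r$scores
    s$best <- s$model == r$best
    s$tie <- r$tie
    s
  }))
  rownames(out) <- NULL
  out
}

#' Recall of model-fit classification
#'
#' For every truth clade: precise recall is the fraction of its
#' alignments whose best-fitting model was trained on that clade; the
#' per-domain match fractions are the fractions whose best-fitting model
#' carries each domain label. Candidates labeled `"universal"` are
#' reported in their own column and excluded from the named domain
#' fractions.
#'
#' @param results list of `classification_result`.
#' @param candidates the [candidate_set()] used.
#' @param truth data frame with `msa_id`, `clade`, `domain`; defaults to
#'   the `truth` attribute attached by [classify_msas()].
#' @return A data frame of class `recall_report`: one row per truth
#'   clade with `n`, `precise_recall`, one column per domain, `universal`
#'   and `tie_fraction`.
#' @export
compute_recall <- function(results, candidates, truth = NULL) {
  if (is.null(truth)) truth <- attr(results, "truth")
  if (is.null(truth)) stop("truth labels are required")
  ids <- vapply(results, function(r) r$msa_id, character(1))
  mt <- match(ids, truth$msa_id)
  if (anyNA(mt))
    stop("missing truth labels for: ",
         paste(ids[is.na(mt)], collapse = ", "))
  info <- candidates$info
  best <- vapply(results, function(r) r$best, character(1))
  bi <- match(best, info$name)
  df <- data.frame(truth_clade = truth$clade[mt],
                   truth_domain = truth$domain[mt],
                   best_clade = info$clade[bi],
                   best_domain = info$domain[bi],
                   tie = vapply(results, function(r) r$tie, logical(1)))
  domains <- c("archaea", "bacteria", "eukaryote")
  out <- do.call(rbind, lapply(split(df, df$truth_clade), function(d) {
    row <- data.frame(clade = d$truth_clade[1],
                      domain = d$truth_domain[1],
                      n = nrow(d),
                      precise_recall = mean(d$best_clade == d$truth_clade))
    for (dom in domains)
      row[[paste0(dom, "_match")]] <- mean(d$best_domain == dom)
    row$universal_match <- mean(d$best_domain == "universal")
    row$tie_fraction <- mean(d$tie)
    row
  }))
  rownames(out) <- NULL
  class(out) <- c("recall_report", "data.frame")
  out
}
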