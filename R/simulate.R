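# Synthetic-data generator: random topologies drawn uniformly from all
# labeled unrooted binary topologies, controlled perturbations of a base
# model, and forward simulation of alignments under GTR20 + gamma (+I).

#' Uniform random unrooted binary topology
#'
#' Draws a topology uniformly from the (2n-5)!! labeled unrooted binary
#' topologies by sequential leaf addition: leaf k is attached to one of the
#' current 2k-5 edges chosen uniformly. Branch lengths are i.i.d.
#' exponential with mean `depth_scale`.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param seed optional integer seed (the R RNG is seeded when given).
#' @param labels leaf labels (default `t1..tn`).
#' @param depth_scale mean of the exponential branch-length distribution.
#' @return An ape `phylo` (unrooted).
#' @export
#' @examples
#' tr <- generate_random_topology(6, seed = 1)
generate_random_topology <- function(n_leaves, seed = NULL,
                                     labels = NULL,
                                     depth_scale = 0.15) {
  if (n_leaves < 3L) stop("n_leaves must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_leaves))
  if (length(labels) != n_leaves) stop("need one label per leaf")
  # adjacency list on arbitrary node ids: leaves 1..n, internals n+1...
  n <- as.integer(n_leaves)
  nextnode <- n + 1L
  edges <- matrix(c(nextnode, 1L, nextnode, 2L, nextnode, 3L),
                  ncol = 2L, byrow = TRUE)
  nextnode <- nextnode + 1L
  if (n > 3L) {
    for (k in 4:n) {
      e <- sample.int(nrow(edges), 1L)
      u <- edges[e, 1L]; v <- edges[e, 2L]
      w <- nextnode; nextnode <- nextnode + 1L
      edges[e, ] <- c(u, w)
      edges <- rbind(edges, c(w, v), c(w, k))
    }
  }
  # serialize to Newick from internal node n+1
  adj <- vector("list", nextnode - 1L)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  nwk <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0L) return(labels[node])
    paste0("(", paste(vapply(kids, nwk, character(1), parent = node),
                      collapse = ","), ")")
  }
  tr <- ape::read.tree(text = paste0(nwk(n + 1L, 0L), ";"))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / depth_scale)
  ape::unroot(tr)
}

#' Perturb a substitution model
#'
#' Adds independent normal(0, `magnitude`) offsets to the log
#' exchangeabilities of the targeted pairs (default: all 190) and
#' renormalizes. `magnitude = 0` returns the base model exactly. Expected
#' distance from the base model ([model_distance()]) grows with
#' `magnitude`, which is how the synthetic generator creates clades whose
#' models differ by a controlled amount.
#'
#' @param base a [substitution_model()].
#' @param magnitude standard deviation of the log-RE offsets (>= 0).
#' @param target_pairs optional character vector of pair labels (e.g.
#'   `"F-Y"`) to perturb; others change only through renormalization.
#' @param seed optional integer seed.
#' @param name name of the derived model.
#' @return A [substitution_model()].
#' @export
#' @examples
#' base <- synthetic_base_model()
#' m <- perturb_model(base, 0.5, seed = 1)
perturb_model <- function(base, magnitude, target_pairs = NULL,
                          seed = NULL,
                          name = paste0(base$name, "_pert")) {
  stopifnot(inherits(base, "substitution_model"))
  if (!is.finite(magnitude) || magnitude < 0)
    stop("magnitude must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (is.null(target_pairs)) seq_len(.N_PAIRS)
         else aa_pair_index(target_pairs)
  R <- base$R
  if (magnitude > 0) {
    R[idx] <- exp(log(pmax(R[idx], 1e-12)) +
                  stats::rnorm(length(idx), 0, magnitude))
  }
  substitution_model(name, normalize_exchangeabilities(R), base$pi,
                     alpha = base$alpha, p_inv = base$p_inv)
}

#' Simulate a protein alignment along a tree
#'
#' Forward simulation under the model: the root state of each site is
#' drawn from the equilibrium frequencies, a rate category (including the
#' invariant class, if any) is drawn per site, and states evolve along
#' each branch with `P(t * rate)`. Sites in the invariant class inherit
#' the root state at every leaf.
#'
#' @param tree ape `phylo` with branch lengths.
#' @param model a [substitution_model()].
#' @param n_sites number of columns to simulate.
#' @param rates a [discrete_gamma_rates()]; defaults to the model's own
#'   heterogeneity parameters.
#' @param seed optional integer seed.
#' @param id alignment id.
#' @return A [protein_msa()].
#' @export
simulate_msa <- function(tree, model, n_sites, rates = NULL,
                         seed = NULL, id = "sim") {
  stopifnot(inherits(tree, "phylo"), inherits(model, "substitution_model"))
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rates)) rates <- .model_rates(model)
  n_sites <- as.integer(n_sites)
  Q <- build_rate_matrix(model$R, model$pi)
  eig <- .eigen_q(Q, model$pi)
  ntip <- length(tree$tip.label)

  # per-site category: 0 = invariant
  ncat <- length(rates$rates)
  catp <- c(rates$p_inv, rates$weights)
  sitecat <- sample.int(ncat + 1L, n_sites, replace = TRUE,
                        prob = catp) - 1L
  siterate <- ifelse(sitecat == 0L, 0, rates$rates[pmax(sitecat, 1L)])

  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tr$edge)
  states <- matrix(0L, nnode, n_sites)
  root <- tr$edge[nrow(tr$edge), 1L]
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$pi)
  # preorder: reverse postorder guarantees parents are assigned first
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    child <- states[par, ]
    for (r in unique(siterate)) {
      if (r == 0) next  # invariant sites keep the parent state
      sel <- which(siterate == r)
      P <- eig$U %*% (exp(eig$lambda * tr$edge.length[e] * r) * eig$Uinv)
      P[P < 0] <- 0
      for (s in unique(child[sel])) {
        at <- sel[child[sel] == s]
        child[at] <- sample.int(20L, length(at), replace = TRUE,
                                prob = P[s, ])
      }
    }
    states[ch, ] <- child
  }
  seqmat <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]],
                   nrow = ntip)
  rownames(seqmat) <- tr$tip.label
  protein_msa(seqmat, id = id)
}

#' Specify a synthetic clade
#'
#' @param clade clade identifier.
#' @param domain one of `"bacteria"`, `"archaea"`, `"eukaryote"`.
#' @param model the clade's true [substitution_model()].
#' @param n_msas number of alignments to simulate (>= 1).
#' @param sites_range integer range `c(min, max)` of alignment lengths.
#' @param taxa_range integer range of taxa per alignment.
#' @param depth_scale mean branch length of the per-alignment trees.
#' @param gc genomic GC content recorded in the manifest.
#' @param seed clade-level seed.
#' @return An object of class `clade_spec`.
#' @export
clade_spec <- function(clade, domain = c("bacteria", "archaea", "eukaryote"),
                       model, n_msas = 30L,
                       sites_range = c(200L, 500L),
                       taxa_range = c(8L, 16L),
                       depth_scale = 0.15,
                       gc = 0.5, seed = 1L) {
  domain <- match.arg(domain)
  stopifnot(inherits(model, "substitution_model"))
  if (n_msas < 1L) stop("n_msas must be >= 1")
  if (length(sites_range) != 2L || sites_range[1] > sites_range[2])
    stop("sites_range must be a non-empty range")
  if (length(taxa_range) != 2L || taxa_range[1] > taxa_range[2])
    stop("taxa_range must be a non-empty range")
  structure(list(clade = clade, domain = domain, model = model,
                 n_msas = as.integer(n_msas),
                 sites_range = as.integer(sites_range),
                 taxa_range = as.integer(taxa_range),
                 depth_scale = depth_scale, gc = gc,
                 seed = as.integer(seed)),
            class = "clade_spec")
}

#' Generate a multi-clade synthetic dataset
#'
#' For every clade specification, draws `n_msas` random trees (taxa count
#' uniform in the clade's range), simulates alignments (length uniform in
#' the sites range) under the clade's true model, and assigns each
#' alignment to the training or validation split. A manifest records
#' clade, domain, alignment id, size and the per-alignment seed, which
#' makes the dataset fully reproducible.
#'
#' @param specs list of [clade_spec()] objects.
#' @param seed master seed; combined with each clade's seed.
#' @param train_fraction fraction of alignments in the training split.
#' @param dir optional directory: when given, FASTA alignments, Newick
#'   trees, PAML truth models and a TSV manifest are written under it.
#' @return An object of class `synthetic_dataset`: list with `clades`
#'   (per clade: list of `msa`, `tree`), `manifest` (data frame), `specs`.
#' @export
generate_clade_dataset <- function(specs, seed = 1L,
                                   train_fraction = 0.8,
                                   dir = NULL) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  stopifnot(all(vapply(specs, inherits, logical(1), "clade_spec")))
  clades <- list()
  manifest <- NULL
  for (sp in specs) {
    set.seed(as.integer((as.numeric(seed) * 7919 +
                           as.numeric(sp$seed)) %%
                          .Machine$integer.max))
    msa_seeds <- sample.int(2^30, sp$n_msas)
    n_train <- max(1L, round(train_fraction * sp$n_msas))
    split <- c(rep("train", n_train),
               rep("validation", sp$n_msas - n_train))
    entries <- vector("list", sp$n_msas)
    for (i in seq_len(sp$n_msas)) {
      set.seed(msa_seeds[i])
      tx <- seq.int(sp$taxa_range[1], sp$taxa_range[2])
      st <- seq.int(sp$sites_range[1], sp$sites_range[2])
      ntaxa <- tx[sample.int(length(tx), 1L)]
      nsites <- st[sample.int(length(st), 1L)]
      tree <- generate_random_topology(ntaxa,
                                       depth_scale = sp$depth_scale)
      id <- sprintf("%s_msa%03d", sp$clade, i)
      msa <- simulate_msa(tree, sp$model, nsites, id = id)
      entries[[i]] <- list(msa = msa, tree = tree)
      manifest <- rbind(manifest, data.frame(
        clade = sp$clade, domain = sp$domain, msa_id = id,
        n_taxa = ntaxa, n_sites = nsites, gc = sp$gc,
        seed = msa_seeds[i], split = split[i],
        stringsAsFactors = FALSE))
    }
    clades[[sp$clade]] <- entries
  }
  ds <- structure(list(clades = clades, manifest = manifest,
                       specs = specs),
                  class = "synthetic_dataset")
  if (!is.null(dir)) write_clade_dataset(ds, dir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$clades), "clades,",
      nrow(x$manifest), "alignments\n")
  print(table(x$manifest$clade, x$manifest$split))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits one FASTA and one Newick file per alignment, one PAML model file
#' per clade, and `manifest.tsv`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_clade_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in dataset$specs) {
    write_paml_model(sp$model,
                     file.path(dir, paste0(sp$clade, "_truth.dat")))
  }
  for (cl in names(dataset$clades)) {
    for (entry in dataset$clades[[cl]]) {
      write_fasta_msa(entry$msa,
                      file.path(dir, paste0(entry$msa$id, ".fasta")))
      writeLines(write_newick(entry$tree),
                 file.path(dir, paste0(entry$msa$id, ".nwk")))
    }
  }
  utils::write.table(dataset$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
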