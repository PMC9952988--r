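#' Construct a protein multiple sequence alignment
#'
#' Sequences are stored as a character matrix (taxa x sites) of upper-case
#' one-letter codes. Gaps (`-`) and ambiguity codes (`X B Z J * ? .`) are
#' retained but treated as missing data by the likelihood machinery.
#'
#' @param sequences named character vector of aligned sequences, or a
#'   character matrix (rows = taxa) of single residues.
#' @param id alignment identifier.
#' @return An object of class `protein_msa` with elements `id`, `seq`
#'   (character matrix), `n_taxa`, `n_sites`.
#' @export
#' @examples
#' protein_msa(c(a = "ARND", b = "ARNE"))
protein_msa <- function(sequences, id = "msa") {
  if (is.character(sequences) && !is.matrix(sequences)) {
    labs <- names(sequences)
    if (is.null(labs) || any(!nzchar(labs)))
      stop("sequences must be named")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("sequences have unequal lengths")
    seq <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(seq) <- labs
  } else if (is.matrix(sequences)) {
    seq <- toupper(sequences)
    dim(seq) <- dim(sequences)
    rownames(seq) <- rownames(sequences)
  } else {
    stop("sequences must be a named character vector or matrix")
  }
  if (nrow(seq) < 2L) stop("an alignment needs at least 2 sequences")
  if (ncol(seq) < 1L) stop("an alignment needs at least 1 site")
  if (anyDuplicated(rownames(seq)))
    stop("duplicate sequence labels")
  .encode_residues(seq)  # validates symbols
  structure(list(id = id, seq = seq,
                 n_taxa = nrow(seq), n_sites = ncol(seq)),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein_msa '", x$id, "': ", x$n_taxa, " taxa x ",
      x$n_sites, " sites\n", sep = "")
  invisible(x)
}

#' Read / write a protein alignment in FASTA format
#'
#' Thin wrappers around ape's FASTA support that validate alignment
#' structure on the way in.
#'
#' @param path file path.
#' @param id alignment id (defaults to file name).
#' @return `read_fasta_msa` returns a [protein_msa()]; `write_fasta_msa`
#'   returns `path` invisibly.
#' @export
read_fasta_msa <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  aa <- ape::read.FASTA(path, type = "AA")
  m <- toupper(as.character(as.matrix(aa)))
  protein_msa(m, id = id)
}

#' @param msa a [protein_msa()].
#' @rdname read_fasta_msa
#' @export
write_fasta_msa <- function(msa, path) {
  stopifnot(inherits(msa, "protein_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(msa$n_taxa)) {
    writeLines(c(paste0(">", rownames(msa$seq)[i]),
                 paste(msa$seq[i, ], collapse = "")), con)
  }
  invisible(path)
}

# Compress an alignment into unique site patterns.
# Returns tipstate (npat x ntaxa integer matrix, 0-based, -1 missing),
# weights, and conststate (state of constant patterns, -1 all-missing,
# -2 variable) for the invariant-site class.
.msa_patterns <- function(msa) {
  code <- matrix(.encode_residues(msa$seq), nrow = msa$n_taxa)
  key <- apply(code, 2, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  tipstate <- t(code[, first, drop = FALSE])
  conststate <- apply(tipstate, 1, function(p) {
    obs <- unique(p[p >= 0])
    if (length(obs) == 0L) -1L
    else if (length(obs) == 1L) obs
    else -2L
  })
  list(tipstate = tipstate, weights = weights,
       conststate = as.integer(conststate),
       labels = rownames(msa$seq))
}

#' Observed amino-acid proportions of an alignment
#'
#' Counts residues over all sequences, ignoring gaps and ambiguity codes,
#' floors unobserved residues at `1e-6`, and renormalizes. These are the
#' "+F" empirical frequencies used during model-fit classification.
#'
#' @param msa a [protein_msa()].
#' @return Named frequency vector of length 20.
#' @export
empirical_frequencies <- function(msa) {
  stopifnot(inherits(msa, "protein_msa"))
  code <- .encode_residues(msa$seq)
  code <- code[code >= 0]
  if (length(code) == 0L)
    stop("alignment '", msa$id, "' has no countable residues")
  f <- tabulate(code + 1L, nbins = 20L) / length(code)
  f <- pmax(f, 1e-6)
  f <- f / sum(f)
  names(f) <- AA_ALPHABET
  f
}
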