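#' The canonical amino-acid alphabet
#'
#' All exchangeability vectors, frequency vectors and file formats in this
#' package use the PAML residue order `A R N D C Q E G H I L K M F P S T W Y V`.
#' The gap symbol is `-`; the symbols `X B Z J * ?` (and `.`) are treated as
#' missing data.
#'
#' @format A character vector of the 20 one-letter residue codes.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname AA_ALPHABET
#' @export
AA_GAP <- "-"

#' @rdname AA_ALPHABET
#' @export
AA_MISSING <- c("X", "B", "Z", "J", "*", "?", ".", "-")

.N_PAIRS <- 190L

#' Names of the 190 unordered residue pairs
#'
#' Pairs are listed in lower-triangle row-major order of the canonical
#' alphabet: `R-A`, `N-A`, `N-R`, `D-A`, ... (row residue first). This is the
#' storage order of every exchangeability vector in the package and the order
#' of the PAML rate-matrix file format.
#'
#' @param sep separator between the two residue codes.
#' @return Character vector of length 190.
#' @export
#' @examples
#' head(aa_pair_names())
aa_pair_names <- function(sep = "-") {
  out <- character(.N_PAIRS)
  k <- 0L
  for (i in 2:20) {
    for (j in 1:(i - 1)) {
      k <- k + 1L
      out[k] <- paste(AA_ALPHABET[i], AA_ALPHABET[j], sep = sep)
    }
  }
  out
}

# (row, col) 1-based indices of each pair in storage order
.pair_indices <- function() {
  idx <- matrix(0L, .N_PAIRS, 2L)
  k <- 0L
  for (i in 2:20) {
    for (j in 1:(i - 1)) {
      k <- k + 1L
      idx[k, ] <- c(i, j)
    }
  }
  idx
}

#' Position of a residue pair in the exchangeability vector
#'
#' Accepts pair labels such as `"F-Y"` or `"Y-F"` (order and separator are
#' irrelevant) and returns the index into the 190-element storage order.
#'
#' @param pairs character vector of pair labels.
#' @return Integer vector of indices in 1..190.
#' @export
#' @examples
#' aa_pair_index("F-Y")
aa_pair_index <- function(pairs) {
  idx <- .pair_indices()
  key <- paste(pmax(idx[, 1], idx[, 2]), pmin(idx[, 1], idx[, 2]))
  out <- vapply(pairs, function(p) {
    res <- strsplit(p, "[-/ ]")[[1]]
    res <- res[nzchar(res)]
    if (length(res) != 2L) stop("malformed pair label: ", p)
    ij <- match(toupper(res), AA_ALPHABET)
    if (anyNA(ij)) stop("unknown residue in pair label: ", p)
    if (ij[1] == ij[2]) stop("pair label repeats a residue: ", p)
    match(paste(max(ij), min(ij)), key)
  }, integer(1))
  unname(out)
}

# map residue characters to 0-based state indices; -1 for gap/ambiguity;
# error on anything else
.encode_residues <- function(x) {
  up <- toupper(x)
  code <- match(up, AA_ALPHABET)
  miss <- up %in% AA_MISSING
  bad <- is.na(code) & !miss
  if (any(bad)) {
    stop("invalid residue symbol(s): ",
         paste(unique(up[bad]), collapse = " "))
  }
  out <- as.integer(code) - 1L
  out[miss] <- -1L
  out
}
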