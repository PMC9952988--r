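#' Read a substitution model from a PAML rate-matrix file
#'
#' The PAML amino-acid "dat" format holds the lower triangle of the
#' symmetric exchangeability matrix as 19 whitespace-delimited rows
#' (row 2 of the matrix first), followed by a line of 20 equilibrium
#' frequencies, all in the canonical residue order
#' `A R N D C Q E G H I L K M F P S T W Y V`. Anything after the frequency
#' line (comments, references) is ignored.
#'
#' @param path path to the model file.
#' @param name model name; defaults to the file name without extension.
#' @return A [substitution_model()].
#' @export
read_paml_model <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  R <- numeric(0)
  freqs <- NULL
  row <- 0L
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    tok <- strsplit(txt, "\\s+")[[1]]
    if (row < 19L) {
      row <- row + 1L
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals))
        stop("line ", ln, ": non-numeric token in triangle row ", row)
      if (length(vals) != row)
        stop("line ", ln, ": triangle row ", row, " has ", length(vals),
             " entries, expected ", row)
      if (any(vals < 0))
        stop("line ", ln, ": negative exchangeability")
      R <- c(R, vals)
    } else if (is.null(freqs)) {
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals))
        stop("line ", ln, ": non-numeric token in frequency line")
      if (length(vals) != 20L)
        stop("line ", ln, ": frequency line has ", length(vals),
             " entries, expected 20")
      if (any(vals < 0))
        stop("line ", ln, ": negative frequency")
      freqs <- vals
    } else {
      break  # trailing comments
    }
  }
  if (row < 19L)
    stop("malformed model file: found only ", row,
         " of 19 lower-triangle rows")
  if (is.null(freqs))
    stop("malformed model file: missing frequency line")
  substitution_model(name, R, freqs)
}

#' Write a substitution model to a PAML rate-matrix file
#'
#' @param model a [substitution_model()].
#' @param path output path.
#' @param digits significant digits (>= 6) used for each value.
#' @return Invisibly, `path`.
#' @export
write_paml_model <- function(model, path, digits = 10) {
  stopifnot(inherits(model, "substitution_model"))
  if (digits < 6) stop("use at least 6 significant digits")
  fmt <- function(x) formatC(x, digits = digits, format = "g", width = -1)
  lines <- character(20L)
  k <- 0L
  for (i in 2:20) {
    lines[i - 1L] <- paste(fmt(model$R[(k + 1L):(k + i - 1L)]),
                           collapse = " ")
    k <- k + i - 1L
  }
  lines[20L] <- paste(fmt(model$pi), collapse = " ")
  ok <- tryCatch({
    writeLines(c(lines[1:19], "", lines[20L]), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write model file: ", path)
  invisible(path)
}
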