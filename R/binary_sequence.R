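#' Construct a binary sequence
#'
#' The sole input of the initial-cluster test: an ordered track of length
#' `L` with ones at the given 1-based positions. Positions must be strictly
#' increasing and lie in `[1, L]`.
#'
#' @param L positive integer, sequence length.
#' @param ones_positions integer vector of 1-based positions carrying a 1;
#'   may be empty. Sorted, strictly increasing after validation.
#' @param labels optional character vector of length `L` naming each
#'   position (e.g. residue identifiers from a structural track).
#' @return An object of class `binseq` with fields `L`, `ones` and derived
#'   count `D`.
#' @examples
#' s <- binary_sequence(10, c(1, 2, 4))
#' s$D
#' d1_prefix(s, 5)
#' @export
binary_sequence <- function(L, ones_positions = integer(), labels = NULL) {
  if (length(L) != 1L || is.na(L) || L < 1 || L != floor(L))
    stop("L must be a positive integer")
  L <- as.integer(L)
  ones <- as.integer(sort(unique(ones_positions)))
  if (length(ones) != length(ones_positions))
    stop("ones_positions must not contain duplicates")
  if (length(ones) && (min(ones) < 1L || max(ones) > L))
    stop("ones_positions must lie in [1, L]")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != L) stop("labels must have length L")
  }
  structure(list(L = L, ones = ones, D = length(ones), labels = labels),
            class = "binseq")
}

#' Parse a binary sequence from a 0/1 string
#'
#' @param s a single string of the characters `0` and `1` (whitespace
#'   ignored).
#' @return A [binary_sequence()].
#' @export
parse_binary_string <- function(s) {
  if (length(s) != 1L || !is.character(s)) stop("expected a single string")
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s)) stop("empty binary string")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), c("0", "1"))
  if (length(bad))
    stop("binary string contains characters other than 0/1: ",
         paste(bad, collapse = " "))
  binary_sequence(length(ch), which(ch == "1"))
}

#' Read a binary sequence from a file
#'
#' Accepts either a plain text file whose first non-empty line is a 0/1
#' string, or a two-column TSV (label, flag in \{0,1\}) taken in file order.
#'
#' @param path file path.
#' @return A [binary_sequence()]; for TSV input, labels are retained.
#' @export
read_binary_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no content in ", path)
  if (!grepl("\t", lines[[1L]]))
    return(parse_binary_string(lines[[1L]]))
  tab <- utils::read.delim(text = lines, header = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("TSV input needs two columns: label, flag")
  flag <- trimws(tab[[2L]])
  if (!all(flag %in% c("0", "1")))
    stop("flag column must contain only 0 and 1")
  binary_sequence(nrow(tab), which(flag == "1"), labels = trimws(tab[[1L]]))
}

#' Number of ones at positions <= x
#'
#' @param seq a [binary_sequence()].
#' @param x integer position(s) in `[0, L]`; vectorized.
#' @return integer vector of prefix counts D1(x).
#' @export
d1_prefix <- function(seq, x) {
  stopifnot(inherits(seq, "binseq"))
  if (any(x < 0 | x > seq$L)) stop("x must lie in [0, L]")
  findInterval(x, seq$ones)
}

#' @export
format.binseq <- function(x, ...) {
  bits <- integer(x$L)
  bits[x$ones] <- 1L
  paste(bits, collapse = "")
}

#' @export
print.binseq <- function(x, ...) {
  cat(sprintf("binary sequence: L = %d, D = %d\n", x$L, x$D))
  if (x$L <= 200L) cat(format(x), "\n", sep = "")
  invisible(x)
}
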