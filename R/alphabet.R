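#' Construct a sequence alphabet
#'
#' An alphabet maps symbol characters to integer indices `1..q`. The default
#' is the 20 canonical amino acids in alphabetical one-letter order followed
#' by the alignment gap `'-'` (index 21), so that serialized Potts parameters
#' have a stable column order. Smaller alphabets (q >= 2) are supported so
#' that exact-enumeration checks can run on tiny state spaces.
#'
#' @param symbols Character vector of distinct single characters, in index
#'   order.
#' @param gap The gap character. If absent from `symbols`, the last symbol
#'   plays the gap role (relevant only to policies that need a gap, such as
#'   non-canonical residue mapping and the oracle's masked-context policy).
#' @return An object of class `"alphabet"`: a list with `symbols`, `q`,
#'   and `gap_index`.
#' @examples
#' ab <- make_alphabet(c("A", "B"))
#' ab$q
#' @export
make_alphabet <- function(symbols, gap = "-") {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) stop("an alphabet needs at least 2 symbols")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be distinct")
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  gap_index <- match(gap, symbols)
  if (is.na(gap_index)) gap_index <- length(symbols)
  structure(
    list(symbols = symbols, q = length(symbols), gap_index = gap_index),
    class = "alphabet"
  )
}

#' The default 21-symbol amino-acid alphabet
#'
#' Twenty canonical amino acids (alphabetical one-letter codes) followed by
#' the gap character `'-'` at index 21.
#'
#' @return An [make_alphabet()] object with `q = 21`.
#' @export
aa_alphabet <- function() {
  make_alphabet(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-"))
}

#' @export
print.alphabet <- function(x, ...) {
  cat("Alphabet: q =", x$q, "; symbols:", paste(x$symbols, collapse = ""),
      "; gap index:", x$gap_index, "\n")
  invisible(x)
}

#' Encode character sequences as integer indices
#'
#' Non-canonical characters (e.g. B, Z, X, '.', lowercase) are mapped to the
#' gap index with a warning, unless `strict = TRUE`, in which case they are
#' an error. Pfam full alignments routinely contain such symbols.
#'
#' @param strings Character vector of equal-length sequences.
#' @param alphabet An [make_alphabet()] object.
#' @param strict Error instead of gap-mapping unknown characters.
#' @return Integer matrix with one row per sequence, entries in `1..q`.
#' @export
encode_sequences <- function(strings, alphabet = aa_alphabet(), strict = FALSE) {
  lens <- nchar(strings)
  if (length(unique(lens)) > 1L)
    stop("sequences are not aligned: lengths differ (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  chars <- matrix(unlist(strsplit(toupper(strings), "")),
                  nrow = length(strings), byrow = TRUE)
  idx <- match(chars, alphabet$symbols)
  bad <- is.na(idx)
  if (any(bad)) {
    if (strict)
      stop("unknown characters in input: ",
           paste(unique(chars[bad]), collapse = " "))
    warning(sum(bad), " non-canonical character(s) mapped to gap (",
            paste(unique(chars[bad]), collapse = " "), ")")
    idx[bad] <- alphabet$gap_index
  }
  matrix(idx, nrow = length(strings))
}

#' Decode an integer matrix back to character strings
#'
#' @param data Integer matrix with entries in `1..q`.
#' @param alphabet An [make_alphabet()] object.
#' @return Character vector of sequences.
#' @export
decode_sequences <- function(data, alphabet = aa_alphabet()) {
  apply(matrix(alphabet$symbols[data], nrow = nrow(data)), 1L,
        paste, collapse = "")
}
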