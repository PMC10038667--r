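#' Construct an integer-encoded multiple sequence alignment
#'
#' An `msa` holds `M` aligned sequences of length `L` as an integer matrix
#' over an alphabet of `q` symbols (entries in `1..q`), plus row identifiers.
#' Row order is preserved by every operation in the package.
#'
#' @param data Integer matrix, `M x L`, entries in `1..q`.
#' @param ids Character vector of `M` row identifiers; rows with empty ids
#'   get synthetic ids `seq<k>`.
#' @param alphabet An [make_alphabet()] object.
#' @return An object of class `"msa"`.
#' @export
new_msa <- function(data, ids = NULL, alphabet = aa_alphabet()) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (nrow(data) < 1L || ncol(data) < 1L) stop("an MSA needs M >= 1 and L >= 1")
  if (anyNA(data) || any(data < 1L) || any(data > alphabet$q))
    stop("MSA entries must lie in 1..q")
  if (is.null(ids)) ids <- character(nrow(data))
  ids <- as.character(ids)
  if (length(ids) != nrow(data)) stop("length(ids) must equal nrow(data)")
  blank <- is.na(ids) | ids == ""
  ids[blank] <- paste0("seq", which(blank))
  structure(list(ids = ids, data = unname(data), alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA: ", msa_depth(x), " sequences x ", msa_length(x),
      " columns (q = ", x$alphabet$q, ")\n", sep = "")
  show <- utils::head(seq_len(msa_depth(x)), 5L)
  for (m in show)
    cat(sprintf(" %-12s %s\n", substr(x$ids[m], 1, 12),
                paste(x$alphabet$symbols[x$data[m, ]], collapse = "")))
  if (msa_depth(x) > 5L) cat(" ...\n")
  invisible(x)
}

#' MSA depth (number of sequences)
#' @param msa An [new_msa()] object.
#' @return Integer `M`.
#' @export
msa_depth <- function(msa) nrow(msa$data)

#' MSA length (number of columns)
#' @param msa An [new_msa()] object.
#' @return Integer `L`.
#' @export
msa_length <- function(msa) ncol(msa$data)

#' Extract a subset of MSA rows
#' @param msa An [new_msa()] object.
#' @param rows Integer vector of row indices.
#' @return An `msa` with the selected rows, in the given order.
#' @export
msa_rows <- function(msa, rows) {
  new_msa(msa$data[rows, , drop = FALSE], msa$ids[rows], msa$alphabet)
}

#' Read an aligned FASTA file into an MSA
#'
#' Records must all have the same length (the file is an alignment, not a
#' collection of unaligned sequences). Parsing is delegated to
#' [Biostrings::readBStringSet()].
#'
#' @param path Path to a FASTA file.
#' @inheritParams encode_sequences
#' @return An [new_msa()] object, rows in file order.
#' @export
read_fasta_msa <- function(path, alphabet = aa_alphabet(), strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  strings <- as.character(set)
  new_msa(encode_sequences(unname(strings), alphabet, strict = strict),
          ids = names(set), alphabet = alphabet)
}

#' Write an MSA to FASTA
#'
#' @param msa An [new_msa()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_msa <- function(msa, path) {
  set <- Biostrings::BStringSet(decode_sequences(msa$data, msa$alphabet))
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Stockholm alignment (read-only convenience)
#'
#' Minimal single-block or interleaved Stockholm reader: `#` annotation lines
#' and the terminating `//` are ignored; sequence lines are `name sequence`
#' pairs, concatenated per name across blocks.
#'
#' @inheritParams read_fasta_msa
#' @return An [new_msa()] object.
#' @export
read_stockholm_msa <- function(path, alphabet = aa_alphabet(), strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|//|$)", lines)
  if (!any(keep)) stop("no sequence lines found in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed Stockholm sequence line: ",
                     lines[keep][bad][1])
  nm <- vapply(parts, `[[`, "", 1L)
  sq <- vapply(parts, `[[`, "", 2L)
  seqs <- vapply(split(sq, factor(nm, levels = unique(nm))),
                 paste, "", collapse = "")
  new_msa(encode_sequences(unname(seqs), alphabet, strict = strict),
          ids = names(seqs), alphabet = alphabet)
}

#' One-hot encode an MSA
#'
#' Each sequence becomes the concatenation of the one-hot encodings of its
#' symbols: block `k` (width `q`) encodes column `k`, so every row has
#' exactly `L` ones.
#'
#' @param msa An [new_msa()] object.
#' @return A numeric `M x (L*q)` matrix of 0/1.
#' @export
one_hot_encode <- function(msa) {
  M <- msa_depth(msa); L <- msa_length(msa); q <- msa$alphabet$q
  X <- matrix(0, M, L * q)
  cols <- as.vector(sweep(msa$data, 2L, (seq_len(L) - 1L) * q, `+`))
  X[cbind(rep.int(seq_len(M), L), cols)] <- 1
  X
}

#' Decode a one-hot matrix back to an integer MSA matrix
#'
#' Inverse of [one_hot_encode()]: the argmax of each width-`q` block.
#'
#' @param x Numeric `M x (L*q)` matrix.
#' @param q Alphabet size.
#' @return Integer `M x (L)` matrix.
#' @export
one_hot_decode <- function(x, q) {
  L <- ncol(x) / q
  stopifnot(L == round(L))
  out <- matrix(0L, nrow(x), L)
  for (k in seq_len(L)) {
    block <- x[, (k - 1L) * q + seq_len(q), drop = FALSE]
    out[, k] <- max.col(block, ties.method = "first")
  }
  out
}

#' Partition MSA rows into model-sized batches
#'
#' Rows are assigned to batches by a uniform random permutation without
#' replacement; all batches have `batch_depth` rows except possibly the last.
#' The plan is deterministic given `seed`.
#'
#' @param msa An [new_msa()] object.
#' @param batch_depth Maximum rows per batch (default 600, a typical
#'   memory-bound context size for MSA-based language models).
#' @param seed Integer seed.
#' @return An object of class `"batch_plan"`: list of row-index vectors plus
#'   the parameters used.
#' @export
plan_batches <- function(msa, batch_depth = 600L, seed = 1L) {
  if (batch_depth < 1L) stop("batch_depth must be >= 1")
  M <- msa_depth(msa)
  perm <- with_seed(seed, sample.int(M))
  batches <- unname(split(perm, ceiling(seq_len(M) / batch_depth)))
  structure(list(batches = batches, batch_depth = as.integer(batch_depth),
                 seed = as.integer(seed)),
            class = "batch_plan")
}

#' @export
print.batch_plan <- function(x, ...) {
  cat("Batch plan:", length(x$batches), "batch(es) of depth <=",
      x$batch_depth, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
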