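#' Hamming distance between two sequences
#'
#' The fraction (or count) of positions where the symbols differ; the gap
#' counts as an ordinary symbol.
#'
#' @param x,y Integer vectors of equal length.
#' @param normalized Return the fraction (default) rather than the count.
#' @return A scalar distance.
#' @export
hamming <- function(x, y, normalized = TRUE) {
  if (length(x) != length(y)) stop("sequences must have equal length")
  d <- sum(x != y)
  if (normalized) d / length(x) else d
}

#' Pairwise normalized Hamming distances
#'
#' All pairwise distances between the rows of `msa` (or between the rows of
#' `msa` and `other`). Computed via one-hot cross-products, so it is fast
#' for the alignment depths used here.
#'
#' @param msa An [new_msa()] object.
#' @param other Optional second [new_msa()] with the same `L`.
#' @return A numeric matrix of normalized distances (`M x M`, or
#'   `M x M_other`).
#' @export
hamming_matrix <- function(msa, other = NULL) {
  L <- msa_length(msa)
  X <- one_hot_encode(msa)
  Y <- if (is.null(other)) X else {
    if (msa_length(other) != L) stop("MSAs must have the same length")
    one_hot_encode(other)
  }
  1 - tcrossprod(X, Y) / L
}

#' Closest natural sequence for each query row
#'
#' For each query sequence, the index of and normalized Hamming distance to
#' the nearest sequence in the natural MSA. With `exclude_self = TRUE`
#' (used when the query MSA *is* the natural MSA), the same-row match is
#' skipped. Ties go to the lowest natural row index.
#'
#' @param query,natural [new_msa()] objects with equal `L`.
#' @param exclude_self Skip same-index matches (requires `query` and
#'   `natural` to have equal depth).
#' @return A data frame with one row per query sequence: `index`,
#'   `distance`.
#' @export
closest_natural <- function(query, natural, exclude_self = FALSE) {
  if (msa_depth(natural) < 1L) stop("natural MSA is empty")
  D <- hamming_matrix(query, natural)
  if (exclude_self) {
    if (msa_depth(query) != msa_depth(natural))
      stop("exclude_self requires query and natural of equal depth")
    if (msa_depth(natural) == 1L)
      stop("no eligible natural sequence after excluding self")
    diag(D) <- Inf
  }
  idx <- apply(D, 1L, which.min)
  data.frame(index = idx, distance = D[cbind(seq_len(nrow(D)), idx)])
}

#' Neighbor counts at radius delta
#'
#' Number of sequences in the MSA (including the sequence itself) within
#' normalized Hamming distance `< delta` of each row. The reciprocal of the
#' count is exactly the sequence weight of [sequence_weights()].
#'
#' @param msa An [new_msa()] object.
#' @param delta Radius in `(0, 1]` (default 0.2).
#' @return Integer vector of counts, one per row.
#' @export
neighbor_counts <- function(msa, delta = 0.2) {
  if (delta <= 0 || delta > 1) stop("delta must lie in (0, 1]")
  D <- hamming_matrix(msa)
  as.integer(rowSums(D < delta - 1e-12 | abs(D) < 1e-12))
}

#' Principal components of a one-hot encoded natural MSA
#'
#' Fits PCA on the mean-centered one-hot encoding of the natural alignment;
#' synthetic alignments are then projected onto this basis (never refit), so
#' natural and synthetic sequence clouds live in the same coordinates.
#'
#' @param natural An [new_msa()] with `M >= 2`.
#' @param k Number of components (reduced, with a warning, if it exceeds
#'   the data rank).
#' @return An object of class `"pca_basis"`: `center` (length `L*q` mean),
#'   `components` (`L*q x k`, orthonormal columns), `sdev`,
#'   `var_explained` (fractions, non-increasing).
#' @export
pca_fit <- function(natural, k = 2L) {
  if (msa_depth(natural) < 2L) stop("PCA needs at least 2 sequences")
  X <- one_hot_encode(natural)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (k > rank) {
    warning("k reduced from ", k, " to data rank ", rank)
    k <- rank
  }
  structure(list(center = pc$center,
                 components = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev,
                 var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]),
            class = "pca_basis")
}

#' @rdname pca_fit
#' @param msa An [new_msa()] to project (the natural mean is subtracted).
#' @param basis A `"pca_basis"` from [pca_fit()].
#' @return `pca_project` returns an `M x k` coordinate matrix.
#' @export
pca_project <- function(msa, basis) {
  X <- one_hot_encode(msa)
  if (ncol(X) != length(basis$center))
    stop("MSA is incompatible with this basis (L*q mismatch)")
  sweep(X, 2L, basis$center) %*% basis$components
}

#' Transfer per-sequence scores by nearest natural neighbor
#'
#' Estimates a score (e.g. an experimentally measured relative enrichment)
#' for each generated sequence as the score of its closest natural sequence
#' (ties to the lowest natural index).
#'
#' @param generated,natural [new_msa()] objects with equal `L`.
#' @param scores Numeric vector, one score per natural row.
#' @return Numeric vector, one transferred score per generated row.
#' @export
transfer_score_nn <- function(generated, natural, scores) {
  if (length(scores) != msa_depth(natural))
    stop("scores must have one entry per natural sequence")
  scores[closest_natural(generated, natural)$index]
}

#' Construct a table of single-mutation effects (DMS table)
#'
#' Holds a reference sequence and measured effects of single-point
#' mutations, keyed by (position, mutant symbol). Reference symbols have
#' implicit effect 0.
#'
#' @param reference Integer vector (length `L`) or character string over
#'   `alphabet`.
#' @param effects Data frame with columns `position` (1-based), `mut`
#'   (mutant symbol character) and `effect` (numeric); an optional `wt`
#'   column is checked against the reference.
#' @param alphabet An [make_alphabet()] object.
#' @return An object of class `"dms_table"`.
#' @export
dms_table <- function(reference, effects, alphabet = aa_alphabet()) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- as.integer(encode_sequences(reference, alphabet))
  L <- length(reference)
  effects$position <- as.integer(effects$position)
  if (any(effects$position < 1L | effects$position > L))
    stop("positions must lie in 1..L")
  mut_idx <- match(effects$mut, alphabet$symbols)
  if (anyNA(mut_idx)) stop("unknown mutant symbol in effects table")
  if (!is.null(effects$wt)) {
    wt_idx <- match(effects$wt, alphabet$symbols)
    if (any(wt_idx != reference[effects$position]))
      stop("wt column disagrees with the reference sequence")
  }
  key <- paste(effects$position, mut_idx, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (position, mut) entries")
  structure(list(reference = as.integer(reference),
                 effect = stats::setNames(as.numeric(effects$effect), key),
                 alphabet = alphabet),
            class = "dms_table")
}

#' Read a DMS table from TSV
#'
#' Expected columns: `position` (1-based), `wt`, `mut`, `effect`.
#'
#' @param path TSV file path.
#' @param reference Reference sequence (string or integer vector).
#' @param alphabet An [make_alphabet()] object.
#' @return A [dms_table()].
#' @export
read_dms_table <- function(path, reference, alphabet = aa_alphabet()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  dms_table(reference, tab, alphabet)
}

#' Additive DMS score of a sequence
#'
#' Sums the tabulated single-mutation effects over the positions where the
#' sequence differs from the reference. Differing positions whose mutation
#' is absent from the table — including any gap at a differing position —
#' contribute 0 and are counted in `n_missing`.
#'
#' @param seq Integer vector of length `L` (or character string).
#' @param table A [dms_table()].
#' @return A list with `score` and `n_missing`.
#' @export
dms_score <- function(seq, table) {
  if (is.character(seq) && length(seq) == 1L)
    seq <- as.integer(encode_sequences(seq, table$alphabet))
  L <- length(table$reference)
  if (length(seq) != L) stop("sequence length must match the reference")
  diff <- which(seq != table$reference)
  gap <- table$alphabet$gap_index
  is_gap <- seq[diff] == gap
  eff <- table$effect[paste(diff, seq[diff], sep = ":")]
  eff[is_gap] <- NA_real_
  list(score = sum(eff, na.rm = TRUE), n_missing = sum(is.na(eff)))
}

#' Additive DMS scores for every row of an MSA
#'
#' @param msa An [new_msa()] object.
#' @param table A [dms_table()].
#' @return A data frame with `id`, `score`, `n_missing`.
#' @export
dms_score_msa <- function(msa, table) {
  res <- lapply(seq_len(msa_depth(msa)),
                function(m) dms_score(msa$data[m, ], table))
  data.frame(id = msa$ids,
             score = vapply(res, `[[`, 0, "score"),
             n_missing = vapply(res, function(r) as.integer(r$n_missing),
                                0L))
}
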