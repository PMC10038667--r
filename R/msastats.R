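#' Empirical frequency tables of an MSA
#'
#' Plug-in (unsmoothed, no pseudocount) one-body frequencies for every
#' column, plus two- and three-body joint frequencies for requested site
#' pairs and triplets. When triplets are requested their constituent pairs
#' are included automatically, so connected correlations can always be
#' formed.
#'
#' @param msa An [new_msa()] object.
#' @param pairs List of integer pairs `c(i, j)` with `i < j` (or `NULL`).
#' @param triplets List of integer triplets `c(i, j, k)`, `i < j < k`.
#' @return An object of class `"freq_tables"`: `f1` (`L x q`, rows sum to
#'   1), `f2` (named list `"i_j"` of `q x q` matrices summing to 1), `f3`
#'   (named list `"i_j_k"` of `q x q x q` arrays), and `M`, `L`, `q`.
#' @export
frequencies <- function(msa, pairs = NULL, triplets = NULL) {
  data <- msa$data
  M <- nrow(data); L <- ncol(data); q <- msa$alphabet$q
  norm_sel <- function(sel, len) {
    sel <- lapply(sel, function(s) sort(as.integer(s)))
    for (s in sel) {
      if (length(s) != len || anyDuplicated(s) || s[1] < 1L || s[len] > L)
        stop("site selections must be ", len, " distinct sites in 1..L")
    }
    unique(sel)
  }
  triplets <- norm_sel(triplets, 3L)
  pairs <- norm_sel(pairs, 2L)
  for (tr in triplets)
    pairs <- c(pairs, list(tr[c(1, 2)], tr[c(1, 3)], tr[c(2, 3)]))
  pairs <- unique(pairs)
  f1 <- msa_freq1(data, L, q)
  f2 <- list()
  for (pr in pairs) {
    tab <- tabulate((data[, pr[2]] - 1L) * q + data[, pr[1]], nbins = q * q)
    f2[[paste(pr, collapse = "_")]] <- matrix(tab, q, q) / M
  }
  f3 <- list()
  for (tr in triplets) {
    code <- (data[, tr[3]] - 1L) * q * q + (data[, tr[2]] - 1L) * q +
      data[, tr[1]]
    f3[[paste(tr, collapse = "_")]] <-
      array(tabulate(code, nbins = q^3), c(q, q, q)) / M
  }
  structure(list(f1 = f1, f2 = f2, f3 = f3, M = M, L = L, q = q),
            class = "freq_tables")
}

get_f2 <- function(f, i, j) {
  key <- paste(sort(c(i, j)), collapse = "_")
  tab <- f$f2[[key]]
  if (is.null(tab)) stop("pair (", i, ", ", j, ") not present in tables")
  if (i <= j) tab else t(tab)
}

#' Second-order connected correlations
#'
#' `C_ij(x, y) = f_ij(x, y) - f_i(x) f_j(y)`: the covariance-like excess of
#' joint symbol usage over the independent product. Rows and columns of the
#' result each sum to zero exactly.
#'
#' @param f A [frequencies()] object containing pair `(i, j)`.
#' @param i,j Site indices.
#' @return A `q x q` matrix.
#' @export
connected_corr2 <- function(f, i, j) {
  get_f2(f, i, j) - outer(f$f1[i, ], f$f1[j, ])
}

#' Third-order connected correlations
#'
#' `C_ijk(x,y,z) = f_ijk(x,y,z) - f_ij(x,y) f_k(z) - f_ik(x,z) f_j(y)
#'  - f_jk(y,z) f_i(x) + 2 f_i(x) f_j(y) f_k(z)`.
#' Summing over any one symbol index gives zero exactly.
#'
#' @param f A [frequencies()] object containing triplet `(i, j, k)`.
#' @param i,j,k Site indices (`i < j < k` as stored; any order accepted).
#' @return A `q x q x q` array.
#' @export
connected_corr3 <- function(f, i, j, k) {
  s <- sort(c(i, j, k))
  key <- paste(s, collapse = "_")
  f3 <- f$f3[[key]]
  if (is.null(f3)) stop("triplet (", key, ") not present in tables")
  # Work in sorted order; the tensor is symmetric under coherent relabeling.
  i <- s[1]; j <- s[2]; k <- s[3]
  q <- f$q
  fij <- get_f2(f, i, j); fik <- get_f2(f, i, k); fjk <- get_f2(f, j, k)
  fi <- f$f1[i, ]; fj <- f$f1[j, ]; fk <- f$f1[k, ]
  C <- f3
  C <- C - outer(fij, fk)                                   # f_ij(x,y) f_k(z)
  C <- C - aperm(outer(fik, fj), c(1, 3, 2))                # f_ik(x,z) f_j(y)
  C <- C - aperm(outer(fjk, fi), c(3, 1, 2))                # f_jk(y,z) f_i(x)
  C + 2 * outer(outer(fi, fj), fk)
}

plugin_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plug-in entropies, mutual information and co-information
#'
#' Shannon entropies (in bits) of one, two or three MSA columns, the mutual
#' information `I_ij = H_i + H_j - H_ij`, and the co-information
#' `I_ijk = H_i + H_j + H_k - H_ij - H_ik - H_jk + H_ijk`. Co-information
#' vanishes for independent variables; negative values indicate synergy
#' (e.g. a parity triple gives exactly -1 bit). No finite-size bias
#' correction is applied: compare only MSAs of equal length and depth.
#'
#' @param f A [frequencies()] object containing the needed pair(s)/triplet.
#' @param i,j Site indices.
#' @param k Optional third site; when given, three-way quantities are
#'   included.
#' @return A list with `H_i`, `H_j`, `H_ij`, `I_ij`, and when `k` is
#'   supplied also `H_k`, `H_ik`, `H_jk`, `H_ijk`, `I_ijk`.
#' @export
entropies_and_information <- function(f, i, j, k = NULL) {
  H1 <- function(s) plugin_entropy(f$f1[s, ])
  H2 <- function(a, b) plugin_entropy(get_f2(f, a, b))
  out <- list(H_i = H1(i), H_j = H1(j), H_ij = H2(i, j))
  out$I_ij <- out$H_i + out$H_j - out$H_ij
  if (!is.null(k)) {
    key <- paste(sort(c(i, j, k)), collapse = "_")
    f3 <- f$f3[[key]]
    if (is.null(f3)) stop("triplet (", key, ") not present in tables")
    out$H_k <- H1(k)
    out$H_ik <- H2(i, k)
    out$H_jk <- H2(j, k)
    out$H_ijk <- plugin_entropy(f3)
    out$I_ijk <- out$H_i + out$H_j + out$H_k -
      out$H_ij - out$H_ik - out$H_jk + out$H_ijk
  }
  out
}

#' r20 statistical-similarity curve between two MSAs
#'
#' For each word length (order) `s`, draws `n_sets` random sets of `s`
#' columns (uniform, without replacement within a set; columns need not be
#' contiguous). In each set, the `top_k` most frequent words (subsequences
#' restricted to those columns; gaps are legal word characters) are
#' identified in the reference MSA — ties at the cut broken by lexicographic
#' word order — and the Pearson correlation between their frequencies in the
#' two MSAs is computed. The per-order score is the mean over sets;
#' degenerate sets (fewer than two distinct reference words, or zero
#' variance in either frequency vector) are skipped and not counted.
#'
#' @param target The MSA being evaluated.
#' @param reference The reference MSA (same `L`).
#' @param orders Integer word lengths (default `2:10`).
#' @param n_sets Column sets per order (default 1000).
#' @param top_k Words retained per set (default 20).
#' @param seed Integer seed for the column draws.
#' @param word_source Which MSA defines the top-`top_k` word list:
#'   `"reference"` (default) or `"target"`.
#' @return An object of class `"r20_curve"`: data frame with `order`,
#'   `score`, `n_used` (non-degenerate sets), plus the call parameters.
#' @export
r20_curve <- function(target, reference, orders = 2:10, n_sets = 1000L,
                      top_k = 20L, seed = 1L,
                      word_source = c("reference", "target")) {
  word_source <- match.arg(word_source)
  L <- msa_length(reference)
  if (msa_length(target) != L) stop("MSAs must have the same length")
  if (max(orders) > L) stop("max order exceeds the number of columns")
  words_of <- function(data, cols)
    do.call(paste, c(lapply(cols, function(j)
      formatC(data[, j], width = 3, flag = "0")), list(sep = ".")))
  score <- numeric(length(orders)); used <- integer(length(orders))
  for (oi in seq_along(orders)) {
    s <- orders[oi]
    cols_sets <- with_seed(derive_seed(seed, paste0("r20-", s)),
                           replicate(n_sets, sample.int(L, s),
                                     simplify = FALSE))
    vals <- numeric(0)
    for (cols in cols_sets) {
      w_ref <- words_of(reference$data, cols)
      w_tgt <- words_of(target$data, cols)
      sel_words <- if (word_source == "reference") w_ref else w_tgt
      tab <- table(sel_words)
      if (length(tab) < 2L) next
      ord <- order(-as.integer(tab), names(tab))
      top <- names(tab)[ord][seq_len(min(top_k, length(tab)))]
      fr <- tabulate(match(w_ref, top), nbins = length(top)) / length(w_ref)
      ft <- tabulate(match(w_tgt, top), nbins = length(top)) / length(w_tgt)
      if (stats::sd(fr) == 0 || stats::sd(ft) == 0) next
      vals <- c(vals, stats::cor(fr, ft))
    }
    score[oi] <- mean(vals)
    used[oi] <- length(vals)
  }
  structure(list(curve = data.frame(order = orders, score = score,
                                    n_used = used),
                 n_sets = as.integer(n_sets), top_k = as.integer(top_k),
                 seed = as.integer(seed), word_source = word_source),
            class = "r20_curve")
}

#' @export
print.r20_curve <- function(x, ...) {
  cat("r20 curve (", x$n_sets, " sets/order, top ", x$top_k, " words from ",
      x$word_source, "):\n", sep = "")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Sequence weights and effective depth
#'
#' Each sequence gets weight `w_i = 1 / n_i`, where `n_i` is the number of
#' sequences (including itself) within normalized Hamming distance `< delta`
#' of sequence `i`. The effective depth is `M_eff = sum_i w_i`, a
#' redundancy-corrected MSA depth; `delta = 0.2` is the conventional radius.
#'
#' @param msa An [new_msa()] object.
#' @param delta Neighborhood radius in `(0, 1]`.
#' @return An object of class `"weight_vector"`: `w`, `n_neighbors`,
#'   `m_eff`, `delta`.
#' @export
sequence_weights <- function(msa, delta = 0.2) {
  if (delta <= 0 || delta > 1) stop("delta must lie in (0, 1]")
  n <- neighbor_counts(msa, delta)
  w <- 1 / n
  structure(list(w = w, n_neighbors = n, m_eff = sum(w), delta = delta),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Sequence weights: M =", length(x$w), ", M_eff =",
      signif(x$m_eff, 6), "at delta =", x$delta, "\n")
  invisible(x)
}
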