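#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via [ape::nj()]) on a symmetric,
#' zero-diagonal distance matrix. Negative estimated branch lengths — a
#' known NJ artifact on non-additive inputs — are clamped to zero with a
#' message. On an additive matrix, NJ recovers the generating tree exactly
#' and the clamp never fires.
#'
#' @param distances Symmetric numeric matrix with zero diagonal, at least
#'   3 taxa.
#' @param labels Optional tip labels (defaults to the matrix dimnames, or
#'   `t1..tn`).
#' @return An [ape::read.tree()]-compatible `"phylo"` tree (unrooted).
#' @export
nj_tree <- function(distances, labels = NULL) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (ncol(distances) != n || max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-12)) stop("diagonal must be zero")
  if (is.null(labels))
    labels <- if (!is.null(rownames(distances))) rownames(distances)
              else paste0("t", seq_len(n))
  dimnames(distances) <- list(labels, labels)
  tree <- ape::nj(distances)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Patristic distance matrix of a tree
#'
#' Entry `(i, j)` is the sum of branch lengths along the unique path between
#' nodes `i` and `j`, over the leaves only or over all nodes (leaves and
#' internal nodes).
#'
#' @param tree A `"phylo"` tree.
#' @param nodes `"all"` (default) or `"leaves"`.
#' @return A symmetric numeric matrix with zero diagonal. For
#'   `nodes = "all"`, rows are ordered tips first then internal nodes (the
#'   `ape` node numbering).
#' @export
patristic_matrix <- function(tree, nodes = c("all", "leaves")) {
  nodes <- match.arg(nodes)
  if (nodes == "leaves") {
    D <- ape::cophenetic.phylo(tree)
  } else {
    D <- ape::dist.nodes(tree)
  }
  unname(D)
}

#' Modified graph Laplacian spectrum of a tree
#'
#' The modified graph Laplacian (MGL) is `D - Delta`, where `Delta` is the
#' patristic distance matrix and `D` is the diagonal matrix of its row sums
#' (total branch length from each node to all others). Row sums of the MGL
#' vanish, so 0 is always an eigenvalue (with the constant eigenvector);
#' the shape of the spectrum distinguishes "tippy" from "stemmy" tree
#' topologies.
#'
#' @param tree A `"phylo"` tree.
#' @param nodes `"all"` (default) or `"leaves"` — which nodes enter the
#'   patristic matrix.
#' @return Numeric vector of eigenvalues, sorted decreasing (all real: the
#'   matrix is symmetric).
#' @export
mgl_spectrum <- function(tree, nodes = c("all", "leaves")) {
  Delta <- patristic_matrix(tree, match.arg(nodes))
  mgl <- diag(rowSums(Delta)) - Delta
  eigen(mgl, symmetric = TRUE, only.values = TRUE)$values
}

#' Bootstrap-aggregated MGL spectral density of an MSA
#'
#' Infers `n_trees` neighbor-joining trees, each from the normalized Hamming
#' distance matrix of a random `subsample`-row sub-MSA, computes each tree's
#' MGL eigenvalue spectrum, and pools all eigenvalues into one spectral
#' density. Pooling over bootstrap trees makes the density insensitive to
#' the topological details of any single inferred tree. The density uses a
#' Gaussian kernel with Scott's bandwidth; the reported skewness is the
#' adjusted Fisher-Pearson sample skewness (negative skewness / rightward
#' shift indicates a "tippy" tree, the opposite a "stemmy" one).
#'
#' @param msa An [new_msa()] object.
#' @param n_trees Number of bootstrap trees (default 200).
#' @param subsample Rows per sub-MSA (default 500; reduced to `M` with a
#'   warning if the MSA is shallower).
#' @param seed Integer seed.
#' @param nodes Node set for the MGL (see [mgl_spectrum()]).
#' @param log_scale Pool `log(eigenvalue)` for the strictly positive
#'   eigenvalues instead of raw values.
#' @return An object of class `"spectral_density"`: pooled `eigenvalues`,
#'   `density` (a [stats::density()] object), `skewness`, `bandwidth`, and
#'   the parameters used.
#' @export
bootstrap_spectral_density <- function(msa, n_trees = 200L, subsample = 500L,
                                       seed = 1L, nodes = "all",
                                       log_scale = FALSE) {
  M <- msa_depth(msa)
  if (subsample > M) {
    warning("subsample reduced from ", subsample, " to MSA depth ", M)
    subsample <- M
  }
  if (subsample < 3L) stop("need sub-MSAs of at least 3 sequences")
  pooled <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    rows <- with_seed(derive_seed(seed, paste0("mgl", b)),
                      sample.int(M, subsample))
    sub <- msa_rows(msa, rows)
    D <- hamming_matrix(sub)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    tree <- suppressMessages(
      nj_tree(D, labels = paste0("s", seq_len(subsample))))
    pooled[[b]] <- mgl_spectrum(tree, nodes = nodes)
  }
  ev <- unlist(pooled)
  vals <- if (log_scale) log(ev[ev > 0]) else ev
  bw <- stats::bw.nrd(vals)  # Scott's rule
  dens <- stats::density(vals, bw = bw)
  structure(list(eigenvalues = ev, values = vals,
                 density = dens, bandwidth = bw,
                 skewness = e1071::skewness(vals, type = 2),
                 n_trees = as.integer(n_trees),
                 subsample = as.integer(subsample),
                 seed = as.integer(seed), nodes = nodes,
                 log_scale = log_scale),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat("MGL spectral density: ", length(x$eigenvalues), " eigenvalues from ",
      x$n_trees, " tree(s) of ", x$subsample, " sequences; skewness = ",
      signif(x$skewness, 4), "\n", sep = "")
  invisible(x)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()], provided
#' so externally inferred trees (e.g. approximate-ML trees) can be imported
#' for the spectral analyses.
#'
#' @param path File path.
#' @return `read_newick` returns a `"phylo"` tree; `write_newick` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `"phylo"` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
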