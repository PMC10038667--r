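# Fixture generators: profile MSAs, random Potts models, tree-evolved MSAs
# and toy mutation-effect tables. These emulate specific statistical features
# of real alignments (column conservation profiles, pairwise couplings,
# phylogenetic correlation) so every analysis is testable without any
# external data; realism beyond the targeted feature is not the goal.

#' Independent-column profile MSA
#'
#' Draws a per-column symbol distribution from a symmetric
#' Dirichlet(`concentration`) and samples every row independently from it.
#' Columns are statistically independent by construction, which makes this
#' the null fixture for correlation statistics: connected correlations
#' vanish at the distribution level.
#'
#' @param L,M Alignment length and depth.
#' @param concentration Dirichlet concentration; large values give
#'   near-uniform columns, small values conserved columns.
#' @param q Alphabet size (default 21).
#' @param alphabet Optional [make_alphabet()].
#' @param seed Integer seed.
#' @return A list with `profile` (`L x q`, rows sum to 1) and `msa`.
#' @export
random_profile_msa <- function(L, M, concentration = 1, q = 21L,
                               alphabet = NULL, seed = 1L) {
  if (L < 1L || M < 1L) stop("need L >= 1 and M >= 1")
  if (concentration <= 0) stop("concentration must be > 0")
  if (is.null(alphabet)) alphabet <- default_alphabet_for(q)
  with_seed(seed, {
    g <- matrix(stats::rgamma(L * q, shape = concentration), L, q)
    profile <- g / rowSums(g)
    data <- matrix(0L, M, L)
    for (i in seq_len(L))
      data[, i] <- sample.int(q, M, replace = TRUE, prob = profile[i, ])
    list(profile = profile,
         msa = new_msa(data, ids = paste0("p", seq_len(M)),
                       alphabet = alphabet))
  })
}

#' Random sparse Potts model
#'
#' Fields are iid Gaussian with sd `field_scale`; each site pair `i < j`
#' carries a full Gaussian `q x q` coupling block (sd `coupling_scale`) with
#' probability `coupling_density`, and zero couplings otherwise.
#'
#' @param L,q Model dimensions.
#' @param coupling_density Probability that a pair is coupled.
#' @param coupling_scale,field_scale Gaussian standard deviations (0 gives
#'   exactly zero parameters).
#' @param alphabet Optional [make_alphabet()].
#' @param seed Integer seed.
#' @return A [potts_model()].
#' @export
random_potts_model <- function(L, q, coupling_density = 0.5,
                               coupling_scale = 1, field_scale = 1,
                               alphabet = NULL, seed = 1L) {
  with_seed(seed, {
    h <- matrix(stats::rnorm(L * q, sd = field_scale), L, q)
    if (field_scale == 0) h[] <- 0
    e <- list()
    if (L >= 2L) for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L)) {
      if (stats::runif(1) < coupling_density && coupling_scale > 0)
        e[[paste0(i, "_", j)]] <-
          matrix(stats::rnorm(q * q, sd = coupling_scale), q, q)
    }
    potts_model(h, if (length(e)) e else NULL, alphabet = alphabet)
  })
}

#' Evolve sequences along a tree
#'
#' Starting from `root` at the root of `tree`, applies a symmetric
#' (Jukes-Cantor-style) substitution process along each branch: every site
#' receives a Poisson(`rate * branch_length`) number of events, each event
#' replacing the current symbol by a uniformly chosen different one. Leaf
#' sequences are returned in tip-label order. This induces controllable
#' phylogenetic correlation between rows — the feature real families have
#' that profile fixtures lack.
#'
#' @param tree A rooted `"phylo"` tree with branch lengths.
#' @param root Integer vector: the ancestral sequence.
#' @param rate Substitution rate per site per unit branch length (>= 0).
#' @param q Alphabet size (default: max of `root` or alphabet size).
#' @param alphabet Optional [make_alphabet()].
#' @param seed Integer seed.
#' @return An [new_msa()] with one row per leaf, ids = tip labels.
#' @export
evolve_on_tree <- function(tree, root, rate, q = NULL, alphabet = NULL,
                           seed = 1L) {
  if (rate < 0) stop("rate must be >= 0")
  root <- as.integer(root)
  if (is.null(alphabet)) {
    if (is.null(q)) q <- max(root, 2L)
    alphabet <- default_alphabet_for(q)
  }
  q <- alphabet$q
  L <- length(root)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root_node <- n_tip + 1L
  seqs <- matrix(NA_integer_, n_node, L)
  seqs[root_node, ] <- root
  # Process edges parent-before-child.
  edges <- tree$edge
  lens <- tree$edge.length
  with_seed(seed, {
    done <- rep(FALSE, n_node); done[root_node] <- TRUE
    pending <- seq_len(nrow(edges))
    while (length(pending)) {
      ready <- pending[done[edges[pending, 1L]]]
      if (!length(ready)) stop("tree edges do not form a rooted tree")
      for (eidx in ready) {
        par <- edges[eidx, 1L]; child <- edges[eidx, 2L]
        s <- seqs[par, ]
        n_events <- stats::rpois(L, rate * lens[eidx])
        for (site in which(n_events > 0L)) {
          for (ev in seq_len(n_events[site])) {
            r <- sample.int(q - 1L, 1L)
            s[site] <- r + (r >= s[site])
          }
        }
        seqs[child, ] <- s
        done[child] <- TRUE
      }
      pending <- setdiff(pending, ready)
    }
    new_msa(seqs[seq_len(n_tip), , drop = FALSE], ids = tree$tip.label,
            alphabet = alphabet)
  })
}

#' Toy table of random single-mutation effects
#'
#' Gaussian effects for a random subset of (position, mutant) pairs, for
#' exercising [dms_score()] without experimental data.
#'
#' @param reference Integer vector or character string.
#' @param n_entries Number of tabulated mutations (default: `2 * L`, capped
#'   at the number of possible single mutants).
#' @param effect_sd Standard deviation of the Gaussian effects.
#' @param alphabet An [make_alphabet()].
#' @param seed Integer seed.
#' @return A [dms_table()].
#' @export
toy_dms_table <- function(reference, n_entries = NULL, effect_sd = 1,
                          alphabet = aa_alphabet(), seed = 1L) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- as.integer(encode_sequences(reference, alphabet))
  L <- length(reference)
  q <- alphabet$q
  all_pos <- rep(seq_len(L), each = q - 1L)
  all_mut <- unlist(lapply(seq_len(L), function(i)
    setdiff(seq_len(q), reference[i])))
  if (is.null(n_entries)) n_entries <- min(2L * L, length(all_pos))
  with_seed(seed, {
    pick <- sample.int(length(all_pos), n_entries)
    dms_table(reference,
              data.frame(position = all_pos[pick],
                         mut = alphabet$symbols[all_mut[pick]],
                         effect = stats::rnorm(n_entries, sd = effect_sd)),
              alphabet = alphabet)
  })
}
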