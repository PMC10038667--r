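#' Construct a Potts (direct coupling analysis) model
#'
#' A Potts model over sequences of length `L` with `q` states per site has
#' site fields `h_i(a)` and pair couplings `e_ij(a, b)`. The Hamiltonian of a
#' sequence `x` is `H(x) = -sum_i h_i(x_i) - sum_{i<j} e_ij(x_i, x_j)`, and
#' sequence probabilities follow the Boltzmann distribution
#' `P(x) = exp(-H(x)/T) / Z`.
#'
#' Couplings are held as a full `L x L x q x q` array with the symmetry
#' `e[i, j, a, b] == e[j, i, b, a]` enforced at construction and zero
#' diagonal blocks; the double sum over `i < j` is the canonical evaluation
#' order, so no term is ever counted twice.
#'
#' @param h Numeric `L x q` matrix of fields.
#' @param e Couplings: a full `L x L x q x q` array, a named list of
#'   `q x q` matrices with names `"i_j"` (`i < j`, rows index site `i`), or
#'   `NULL` for the zero-coupling (independent-site) model.
#' @param alphabet Optional [make_alphabet()] object with `q` symbols,
#'   attached to sampled MSAs.
#' @return An object of class `"potts_model"` with elements `L`, `q`, `h`,
#'   `e`, `alphabet`.
#' @export
potts_model <- function(h, e = NULL, alphabet = NULL) {
  h <- as.matrix(h)
  L <- nrow(h); q <- ncol(h)
  if (L < 1L || q < 2L) stop("need L >= 1 and q >= 2")
  if (anyNA(h) || any(!is.finite(h))) stop("fields must be finite")
  if (is.null(e)) {
    e <- array(0, c(L, L, q, q))
  } else if (is.list(e)) {
    arr <- array(0, c(L, L, q, q))
    for (nm in names(e)) {
      ij <- as.integer(strsplit(nm, "_")[[1]])
      if (length(ij) != 2L || ij[1] >= ij[2] || ij[2] > L)
        stop("coupling names must be 'i_j' with i < j <= L; got ", nm)
      arr[ij[1], ij[2], , ] <- e[[nm]]
      arr[ij[2], ij[1], , ] <- t(e[[nm]])
    }
    e <- arr
  }
  if (!identical(dim(e), as.integer(c(L, L, q, q))))
    stop("couplings must be an L x L x q x q array")
  if (anyNA(e) || any(!is.finite(e))) stop("couplings must be finite")
  for (i in seq_len(L)) {
    if (any(e[i, i, , ] != 0)) stop("self-couplings must be zero")
    for (j in seq_len(L)) {
      if (max(abs(e[i, j, , ] - t(e[j, i, , ]))) > 1e-12)
        stop("couplings must satisfy e[i,j,a,b] == e[j,i,b,a]")
    }
  }
  if (is.null(alphabet)) alphabet <- default_alphabet_for(q)
  if (alphabet$q != q) stop("alphabet size must equal q")
  structure(list(L = L, q = q, h = unname(h), e = unname(e),
                 alphabet = alphabet),
            class = "potts_model")
}

default_alphabet_for <- function(q) {
  if (q == 21L) return(aa_alphabet())
  if (q > 52L) stop("no default alphabet for q > 52; supply one")
  make_alphabet(c(LETTERS, letters)[seq_len(q)])
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- sum(vapply(seq_len(x$L), function(i)
    sum(vapply(seq_len(x$L), function(j)
      i < j && any(x$e[i, j, , ] != 0), TRUE)), 0L))
  cat("Potts model: L =", x$L, ", q =", x$q, ";", nz,
      "non-zero coupling pair(s)\n")
  invisible(x)
}

#' Potts model Hamiltonian
#'
#' `H(x) = -sum_i h_i(x_i) - sum_{i<j} e_ij(x_i, x_j)`. Lower values mean
#' more probable sequences at any temperature.
#'
#' @param model A [potts_model()].
#' @param x An integer vector of length `L`, an integer matrix (rows are
#'   sequences), or an [new_msa()] object.
#' @return Numeric vector of energies, one per sequence.
#' @export
hamiltonian <- function(model, x) {
  X <- as_seq_matrix(x, model)
  M <- nrow(X); L <- model$L
  fld <- numeric(M); pr <- numeric(M)
  for (i in seq_len(L)) fld <- fld + model$h[i, X[, i]]
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L))
      pr <- pr + model$e[cbind(i, j, X[, i], X[, j])]
  }
  -(fld + pr)
}

as_seq_matrix <- function(x, model) {
  if (inherits(x, "msa")) x <- x$data
  if (is.vector(x)) x <- matrix(as.integer(x), nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$L) stop("sequence length must equal model L")
  if (anyNA(x) || any(x < 1L) || any(x > model$q))
    stop("sequence entries must lie in 1..q")
  x
}

#' Statistical energy score of sequences
#'
#' The negative Hamiltonian `-H(x)`: higher scores mean more family-like
#' sequences under the fitted model.
#'
#' @inheritParams hamiltonian
#' @return Numeric vector of scores.
#' @export
statistical_energy_score <- function(model, x) -hamiltonian(model, x)

#' Exact Boltzmann distribution by enumeration
#'
#' Enumerates all `q^L` sequences and computes
#' `P(x) = exp(-H(x)/T) / Z` exactly. Guarded to `q^L <= 1e6`; intended for
#' the small models used as enumeration oracles.
#'
#' @param model A [potts_model()].
#' @param temperature Sampling temperature `T > 0` (default 1).
#' @return An object of class `"potts_distribution"`: `states` (a
#'   `q^L x L` integer matrix, first site varying fastest), `prob`, `log_z`,
#'   `temperature`.
#' @export
exact_distribution <- function(model, temperature = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  n <- model$q^model$L
  if (n > 1e6) stop("state space q^L = ", n, " exceeds enumeration guard 1e6")
  states <- as.matrix(expand.grid(rep(list(seq_len(model$q)), model$L),
                                  KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  storage.mode(states) <- "integer"
  lw <- -hamiltonian(model, states) / temperature
  log_z <- log_sum_exp(lw)
  structure(list(states = states, prob = exp(lw - log_z), log_z = log_z,
                 temperature = temperature),
            class = "potts_distribution")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact single-site conditional distribution
#'
#' The probability of each symbol at `site` given the rest of the sequence:
#' `p(a) proportional to exp(h_i(a) + sum_{j != i} e_ij(a, x_j))`. This is
#' the conditional implied by the Boltzmann distribution at `T = 1`.
#'
#' @param model A [potts_model()].
#' @param seq Integer vector of length `L` (the value at `site` is ignored).
#' @param site Site index in `1..L`.
#' @return Numeric probability vector of length `q`, summing to 1.
#' @export
conditional_distribution <- function(model, seq, site) {
  lg <- conditional_logits(model, seq, site)
  p <- exp(lg - max(lg))
  p / sum(p)
}

conditional_logits <- function(model, seq, site, exclude = integer(0)) {
  if (site < 1L || site > model$L) stop("site out of range")
  lg <- model$h[site, ]
  for (j in seq_len(model$L)) {
    if (j == site || j %in% exclude) next
    lg <- lg + model$e[site, j, , seq[j]]
  }
  lg
}

#' Sampling configuration for Metropolis-Hastings
#'
#' @param n_steps Monte Carlo steps per chain; default is the heuristic
#'   `10 * L * q` sweeps-worth of single-site moves (set when the model is
#'   known, i.e. inside [metropolis_sample()]).
#' @param temperature Sampling temperature `T > 0`; `T < 1` concentrates
#'   sampling on low-energy sequences, trading diversity for score.
#' @param n_chains Number of independent chains (one output sequence each).
#' @param init `"random"` (uniform sequences) or `"from_msa"` (rows sampled
#'   from `init_msa`).
#' @param init_msa An [new_msa()] used when `init = "from_msa"`.
#' @param seed Integer seed.
#' @return A list of class `"sampling_config"`.
#' @export
sampling_config <- function(n_steps = NULL, temperature = 1, n_chains = 1L,
                            init = c("random", "from_msa"), init_msa = NULL,
                            seed = 1L) {
  init <- match.arg(init)
  if (!is.null(n_steps) && n_steps < 0) stop("n_steps must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (n_chains < 1L) stop("n_chains must be >= 1")
  if (init == "from_msa" && is.null(init_msa))
    stop("init = 'from_msa' requires init_msa")
  structure(list(n_steps = n_steps, temperature = temperature,
                 n_chains = as.integer(n_chains), init = init,
                 init_msa = init_msa, seed = as.integer(seed)),
            class = "sampling_config")
}

#' Metropolis-Hastings sampling from a Potts model
#'
#' Each step proposes a mutation at a single uniformly chosen site to a
#' uniformly chosen different symbol, accepted with probability
#' `min(1, exp(-dH/T))`. Chains are independent and updated in lockstep
#' (vectorized across chains), which leaves each chain's law unchanged.
#'
#' @param model A [potts_model()].
#' @param config A [sampling_config()].
#' @param diagnostics If `TRUE`, attach an attribute `"diagnostics"` with the
#'   count of rejected downhill proposals (always 0 by construction — exposed
#'   for instrumented checks), the acceptance rate, and a mean-energy trace
#'   over chains recorded every `max(1, N %/% 50)` steps for a stationarity
#'   eyeball (compare the two halves of the trace).
#' @return An [new_msa()] of `n_chains` sequences (final chain states).
#' @export
metropolis_sample <- function(model, config = sampling_config(),
                              diagnostics = FALSE) {
  L <- model$L; q <- model$q
  N <- if (is.null(config$n_steps)) 10L * L * q else config$n_steps
  n <- config$n_chains
  Tt <- config$temperature
  h <- model$h; e <- model$e
  with_seed(config$seed, {
    if (config$init == "random") {
      X <- matrix(sample.int(q, n * L, replace = TRUE), n, L)
    } else {
      src <- config$init_msa$data
      X <- src[sample.int(nrow(src), n, replace = TRUE), , drop = FALSE]
      if (ncol(X) != L) stop("init_msa length must equal model L")
    }
    n_down_rej <- 0L; n_acc <- 0
    every <- max(1L, N %/% 50L)
    trace <- numeric(0)
    rows <- seq_len(n)
    for (step in seq_len(N)) {
      sites <- sample.int(L, n, replace = TRUE)
      r <- sample.int(q - 1L, n, replace = TRUE)
      old <- X[cbind(rows, sites)]
      new <- r + (r >= old)
      dh <- -(h[cbind(sites, new)] - h[cbind(sites, old)])
      if (L >= 2L) for (j in seq_len(L)) {
        sel <- which(sites != j)
        if (!length(sel)) next
        xj <- X[sel, j]
        dh[sel] <- dh[sel] -
          (e[cbind(sites[sel], j, new[sel], xj)] -
             e[cbind(sites[sel], j, old[sel], xj)])
      }
      acc <- log(runif(n)) < -dh / Tt
      if (diagnostics) {
        n_down_rej <- n_down_rej + sum(dh < 0 & !acc)
        n_acc <- n_acc + sum(acc)
      }
      if (any(acc)) X[cbind(rows[acc], sites[acc])] <- new[acc]
      if (diagnostics && step %% every == 0L)
        trace <- c(trace, mean(hamiltonian(model, X)))
    }
    out <- new_msa(X, ids = paste0("chain", rows), alphabet = model$alphabet)
    if (diagnostics)
      attr(out, "diagnostics") <- list(
        n_downhill_rejected = n_down_rej,
        acceptance_rate = if (N > 0) n_acc / (as.double(N) * n) else NA_real_,
        energy_trace = trace)
    out
  })
}

#' Exact Potts-conditional oracle as a masked-sequence model
#'
#' Wraps a Potts model into the masked-sequence-model contract: for each
#' masked cell `(m, i)` the returned logits are the log of the exact
#' single-site conditional of site `i` given row `m`'s unmasked context.
#' Masked cells within one row are treated as independent given the context,
#' mirroring the pseudolikelihood structure of masked language modeling.
#' Other masked context cells are handled per `masked_context`: `"gap"`
#' treats them as the gap symbol, `"drop"` removes their coupling terms.
#' Both policies agree when at most one cell per row is masked.
#'
#' @param model A [potts_model()].
#' @param masked_context `"gap"` or `"drop"`.
#' @return A function of class `"masked_sequence_model"` taking
#'   `(masked_msa, mask)` and returning an `M x L x q` array of logits
#'   (finite at every masked cell; zero elsewhere).
#' @export
potts_oracle_mlm <- function(model, masked_context = c("gap", "drop")) {
  masked_context <- match.arg(masked_context)
  gap <- model$alphabet$gap_index
  fn <- function(masked, mask) {
    M <- msa_depth(masked); L <- msa_length(masked)
    if (L != model$L) stop("MSA length must equal model L")
    logits <- array(0, c(M, L, model$q))
    if (nrow(mask) == 0L) return(logits)
    for (m in unique(mask[, 1L])) {
      cols <- mask[mask[, 1L] == m, 2L]
      ctx <- masked$data[m, ]
      if (masked_context == "gap") {
        ctx[is.na(ctx)] <- gap
        excl <- integer(0)
      } else {
        ctx[is.na(ctx)] <- 1L  # excluded below; value never read
        excl <- cols
      }
      for (i in cols)
        logits[m, i, ] <- conditional_logits(model, ctx, i,
                                             exclude = setdiff(excl, i))
    }
    logits
  }
  new_mlm(fn)
}

#' Wrap a function as a masked-sequence model
#'
#' The contract: `fn(masked_msa, mask)` returns a finite `M x L x q` logit
#' array; values at unmasked cells are unused. Softmax-normalizing the logit
#' vector of a cell gives the model's conditional symbol probabilities.
#'
#' @param fn A function `(masked_msa, mask) -> array`.
#' @return `fn`, classed `"masked_sequence_model"`.
#' @export
new_mlm <- function(fn) structure(fn, class = c("masked_sequence_model",
                                                "function"))

#' Constant-logit stub models
#'
#' `constant_mlm(logits)` always emits the same logit vector at every cell;
#' `uniform_mlm()` is the all-zero special case (uniform conditional).
#' Useful as degenerate fixtures: under `constant_mlm` the iterative masking
#' procedure reaches its fixed point in one iteration.
#'
#' @param logits Numeric vector of length `q`.
#' @return A `"masked_sequence_model"`.
#' @export
constant_mlm <- function(logits) {
  logits <- as.numeric(logits)
  new_mlm(function(masked, mask) {
    q <- masked$alphabet$q
    if (length(logits) != q) stop("stub logit length must equal q")
    array(rep(logits, each = msa_depth(masked) * msa_length(masked)),
          c(msa_depth(masked), msa_length(masked), q))
  })
}

#' @rdname constant_mlm
#' @export
uniform_mlm <- function() {
  new_mlm(function(masked, mask)
    array(0, c(msa_depth(masked), msa_length(masked), masked$alphabet$q)))
}
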