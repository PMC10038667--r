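# Shared fixtures and independent oracles for the test suite.

ab2 <- make_alphabet(c("A", "B"))
ab4 <- make_alphabet(c("A", "C", "G", "-"))

# A fully-coupled random L=3, q=2 model used wherever an enumeration oracle
# is needed.
tiny_potts <- function(seed = 7) {
  random_potts_model(3, 2, coupling_density = 1, coupling_scale = 0.8,
                     field_scale = 0.5, seed = seed)
}

# Map sequence rows to state indices in exact_distribution() order (first
# site varying fastest).
state_code <- function(data, q) {
  code <- rep(1L, nrow(data))
  mult <- 1L
  for (i in seq_len(ncol(data))) {
    code <- code + (data[, i] - 1L) * mult
    mult <- mult * q
  }
  code
}

empirical_dist <- function(data, q) {
  tabulate(state_code(data, q), nbins = q^ncol(data)) / nrow(data)
}

tv_dist <- function(p, r) 0.5 * sum(abs(p - r))

# Independent brute-force Hamiltonian: explicit double loop, no shared code
# with the package implementation.
bf_hamiltonian <- function(model, x) {
  s <- 0
  for (i in seq_along(x)) s <- s + model$h[i, x[i]]
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (i < j) s <- s + model$e[i, j, x[i], x[j]]
  }
  -s
}

# The 8-row parity alignment: column 3 is the XOR of two uniform bits.
parity_msa <- function() {
  g <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  keep <- (g[, 1] + g[, 2] + g[, 3]) %% 2 == 1  # x3 = xor(x1, x2) in 1/2 coding
  new_msa(g[keep, , drop = FALSE], alphabet = ab2)
}

# Full factorial alignment: every q^L combination once (exact independence
# at the distribution level).
factorial_msa <- function(L, q, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- make_alphabet(LETTERS[seq_len(q)])
  data <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  dimnames(data) <- NULL
  new_msa(data, alphabet = alphabet)
}

msa_from_strings <- function(strings, alphabet = aa_alphabet()) {
  new_msa(encode_sequences(strings, alphabet), alphabet = alphabet)
}
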