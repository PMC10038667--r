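---
title: "Methods: iterative masking generation and MSA comparison statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative masking generation and MSA comparison statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itermask)
```

# The problem

Masked-language models trained on multiple sequence alignments (MSAs) of
homologous proteins assign, to any masked alignment cell, a conditional
distribution over amino-acid symbols given the unmasked context. They are
not generative models in the usual sense — there is no tractable joint
distribution to sample — but their conditionals can be exploited to
*generate* new family members. This package implements that generation
scheme (the iterative masking procedure), the Potts-model machinery that is
the standard baseline for coevolution-aware sequence generation, and the
statistics used to judge whether a synthetic alignment reproduces the
natural one: low- and higher-order column statistics, the distribution of
sequences in sequence space, and the apparent phylogeny.

Everything runs against a *model contract*, not a particular network: a
masked-sequence model is any function taking a masked alignment and
returning an `M x L x q` array of logits (see `new_mlm()`). The package
ships an exact Potts-conditional oracle honoring the contract, so the whole
pipeline is validated against enumeration at desk scale; an adapter to a
pretrained transformer is the same one-function interface.

# The iterative masking procedure

Given an input alignment of `M` sequences and `L` columns over `q = 21`
symbols (20 amino acids + gap), one round of the procedure:

1. masks every cell independently with probability `p` (gaps are maskable
   like residues — the alignment must stay an alignment, so the gap symbol
   is also a legal fill);
2. evaluates the model once on the masked alignment;
3. fills all masked cells simultaneously, either greedily (argmax logit,
   ties to the lowest symbol index for determinism) or by sampling
   `softmax(logits / T_sel)`.

Rounds repeat `I` times with fresh Bernoulli masks. Defaults are `p = 0.1`
and `I = 200`, the regime where generated-alignment properties (scores,
diversity, distance to the input) have reached their plateau while the
family's contact structure is preserved; the product `p * I = 20` is the
expected number of times each cell is rewritten. Greedy selection is the
`T_sel -> 0` limit of softmax selection; raising `T_sel` trades sequence
quality for originality. Deep alignments are partitioned into random
batches of at most `batch_depth = 600` rows (a typical model context
limit), each batch is iterated independently, and the outputs are
concatenated, so the synthetic alignment has exactly the natural depth.

Two restricted scopes mask only the first row, the remaining rows acting as
context — either fixed, or resampled from a pool each round
(`first_row_variable_context`). These converge much faster; `I = 20`
suffices in practice.

**Known limitation — simultaneous fills.** Filling several masked cells of
one row in a single round draws each from its *single-site* conditional,
ignoring dependencies among the masked cells (exactly the pseudolikelihood
structure of the masked-language objective). The update is therefore not an
exact Gibbs step whenever two masked cells share a row. With the Potts
oracle on an enumerable model this bias is directly measurable: at
`p = 0.1` on `L = 3` the stationary law of a first-row run deviates from
the exact Boltzmann distribution by total variation of roughly 0.05 under
the gap-context policy. At `p = 0.05`, where over 95% of filling events
touch a single cell, the chain is per-site Gibbs to good approximation and
the deviation drops near Monte-Carlo noise (~0.02). The long-run
consistency checks in the test suite and acceptance script therefore run at
`p = 0.05` with the drop-coupling context policy; the `p = 0.1` default for
*generation* is unaffected (generation never relies on exactness of the
stationary law).

# Potts models

A Potts (direct coupling analysis) model has Hamiltonian
`H(x) = -sum_i h_i(x_i) - sum_{i<j} e_ij(x_i, x_j)` and Boltzmann
distribution `P(x) = exp(-H(x)/T)/Z`, with `T = 1` the default (models are
fitted at `T = 1`). The statistical energy score of a sequence is `-H(x)`
— higher is more family-like. Couplings are stored as a full
`L x L x q x q` array with `e[i,j,a,b] = e[j,i,b,a]` enforced, and the
`i < j` sum is the canonical evaluation, so no pair is double-counted.

*Sampling* uses Metropolis–Hastings with single-site proposals (uniform
site, uniform different symbol), acceptance `min(1, exp(-dH/T))`, chains
updated in lockstep (vectorized across chains; each chain's law is
untouched). The default chain length heuristic is `10 * L * q` steps; a
mean-energy trace between chain halves is available as a stationarity
diagnostic. Lowering `T` concentrates sampling on low-energy sequences:
mean score rises, pairwise Hamming diversity collapses — the score/diversity
trade-off the acceptance checks quantify.

*Exact enumeration* (`exact_distribution()`, guarded to `q^L <= 1e6`) is
the oracle for every sampling and conditional computation, and also
exposes the gauge invariance `h_i(.) -> h_i(.) + c_i` that tests assert.

*Fitting* (`fit_boltzmann_machine()`) is a minimal Boltzmann machine:
parameters move along the mismatch between data and model one/two-body
frequencies with an L2 penalty `lambda` on every parameter (default
`1e-2`; `1e-3`–`1e-2` is the usual range, with stronger regularization for
shallow alignments). Model moments come from exact enumeration when
`q^L <= 4096` — which makes the independent-site closed form (`softmax(h)`
equals the site frequencies at `lambda = 0`) testable to `1e-3` — and from
persistent Metropolis chains otherwise (a persistent
contrastive-divergence scheme). Convergence is declared on the maximum
absolute moment error; non-convergence returns best-so-far with a warning.
Reported parameters are put in the zero-sum gauge (distribution-preserving;
makes parameters comparable across runs). Parity with any external
fitting codebase is a non-goal; `lambda` here is an L2 scale of this
fitter and maps onto other tools' regularization only in order of
magnitude.

*The oracle* (`potts_oracle_mlm()`) returns, at each masked cell, the log
of the exact single-site conditional given the row's unmasked context.
Masked cells elsewhere in the row are handled by one of two documented
policies: treated as gaps (`"gap"`, the default — mirrors what a trained
model sees, a context symbol it must read through) or excluded from the
coupling sum (`"drop"`). The policies coincide whenever at most one cell
per row is masked; the true joint conditional over a mask is exponential in
mask size and is deliberately not computed, mirroring the
pseudolikelihood structure of the modeled objective.

# Comparison statistics

All statistics are plug-in (no pseudocounts, no finite-size bias
correction): entropies and informations carry a systematic finite-size
bias, so only alignments of equal depth and length should be compared —
the generation procedure guarantees exactly that.

- **Frequencies and connected correlations.** `f_i`, `f_ij`, `f_ijk`, with
  `C_ij = f_ij - f_i f_j` and the five-term third-order
  `C_ijk`. Marginalizing any symbol index of `C_ij` or `C_ijk` gives zero
  identically; the suite asserts this to `1e-12` on random alignments.
- **Information.** Entropies in bits (base-2 logs, chosen so the parity
  triple's co-information is exactly -1);
  `I_ij = H_i + H_j - H_ij`;
  `I_ijk = H_i + H_j + H_k - H_ij - H_ik - H_jk + H_ijk`. Negative
  co-information indicates synergy.
- **r20.** For word lengths 2–10, draw 1000 random column sets ("non-
  contiguous" is read as *not necessarily contiguous*: uniform sampling,
  no adjacency exclusion), find the 20 most frequent words in the
  *reference* alignment (ties at the cut broken lexicographically), and
  correlate their frequencies in the two alignments; average over sets.
  Selecting the word list in the reference (rather than per-MSA) is one of
  two defensible readings; the other is available via `word_source`.
  Degenerate sets (fewer than two distinct words, or zero variance) are
  skipped and not counted. Words may contain gaps.
- **Sequence space.** Normalized Hamming distances (gap = ordinary
  symbol); closest-natural lookup by exact brute force; neighbor counts at
  radius `delta = 0.2`, whose reciprocals are the sequence weights
  `w_i` with effective depth `M_eff = sum_i w_i`; PCA of the one-hot
  encoded *natural* alignment only, synthetic data projected onto that
  basis, never refit; nearest-neighbor score transfer; additive
  single-mutation (DMS) scores, where untabulated mutations — including
  any gap at a differing position — contribute 0 and are counted in
  `n_missing` (an explicit policy: reported alongside every score).
- **Phylogeny.** Neighbor-joining trees on normalized Hamming distances
  stand in for approximate-ML inference — the spectral summaries of
  interest are coarse topology statistics, and externally built trees can
  be imported as Newick. The modified graph Laplacian of a tree is
  `D - Delta` with `Delta` the patristic matrix and `D` its diagonal row
  sums; its row sums vanish, so 0 is always an eigenvalue (asserted to
  `1e-8` relative). The node set is *all* nodes by default (leaves +
  internal), with a leaves-only flag, and eigenvalues are pooled raw with
  a log-scale option — both choices the literature leaves open, both
  behind flags. Spectra are bootstrap-aggregated: 200 trees from random
  500-sequence sub-MSAs by default, eigenvalues pooled into one density
  (Gaussian kernel, Scott's bandwidth) summarized by adjusted
  Fisher–Pearson skewness. Negative skewness / rightward shift marks
  "tippy" trees; the opposite "stemmy" ones.

# Synthetic data

The generators emulate one statistical feature each, not realism:

- `random_profile_msa()` — independent columns from symmetric Dirichlet
  profiles: the null fixture (connected correlations vanish at the
  distribution level).
- `random_potts_model()` — sparse Gaussian couplings and fields: the
  enumerable ground truth for sampling, fitting and the oracle. The
  recurring oracle model is `L = 3, q = 2`, fully coupled, coupling sd 0.8
  and field sd 0.5 — strong enough that conditionals are far from uniform,
  small enough for exact enumeration.
- `evolve_on_tree()` — symmetric (Jukes–Cantor-style) substitutions along
  a tree: controllable phylogenetic correlation, the feature profile
  fixtures lack. No indels, no realistic substitution matrices.
- `toy_dms_table()` — Gaussian effects on random single mutants.

What passing tests on these fixtures does *not* show: behavior under the
full 21-symbol alphabet at realistic lengths with a real pretrained model,
alignment errors, or biased taxon sampling. The fixtures validate the
*machinery* (exactness of statistics, correctness of samplers and
bookkeeping), not biological performance.

# Numerical choices and problem sizes

- All randomness flows from explicit integer seeds; pipeline stages derive
  independent seeds from one global seed via a stable tag hash
  (`derive_seed()`), so runs are reproducible end to end and byte-identical
  reports are a tested invariant.
- Greedy ties break to the lowest symbol index; r20 rank-20 ties break
  lexicographically; nearest-neighbor ties to the lowest natural index.
- Negative neighbor-joining branch lengths are clamped to zero (logged);
  on additive matrices NJ is exact to `1e-10` and the clamp never fires.
- Enumeration is guarded at `q^L <= 1e6`; the fitter switches from exact
  to sampled moments at `q^L > 4096`.
- Long-run checks use an `L = 3, q = 2` model with 20,000 chains of 2,000
  Metropolis steps (total-variation tolerance 0.02) and a 200,000-round
  first-row oracle run with 10% burn-in (tolerance 0.03); the fitter
  check uses 20,000 training sequences and 4,000 persistent chains.
  These sizes put Monte-Carlo noise comfortably below the stated
  tolerances while keeping the full suite around a minute.
- Plug-in mutual information on finite samples is positively biased;
  exact-zero assertions are made only at the distribution level (full
  factorial fixtures), never on finite samples.

# Known limitations

- Simultaneous mask filling ignores within-round dependencies (see above);
  at the default `p = 0.1` this is by design — it is the procedure, and
  the bias it induces on stationary laws is documented and measured.
- The Boltzmann-machine fitter targets moment recovery on enumerable
  models; it makes no claim of parity with large-scale DCA fitting
  pipelines, and its `N`-steps-to-equilibrium heuristic (`10*L*q`) is a
  default, not an estimate.
- Neighbor joining on Hamming distances is a deliberate stand-in for
  likelihood-based tree inference; individual topologies are not trusted,
  only pooled spectral summaries.
- Scoring against profile HMMs and structure predictors is out of scope;
  the statistical-energy score is the only sequence-level score shipped.
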