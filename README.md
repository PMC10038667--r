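# itermask

Generating protein sequences from masked-sequence models by **iterative
masking**, and measuring how faithfully synthetic multiple sequence
alignments (MSAs) reproduce natural ones.

## The problem

Language models trained on MSAs with the masked-token objective assign
conditional symbol probabilities to any masked alignment cell, but provide
no joint distribution to sample sequences from. The iterative masking
procedure turns those conditionals into a generator: repeatedly mask each
cell of an alignment with probability *p*, evaluate the model once, and
fill every masked cell from the returned logits (greedy argmax, or softmax
at a selection temperature), for *I* rounds — defaults *p* = 0.1,
*I* = 200, so each cell is rewritten *pI* = 20 times on average. Deep
alignments are processed in random 600-row batches and reassembled at the
natural depth.

The package is written for researchers who want to study, test or extend
this generation scheme and the statistics used to evaluate it, without
needing pretrained weights: any function obeying the one-line
masked-sequence-model contract (`new_mlm()`) plugs in, and an **exact
Potts-conditional oracle** makes every stage verifiable against brute-force
enumeration.

Alongside generation it implements the standard coevolution baseline and
the full comparison battery:

- **Potts / DCA models** — Hamiltonian
  `H(x) = -Σ h_i(x_i) - Σ_{i<j} e_ij(x_i, x_j)`, Boltzmann sampling by
  single-site Metropolis–Hastings at temperature *T*, statistical-energy
  scores `-H(x)`, exact enumeration on small state spaces, and a minimal
  Boltzmann-machine fitter with L2 regularization λ.
- **MSA statistics** — plug-in frequencies, connected correlations
  `C_ij = f_ij - f_i f_j` and their third-order analogue, mutual
  information and co-information in bits, r20 word-frequency curves,
  sequence weights and effective depth
  `M_eff(δ) = Σ_i |{i′ : d_H(x_i, x_i′) < δ}|⁻¹` at δ = 0.2.
- **Sequence space** — Hamming distances, closest-natural lookup, neighbor
  counts, one-hot PCA in the natural basis, nearest-neighbor score
  transfer, additive single-mutation (DMS) scores.
- **Phylogeny** — neighbor-joining trees, patristic distances, modified
  graph Laplacian (MGL) spectra with bootstrap-aggregated spectral
  densities and skewness summaries ("tippy" vs "stemmy" tree shapes).

## Worked example

Sample a "natural" alignment from a known Potts model, regenerate it with
the iterative masking procedure driven by the exact conditional oracle,
and compare the two alignments:

```r
library(itermask)

model    <- random_potts_model(L = 8, q = 3, coupling_density = 0.4,
                               coupling_scale = 0.5, field_scale = 0.5,
                               seed = 55)
natural  <- metropolis_sample(model, sampling_config(n_steps = 2000,
                                                     n_chains = 200,
                                                     seed = 1))
synthetic <- generate_synthetic_msa(natural, potts_oracle_mlm(model),
                                    generation_config(p = 0.1,
                                                      iterations = 200,
                                                      seed = 2))
report <- run_compare(natural, synthetic, potts = model,
                      config = compare_config(seed = 3, r20_orders = 2:6,
                                              n_trees = 10, subsample = 60))
print(report)
```

```
MSA comparison report
  L = 8 ; M natural = 200 ; M synthetic = 200 
  mean energy score: natural 3.0806 synthetic 5.6959 
  r20: 2:0.738 3:0.658 4:0.531 5:0.433 6:0.372 
  M_eff: natural 91.901 synthetic 2.8363 
  MGL skewness: natural -0.1656 synthetic 1.963 
```

Reading the numbers: greedy iteration drives sequences toward high
statistical-energy scores (5.70 vs the natural mean 3.08) while collapsing
diversity — the effective depth drops from 91.9 to 2.8 as the 200 rows
converge onto a few local optima, and the MGL skewness flips sign as the
apparent phylogeny becomes extremely "stemmy". The r20 curve decays with
word length as higher-order statistics get harder to match. On this tiny,
strongly coupled toy model the collapse is far more pronounced than on
real families; the mechanics, not the magnitudes, are the point.

The same pipeline is scriptable from a shell via the thin CLI in
`exec/itermask` (`generate`, `sample`, `score`, `fit`, `stats`, `meff`,
`closest`, `spectra`, `compare`).

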