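---
title: "Kernel regression models for metabolite identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel regression models for metabolite identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iokr)
```

This vignette is the package's own account of its models, the assumptions
behind them, the tunable parameters, the synthetic data they are exercised on,
and the numerical and design choices that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The identification problem

An unknown metabolite is fragmented and measured as an MS/MS spectrum: a peak
list of (mass-to-charge, intensity) pairs. Identification means ranking a
candidate set of molecules — in practice, database molecules with the query's
molecular formula — so that the true structure sits at the top. Molecules are
represented by binary fingerprints: length-`d` 0/1 vectors marking the
presence of substructures and other molecular properties. Neither spectra nor
molecules live in a vector space a regression can use directly, so both sides
are kernelized: an input kernel `k_x` on spectra with feature map `φ`, an
output kernel `k_y` on fingerprints with feature map `ψ`.

## The two regression directions

**Forward (IOKR).** `h : X → F_y` minimizes
`Σ_i ‖h(x_i) − ψ(y_i)‖² + λ_h ‖h‖²`. With `h(x) = Wφ(x)` the solution is the
representer expansion `h(x) = Σ_i α_i(x) ψ(y_i)`,
`α(x) = (λ_h I_ℓ + K_X)⁻¹ k_X^x`. The operator `W` itself is never
materialized — every downstream quantity (pre-image distances, cosine scores)
is a function of `α`, `K_Y` and output-kernel evaluations, so the model object
stores only a Cholesky factor of `(λ_h I + K_X)` and `K_Y`. Prediction is a
nearest-neighbour (pre-image) search over the candidate set:
`d²(y) = α'K_Y α + k_y(y,y) − 2 α'k_Y^y`.

**Reverse (IOKRreverse).** The same machinery with input and output swapped:
`g(y) = Σ_i β_i(y) φ(x_i)`, `β(y) = (λ_g I_ℓ + K_Y)⁻¹ k_Y^y`, and the
pre-image compares predicted spectrum embeddings with the observed one in
`F_x`. The motivation is hubness: in high-dimensional nearest-neighbour
retrieval some points become neighbours of disproportionately many queries,
and reversing the regression (shrinking the *candidate* side rather than the
query side) mitigates it. The cost structure is asymmetric — the reverse
direction solves one linear system column per candidate, which is why the
implementation computes `β` for the union of a fold's candidates once and
reuses columns across queries.

**Scores.** Both directions produce the normalized cosine compatibility
`s(x,y) ∈ [−1, 1]` (forward: `α'k_Y^y / (√(α'K_Y α) √(k_y(y,y)))`). When all
candidate self-kernels are 1 and the prediction norm is fixed, ranking by
descending cosine equals ranking by ascending squared distance; the package
keeps both and the test suite asserts their agreement on normalized kernels.

## Late fusion

Each (input kernel × output kernel × direction) triple gives one score
function; `K` of them are combined linearly with weights `w` learned by
minimizing the margin-rescaled structured Hinge objective

```
J(w) = (λ/2)‖w‖² + (1/ℓ) Σ_i max_{y ∈ Y_i} [ Δ(y_i, y) − w'(s(x_i,y_i) − s(x_i,y)) ]
```

with `Δ` the normalized Hamming distance between fingerprints (0 at the truth,
so the hinge is never negative). The optimizer is mini-batch subgradient
descent with Pegasos steps `t_k = 1/(λk)`: weights start at zero, each epoch
randomly permutes the training queries into contiguous batches, and the
per-batch update is `w ← w − t_k (λw + avg of active hinge subgradients)`.
The per-example objective can be written with an `ℓ`-scaled regularizer; the
implementation resolves that bookkeeping so that the full objective `J(w)`
above is what the update descends — the per-epoch `J(w)` trace is stored on
the fitted object and audited by the tests (`J(w_final) ≤ J(0)` on every
synthetic instance in the suite). No projection or averaging step is applied,
ties in the loss-augmented argmax break to the lowest candidate index, and a
fixed seed gives bit-identical weights.

## Kernels and preprocessing

- **Probability product kernel (PPK)** on peak lists: each peak is a 2-D
  Gaussian in (m/z, intensity) with standard deviations `σ_m` (Daltons) and
  `σ_i` (intensity units); the kernel is the integrated product of the two
  spectrum densities. `σ_m` and `σ_i` are required configuration with no
  hidden defaults — their scale depends on the instrument and on intensity
  preprocessing. By default each spectrum's intensities are rescaled to
  maximum 1 before evaluation (configurable off), which puts `σ_i` on a
  common scale; no other intensity recalibration is applied.
- **Fingerprint kernels**: linear (`fp'fp`), Tanimoto
  (`|∩|/|∪|`, the 0/0 case of two all-zero fingerprints defined as 1 by
  convention and logged), Gaussian (`exp(−γ·Hamming count)`), and
  Gaussian–Tanimoto (Gaussian in the Tanimoto feature space,
  `exp(−γ(2 − 2k_tan))`).
- **Bandwidth selection**: `γ` is chosen from a grid by maximizing the Shannon
  entropy of the kernel-value distribution over training pairs — values are
  binned into 100 equal-width bins on [0, 1], off-diagonal pairs only, ties
  to the smaller `γ`. The bin count and tie rule are this package's choices;
  entropy maximization favours the bandwidth that spreads kernel values
  rather than saturating them at 0 or 1.
- **Centering and normalization**: every kernel is centered in feature space
  with training statistics and then cosine-normalized — the result is the
  cosine similarity in the centered feature space. Cross matrices (test or
  candidate rows against training columns) are centered with train-side means
  only and normalized with their centered self-kernels. Centering an
  already-centered matrix is refused outright (double centering is silent and
  wrong), and a centered self-kernel at or below 1e−12 — a point
  indistinguishable from the training mean — is an error naming the offending
  id rather than a division by almost-zero.
- **Uniform multiple-kernel combination** takes the entrywise mean of
  centered+normalized input Grams (equivalent to equal-weight summation up to
  a scale the cosine scores are invariant to), then re-normalizes.

## The evaluation protocol

Five-fold cross-validation grouped by molecular structure: all spectra of one
structure share a fold, so no test query has a training spectrum of the same
molecule. Per round, three folds train the regression models, one fold trains
the fusion weights (and selects the fusion `λ` by inner 4-fold top-1
accuracy, ties to the larger `λ`), and one fold is tested. The ridge
parameters `λ_h`, `λ_g` are selected per model by inner-CV mean squared error
computed entirely with the kernel trick (ties to the larger, i.e. more
regularized, value); the default grid spans decades `1e−5 … 10` and is plain
configuration, not an estimate of any particular dataset's optimum. The inner
CV reuses the already-preprocessed training kernel without re-centering
inside each inner split — centering is a smooth function of the data and the
selection is a discrete argmin over a decade grid, so the simplification does
not move the selected value in practice and keeps the tuner `O(grid ×
folds)` Cholesky factorizations.

Ranking is pessimistic under ties: the truth's rank counts every strictly
better candidate *and* every tied non-truth candidate, so constant scores
yield rank `n_c` and degenerate scorers can never inflate top-k accuracy.
Queries whose truth is missing from the candidate set are flagged, logged and
excluded from accuracy denominators (the synthetic generator never produces
them; file-based inputs might).

Nothing is learned from the test fold: all centering statistics, `λ`, `γ`
and fusion weights derive from train/validation folds. The test suite
enforces this by corrupting test-fold fingerprints and asserting the trained
quantities are bit-identical.

## The synthetic benchmark

Real reference spectra link structure to peaks through fragmentation
chemistry; the generator replaces that with the simplest mechanism that
produces the input–output dependence the method exploits: every fingerprint
bit owns a few characteristic fragment masses (drawn once per view from a
shared pool, so distinct bits can collide), and a molecule's spectrum is the
noisy union of its active bits' peaks — Gaussian m/z jitter, intensity
`|1 + N(0, σ)|`, per-peak dropout, plus uniform noise peaks. Multiple
independent views of the same molecules stand in for multiple input kernels.
Candidate sets contain the truth, near decoys (the truth's fingerprint with a
few bits flipped, given fresh ids so difficulty is controlled by the flip
count alone) and far decoys (other molecules). Setting the dropout
probability to 1 switches the signal off entirely, giving exact chance-level
ground truth.

Default conditions: 80 molecules, 64-bit fingerprints in 16 correlated
blocks (within-block bits copy a shared latent Bernoulli with probability
0.8), activation probability 0.3, 2 characteristic peaks per active bit from
a 200-mass pool on 50–500 Da, m/z jitter 0.01 Da, intensity noise 0.2,
dropout 0.1, 3 noise peaks, 10 candidates per query with 2-bit near decoys
and half far decoys, 2 views. These are plausible desk-scale analogues of
reference-library data — small enough that the full protocol runs in seconds,
hard enough that accuracies sit well away from both ceiling and chance.

What passing tests on this generator do **not** show: performance on real
spectra. The generator has no fragmentation trees, adducts, isotope
patterns, collision-energy structure or instrument-specific noise, and its
fingerprints are far shorter than real molecular-property vectors. The tests
establish that the estimators, preprocessing and optimizer are correct and
well-calibrated, not that any particular accuracy carries over.

## Numerical choices

- `(λI + K)` is solved by Cholesky. Centered kernels are singular by
  construction (rank ≤ ℓ−1); `λ > 0` restores definiteness. If factorization
  still fails from round-off, jitter `1e−10 · trace/ℓ` is added once, then
  failure is loud.
- Queries are solved in blocks (multi-right-hand-side triangular solves);
  results are identical to per-query solves to round-off, which the tests
  assert.
- Squared distances that come out slightly negative from cancellation are
  clipped to zero (logged at debug level).
- Degenerate prediction norms (`α'K_Yα ≤ 1e−12`) yield all-zero cosine
  scores with a warning instead of NaN.
- All randomness flows from one master seed through named child streams
  (fingerprints, fragment tables, per-spectrum noise, candidates, fold
  shuffles, SGD batches), so every stage is independently reproducible and
  identical seeds give identical results end to end.

## Problem sizes used by the checks

The acceptance script and test suite run at deliberately small scale: oracle
comparisons at ℓ = 30 training points with 10 queries × 20 candidates,
interpolation checks at ℓ = 25–30, chance-level calibration at 100 pure-noise
queries with 50 candidates each, fusion-recovery runs at 250 molecules
(150/50/50 train/validation/test) over five seeds, and the full protocol
demonstration at 40–60 molecules. These sizes were chosen so each property is
measured with enough resolution to be meaningful (e.g. 50+ test queries where
percentages are compared) while the whole suite stays interactive.

## Known limitations

- MGF is the only spectrum format read; mzML/mzXML conversion is upstream.
- Fingerprints are consumed as data; nothing is computed from structures.
- Fragmentation-tree input kernels are supported only as precomputed Gram
  matrices.
- The fusion optimizer's residual weight noise scales with the final step
  size `1/(λ k_total)`; with few validation queries and very thin score
  margins the learned combination can under-resolve models that an infinite
  optimization would zero out. The protocol's validation-based `λ` selection
  is the guard the method itself provides.
- No statistical significance testing between methods is included.
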