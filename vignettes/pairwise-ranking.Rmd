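---
title: "Pairwise learning-to-rank for conformer ensembles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise learning-to-rank for conformer ensembles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molrank)
```

## The problem

Virtual screening over conformer or isomer ensembles rarely needs the
*value* of a molecular property — it needs the *order*: which configuration
of a molecule has the lowest energy, which candidate should be passed to an
expensive DFT calculation first.  A regression model trained pointwise
optimises the wrong quantity for this task: when the configurations of one
molecule have very similar property values but different molecules sit on
wildly different absolute scales (total electronic energies are the extreme
case), most of a pointwise model's capacity is spent explaining
between-molecule scale, and the within-molecule ordering — the part a
screen actually uses — is drowned out.

`molrank` implements the pairwise alternative: a Siamese learning-to-rank
framework in which one scoring network, applied to both members of a pair
of configurations *of the same molecule*, is trained to predict which one
ranks higher.  Absolute scale cancels in the score difference by
construction, which is exactly why the approach excels on
absolute-energy-like properties.

## The scorer

The shared branch is a distance-based graph neural network.  For a
structure with nuclear charges $Z_1,\dots,Z_n$ and coordinates
$r_1,\dots,r_n$ (Å):

1. **Embedding.** $x_i^{0} = a_{Z_i}$, a learned vector per element
   ($F$ features; default 128, the experiments here use 64).
2. **Distance featurisation.** Each pair distance $d_{ij}$ is expanded on a
   Gaussian grid, $[e^{-\gamma (d_{ij}-\mu_k)^2}]_{k=1..K}$ with $K = 300$
   centers $\mu_k = 0.0, 0.1, \dots, 29.9$ Å and $|\gamma| = 1$.  (A
   positive sign in the exponent would diverge; the decaying-Gaussian
   convention is used and the configuration stores the magnitude.)
3. **Interaction rounds** ($T$ rounds; default 3, experiments use 2).
   Messages
   $$m_i = \sum_{j \ne i} \phi(d_{ij})\; x_j \odot
     W_2\,\sigma(W_1\,\mathrm{rbf}(d_{ij}) + b_1) + b_2$$
   followed by a residual update $x_i \leftarrow x_i + U_2\,\sigma(U_1 m_i
   + c_1) + c_2$, then one shared atom-wise dense layer.  $\sigma$ is the
   shifted softplus $\mathrm{ssp}(x) = \ln(0.5 e^x + 0.5)$ throughout.
4. **Learnable cutoff.** $\phi(d) = 1 - 6u^5 + 15u^4 - 10u^3$,
   $u = d/r_\mathrm{cut}$, clamped to zero beyond the cutoff (the raw
   polynomial goes negative there).  $r_\mathrm{cut}$ is a *trained*
   parameter, kept positive through a softplus reparameterisation and
   initialised at 10 Å.
5. **Prediction layer.** Per-atom
   $p_i = u \odot E_i + w_1 \odot \mathrm{atw}^{(1)}_i + w_2 \odot
   \mathrm{atw}^{(2)}_i$, where $E$ is the embedding and
   $\mathrm{atw}^{(1)},\mathrm{atw}^{(2)}$ are the outputs of the two final
   atom-wise layers — a skip connection that lets gradients reach shallow
   depths directly.
6. **Readout.** The $p_i$ are summed over atoms and mapped linearly to one
   scalar score.  Sum pooling keeps the score size-extensive and
   permutation invariant; since every other ingredient depends only on
   $Z$ and pair distances, the score is exactly invariant to rigid
   rotations, translations, and atom relabelling.

Two architectural choices were genuinely open and are resolved as follows.
Each round applies the interaction step first and the atom-wise layer
second, so the two tapped atom-wise outputs are the final two rounds'
outputs and every interaction block contributes to the score; with the
opposite ordering the last interaction would receive no gradient at all.
And because $\phi(d_{ij})$ is a scalar weight, applying it to the whole
$j$-term or to $x_j$ alone is mathematically identical; it is implemented
as a scalar weight on the term.

## Pairwise heads and objectives

Both Siamese branches are literally the same function (one scorer applied
twice), so antisymmetry is exact by construction rather than learned:

* **Pairwise entropy** — $p = \operatorname{logistic}(s_a - s_b)$ trained
  as a binary classifier with labels $(1,0)$ if $t_a > t_b$, $(0,1)$ if
  $t_a < t_b$, $(0.5, 0.5)$ on ties (ties compared exactly as stored; an
  optional absolute tolerance, default 0, may declare near-ties).
  Probabilities are clipped at $10^{-7}$ inside the loss.
* **Pairwise squared** — the same scorer, with
  $((s_a - s_b) - (t_a - t_b))^2$ instead of the classification loss.
* **Pointwise** — the traditional baseline, $(s - t)^2$ per structure.

Because the head is an increasing function of the score difference,
sorting a group by branch score coincides with any reasonable aggregation
of pairwise outranking probabilities; the test suite verifies this against
a brute-force aggregation over all ordered pairs.

The same three objectives also drive an MLP head
(dense 128 → tanh → dense 64 → tanh → dense 1) over precomputed fixed-length
molecular embeddings read from a delimited table.  The activation after the
64-unit layer and the linear output are choices made here (the hidden
activation is tanh, so tanh is used again); they are flagged as such.

## Training

Gradients are hand-written reverse-mode differentiation, verified
end-to-end against central finite differences in the test suite
(`test-gradients.R`); the optimiser is Adam with standard moment
coefficients (the reference protocol leaves the optimiser unreported; Adam
is the field default for this model family, and plain SGD is available).
Dense layers use fan-in-scaled uniform initialisation; embeddings are
seeded standard normal scaled by $1/\sqrt F$.  Defaults mirror the
reference protocol: 64 pairs per batch, up to 60 epochs, learning rate
$10^{-4}$.  Training pairs are drawn within conformer groups only, with a
per-group budget (the reference protocol does not state a pair budget; it
is a free parameter here, 20 pairs/group in the experiments).  Tie pairs
stay in the batches — the entropy loss handles soft labels natively.
Optional early stopping (patience on a held-out loss) exists but is off by
default.  Every shuffle derives from the configured seed, so training is
bit-reproducible at fixed thread count.

Batches iterate over structures; vectorisation happens across atom pairs
*within* a structure (dense all-pairs distances, no neighbour lists —
exact and entirely adequate at the molecule sizes targeted), so no padding
or masking is needed.  Per-structure geometry (pair lists and RBF rows) is
parameter-independent and cached across epochs.

## Evaluation

Groups are ranked by scoring each member once.  By default rank 1 is the
*smallest* property value (the convention for energies, where "best" means
most stable); the orientation is configurable per property, and predicted
and true rankings always share one orientation.  Four metrics are averaged
over held-out groups:

* **rank MAE** — mean |predicted − true| rank position;
* **Spearman** — Pearson correlation of the rank vectors, average ranks on
  ties, undefined (reported missing) under zero variance;
* **nDCG** — linear gain $n - r$ for the item with true rank $r$,
  $\log_2(\text{position}+1)$ discount, normalised by the ideal ordering.
  The gain/discount convention is unstated in the reference protocol, so
  printed nDCG values are comparable only within this convention;
* **top-1 frequency** — fraction of groups whose predicted best member is
  truly best (tied minima count as correct).

Dispersion across groups is reported as both the standard deviation and a
normal-approximation 95% CI half-width $1.96\,s/\sqrt{n}$ (the reference
protocol is ambiguous about which its "±" values are, so both are given).

## Synthetic ensembles

The generator emulates the *structure* of large quantum-chemistry
ensembles — one base geometry per molecule plus many perturbed
nonequilibrium copies — without any quantum chemistry: base geometries are
random point clouds (uniform in a box, minimum interatomic distance 0.8 Å
by rejection), conformers add Gaussian coordinate noise, and properties
are analytic functionals of the geometry:

* `energy` — $\sum_{i<j} Z_i Z_j / d_{ij}$, a smooth surrogate for
  absolute energetic properties, optionally shifted by a per-molecule
  Gaussian constant to emulate total-energy scale differences between
  molecules;
* `gap` — a nearest-neighbour (soft-minimum) term minus a long-range
  inverse-distance term, a surrogate for difference-type properties.

Both surrogates are exactly invariant under the transformations the
backbone is invariant under, so any ranking failure is attributable to
learning, never to representation mismatch.  What the generator does *not*
emulate: chemically valid bonding, realistic property distributions,
element-specific geometry preferences.  Passing the recovery experiment
therefore demonstrates that the pipeline can learn to rank a smooth
geometry-dependent functional from examples — not that it reaches any
particular accuracy on real quantum-chemistry data.

## The desk-scale experiments

`ranking_experiment()` is the package's end-to-end protocol: generate 40
molecules (12 conformers, 4–8 atoms, 0.3 Å perturbations), split 30/10 at
the molecule level (no configuration of a held-out molecule is ever seen
in training), train a 64-feature, 2-round scorer for 40 epochs at learning
rate $10^{-3}$ with 20 pairs per group, and evaluate the four metrics on
the held-out molecules against the untrained initialisation as baseline.
These sizes are deliberate desk-scale choices — large enough for the
ordering signal to be learnable, small enough to run routinely; the
learning rate is larger than the large-ensemble default because the run
takes ~400 optimisation steps rather than millions.

The companion run adds per-molecule offsets to `energy` at 100× the mean
within-group spread and trains pairwise-entropy and pointwise models under
identical budgets.  Offsets cancel in every pair difference, so the
pairwise model is untouched; the pointwise model must regress targets
dominated by molecule-level constants that are unpredictable for held-out
molecules, and its held-out ranking collapses — the mechanism behind the
pairwise advantage on absolute-energy-like properties, reproduced in
miniature.  `scripts/acceptance.R` recomputes both experiments from
scratch and writes the headline numbers.

## Numerical choices and degenerate inputs

* Shifted softplus is computed as
  $\max(x,0) + \log(1+e^{-|x|}) - \ln 2$ (overflow-safe).
* $\phi$ is clamped to exactly 0 at and beyond $r_\mathrm{cut}$; its
  analytic $r_\mathrm{cut}$-gradient is likewise zero there.
* Score ties in ranking break stably by structure id; property ties get
  average true ranks (Spearman), grouped relevances (nDCG), and count as
  hits (top-1).
* Single-atom structures are valid: the neighbour sum is empty and the
  score reduces to the embedding/readout path.
* A group with zero property variance yields an undefined Spearman,
  reported as missing and excluded (with a count) from the aggregate.
* The test-group count is `round(fraction × n_groups)`, minimum 1.
* Checkpoints are JSON (metadata block + flat parameter vector) — portable
  text at full double precision for all practical purposes; exact
  reproducibility claims attach to re-running from a manifest, not to
  checkpoint round trips.

## Known limitations

Dense all-pairs distances make the cost quadratic in atom count — fine for
small-molecule ensembles, wrong for proteins.  No periodic boundary
conditions, no coordinate gradients (forces), no listwise objectives.
Training is CPU-bound R; the implementation is written for correctness,
reproducibility and desk-scale experiments, not for GPU-scale throughput.
The synthetic benchmark shows mechanism, not chemistry-grade accuracy.
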