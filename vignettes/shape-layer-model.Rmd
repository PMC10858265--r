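---
title: "A layered recurrent-graph model of DNA shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered recurrent-graph model of DNA shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA shape features — minor groove width (MGW), the inter-base-pair step
parameters (Shift, Slide, Rise, Tilt, Roll, HelT), the intra-base-pair
parameters (Shear, Stretch, Stagger, Buckle, ProT, Opening) — describe the
local 3D conformation of the double helix, and proteins read them out
alongside direct base contacts. Deriving them from simulations or crystal
structures is slow, so high-throughput prediction from sequence alone is
the standard approach. The classic tool is a *pentamer query table*: the
mean shape value at the centre of every 5-mer seen in a simulation corpus,
applied by sliding window. A table of width 5 structurally cannot see more
than 2 bp of flanking sequence, and it silently inherits whatever flank
composition the training corpus happened to pair with each pentamer.

`deepshape` implements the successor model: a per-nucleotide recurrent
graph network whose receptive field grows by exactly one base pair per
layer, so the flanking influence admitted into a prediction is an explicit,
selectable quantity rather than an accident of table width.

## Model

A sequence is a chain of nodes — one per nucleotide for per-bp features,
one per dinucleotide step for inter-bp features — with one-hot feature rows
(4 or 16 channels; `N` encodes as the average over compatible bases). One
uniform "N cap" node is added at each end and self-linked, so every node,
terminal or not, has a 5' and a 3' neighbour; caps are dropped from the
final profile. A width-1 convolution (the *self layer*) lifts channels to
`filter_size` features. Then `L` *shape layers* run; in each, for node $i$
with state $X_i$:

$$\lambda = \omega_1 X_{i-1} + \omega_2 X_{i+1} + B_1, \qquad
  \alpha  = \theta_1 X_{i-1} + \theta_2 X_{i+1} + B_2,$$
$$u = \mathrm{BN}(\mathrm{ReLU}(\lambda \odot X_i + \alpha)), \qquad
  \tilde X_i = \mathrm{GRU}(u,\; X_i),$$

where $\omega_{1,2}, \theta_{1,2}$ are `filter_size` × `filter_size`
matrices, $B_{1,2}$ bias vectors, BN is batch normalization (batch
statistics while training, frozen running statistics at prediction), and
the GRU cell uses sigmoid gates and a tanh candidate
($z = \sigma(W_z u + U_z h + b_z)$, $r = \sigma(W_r u + U_r h + b_r)$,
$n = \tanh(W_n u + U_n (r \odot h) + b_n)$,
$h' = (1-z)\odot h + z \odot n$). Each layer has a scalar output head per
node: the mean over the `filter_size` channels, passed through tanh. Since
one layer moves information one node, the head of layer $k$ sees exactly
$k$ bp of flanks for per-bp features and $k{+}1$ bp for step features
(a base sits in two step nodes); `receptive_radius()` verifies this
empirically by perturbation probing, and the locality is exact — an edit
beyond the radius changes nothing, to the last bit.

Interpretation choices where the architecture description is ambiguous,
resolved once and fixed here:

* $\lambda \odot X_i$ is the diagonal (elementwise) action of the gate
  vector $\lambda$ on $X_i$. Treating $\lambda$ itself as a dense
  per-node matrix would require order-3 weight tensors, which is neither
  the natural reading of $\omega_1 X_{i-1}$ with matrix-valued
  $\omega_1$ nor computationally reasonable.
* The GRU convention is the standard one above; alternative
  parameterizations differ in bookkeeping, not capacity.
* Batch normalization sits after the ReLU; running statistics use
  momentum 0.1.
* The head takes tanh *of the channel mean* (not the mean of tanhs): this
  is what guarantees a strict (−1, 1) bound on the emitted scalar.
* Dropout (training only) is applied to the copy of the layer output that
  feeds that layer's head, keeping the recurrent trunk deterministic; the
  trunk is regularized indirectly because every layer's head contributes
  to the loss.
* The self layer is a pure linear transform (no nonlinearity).

## Targets, loss, and training

Raw shape values are normalized as $\hat S = (S - \tilde S)/(S_{99} -
S_{1})$ with the median and the 1st/99th percentiles of the pooled
training values (linear-interpolation percentiles, fixed so stats files
reproduce bit-exactly). The denominator is written here in
orientation-preserving order; with ascending percentiles the reversed
difference would be negative and would silently flip every profile.
Extremes may normalize outside $[-1, 1]$; the tanh head is the bound, and
predictions invert the normalization on output.

The loss is the multi-layer masked MAE: for each layer, the mean absolute
error over *defined* nodes only (undefined terminal values — MGW and EP
carry a 2-bp margin — are masked out entirely), then the unweighted mean
over layers. Training all heads at once is what makes depth selectable at
prediction time without retraining. Optimization is plain SGD with
momentum; mini-batches group sequences of equal length (default batch 32),
so variable-length corpora train without padding and cap semantics stay
exact. Every run is bit-reproducible from its seed (initialization, batch
order, dropout). Gradients are analytic and are checked against central
finite differences in the test suite; a reloaded model predicts
bit-identically.

Defaults follow the published operating point — 7 shape layers, filter
size 64, dropout 0.5, learning rate 0.05, momentum 0.95, 1500 epochs —
and `grid_search()` reproduces the hyperparameter protocol (fixed 90/10
train/validation split, lowest deepest-layer validation MAE wins).

## The synthetic ground truth

Real training corpora come from Monte-Carlo simulation pipelines that this
package does not reproduce; instead, `make_ground_truth()` instantiates
the structural assumption the model itself encodes: the value at a
position is its own base's (or step's) contribution plus flank
contributions that decay geometrically with distance,

$$v_i = c(u_i) + \sum_{d=1}^{R} g(d, 5', b_{i-d}) + g(d, 3', b_{i+d}).$$

Defaults, chosen once as the study conditions: radius $R = 4$, decay
$\gamma = 0.6$, centre-table spread 1.0, nearest-flank contribution scale
0.5 (flank effects comparable to core effects, decaying visibly but
slowly — distant flanks still matter, which is the regime the layered
model exists for), Gaussian position-wise noise with sd equal to 5% of
the realized value range, and corpora of 2121 sequences of length 15–25,
mirroring the reference simulation corpus. Each distance-$d$ contribution
slice is rescaled so its largest magnitude is exactly
$0.5\,\gamma^{d-1}$, making the decay bound a construction property
rather than an expectation. Fluctuation surfaces (for `-FL` features) are
strictly positive smooth functions of the same windows,
$0.5\,e^{\text{additive terms}}$.

What this emulates: variable lengths, per-position real values, NA-masked
termini, flank effects decaying with distance, uneven k-mer context
coverage (on demand, via the constrained-context mode). What it does not:
the noise structure, artifacts, and physical correlations of real
simulation data, nor any physical realism of the values themselves. Tests
passing on this generator therefore demonstrate that the machinery
recovers a known flank-decay law from data — not that the shipped code
predicts real DNA geometry; for that one would retrain on a real corpus
via `load_training_file()`.

Because the truth is known exactly, method comparisons
(`compare_methods()`) score predictors against *noiseless* profiles on
held-out sequences, so reported MAEs are method error, not irreducible
noise. On the default conditions a 7-layer model (desk-scale
configuration below) reaches one-half to one-third of the pentamer
table's error at layer 4, with layer-wise error non-increasing up to the true
radius — the query table's residual is exactly the distance-3 and -4
structure it cannot see.

## The query-table baseline and its bias

`kmer_table()` rebuilds the classic approach: every window's central
value accumulates under its k-mer; prediction is sliding-window lookup;
flank positions and missing k-mers stay undefined (no imputation —
interpolating a table is precisely the bias the layered model avoids; an
explicit narrower fallback table can be supplied, off by default). For
step features the centre step of a window of `k` nucleotides is the one
whose 5' base is at offset `floor(k/2) - 1`. `flank_bias_report()`
quantifies context bias: for each k-mer, the total-variation distance of
its observed (5', 3') outer-base pairs from uniform — 0 for even
coverage, 15/16 for a k-mer seen in a single context, as in the
constrained corpus where `ACGTA` occurs only inside `CACGTAG`.

## Binding-specificity regression

`bind_ridge()` is the standard evaluation layer for feature sets:
position-specific k-mer indicators ($4n$, $16(n-1)$, $64(n-2)$ columns
for 1/2/3-mers) and per-position shape profiles ($n$ per bp feature,
$n-1$ per step feature), ridge regression with nested 10-fold
cross-validation (inner folds select $\lambda$ from 13 values log-spaced
$10^{-6}..10^{6}$), pooled out-of-fold $R^2 = 1 - SSE/SST$ (the folds
are pooled before assessment, so this is the coefficient of
determination, not squared Pearson). Shape columns are normalized
column-wise; the normalization statement being loose in the source
protocol (minimum, maximum and standard deviation are all mentioned),
min–max to $[0,1]$ is the default with z-scoring as an option.
Affinities are used as given, with an optional log transform. In the
synthetic experiments, log-affinity is wired as a linear function of
noiseless shape profiles that include step features; since step truths
depend on dinucleotide identity, 1-mer indicators cannot represent them
and the shape-augmented model measurably outperforms the 1-mer model —
the qualitative claim the feature set exists to support.

## Numerical and scale choices

* Problem sizes: tests and the acceptance script train the recovery model
  with filter size 32, dropout 0.1 and 40 epochs on the 2000-sequence
  corpus — the package's desk-scale configuration; accuracy there is
  limited by training length, not architecture, and the published
  defaults remain the defaults.
* Receptive-field probing uses tolerance 1e−9 on the normalized scale;
  beyond the architectural radius differences are exactly zero, so the
  tolerance only guards the inner side.
* Ridge solves use the closed normal-equations form with an unpenalized
  intercept (columns centred on the training fold); $\lambda \to 0$
  reproduces least squares to 1e−6 on well-conditioned designs.
* Degenerate inputs fail loudly: all-identical values in
  `compute_norm_stats()`, zero defined nodes in the loss, rank-0 designs,
  non-finite training loss (divergence) all raise errors rather than
  returning numbers.
* Ties in `grid_search()` resolve to the first configuration
  (`which.min`).

## Known limitations

No GPU path and no joint multi-feature training; per-step query tables
with even-window conventions other than the one above are not provided;
`EP` is registered but, like every feature here, is only as good as the
training data supplied — the package ships no trained weights and makes
no claim about real DNA until trained on real shape tables; modified or
mismatched bases are not encodable.
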