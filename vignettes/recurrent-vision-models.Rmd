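---
title: "Recurrent vision models with entropy-threshold decisions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent vision models with entropy-threshold decisions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `rvt`, the conventions and
tunable parameters behind them, the choices made where the underlying
methodology leaves the design open, and what the desk-scale synthetic
experiments can and cannot show.

## 1. The architecture family

All networks are built from the same block template: a stride-1,
size-preserving (zero-padded "same") convolution, batch normalisation, and
a rectified linear unit, with 2×2 stride-2 max pooling between blocks and a
global-average-pool + dense softmax readout at the top. The full-scale
family has seven blocks with feature maps 96, 128, 192, 256, 512, 1024,
2048 and kernels 7, 5, 3, 3, 3, 3, 1 on a 128×128×3 input; pooling follows
blocks 1–6, so block *n* runs at 128/2^(n−1) pixels.

* **B** is that feedforward stack.
* **B-K** widens kernels to 11, 7, 5, 5, 5, 5, 3 (+4 in block 1, +2
  elsewhere).
* **B-F** doubles every feature-map count.
* **B-D** runs each block's convolution twice (the second F→F convolution
  has exactly the shape of BL's lateral convolution, which is what makes
  the two controls parameter-comparable).
* **BL** adds a lateral convolution from the block's own activations at the
  previous time step:
  `H_{t,n} = φ(W_n^b ∗ η(H_{t,n−1}) + W_n^l ∗ H_{t−1,n} + b_n)`,
  unrolled for T = 8 steps with a readout per step.
* **B-U** (`build_bu()`) is BL's unrolled graph with unique parameters per
  convolution: T copies of the bottom-up stack, T−1 lateral copies (the
  t = 1 lateral input is the zero stack and has no weights), and one
  readout per former time step.

Reduced scales (`make_spec(family, list(...))`) keep these family deltas
intact — B-F still doubles F, B-D still duplicates convolutions, B-K still
adds +4/+2 to the kernel pattern — so parameter-matching logic remains
testable on two-block, 16-pixel instances.

**Initial lateral state.** `H_{0,n} = 0` for all layers. Nothing else makes
the first sweep well defined without extra assumptions, and it has the
attractive consequence that BL at t = 1 is *exactly* the feedforward sweep
of its bottom-up skeleton (asserted to 1e−12 in the tests).

**Unrolling conventions.** `unroll(spec, mode)` materialises the
computational graph in *engineering* time (feedforward edges take no time;
lateral edges take one step) or *biological* time (every edge takes one
tick). For lateral-only recurrence the two graphs are isomorphic: the
engineering node (t, n) sits at biological tick t + n − 1, with the input
clamped at every tick and readout t read at tick t + N − 1. The package
implements both schedulers and the test suite checks per-readout equality
to 1e−6 on a 2-layer, 3-step fixture; nodes that cannot reach a readout
are omitted from the biological graph.

## 2. Parameter accounting

`count_parameters()` counts convolution weights, per-time-step batch-norm
gain and shift (2 per feature map per time step — normalisation is applied
independently at every time step, so a T-step BL carries T copies), and
the readout weights and bias. Two conventions deserve comment:

* **No separate convolution biases.** Every convolution is followed
  immediately by batch normalisation, whose shift β *is* the layer's
  additive degree of freedom; a conv bias would be redundant and is not
  allocated. This is the standard practice for conv+BN stacks, and it is
  the only convention under which the package's closed-form totals
  simultaneously reproduce all the published figures this family is known
  by: B 11.0M, B-K 39.8M, B-F 40.0M, BL 28.9M, B-U 212.7M, and the
  ≈60,000 batch-norm parameters added across BL's time steps
  (7 × 8512 = 59,584). Counting per-conv biases would push B-U to
  212.75M → 212.8M, off the printed value.
* **Running statistics are excluded**: they are not trainable.

One discrepancy is irreducible: the deeper control B-D computes
28,819,848 parameters (28.8M) from its architecture rows, while the
published table prints 28.9M — the same figure as BL. No counting
convention closes the gap (even adding biases *and* running statistics
reaches only 28.85M), because B-D lacks BL's seven extra sets of
batch-norm parameters: the two models share their convolution subtotals
exactly, and differ by precisely those 7 × 8512 − 8512 parameters. The
package reports the arithmetic truth; `scripts/acceptance.R` emits 28.8
for B-D.

`count_flops()` uses the convention *one multiply–add = 2 floating-point
operations*, counting convolution and dense multiply–adds only; pooling
comparisons, batch-norm arithmetic and element-wise work are excluded by
default but can be toggled via `include=`. Lateral products against the
zero state at t = 1 are counted by default (`skip_zero_lateral = FALSE`),
so per-time-step cost is constant for BL. Every `cost_profile` carries its
convention tag, and all comparative analyses in the package (SAT curves,
matched-cost selection, readout-site spacing) depend only on cost *ratios
and orderings*, which are convention-invariant.

## 3. Anytime decisions and the speed–accuracy trade-off

The decision mechanism never halts the computation graph; it measures when
a run *would* have stopped. Given the T per-step softmax outputs for an
image:

* the **cumulative readout** at t is the arithmetic mean of steps 1..t (a
  convex combination of simplex points, so no renormalisation); it is the
  default `readout_mode` because accuracies for recurrent models are
  conventionally reported from cumulative readouts;
* confidence is the Shannon entropy of the readout in **nats** (the base is
  a convention; thresholds are tagged so bits users can divide by ln 2);
* under `threshold_based` policy the reaction time is the first t with
  entropy ≤ θ (**inclusive**, so θ = ln C — the entropy ceiling — always
  stops at t = 1), falling back to T when the threshold is never reached;
* argmax ties break toward the lowest class index (a documented, arbitrary
  but deterministic rule).

`sat_curve()` sweeps θ over (by default) every unique entropy observed in
the evaluation set plus the endpoints 0 and ln C — the finest grid on which
operating points can differ, so every achievable point appears. For each θ
it records accuracy, mean per-image cost at the decision, and the cost
histogram (fraction of images deciding at each cost, with accuracy at that
cost); the weighted mean of the histogram reproduces the curve point
exactly, an invariant the tests assert. `matched_cost_threshold()` picks
the θ minimising |mean cost − target|, ties toward the larger (cheaper) θ.

For paired model comparison `mcnemar_test()` builds the discordant counts
b and c and uses the exact two-sided binomial test when b + c < 25, else
the continuity-corrected statistic (|b−c|−1)²/(b+c). The threshold 25 is
the package's documented rule (the variant can be forced); note that at
the degenerate edge b = c the base-R implementation zeroes its continuity
correction while this package follows the formula literally
((0−1)²/(b+c)), so cross-checks against `stats::mcnemar.test` are made
away from that edge. `bonferroni()` caps p·m at 1.

## 4. Training

`train_config()` defaults mirror the full-scale recipe: 90 epochs, batch
100, Adam with learning rate 0.005 and ε = 0.1, L2 coefficient 1e−6 (as
λ·Σw² over convolution and readout weights), random crop covering at least
one third of the image area, left-right flips, and small photometric
jitter, with inputs scaled to [−1, 1]. Where the recipe is silent the
package chooses: crop aspect ratio in [3/4, 4/3]; brightness jitter ±0.1,
saturation/contrast ×[0.9, 1.1]; constant learning rate; a fixed 80/20
train/validation split drawn from the seed. The loss for multi-readout
models is the cross-entropy at each readout averaged across readouts
(`multi_readout_loss()`), which reduces to ordinary cross-entropy at
T = 1.

The forward/backward engine is written in array R (im2col convolutions on
BLAS matrix multiplies) and is verified against central finite differences
to ~1e−8 relative error for BL, B-D and B-U — including backpropagation
through time across the lateral edges and through the per-time-step batch
normalisation. Numerical choices: batch-norm ε = 1e−5 with running-mean
momentum 0.9 (evaluation mode uses running statistics; each time step
updates its own statistics from its own activations only); He fan-in
initialisation for convolutions, fan-in-scaled Gaussian for the readout,
zero biases; max-pool gradient ties route to the first window position in
column-major order; odd spatial sizes pool with −∞ padding (ceiling
semantics).

**Desk scale.** The reference desk-scale conditions used by the heavier
tests are: synthetic task with 10 classes at 16×16 (50 images/class for
training, 20/class held out), BL with two blocks (F = 8, 16), T = 4;
training for 14 epochs, batch 20, learning rate 0.01, Adam ε = 1e−3, no
augmentation. The smaller ε matters: with desk-scale gradient magnitudes
the full-scale ε = 0.1 dominates the Adam denominator and freezes
learning. Under these conditions the model trains well above chance, its
cumulative-readout accuracy rises across time steps on average over seeds,
and its SAT curve rises with mean cost and saturates — the qualitative
signatures of the full-scale phenomena. Full-scale accuracies are out of
reach at this scale by design.

## 5. Fitting network reaction times to subject data

The reaction-time pipeline mirrors a binary (super-category) discrimination
experiment:

1. **Sites.** Multi-readout models (BL, B-U) use their T readout positions.
   Single-readout feedforward models supply a candidate list of
   rectifier-output layers with cumulative costs; `place_readout_sites()`
   selects 8 by minimising the maximum deviation of the cumulative costs
   from the even-spacing anchors j·total/8 (exact dynamic programme; ties
   toward earlier candidates).
2. **Projection.** Site activations are projected to d = 512 dimensions by
   PCA fitted on training images (`fit_projection()`); recurrent models
   pool all time steps into one fit. The decomposition is exact SVD, so
   the seed argument only pins downstream reproducibility; ambient
   dimensions ≤ d get an identity-with-padding map, preserving distances.
3. **Readout.** A recurrent sigmoid readout
   y_t = σ(α y_{t−1} + w·p_t + b), y_0 = 0.5, with a single (α, w, b)
   shared across sites, trained by full-batch Adam (learning rate 0.001,
   1000 iterations) on class-weighted binary cross-entropy, weights
   inversely proportional to class frequency. Feedforward models get an
   independent static (w, b) per site and no α. Setting α = 0 provably
   collapses the recurrent readout to per-site logistic readouts, which
   the tests assert.
4. **Reaction times.** The binary entropy −y ln y − (1−y) ln(1−y) of the
   sigmoid output is thresholded exactly as in the category case: the
   first of 8 sites at or below θ, site 8 as fallback. Across model
   seeds, sigmoid *outputs* are averaged before entropies are taken (the
   averaging stage is a design choice; averaging entropies or reaction
   times instead would also be defensible, but output averaging keeps the
   quantity a probability).
5. **Threshold fitting.** `rt_fit()` runs double leave-one-out
   cross-validation: every (subject, image) fold fits θ on the remaining
   cells by maximising the Pearson correlation between network reaction
   times and the training subjects' mean reaction times over training
   images, then predicts the held-out cell. The θ grid is every observed
   site entropy plus the endpoints 0 and ln 2, which makes the per-fold
   maximiser exact; among tied maximisers the largest θ (earliest
   decisions) wins. Folds with a constant training vector are flagged and
   fall back to the global median of the fitted thresholds; an entirely
   constant subject matrix is an error. Fold hygiene — the held-out cell
   never influences its own prediction — is asserted by perturbation in
   the tests. Per-subject Pearson correlations of the assembled
   predictions, the leave-one-subject-out consistency (`human_consistency`,
   a lower bound on the noise ceiling), the paired sign-flip permutation
   test (10,000 draws, identity included so p ≥ 1/(n+1); exact enumeration
   for n ≤ 16), and Benjamini–Hochberg FDR control complete the
   statistics.

A note on exact threshold recovery: with continuously distributed
entropies, a held-out image can carry an entropy value strictly between
the fitted and the planted threshold, so cross-validated recovery is exact
only up to one grid step. The recovery tests therefore use replicated
difficulty levels (so held-out images share entropy values with training
images), under which zero-noise recovery is exact and held-out
correlations equal 1.

## 6. Lateral-weight components

`extract_templates()` unpacks a layer's K×K×F×F lateral array into F²
flattened K² templates, ordered row-major over (source, target) with
source varying fastest — the documented convention that makes loadings
reproducible. Templates are normalised to unit Euclidean length
(`normalize_templates()`; all-zero templates cannot be normalised and are
excluded with a warning and a count). `lateral_pca()` then runs
**mean-centred** PCA with each template as a sample — centring is the
standard definition and is recorded in the object; variance-explained
fractions are of total variance. Components are unit vectors reported in
their positive form; the sign-flipped negative form is the same component
seen from negatively-loading templates, and `top_loading_pairs()` returns
the strongest positive and negative (source, target) pairs with direction
preserved. The generative-recovery test plants three orthogonal patches
with graded coefficient variances and recovers each at |r| > 0.99 under
σ = 0.01 noise. Reproducing any *particular* full-scale component
structure would require the original trained weights and is out of scope.

## 7. The synthetic data generator

`synth_task()` emulates the features of a large recognition task that the
pipeline actually consumes: (a) multi-class images with *graded
difficulty* — each class has a procedural prototype (distinct shape ×
colour on mid-grey), corrupted by additive Gaussian pixel noise with
per-image σ ~ U(0, 0.8) — so entropy-threshold reaction times vary across
images; (b) a binary super-category partition (even/odd class index)
standing in for animate/inanimate. Defaults: 10 classes, 32×32 pixels
(16×16 in the desk-scale test conditions), clipped to [0, 1],
byte-reproducible given the seed. A nearest-prototype classifier is
perfect at difficulty 0 and degrades monotonically across difficulty bins
(Monte-Carlo asserted). What it does **not** emulate: natural-image
statistics, category structure, background clutter, or scale/pose
variation — so passing tests demonstrate the pipeline's correctness and
qualitative behaviour, not performance claims about natural images.

`synth_subject_rts()` generates subject×image matrices from a reference
model's entropy trajectories with a planted threshold θ\*: subject s
responds gain_s · site(θ\*, image) + offset_s + trial noise, averaged over
6 repeats per image. Defaults model a 20-subject, 96-image group on a
millisecond scale: gain 70 ± 10 ms per site, offset 450 ± 50 ms, trial
noise 200 ms — chosen once so that subject consistency lands around 0.8,
typical of speeded categorisation groups. `synth_entropy_trajectories()`
provides the reference trajectories: per-image confidence grows with a
rate decreasing in difficulty, so harder images cross any threshold later
(Spearman-checked).

## 8. Interfaces and artifacts

Specs serialise as YAML; checkpoints are RDS files carrying spec,
parameters, and batch-norm state, with a JSON manifest naming every
parameter by (block, convolution, time step) and recording the
channel order and [−1, 1] input scaling. Decisions, SAT curves,
reaction-time matrices, and lateral components export as CSV with JSON
sidecars; every CLI run writes a manifest echoing arguments, seed, and
versions. Image resizing in the preprocessing path delegates to
`EBImage::resize` (bilinear); PNG IO uses the `png` package.

## 9. Known limitations

* The engine is CPU array code: it is exact (gradient-checked) but not
  fast; full-scale training is out of its intended range, and the
  desk-scale experiments above are sized to minutes on one CPU.
* Only lateral recurrence is implemented; top-down connections would break
  the engineering/biological unrolling equivalence this package relies on.
* Batch-norm evaluation uses running statistics with momentum 0.9, which
  need a few training batches to settle; very short runs evaluate with
  partially-converged statistics.
* `rt_fit()` assumes a complete subject×image matrix (repeats already
  averaged); missing cells must be handled upstream.
* The B-D parameter total is reported as computed (28.8M), which differs
  from the published 28.9M; see §2.
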