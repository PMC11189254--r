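---
title: "Model and methods: one-shot sequence memory in a hippocampal circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: one-shot sequence memory in a hippocampal circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipposeq)
```

## The model

`hipposeq` implements a rate-based model of the hippocampal loop
EC &rarr; DG &rarr; CA3 &rarr; EC that stores sequences of binary patterns
*online and in one shot*: each pattern is presented exactly once and triggers
exactly one weight update per plastic pathway. The central idea is that CA3
does not store the sequence itself. Instead, CA3 holds a *pre-trained cyclic
intrinsic sequence* of random sparse patterns, generated by its recurrent
weights, and the incoming sequence is hetero-associated with it on the fly:
the encoder pathway (DG &rarr; CA3, or EC &rarr; CA3 when DG is ablated)
learns cue &rarr; intrinsic-state, and the decoder pathway (CA3 &rarr; EC)
learns intrinsic-state &rarr; pattern. At retrieval a single cue selects a
CA3 state, the recurrent dynamics then plays the intrinsic cycle forward,
and the decoder emits the stored sequence in order.

Every layer is made of **centered neurons**: the output is
`h_j = phi(sum_i (x_i - mu_i) w_ij + b_j)`, where the offsets `mu_i` equal
the mean activity of the presynaptic layer. Centering makes the presynaptic
drive mean-free, which is what lets a single update store a pattern without
an iterative solve.

All plastic synapses learn by **Hebbian descent**: the update is the outer
product of the centered presynaptic activity and the output error,

```
dw_ij = -eta * (x_i - mu_i) * (h_j - t_j),      db_j = -eta * (h_j - t_j),
```

and, for tied-weight autoencoders (reconstruction
`z_i = phi(sum_j (h_j - lam_j) w_ij + c_i)`),

```
dw_ij = -eta * (h_j - lam_j) * (z_i - x_i),     dc_i = -eta * (z_i - x_i),
```

with an optional hidden-bias update `db_j = -eta * (h_j - lam_tilde)` that
regularizes the mean hidden activity towards a target. Because the update
vanishes when output equals target, repeated material costs nothing, and
storing new material overwrites old weights only as much as needed — a
graded, on-demand forgetting instead of catastrophic interference or a fixed
decay timescale.

## Architecture, sizes and activities

Sizes follow anatomical ratios relative to the EC size `N`: CA3 has
`round(2.3 N)` neurons and DG `round(10.9 N)`. Because the models are
orders of magnitude smaller than a real hippocampus, activity levels are
scaled up so that enough units are active for robust association:

| quantity | default | meaning |
|---|---|---|
| `ec_activity` | 0.35 | fraction of EC units active per pattern |
| `dg_activity` | 0.03 | target DG activity (sparse expansion) |
| `ca3_activity` | 0.25 | activity of the intrinsic CA3 patterns |
| `T_intr` | `N` | length of the cyclic intrinsic sequence |
| `eta` (one-shot) | `20 / N` | learning rate of the plastic pathways |
| momentum | 0.9 | sensory codec pre-training only |

The one-shot learning rate follows the empirical size law `eta = 20/N`
(0.1 at `N = 200`); our own scans confirm that recall quality peaks near
this value, with weaker storage below it and heavier overwriting above it.
Connectivity is all-to-all; sparse or random connectivity masks are out of
scope because at these small sizes they dominate the results.

## Pre-training the fixed pathways

Three pathways are trained offline, once, and then frozen:

* **CA3 recurrent** (`pretrain_ca3()`): hetero-association of each intrinsic
  pattern with its successor, 100 epochs, batch 10, `eta = 1`, with 10% of
  input units flipped afresh every epoch so that transitions tolerate noisy
  states. Intrinsic patterns are sampled at the CA3 activity level and
  duplicates are rejected so every position is unambiguous. A
  self-consistency score (mean correlation of one-step transitions with the
  true successors) below 0.99 is reported as a warning.
* **DG separator** (`pretrain_dg()`): a tied-weight autoencoder from EC to
  DG trained on 4000 random binary patterns — one epoch, batch 10, learning
  rate 100 — with hidden offsets and target activity 0.03. The very large
  learning rate saturates the sigmoid hidden units, so the binarized code is
  both sparse and nearly binary by construction. DG is *generic*: it never
  sees the data distribution it will separate.
* **Sensory codec** (`pretrain_sensory()`): a tied-weight autoencoder from
  pixels to EC with per-pixel offsets equal to the dataset mean, hidden
  offsets 0.35, batch 100, `eta = 0.01`, momentum 0.9, 10 epochs. At
  inference the encoder output is a step function (binary EC codes); inside
  the updates both directions use the sigmoid, because a step output carries
  no graded error to descend.

**Weight initialization.** Hetero-associative pathways start from exact
zeros: per-unit targets break the symmetry immediately, and zero
initialization makes one-shot storage fully reproducible. Tied-weight
autoencoders *cannot* start from zeros: the tied update is identical for
every hidden unit when all hidden activities coincide, so the code would
never differentiate. They therefore start from small Gaussian weights
(sd 0.01, seeded).

## Storage, retrieval, replay

During **storage** (`store_sequence()`) the CA3 state follows the clean
intrinsic cycle — the model assumes the theta rhythm suppresses the
DG &rarr; CA3 drive during encoding, so the encoder's own (possibly
imperfect) output never decides which CA3 state gets associated. The first
intrinsic position is drawn uniformly at random. During **retrieval**
(`retrieve()`) the roles flip: the cue is pushed through the encoding path
once, then the plastic encoder is silenced and the recurrent dynamics takes
over; every state is decoded on the way. Binary states are propagated
between subregions by thresholding the sigmoid output at 0.5, with an exact
tie mapping to inactive so that sparse codes stay sparse.

A retrieval trajectory is classified (`relaxation` field) by comparing the
post-transient CA3 states with the intrinsic sequence: `correct` if they
ride the cycle at the cue's own positions with mean correlation at least
0.9 after discarding a transient of up to 5 steps, `shifted` if they ride
it at a wrong offset, `spurious` otherwise. The transient length matches
the degraded initial phase observed for ambiguous cues; the 0.9 criterion
is our choice, exposed as an argument.

**Replay** (`replay()`) runs the model with no input at all: looping over
the stored part of the intrinsic cycle, each CA3 pattern is decoded to a
reconstructed EC pattern and the *direct* EC &rarr; CA3 encoder is
re-trained on (reconstruction &rarr; intrinsic pattern), ten passes by
default; the decoder is frozen. Replay exists for the DG-less
configuration, where the low-dimensional encoder cannot cope with
correlated inputs on one shot; reconstructions are imperfect but repeated
exposure outweighs that.

## Datasets

`gen_rand()` draws patterns with an exact count of active units
(`round(activity * n)`), not Bernoulli draws, so activity is conserved
exactly. `gen_rand_corr()` chains patterns by flipping 10% of all units per
step (half on-to-off, half off-to-on), which yields an expected
consecutive-pair correlation of `(0.30 - 0.35^2)/(0.35 * 0.65) = 0.78` at
the default activity — a closed form the tests pin down — while distant
patterns decorrelate. Cue noise (`add_binary_noise()`) flips
`round(noise_pct * n_on)` units of each polarity; defining the percentage
relative to the *on-units* keeps activity conserved (the common worked
example of "20% noise" is arithmetically ambiguous between bases; ours is
the on-unit base, and the count is an argument).

`gen_synthetic_images()` provides a self-contained stand-in for
handwritten-digit images: smoothed random blobs pushed through a steep soft
threshold. It reproduces the two statistics the codec cares about — pixel
mass concentrated near 0 and 1, and per-image foreground between 10% and
50% — but none of the semantic structure of real digits (no classes, no
stroke correlations), so codec tests demonstrate binarization and
reconstruction, not digit recognition. Real MNIST IDX files are supported
via `load_mnist()`.

## Evaluation conventions

Performance is the Pearson correlation between a retrieved pattern and its
ground truth, computed *per pattern across units*; an averaging-over-
patterns reading of the correlation normalization exists, but only the
per-pattern reading produces one value per sequence position, which is what
the recall curves plot. Zero-variance vectors (e.g. an all-off retrieved
state) get correlation 0 with a `zero_variance` attribute rather than an
error, since silence is a legitimate failure output. Each curve carries a
least-squares trend line and a baseline — the correlation of the retrieved
patterns with the mean ground-truth pattern — which is the score of the
trivial model that always outputs the average.

Empirical capacity is the length of the most recent contiguous block of
positions whose direct encode-decode correlation stays at or above a
threshold (default 0.9). Under graded forgetting the curve rises toward
the present, so the recent block is the natural notion; no sharp criterion
is canonical, and the threshold is an argument.

The pattern-separation summary reports the most-correlated pair in the
source space together with that same pair's correlation in the target
space. We deliberately do not report the maximum over all target-space
pairs as the headline number: over ~20,000 pairs the maximum is an
extreme-value statistic that sits well above the typical mapped
correlation, and it answers a different question than "what happened to
the worst pair".

## The theoretical capacity demonstration

With one-hot CA3 codes, `2.3 N` arbitrary patterns can be stored exactly:
the codes are orthogonal, so the weight rows addressed by different
patterns do not interact. The demonstration
(`plastic_act = "step"`, `update_bias = FALSE`) makes the two idealizations
this argument silently relies on explicit. First, the error signal must be
the step output, so that updates vanish entirely once a pair is exact;
the sigmoid error never reaches zero and keeps perturbing stored pairs.
Second, the bias update must be suspended: with `mu = 1/n` the retrieval
membrane is `w_kj + b_j`, and the bias accumulates *every* pattern's error
into an offset shared by all patterns — interference of order `eta` per
pattern that the orthogonality argument excludes. With both idealizations
in place, all `2.3 N` patterns decode exactly from their codes; with the
graded default rule they do not, which is precisely the difference between
the theoretical bound and online behavior.

## Known limitations

* The empirical one-shot capacity of the graded rule falls well short of
  the theoretical bound, and the recent-block criterion at threshold 0.9
  is demanding: the bottleneck is the CA3 &rarr; EC decoder, whose stored
  margin per pattern competes with interference that grows like the square
  root of the number of subsequent patterns. A signal-to-noise argument
  bounds the recent block at roughly `n_in / z^2` input units even in the
  most favorable (unsaturated) regime — and that regime has *no* recency
  gradient at all, so the graded-forgetting regime necessarily operates
  below it. Consequently the capacity ratio reported by the acceptance
  analysis is conservative with respect to looser thresholds: at a
  threshold near 0.75 the same curves reach back several times further.
* The intrinsic sequence is installed by supervised pre-training, not
  self-organization, and there is exactly one cyclic sequence: storing more
  material than `T_intr` positions is refused rather than distributed
  across multiple sequences.
* One pattern per timestep, fixed frame rate, no autonomous decision of
  when to store; cues must be presented in EC (or SI) coordinates.
* CA1 and novelty/familiarity signalling are not modelled.

## Problem sizes used by the test suite

The packaged tests run models at `N` between 40 and 200 with sequence
lengths up to 460 and, for properties that are statistical rather than
exact (replay improvement, relaxation tallies, DG decorrelation), average
over 3–5 seeds. These sizes were chosen as the smallest at which each
qualitative effect is stable across seeds; all headline quantities are
recomputed at the reference size `N = 200` (`N = 100` for the one-hot
demonstration, whose cost grows with `T_intr`).
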