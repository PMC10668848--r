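---
title: "Open-set herd identification: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-set herd identification: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Identifying individual animals from face images on a working farm is an
*open-set* recognition (OSR) problem: a model trained on the herd's known
individuals must both classify those individuals correctly and flag
animals it has never seen (new arrivals, untagged animals) as *unknown*.
A closed-set classifier silently assigns every novel animal to some known
identity, which is exactly the failure mode that matters for herd
monitoring and disease control. The difficulty is compounded in breeds
with uniform coat color, where individuals differ only in subtle facial
texture and markings, and by trough-side camera conditions: varying
illumination, fog, partial and overlapping faces, and widely varying head
poses and apparent sizes.

`openherd` implements a joint training objective for this setting —
an additive-margin softmax (AM-Softmax) classification head combined with
per-class *reciprocal points* under an adversarial margin constraint
(AMC) — together with the full evaluation protocol (random known/unknown
splits, openness ladder, AUROC / OSCR / CSA / macro-F1) and a procedural
synthetic herd generator so that the whole pipeline runs and is tested
without any proprietary footage.

## Model

### Feature extractor

Every image `x` is mapped to an embedding `f(x)` of dimension
`embed_dim` (default 128). The method is agnostic to the extractor: the
default is a small from-scratch CNN (four `conv 3x3 -> ReLU -> 2x2
average pool` blocks, then a linear projection), and any function
`(images, params) -> n x embed_dim` — e.g. a wrapper around an externally
pretrained network — plugs in through `backbone_spec(forward_fn = ...)`
and is accepted by training and evaluation unchanged. We deliberately
omit batch normalization: at desk scale it adds trainable state and
batch-coupling without measurable benefit, and keeping the blocks plain
makes the hand-derived backward pass easy to verify against finite
differences (which the test suite does).

At production scale this method is typically run with large pretrained
backbones (ResNet50, ViT-L) behind the same contract; shipping such
weights is out of scope here, and all bundled results use the small CNN.

### AM-Softmax head

The classification head is a cosine classifier: both the feature vector
and each class weight column are unit-normalized (`eps = 1e-12`; zero
vectors normalize to zero with a warning), logits are `s * cos(theta_c)`,
and the additive margin `m` is subtracted from the correct class only:

$$
L_{AM} = -\frac{1}{n}\sum_{i=1}^{n}
\log\frac{e^{s\,(W_{\hat c}^\top f_i - m)}}
{e^{s\,(W_{\hat c}^\top f_i - m)} + \sum_{c\neq\hat c}e^{s\,W_c^\top f_i}}.
$$

With `m = 0` this reduces exactly to softmax cross-entropy on `s`-scaled
cosine logits (a test asserts this to 1e-6). The margin tightens each
class into a narrower angular cone and widens inter-class gaps —
intra-class compactness buys room for unknowns. The defaults are
`s = 10` and `m = 0.5`; ablations over `m` in this family of losses
consistently show a broad optimum around 0.4–0.6.

### Reciprocal points and the adversarial margin constraint

Each known class `k` owns a learnable reciprocal point `P_k` (initialized
from a zero-mean Gaussian, sd 0.1) and a learnable nonnegative margin
`R_k` (initialized at 0 and clamped `>= 0` after every optimizer step —
a negative margin is meaningless). Two distances appear:

* `d_e(f, P_k)` — squared Euclidean distance divided by `embed_dim`
  (dimension-averaged so its scale is comparable across embedding sizes);
* `d(f, P_k) = d_e(f, P_k) - f \cdot P_k` — the combined distance used
  for scoring and classification.

The AMC loss is a hinge on the Euclidean part only:

$$
L_{AMC} = \frac{1}{n}\sum_i \max\bigl(d_e(f(x_i), P_{k_i}) - R_{k_i},\, 0\bigr),
$$

bounding how far a class's features may drift from its reciprocal point
and thereby bounding the open space left to unknowns.

### Why a distance cross-entropy term is part of the training objective

The reciprocal-point framework that this method builds on trains its
distance geometry with a softmax cross-entropy over the distance logits
`gamma * d(f, P_k)` — each class's features are pushed to *maximal*
combined distance from their own reciprocal point relative to the other
classes', so unknowns (far from every class) end up near *all*
reciprocal points and score low. One reading of the method replaces this
cross-entropy entirely with AM-Softmax. Implementing that reading showed
it cannot work at any scale we could test: `R_k` inflates until the AMC
hinge deactivates (within a few epochs), the reciprocal points then
receive no gradient at all, and the mandated known-ness score
`max_k d(f, P_k)` degenerates into a feature-norm statistic (AUROC
dropped from ~95 to ~73 under otherwise identical conditions). We
therefore keep the reciprocal-point framework's distance cross-entropy
(`arpl_ce_loss()`) alongside the other two terms, with AM-Softmax
replacing only the conventional softmax classifier:

$$
L = L_{AM} + \lambda_{AMC}\, L_{AMC} + \lambda_{DCE}\, L_{DCE}.
$$

`combined_loss()` defaults to `lambda_dce = 0` (the bare AM + AMC
composition, whose breakdown invariant `total = am + lambda * amc` some
callers rely on); `train_config()` defaults to `lambda_dce = 1`, which is
what every bundled experiment uses. `lambda_amc` defaults to 0.1 and
`gamma` to the value noted in the defaults section; neither weighting is
fixed by the protocol this package follows, so both are exposed in the
config.

### Decision rule and scoring

The known-ness score of a test sample is `max_k d(f(x), P_k)` — higher
means more known-like. A sample is rejected as unknown when the distance
to all reciprocal points falls below a threshold `tau`
(`decide(table, tau)`); all reported metrics are threshold-free sweeps,
so `tau` never needs to be calibrated for evaluation. Closed-set
predictions come, by default, from the AM-Softmax cosine argmax
(`predict_from = "am_head"`); the maximum-distance rule
(`predict_from = "rp_distance"`) is available because the method's two
descriptions disagree on which head classifies, and the config switch
lets users reproduce either. Ties in any argmax resolve to the lowest
class index, fixed for reproducibility.

## Evaluation protocol

* **Splits.** `make_splits()` draws `n_trials` random partitions of the
  herd into `n_known` known and the rest unknown individuals (default
  10 known / 7 unknown of a 17-head herd, 5 trials). Training sees only
  known-id images from the training day; testing uses the other days.
* **CSA** — accuracy over known test samples only.
* **AUROC** — all knowns pooled against all unknowns, rank-based
  (ties credit 0.5), invariant to monotone score transforms.
* **OSCR** — area under the curve of correct-classification rate vs
  false-positive rate swept over all observed scores;
  right-continuous step integration by default (trapezoidal via config).
  `OSCR <= CSA` always, since CCR is bounded by closed-set accuracy.
* **Closed-set report** — overall accuracy, macro F1 (the averaging
  convention is not fixed by the protocol this package follows; we use the
  unweighted class mean and say so), and confusion matrices as counts
  plus row percents.
* **Openness.** Two conventions ship because they are mutually
  inconsistent in common usage: the simple ratio
  `1 - k_train/k_test` and the classical square-root form
  `1 - sqrt(2 k_train / (k_test + k_target))`. At 1 known and 7 unknown
  individuals only the square-root form yields the quoted 64.64%.
  `sweep_openness()` reports both.
* **Aggregation** — per-metric mean and spread across trials; the spread
  is the sample standard deviation, labeled explicitly
  (`spread = "population"` available), because "mean and variance"
  reporting at ±0.02 scale against ~90-point scores is ambiguous.

## Synthetic herd generator

The generator emulates the *structure* of trough-side CCTV herd data, not
its photometric realism:

* **Identity.** Each animal is a latent parameter vector: a two-component
  oriented sinusoid "coat texture" plus six elliptical markings with
  identity-specific positions, shapes and contrasts, all drawn as
  `population mean + sigma_id * scale * N(0,1)`. `sigma_id` is the
  inter-individual similarity dial: 0 makes the herd pixel-identical,
  larger values disperse it (a nearest-centroid pixel classifier's
  accuracy rises monotonically with `sigma_id`; tested). The marking
  count is configurable and fixed at 6 across identities so parameter
  vectors are commensurable and `sigma_id = 0` collapses exactly.
* **Nuisance.** In-plane rotation, multiplicative illumination, fog
  (Gaussian blur plus additive white haze), partially captured faces
  (off-center zoomed crops), rectangular occluders, apparent head size,
  and pixel noise — the qualitative factor list of real trough footage.
  Magnitudes of these factors are not quantified anywhere; the
  defaults (±20°, 0.75–1.25x brightness, fog up to 0.25, 8% crop/occlusion
  probability, 0.85–1.15x scale, 0.02 noise sd) were fixed once as a
  plausible emulation and are not tuned per experiment.
* **Bookkeeping.** Images are written as 8-bit PNGs with a CSV manifest
  (`image_path,individual_id,day,session`); sessions default to
  morning/noon/night and, by default, do not shift the image distribution
  (feeding times are merged within a day in the protocol we follow); an
  optional per-session illumination shift emulates time-of-day. Grayscale
  is the default because a single-color breed carries little identity
  signal in color; RGB output is available.

What passing tests on this generator do **not** show: robustness to real
photometric variation, to detection/cropping errors, or to the long-tail
pose distribution of live animals. The generator's role is to make the
method's *mechanics* — losses, geometry, protocol, metrics — fully
testable and reproducible.

## Defaults and problem sizes

Desk-scale defaults, all overridable in the YAML config:

| parameter | default | note |
|---|---|---|
| image size | 64 px | 224 px available; all bundled runs use 64 |
| `embed_dim` | 128 | not stated in the source protocol; package choice |
| `s`, `m` | 10, 0.5 | as stated in the protocol |
| batch size | 32 | as stated |
| optimizer | Adam, lr 2e-3 | the protocol's 1e-4 is a fine-tuning rate
for large pretrained backbones; a small CNN trained from scratch for tens
of epochs needs a larger step. 1e-4 remains available in the config |
| `lambda_amc` | 0.1 | unprinted; exposed |
| `lambda_dce` | 1 (training) | see the distance cross-entropy section |
| `gamma` | 3 | unprinted; larger temperatures sharpen the distance
softmax and measurably improve unknown separation on the synthetic herd |
| epochs | 40 (default), 20 in bundled checks | |
| augmentation | `"light"` | brightness/shift/noise jitter; `"strong"`
(zoom crops, occluders) trades unknown rejection for closed-set
robustness; `"none"` disables |
| herd | 17 ids, 8 images/session, 3 sessions, 2 days | 240 training
images at 10 known ids; one day trains, the other tests |

The bundled verification runs train on one day and test on the held-out
day: 17 identities at `sigma_id = 2.0`, 10 known / 7 unknown, 20 epochs.
This sizing keeps a full multi-trial experiment in minutes on one CPU
while leaving enough signal to demonstrate parameter recovery
(CSA ≥ 95%, AUROC ≥ 90% on the majority of trials).

## Numerical choices

* Normalization epsilon 1e-12 for features and weight columns; zero
  vectors normalize to zero with a warning rather than erroring.
* All softmaxes are computed with max-subtraction for stability.
* Adam (beta1 0.9, beta2 0.999, eps 1e-8); `R` clamped to `[0, Inf)`
  after each step.
* He-scaled Gaussian initialization for conv weights, fan-in scaling for
  the projection and head; reciprocal points `N(0, 0.1^2)`.
* Every random draw flows from one user seed expanded per purpose by a
  fixed mixing function (`derive_seed`), so datasets are byte-identical
  and training runs bit-identical under a repeated seed.
* AMC subgradient at the hinge is 0 (the `>` convention), so the loss,
  its gradient, and the "all samples inside their margins" state are
  mutually consistent.

## Known limitations

* The small CNN underfits herds with very low `sigma_id` (strongly
  look-alike animals) at desk scale; the production-scale remedy — pretrained
  backbones — is supported via `forward_fn` but no weights ship.
* Openness-ladder runs at low known counts (1–2 individuals) are noisy:
  with one known class the AM-Softmax term is degenerate
  (single-class softmax) and only the distance terms train.
* The generator's nuisance model is qualitative; none of its magnitudes
  are calibrated to measured farm footage.
* Only whole-image labels are synthesized — no detection boxes, no video.
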