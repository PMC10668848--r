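# openherd

Open-set recognition for individual livestock identification from face
images, in R.

On a working farm, a face-recognition model trained on the current herd
will be shown animals it has never seen — new arrivals, untagged animals,
neighbours' stock. A closed-set classifier silently labels every such
animal as one of the knowns; for herd monitoring and disease control that
is the worst possible failure. `openherd` implements an *open-set*
identification method: it classifies the known individuals **and**
rejects unknown ones, and it ships the full evaluation protocol and a
synthetic herd generator so everything runs end-to-end with no
proprietary footage.

## The method

Each image `x` passes through a feature extractor `f` (a small trainable
CNN by default; any pretrained extractor plugs in behind the same
contract). Three jointly trained components shape the embedding space:

* **AM-Softmax head** — cosine classifier with an additive margin on the
  correct class:

  `L_AM = -1/n Σ log [ e^{s(W_ĉᵀfᵢ − m)} / (e^{s(W_ĉᵀfᵢ − m)} + Σ_{c≠ĉ} e^{s W_cᵀfᵢ}) ]`

  with `s = 10`, `m = 0.5`. Features and weight columns are
  unit-normalized; the margin compacts each identity into a narrow
  angular cone.

* **Reciprocal points + adversarial margin constraint (AMC)** — every
  known class `k` owns a learnable point `P_k` and margin `R_k ≥ 0`;
  the hinge `L_AMC = mean( max(d_e(f, P_k) − R_k, 0) )` (with `d_e` the
  dimension-averaged squared Euclidean distance) bounds how much open
  space the class may claim.

* **Distance cross-entropy** — softmax cross-entropy over the combined
  distances `d(f, P_k) = d_e(f, P_k) − f·P_k`, which trains the distance
  geometry that open-set scoring relies on (see the methods vignette for
  why this term is kept).

At test time the **known-ness score** of a sample is
`max_k d(f(x), P_k)`; a sample whose distance to all reciprocal points
falls below a threshold τ is rejected as *unknown*, and threshold-free
metrics sweep τ over all observed scores:

* **CSA** — closed-set accuracy over known test samples,
* **AUROC** — rank-based known-vs-unknown separation,
* **OSCR** — area under correct-classification rate vs false-positive
  rate,
* **openness** — both the ratio (`1 − k_train/k_test`) and square-root
  (`1 − √(2 k_train/(k_test + k_target))`) conventions.

## Worked example

Generate a synthetic 17-head herd, train on 10 known individuals on
day 1, and evaluate open-set recognition on the held-out day:

```r
library(openherd)

ids <- make_identities(17, sigma_id = 2.0, seed = 101)
manifest <- generate_dataset(ids, per_id_per_session = 8,
                             nuisance = nuisance_config(),
                             out_dir = "herd_data", seed = 202, days = 1:2)

splits <- make_splits(sort(unique(manifest$individual_id)),
                      n_known = 10, n_trials = 5, seed = 7)
model <- train(manifest, splits[1, ],
               config = train_config(epochs = 20, seed = splits$seed[1]))
scores <- score_test_set(model, manifest)
metric_report(scores)
#> # A tibble: 1 × 3
#>     csa auroc  oscr
#>   <dbl> <dbl> <dbl>
#> 1  97.5  94.2  92.5
```

`csa` is the percent of known-individual test images classified to the
right animal; `auroc` the percent probability that a random known image
outscores a random unknown one; `oscr` the area (percent) under the
correct-classification vs false-acceptance curve — the single number
that penalizes both misclassifying knowns and accepting unknowns.
`decide(scores, tau)` applies a concrete rejection threshold;
`autoplot(scores)` shows the known/unknown score densities;
`run_experiment()` drives the whole multi-trial protocol from one YAML
config, and `sweep_openness()` reproduces the openness ladder
(7 unknowns fixed, knowns from 10 down to 1).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/openherd run --config cfg.yaml --out run_dir
```

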