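---
title: "Methodology: outcome-supervised MIL risk scoring for prostate TMAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: outcome-supervised MIL risk scoring for prostate TMAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the method implemented by `pcai`, every
calibrated parameter with its rationale, the scope of the synthetic
emulation, and the known limitations. The README shows a worked
end-to-end example; here the focus is on *why* each piece looks the way
it does.

## 1. Labels from outcomes

The endpoint is the composite **bad outcome** — biochemical recurrence
(BCR), metastasis, or cancer-specific death, whichever comes first;
event-free cases are right-censored at last follow-up
(`derive_bad_outcome()`). Binary risk labels are then derived with two
horizons (`assign_risk_label()`):

* **high**: bad outcome within 3 years (boundary `<= 3`), or — in
  training mode only — local spread at surgery (any of pN, pV, pL);
* **low**: event-free over more than 5 years (`> 5`) and, in training
  mode, all *present* spread flags `FALSE` with at least one present
  (a missing flag cannot assert absence of spread);
* **undefined** otherwise: excluded from direct supervision, but such
  cases still matter — they are the pseudo-labeling candidate pool and
  they count in the survival analyses.

Test mode drops the spread clauses so that the evaluation label depends
only on observed outcome. The asymmetry is deliberate: spread flags are
a surgical finding that strengthens a weak training label, but using
them at test time would leak a non-imaging variable into the target.

## 2. Preprocessing and instances

Spot images are mapped to optical density, `-log(max(v, 1e-3))` with
the natural log, so pixel values are proportional to stain quantity;
the `1e-3` floor caps the OD at ~6.91 and keeps the transform finite on
black pixels (`od_transform()`). Each spot is then standardized
per channel to zero mean and unit SD over its tissue pixels
(`normalize_od()`). This removes additive per-spot and per-channel
staining differences — which is exactly why the remaining, *channel
mixing* differences (hue) matter for the confound analysis in section 5.

Instances are non-overlapping `patch_px` tiles laid on the resampled
spot with a random per-axis offset; tiles under 25% tissue are dropped
(`make_instances()`). The offset is drawn uniformly but truncated so a
spot that can hold a patch always yields at least one tile — a bag must
not be empty for an assessable spot. Three magnification contexts form
the ensemble: scale 1.0 (nuclear detail), 0.25 (glandular
architecture), 0.5 with a larger patch (both); their probabilities
combine linearly with weights 0.25/0.25/0.5 (`pcai_ensemble()`).
Color augmentation perturbs brightness ±2%, contrast ±5%, saturation
±20% and hue ±5% in that order (`augment_color()`), and the 8 dihedral
variants of a patch are available exactly once each
(`dihedral_variant()`).

## 3. The MIL model

No tensor backend is available to this package, so the model is
implemented natively in R with sizes chosen for CPU tractability:

* a **frozen random convolutional encoder** (two 3x3 convolution +
  mish + pooling stages, mean+max global pooling; weights drawn once
  from `model_spec()$seed` and never trained). Random convolutional
  features are a standard cheap featurizer; freezing them makes
  training a small convex-ish head problem and keeps every experiment
  deterministic given its seeds.
* a **trainable attention head** (one hidden layer, mish, batchnorm):
  one logit per instance, softmax into weights that sum to one; the
  bag embedding is the attention-weighted sum of instance features.
  The bag output is invariant to instance order by construction.
* a **trainable decoder** (two hidden layers, mish, batchnorm,
  2-class softmax).

Gradients for both heads, including the batchnorm backward pass, are
hand-derived and verified against numerical differentiation in the
test suite; optimization is Adam at learning rate `1e-3`, batch size 8.
A training epoch refuses to proceed if its draft contains a single
class, rather than silently fitting a constant.

Default head sizes (`model_spec()`: attention 16, decoder 32/16,
feature width 32) are deliberately small: the synthetic worlds plant a
strong morphological signal (section 4), so the scientific content is
in the *procedure* — curation, drafting, ensembling, evaluation — not
in representational capacity.

## 4. The synthetic TMA world

`simulate_world()` emulates just enough of a TMA cohort for every
downstream stage to be testable:

* **Latent risk** per case, `u ~ Beta(m * c, (1 - m) * c)` with TMA
  mean `m` and concentration `c = 0.8`. The small concentration makes
  the population bimodal (clearly-low/clearly-high), which is what
  gives a planted-statistic threshold its discriminative headroom.
* **Survival**: `T ~ Exponential(lambda0 * exp(beta * u))` with
  `beta = 5`, censoring `C ~ Uniform(0, 10)` years, follow-up `= C`,
  event iff `T <= C`. `lambda0` is calibrated by root-finding so the
  mean event probability equals the target prevalence **0.237**
  (`calibrate_base_rate()`). The `beta`/concentration pair was
  calibrated once against the generator's own invariant — a threshold
  on the planted statistic must reach AUC > 0.95 on a
  strong-morphology, confound-free world — *before* any model results
  were inspected; weaker values produced a world that violated its own
  learnability bound.
* **Morphology**: nuclei-like dark blobs on an eosin-pink disc; blob
  count `60 * (1 + effect * (2u - 1))` at 192 px, so
  `morphology_effect` scales how visibly risk is planted. The
  **planted statistic** — fraction of tissue pixels with mean OD
  above 0.6 — is the independent oracle for what any image model can
  see (`planted_stat()`).
* **Confounds** (all per-TMA, all optional): an additive channel stain
  shift (removed by OD standardization, and shipped precisely to show
  that); a **hue rotation** (`tma_hue`) that mixes channels and
  therefore *survives* standardization; pale fold **artifacts**
  (`tma_artifact`); a section-thickness **noise multiplier**
  (`tma_thickness`). With `stain_follows_risk = FALSE` each TMA gets a
  random signature, uncorrelated with risk.
* **Label noise**: with `unrepresentative_rate`, a spot is rendered
  from `1 - u` while keeping its case's label — the unrepresentative
  spot a 0.6 mm core can be.

Problem sizes are the package's own choice for CPU-scale experiments:
192 px spots, 8 TMAs x 25 cases by default, one spot per case. They are
not claims about real cohort sizes.

## 5. Curation, drafting, and the ablation

Two-stage training (`two_stage_train()`): a stage-1 model fits the raw
TMA-balanced draft; its predictions **denoise** the training set —
discard iff the predicted probability of the sample's own label falls
below 0.1 (a configurable quantification of "confidently
contradicted") — and **pseudo-labeling** adds event-free short-follow-up
cases per TMA as lows, longest follow-up first, until balance or
depletion, ties broken by case id. Denoising never relabels;
pseudo-labeling only adds lows. Stage 2 trains on the curated set.
The test split is fixed before any curation and never pseudo-labeled;
test-set denoising is computed but always reported alongside the raw
metric, since cleaning the test set with one's own model cannot give an
unbiased estimate.

**Epoch drafting**: `tma_balanced_draft()` takes
`k = min(#high, #low)` per TMA per class each epoch, so within every
TMA the signature carries zero label information in expectation.
`global_balanced_draft()` balances classes only globally and is the
ablation baseline.

The **sampling ablation** (`ablation_arms()`) compares three arms with
shared world, split, features and stage-1 model: global drafting,
TMA-balanced drafting, TMA-balanced + curated. Its canonical study
conditions, `confounded_world_config()`, were designed
mechanism-first:

* TMAs differ strongly in outcome mix (`tma_risk_spread = 0.45`) while
  carrying *random* handling signatures (hue 0.08, artifacts 10,
  thickness 0.6) — so within the training set, recognising a TMA's
  signature predicts its majority label;
* evaluation holds out whole TMA blocks (`split_by = "tma"`), so a
  memorized signature transfers at chance while genuine morphology
  transfers fully (the same reason real studies withhold entire TMA
  blocks);
* `unrepresentative_rate = 0.2` caps how well morphology can explain
  the training labels, letting the trivially separable signature (a
  linear probe reads the hue fingerprint from the frozen-encoder
  features at R² = 0.99) compete for the optimizer's attention;
  morphology is moderate (`morphology_effect = 0.5`).

Over nine consecutive seeds the held-out AUC medians order
global 0.654 ≤ TMA-balanced 0.684 ≤ TMA-balanced + curated 0.730.
The ordering is directional — run-to-run spread of a single seed is
larger than the arm gaps, which is why the experiment is defined as a
median over seeds.

## 6. Evaluation suite

* **AUC**: rank-based with half credit for ties; equal by construction
  to the concordant-pair fraction (tested exhaustively). Bootstrap CIs
  resample at case level (1000 iterations, percentile).
* **Paired comparison**: permutation test swapping the two predictors'
  scores per sample, two-sided, `+1`-smoothed p-value.
* **Weighted kappa**: linear block-distance weights
  `|i - j| / (k - 1)`, `kappa = 1 - sum(w O) / sum(w E)`.
* **Case aggregation**: max over assessable spots; unassessable spots
  are excluded with a message, never imputed.
* **Survival**: Kaplan-Meier per binned score (7 equal-width bins on
  [0, 1], right-closed) via `survival::survfit`; Cox proportional
  hazards via `survival::coxph`, hazard ratio reported per 0.1 score
  units, optionally age/PSA-adjusted. Build-vs-buy: the survival
  machinery is delegated to the `survival` package and cross-checked
  against hand oracles; the rank statistics and kappa are implemented
  here (block-distance-weighted kappa is not available in the installed
  libraries) and cross-checked against `pROC` where possible.

## 7. Limitations

* The encoder is frozen and random; absolute AUCs on real histology
  would require a trained deep backbone. All experiments here are
  therefore *relative* statements on synthetic worlds with planted
  effects, plus exact recomputations of published table statistics.
* The synthetic world plants one morphological axis (nuclei density);
  real Gleason patterns are far richer, so the generator can validate
  procedure, not pathology.
* Pseudo-labeled lows are only *likely* lows: at high TMA risk spread
  their purity drops (~75% in the canonical confounded world), which
  is part of why the curated arm's advantage is directional rather
  than large.
* Test-set "cleaned" metrics are intrinsically optimistic and are only
  ever reported next to the raw ones.
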