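# interdrug

Multimodal graph attention models for drug–drug interaction (DDI)
prediction, with a structured regularization suite and a fully synthetic,
planted-signal evaluation harness.

## The problem

Predicting whether two drugs interact is a central task in pharmacovigilance
and polypharmacy safety. Each drug is described by several feature
*modalities* (structural fingerprints, adverse-effect profiles, expression
signatures, …), by categorical pharmacological *contexts* (therapeutic
classes, ATC-like codes) and by co-prescription counts; the interaction
itself is an undirected binary label on a drug pair. `interdrug` learns one
embedding per drug from all of these sources jointly and scores pairs with a
symmetric cross-attention head.

## The model

Per-modality kernel similarities S⁽ᵐ⁾ are fused convexly,
S^fused = Σₘ λₘ S⁽ᵐ⁾ with trainable simplex weights λ (softmax
parameterization), and sparsified into a relational drug graph (kNN or
thresholding). Drug embeddings come from graph-attention propagation with
residuals, row normalization and multi-hop aggregation Z = Σₖ γₖ H⁽ᵏ⁾.
Training jointly minimizes

* L_ctr + λ₁·L_sim + λ₂·L_sup — triplet contrastive alignment, cosine
  reconstruction of the fused similarity (the gradient path into λ), and the
  supervised task loss (pair-level BCE plus per-drug class cross-entropy);
* α₁·L_ctx + α₂·L_lap + α₃·L_co + α₄·L_mmd + α₅·L_rank + α₆·L_ent — context
  co-membership alignment (trace form 2·tr(ZᵀLₚZ)), Laplacian smoothness on
  the unified topology G = Σₘ S⁽ᵐ⁾ + Σₚ Rₚ, KL calibration against
  co-prescription probabilities with confidence prior ρ = min(1, ln(1+O)),
  Gaussian-kernel MMD across per-modality embedding views, margin ranking,
  and an entropy confidence regularizer.

All gradients are hand-derived and analytic (no autodiff); the complete
training gradient is verified against central finite differences in the test
suite. An ablation harness reproduces the three module-removal variants
(`no_msi`, `no_gbap`, `no_cmrg`) and a reduced-training-data robustness
sweep. Because no external benchmark is bundled, a synthetic cohort
generator plants a known cluster structure (one informative modality,
correlated contexts, elevated within-cluster co-prescription, noisy
within-cluster pair labels) so that fusion-weight recovery and predictive
floors are verifiable. See `vignettes/methods.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(interdrug)

cohort <- generate_cohort(n_drugs = 120, n_modalities = 4, n_clusters = 3,
                          seed = 42)
cohort
#> Synthetic drug cohort: 120 drugs, 4 modalities, 3 clusters
#>   pair labels: 4944 pairs ( 2472 positive )

cfg <- train_config(hidden_dim = 32, n_heads = 2, gnn_layers = 2,
                    learning_rate = 0.02, batch_size = 2048,
                    steps_per_epoch = 1, max_epochs = 40,
                    early_stop_patience = 10, seed = 1)
model <- train_ddi(cohort, cfg)
model
#> Trained DDI model: 120 drugs, 4 modalities; best epoch 16
#>   fusion weights: 0.366 0.211 0.211 0.211

evaluate_model(model)
#> $accuracy 0.929  $recall 0.895  $f1 0.927  $roc_auc 0.932  $pr_auc 0.94
```

The learned fusion weight is maximal on modality 1 — the modality the
generator made informative — and the held-out ROC-AUC of 0.93 approaches the
ceiling of ≈0.95 implied by the 5% label noise. Attention maps for any pair
are available with `attention_report(model, "D0001", "D0002")` and export to
three-column text via `write_attention_map()`.

## Command line

```sh
Rscript inst/cli/interdrug.R simulate --n-drugs 200 --seed 1 --out-dir data/
Rscript inst/cli/interdrug.R build-graph --in-dir data/ --out-dir graph/ --knn-k 10
Rscript inst/cli/interdrug.R train --in-dir data/ --out-dir run/ --seed 1
Rscript inst/cli/interdrug.R evaluate --predictions run/predictions_test.tsv --out run/metrics2.tsv
Rscript inst/cli/interdrug.R predict --model run/model.rds --pairs pairs.tsv --out-dir scores/ --attention
```

Every command writes a `manifest.json` (config snapshot, input digests,
seed, version) next to its outputs; identical inputs and seed reproduce a
run exactly.

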