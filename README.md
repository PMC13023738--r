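# smccanet

Sparse multi-view canonical correlation and population-graph classification
for multimodal biomarker studies.

## What this package is for

Cohorts in imaging-transcriptomics measure every subject in several
modalities at once — structural-imaging region volumes, PET regional uptake
ratios, and gene expression.  Analysts face two linked problems: finding the
small sets of features that co-vary *across* modalities (candidate
biomarkers), and classifying a rare diagnosis class against a much larger
prodromal class without fooling themselves under extreme class imbalance.
`smccanet` implements a two-stage answer:

**Stage I — adaptive sparse multi-view CCA.**  Per-view weight vectors
`w_k` are fitted so the canonical variates `X_k w_k` agree across view
pairs, under the scale convention `‖X_k w_k‖₂ = 1` and a composite penalty
`λ_k [β ‖w_k‖_FGL + (1−β) ‖w_k‖₁]` (fused-group + lasso).  Two loss
variants are provided:

* `fit_radasmcca()` — robust: minimises the **un-squared** pairwise
  distance `Σ_{i<j} ‖X_i w_i − X_j w_j‖₂` by IRLS, damping gradient
  dominance by strongly correlated pairs;
* `fit_unadasmcca()` — uncertainty-weighted: minimises
  `Σ_{i<j} d_ij²/(2σ_ij²) + log σ_ij`, with the closed-form update
  `σ_ij = d_ij` down-weighting poorly matched pairs.

Model and λ selection use internal five-fold cross-validation on the mean
canonical correlation (`select_model()`); features are ranked by `|w|`
(`rank_features()`).  A training-only moderated differential-expression
gate (`fit_gene_models()`, `moderate_variances()`, `select_degs()`) screens
the gene view with the strict rule `p < 0.05` and `|logFC| > 0.5`.

**Stage II — population-graph classifier.**  Selected features define a
cosine-similarity kNN subject graph (self-loops, symmetric normalisation
`D^{-1/2}(A+I)D^{-1/2}`); a per-view graph-convolution encoder with
feature-wise self-expression (`H ← HC`) and scaled dot-product
self-attention feeds a linear head; views are trained jointly with Adam and
fused by mean softmax probability.  Held-out subjects are attached to the
trained graph post hoc — they are never seen during training.

Around the two stages: a synthetic multimodal generator
(`generate_multimodal()`), a leakage-guarded repeated stratified
cross-validation harness (`run_rscv()`, `stratified_split()`,
`make_folds()`, `auc()`, `bootstrap_ci()`, `wilcoxon_signed_rank()`), an
ablation runner (`run_ablation()`), and an unsupervised subtyping pipeline
(`subtype_analysis()`: validity indices, consensus clustering, clinical
contrasts, conversion cross-tabulation).

## Worked example

```r
library(smccanet)
ds <- generate_multimodal(sim_config(n_subjects = 160, dims = c(30L, 25L, 120L),
                                     support_size = 6L, class_fraction = 0.15,
                                     class_effect = 1.2, seed = 42))
ds
#> multimodal_dataset: 160 subjects, 3 view(s)
#>   smri   30 features
#>   pet    25 features
#>   gene   120 features
#>   positives: 24 / 160

model <- fit_radasmcca(ds, penalty_config(lambdas = 0.1, beta = 0.5))
pairwise_ccc(ds, model)
#> $pairwise
#>  smri:pet smri:gene  pet:gene
#> 0.9701705 0.9876120 0.9878455
#>
#> $mean_ccc
#> [1] 0.981876
```

The three canonical variates correlate at ~0.97–0.99: the solver has found
the shared latent factor.  The ranking puts the planted signal features
(columns 1–6 of each view) on top:

```r
head(rank_features(model, ratio = 0.2)$per_view$smri, 3)
#>     feature      weight abs_weight index
#> 1 smri_f006  0.02464237 0.02464237     6
#> 2 smri_f005 -0.01894796 0.01894796     5
#> 3 smri_f003 -0.01742188 0.01742188     3
```

End-to-end cross-validated classification (Stage I + graphs + classifier
refitted inside every fold, validation folds attached post hoc):

```r
sp  <- stratified_split(ds$labels, 0.2, seed = 1)
dev <- subset_subjects(ds, sp$dev_indices)
run_rscv(dev, pipeline_config(model = model_config(epochs = 30L),
                              graph = graph_config(8L)),
         repeats = 2, folds = 4, seed = 1)
#> cv_result: 2 x 4 = 8 iterations
#>     model  mean_auc     sd_auc  ci_lower ci_upper
#>  pipeline 0.9884921 0.01272594 0.9796214 0.995835
```

A mean AUC of 0.99 with a tight fold-level bootstrap interval: on this
easy synthetic world the pipeline separates the rare positives almost
perfectly; permuting labels drives it to ~0.5 (see the acceptance tests).

## Command line

```sh
Rscript inst/cli/smccanet.R simulate --n 323 --seed 1 --out data/
Rscript inst/cli/smccanet.R deg --expr data/gene.tsv --pheno data/pheno.tsv \
        --p 0.05 --lfc 0.5 --out degs.json
Rscript inst/cli/smccanet.R associate --views data/smri.tsv data/pet.tsv \
        data/gene.tsv --pheno data/pheno.tsv --grid 0.01,0.1,1,10 \
        --folds 5 --out model.json
```

## Documentation

The methods vignette
(`vignettes/two-stage-multimodal-pipeline.Rmd`) explains the models, the
numerical choices (scale constraint, monotone safeguard, fused-group
majorization, floors), what the synthetic generator does and does not
emulate, and known limitations.
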