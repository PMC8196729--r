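# omisurv

Two-arm multiomics subtyping of cancer recurrence risk, with a downstream
prognostic risk-score panel. The package targets the common clinical-genomics
setting where gene expression, CpG methylation and miRNA expression are
measured on the same patients together with a right-censored time to
recurrence, and the question is: *do the omics layers jointly define patient
subgroups with different recurrence hazards, and can those subgroups be
distilled into a small portable biomarker panel?*

It is written for biostatisticians and computational biologists; everything
is callable from R, and the `analysis/` scripts run the whole study workflow
on a bundled synthetic cohort with known ground truth.

## The method

Two independent arms derive two-group subtypes from three omics blocks
(each filtered, per-feature z-scored, sample-aligned):

* **Similarity network fusion.** Squared-Euclidean distances per block feed
  a self-tuning Gaussian kernel `W(i,j) = exp(-d(i,j) / (sigma * eps_ij))`,
  `eps_ij = (mean_i + mean_j + d_ij)/3` over K-nearest-neighbor distances
  (K = 20, sigma = 0.5). T = 20 cross-diffusion iterations
  `P_v <- S_v * mean(P_-v) * S_v^T` fuse the per-omics graphs; spectral
  clustering of the fused graph (cluster number by Laplacian eigen-gap, with
  a rotation-cost heuristic reported alongside) yields the subgroups.
* **Autoencoder latent features.** The blocks are stacked (n x 2300 for the
  preset cohort) and compressed through a 500-200-500 tanh autoencoder
  trained by plain SGD; the 200 bottleneck activations are new features.
  Nodes with univariate Cox p < 0.05 against time-to-recurrence are
  clustered by silhouette-selected k-means.

Each arm's subgroups are aligned to high/low risk by Kaplan-Meier median
survival and compared by log-rank test and Harrell's C-index. Wilcoxon
rank-sum tests rank features between subgroups; the top 100/100/50
(expression / methylation / miRNA) lists of the two arms are intersected
with a direction-concordance check. The two most significant intersected
features per omics (six in all) enter a multivariate Cox fit defining the
risk score `sum_i beta_i * x_i`, dichotomized at a maximally selected
log-rank cutpoint and evaluated by KM curves, log-rank, C-index and the
5-year cumulative/dynamic AUC (IPCW, Kaplan-Meier censoring weights). An
RBF-SVM under stratified 5-fold x 10-repetition cross-validation checks how
well the subtype labels transfer to held-out samples.

A synthetic-cohort generator with planted subgroup structure (Bernoulli
high-risk indicator, mean-shifted informative features, exponential
proportional-hazards recurrence times, independent censoring,
subgroup-tilted clinical covariates) makes every stage testable against
known truth; `prad_preset()` emulates a 494-sample cohort with exactly 60
recurrence events.

## Worked example

The numbered drivers under `analysis/` run the study workflow on the preset
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # build + write the 494-sample cohort
Rscript analysis/02_preprocess.R   # filter, z-score, stack (494 x 2300)
Rscript analysis/03_subtyping.R    # both arms + DE + intersection
Rscript analysis/04_classifier.R   # SVM label-transfer CV
Rscript analysis/05_panel.R        # risk panel + evaluation
```

`analysis/03_subtyping.R` prints:

```
[snf] high-risk n = 111; log-rank chi2 = 60.50 (p = 7.36e-15); C-index = 0.696
[ae] high-risk n = 111; log-rank chi2 = 60.50 (p = 7.36e-15); C-index = 0.696
SNF cluster-number estimates: eigen-gap 2, rotation cost 2
AE: 51 of 200 bottleneck nodes pass the Cox screen; silhouette-optimal k = 2
cross-arm intersection: 250 features (250 concordant directions)
```

Both arms find the planted two-subgroup structure (the preset plants a
high-risk prevalence of 0.22, i.e. ~109 of 494 samples; both arms tag 111),
the eigen-gap correctly says k = 2, and the two arms' top-250 feature lists
agree almost completely with identical regulation directions — expected,
since both arms recovered essentially the same subgroups.

`analysis/05_panel.R` then prints:

```
panel features: gene_0448, gene_0343, cg00000587, cg00000332, mir_204
risk-score cutoff: 0.3464 (high-risk n = 130)
panel alone:      C-index 0.691 | log-rank p 9.89e-13 | 5-year AUC 0.777
panel + clinical: C-index 0.690 | log-rank p 9.18e-15 | 5-year AUC 0.792
```

Here the six candidate features reduce to five after the univariate Cox
pre-screen (one miRNA misses p < 0.05); the fitted score separates the
cohort into 130 high- vs 364 low-risk samples whose recurrence curves differ
at p ~ 1e-13 — with the standing caveat, printed by the script, that a
maximally selected cutpoint inflates this p-value. The 5-year AUC of ~0.78
means: for a random (case by 60 months, censoring-weighted) / (still at risk
past 60 months) pair, the score ranks the case higher ~78% of the time.

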