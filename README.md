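# progsig

Discovery and application of **progression gene signatures (PGSs)** for
solid tumours, in R.

Expression-only prognostic signatures travel badly between cohorts.
`progsig` implements a pipeline that anchors biomarker discovery in gene
*function*: candidate genes must be ubiquitously and highly expressed in the
tumour cohort **and** essential for cancer-cell survival in shRNA depletion
screens before they are allowed to compete for association with
tumour-progression incidence. The surviving genes form a PGS, and a trained
scoring model maps a sample's signature expression to a progression
probability reported on a −50..+50 risk score.

## The method in brief

1. **Candidate pool** — rank genes by a robust ubiquity statistic (per-gene
   5th percentile of log2 expression across samples) and cut at a
   percentile (99th percentile of a ~20,000-gene universe → 200 genes);
   optionally refine the pool size by the BIC of the downstream model.
2. **Survival genes** — from shRNA screens, compute each gene's two-stage
   mean log2 fold change (shRNAs within cell line, then across cell
   lines); call genes with mean FC < 0, significance confirmed by
   one-tailed per-shRNA t-tests, Fisher's combined probability
   (χ² = −2Σ ln pᵢ on 2k df) and Benjamini–Hochberg FDR.
3. **Signature assembly** — backward stepwise logistic regression of the
   binary progression indicator on z-scored survival-gene expression,
   removing the worst covariate while its Wald p ≥ 0.25.
4. **Risk model** — PCA over the signature genes (one PC per gene), PC
   screening by a 1000-tree random forest at a percent-contribution cutoff
   of 0.05, iterated until the forest retains all PCs; then gradient
   boosting of 3-tanh-unit networks (100 stages, learning rate 0.1) with
   tenfold cross-validation. Probability p becomes the risk score
   100·(p − 0.5) ∈ [−50, 50]; score > 0 ⇒ high-risk.
5. **Evaluation** — ROC/AUC (Mann–Whitney), paired DeLong curve
   comparisons against baseline biomarkers, confusion matrices with
   Fisher's exact test, Kaplan–Meier/log-rank, Cox proportional hazards,
   treatment-benefit and hypoxia contrasts.

A synthetic-cohort generator (`simulateCohort()`) produces expression,
clinical and screen data in which a single latent risk factor drives
planted-gene expression, progression and survival simultaneously, so the
entire pipeline is testable at desk scale with no downloads. Validation
utilities cover outcome recoding for external cohorts, stratified
train/validation splitting, training-parameter replay vs cohort-internal
z-scoring, and qPCR ΔCt panels (ΔCt = Ct(reference) − Ct(gene)).

## Worked example

```r
library(progsig)

cfg    <- simulationConfig(nSamples = 200, nGenes = 500, nPlanted = 10,
                           nCellLines = 8, seed = 42)
cohort <- simulateCohort(cfg)
run    <- runPipeline(cohort@experiment, cohort@screen, percentile = 98,
                      seed = 42, label = "demo")
print(run)
print(run$report)
head(run$scores, 4)
```

```
PgsRun 'demo'
  pool: 10 genes | survival genes: 10 | signature: 5 genes
  out-of-fold AUC: 0.6682
EvaluationReport
  confusion (group x progressed):
      progressed
group    0   1
  low   76   5
  high  15 104
  Fisher exact p: 2.65e-33
  KM median DFS: low = 31.7, high = 12.6 | log-rank p: 0.000912
  hypoxia Welch t p: 2.88e-05
      sample_id probability     score group
S0001     S0001   0.6049160 10.491604  high
S0002     S0002   0.7631676 26.316765  high
S0003     S0003   0.5442354  4.423537  high
S0004     S0004   0.5240791  2.407910  high
```

Reading the output: the 98th-percentile ubiquity cut of this 500-gene toy
cohort keeps 10 genes; all 10 deplete in the screen (mean FC < 0) and the
stepwise stage retains 5 of them (here, 5 of the 10 planted genes). The
honest (out-of-fold) AUC for progression is 0.67 on this small cohort;
risk groups split 81/119 with progression strongly concentrated in the
high-risk group (Fisher p ≈ 3e-33), a median DFS of 12.6 vs 31.7 months
(log-rank p ≈ 9e-4), and higher hypoxia scores among high-risk patients.
Each sample's score is 100·(probability − 0.5), so S0002 at p = 0.763
scores +26.3 and is called high-risk.

Model persistence: `writeRiskModel()` / `readRiskModel()` serialize the
whole scoring pipeline (gene normalization, PCA stack, selected PCs,
boosted ensemble) to JSON at full precision; a reloaded model reproduces
scores to 1e-10.

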