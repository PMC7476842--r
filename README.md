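# rpskit

Response-probability scores (RPS) for predicting pathologic complete
response to neoadjuvant chemotherapy from pretreatment gene expression.

## The problem

Neoadjuvant chemotherapy (NCT) helps only the minority of breast-cancer
patients who reach a pathologic complete response (pCR); the rest are left
with residual disease (RD) and the side effects. In triple-negative breast
cancer (TNBC) there is no established expression-based predictor of NCT
response. rpskit is for computational biologists who want to build such
predictors from labelled pretreatment cohorts: rather than a small fixed
gene panel, it weights *every* gene by its discriminative evidence and
scores each new sample with a rank-based single-sample statistic.

## The method

1. **Signature construction.** Per gene *i*, fit
   `logit P(pCR) = β₀ + β₁·xᵢ` on the training cohort. The raw weight
   `−log₁₀ pᵢ` goes to the up profile `w⁺` if `β₁ > 0`, to the down profile
   `w⁻` if `β₁ < 0` (the other side is 0); weights are trimmed at 10 and
   min-max rescaled to [0, 1] over the pooled profiles.
2. **Single-sample scoring** (modified BASE statistic). Median-center the
   cohort, sort each sample's profile descending as `e₁ ≥ … ≥ e_g`, and form
   foreground and background cumulative curves
   `f(i) = Σ_{k≤i} e_k w_k / Σ_{k≤g} e_k w_k`,
   `b(i) = Σ_{k≤i} e_k (1−w_k) / Σ_{k≤g} e_k (1−w_k)`.
   The raw statistic is `f − b` at the index of maximal |f − b|, z-normalized
   against a 1000-permutation null of the profile; the final score is
   `RPS = RPS⁺ − RPS⁻`. High RPS ⇒ the sample resembles known responders.
3. **Evaluation & annotation.** ROC/AUC by threshold sweep (= Mann-Whitney
   concordance), rank-sum and tertile-enrichment statistics, a balanced
   random-forest classifier combining the score with age/stage/grade under
   repeated 10-fold CV, walking-sum pathway enrichment
   `ES = (Σ gᵢdᵢ/(nN) − 0.5)·2` of gene sets in the weight-ranked signature,
   and Spearman correlation with tumor-microenvironment components.

A synthetic-cohort generator (`simulate_cohort()`) with planted
differentially expressed genes, batch shifts, and response-tilted clinical
covariates makes the whole pipeline testable without any external data.

## Worked example

```r
library(rpskit)
library(dplyr)

sim <- simulate_cohort(n_genes = 500, n_samples = 120, n_de_genes = 80, seed = 1)
train <- sim$annotations$sample_id[1:60]
test  <- sim$annotations$sample_id[61:120]

sig <- build_rps_signature(sim$expression[, train],
                           filter(sim$annotations, sample_id %in% train))
sig
#> <rps_signature> 500 genes (235 up-weighted, 265 down-weighted, 0 non-converged)
#>   trim = 10, log base = 10

scores <- score_cohort(sim$expression[, test], sig, n_perm = 300, seed = 9)
scores[1:3, c("sample_id", "rps_plus", "rps_minus", "rps")]
#>   sample_id rps_plus rps_minus   rps
#> 1 s0061         1.74    -1.81   3.54
#> 2 s0062        -1.11     1.31  -2.43
#> 3 s0063        -1.88    -0.809 -1.07

ann <- sim$annotations[match(scores$sample_id, sim$annotations$sample_id), ]
glance(roc_curve(scores$rps, ann$response))
#>     auc n_pcr  n_rd
#> 1     1    20    40
rank_sum_test(scores$rps[ann$response == "pCR"],
              scores$rps[ann$response == "RD"])$p_value
#> [1] 3.55e-10
```

The held-out AUC of 1 reflects the strong planted effect (80 of 500 genes
shifted by 1 SD): per-sample scores separate the planted responder class
completely, and the rank-sum test agrees. `autoplot()` methods draw the ROC
curve, score distributions by response group, and CV feature importances;
`tidy()`/`glance()` return per-threshold, per-gene, or per-repeat tibbles
from every fitted object.

A command-line wrapper ships in `inst/exec/rpskit`
(`rpskit simulate | preprocess | build | score | compare | evaluate | enrich`),
each subcommand a thin layer over the functions above.

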