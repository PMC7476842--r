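---
title: "Response-probability scores: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-probability scores: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpskit)
library(dplyr)
```

## The problem

Neoadjuvant chemotherapy (NCT) — chemotherapy given before surgery — benefits
only a minority of breast-cancer patients: those who reach a pathologic
complete response (pCR) have much better outcomes than those left with
residual disease (RD), yet the majority are non-responders who still endure
the side effects. For triple-negative breast cancer (TNBC; ER-, PR-, Her2-)
no clinically established expression-based predictor of NCT response exists.
rpskit implements a whole-transcriptome framework for this prediction task:
instead of a small fixed gene panel, every gene contributes to a pair of
weight profiles according to how well it discriminates responders in a
labelled training cohort, and each new patient receives a single
response-probability score (RPS) from their pretreatment expression profile
alone.

## The model

**Weight profiles.** For each gene $i$, a univariate logistic regression

$$\operatorname{logit} P(Y = 1) = \beta_0 + \beta_1 x_i$$

is fitted on the training cohort ($Y = 1$ for pCR, $x_i$ = log2 expression).
The gene's raw weight is $-\log_{10} p_i$, assigned to the *up* profile
$w^+$ when $\beta_1 > 0$ (higher expression in responders) and to the *down*
profile $w^-$ when $\beta_1 < 0$; the other side is zero. Raw weights are
trimmed at 10 (so $p = 10^{-10}$ saturates the scale) and min-max rescaled
to $[0, 1]$ jointly over the pooled raw weights of both profiles.

**Single-sample scoring.** A sample's profile is median-centered (per gene,
across the cohort), sorted in descending order, and compared against each
weight profile through two cumulative curves,

$$f(i) = \frac{\sum_{k \le i} e_k w_k}{\sum_{k \le g} e_k w_k}, \qquad
  b(i) = \frac{\sum_{k \le i} e_k (1 - w_k)}{\sum_{k \le g} e_k (1 - w_k)},$$

a rank-based construction in the BASE family: if highly weighted genes sit
among the sample's most-expressed genes, the foreground $f$ runs ahead of
the background $b$. The raw statistic is $f(i) - b(i)$ at the index of
maximal absolute deviation (sign-preserving, so *depletion* of a profile at
the top of a sample yields a negative value). Each side's raw statistic is
z-normalized against a null distribution from 1000 random permutations of
the expression values across gene labels, and the final score is

$$\mathrm{RPS} = \mathrm{RPS}^{+} - \mathrm{RPS}^{-}.$$

High RPS means the sample looks like known responders from both directions:
responder-up genes highly expressed *and* responder-down genes lowly
expressed.

## Worked example

```{r worked}
sim <- simulate_cohort(n_genes = 500, n_samples = 120, n_de_genes = 80, seed = 1)
train <- sim$annotations$sample_id[1:60]
test <- sim$annotations$sample_id[61:120]

sig <- build_rps_signature(sim$expression[, train],
                           filter(sim$annotations, sample_id %in% train))
sig
scores <- score_cohort(sim$expression[, test], sig, n_perm = 300, seed = 9)
ann <- sim$annotations[match(scores$sample_id, sim$annotations$sample_id), ]
glance(roc_curve(scores$rps, ann$response))
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `trim` | 10 | cap on raw $-\log_{10} p$ weights; prevents a handful of extreme genes from dominating both the rescale and the foreground sums |
| `log_base` | 10 | base of the $-\log p$ transform; base 10 makes the cap correspond to $p = 10^{-10}$ and is the conventional significance scale |
| `n_perm` | 1000 | permutation-null size per sample; the null-mean/sd estimates have relative error $\sim 1/\sqrt{n_\mathrm{perm}}$ |
| `mode` | `"max_abs"` | sign-preserving maximal deviation; `"max_signed"` is available but cannot express top-depletion as a negative score |
| `folds`, `repeats` | 10, 100 | cross-validation layout of the combined clinical + RPS random-forest classifier |
| `ntree` | 500 | trees per forest (the randomForest default) |
| `min_size` | 20 | gene sets smaller than this after intersection with the signature universe are excluded from enrichment |

## Numerical and design choices

Several points are underdetermined by the method's verbal description; the
package fixes them as follows, and each is covered by a test.

- **Rescaling domain.** The min-max rescale of raw weights is computed over
  the *pooled* raw weights of both profiles, not per profile. Per-profile
  rescaling would silently re-balance $\mathrm{RPS}^{+}$ against
  $\mathrm{RPS}^{-}$ whenever the two sides' significance ranges differ.
  Because every gene is zero on at least one side, the pooled minimum is
  zero and zeros stay zero. A consequence worth knowing: on a cohort with
  no true signal, no gene reaches the trim cap, so the rescale denominator
  is the null maximum of $-\log_{10} p$ (about 2.5 at 1000 genes) and a
  weight threshold such as 0.2 then corresponds to a lenient $p \approx
  0.3$; chance-level "recovery" at that threshold is therefore ~25%, not a
  few percent. Thresholded gene counts are only comparable between
  signatures whose denominators are comparable.
- **Negative relative expression.** Median-centered values are negative for
  half the genes, which would make the cumulative sums non-monotone.
  Profiles are shifted by their minimum before the curves are formed; this
  preserves rank order and keeps both normalizing sums strictly positive.
- **Null normalization.** The raw deviation is z-transformed,
  $(\mathrm{raw} - \mu_\mathrm{null})/\sigma_\mathrm{null}$. An empirical
  quantile transform was considered and rejected: at 1000 permutations its
  resolution is bounded at $10^{-3}$ and it saturates for exactly the
  samples of greatest interest.
- **Separation.** With a univariate predictor, complete or quasi-complete
  separation (the class-wise expression ranges do not overlap) means the
  logistic MLE does not exist; such genes are flagged non-converged and
  excluded (weight zero) rather than given arbitrarily capped weights, since
  their Wald p-values are meaningless.
- **Ties.** Descending sorts break ties by gene id; probe collapse breaks
  mean ties toward the lexicographically smaller probe id; quantile
  normalization gives within-sample ties the mean of the reference values at
  the tied ranks; tertile boundaries assign boundary scores to the lower
  tertile. All choices are for determinism only.
- **Per-sample RNG streams.** Each sample's permutation stream is seeded by
  the master seed plus a content hash of its gene-id-sorted profile. Scores
  are therefore invariant to sample order and gene order, identical profiles
  score identically, and cohort scoring parallelizes trivially.
- **Consensus-score IQR.** The median-0 / IQR-1 rescaling of the consensus
  comparator uses type-2 quantiles, under which the IQR of $(1,2,3,4)$ is 2;
  R's default type-7 convention would give 1.5 and a different (though
  affinely equivalent) scale.
- **Batch adjustment.** `adjust_batches()` defaults to the parametric
  empirical-Bayes location-scale adjustment (ComBat, via the sva package).
  Note that EB shrinkage intentionally leaves small residual batch-mean
  differences; the `center_scale` method removes per-gene batch means
  exactly (at the cost of no shrinkage) and `none` is a pass-through. The
  order of quantile normalization relative to cohort merging is left to the
  caller, as it is not determined by the method.
- **CV pooling.** Held-out random-forest probabilities are pooled across
  the 10 folds before one AUC per repeat is computed (`pooling =
  "fold_average"` averages per-fold AUCs instead). At TNBC-scale cohorts a
  per-fold AUC rests on ~6 responders and is extremely noisy; both modes
  are unbiased at chance level under label-independent features.
- **Enrichment ranking and sentinel.** Signature genes are ranked descending
  by signed weight $w^+ - w^-$ (zero-weight genes retained, tie-break by
  gene id), and the walking-sum gap of the last hit uses the sentinel
  $r_{n+1} = N + 1$. This is the only reading under which a set
  concentrated at the top of the ranking approaches $+1$, matching the
  interpretation that positive enrichment means enrichment among
  responder-up genes.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` generates Affymetrix-style log2 intensities: baseline
gene means $\mathcal{N}(7, 1.5)$, i.i.d. Gaussian within-gene noise
(`noise_sd = 1`), a planted set of differentially expressed genes (default
200 of 2000, half up / half down in responders, shift = `effect_size`
$\times$ `noise_sd`), per-gene batch shifts
($\mathcal{N}(0, 0.3)$ across 2 batches), a one-third responder rate (the
typical NCT pCR rate), and ordinal stage/grade covariates tilted toward
response with log-odds slope 0.5 (more advanced disease responds somewhat
better, mirroring the clinical confounding the evaluation module must
handle). The default 240 samples support a 120/120 train/validation split.

The generator deliberately omits gene-gene correlation structure,
probe-level artifacts (cross-hybridization, spatial effects), heavy-tailed
noise, and any coupling between clinical covariates and expression. Passing
tests on these cohorts therefore demonstrates that the machinery is
correct and well-calibrated — recovery of planted signal, chance-level
behavior under the null, determinism — not that any particular AUC will be
attained on real microarray cohorts, where correlated genes reduce the
effective number of independent markers and batch confounding can be far
less benign.

## Problem sizes used by the tests

The test suite and acceptance script exercise: oracle equivalence of the
scoring core on 200 random 100-gene instances; null calibration on 200
permuted profiles at 500 permutations each; full-scale recovery on the
default 2000-gene, 240-sample cohort at 1000 permutations; classifier
calibration at n = 200 with 10-fold CV; and smaller cohorts (200–1000
genes) for property checks. These sizes were chosen so each property is
measured at, or safely above, the scale where its asymptotics apply.

## Known limitations

- Weight profiles come from *marginal* per-gene fits; correlated genes
  share credit, and no multiple-testing adjustment is applied (by design —
  weights are evidence scores, not significance claims).
- The permutation null treats genes as exchangeable within a sample; strong
  expression-variance structure across genes is not reflected in it.
- The thresholded-recall caveat of the pooled rescale (above) means
  "number of genes with weight > t" is not a stable quantity across
  cohorts.
- Immune/stromal abundance components are consumed as a precomputed table;
  the package does not re-implement microenvironment decomposition.
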