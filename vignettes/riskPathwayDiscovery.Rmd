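---
title: "Discovering cancer risk pathways and risk lncRNAs from paired tumor-normal RNA-seq"
author: "lncRiskPath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cancer risk pathways and risk lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncRiskPath)
```

## The question and the approach

Individual lncRNAs have been tied to individual cancer pathways, but a
marker panel that is useful across cancers has to show a *joint* effect:
the same pathways dysregulated in every cohort, driven in part by the same
lncRNAs. `lncRiskPath` implements a multi-cohort discovery procedure for
exactly that setting. Given several paired tumor–normal RNA-seq cohorts it

1. quantifies expression as log2 RPKM from exon-level counts and screens
   features;
2. finds differentially expressed (DE) lncRNAs and mRNAs per cohort
   (two-tailed t-test, Benjamini–Hochberg at 5%);
3. computes, for every DE feature $m$ and tumor sample $n$, the expression
   change $\Delta e_m^n = x_m^n - \bar y_m$ against the mean of the
   cohort's matched normals;
4. scores every pathway per cohort by a Wilcoxon signed-rank test on the
   pooled $\Delta e$ of its DE members, and calibrates the observed
   significance with size-preserving permutations (random same-size sets
   drawn from the DE universe);
5. intersects the significant candidate pathways (permutation FDR < 0.05)
   across all cohorts into **risk pathways**;
6. extracts **risk lncRNAs** — lncRNAs DE in *every* cohort that belong to
   a risk pathway — and verifies that this common subset scores the risk
   pathways at least as strongly as their full lncRNA membership;
7. tests each risk pathway for hallmark gene-set enrichment
   (upper-tail hypergeometric, joint BH);
8. validates the risk lncRNAs as classification features (linear SVM and
   Gaussian naive Bayes under stratified cross-validation, rank-based AUC,
   Golub-style weighted voting) and as a prognostic signature
   (median split of a mean z-score, Kaplan–Meier, log-rank, univariate
   Cox with Efron ties).

Every stage is exposed as a documented function returning plain
data structures, and `runPipeline()` chains them with a single seed.

## Statistical core

**Expression.** For feature $f$ in sample $s$,
$\mathrm{RPKM}_{f,s} = 10^9\, rr_{f,s} / (tr_s\, L_f)$ with $rr$ the raw
count summed over the feature's exons, $tr$ the sample's total exon count
and $L$ the summed exonic length in bp. Features with RPKM zero in all
samples are dropped; features missing (NA, i.e. unquantified — distinct
from zero) in strictly more than 30% of samples are dropped; remaining
zeros become 0.05 before log2. The strict-greater reading of the 30% rule
means a feature missing in exactly 30% of samples is retained. Because
RPKM is a relative measure, a large one-sided change in the mass of
perturbed transcripts re-expresses itself as an opposite global shift of
all unperturbed features; this is a property of the normalization, not a
bug, and the permutation calibration below is what keeps pathway-level
inference honest against it.

**Pathway scoring.** The signed-rank test is implemented with Pratt zero
handling (zeros are mid-ranked with the rest, then dropped from the
statistic) and mid-ranked ties. For up to 25 nonzero values the exact null
of $W$ is built by convolution over the (possibly half-integer) rank
values, so ties and zeros are exact; beyond that a normal approximation
with variance $\sum r_i^2/4$ and a 0.5 continuity correction is used. The
two-sided p-value is $P(|W-\mu| \ge |W_{obs}-\mu|)$, $\mu = \sum r_i / 2$.

**Permutation calibration.** For each pathway with at least
`minMembers = 3` DE members, `B` random feature sets of the same size are
drawn without replacement from the DE universe and re-scored. The default
permutation p-value is the (+1)-corrected exceedance
$(\#\{p_b \le p_{obs}\}+1)/(B+1)$, which is bounded below by $1/(B+1)$ and
uniform under the null. The literal "share of insignificant permutations"
reading ($\#\{p_b \ge 0.05\}/B$) is retained behind
`mode = "insignificance"` because the two conventions answer subtly
different questions; the exceedance form is the default since it is a
valid p-value and composes correctly with BH. BH is applied to the
permutation p-values across testable pathways within each cohort.

**Enrichment.** With universe size $N$, pathway size $K$, term size $n$
and overlap $k$, $p = \sum_{j=k}^{\min(n,K)} \binom{K}{j}\binom{N-K}{n-j}
/ \binom{N}{n}$, evaluated in log space (log-binomials, log-sum-exp). The
universe is the union of genes in any pathway or hallmark set — a fixed
annotation universe; the literal per-pair union is available
(`universe = "pairwise"`) but makes $p$ depend only on the overlap
geometry of the two sets, which is rarely what one wants.

## Open design points and how they were resolved

The procedure as published leaves several details open; the package makes
one choice each, keeps the alternative behind a flag, and records the
rationale here.

* **t-test variant** — Welch by default (tumor and normal variances
  genuinely differ); pooled variance via `varEqual = TRUE`.
* **BH families for DE** — separately within lncRNAs and within mRNAs per
  cohort (they are reported as separate families);
  `separateFamilies = FALSE` pools.
* **Matched normals** — every tumor is compared against all normals of
  its cohort, summarized by the mean (`center = "median"` available).
  Per-patient 1:1 pairing is rarely complete in real cohorts, and the mean
  of matched normals is the minimal-assumption reduction.
* **Pooling $\Delta e$** — member-by-tumor values are pooled into one
  vector per pathway per cohort (one test per pathway per cohort);
  treating values as exchangeable across samples matches the single
  reported p-value per pathway.
* **Train/validation interplay** — samples are split once per seed into
  5 stratified folds; DE, $\Delta e$ and pathway testing run on the 4/5
  training portion; classifier evaluation runs its own cross-validation.
  The split is *not* redrawn per permutation.
* **Risk-lncRNA membership** — "within the risk pathways" is read as
  membership in at least one risk pathway (`membership = "all"`
  available); the permutation null for the common-subset evaluation draws
  from all pathway-annotated lncRNAs, not only DE ones.
* **Risk score** — mean of per-feature z-scored expression across tumors,
  median split, ties at the median broken by sample id so the split is
  deterministic. Survival tests are two-sided: a "high-risk" group with
  *longer* survival is still a separation.

## The synthetic cohorts

Real multi-cohort data cannot ship with a package, so the generator in
`simulateCohorts()` is a first-class module with its own ground truth.
Its defaults define the package's reference conditions:

| parameter | default | meaning |
|---|---|---|
| cohorts | 3 | paired tumor–normal cohorts |
| samples | 20 + 20 per cohort | tumors + normals |
| features | 1600 mRNA + 400 lncRNA, 3 exons each | exon lengths 100–2000 bp |
| pathways | 100, sizes 10–40 | 3 risk + 3 decoy among them |
| risk lncRNAs | 8 | shared members of all risk pathways |
| `deLog2fc` | 1.5 | implanted log2 fold change |
| `deFraction` | 0.05 | extra DE features per cohort, random sign |
| `nbDispersion` | 0.2 | NB variance $\mu + 0.2\mu^2$ |
| `baselineMeanLog` | 4 (sdlog 0.5) | lognormal exon baselines |
| `missingRate` | 0.02 | feature-sample cells set NA |
| `hazardRatioHighRisk` | 3 | hazard of latent high-risk tumors |
| `censoringRate` | 0.3 | expected censored fraction |

Counts are negative binomial around lognormal exon baselines. Risk
pathways are implanted as a coordinated 1.5-log2 *repression* of all
members (risk lncRNAs included) in every cohort; each cohort additionally
gets one coordinatedly *activated* decoy pathway, which produces realistic
cohort-specific candidates that the intersection must reject. The extra DE
features are drawn from pathway-unannotated features with random signs —
as in real tumors, most differential expression falls outside any curated
pathway — so the permutation universe mixes directions without
manufacturing pathway-level signal. Two generator choices deserve
emphasis because RPKM forced them: baselines use sdlog 0.5 so no single
feature dominates library mass, and implanted directions are arranged so
the net shifted read mass stays small; otherwise the relative nature of
RPKM converts implant mass into an artificial global shift of every null
feature. Survival is exponential with rate $1/1000\ \mathrm{days}^{-1}$,
censoring by an independent exponential matched to the target censoring
fraction; a latent half of the tumors carries the hazard multiplier and a
$fc/2$ relief of the risk-lncRNA repression, so the expression-based
median split can find the latent groups.

What the generator does **not** emulate: batch effects, per-patient
tumor–normal pairing, isoform structure, overlapping exons, GC/length
biases, correlated noise between features, and non-proportional hazards.
Passing tests therefore show the *procedure* is correct and calibrated
under a faithful null and a detectable implanted signal; they do not show
that any particular real-data finding replicates.

## Numerical and degeneracy conventions

* Zero-variance features with equal means: $t = 0$, $p = 1$; with unequal
  means $p = 0$ (infinite evidence at machine scale).
* All-zero $\Delta e$ vectors: $p = 1$ with a warning.
* Features with fewer than 2 finite values per group get NA statistics
  and are excluded from BH.
* Pathways under `minMembers` are "untestable": excluded from BH and
  never candidates.
* SVM features are z-scored with training-fold statistics (zero SDs map
  to 1); decision values, not hard labels, feed the ROC; naive Bayes uses
  Gaussian class conditionals on the same scaled features.
* Leave-one-out CV is deterministic, so `repeats` collapses to one pass.
* All randomness flows from explicit seeds through derived child streams;
  no exported function reads or disturbs the caller's RNG state.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the full pipeline at the
reference fixture scale (3 cohorts x 40 samples, 2000 features, 100
pathways, B = 200 permutations), recovery sweeps over 20 generator seeds,
null calibration on global-null cohorts of the same size, survival power
at 200 tumors and hazard-ratio recovery at 500 tumors. These sizes were
chosen so each property is measured with useful Monte-Carlo resolution
while a complete run stays in the tens of seconds on one CPU; statistical
thresholds carry explicit binomial slack for the finite number of seeds.

## Limitations

With B permutations the smallest attainable permutation p-value is
$1/(B+1)$, so after BH across $m$ testable pathways the smallest
attainable FDR is roughly $m/(4(B+1))$ when four implanted pathways tie
at the floor — at B = 200, cohorts with many testable pathways can leave
even a perfect pathway above the 5% line. Use B = 1000 (the default in
`pipelineConfig()`) when the DE universe is large. The t-test on log2
RPKM inherits RPKM's compositional sensitivity; the pathway stage is
calibrated against it, but the DE stage is not. The weighted-voting
curve reports apparent error under honest training-fold ranking; the
intentionally leaky variant (`rankOn = "all"`) exists only as a
diagnostic of what selection bias would look like.
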