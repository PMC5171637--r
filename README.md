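# lncRiskPath

Multi-cohort discovery of **cancer risk pathways** and **cancer risk
lncRNAs** from paired tumor–normal RNA-seq, for computational biologists
who want a tested, reusable implementation of the whole chain — expression
screening through survival validation — that runs end-to-end on simulated
cohorts with known ground truth.

## What it computes

Per cohort, exon counts become filtered log2 RPKM
(`RPKM = 1e9 * rr / (tr * L)`; all-zero features dropped, >30%-missing
features dropped, zeros set to 0.05 before log2). DE lncRNAs/mRNAs are
called by two-tailed t-test with Benjamini–Hochberg control at 5%. For
each DE feature *m* and tumor *n* the expression change is

    Δe(m, n) = x(m, n) − mean(y(m, 1..q))        # q matched normals

and each pathway is scored by a Wilcoxon signed-rank test (exact,
Pratt zeros, tie-aware) on its members' pooled Δe, calibrated by
size-preserving permutations: B random same-size sets from the DE
universe, permutation p = (#{p_b ≤ p_obs}+1)/(B+1), BH across pathways.
Pathways significant in **every** cohort are risk pathways; lncRNAs DE in
every cohort inside a risk pathway are risk lncRNAs. Downstream:
hypergeometric hallmark enrichment (log-space tail), SVM / naive-Bayes
cross-validated classification with rank-based AUC, Golub weighted-voting
curves, and survival stratification (median split of a mean z-score;
Kaplan–Meier, log-rank, univariate Cox).

A negative-binomial cohort simulator (`simulateCohorts()`) implants risk
pathways, risk lncRNAs and a high-hazard latent group, so every stage has
an oracle.

## Worked example

```r
library(lncRiskPath)

cfg <- pipelineConfig(simulation = list(seed = 42L),
                      B = 200L, cvRepeats = 5L, seed = 7L)
s <- runPipeline(cfg, "run42", verbose = FALSE)

s$riskPathways
#> [1] "PW0001" "PW0002" "PW0003"
s$riskLncrnas
#> [1] "LNC00081" "LNC00103" "LNC00126" "LNC00127"
#> [5] "LNC00180" "LNC00195" "LNC00341" "LNC00345"
unlist(s$nCandidatesPerCohort)     # candidate pathways per cohort
#> C1 C2 C3
#>  4  4  4
round(unlist(s$meanAucPerCohort), 3)
#>    C1    C2    C3
#> 0.906 0.968 0.917
signif(unlist(s$logrankPPerCohort), 3)
#>       C1       C2       C3
#> 5.04e-01 1.65e-05 1.13e-01
```

The three implanted risk pathways and all eight implanted risk lncRNAs
are recovered exactly (each cohort also flags its own decoy pathway,
which the cross-cohort intersection removes). The risk lncRNAs separate
tumor from normal with mean five-fold-CV SVM AUC ≈ 0.91–0.97. At this
deliberately small scale (20 tumors per cohort) the log-rank test is
significant in one cohort and not the others — survival power needs more
patients, and the shipped checks demonstrate it at n = 200, where
log-rank p < 0.01 in every tested seed. Elementary pieces are usable on
their own:

```r
wilcoxonSignedRank(c(1.2, 0.8, 2.1, 1.7, 0.4))$p.value
#> [1] 0.0625                       # exact: 2/2^5
hypergeomEnrich(paste0("g", 1:5), paste0("g", 2:5), paste0("g", 1:10))$p
#> [1] 0.02380952                   # C(5,4)*C(5,0)/C(10,4)
```

## Layout

* `R/` — simulator, quantification, DE, pathway/permutation machinery,
  risk-lncRNA extraction, enrichment, classification, survival, pipeline.
* `vignettes/riskPathwayDiscovery.Rmd` — the methods vignette: model,
  conventions, generator design, limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (sign-flip enumeration, exhaustive draws,
  prime-factorized binomials, hand risk tables).
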