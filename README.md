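# statresp

Predicting inter-individual LDL-cholesterol (LDLC) response to statin
treatment from lymphoblastoid cell line transcriptomes and genotype
dosages.

Statins lower LDLC, but individuals differ widely in how much, and known
DNA variants explain only a few percent of that variation. `statresp`
implements a transcriptomics-first pipeline for the problem, aimed at
statistical geneticists and pharmacogenomics analysts:

1. **Response phenotype** — the relative change
   `log(mean post-treatment LDLC) − log(mean pre-treatment LDLC)`
   (duplicate visits averaged), residualized on clinical covariates that
   survive a regression screen (age, by default, at α = 0.05).
2. **Extreme-responder selection** — for candidate tail sizes *N*, the
   *N*/2 highest and lowest responders are clustered by non-negative
   matrix factorization (rank 2, multiplicative updates, best of many
   restarts) on the 2,000 genes with the largest group mean difference,
   after mapping expression through the per-gene normal CDF (the
   "1 − P" transform). Cluster quality is scored by
   *purity* = (1/n)·Σᵢ maxⱼ nᵢʲ and
   *entropy* = −(1/(n log₂ l))·Σᵢ Σⱼ nᵢʲ log₂(nᵢʲ/nᵢ)
   against the true high/low labels, with a random-set baseline; the
   largest *N* with purity ≥ 0.9 is kept. Consensus matrices across
   ranks with cophenetic correlation and dispersion diagnostics back the
   rank-2 choice.
3. **Signature genes** — a variance-stabilized relative difference
   d(i) = (x̄_H(i) − x̄_L(i)) / (s(i) + s₀(i)), with gene-specific
   scatter s(i) = √((SS_H + SS_L)/(N(N−1))) and a SAM-style fudge factor
   that *varies per gene*: s₀(i) = s₀ᵐᵃˣ·(1 − F̂(s(i))), tuned to
   flatten the spread of |d| across the scatter range. Significance from
   a balanced label-permutation null (pooled across genes); the top 100
   genes form the signature (SG).
4. **Feature models** — SG expression; best cis-eQTL dosages of SG genes
   (strongest SNP per gene at p < 5×10⁻⁸); combined; *substitution*
   (dosages replace expression for covered genes); GWAS response SNPs;
   all features.
5. **Prediction** — radial-basis SVMs (kernlab, C = 1, median-heuristic
   kernel width) under 1,000 stratified 90/10 holdouts: rank-based AUC
   for classifying high vs low tails as a function of the tail fraction,
   and cross-validated explained variance (directional out-of-sample r²)
   for the continuous response.

A first-class synthetic cohort generator (`simulate_cohort()`) plants a
co-expressed signature module, cis-eQTLs with tunable dosage→expression
R², trait SNPs, an age effect, array batches, and visit-level LDLC
measurement noise — so every stage is testable against known truth
without controlled-access human data.

## Worked example

```r
library(statresp)

co <- simulate_cohort(sim_config(n_samples = 372, seed = 1))
files <- write_cohort(co, "cohort")

cfg <- pipeline_config(
  expression = files[["expression"]], phenotypes = files[["phenotypes"]],
  genotypes = files[["genotypes"]], eqtl = files[["eqtl"]],
  gwas = files[["gwas"]], out_dir = "out",
  N_grid = seq(20, 80, 8), n_random_sets = 10, nmf_runs = 10,
  cv_repeats = 100, seed = 1)
man <- run_pipeline(cfg)

man$stages$predict$explained_variance_pct$sg
#> [1] 16.11141
sw <- read.delim("out/auc_tail_sweep.tsv")
sw[c(2, 19), ]
#>    fraction   n       auc      auc_se
#> 2      0.15  54 0.9277778 0.010638079
#> 19     1.00 372 0.6392521 0.008460166
```

Read: on a seeded synthetic cohort at the default operating point (100
planted signature genes carrying 12.3% of response variance, 36 strong
eQTLs, 7 trait SNPs), the discovered-signature SVM classifies the 15%
extremes with AUC 0.93, decays toward chance at the full cohort (0.64) —
extreme responders are far easier to tell apart than middle ones — and
the regression model explains ~16% of response variance out of sample
(above the planted 12.3% because the signature was selected on the same
cohort, the same optimism the real design carries). Stage outputs
(`purity_curve.tsv`, `signature.tsv`, `auc_tail_sweep.tsv`,
`explained_variance.tsv`) and a seed/checksum manifest land in `out/`.

A thin CLI covering `simulate` and `run-all` ships in
`inst/cli/statresp.R`.

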