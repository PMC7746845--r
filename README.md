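# reosig

Rank-based gene-pair signatures for predicting drug response, and tools for
choosing cell-line models that actually represent clinical tumour tissue.

## The problem

Drug-resistant vs drug-sensitive cell-line panels are the workhorse of
mechanism and biomarker discovery, but lines from different labs disagree
with each other and, worse, with patient tissue. `reosig` implements a
two-part analysis for this situation, developed around adjuvant tamoxifen
response in ER+ breast cancer but applicable to any drug/tissue pairing:

1. **Cell-line model selection.** Genes associated with relapse-free
   survival in treated patients (univariate Cox screening, BH-FDR) are
   compared against differentially expressed genes between resistant and
   sensitive lines (SAM permutation FDR). For each cell-line dataset, among
   the *n* genes shared by both lists, *k* agree in direction (hazard-increasing
   ⇔ up in resistant). Under the null of unrelated lists,
   *k* ~ Binomial(*n*, ½), so the one-sided tail

   p = P(X ≥ k) = Σ_{i=k}^{n} C(n, i) (½)^n

   measures whether a line's resistance programme reproduces the clinical
   one above chance. The dataset with the highest significant consistency
   ratio *k*/*n* is the representative model.

2. **REO gene-pair signature.** From the direction-consistent candidate
   genes, all C(n,2) within-sample order indicators
   I[Expr(G_i) > Expr(G_j)] are screened with univariate Cox regression
   (Efron ties, Wald tests, FDR < 10%); every retained pair is oriented so
   that `gene_hi` above `gene_lo` votes high risk (β > 0). All combinations
   of retained pairs are then enumerated; each combination classifies a
   sample as low risk when at least half of its pairs show the
   sensitivity-associated ordering, and the combination with the maximum
   Harrell C-index becomes the signature. Because only within-sample
   orderings enter, the classifier is exactly invariant to any strictly
   increasing per-sample transform — i.e. robust to batch effects and
   normalisation choices, and applicable to a single profile.

Supporting modules provide hypergeometric gene-set over-representation,
Kaplan–Meier/log-rank/hazard-ratio evaluation, TSV/GMT readers, and a
synthetic-data generator that emulates matched cell-line and tissue cohorts
with planted ground truth (two-group log-scale Gaussian expression;
proportional-hazards survival by inverse-transform sampling; a tunable
fraction of sign-consistent planted genes; optionally a planted pair
signature whose majority-vote high-risk group carries a chosen hazard
ratio).

## Worked example

Simulate a training cohort in which a two-pair signature's high-risk group
carries a true hazard ratio of 4, recover the signature, and validate it on
an independent cohort:

```r
library(reosig)

ps <- list(pairs = data.frame(gene_hi = c("g00001", "g00003"),
                              gene_lo = c("g00002", "g00004")),
           beta = log(4))
train <- simulate_tissue(tissue_sim_config(30, 250, planted_signature = ps,
                                           seed = derive_seed(1, 300)))

screen <- screen_pairs(train$expr, train$cohort, sprintf("g%05d", 1:4), fdr = 0.10)
opt <- optimize_combination(screen, train$expr, train$cohort)
opt$signature
#> REO gene-pair signature: 2 rule(s), vote rule 'at_least_half_sensitive_low'
#>  gene_hi gene_lo      beta            p            q
#>   g00003  g00004 0.5572513 0.0001374753 0.0008248518
#>   g00001  g00002 0.4583858 0.0015488573 0.0046465719

validation <- simulate_tissue(tissue_sim_config(30, 250, planted_signature = ps,
                                                seed = derive_seed(1, 401)))
ev <- evaluate_signature(opt$signature, validation$expr, validation$cohort)
#> validation: 196 low / 54 high risk; HR = 3.56 (95% CI 2.50-5.06),
#> log-rank p = 6.48e-14
```

Both planted pairs are recovered (training C-index 0.619) and the
classification transfers to the unseen cohort with a hazard ratio close to
the planted value. The tissue/cell-line consistency test is a one-liner —
114 overlapping genes of which 84 agree in direction:

```r
binomial_tail(114, 84)
#> [1] 2.126872e-07
```

`run_pipeline()` chains every stage (cell-line DEGs → tissue survival
screens → concordance gate → candidate genes → pair signature → validation)
from a single config with one master seed, writing all intermediate tables,
the signature JSON, and a run log to a directory. A thin command-line
wrapper is installed at `inst/cli/reosig.R` (subcommands `sam`, `coxscreen`,
`concord`, `enrich`, `signature`, `classify`, `evaluate`, `run`).

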