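---
title: "Methods: cell-line model selection and REO gene-pair signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-line model selection and REO gene-pair signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

# Overview

`reosig` implements two linked analyses for drug-response transcriptomics:
selecting a resistant/sensitive cell-line dataset that reproduces the
survival-associated expression programme of treated patients, and building a
relative-expression-ordering (REO) gene-pair signature that predicts
response from a single expression profile. This vignette documents the
statistical models, the package's default parameters and why they were
chosen, the synthetic-data generator used for all testing, the numerical
conventions, and the design decisions taken where the procedure admitted
more than one reasonable reading.

# Models and assumptions

## Survival-gene screening

Each gene is screened with a univariate Cox proportional-hazards model on
its (log-scale) expression; `beta` is the log hazard ratio per expression
unit, tested with a Wald statistic and BH-adjusted across genes
(`screen_survival_genes()`, default FDR < 0.2). Assumptions: proportional
hazards per gene, independent censoring, and — as in any marginal screen —
that per-gene associations are interpretable even though genes act jointly.
The fits use the Efron approximation for tied event times (the default in
the major survival libraries, more accurate than Breslow when ties are
common) and Wald rather than likelihood-ratio p-values for speed across
thousands of genes. Monotone likelihood (risk perfectly separating events)
is detected when `|beta| > 15` during fitting; such genes are flagged
non-converged and excluded from the BH family rather than surfacing as
spurious top hits. A constant covariate yields `beta = 0`, `p = 1`,
`converged = FALSE`.

## Differential expression in cell lines

Resistant vs sensitive contrasts use the SAM moderated statistic
`d = (mean_R - mean_S) / (s + s0)`, with `s` the two-group pooled standard
error and `s0` an exchangeability constant that prevents low-variance genes
from dominating. `s0 = "auto"` follows the classic recipe: candidate values
are the 0, 5, …, 100th percentiles of `s`, and the one minimising the
coefficient of variation of `mad(d)` across twenty `s`-quantile windows is
chosen (falling back to `median(s)` if the search degenerates). The null
distribution of `|d|` comes from group-label permutations: when the number
of distinct label assignments is at most `n_perm` (e.g. 20 for a 3 vs 3
design) every assignment is enumerated, eliminating Monte-Carlo noise at
exactly the sample sizes where it matters most; otherwise `n_perm` random
assignments are drawn. The per-gene q-value is the median false-call count
over permutations divided by the observed call count at that `|d|`
threshold, with the proportion of true nulls fixed conservatively at 1,
clipped to `[0, 1]`, and made monotone non-increasing in `|d|` by a reverse
cumulative maximum. DEGs are genes with `q` below the cutoff (default
FDR < 0.2), signed by the direction of `d`.

## Tissue/cell-line concordance

The working hypothesis is that hazard-increasing genes in tissue correspond
to genes up-regulated in resistant lines (and symmetrically for
hazard-decreasing/down-regulated). For two signed lists sharing `n` genes of
which `k` agree in sign, consistency above chance is tested with the exact
one-sided binomial tail `P(X >= k)`, `X ~ Binomial(n, 1/2)`. The test is
one-sided by construction — only above-chance consistency makes a cell line
a candidate model. Across a panel of cell-line datasets the p-values are
BH-adjusted within the panel (`evaluate_panel()`); the all-pairs
cross-dataset table (`pairwise_dataset_consistency()`) reports raw p-values,
as such exploratory tables usually do. The representative cell line is the
dataset with the maximum consistency ratio among those with adjusted
p < 0.05; the gate is overridable (`force_cell`) because a user may have
external reasons to trust a specific line.

## Candidate genes and the REO signature

Candidate genes are required to agree in sign across *all* tissue cohorts
and with the representative cell line (`select_candidates()`); this
double-filtering is what justifies treating them as drug-resistance-related
rather than generically prognostic. From `n` candidates, all `C(n, 2)`
within-sample order indicators `I[Expr(a) > Expr(b)]` are built; constant
indicators are dropped (they carry no information and break the Cox fit),
the rest are screened exactly like genes (Efron Cox, Wald, BH, default
FDR < 0.1), and retained pairs are re-oriented so `beta > 0` — the
`gene_hi > gene_lo` ordering always votes high risk, refitting after a swap
so the reported statistics are exact even in the presence of ties.

Signature optimisation enumerates every non-empty subset of the retained
pairs, classifies each sample by majority vote, scores the binary risk
label with Harrell's C-index, and keeps the maximiser. Ties are broken in
favour of the smaller subset, then the lexicographically earlier rule
combination; the search is deterministic. Beyond 20 rules the exhaustive
search refuses to run unless capped (`max_size`) — `2^m` growth — and a
documented greedy forward-selection fallback (`method = "greedy"`) is
available for larger rule sets.

Three readings were genuinely open and are fixed as follows:

* **"Consistent with sensitivity".** A rule votes *sensitive* when its
  risk-oriented indicator is 0, i.e. the ordering associated with lower
  hazard under the fitted Cox orientation. This is the only reading that
  aligns the majority vote with the Cox directionality of each pair.
* **"At least half".** Implemented inclusively: a sample is low risk when
  sensitive votes `>= rules/2`. For odd rule counts this is ordinary
  majority; for even counts a tie goes to low risk, matching the
  sensitive-leaning tie convention below.
* **C-index predictor.** The binary high/low label (high = 1), not the
  vote fraction: the procedure classifies first and scores the
  classification, which is also what makes the selected signature directly
  transferable to new samples.

Expression ties within a pair give indicator 0 (sensitive-leaning); ties
have probability zero on continuous data and the choice only matters for
quantised inputs, where determinism is worth more than symmetry.

## Enrichment

Over-representation of a gene list against a GMT collection uses the exact
hypergeometric upper tail. The background is the set of genes on the
expression matrix (not the genome): the array defines what could have been
observed. Sets are intersected with the background before their size `m` is
counted, and query genes absent from the background are dropped with a
logged count, so `N`, `n`, `m`, `k` are always internally consistent.

# The synthetic-data generator

All tests and examples run on synthetic data with known truth, because the
original cohorts are external accessions. The generator emulates:

* **Cell lines** (`simulate_cellline()`): per-gene baselines `N(7, 1)` on a
  log2-like scale, a `±lfc/2` group shift for planted genes (sign = up/down
  in resistant), Gaussian noise (`noise_sd`, default 0.5, typical of
  RMA-processed arrays), small group sizes (3 vs 3 by default) matching
  real resistant/sensitive panels.
* **Tissue cohorts** (`simulate_tissue()`): Gaussian expression, linear
  predictor `eta = sum_g beta_g x_g`, event times by inverse-transform
  sampling `T = H0^{-1}(-log U / exp(eta))` — exactly proportional hazards
  by construction — with an exponential (default rate 0.05/month, median
  baseline survival ~14 months) or Weibull baseline, and uniform
  administrative censoring on `(0, censor_horizon)` (default 60 months),
  the simplest mechanism satisfying independent censoring. A planted
  signature (`planted_signature`) adds its log hazard ratio to the samples
  in the signature's own majority-vote high-risk group, so the signature's
  risk split carries a known HR: planting the effect on the joint
  orientation (rather than additively per pair) is what makes the planted
  subset the population C-index maximiser and hence recoverable — under
  additive per-pair effects a single pair is provably the better binary
  classifier and exact subset recovery would be ill-posed.
* **Matched pairs** (`simulate_matched()`): the planted cell-line DEG signs
  agree with the planted tissue coefficient signs for exactly
  `round(consistency_rho * n_planted)` genes, making the concordance
  hypothesis a dial with known truth.

Seeding: one master seed; every stage consumes a child seed derived by a
fixed Lehmer-style mixing step (`derive_seed(seed, offset)`), so any stage
can be reproduced in isolation and whole-pipeline runs are byte-identical.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: probe-level artefacts, batch effects
(ironically, the REO construction's main selling point can only be tested
here through synthetic monotone distortions), correlated gene-gene
expression, non-proportional hazards, informative censoring, and
cohort-level heterogeneity in platforms or follow-up. Tests demonstrate
correctness of the machinery and recoverability under the stated model, not
clinical performance.

A note on marginal screening power: when many planted genes each carry
`|beta| = 1` with unit expression SD, the omitted covariates act as strong
frailty for each univariate fit and attenuate every marginal estimate; the
recovery tests therefore assert sign-correct recovery of most, not all,
planted genes. This mirrors real marginal screens, which also under-call in
the presence of polygenic survival structure.

# Numerical conventions

* Binomial and hypergeometric tails are computed via the exact,
  log-space-stable distribution functions (`pbinom`/`phyper` upper tails);
  values near `1e-300` do not underflow. Display formatting follows the
  field convention of printing values below `1e-16` as `<1.00E-16`
  (`format_pvalue()`), while the numeric value is retained. Note that
  evaluating the textbook `1 - sum(...)` form in double precision instead
  floors the achievable accuracy near `1e-16` by cancellation; published
  tables computed that way can disagree with the exact tail in the third
  significant figure at extreme values.
* TSV writers emit 17 significant digits, so write/read round trips
  reproduce doubles exactly.
* Missing expression values are a hard error, never imputed: a silently
  imputed value could flip an order indicator and corrupt every downstream
  vote. Duplicate gene rows must be collapsed explicitly
  (`collapse_duplicate_genes()`, `max_variance` keeps the most informative
  probe; `mean` averages) because probe summarisation is a modelling choice
  the user should make consciously.
* Expression and phenotype tables are joined by sample id, never by
  position; unmatched samples are dropped with a warning and fewer than two
  shared samples is an error.
* Cox convergence: score tolerance `1e-9`, at most 50 Newton iterations,
  separation flagged at `|beta| > 15`.

# Problem sizes used by the test-suite

Unit and acceptance tests run at deliberately modest sizes chosen to make
every statistical check sharp but quick: 2000-gene cell-line panels for
ranking/FDR behaviour, 200–500-sample tissue cohorts for coefficient and
signature recovery, 200-replicate null calibrations for the log-rank and
enrichment type-I error (asserted within [0.02, 0.09] at nominal 0.05), and
brute-force oracle comparisons (grid-search Cox, enumerated hypergeometric
draws, naive subset loops) on fixtures small enough to enumerate. The
pipeline integration fixture uses two 400-sample tissue cohorts, two 3v3
cell lines at planted consistency 0.9/0.5, and a 250-sample training cohort
with a planted two-pair signature at HR 4.

# Known limitations

* The exhaustive subset search is exponential; 20 rules (about a million
  combinations) is near the practical ceiling, and the greedy fallback has
  no optimality guarantee.
* Maximising the training C-index over all combinations overfits by
  construction; the honest performance estimate is the validation-cohort
  hazard ratio and log-rank test, never the training C-index.
* The concordance test treats genes as independent Bernoulli trials; genes
  co-regulated in both systems inflate the effective consistency.
* Marginal Cox screening inherits the usual caveats of univariate selection
  under correlated, polygenic survival structure (see the frailty note
  above).
* The vote rule weighs all pairs equally; no attempt is made to weight
  rules by effect size.
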