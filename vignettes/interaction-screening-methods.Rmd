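---
title: "Models and methods behind snpint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snpint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpint)
```

`snpint` screens pairs of SNPs for joint (epistatic) effects on a binary
disease outcome, validates them in split cohorts, and turns the qualified
pairs into a polygenic risk score. This vignette records the statistical
model, the parameters that matter, the behaviour of the synthetic-data
generator, and the numerical and design choices a maintainer should know
about.

## The pattern search

Every candidate model for a SNP pair is a logistic (or, for expression
traits, linear) regression of the outcome on covariates plus one to three
genotype-derived terms. The terms are built from per-SNP encodings — a
genotype is a minor-allele count $g \in \{0,1,2\}$, encoded additively
($g$), dominantly ($\mathbb{1}[g \ge 1]$) or recessively
($\mathbb{1}[g = 2]$), in the original direction or reversed
($2-g$ for additive, $1-x$ for the binary codes, i.e. the coding obtained
by swapping minor and major alleles) — and combined into one of four model
families:

| family   | terms                         |
|----------|-------------------------------|
| `Full`   | SNP1 + SNP2 + SNP1×SNP2       |
| `M1_int` | SNP1 + SNP1×SNP2              |
| `M2_int` | SNP2 + SNP1×SNP2              |
| `Int`    | SNP1×SNP2                     |

Not every (family × coding) combination is a distinct model: with an
intercept present, reversing a coding is an affine change of basis whenever
the matching main effect is in the model. `sipi_patterns()` therefore
enumerates the raw grid and collapses models whose design columns span the
same space on the exhaustive genotype grid, which leaves 9 patterns per
mode pair and hence 9 in the additive-additive scope and 45 in the full
scope (mode pairs AA, DD, DR, RD, RR). The counts are derived by the
collapse, not hard-coded, and the test suite re-verifies pairwise
non-equivalence by rank tests. Mixed additive–binary mode pairs (AD, DA,
AR, RA) are outside the searched family by design.

Per pair, every pattern in scope is fitted and the lowest-BIC model wins,
with BIC $= -2\ell + k\ln n$ counting all estimated parameters (intercept,
covariates, genotype terms, plus the residual variance under the linear
link). The pair's headline p-value is the Wald p of the winning pattern's
interaction term; for two-term patterns the main-effect p is reported as
well but the interaction term carries the headline. Exact BIC ties resolve
to the canonical order `Int` < `M1_int` < `M2_int` < `Full`, then
lexicographic label — ties essentially never occur on real data, but the
rule makes results order-independent.

## Screening workflow and thresholds

The screening defaults in `screen_config()` are the ones appropriate for a
candidate-pathway scan of several thousand SNPs:

* cohort split: half of the cases from each study site to discovery, half
  to validation (`split_cohort()`, balanced so global totals differ by at
  most the rounding of fractional site halves);
* stage 1: the 9-pattern additive screen on all candidate pairs in the
  discovery set, survivors at P < 0.001;
* stage 2: the 45-pattern search on survivors; the validation and combined
  sets are searched with the full scope directly, each set selecting its
  own best-BIC pattern (sets can and do disagree on the pattern while
  agreeing on the signal — both per-set results are kept);
* qualification: `validated` = P < 0.001 in both halves; `promising` =
  validated and combined P < 10⁻⁵; `bonferroni_significant` = combined P
  below 0.05 divided by the number of pairs tested; and
  `interaction_stronger` = combined interaction P below both constituent
  SNPs' individual-effect P (best single-SNP mode among A/D/R).

Combined-set analyses refit on the pooled cohort rather than meta-analysing
the halves, matching the single-OR reporting convention. Covariates — study
site as treatment-coded dummies plus six principal components — are always
in the model and never candidates for removal.

Genotype QC precedes all of this: SNPs are dropped for call rate < 95%,
call rate < 99% with MAF < 5%, MAF < 1%, or exact Hardy–Weinberg
P < 10⁻¹² (first failed rule recorded as the reason), and interaction
scans further restrict to MAF > 5% panels pruned so no same-chromosome
pair within 100 kb has genotype $r^2 > 0.8$. The Hardy–Weinberg test is
the exact conditional test (recurrence over heterozygote counts); LD is
squared genotype correlation, since no phase information is assumed. When
pruning finds an offending pair it keeps the more informative marker:
higher call rate, then higher MAF, then the smaller position.

## The interaction-based risk score

Qualified pairs are grouped into clusters keyed by hub SNPs (a hub is a SNP
recurring across many pairs); each pair is assigned to the cluster of its
higher-count member so the clusters partition the pairs. Within a cluster,
pairs are pruned so that no two retained interaction-coded vectors have
|Pearson r| ≥ 0.7 — the absolute value is used because an anticorrelated
near-duplicate is just as redundant in a joint model — keeping the smaller
combined-set p-value first. Stepwise selection (forward with backward
elimination at the same entry/stay level; candidates ordered by marginal p;
a pair's term block enters and leaves as a unit, judged by its interaction
term's Wald p) runs at P < 0.1 within clusters and at P < 0.01 or
P < 10⁻⁵ globally for the larger and smaller multi-pair models.

The risk score of `fit_prs()` is the genotype-only part of the joint
logistic linear predictor — covariates are excluded so the score is a
property of the genotype — min–max scaled to 0–100 on the training cohort.
Subjects are cut into 7 groups at the score percentiles
{1, 10, 25, 75, 90, 99}: top 1%, 1–10%, 10–25%, middle 50% (the reference
group for odds ratios), 75–90%, 90–99%, bottom 1%. The two interior
boundaries (10/25 and 75/90) interpolate between the named extreme groups
and the middle half; with scores built from a handful of discrete codings,
percentile boundaries can land on ties, in which case the affected groups
absorb the tied mass (degenerate all-equal scores are flagged rather than
grouped). AUCs are computed by the rank statistic, compared with the DeLong
test for correlated ROC curves (via pROC), and internally validated by a
subject-resampling percentile bootstrap (1000 draws by default).

## The synthetic-data generator

No individual-level genotype data of the scale this pipeline targets can be
shipped, so `sim_config()`/`simulate_genotypes()`/`simulate_phenotype()`
generate cohorts with the structure the analysis assumes:

* genotypes are sums of two independent haplotypes; within an LD block the
  haplotypes come from a latent multivariate normal whose pairwise
  correlation is solved numerically (Gaussian copula) so the genotype
  $r^2$ hits the block's target — this reaches arbitrary MAF/r² targets
  without a haplotype reference panel, and reports the feasible bound when
  a target is unreachable for the given MAFs;
* Hardy–Weinberg holds within each ancestry subpopulation; population
  structure is induced by subpopulation MAF offsets rather than injected
  PC scores, so `compute_pcs()` is exercised for real;
* the phenotype is Bernoulli with a logistic linear predictor combining
  per-site effects (drawn once from $N(0, \sigma_\text{site})$) and the
  configured true SNP and SNP-pair effects; the intercept is calibrated by
  root finding so the expected marginal prevalence equals the configured
  baseline — 22.6% by default, the aggressive-disease share of the cohort
  this design emulates;
* expression traits are the interaction coding times a slope plus Gaussian
  noise.

Default MAFs in the presets span 0.06–0.5, the range typical of the
candidate panels this workflow is used on, and the `klk3_like` preset wires
one hub SNP (MAF 0.12, an individual effect of OR 1.3) into six true pairs
with ORs 0.75–2.0 across interaction patterns and both coding directions —
the hub-and-spokes topology that interaction-based risk scores are built
from. What the generator deliberately does **not** emulate: realistic
recombination maps and long-range LD decay, genotyping batch effects,
imputation dosages, relatedness, or ascertainment. Passing tests on these
cohorts therefore demonstrate correctness of the statistical machinery
under the stated generative model, not robustness to every artefact of
real array data.

## Numerical choices

* Logistic fits use iteratively reweighted least squares capped at 100
  iterations (convergence tolerance 10⁻¹⁰, so fits agree with an
  independent Newton solver to well below the 10⁻⁸ relative tolerance the
  tests demand). Quasi-separation is flagged as non-convergence when any
  coefficient exceeds 15 on the logit scale; non-converged patterns are
  excluded from BIC selection. A pattern whose term columns are constant
  or aliased over complete cases — or with fewer complete cases than
  parameters plus ten — is "not evaluable", a distinct state from a failed
  fit, and a pair with no evaluable pattern is dropped with a signal
  rather than an error.
* Missing genotypes propagate through encodings and are handled by
  complete-case analysis per model fit; principal components mean-impute
  missing genotypes before the decomposition.
* Wald inference is used throughout (normal for logistic, t for linear),
  matching the convention of reporting per-term OR with 95% CI.
* All randomness (splits, simulations, bootstrap) flows through explicit
  integer seeds, and seeded code restores the caller's RNG state.

## Problem sizes used in the test suite

The statistical acceptance checks run at sizes chosen to make the
binomial/simulation bands tight while staying desk-scale: 2,000 null
replicates of n = 3,000 for type-I calibration of the conventional
additive full test (99% binomial band around 0.05); 200 replicates each for
pattern recovery (dominant–dominant interaction, OR 2.5, n = 5,000) and CI
coverage (additive reverse-original interaction, OR 1.29, n = 20,000); and
50 end-to-end replicates of the two-stage screen on n = 10,000 cohorts with
one true hub pair (OR 2.0) and 20 null pairs each, totalling 1,000 null
pairs for the false-discovery check.

## Known limitations

* The 45-pattern scope excludes mixed additive–binary mode pairs; if the
  truth is, say, additive-by-dominant, the search lands on the nearest
  pattern in scope (usually the right family with a binary approximation
  of the additive axis).
* BIC selection among nested and overlapping patterns is consistent but
  not unbiased at a fixed n; the headline p-value of the selected pattern
  inherits selection optimism, which is why qualification always requires
  independent replication in the validation half.
* Percentile risk groups assume a reasonably continuous score; scores
  built from one or two discrete codings produce collapsed boundaries (see
  above).
* The eQTL scan consumes the expression matrix as-is — normalisation and
  transformation are the caller's responsibility — and the Bonferroni
  denominator `n_tests` is an explicit input because the number of tests
  in a campaign is a study-design fact, not something inferable from one
  call.
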