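# snpint

Pairwise SNP–SNP interaction (epistasis) screening for binary disease
outcomes, and polygenic risk scores built from interaction terms rather than
individual SNP effects.

The package is aimed at genetic-epidemiology analyses of the kind used to
study prostate-cancer aggressiveness: a few thousand candidate-pathway SNPs,
a large case cohort with a binary endpoint (aggressive vs. non-aggressive
disease), study-site and principal-component covariates, and the question of
whether *pairs* of SNPs carry signal that their individual effects miss.

## The model search

The conventional epistasis test fits one logistic model per SNP pair — both
additive main effects plus their product (`AA_Full`):

```
logit P(y = 1) = α + β₁·SNP1 + β₂·SNP2 + β₃·SNP1×SNP2 + γ·covariates
```

That is the most complex interaction pattern (9 distinct risk groups) and is
underpowered when the true joint effect is simpler. `snpint` instead searches
a family of candidate patterns per pair and keeps the one with the lowest
BIC:

* **inheritance modes** per SNP: additive (A; coding 0/1/2), dominant (D;
  carrier indicator), recessive (R; minor-homozygote indicator),
* **coding directions**: original (counting the minor allele) or reverse,
* **model families**: `Full` (SNP1 + SNP2 + SNP1×SNP2), `M1_int`
  (SNP1 + SNP1×SNP2), `M2_int` (SNP2 + SNP1×SNP2), `Int` (SNP1×SNP2 only).

After collapsing models whose design columns span the same space, the
additive–additive scope contains **9 patterns** and the full scope over mode
pairs AA/DD/DR/RD/RR contains **45**. For two additive SNPs the product term
takes values {0, 1, 2, 4}; binary-mode `Int`/`M_int`/`Full` families induce
2/3/4 distinct risk groups. A two-stage workflow (additive 9-pattern screen
at P < 0.001, then the 45-pattern search; site-stratified
discovery/validation halves; Bonferroni and replication criteria) mirrors
how such scans are run at the 10⁷-pair scale.

On top of qualified pairs the package builds an interaction-based polygenic
risk score: hub-SNP clusters, correlated-pair pruning (|r| < 0.7 on the
interaction codings), within-cluster and global stepwise selection, a joint
logistic fit whose genotype-only linear predictor is rescaled to 0–100, and
seven percentile risk groups (top 1% … bottom 1%) compared by odds ratio
against the middle 50% and by AUC (DeLong test, bootstrap CI).

All of it runs on plain data structures: genotypes in a light `geno`
container (PLINK bed/bim/fam or a TSV dialect), everything else tibbles in /
tibbles out, with `tidy()`/`glance()` on fitted objects and `autoplot()` for
the 3×3 prevalence heat tables and risk-group prevalences.

## Worked example

Everything below is reproducible offline: the synthetic-data module
generates a cohort with the statistical structure the analysis assumes
(block LD via a Gaussian copula, site effects, a logistic phenotype
calibrated to 22.6% prevalence, configured true interaction pairs).

```r
library(snpint)
library(dplyr)

# a 10,000-subject cohort with one hub SNP in six true interaction pairs
cfg <- snpint:::fixture_presets("klk3_like", seed = 7)
g   <- simulate_genotypes(cfg)
ph  <- simulate_phenotype(g, cfg)
covars <- tibble::tibble(site = attr(g, "site")) |>
  bind_cols(compute_pcs(g, 6)[-1])

# scan one true pair and one null pair with the full 45-pattern search
pairs <- tibble::tibble(snp1 = c("snp20", "snp10"), snp2 = c("rs_hub", "snp30"))
interaction_scan(g, ph$y, pairs, covars, scope = "sipi")
#> # A tibble: 2 × 10
#>   snp1  snp2   pattern            p_int    bic n_used    or or.conf.low or.conf.high evaluable
#>   <chr> <chr>  <chr>              <dbl>  <dbl>  <int> <dbl>       <dbl>        <dbl> <lgl>
#> 1 snp20 rs_hub DD_M2_int_o2 0.000000144 10298.  10000  1.61        1.35         1.93 TRUE
#> 2 snp10 snp30  AA_int_rr    0.0249      10779.  10000  1.05        1.01         1.09 TRUE
```

The true pair (generated under a dominant–dominant interaction-only model)
is flagged at P = 1.4×10⁻⁷ with a closely related dominant-mode pattern —
BIC selection can land on a neighbouring pattern of the same shape — while
the null pair's best of 45 patterns sits at P = 0.02, far from any
screening threshold.

```r
# risk score from the six generating pairs, seven percentile groups
m  <- fit_prs(ph$y, g, mutate(cfg$true_pairs, p_combined = 1e-8), covars)
group_prevalence(m$training$group, ph$y)
#> # A tibble: 7 × 3
#>   group     n prevalence
#>   <fct> <int>      <dbl>
#> 1 1        89     0.0112
#> 2 2       738     0.0678
#> 3 3       794     0.101
#> 4 4      5309     0.178
#> 5 5      1778     0.326
#> 6 6      1192     0.477
#> 7 7       100     0.680
```

Aggressiveness prevalence climbs monotonically from 1% in the lowest-score
group to 68% in the top group (the cohort-wide prevalence is 22.6%); the
corresponding group odds ratios against the middle-50% reference run from
0.05 to 9.5, and the score's AUC is 0.71.

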