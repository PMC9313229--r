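# pairsurv

Prognostic gene-**pair** discovery from single-sample differential
correlation networks, for mutation-stratified tumor cohorts.

## The problem

Most prognostic-biomarker searches rank single genes by differential
expression. But the co-expression *relationship* between two genes can
carry prognostic information that neither gene carries alone: a tumor in
which a normally tight gene–gene correlation is broken may behave
differently from one in which it is intact. `pairsurv` implements a
pipeline that quantifies, per patient, how much each gene pair's
correlation is perturbed, and then asks whether that perturbation
stratifies survival. It was designed for TP53-stratified breast-cancer
cohorts (a wild-type group and a somatic-mutation group analyzed
separately against a normal-tissue reference panel) but is agnostic about
the grouping variable.

## The statistic

For genes *i*, *j* and a normal reference panel of *n* samples, the
package computes the Pearson correlation `PCC_n(x_i, x_j)` over the
panel, then re-computes it with **one** tumor sample appended:

```
ΔPCC(x_i, x_j) = | PCC_{n+1}(x_i, x_j) − PCC_n(x_i, x_j) |
```

A patient whose expression conforms to normal co-expression structure
leaves the correlation essentially unchanged; a sample that breaks the
relationship produces a large ΔPCC. A pair is retained for analysis when,
for at least one patient, (1) the panel correlation is significant
(p < α), (2) the augmented correlation is still significant, and (3) the
two differ significantly (Fisher r-to-z). Retained pairs are further
filtered to those whose mean ΔPCC exceeds the grand mean, then each pair
stratifies the group's patients into Large/Small ΔPCC clusters
(exact minimum within-cluster-variance 2-partition); the clusters are
compared by the log-rank test (BH-corrected per group) and a univariate
Cox proportional-hazards model (Efron ties) giving hazard ratio, Wald p,
and Harrell's concordance. Finally each group gets a signed, weighted
gene correlation network whose nodes carry per-gene prognostic
annotations, and the two networks are compared edge-by-edge (including
pairs with *opposite* correlation signs in the two groups).

Everything runs offline: a seeded synthetic-cohort generator plants
perturbed pairs and survival effects with known truth, so the whole
pipeline is testable without controlled-access clinical data.

## Worked example

```r
library(pairsurv)

cohort <- make_benchmark_cohort("small", seed = 1)   # 40 genes, 60+60 patients
groups <- split_cohort(cohort$clinical)
surv   <- derive_survival(cohort$clinical)

delta <- build_delta_matrix(cohort$reference, cohort$tumor[, groups$mut_ids],
                            group_label = "mTP53")
sel   <- select_pairs(delta, alpha = 0.05)
sel   <- average_delta_filter(delta, sel)
results <- rank_pairs(delta, surv, pairs = sel)
results[, 1:9]
#> # A tibble: 5 × 9
#>   pair      n_large n_small   logrank_p   adj_p hazard_ratio   cox_p concordance
#>   <chr>       <int>   <int>       <dbl>   <dbl>        <dbl>   <dbl>       <dbl>
#> 1 G001_G002      18      42     5.57e-8 2.79e-7        5.68  1.02e-6       0.658
#> 2 G002_G003      11      49     1.79e-1 2.99e-1        1.61  1.82e-1       0.547
#> 3 G002_G004      24      36     1.25e-1 2.99e-1        1.56  1.28e-1       0.586
#> 4 G001_G003      18      42     8.81e-1 8.81e-1        0.952 8.80e-1       0.480
#> 5 G003_G004      18      42     8.65e-1 8.81e-1        0.946 8.64e-1       0.480
```

The generator planted a perturbation in pair `G001_G002` for 18 of the 60
mutated-group patients and gave that stratum a 6-fold hazard. The ranking
recovers exactly those 18 patients as the Large-ΔPCC cluster, with an
estimated hazard ratio of 5.68 and a BH-adjusted log-rank p of 2.8e-7;
every other tested pair is null. `n_large + n_small` always equals the
group size (60).

```r
gcn <- build_gcn(cohort$tumor[, groups$mut_ids], sel, surv, group_label = "mTP53")
gcn
#> <gcn mTP53> 4 genes, 6 edges (2 positive / 4 negative)
export_graphml(gcn, "gcn_mut.graphml")   # round-trips via import_graphml()
```

The staged pipeline (`pipeline_simulate()` → `pipeline_select()` →
`pipeline_survival()` → `pipeline_gcn()` → `pipeline_compare()` →
`pipeline_diffexpr()`) writes each stage's artifact plus a JSON manifest;
`inst/cli/pairsurv.R` wraps the stages for shell use:

```sh
Rscript inst/cli/pairsurv.R all --dir out --seed 3
```

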