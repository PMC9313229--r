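---
title: "Methods: single-sample differential correlation and gene-pair survival ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sample differential correlation and gene-pair survival ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsurv)
```

## The model

`pairsurv` treats a gene pair, not a gene, as the unit of prognostic
analysis. The pipeline has four stages, run separately for each patient
group (e.g. wild-type vs mutated TP53):

1. **Single-sample perturbation.** For each pair of core genes, the
   Pearson correlation is computed over a normal reference panel of $n$
   samples, and again with one tumor sample appended. The absolute
   difference, $\Delta PCC = |PCC_{n+1} - PCC_n|$, measures how strongly
   that one patient breaks the normal co-expression relationship. Because
   one point among $n$ can move a correlation only through leverage, an
   informative $\Delta PCC$ means the patient is a genuine outlier
   relative to the panel's bivariate structure, not merely noisy.

2. **Pair selection.** A (patient, pair) combination counts as perturbed
   when three conditions hold at level $\alpha$: the panel correlation is
   significant; the augmented ($n+1$) correlation is still significant;
   and the two differ significantly by the Fisher r-to-z comparison. A
   pair is retained when at least one patient perturbs it. Retained pairs
   are then filtered to those whose per-pair mean $\Delta PCC$ strictly
   exceeds the grand mean of all (patient, pair) entries.

3. **Survival ranking.** Each retained pair partitions the group's
   patients into a Large and a Small $\Delta PCC$ cluster. The two
   clusters' overall survival is compared by the log-rank test, with
   Benjamini–Hochberg adjustment across all pairs tested in the group,
   and by a univariate Cox proportional-hazards model on the
   Large-cluster indicator (hazard ratio, Wald p, Harrell's concordance).

4. **Enriched networks.** Each group's retained pairs form a gene
   correlation network: edge weight is the group-level correlation with
   its sign and p-value; each node carries a prognostic annotation from a
   per-gene continuous-covariate Cox fit (`favorable` / `unfavorable` /
   `none`) plus that model's concordance. The two groups' networks are
   compared edge-by-edge; a *sign flip* is reported only when both edges
   are individually significant, since a flip between two noise-level
   correlations is not a finding.

Assumptions: expression is on a roughly Gaussian, log-like scale (Pearson
correlation and the $t$-based p-values are calibrated for that);
survival is right-censored with proportional hazards between clusters;
the reference panel is homogeneous, so a large $\Delta PCC$ reflects the
patient, not panel substructure.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `alpha` | 0.05 | level for all three selection criteria, edge significance, and prognostic-type calls |
| reference panel size | 100 | drives both the precision of $PCC_n$ and the leverage a single sample can exert; 100 is the panel size the selection criteria were calibrated for |
| `min_cluster` | 5 | smallest cluster allowed into the log-rank/Cox stage; survival tests on near-singleton clusters are unstable |
| `fc_threshold` | 1 (log2) | differential-expression gate: "more than twice in one group than the other" |
| `correlation_kind` | pearson | `spearman` substitutes rank correlation throughout (same $t$ p-value form) |
| `subsample_fraction`, `subsample_repeats` | 0.9, 3 | robustness screen: re-rank on random 90% subsets and count how often top pairs stay significant under BH log-rank < 0.05 and Cox p < 1e-4 |

The three selection criteria share a single raw `alpha` per (patient,
pair); no multiplicity control is applied *within* the selection step
(the multiplicity burden is carried by the BH family in the ranking
step). The BH family is all pairs tested within one group; the two
groups are separate families because they are analyzed separately.

## Numerical choices

* **Stratification is the exact Ward-criterion split.** The clustering
  feature is the patients' scalar $\Delta PCC$ for the pair (the quantity
  the Large/Small columns of the result tables summarize). For scalar
  data the optimal two-cluster partition under the within-cluster
  sum-of-squares (Ward) criterion is contiguous in sorted order, so the
  package finds it exactly by scanning the $n-1$ cut points with
  cumulative sums. Greedy agglomerative Ward (as in `hclust`) was
  rejected: its top-level split disagrees with the optimal partition on a
  substantial fraction of unstructured inputs, and an exact optimum is
  deterministic by construction. Ties between cut points resolve to the
  smallest cut; patients are pre-sorted by (value, sample id), so the
  result is independent of input order. All-identical values are
  degenerate and the pair is skipped with a recorded reason.
* **Fisher independent-groups z.** Criterion 3 compares $PCC_n$ and
  $PCC_{n+1}$ with the independent-samples r-to-z test even though the
  two samples overlap in $n$ points. The overlap makes the test slightly
  conservative for detecting the added sample's effect; the choice is
  recorded in the delta-matrix sidecar metadata, and overlap-corrected
  variants are an extension hook.
* **BH with step-up enforcement.** The adjusted value is the running
  minimum (from the largest rank down) of $\min(1, p_{(j)} m / j)$ —
  i.e. `stats::p.adjust(method = "BH")`. The plain $\min(1, pm/j)$ map
  alone can produce a non-monotone adjusted sequence; the running minimum
  is an intentional strengthening.
* **Cox fits** use the Efron approximation for ties (day-resolution
  survival times tie heavily), convergence tolerance 1e-9, at most 100
  Newton iterations. A monotone partial likelihood (complete separation)
  is reported as an infinite hazard ratio with an explicit flag rather
  than the meaningless capped coefficient.
* **p-values for correlations** come from the exact $t$ transform
  $r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df; $|r| = 1$ maps to $p = 0$.
  Zero-variance genes give undefined correlations: the scalar operations
  error, the matrix builders record `NA` entries with a count.
* **Duplicate gene symbols** on input collapse to the highest-mean row
  (deterministic and logged); expression is taken as already normalized,
  with an explicit opt-in `log2(x+1)` flag, because correlation is
  scale-sensitive and a silent transform would be unauditable.
* Patients with missing or zero survival time are dropped and counted:
  zero-length follow-up is uninformative and breaks partial-likelihood
  tie handling.

## What the synthetic generator emulates — and what it does not

`simulate_expression()` draws the reference panel and both tumor groups
from a multivariate normal with block-equicorrelated structure (Gaussian
sampling is the law under which the Pearson coefficient is the natural
dependence parameter, matching the pipeline's own assumptions).
`simulate_survival()` draws exponential event times whose hazard is
multiplied for patients in a planted pair's perturbed stratum, with
administrative censoring at a horizon (default 3650 days) plus uniform
early dropout (default probability 0.2); baseline hazard 5e-4/day puts
median survival near 3.8 years, a realistic order for breast-cancer
overall survival. Exponential hazards make the planted multiplier
exactly the quantity the Cox model estimates.

**Planting perturbed pairs.** The three selection criteria define a
*detection band* for the augmented correlation, in atanh space: it must
stay above the significance floor (criterion 2) yet sit at least a
Fisher-z margin below the panel correlation (criterion 3). Two
consequences drove the design. First, a perturbed patient must be a
controlled high-leverage point: affected patients get their pair values
displaced against the pair's co-expression direction, with the radius
computed from the *realized* panel correlation so the induced augmented
correlation lands inside the band (the requested magnitude is clamped to
the band; a relative jitter, default 0.15, scatters patients around the
calibrated displacement). Random draws from a weakly-correlated law do
not work: most land concordant with the panel and extreme ones overshoot
below the significance floor. Second, the band is empty unless the panel
correlation clears a size-dependent floor — about 0.60 for a 50-sample
panel, about 0.45 for 100 — so the `small` preset places its planted
blocks at r = 0.85/0.80/0.75, comfortably above the floor its
deliberately small panel imposes, while `paper_shaped` (100-sample
panel) uses 0.75/0.70/0.65. The generator warns when asked to plant in
a pair whose realized panel correlation is below the floor.

Each planted pair perturbs a random subset (`affected_fraction`,
default 0.3) of its group — the headline use case finds Large clusters
that are small minorities of the cohort, so perturbing everyone would be
the wrong shape. All draws come from one master seed via fixed named
substreams (expression / affected-set / perturbation / survival /
dropout), so components regenerate independently and presets with the
same seed use disjoint streams.

The generator does **not** emulate RNA-seq count noise, batch effects,
normalization artifacts, subtype-specific expression programs, or
non-proportional hazards. Passing tests therefore demonstrate that the
statistics are computed correctly and that the pipeline recovers planted
effects of realistic size under its own model assumptions — not that
real cohorts satisfy those assumptions.

## Problem sizes

The test suite and acceptance script run the `small` preset (40 genes =
780 pairs, 50-sample panel, 60+60 patients) for end-to-end checks —
seconds per run — with 20 seeds for planted-pair recovery, 50 seeds per
true hazard ratio for Cox CI coverage, 500 stratify-then-log-rank
replicates for null calibration of the per-pair test, and 10 null
cohorts for the BH-level calibration. The `paper_shaped` preset (129
genes, 124+65 patients, 100-sample panel) reproduces the shape of a
real TP53-stratified cohort at one quarter scale for heavier manual
runs.

## Known limitations

* Criterion 3 ignores the $n$-point overlap between the compared
  samples (see above); its `alpha` is raw, per pair.
* The average-$\Delta PCC$ filter compares per-pair means against the
  grand mean over retained pairs — chosen because downstream ranking is
  per pair; a per-patient reading of the same filter would keep a
  different set. Strict inequality means a degenerate group in which
  every pair has the same mean retains nothing.
* Node-level concordance in the enriched network is the per-gene Cox
  model's Harrell C, not a pair-level quantity.
* Correlation-based selection inherits Pearson's sensitivity to single
  outliers — which is also precisely the leverage the method exploits;
  the Spearman option and the subsample robustness screen are the
  built-in checks on that sensitivity.
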