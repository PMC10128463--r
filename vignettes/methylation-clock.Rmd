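---
title: "Methylome landscapes and an elastic-net epigenetic clock from CGmap calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome landscapes and an elastic-net epigenetic clock from CGmap calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methage)
```

## The problem this package addresses

Vertebrate genomes are methylated almost exclusively at CpG dinucleotides,
and the methylation landscape changes with age: global CpG methylation
drifts slowly downward, a minority of sites gain methylation, and a small
set of strongly age-associated positions is informative enough to predict
chronological age with a penalized linear model — an *epigenetic clock*.
`methage` implements the full desk-side analysis path for such a study in
a short-lived model frog (*Xenopus tropicalis*) or any organism with
per-cytosine bisulfite calls:

1. **IO** — CGmap files (8-column per-cytosine calls), sample sheets,
   GFF3/GFF annotation, BED target regions.
2. **Matrix building** — "common sites": a CpG enters the matrix only if
   its read coverage passes a floor in *every* sample.
3. **Methylome descriptors** — per-context means, level distributions,
   500-kb chromosome tracks, pooled-group Kolmogorov–Smirnov comparisons,
   autocorrelation over the k nearest CpG neighbors.
4. **Feature profiles** — metagene and repeat-body methylation with scaled
   body deciles and fixed-width flanks.
5. **Age association** — per-site Pearson correlation with age and one-way
   ANOVA across age groups, Benjamini–Hochberg adjustment, rank-sum
   selection, collapse of selected sites into capture regions for targeted
   re-sequencing, and nearest-element annotation.
6. **The clock** — elastic-net regression of age on methylation levels
   with leave-one-out cross-validation (LOOCV), grid search, and
   cross-fold feature-union reporting.
7. **Cohort structure** — PCA with low-variance filtering, Spearman sample
   clustering, top-variable-site clustering.
8. **Synthetic cohorts** — a generator that emits CGmap files with known
   ground truth, so every stage above is validated end to end without any
   sequencing data.

## The clock model

For ages $y \in \mathbb{R}^n$ and a samples-by-sites level matrix
$X \in [0,1]^{n\times p}$, `enet_fit()` minimizes

$$
\frac{1}{2n}\lVert y - b\mathbf{1} - Xw \rVert_2^2
  + \alpha\,\lambda_1 \lVert w \rVert_1
  + \tfrac{1}{2}\,\alpha\,(1-\lambda_1)\lVert w \rVert_2^2 ,
$$

with unpenalized intercept $b$. **The loss carries a $1/(2n)$ factor**, so
$\alpha$ is only meaningful relative to that convention (it is the
scikit-learn `ElasticNet` convention; `glmnet`'s `lambda` coincides when
neither the features nor the response are standardized). The shipped
default is $\alpha = 0.00283693$, $\lambda_1 = 0.5$ — hyperparameters of
the published frog clock, reproducible here with
`grid_search_hyperparams()`, which scores every grid pair by LOOCV mean
squared error and breaks exact ties toward the sparser model (larger
$\alpha$, then larger $\lambda_1$).

Features enter as raw methylation fractions. Levels already share the
$[0,1]$ scale, and the source analysis gives no indication of feature
scaling, so `standardize = FALSE` is the default; a switch exists because
the L1 penalty is not scale-invariant and users porting coefficients
should know which convention they are in.

The solver is cyclic coordinate descent with exact per-coordinate
minimization and a fixed feature order, so a fit is a deterministic,
bit-reproducible function of its inputs. Convergence is declared when the
largest coefficient update in a sweep, relative to the largest coefficient
magnitude, falls below `tol` (default `1e-4`, the scikit-learn tolerance
scale; at the small default $\alpha$ on correlated methylation features a
much tighter absolute rule would spend tens of thousands of extra sweeps
on changes far below the noise floor of the data). The limit cases are
tested against closed forms: $\alpha \to 0$ equals OLS, $\alpha \to
\infty$ gives the null model, and the one-feature fit equals the
soft-threshold solution
$w = S(\widetilde{xy}, \alpha\lambda_1) / (\widetilde{xx} +
\alpha(1-\lambda_1))$ with $1/n$-scaled centered moments.

`loocv_clock()` fits $n$ models, each predicting its held-out sample, and
reports **both** $R^2$ readings: the squared Pearson correlation between
predicted and actual age (the reading usually quoted for clock scatter
plots) and the coefficient of determination $1-\mathrm{SS_{res}}
/\mathrm{SS_{tot}}$, which is lower whenever predictions are biased —
young samples overestimated, old underestimated, the classic compression
of a regularized clock. MAE is in years. The *feature union* — every site
with nonzero weight in at least one fold, with its fold count — is the
interface to `feature_overlap()`, which partitions those sites by
capture-region membership (point-in-interval on 0-based half-open
regions).

## Age-association selection

`site_age_stats()` computes, per site, the Pearson correlation with
numeric age (two-sided t test on $n-2$ df) and the one-way ANOVA F across
age-group labels, vectorized over sites; the unit tests pin both to
`cor.test()` and `anova(lm())` per site at `1e-10`. Correlation is against
age in years, not group index. Zero-variance sites have no defined
correlation: they are flagged, reported as `NA`, and never ranked.

Both p-value vectors are BH-adjusted. Because the analysis says only
"ranked by correlation and ANOVA adjusted p-values", a concrete,
deterministic rule is needed: each site receives a rank under each
criterion (ties within equal adjusted p broken by raw p, then genomic
order) and `combined_rank` is the **rank sum** — a site best on both
criteria scores 2. The `top_n` smallest rank sums are selected (default
4500, the probe-design budget of the source study). The rank sum treats
the two criteria symmetrically; an intersection or a single-criterion rule
would be equally consistent with the published wording, and the choice is
surfaced here rather than buried.

`collapse_to_regions()` merges selected sites closer than `merge_gap_bp`
(default 200) and pads each region by `pad_bp` (default 60), re-merging
any overlap the padding creates, so the output is a non-overlapping BED
ready for probe design. The two defaults are not inferable from the
published analysis (which reports ~3400 regions from 4500 sites, i.e.
~0.75 regions per site); they were fixed once so that the default
synthetic cohort reproduces that ratio and are plainly exposed as
parameters. `annotate_nearest_element()` reports **all** equidistant
nearest elements (the `-t all` semantics of `bedtools closest`), with
distance 0 inside an element and otherwise the bp gap to the nearest
contained base.

## Methylome descriptors: conventions that matter

* **Context means** (`context_means()`) are unweighted means of per-site
  levels, in percent, per dinucleotide (CpG/CpA/CpC/CpT) — not
  read-weighted, matching the convention of CGmapTools summary tables.
* **Common matrix**: "common" means passing the floor in *all* samples.
  An any-k-of-n relaxation exists (`min_samples`) but is off by default.
  The floor is `>=` by default; `strict = TRUE` switches to `>`, covering
  the "more than 100 reads" reading of targeted panels, where the
  difference is immaterial at 100x but should be the user's call.
* **Pooling** (`pool_group()`) sums methylated and total counts per site
  and recomputes the level — the count-level equivalent of merging a
  group's alignments and re-calling. Pooling *levels* instead would weight
  a 2-read site as heavily as a 200-read site.
* **KS comparison** uses the asymptotic two-sample p-value; at the site
  counts of pooled methylomes an exact computation changes nothing.
* **Neighbor autocorrelation** is over the k-th *closest* CpG in genomic
  order, not a fixed bp offset, pooled across chromosomes, never across
  them; lags with fewer than 3 pairs or zero variance are `NA`, so a
  constant methylome reports missing, not spuriously perfect,
  correlation.
* **Strand handling**: CGmap reports reverse-strand cytosines at their own
  position (`base = "G"`); the pipeline treats every reported position as
  its own site and never merges symmetric CpG dyads by default, so site
  counts match per-position conventions. `merge_cpg_strands()` is the
  explicit opt-in.
* All internal intervals are 0-based half-open; CGmap positions are
  1-based points; the IO layer is the only place the conventions meet.

## The metagene profile

Each site inside an element maps to the decile of its fractional position
along the element, measured 5' to 3' (strand-aware; unstranded repeats are
profiled as `+`, which is immaterial for their aggregate, symmetric
profile). Flanks are 2000 bp in 200-bp bins, genomic, and deliberately not
masked against neighboring elements. A site in two overlapping elements
contributes one observation per element — documented behavior, tested
against a brute-force incidence count. Body resolution of 10 bins is the
decile convention; repeat-body profiles use `min_element_length = 1000` to
restrict to repeats longer than 1 kb.

## The synthetic cohort generator

`sim_config()` defines the study conditions; `simulate_cohort()` emits
CGmap files, a sample sheet and a JSON truth file, byte-identical for
identical seeds. Defaults mirror the whole-genome study design:

| parameter | default | what it encodes |
|---|---|---|
| ages | 1, 5, 9 years x 3 replicates | the 3x3 cohort design |
| baseline mixture | 70% high (>0.8), 3% low (<0.05), rest spread | the bimodal vertebrate CpG landscape ("~70% of sites above 80% methylation, ~3% below 5%") |
| `fraction_drift` | 0.04 (200 of 5000 sites) | planted age-associated positions |
| slope magnitude | 0.08–0.14 per year, 84% negative | strong age-DMPs, majority losing methylation |
| `drift_pair_fraction` | 0.5 | half the drift sites sit in <200 bp pairs drifting coherently, as age-DMRs span neighboring CpGs; gives ~0.75 capture regions per selected site |
| coverage | negative binomial, mean 12, size 20, floored at 1 | a 9–15x whole-genome run with realistic site-level dispersion |
| `noise_sd` | 0.03 | biological noise on the latent level (natural scale) |
| `rho_by_group` | young 0.7 > mid 0.5 > old 0.3 | AR(1) spatial correlation of the noise field, decaying with age |
| non-CpG level | Beta(1, 199), mean 0.005 | near-zero CpH methylation |

Per site and sample the latent level is `clamp(baseline + slope * age +
AR(1) noise, 0, 1)`; the observed call is `Binomial(coverage, latent)`.
Drift sites receive baselines with room to move (0.75–0.95 for falling
sites, 0.05–0.30 for rising ones). The slope range was fixed a priori by a
power analysis: at 12x coverage the binomial noise on a single site is
roughly 0.10 sd, so a slope of ~0.1/year gives planted sites an expected
|r| of ~0.93–0.96 across the 8-year design — clearly detectable, as the
sites a capture panel targets must be. `sim_config_tbseq()` is the
targeted-sequencing preset: 16 samples over nine ages from 2.3 to 10.9
years at mean 300x on a small panel.

Two generator modes serve different validations. The default `"bimodal"`
mode produces realistic landscapes; its spatial correlation is mild
because the i.i.d. bimodal baseline dominates the variance. The `"ar1"`
mode makes the AR(1) field the only variance source, so the lag-k
autocorrelation has the closed form $\rho^k$ — the oracle used to validate
`neighbor_autocorrelation()`, including the ordering property that lower
$\rho$ lowers every lag (the young > mid > old pattern).

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: bisulfite conversion failure, mapping
bias, batch effects, nonlinear (logistic-like) age trajectories, CpG
islands and other large-scale covariance structure beyond AR(1), and
coverage that varies systematically with GC content. Results on synthetic
cohorts validate the *computations*, not the biology.

## Parameter-recovery checks and their definitions

On the default cohort (seed fixed), the acceptance suite asserts:

* the top-200 rank-sum selection recovers at least 90% of the planted
  sites **present in the 3x common matrix**, and separately that at least
  180 of the 200 planted sites are present. The conditioning matters: at
  12x mean coverage about 3% of sites randomly miss a 3x floor in at
  least one of nine samples, and a site absent from the matrix is
  invisible to any selection rule — recovery measures the selection, not
  the sequencing. The retention assertion keeps the definition honest.
* the LOOCV clock at the default hyperparameters reaches MAE <= 1.5 years
  and squared-Pearson R^2 >= 0.8;
* PC1 of the 5x matrix (after dropping the lowest-variance 10% of sites,
  the `removeVar = 0.1` convention) has the largest age correlation of
  all components;
* KS on two same-distribution groups rejects at ~5% over 200 replicates;
* the metagene profile recovers a planted promoter dip; pooled CpG means
  fall Young > Mid > Old;
* two runs from one seed are byte-identical end to end.

Problem sizes (5000 CpG sites, 9 samples, 200 replicates for the KS
calibration) keep the whole validation in the tens of seconds while
leaving every statistic comfortably inside its asymptotic regime.

## Numerical and design choices

* **PCA**: centering on, scaling off (the PCAtools-style default);
  zero-variance sites always dropped, then the lowest-variance fraction
  (`remove_var_fraction`, default 0.1); deterministic sign convention
  (largest-magnitude loading positive per component). With n samples the
  last component is numerically null and is reported with its near-zero
  variance share.
* **Sample clustering**: Spearman correlation (invariant to monotone
  per-sample transforms), distance `1 - cor`, complete linkage. Site
  clustering uses Euclidean distance on level vectors — the published
  analysis names only the linkage; Euclidean keeps rising and falling
  clusters apart by magnitude, and the choice is documented rather than
  implied. `k = 5` matches the published site-cluster display.
* **BH adjustment** delegates to `p.adjust`; `NA` (zero-variance) sites
  stay `NA` and do not consume rank positions.
* **Degenerate inputs** fail loudly and early: constant ages, constant
  sample columns, empty level vectors, zero-length elements and
  `start >= end` intervals are validation errors; an impossible coverage
  floor returns an *empty matrix with a warning* because an empty
  intersection is a legitimate (if disappointing) result of a floor, not
  a programming error.
* **Determinism**: the only stochastic component is the generator, seeded
  once from its config; the pipeline proper is a pure function of its
  inputs, which is what makes the byte-identity acceptance check
  possible.

## Known limitations

* The clock is a proof-of-principle n = 9 instrument: LOOCV folds share
  all but one sample, so fold models are highly correlated and the
  feature union (~100–300 sites) overstates the stability of any single
  fold's support.
* No imputation: a site missing the floor in one sample is dropped
  genome-wide rather than smoothed (beta-binomial shrinkage is out of
  scope).
* `region_mean_coverage()` measures depth at CpG sites inside regions,
  which tracks — but is not identical to — per-base depth averaging over
  all positions.
* Chromosome-name matching is exact string equality; no alias table.
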