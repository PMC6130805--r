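---
title: "Polygenic risk scores for psychosis cohorts: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk scores for psychosis cohorts: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`psyprs` implements the pruning-and-thresholding (P+T) polygenic risk score
workflow used in psychiatric genetics to ask whether the common-variant
signal for schizophrenia or bipolar disorder discriminates cases, their
unaffected first-degree relatives, and screened controls. The package
covers the full path from raw inputs to the reported statistics:

1. **Inputs** — discovery GWAS summary statistics (variant, effect allele,
   odds ratio, P-value), target-cohort hard-call genotypes (PLINK
   bed/bim/fam or VCF), and a phenotype table (case / relative / control,
   DSM diagnosis subgroup, centre of ascertainment).
2. **Variant QC and structure** — minor-allele-frequency and
   Hardy–Weinberg filters plus windowed LD pruning select a
   near-independent SNP set; PCA on that set yields ancestry covariates.
3. **Scoring** — discovery effects are allele-harmonised onto the target,
   variants passing each of ten P-value thresholds (after LD pruning) are
   summed as dosage × log(OR).
4. **Evaluation** — covariate-adjusted logistic regression, Nagelkerke
   pseudo-R², full/reference AUC, and decile odds ratios on
   control-anchored Z-standardised scores.
5. **Synthetic data** — a liability-threshold simulator generates all of
   the above from scratch, so every stage is testable without access to
   consortium data.

# The scoring model

For individual $i$ and selected variant set $S(p_T)$, the raw score is

$$\mathrm{PRS}_i(p_T) \;=\; \sum_{j \in S(p_T)} g_{ij}\,\hat\beta_j,$$

where $g_{ij} \in \{0,1,2\}$ counts copies of the discovery effect allele
after harmonisation and $\hat\beta_j = \log \widehat{OR}_j$. The selection
$S(p_T)$ contains the variants that (i) survived LD pruning and (ii) have
discovery $p_j \le p_T$. The default threshold ladder is
$5\times10^{-8}, 10^{-6}, 10^{-4}, 10^{-3}, 0.01, 0.05, 0.1, 0.2, 0.5, 1$.

Decisions a user may want to revisit, with their defaults:

* **Threshold comparison is inclusive** ($p \le p_T$). Method sections in
  this literature write the thresholds both as strict and as bare cut
  points; the choice only matters for variants exactly at a boundary and is
  configurable (`inclusive = FALSE`).
* **Variant matching is by identifier**, with a `chrom:pos` fallback behind
  `match_by = "pos"`, because consortium tables and chip data share rsIDs.
* **Strand policy**: alleles are matched directly, as swapped, or after
  complementing both target alleles. Palindromic A/T and C/G variants
  cannot be resolved without allele-frequency comparison, which is out of
  scope, so they are dropped by default (`drop_palindromic = TRUE`).
* **Missing calls are mean-imputed** as $2f_j$ (twice the target
  risk-allele frequency), so a fully missing individual scores at the
  cohort-mean contribution. The alternative (`missing_policy =
  "observed"`) rescales each individual's observed sum instead.
* **LD pruning for scoring reuses the PCA pruning parameters**
  ($r^2 < 0.2$, 1500-SNP window, 150-SNP shift) because no separate values
  are established for the scoring stage; both are configurable through
  `qc_thresholds()`. The scoring pool applies no MAF floor — the 10% MAF
  filter belongs to the PCA SNP selection only.

# QC and population structure

`apply_qc()` removes variants with minor allele frequency below 10% or a
1-df Hardy–Weinberg goodness-of-fit P below $10^{-3}$ (computed on all
samples by default; the chi-square compares observed genotype counts with
$p^2, 2pq, q^2$ expectations). `ld_prune()` slides a 1500-variant window by
150 variants over the (chrom, pos)-sorted list and, within each window,
removes one member of every pair with squared dosage correlation
$\ge 0.2$. Where the original tooling's removal choice is unknowable, the
invariant treated as normative is that **no surviving within-window pair
reaches the threshold**; the member removed here is the one with the lower
MAF (ties: later file order), which keeps the procedure deterministic and
idempotent. Pairwise $r^2$ uses pairwise-complete observations, and a
zero-variance overlap counts as unlinked.

`pca_genotypes()` follows the classic ancestry-PCA standardisation: mean
imputation of missing calls, centring by $2f_j$ and scaling by
$\sqrt{2f_j(1-f_j)}$, then top-$k$ left singular vectors (default
$k = 3$, the usual number of ancestry covariates). Signs are fixed so each
component's largest-magnitude entry is positive, which makes results
reproducible across BLAS implementations.

# Evaluation

For each threshold, `evaluate_contrast()` fits

* full model: `group ~ PRS + PC1 + PC2 + PC3 + centre`,
* reference model: `group ~ PC1 + PC2 + PC3 + centre`,

by IRLS (`stats::glm`, relative tolerance $10^{-8}$, 100 iterations) and
reports the PRS coefficient's Wald P, Nagelkerke's pseudo-R²

$$R^2_{N} \;=\; \frac{1 - \exp\!\big(-\tfrac{2}{n}(\ell_{full} - \ell_{ref})\big)}
                   {1 - \exp\!\big(\tfrac{2}{n}\ell_{ref}\big)},$$

and the in-sample AUC of both models' fitted probabilities. The AUC is the
rank-based Mann–Whitney statistic with ties counted one half — exactly the
probability that a random case outranks a random control. Notes:

* AUC is **in-sample**, matching the full/reference comparison convention;
  no cross-validation is attempted, so absolute AUCs are optimistic. This
  is a documented limitation, not an oversight.
* Centre indicators are treated with the first centre as reference level;
  single-centre cohorts drop the covariate.
* No multiple-testing correction is applied across the ten thresholds;
  per-threshold P-values are reported as is.
* Separated or non-converged fits are flagged and propagate a warning
  rather than an error, because strong planted effects legitimately push
  fits toward the boundary.

**Z-standardisation** uses the mean and (n−1) standard deviation of the
*controls of each centre*, so a control population anchors the scale in
every centre. A score column that is constant across the whole cohort
(no variant passed a stringent threshold) is set to zero with a warning.

**Decile analysis** allocates the combined two-group sample to deciles of
the Z-standardised score by rank (ties broken by stable sample order, so
decile sizes are as equal as $n \bmod 10$ allows), merges deciles 5–6 as
the reference, and fits logistic regression on eight decile indicators plus
any covariates. ORs are $\exp(\hat\beta)$ with Wald 95% CIs. Without
covariates this reproduces the crude 2×2 odds ratios exactly (the factor
model is saturated). Whether the original analyses pooled both groups or
anchored deciles on controls is not documented; both are supported
(`boundaries = "combined"` (default) or `"controls"`), neither is asserted
to be the original.

Case subgroup contrasts pool schizophrenia with schizoaffective disorder,
keep bipolar disorder with psychotic features separate, and collect all
remaining diagnoses as "other psychotic disorders"; unrecognised labels
default into the latter with a logged notice. Relatives are only ever
contrasted with controls.

# The synthetic study

`simulate_discovery()` and `simulate_cohort()` generate a complete study
under an additive liability-threshold model:

* Variant frequencies $f_j \sim U(0.05, 0.5)$; a fraction of variants is
  causal with effects $\beta_j \sim N\!\big(0,\, h^2 / (m_c \cdot
  2f_j(1-f_j))\big)$, so the planted genetic variance equals
  $h^2$. Discovery estimates add noise of variance $1/(2f_j(1-f_j)\,N_d)$;
  odds ratios are $\exp(\hat\beta_j)$. Specifying effects on the liability
  scale and exponentiating is an approximation to a logistic GWAS that is
  accurate for small per-variant effects; it is used deliberately for
  transparency and speed.
* Liability is $\sum_j (g_{ij} - 2f_{jc})\beta_j + e_i$ with
  $e_i \sim N(0, 1-h^2)$; disease occurs above
  $\Phi^{-1}(1-\text{prevalence})$.
* **Cases** are rejection-sampled affected individuals. **Controls** are
  unaffected; with screening (default), two simulated parents and a sibling
  must also be unaffected, emulating "no personal or family history".
* **Relatives** are unaffected full siblings of affected probands. The
  proband's family is ascertained by *family-level* rejection — fresh
  parents and proband per attempt — because relatives of
  population-ascertained cases come from families weighted by their
  probability of producing an affected child. Re-drawing the proband
  within a fixed family would keep the family distribution unweighted
  (under-enriching relatives) and, at 1% prevalence, would exceed any
  practical per-family retry cap for low-risk families. The sibling is
  then re-drawn within the accepted family until unaffected (cap 1000).
  The sibling–proband dosage correlation at causal variants is the
  Mendelian 0.5 in expectation.
* **Centres** draw their own allele frequencies from a Balding–Nichols
  distribution around $f_j$ with drift `fst_drift`, so PCA has real
  structure to find; `fst_drift = 0` disables it.

Default design (the conditions of the emulated study, scaled down):
$m = 2000$ variants, $h^2 = 0.4$, prevalence 1%, $N_d = 50\,000$,
600 cases / 300 controls / 300 sibling relatives across 3 centres,
screened controls, `fst_drift = 0.01`. Values not fixed by the emulated
design were chosen once as realistic for the field: three centres stand in
for a multi-centre consortium; Fst 0.01 is typical of within-European
structure; the 5–50% frequency range covers common chip variants.

**Why half the variants are causal.** The emulated trait is highly
polygenic — thousands of contributing common variants in a genome-wide
panel. At 2000 simulated variants, a small causal fraction would
concentrate $h^2$ into few large effects, discovery power would saturate
at $p < 5\times10^{-8}$, and the characteristic rise of variance explained
with more liberal thresholds could not exist. With 1000 weak causal
variants the discovery GWAS is in the partial-power regime that P+T
scoring actually operates in, and the R²-versus-threshold curve rises and
plateaus around $p_T = 0.05$, as it does in real cohorts.

What the simulator deliberately does **not** model: realistic LD maps
(variants are in linkage equilibrium unless the block-correlation exercise
mode is on), imputation error, genotyping batch effects, assortative
mating, and diagnosis-subgroup-specific architectures. Diagnosis labels
are assigned to simulated cases with the published composition of a
broadly-defined-psychosis cohort but carry no genetic meaning. Passing
tests on synthetic data therefore validate the *pipeline arithmetic and
the qualitative ordering of effects*, not absolute real-data effect sizes:
at this reduced scale the per-variant effects are far larger than in real
GWAS, so variance explained and AUC run far above the single-digit
percentages seen in practice.

# Numerical choices and degenerate inputs

* Logistic fits: IRLS tolerance $10^{-8}$, max 100 iterations; separation
  flagged via boundary fitted probabilities.
* Discovery P-values are floored at $10^{-300}$ to stay in $(0,1]$.
* A constant PRS column evaluates to P = 1, R² = 0 rather than erroring.
* Empty deciles report `NA` odds ratios, never an exception.
* Monomorphic variants: HWE P defined as 1 (nothing testable); PCA drops
  them; allele frequency of an all-missing variant is an error.
* Quantities with documented tie rules: AUC (midranks), decile allocation
  (stable order), LD-pruning removal (lower MAF, then later file order).

# Problem sizes used in the test suite

The shipped tests exercise the defaults end to end: ten seeds of the full
600/300/300 study for the qualitative pattern checks, 200 small null
replicates (300 variants, 120+120 samples, single threshold) for type-I
calibration, 2000 simulated families for the Mendelian check, and a
2000-variant block-correlated cohort for the pruning invariant. These
sizes were chosen so the whole suite completes in minutes on a laptop
while keeping every Monte-Carlo margin generous.

# Known limitations

* In-sample AUC and R² (no cross-validation or liability-scale
  conversion).
* Hard-call genotypes only; no dosage/imputed-probability input.
* No clumping (index-SNP selection by association P); pruning is
  P-agnostic.
* Variant matching trusts identifiers; no liftover between builds.
* The simulator's linkage-equilibrium default means pruning removes almost
  nothing in simulated data unless block mode is enabled — by design, so
  scoring tests are exact.
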