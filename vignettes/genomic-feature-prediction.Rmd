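---
title: "Genomic prediction with GWAS-preselected features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with GWAS-preselected features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection predicts the additive genetic merit (the genomic
estimated breeding value, GEBV) of selection candidates from genome-wide
SNP genotypes. The workhorse model, GBLUP, treats every marker as
contributing equally to a single genomic relationship kernel. When an
independent discovery population is available, a genome-wide association
study (GWAS) in that population can flag markers likely to sit near
causal variants, and the genomic-feature extension (GFBLUP) gives those
preselected markers their own variance component. Whether this helps
depends on how much of the causal signal the feature set actually
captures; this package provides both models, the GWAS and preselection
machinery that links two cohorts, and a synthetic-data generator with a
known QTL architecture so each claim can be tested.

The intended design has two cohorts genotyped on a shared (dense,
typically imputed) panel: a *discovery* cohort that is scanned once, and
a *reference/validation* cohort in which prediction accuracy is measured
by repeated cross-validation. The package defaults mirror a realistic
pig-breeding deployment: a discovery cohort of 685 and a target cohort
of 651 animals, two moderately heritable carcass traits (backfat
thickness on the millimetre scale, loin muscle area in cm^2 — the latter
computed from caliper height and width as `loin_muscle_area()`, area =
height x width x 0.7), and sex and age as fixed effects.

## Models

**GBLUP.** With corrected phenotypes $y$ on the reference animals,

$$y = \mathbf{1}\mu + Zu + e,\qquad u \sim N(0,\, G\sigma^2_u),\qquad
e \sim N(0,\, I\sigma^2_e),$$

where $G$ is the genomic relationship matrix (GRM). `build_grm()` uses
the standardized-dosage form
$G_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}$
with $p_i$ the sample frequency of the counted allele; the VanRaden
ratio form is available behind `method = "vanraden1"`. Missing dosages
are mean-imputed before centering and zero-variance SNPs are skipped
with $m$ reduced. An exact algebraic consequence of this scaling — used
as the module's oracle in the tests — is the partition identity: for any
disjoint split of the panel into a feature set ($m_f$ SNPs, kernel
$G_f$) and remainder ($m_r$, $G_r$) computed with **shared** allele
frequencies, $(m_f G_f + m_r G_r)/(m_f+m_r)$ equals the full-panel $G$
to machine precision. Frequencies are recomputed per subset by default
(the `allele_freq` argument restores the shared-frequency convention
when the identity is wanted exactly).

**GFBLUP.** Two random genetic effects,

$$y = \mathbf{1}\mu + Zf + Zr + e,\qquad f \sim N(0, G_f\sigma^2_f),
\qquad r \sim N(0, G_r\sigma^2_r),$$

with $G_f$ built from the preselected markers and $G_r$ from the rest.
After the two-kernel variance components are estimated, the kernels are
collapsed for prediction:

$$G_{new} = \lambda G_f + (1-\lambda) G_r,\qquad
\lambda = \frac{\sigma^2_f}{\sigma^2_f + \sigma^2_r},$$

and a single-kernel BLUP with total genetic variance
$\sigma^2_f+\sigma^2_r$ produces the GEBVs. The collapse is an
approximation to the exact two-effect solution; `gfblup_predict(method
= "two_kernel")` keeps the exact solve as an internal cross-check (the
two agree exactly when $G_f = G_r$, and closely otherwise — the test
suite pins both properties).

## Variance components

`estimate_reml()` maximizes the restricted likelihood
$-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ by average-information
(AI) REML. Numerical choices that matter:

* **Step control.** An AI step is accepted only if it keeps every
  variance feasible and does not decrease the restricted likelihood.
  When a component heads for zero, an active-set proposal pins it at the
  floor and takes the AI step in the free coordinates — this avoids the
  slow geometric "EM crawl" that otherwise dominates fits where the
  feature kernel carries no variance. The fallback is the EM update
  $\sigma^2_{new} = \sigma^2 + \sigma^4\,(y'PKPy - \mathrm{tr}(PK))/n$,
  step-halved if needed, so the likelihood never decreases across
  accepted iterations.
* **Floor.** Variances are constrained to $\ge 10^{-8}\,\mathrm{var}(y)$
  rather than zero so the AI matrix stays invertible; estimates at the
  floor are flagged `boundary`.
* **Convergence.** $|\Delta \log L| < 10^{-8}$ *and* relative parameter
  change below $10^{-6}$ — the second condition guards flat likelihood
  directions, where the likelihood stabilizes well before the variance
  estimates do. At most 200 iterations; non-convergence is flagged on
  the result, never raised as an error.
* **Single-kernel speed.** With one kernel the model is diagonalized
  once by an eigendecomposition of $K$, making every iteration
  $O(np^2)$; this is what makes per-fold re-estimation in
  cross-validation affordable.
* **Errors.** A kernel equal to the identity makes $\sigma^2_g$ and
  $\sigma^2_e$ unidentifiable and is refused, as are constant responses
  and rank-deficient fixed designs.

Standard errors come from the inverse AI matrix; the heritability
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ (sum of genetic components
in the two-kernel case) gets a delta-method SE.

`correct_phenotypes()` implements the phenotype-correction convention
used throughout: fit the animal model with fixed effects (intercept,
sex, age, and the leading GRM principal components — three by default),
estimate $b$ by GLS at the REML variances, and take *corrected = y −
Xb̂*. The genetic and residual parts are deliberately retained; they are
the signal prediction needs. Principal components are taken from the
GRM itself (eigenvectors scaled by the square root of their
eigenvalues, sign fixed so the largest-magnitude loading is positive).

## Association scan and preselection

`mlma_scan()` is the mixed-linear-model association test: the null model
$y = \mathbf{1}\mu + g + e$ is fitted once by REML, $\sigma^2_g$ is then
fixed, and each SNP is tested by GLS under
$V = G\hat\sigma^2_g + I\hat\sigma^2_e$ with a Wald $\chi^2_1$ p-value.
$V^{-1}$ (and the mean projection) is formed once and reused across all
SNPs. The candidate SNP remains in the GRM — no leave-one-chromosome-out
— matching the fixed-null-variance scheme this scan reimplements;
proximal contamination is accepted. Zero-variance SNPs are flagged
untestable rather than dropped, and `genomic_inflation()` reports
$\lambda_{gc}$ = median $\chi^2$ / 0.4549.

`preselect()` bins SNPs at p < 0.05, 0.005, 0.0005, 0.00005 (strict
inequality, so the bins are nested), and `intersect_with_panel()`
matches discovery keys into the target panel **allele-aware**: the
canonical key is `chrom:pos` plus the alphabetically ordered allele
pair, so a position carried with a different allele pair does not
match. Strand flips and multiallelic sites are out of scope — both
cohorts are assumed imputed to the same reference panel. The
per-threshold counts report (`feature_report()`) gives the two-column
discovery/feature structure used downstream.

## Cross-validated accuracy

`cross_validate()` runs the 5-fold x 5-repeat scheme: per repeat a
fresh uniform random partition (sizes differ by at most one — 651
individuals split 131/130/130/130/130), per fold the held-out fifth's
phenotypes are treated as missing, and accuracy is the Pearson
correlation between held-out corrected phenotypes and GEBVs. The
reported accuracy is the mean of the 25 split correlations with its
standard error. Design choices:

* accuracy is the raw correlation with the corrected phenotype — no
  division by $\sqrt{h^2}$;
* variance components are re-estimated within every training split
  (conservative: no leakage from the validation fifth);
* for GFBLUP the feature set is a fixed external input from the
  discovery scan — never re-selected per fold;
* validation phenotypes are unread during training by construction: the
  predictors receive a phenotype vector restricted to the reference ids;
* the partition seed is recorded on the result, and identical seeds give
  identical folds, so model comparisons can share splits.

## What the synthetic generator emulates — and what it does not

`simulate_study()` draws per-SNP allele frequencies uniformly from
`maf_range` once (a shared base population) and samples haplotypes for
both cohorts from that spectrum, so the cohorts are related but not
identical — cross-cohort frequency correlation is high and SNP
intersection is nontrivial. Local LD comes from a first-order
Gaussian-copula Markov chain along each chromosome: a latent AR(1)
process with lag-one correlation `ld_rho` thresholded at the per-locus
frequency. This was chosen over coalescent simulation for speed and
closed-form expectations; LD decays geometrically with marker distance.

`ld_rho` defaults to 0.99 on the latent scale (about 0.7 at the
genotype level). This is deliberate: commercial pig populations have
small effective size and dense imputed panels, so the number of
effectively independent chromosome segments is on the order of a few
hundred — the regime in which a 651-animal reference population attains
cross-validated accuracies around 0.3-0.5 for a trait with $h^2 =
0.45$. A panel of 5,000 simulated markers with this LD reproduces that
regime; with weak LD the same panel would behave like thousands of
independent segments and accuracy would be unrealistically low for the
cohort sizes emulated.

Traits follow
$y_i = \mu + \beta_{sex}\,\mathrm{sex}_i + \beta_{age}\,(\mathrm{age}_i-\bar a)
+ \sum_q a_q x_{iq} + e_i$ with QTL effects drawn i.i.d. normal and
scaled so the genetic variance is $h^2 \cdot$ `trait_var` in
expectation; the residual variance is set from the realized genetic
variance so the heritability is right on average in every sample. The
defaults (mean 40.3, variance 24.3, $h^2 = 0.45$, 200 QTLs, sex effect
+2, age uniform on 140-220 days with slope 0.05/day) put the trait on
the loin-muscle-area scale of the emulated study. `prop_shared_qtl`
controls how much of the QTL architecture the two cohorts share (keys
*and* effects for the shared fraction); it defaults to 1 — a knob, not
a claim, since the true cross-population genetic correlation is
unknown. A `qtl_in_panel = FALSE` flag withholds causal SNPs from the
typed panel to mimic untyped causal variants.

Not emulated: coalescent/forward population-genetic realism, sequence
mutations, genotyping error, selection, pedigree structure, or
population admixture. Passing tests therefore show that the estimators
are correct and calibrated under a clean additive architecture with
stationary LD — not that any particular real population will show the
same GFBLUP-vs-GBLUP ranking, which in real data depends on how much
causal signal the preselected features capture.

## Quality control

`apply_qc()` applies, in a fixed order: individual call rate > 0.90,
SNP call rate > 0.90, minor allele frequency > 0.01, exact
Hardy-Weinberg p > 1e-6, then sex-chromosome and monomorphic removal
(thresholds are exclusive, matching the "greater than" convention of
the criteria they reproduce; allele frequencies are recomputed after
individual removal). The HWE test is the exact conditional test on the
heterozygote count given allele counts — the PLINK-style exact test —
computed by deterministic enumeration, which is cheap at study scale.
The report's per-stage counts always reconcile with the input SNP count,
and re-running QC on its own output changes nothing.

PLINK I/O implements the v1 SNP-major binary layout directly (magic
bytes `0x6C 0x1B`, mode `0x01`, two bits per genotype). Dosage is the
count of the **second** bim allele; the missing code round-trips as
`NA`.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on
synthetic data at deliberately moderate sizes: REML oracle comparisons
at n ≤ 25 where brute-force maximization is dependable; heritability
recovery and cross-validation at the emulated study scale (651
individuals, 5,000 markers); scan calibration at 500 individuals and
2,000-5,000 independent markers, where the binomial and
Kolmogorov-Smirnov reference distributions apply. These sizes were
chosen so every check completes quickly on a laptop while remaining in
the statistical regime the methods target.

## Known limitations

* The combined-kernel GFBLUP solver is the standard approximation; the
  exact two-kernel solver is kept as a cross-check, not the default.
* No LD pruning/clumping of preselected SNPs; feature sets are p-value
  bins only.
* No multi-trait REML, dominance/epistasis, Bayesian alternatives,
  pedigree or single-step matrices, imputation, VCF parsing, or
  strand-flip resolution.
* With very small feature sets the feature variance often estimates at
  the boundary; the fit is flagged and GFBLUP then behaves like GBLUP
  on the remainder kernel, which is the correct degenerate behaviour.
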