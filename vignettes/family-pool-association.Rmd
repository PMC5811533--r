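---
title: "Methods: family-pool candidate-gene association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-pool candidate-gene association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The study design this package analyses

Wild-caught, inseminated female mosquitoes are reared as isofemale lines:
each family is the progeny of one mother and (assumed) one father. Female
offspring of each family are exposed to a discriminating insecticide dose
in a WHO-tube bioassay and the family's proportionate mortality is the
quantitative resistance phenotype. DNA from the offspring of each family
is pooled and genotyped on a two-colour (cy3/cy5) candidate-gene SNP
array, so for every family and SNP we observe a pair of channel
intensities rather than discrete genotypes. The mothers (and additional
wild females) are genotyped individually on the same array; those
individual data calibrate the pooled analysis.

The pipeline estimates per-SNP dye bias from individual heterozygotes,
converts pooled signals to family allele frequencies, detects and
corrects inversion-driven stratification with a control-SNP PCA, scans
for frequency-mortality association by rank-transformed partial
correlation, decomposes phenotypic variance by stepwise regression, and
provides the replication-stage machinery (allelic odds-ratio tests,
tag-SNP selection, temporal tracking) used to confirm candidates in
independent samples.

## Pooled allele frequencies and dye bias

In a heterozygote the true allelic ratio is 1:1, so the mean cy3:cy5
signal ratio over heterozygous individuals measures the per-SNP dye bias
$k$: a mean ratio of 0.5 means a twofold cy5 excess, $k = 0.5$. We use
the arithmetic mean of per-individual ratios (not the ratio of means)
because the accompanying QC criterion needs the across-individual
standard deviation of the same quantity, and we require at least two
heterozygotes per SNP. Heterozygote ratios with a zero cy5 signal are
infinite; they are dropped and counted, and a SNP left with fewer than
two usable heterozygotes is excluded.

Pool frequencies follow the corrected estimator

$$p(X) = \frac{X}{X + k\,Y}, \qquad p(Y) = 1 - p(X),$$

with $X$ the raw cy3 and $Y$ the raw cy5 pool signal. With noiseless
signals and the true $k$ this inverts the signal model exactly for any
$k$; using $k \equiv 1$ on dye-biased data inflates the frequency error,
and both properties are enforced by tests.

SNPs are excluded when (1) $k$ exceeds the empirical 95th percentile of
the $k$ distribution across SNPs, or (2) the standard deviation of the
heterozygote ratio exceeds the 95th percentile of its own distribution.
We read "percentile of the range" as the empirical percentile of the
distribution (the linear-interpolation definition used by
`stats::quantile()` type 7): a min-max range is a single interval and
carries no 95th percentile. Percentiles are computed over SNPs that pass
the two-heterozygote minimum; whether the original analysis did this
before or after the minimum is not stated, and the choice moves the
cutoffs only marginally.

## Stratification and the inversion

A large paracentric inversion suppresses recombination over >20 Mb of
chromosome arm 2L (breakpoints near 22 and 42 Mb), so the arrangement
segregates as a single locus carrying arrangement-specific allele
frequencies. Karyotype variation between families then masquerades as
association wherever the phenotype covaries with karyotype. We detect
this with a PCA of the family-by-control-SNP frequency matrix: control
SNPs (intergenic/non-candidate) carry stratification but no candidate
effects. Columns are standardized before decomposition — the source
analysis does not state its scaling, and standardization stops
high-variance (intermediate-MAF) SNPs from dominating. Components are
sign-fixed (largest-|loading| SNP positive) so reports are reproducible.

Localization of a component to the inversion is quantified by the
per-SNP |Pearson r| between control-SNP frequencies and component
scores, compared inside versus outside the region with a two-sided
Mann-Whitney test (normal approximation with tie correction; exact
distribution when both groups have at most eight SNPs). Cluster-level
differentiation uses a Hudson-type two-population $F_{ST}$ per SNP with
finite-sample correction — the original analysis does not name its
estimator, and Hudson's is robust to unequal cluster sizes; negative
estimates are retained and flagged rather than truncated. LD is the
composite $r^2$ (squared dosage correlation): the pipeline has no phase
information, and composite $r^2$ tracks haplotype $r^2$ closely for
unphased data. Cluster labels, where needed, come from seeded k-means on
leading genotype PCs — a deliberately simple, deterministic stand-in for
model-based assignment, which is out of scope.

## The association scan

For each SNP, family allele frequency and proportionate mortality are
rank-transformed (average ranks for ties) and their partial correlation
computed given the covariate model; covariates are rank-transformed too.
The source describes "rank-transformed data" without saying whether
covariates were included in the transform; we rank them by default and
expose `rank_covariates = FALSE` to switch. With covariates $Z$, the
statistic is the correlation $r$ of the residuals of both variables on
$[1, Z]$, with $t = r\sqrt{(n-2-k)/(1-r^2)}$ on $n-2-k$ df, two-sided P.
Ranks are recomputed within each SNP's complete-case family set, and
missing pooled cells propagate as missing (pairwise-complete analysis),
never imputed. Two covariate models are standard: humidity alone, and
humidity plus PC1 (the inversion proxy); both are reported because PC1
correction can also absorb genuine inversion-linked effects.

No formal genome-wide threshold is imposed — with ~98 families only
moderate-to-large effects are detectable, and the workflow is ranking
followed by replication. The variance decomposition uses classic forward
stepwise selection with backward elimination (entry P 0.05, removal
0.10, nested-model F tests; the original used a commercial package
without stating thresholds, and these are that tradition's defaults),
with humidity forced in first and cumulative $r^2$ reported per step.

## Power

The minimal detectable correlation uses the Fisher z approximation,
$r = \tanh\!\big((z_{1-\alpha/2} + z_{\text{power}})/\sqrt{n-3}\big)$
with $\alpha = 0.05/894$ and $n = 98$, giving 0.462 — matching the
published figure of 0.46 and confirming that the reported "slope" on
rank-standardized data is a correlation. `empirical_power()` checks the
formula by simulating bivariate-normal samples and testing at the same
alpha; at the analytic threshold it returns 0.80 within Monte Carlo
error.

## Replication statistics

Allelic tests count two alleles per homozygote and one per heterozygote
into a 2×2 class-by-allele table: Pearson chi-square without continuity
correction (a flag enables Yates) and the odds ratio with a Wald
interval. When any cell is zero the Haldane-Anscombe 0.5 correction is
applied to every cell for the odds ratio only, and flagged; the
chi-square always uses the uncorrected table. Across-population
mean/SD of odds ratios is reported on the OR scale to match the usual
tabular presentation, although the log scale is statistically
preferable — both are computable from the per-population output.
Tag-SNP selection approximates LD by family-wise Pearson correlation of
frequency vectors, restricted to candidates within ±0.10 MAF of the
target, maximizing |r| with ties broken by MAF similarity then genomic
proximity. Temporal stability is a k×2 heterogeneity chi-square;
"stability" is a failure to reject, reported but never asserted.

## What the simulator emulates, and what it does not

`sim_config()` defaults encode the study conditions: 98 families of
10–20 female offspring (uniform, median 15), a 1536-SNP panel with 195
control SNPs of which 32 sit inside the inversion, a target-site
resistance allele at frequency 0.94, three metabolic-gene SNPs at
intermediate frequency, an inversion karyotype frequency of 0.5 (which
yields the two homokaryotypic and one heterokaryotypic clusters seen in
individual genotyping), and per-SNP dye bias log-uniform on [1/3, 3]
with 1% multiplicative signal noise.

Mortality follows a logit-binomial liability model — the minimal
generative model reproducing the reported familial correlation,
humidity dependence and SNP effects, none of which are given a
generative form in the source:

$$\Pr(\text{death}) = \operatorname{logit}^{-1}\!\Big(\beta_0 +
\beta_H (H - \bar H) + \textstyle\sum_g \beta_g (G_g - 2p_g) +
\beta_{2La}(K - 2f) + u_{\text{fam}}\Big),$$

with $u_{\text{fam}} \sim N(0, \sigma_f^2)$. Covariates and dosages are
centred so `baseline_logit` is the population-mean logit. Humidity is
drawn per assay day (uniform over 55–90 %RH, a plausible field-insectary
range; the observed schedule is not published, so the range is
user-overridable) and families are assigned to days round-robin,
reproducing the shared-environment covariate structure. Defaults
$\beta_H = -0.05$ per %RH and $\sigma_f = 0.8$ put the
humidity-mortality correlation near the reported −0.4; the strongest
metabolic effect ($\beta = -1.2$ per allele copy at frequency 0.37)
produces a family-level frequency-mortality correlation near the
analytic detection limit of 0.46. A karyotype effect
($\beta_{2La} = +0.5$ per inverted-arrangement copy) reproduces the
observed inversion-resistance association that makes PC1 correction
meaningful. The inversion is a biallelic karyotype locus: inversion-span
SNPs are transmitted as one block with the arrangement, and non-causal
span SNPs get arrangement-specific frequencies from a Balding-Nichols
draw with $F = 0.3$, which reproduces the observed contrast in
PC1-correlation between inversion (mean |r| ≈ 0.4) and non-inversion
(≈ 0.1) control SNPs. The causal metabolic SNPs inside the span are
deliberately not arrangement-differentiated, mirroring the observed
independence of those markers from karyotype.

The simulator does not model recombination maps or coalescent history,
larval ecology, hybridization chemistry beyond the two-channel
mean/noise model, male bioassays (females only by default), or
multiple insemination. Passing tests therefore demonstrate the
statistical machinery under the assumed generative model, not the
biological fidelity of that model: in real data, LD decay within
arrangements, assay-plate artefacts, and family relatedness beyond the
single-father assumption would add noise the simulation does not.

## Numerical choices and degenerate inputs

One root seed drives every stage through documented derived streams
(`derive_seed()`), so stages are independently reproducible and
individual- and pool-signal simulations share the same per-SNP $k$.
Signal noise is mean-preserving lognormal, so signals are non-negative
by construction and `signal_cv = 0` is exactly noiseless. Cells with
$X = Y = 0$ are missing, not 0/0. The partial correlation requires at
least one residual degree of freedom; zero residual variance is
reported as a missing result with a reason, not an error. HWE exact
P-values sum probabilities `<= p_obs` with a relative tolerance of 1e-9
to absorb floating-point ties. Collinear stepwise candidates
($R^2 > 0.999$ with the included set) are skipped with a warning.
Tables are written as UTF-8 TSV with `'.'` for missing and floats at 15
significant digits so that written tables re-read to equal values.

## Problem sizes used by the test suite

Unit tests run on miniature designs (about 12 families × 60 SNPs); the
scenario and acceptance checks simulate the full default design (98
families, 1536 SNPs) once per seed and reuse it, with ten seeded
replicates for the planted-effect recovery check, three for the type-I
calibration, 5000 Monte Carlo replicates for the power check, and
exhaustive enumeration for the 2×2 (totals ≤ 50) and HWE (totals ≤ 20)
oracle-equivalence checks. The whole suite completes in well under a
minute on one CPU.

## Known limitations

* The QC percentile rules are distribution-relative: they always flag
  about 5% of SNPs per criterion, even when all estimates are good.
  This mirrors the published procedure rather than an optimal filter.
* PC1 correction is imperfect by construction: it removes
  inversion-wide signal, causal or not, which is why both covariate
  models are reported.
* The family is the analysis unit; no kinship/mixed-model machinery is
  provided, and within-family genotype sampling error at small
  offspring counts is absorbed into residual noise.
* Replication odds ratios from small samples are noisy, and the
  zero-cell correction biases them toward the null; the flag records
  when it was applied.
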