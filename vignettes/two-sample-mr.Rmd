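---
title: "Two-sample bidirectional Mendelian randomization with mrlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample bidirectional Mendelian randomization with mrlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlink)
```

## The model

Mendelian randomization (MR) treats genetic variants as instrumental
variables for an exposure. Because alleles are assigned at conception,
an SNP that reliably shifts an exposure — here, the relative abundance
of a gut-microbial taxon — supports a causal reading of its downstream
association with an outcome such as food allergy, provided three
assumptions hold: *relevance* (the SNP is associated with the
exposure), *exchangeability* (the SNP is independent of confounders),
and *exclusion restriction* (the SNP affects the outcome only through
the exposure).

In the two-sample design the SNP–exposure effects $\hat\gamma_j$ (with
standard errors $\sigma_{\gamma j}$) and SNP–outcome effects
$\hat\Gamma_j$ (with $\sigma_{\Gamma j}$) come from different GWAS
cohorts' summary statistics. Each SNP contributes a Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$. The estimators combine
these ratios:

* **IVW** — the precision-weighted mean with weights
  $w_j = \hat\gamma_j^2 / \sigma_{\Gamma j}^2$, identical to weighted
  least squares of $\hat\Gamma$ on $\hat\gamma$ through the origin with
  weights $1/\sigma_{\Gamma j}^2$. Under the default *multiplicative
  random-effects* model the fixed-effect standard error
  $(\sum_j w_j)^{-1/2}$ is inflated by
  $\sqrt{\max(1, Q/(J-1))}$, where $Q$ is Cochran's statistic, so
  heterogeneity widens but never narrows the interval.
* **MR-Egger** — weighted least squares with a free intercept after
  orienting all instruments to non-negative exposure effects. The slope
  estimates the causal effect under InSiDE (instrument strength
  independent of direct effects); the intercept estimates the average
  directional pleiotropy, and its two-sided $t_{J-2}$ test is the
  pleiotropy diagnostic.
* **Weighted median** — the 50th percentile of the ratio distribution
  under normalised IVW weights (cumulative percentile
  $s_j = \sum_{k \le j} w_k - w_j/2$, linear interpolation at 0.5),
  consistent while valid instruments carry more than half the weight.
  Its standard error comes from a parametric bootstrap that redraws
  both effect series from their reported normal laws.

For a binary outcome all effects are per-allele log odds ratios, and
reports carry $\mathrm{OR} = e^{\hat\beta}$ with the 95% interval
$e^{\hat\beta \pm 1.96\,\mathrm{se}}$.

Instrument strength is screened per SNP with
$R^2 = \dfrac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,\mathrm{SE}^2 N f(1-f)}$
and $F = R^2 (N-2)/(1-R^2)$, where $f$ is the effect-allele frequency.
The $f(1-f)$ terms cancel algebraically, leaving
$\beta^2/(\beta^2 + \mathrm{SE}^2 N)$; we keep the frequency in the
signature and refuse records without it, so a missing frequency fails
loudly instead of silently pretending to carry strength information.
For strong instruments $F$ is close to the squared z-statistic
$(\beta/\mathrm{SE})^2$; instruments with $F < 10$ are removed.

## The pipeline and its tunables

`run_pair()` executes, in order, p-value selection, clumping, allele
harmonization, weak-instrument filtering, estimation, and the
sensitivity battery, logging the SNP count after every stage. All
tunables live in `mr_config()`:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5e-6 | candidate-instrument cutoff, strict `<`. The microbiome GWAS convention; few taxa reach 5e-8. |
| `clump_r2` | 0.001 | maximum tolerated LD $r^2$ between retained SNPs |
| `clump_kb` | 10000 | clumping window (kb) |
| `palindrome_eaf_limit` | 0.42 | palindromic SNPs with either frequency in [0.42, 0.58] are dropped |
| `f_min` | 10 | weak-instrument threshold on $F$ |
| `ivw_model` | `"random"` | multiplicative random effects (never below the fixed-effect se) |
| `n_boot` | 5000 | weighted-median bootstrap replicates |
| `presso_n_sim` | 1000 | MR-PRESSO simulations (minimum enforced) |
| `alpha` | 0.05 | verdict and reporting level |
| `seed` | 1 | base seed; per-analysis seeds are derived deterministically |

Clumping is greedy: sort by ascending p (ties broken by chromosome,
then position, for determinism), accept the best remaining SNP, and
remove unaccepted same-chromosome SNPs within the window whose LD
$r^2$ reaches the threshold. Without an LD table every same-chromosome
SNP inside the window is treated as correlated — with a threshold as
strict as $r^2 < 0.001$, assuming independence for an unknown pair
would be the riskier default. When an LD table *is* supplied, pairs
absent from it are taken as uncorrelated, since such tables enumerate
the correlated pairs.

Harmonization aligns each outcome record onto the exposure's effect
allele: identical pairs are copied, swapped pairs negate the outcome
beta and reflect its frequency, strand complements are complemented
first. Palindromic A/T and C/G pairs carry no strand information in
their labels, so they are kept only when both allele frequencies are
outside the ambiguity band *and* on the same side of 0.5 after label
alignment. A palindrome whose frequencies sit on opposite sides would
be consistent with a strand flip; we drop it rather than guess — a
deliberately conservative rule that costs a few instruments and avoids
a sign error in $\hat\Gamma_j$. Palindromes lacking a frequency are
likewise dropped, never imputed.

## Sensitivity battery

* **Egger intercept test** — directional-pleiotropy verdict at
  `alpha`.
* **Cochran's Q** about both the IVW and the Egger fit, with $J-1$ and
  $J-2$ df. Because the Egger fit spends one more parameter on the
  same weighted residuals, $Q_{\mathrm{egger}} \le Q_{\mathrm{ivw}}$
  always.
* **MR-PRESSO** — residuals are taken about leave-one-out IVW fits so
  an outlier cannot mask itself; the global RSS is compared against a
  parametric null rebuilt from the fitted values (`n_sim` draws,
  add-one p-values so no empirical p is exactly zero); per-SNP outlier
  p-values are Bonferroni-adjusted; the distortion test compares the
  outlier-corrected IVW estimate against 500 random outlier sets of
  the same size, and is marked not-applicable when nothing is flagged.
* **Leave-one-out** — one IVW re-fit per excluded SNP; the influence
  verdict fires when an exclusion flips the sign or moves the p-value
  across `alpha`.

`run_plan()` orchestrates many traits in both directions (the reverse
direction literally swaps the trait roles), reports one row per
(exposure, outcome, direction, method), flags significance at raw
`alpha` — mirroring how such screens are usually read — and adds a
clearly-labelled Benjamini–Hochberg column `p_bh` for readers who want
multiplicity control across taxa. Traits that fail a stage (no SNP
below threshold, no overlap, all instruments weak) produce structured
`"not_analyzable"` rows; a batch never aborts on one trait.

## What the generator simulates — and what it does not

`sim_scenario()`/`simulate_pair()` draw, per SNP: a frequency
$f_j \sim U(0.1, 0.9)$, a true instrument effect
$\gamma_j \sim U(0.05, 0.2)$, and a direct effect $\alpha_j \sim
N(\mu_\alpha, \sigma_\alpha)$, optionally correlated with $\gamma_j$
(`inside_violation` is that correlation, 0 preserving InSiDE). True
outcome effects are $\Gamma_j = \beta \gamma_j + \alpha_j$. Observed
effects add noise with the quantitative-trait standard error
$\sigma = (2 N f (1-f))^{-1/2}$ at unit phenotypic variance — the same
frequency/sample-size law the $R^2$ formula encodes. Default sample
sizes are 18,340 (a microbiome-consortium-scale exposure GWAS) and
169,716 (a large binary-outcome GWAS); the default $\gamma$ range
yields instrument F-statistics of roughly 25–400, the regime the
screening step is designed for. `noise_scale = 0` gives noiseless
observations (standard errors keep their analytic values so weights
stay defined), which the estimators must invert exactly.

Deliberately not modelled: LD between instruments (the clumping LD
path is tested with hand-built tables), case/control imbalance in the
binary outcome (effects live directly on the ln(OR) scale; the
logistic SE inflation of a 3,777-case/165,939-control design is out of
scope), genotype-level data, and allele-frequency differences between
cohorts. Passing tests therefore demonstrate the statistical machinery
under the stated generative model, not robustness to cohort
mismatches, stratification, or winner's-curse selection in real GWAS.

## Numerical and testing choices

* Simulated p-values are floored at the smallest positive double:
  strong instruments otherwise underflow to an exact zero, which the
  record invariant $p \in (0, 1]$ rightly rejects.
* All resampling (weighted-median bootstrap, MR-PRESSO, distortion
  draws) runs under an explicit mandatory seed through a helper that
  saves and restores the caller's RNG state; reruns are byte-identical
  and nothing leaks into the global stream.
* Null calibration is asserted for the fixed-effect IVW z-test, which
  is conditionally exactly standard normal under the homogeneous null;
  the default random-effects variant is conservative by construction
  (its se is floored at the fixed-effect value), which is the intended
  behaviour, not a calibration defect.
* Parameter-recovery tolerances are three Monte-Carlo standard errors
  of the replicate mean plus the known finite-sample allowances: ratio
  estimators attenuate by order $1/F$, and the Egger slope dilutes by
  $\overline{\sigma_\gamma^2}/\mathrm{var}(\gamma)$ when exposure
  effects are noisy (no NOME correction is applied).
* Problem sizes in the test suite — 1000 null replicates for IVW
  calibration, 200 for MR-PRESSO at 1000 simulations each, 500
  recovery replicates, 300 Egger-recovery replicates, 200 spike
  replicates — keep every Monte-Carlo band at most a third of the
  effect being asserted while the whole suite stays interactive.

## Worked example

```{r example, eval = FALSE}
pair <- simulate_pair(sim_scenario(n_snp = 7, beta_causal = log(0.65),
                                   gamma_range = c(0.08, 0.2),
                                   n_exposure = 2e5, seed = 11))
res <- run_pair(pair$exposure, pair$outcome,
                mr_config(seed = 11, n_boot = 2000))
res$fit
res$sensitivity
res$attrition
```

## Known limitations

* No mode-based, multivariable, or contamination-mixture estimators;
  no Radial-MR, Steiger filtering, or $I^2_{GX}$ correction for Egger
  regression.
* LD is supplied or absent, never computed from genotypes; no liftover
  or GWAS-VCF input.
* The conservative palindrome and no-LD-source rules trade instruments
  for safety; with very few candidates this can leave a trait
  `"not_analyzable"`.
* Effects are interpreted on the ln(OR) scale throughout; converting a
  quantitative-exposure effect into "per unit" terms is the caller's
  responsibility.
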