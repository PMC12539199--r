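---
title: "Methods: triangulated MR screening of metabolite mediators"
author: "mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triangulated MR screening of metabolite mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Adiposity raises the risk of endometrial cancer, and circulating metabolites
are plausible intermediates on that pathway. `mrscreen` implements a
triangulation design that screens a panel of metabolite-like traits for
mediation evidence by combining two lines of evidence with different bias
structures: covariate-adjusted observational regressions in a cohort, and
two-sample Mendelian randomization (MR) built from GWAS summary statistics.
A phenome-catalogue scan then asks whether the instruments of the putative
mediators are co-associated with other traits more than chance predicts,
which would point to shared genetic architecture rather than a clean
mediating pathway.

The package ships a synthetic-study generator with a known mediation ground
truth, so every stage of the pipeline can be exercised end to end and its
operating characteristics measured against planted effects.

## Models and estimators

### Univariable two-sample MR

For harmonized per-variant effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$ with
outcome standard errors $\sigma_{Yj}$ and weights $w_j = 1/\sigma_{Yj}^2$:

* **Wald ratio** (single instrument): $\hat\theta = \hat\beta_Y/\hat\beta_X$
  with first-order delta-method standard error $\sigma_Y/|\hat\beta_X|$.
  No second-order term is included; this is the simplest defensible choice
  and is stated here so tests can be exact.
* **IVW, multiplicative random effects**: zero-intercept weighted regression
  of $\hat\beta_Y$ on $\hat\beta_X$;
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$. Heterogeneity is Cochran's
  $Q = \sum w_j(\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$ and the
  standard error scales the fixed-effect variance by $Q/(L-1)$ **without
  flooring** — an under-dispersed instrument set genuinely shrinks the SE.
* **MR-Egger**: the same regression with a free intercept after orienting
  each pair so $\hat\beta_{Xj} \ge 0$; the intercept estimates average
  directional pleiotropy. Here the residual scale **is floored at 1**
  (inflation-only). The asymmetric flooring convention between IVW-MRE and
  Egger mirrors the dominant implementations of the two cited estimators;
  both choices are unit-tested against generic weighted-least-squares
  oracles.
* **Weighted median**: the 0.5 point of the weighted empirical distribution
  of per-variant ratios $r_j$, interpolated linearly on standardized
  cumulative weights $s_j = (\mathrm{cum}(w)_j - w_j/2)/\sum w$; weights are
  first-order inverse variances of the ratios. Consistent when at least
  half the weight comes from valid instruments.
* **Weighted mode**: the maximizer of a normal-kernel weighted density of
  the ratios with bandwidth $\phi \cdot 0.9\,\min(\mathrm{sd}(r),
  \mathrm{mad}(r))\,L^{-1/5}$ ($\phi = 1$ by default), located on a 512-point
  grid over the ratio range padded by three bandwidths. Consistent when the
  largest homogeneous cluster of instruments is valid.

Median and mode standard errors come from a seeded parametric bootstrap
(default 1,000 resamples of the betas from their sampling distributions).
All p-values are two-sided normal — the two-sample MR convention — and all
intervals are $\hat\theta \pm 1.96\,\mathrm{se}$. Binary outcomes are
analysed on the log-odds scale and additionally reported as odds ratios.

Dispatch follows the screen's rule: one instrument gives the Wald ratio
only, two give IVW-MRE only, three or more add the three sensitivity
estimators.

### Multivariable MR

`mvmr_fit()` regresses outcome betas on the $L \times K$ matrix of exposure
betas through the origin with weights $1/\sigma_{Yj}^2$; the coefficients
are direct effects conditional on the other exposures. The residual scale
$Q/(L-K)$ multiplies the covariance (again unfloored). Two diagnostics are
attached:

* **Conditional F**: for exposure $k$, its beta column is regressed on the
  other columns (weights $1/\sigma_{X_k j}^2$, through the origin); the
  weighted residual sum of squares $Q_{x_k}$ divided by $L-K+1$ measures
  instrument strength conditional on the other exposures. Covariances
  between exposures' summary statistics are set to zero throughout — the
  summary-data setting gives no phenotypic covariance to use, and this is a
  documented limitation.
* **Adapted heterogeneity $Q_A$**:
  $\sum_j \hat w_j (\hat\beta_{Yj} - \sum_k \hat\theta_k
  \hat\beta_{X_k j})^2$ with
  $\hat w_j = 1/(\sigma_{Yj}^2 + \sum_k \hat\theta_k^2 \sigma_{X_k j}^2)$,
  referred to $\chi^2_{L-K}$. The weights are evaluated once at the fitted
  coefficients (single pass). The literature also contains an iterated
  variant; the single-pass form was chosen because it is deterministic and
  directly testable, and the source method description does not pin down
  the iteration.

The per-mediator scan fits a two-exposure model (exposure + one mediator at
a time) and reports the attenuation fraction
$1 - \hat\theta_{\text{direct}}/\hat\theta_{\text{total}}$ against the
univariable IVW total effect. When the total effect is not distinguishable
from zero (point estimate within $1.96\,\mathrm{se}$ of zero) the ratio is
suppressed with a reason flag rather than reported — attenuation of a null
effect is not interpretable. A lower-powered exposure GWAS can be supplied
for the multivariable step so that the exposure's (far more numerous)
instruments do not dilute the conditional strength of the mediator's
instruments, matching the design this screen emulates.

### Instruments and harmonization

Instrument selection takes variants below a p-value threshold (strict `<`)
and greedily clumps them: the smallest-p unclaimed variant is kept, and
unclaimed variants with $r^2$ at or above the threshold against it are
discarded; ties at equal p break lexicographically on variant id so runs
are reproducible. Defaults are p < 5e-9 for the adiposity-like exposure,
p < 5e-8 for metabolite-like traits, and $r^2 < 0.001$. Mean instrument
strength is reported as $\overline{(\hat\beta/\mathrm{se})^2}$.

Harmonization aligns outcome betas to the exposure's effect alleles:
matching orientations are kept, swapped orientations flip the outcome beta
sign, incompatible allele pairs and variants absent from the outcome are
dropped with a reason (proxy-variant search would need an external LD
reference and is out of scope). Palindromic (A/T, C/G) pairs are dropped
when either allele frequency is missing or the exposure frequency lies in
(0.42, 0.58); outside that window they are oriented by frequency. The
window is configurable; the default is standard practice where the source
design left the rule implicit. Multivariable harmonization uses the
intersection of variants present in all exposures and the outcome — absent
associations are never imputed as zero, which would fabricate information.

### Observational arm

Continuous traits are inverse rank-normal transformed (IRNT):
$\Phi^{-1}((\mathrm{rank}-0.5)/n)$ with average ranks for ties, the
offset-0.5 form, fixed so tests are exact. Models are complete-case linear
or logistic regressions (`stats::lm` / `stats::glm`; IRLS convergence 1e-8,
at most 50 iterations; separation is an explicit error). Case status uses
the registry rule: a recorded diagnosis with assessment age strictly below
diagnosis age is an incident case; any other recorded diagnosis is
prevalent and excluded from analysis; no record means control. Equal ages
count as prevalent — the strict inequality is applied literally. Two
adjustment sets are reported: age + assessment centre, and fully adjusted
(adding smoking, alcohol, education, physical activity, HRT use, menopause
status and reproductive-age covariates where present).

The discovery scan (exposure to mediators) flags at the Bonferroni
threshold 0.05 divided by the panel size — 0.05/249 for a full
metabolomics panel — while the hypothesis-driven scan (mediators to
outcome) uses uncorrected 0.05, by design of the screen.

### The four-part sequential screen

1. **Part I** — exposure on outcome: pass if the IVW p-value is below 0.05
   *and* every available sensitivity estimator agrees in sign with IVW.
   "Consistency" of the sensitivity estimators is operationalized as sign
   agreement of point estimates with no p-value requirement — the only
   quantified reading compatible with a screen that sets no significance
   threshold for those methods.
2. **Part II** — exposure on each mediator: IVW p below 0.05/(panel size),
   and, when a cohort is supplied, sign agreement between the MR and
   observational estimates.
3. **Part III** — each passing mediator on the outcome (Wald if a single
   instrument, IVW otherwise): uncorrected p < 0.05 plus the triple-sign
   mediation rule
   $\mathrm{sign}(X{\to}M)\cdot\mathrm{sign}(M{\to}Y) =
   \mathrm{sign}(X{\to}Y)$, the standard two-step MR direction-consistency
   convention.
4. **Part IV** — per-mediator multivariable attenuation of the direct
   exposure effect, with conditional F and $Q_A$ attached.

Every entity receives exactly one auditable decision per stage with a
reason code, the stage chain short-circuits when nothing passes, and the
subset invariant (Part IV entities within Part III passes within Part II
passes) is asserted on every run. With several outcomes (overall disease
plus histological subtypes) the gates are evaluated against the overall
outcome and all outcomes are estimated and reported; the alternative —
gating per subtype — is defensible but would make the pass set
outcome-dependent, so the simpler rule was chosen and is stated here.

### Off-target enrichment (Part V)

Instruments of the signal mediators are looked up in a local
PhenoScanner-like catalogue at p < 1e-10 (strict). The null distribution
re-draws the same *number of metabolites* (not SNPs) from the non-signal
pool 100 times and pools their instruments — the metabolite is the redraw
unit because it preserves each metabolite's instrument structure. Counts
are per-variant-distinct per trait and domain; proportions (counts over
instrument-set size) are reported alongside because redraw sets can differ
in instrument number. The empirical p-value uses the add-one rule
$(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{iter}}+1)$, so it can
never be zero from finite redraws. Because counts are integers, ties
between observed and null counts make the empirical p slightly
conservative; the calibration tests account for nothing more than this.

## The synthetic-study generator

`sim_config()` fixes a mediation structure: genotypes
$G_{ij} \sim \mathrm{Binomial}(2, \mathrm{maf}_j)$ with MAF uniform on
(0.05, 0.45); exposure $X = \sum_j a_j G_j + 0.3\,U + \varepsilon$,
standardized, with $U$ a shared confounder; mediators
$M_m = \gamma_m X + \sum_j b_{mj} G'_{mj} + 0.15\,U + \varepsilon_m$,
standardized; outcome
$D \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha + \tau_{\text{direct}} X
+ \sum_m \delta_m M_m + \text{pleiotropy}))$ with $\alpha$ solved so mean
risk matches the target prevalence. Noise variances are chosen so each
latent trait has unit variance, which keeps planted per-allele effects in
SD units after standardization. Each panel (exposure, mediator, outcome,
subtypes, observational, optional low-powered exposure) draws from its own
deterministic substream of one master seed, emulating non-overlapping GWAS
samples; variant metadata are drawn once so panels share the same variants.

Default parameters, chosen once as a realistic desk-scale emulation:

* `n_samples_per_panel` 20,000 — large enough that per-variant regressions
  are in their asymptotic regime, small enough for thousand-replicate
  calibration runs.
* `instrument_effect_scale` 0.07 SD per allele — per-SNP F around 40 at
  n = 20,000, the strength the emulated adiposity and metabolite GWAS
  instruments report.
* `baseline_prevalence` 0.05 — with a rare-ish outcome, marginal per-allele
  log-odds are close to the conditional coefficients, so summary-level MR
  estimands stay close to the planted log-odds effects (logistic
  non-collapsibility is a real feature of the design, not an artifact, and
  at this prevalence it contributes only a few percent of attenuation).
* `pleiotropy_mean` 0.04, `pleiotropy_sd` 0.02 log-odds per allele for
  invalid instruments — the same order as the per-allele effect through the
  exposure pathway ($\tau a \approx 0.59 \times 0.07$), i.e. directional
  pleiotropy that matters but does not dominate.
* the default mediation structure ($\gamma = (0.3, 0.2)$,
  $\delta = (0.5, 0.1)$, $\tau_{\text{direct}} = 0.1$, hence
  $\tau_{\text{total}} = 0.27$) is the package's worked reference scenario.

Per-variant summary statistics come from single-variant OLS (continuous) or
exact per-variant logistic maximum likelihood (binary; the Newton iteration
runs on the per-genotype sufficient statistics, which is algebraically the
same MLE as `glm` and is verified against it to numerical precision).
Monomorphic variants are emitted with `se = Inf` and excluded by selection.
Instruments are mutually independent by default; an optional synthetic
LD-block mode duplicates each exposure instrument with a correlated twin
(genotype copied with probability $\sqrt{r^2}$) and emits the pair table,
giving clumping a real test surface.

What the generator does **not** emulate: realistic LD beyond the twin mode,
relatedness and mixed-model GWAS, imputation error, sex chromosomes,
selection into the cohort, missing data (unless configured), or assay batch
structure. Passing tests therefore demonstrate correctness of the
estimators and of the screen's logic under clean sampling assumptions —
not robustness to everything real cohort data can do.

## Numerical choices and edge cases

* Bootstrap and redraw streams derive from one master seed via labelled
  substreams; reruns are byte-identical (reports serialize without
  timestamps).
* Clump ties at equal p break on variant id; `sign(0)` counts as agreeing
  in every sign rule; an exactly-zero SE yields p = 1 when the estimate is
  zero and the smallest representable double otherwise.
* `ivw_mre` refuses a single variant (the caller must use the Wald ratio);
  Egger refuses fewer than three variants or an orientation-degenerate
  exposure vector; ratio-based estimators refuse zero exposure betas.
* All-zero exposure columns in multivariable fits are NA-flagged and
  excluded rather than propagating a singular solve; remaining rank
  deficiency is an error.
* The observational logistic fit treats non-convergence or a coefficient
  beyond 20 on the log-odds scale as separation and errors out explicitly.

## Study-scale choices in the shipped checks

The packaged calibration and recovery checks run at sizes chosen to put
each property in the regime where its contract applies while staying
desk-scale: null calibration uses 1,000 two-sample replicates at 20,000
individuals per panel with 50 instruments; effect recovery uses 200
replicates at the same panel size with 100 instruments and a planted
log-odds effect of 0.59 per SD (odds ratio about 1.8, the magnitude scale
of the adiposity–endometrial-cancer relationship); the robust-estimator
contrast uses GWAS-scale panels (300,000 for the exposure, 150,000 for the
outcome) because the weighted median's advantage over IVW and the Egger
intercept's recovery of mean pleiotropy are asymptotic properties —
at small panel sizes instrument-strength noise (violating the
no-measurement-error assumption) dominates both, which is itself a
documented behaviour, not a defect. Mediation-attenuation recovery uses
200 replicates per scenario at 40,000 per panel — large enough that
mediator-beta measurement error no longer leaks mediated signal into the
direct effect — with mediated proportions 0, 0.5 and 1 of a total log-odds
effect of 0.59; the attenuation summary averages the replicates where the
ratio is defined (the near-zero-total guard must stay rare, and is
asserted to).

## Known limitations

* Exposure–exposure covariance in multivariable MR is assumed zero
  (summary-data setting).
* No proxy-variant lookup; unmatched variants are dropped and logged.
* The attenuation fraction is a point decomposition with component CIs;
  no product-of-coefficients variance or bootstrap CI for the mediated
  proportion is computed.
* The enrichment scan's empirical p is conservative under heavy count ties
  (integer counts, add-one rule).
* Weak instruments bias two-sample MR towards the null and inflate the
  Egger intercept; conditional F and mean F are reported so users can see
  when they are in that regime.
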