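---
title: "Methods: PRS association and absolute risk of contralateral breast cancer in BRCA1/2 carriers"
author: "cbcprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS association and absolute risk of contralateral breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbcprs)
```

## The problem

Women carrying a pathogenic BRCA1 or BRCA2 variant who have had a first
breast cancer face a high risk of a second primary in the opposite breast
(contralateral breast cancer, CBC) — on the order of 20–25% within ten
years. Whether to undergo risk-reducing contralateral mastectomy is a
consequential decision, and a common-variant polygenic risk score (PRS) may
refine the individual risk on which that decision rests. `cbcprs`
implements the full analysis chain for this question: scoring and
standardizing a multi-variant PRS, constructing a retrospective
left-truncated survival cohort, estimating the hazard ratio per SD of the
PRS with appropriate stratification and clustering, and converting that
hazard ratio into PRS-percentile-specific absolute risk curves anchored to
an external incidence schedule.

## PRS scoring and standardization

The raw score is the weighted allele count
$\mathrm{PRS}_i = \sum_j w_j g_{ij}$, where $g_{ij} \in [0,2]$ is the
effect-allele dosage (hard calls or imputed expected counts) and $w_j$ the
published per-allele log odds ratio. Three flavors (overall, ER-positive,
ER-negative) reweight the same variants. Before scoring, source dosages are
aligned to the panel's effect alleles: a dosage coded on the other allele
becomes $2 - d$; variants whose allele pair does not match the panel are
dropped; strand-ambiguous pairs (A/T, C/G) are dropped when the source
allele frequency is more than 0.2 from the panel frequency, because strand
cannot then be resolved. Missing dosages are mean-imputed at $2p_j$, the
expected count under Hardy–Weinberg — the standard PRS convention — and
subjects missing more than 20% of the panel are flagged.

Standardization follows the two-population contract used in carrier
studies: center on the mean of the *analysis cohort* (affected and
unaffected alike) and scale by the SD of an *external reference* (general
population controls), so hazard ratios per SD are directly comparable with
general-population odds ratios per SD. The reference SD is a required
input with no default: it is a property of the external control series and
is not printed in the source material, so the package refuses to guess it.
Tests and simulations supply 1.0, consistent with the simulated panels
whose raw-score variance is calibrated to 1.

## Cohort eligibility and time at risk

Time is measured in years since the first breast cancer, and every woman
enters the risk set at exactly 1.0 year: a CBC within the first year is
considered synchronous (possibly a misclassified metastasis) and the woman
is excluded, so earlier time contributes no risk. Exclusions are logged one
reason per applied rule: missing baseline (ascertainment) age, synchronous
CBC (judged on exact dates when available, otherwise on the age
difference), known metastatic first tumor (unknown status is retained and
assumed non-metastatic), and a first cancer less than one year before
baseline — the last is a reason code this package adds because such women
can never enter the risk set.

Exit is the qualifying CBC age, or the earliest of baseline age,
risk-reducing mastectomy and death. Event definitions: `all_cbc` (invasive
or in situ), `invasive_only` (in situ CBCs censor at their diagnosis age),
and ER-specific definitions in which CBCs of the alternative ER status
censor at the CBC age. On unimputed data a CBC of *unknown* ER status also
censors under the ER-specific definitions; in the imputation path ER is
completed per dataset first, so this rule only bites when the ER-specific
analysis is run without imputation. A distant-relapse sensitivity
additionally censors at relapse and drops women whose relapse precedes
entry. The reading of the relapse-exclusion window is genuinely ambiguous
in the source description (relative to baseline versus relative to entry);
the package implements exit-before-entry exclusion, which is the reading
that follows mechanically from the time scale.

Birth-cohort quartiles are computed on the analysis cohort's observed
birth-year distribution with linear-interpolation quantiles (type 7),
recorded in the output metadata; degenerate distributions collapse to
fewer levels rather than erroring.

## Association models

The main model is a Cox partial likelihood with delayed entry at 1 year,
stratified by country (each country has its own baseline hazard), adjusted
for birth-cohort quartiles, with variance estimated by the cluster-robust
sandwich over family identifiers, since relatives share genotype and
environment. Fitting is delegated to the `survival` package; ties use the
Efron approximation (the accurate default; the source is silent on ties).
Duplicating every record within its family leaves both the point estimate
and the cluster-robust SE invariant while the naive SE shrinks by
$1/\sqrt{2}$ — the sandwich-algebra property the tests assert (under
Breslow ties, where the invariance is exact).

The categorical analysis cuts the standardized PRS at the 5/10/20/40/60/
80/90/95 percentiles of the *unilateral-case* distribution (half-open
bands, 40–60 reference). Under a standard-normal PRS and log-linear
per-SD effect $\beta$, the expected band hazard ratio is a ratio of
truncated-normal expectations,
$E[e^{\beta z} \mid z \in B] / E[e^{\beta z} \mid z \in \text{ref}]$,
computed by quadrature to 1e-8; the tests verify this against the closed
form $e^{\beta^2/2}\,[\Phi(b-\beta)-\Phi(a-\beta)]/[\Phi(b)-\Phi(a)]$ and
check that large-sample categorical fits agree with the prediction — the
"gray line" consistency between the categorical and continuous models.
A useful reflection identity, asserted in the tests, is
$\mathrm{HR}_{0\text{–}5}(\beta) = \mathrm{HR}_{95\text{–}100}(-\beta)$:
negating the PRS maps the bottom band onto the top band and fixes the
symmetric reference.

The PRS-by-age interaction model contains the PRS and its product with the
uncentered age at first cancer, so the "main effect" is the per-SD HR
extrapolated to age zero and the interaction the per-year multiplier; age
group fits (`<40`, `[40,50)`, `>=50`; boundary ages join the older group)
refit the continuous model on subsets. Variant-class subgroups (class I:
unstable or no protein; class II: stable mutant protein) are subset refits
keyed on the class column. No multiplicity adjustment is applied (two-sided
$\alpha = 0.05$), matching the source analysis.

Diagnostics: proportional hazards via the score test on scaled Schoenfeld
residuals against Kaplan–Meier-transformed time (`cox.zph`,
`transform = "km"` — the common reading of "transformed time"); refused
below 10 events. Linearity via a restricted cubic spline with three knots
at the 10/50/90 PRS percentiles, compared to the linear model by
likelihood ratio on the *unclustered* partial likelihood — a likelihood
ratio has no sandwich analogue, and the clustered fit is reported
alongside. Discrimination via Harrell's C counted within country strata
with left truncation honored, CI by a percentile bootstrap over whole
family clusters (1,000 resamples by default; the source states clustering
but not the method). Whether the published C used the PRS alone or the
full adjusted linear predictor is not stated; both are exposed and the
default is PRS-only.

## Missing covariates

Covariates (including CBC ER status) are imputed by chained equations:
variables visited in order of ascending missing fraction, binary variables
by logistic regression, 3+-level categoricals by proportional odds,
continuous variables by linear regression with predictive-mean matching
(5 donors), with approximate posterior draws of the model coefficients
between iterations. The event indicator and log follow-up time enter every
imputation model — standard survival-imputation practice. Ten completed
datasets and ten iterations are the defaults (the iteration count is this
package's choice; the source states only the dataset count). Pooling
follows the stated mean-of-estimates rule for the point estimate; the
Rubin total variance (within + $(1+1/m)\times$ between) is also computed
and drives the pooled intervals, clearly labeled, because the mean rule
alone yields no interval.

## The constrained-incidence calculator

Relative hazards alone do not give a woman her absolute risk. The
calculator takes an external marginal CBC incidence schedule
$\lambda_m(t)$ (by age group at first cancer, in years since first
cancer), a per-SD effect $\beta_{\mathrm{eff}} = \beta + \gamma \cdot
\mathrm{age}$ (interaction evaluated at a representative age: 35, 45, 55),
and a discretized standard-normal PRS population — 99 equal-weight
percentile nodes $z_k = \Phi^{-1}((k-0.5)/99)$ by default, Gauss–Hermite
quadrature available as an accuracy cross-check. It then solves for the
baseline hazard $\lambda_0(t)$ such that the PRS-density-averaged
incidence reproduces the marginal schedule, by forward recursion:

$$\lambda_0(t) = \lambda_m(t)\,
\frac{\sum_k w_k S_k(t)}{\sum_k w_k S_k(t) e^{\beta_{\mathrm{eff}} z_k}},
\qquad
S_k(t+\Delta) = S_k(t)\,
e^{-\lambda_0(t) e^{\beta_{\mathrm{eff}} z_k} \Delta},$$

with $S_k(0) = 1$. The deflation factor is the risk-weighted composition
of the surviving cohort: high-PRS women are depleted faster, so the
baseline hazard must exceed the naive $\lambda_m e^{-\beta^2/2}$-type
correction at later times. In the continuous-time limit
$d\bar S/dt = -\lambda_m \bar S$ exactly, so the density-weighted survival
equals the marginal survival; at step $\Delta$ the discrepancy is first
order in $\Delta$, and the tests verify both the ~20-fold shrinkage from
$\Delta = 1$ to $\Delta = 0.05$ years and an absolute deviation below
1e-3 at $\Delta = 0.05$. Percentile curves are then
$F(t \mid z_p) = 1 - \exp(-\sum_{u \le t} \lambda_0(u)
e^{\beta_{\mathrm{eff}} z_p} \Delta)$.

Numerical choices: default $\Delta = 0.1$ year (0.05 in the conservation
checks); schedules coarser than the grid are filled stepwise-constant;
the risk clock starts at the first cancer, with the 1-year entry offset
applied only when comparing against cohort Kaplan–Meier output; a single
central node ($z = 0$, $w = 1$) reproduces the marginal curve exactly for
any effect size, which the tests assert as a degeneracy check. Age enters
the effective beta uncentered, consistent with reporting a main effect
plus per-year interaction; a centering offset can be applied by passing
`age - center`. The external schedule itself is user-supplied input — the
published percentile risks depend on a prospective-consortium schedule
that is not printed anywhere reproducible, so the package treats the
schedule as data and validates its structure only.

## What the simulator emulates — and what it does not

The simulator exists so that every stage above has a ground-truth
acceptance surface. It reproduces, at the scale of the BRCA1 carrier
series by default: cohort size (6,591; 4,208 for the BRCA2 configuration),
event fraction (1402/6591 and 647/4208, enforced by calibrating the
baseline hazard against the realized censoring and linear predictors),
age-at-first-cancer distribution (truncated normal on [18, 85], means
41.8/44.5 from the cohort description; SD 10 is this package's choice of a
realistic spread, as only ranges are printed), country strata (5, with
geometrically decaying weights mimicking few large and many small
studies), family clustering via explicit parental genotypes and Mendelian
transmission (family sizes 1/2/3 with probabilities 0.906/0.080/0.014,
matched to the printed cluster counts: 5,923 clusters among 6,591 women,
554 with more than one member), administrative censoring with ~6-year
median follow-up past entry, risk-reducing mastectomy (3%) and death
(0.8%) as competing censoring, in situ CBCs (10%), CBC ER status
(7/32/61% positive/negative/unknown), and covariate missingness of the
observed magnitude (e.g., 56% for ER of the first tumor). Events follow
the proportional-hazards truth
$\lambda(t \mid z, a) = \lambda_b(t) e^{(\beta + \gamma a) z}$ drawn by
inversion of the piecewise cumulative hazard, with an overflow guard on
the linear predictor.

Deliberately not modeled: linkage disequilibrium between variants,
genotype-imputation uncertainty beyond optional fractional dosage noise,
ascertainment through family-history-driven clinic referral (the real
series is clinic-ascertained and therefore risk-enriched), and
calendar-time effects. Consequently, passing recovery tests demonstrate
that the *estimators* are unbiased under the stated model at the stated
scale — they cannot demonstrate robustness to referral bias or index-event
bias, which the source discusses as limitations of the design itself.

One master seed drives the whole simulation; each stage derives a
deterministic child seed, so outputs are byte-identical under a fixed
configuration and stages are perturbation-isolated. The default
missingness mechanism is MCAR (the source does not state a mechanism);
a MAR-on-country option exists to stress the imputer.

## Validation problem sizes

The test suite runs parameter recovery at the full cohort scale
(20 replicates of 6,591 and 4,208 subjects with 313 variants each, and of
the 3,154-subject under-40 subgroup), the closed-form concordance
cross-check at n = 50,000 uncensored, the gray-line categorical/continuous
consistency at n = 50,000, and 200-replicate null-calibration sweeps for
the Schoenfeld and spline diagnostics at n = 300 each. Smaller sizes
(n = 300–12,000) are used where an oracle is exact or a property is
structural. These sizes were chosen so each Monte-Carlo tolerance (3 MC
SEs unless an exact oracle exists) is meaningfully tight.

## Worked example

```{r example, eval = FALSE}
library(cbcprs)

cfg <- sim_config(seed = 5) # BRCA1-scale defaults
sim <- simulate_cbc_study(cfg, flavor = "er_negative")
elig <- apply_eligibility(sim$records)
iv <- build_risk_intervals(elig$records, event_definition = "all_cbc")
fit <- fit_cox_continuous(iv)
print(fit)
harrell_c(iv, nboot = 0)$c
km_cumulative_risk(iv, horizon = 10)$risk

# absolute risk at the 5th/95th percentile for a first cancer before 40
sched <- constant_incidence_schedule(0.25, horizon = 10, dt = 0.05)
bl <- constrain_baseline(sched, effective_beta(log(1.12), 0, 35))
subset(percentile_risk_curves(bl, c(5, 95)), abs(t - 10) < 1e-9)
```

## Known limitations

* No competing-mortality adjustment in the absolute-risk curves; risks are
  net of death, appropriate for the young, high-risk population but
  optimistic at older ages.
* No Fine–Gray competing-risk estimation for the ER-specific analyses;
  alternative-status events are censored, matching the source analysis.
* The imputer draws coefficients from an asymptotic normal approximation
  rather than an exact posterior; adequate at the cohort sizes used, but
  not a substitute for a fully Bayesian imputation at small n.
* The constrained-incidence recursion assumes the external schedule and
  the hazard-ratio scale refer to the same time origin and population;
  the package checks grid structure, not epidemiological compatibility.
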