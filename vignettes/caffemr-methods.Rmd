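---
title: "Methods: two-sample MR of caffeine exposures on kidney traits"
author: "caffemr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of caffeine exposures on kidney traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caffemr)
```

## The design

Habitual caffeine consumption correlates with kidney function in
observational data, but the correlation is confounded (lifestyle,
smoking, socio-economics) and potentially reverse-causal (declining
kidney function changes both caffeine clearance and drinking habits).
Two-sample Mendelian randomization (MR) sidesteps both problems by
using genetic variants as instruments: variant–exposure associations
come from a GWAS of the exposure (plasma caffeine level, or
self-reported caffeine intake), variant–outcome associations from an
independent GWAS of a kidney trait (log eGFR from creatinine or
cystatin C, BUN, log UACR, urinary sodium, CKD), and the causal effect
is estimated from the ratio of the two.

The instruments are *cis* variants at the two loci with established
roles in caffeine pharmacokinetics: *CYP1A2*, encoding the enzyme
responsible for the large majority of caffeine clearance, and *AHR*,
its transcriptional regulator. Because variants within each locus are
in substantial linkage disequilibrium, one signal — the strongest — is
kept per locus, giving two instruments per exposure
(`caffeine_instruments()`): rs4410790 (*AHR*) and rs2472297 (*CYP1A2*)
for plasma caffeine; rs4410790 and rs2470893 for intake. With only two
instruments, pleiotropy-robust estimators (MR-Egger, MR-PRESSO,
weighted median/mode) are not identified — they need at least three
variants — so the pipeline deliberately stops at Wald/IVW and leaves
those methods out of scope.

## Estimator

For variant $j$ with harmonized exposure association
$(\hat\beta_{Xj}, \sigma_{Xj})$ and outcome association
$(\hat\beta_{Yj}, \sigma_{Yj})$, the Wald ratio is

$$\hat\theta_j = \frac{\hat\beta_{Yj}}{\hat\beta_{Xj}},$$

with standard error, to first order,
$\sigma_j = \sigma_{Yj} / |\hat\beta_{Xj}|$ — the standard error of the
variant–outcome association divided by the variant–exposure
association. The second-order (full delta-method) option adds the
exposure-side term:
$\sigma_j^2 = \sigma_{Yj}^2/\hat\beta_{Xj}^2 +
\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$.

Ratios are pooled by inverse-variance weighting with $w_j = 1/\sigma_j^2$:
$\hat\theta = \sum w_j \hat\theta_j / \sum w_j$,
$\mathrm{se}(\hat\theta) = (\sum w_j)^{-1/2}$, and heterogeneity is
summarized by Cochran's $Q = \sum w_j(\hat\theta_j - \hat\theta)^2$ on
$k-1$ degrees of freedom.

"Random-effects IVW" is ambiguous at $k = 2$, so both common readings
are implemented and the choice is exposed rather than hidden:

* **multiplicative** (default): the fixed-effect point estimate with
  its SE inflated by $\sqrt{\max(1, Q/(k-1))}$. The floor at 1
  guarantees the random-effects SE is never smaller than the
  fixed-effect SE.
* **additive DerSimonian–Laird**:
  $\tau^2 = \max\{0, (Q-(k-1))/(\sum w_j - \sum w_j^2/\sum w_j)\}$,
  re-weighting by $w_j^* = 1/(\sigma_j^2+\tau^2)$.

For $k = 2$ variants with equal SEs the two flavors provably coincide;
the test suite uses this as a cross-check, and checks both against
`metafor` as an independent meta-analysis implementation. Confidence
intervals and two-sided p-values use the normal reference distribution
(matching standard summary-data MR practice and the 95% CI
convention), with no multiple-testing adjustment across outcomes.
Binary outcomes (CKD) are analyzed on the log-odds scale and reported
as odds ratios via `glance()` and `forest_table()`. Exposure betas
with $|\hat\beta_{Xj}| < 10^{-12}$ are treated as zero and refused
(undefined ratio); instruments with $|\hat\beta_{Xj}|/\sigma_{Xj} < 3$
trigger a weak-instrument warning.

### Choosing the SE order

The first-order SE is the default because it is the conventional
summary-data MR formula and is accurate whenever
$\theta\,\sigma_{Xj}/\hat\beta_{Xj} \ll \sigma_{Yj}/\hat\beta_{Xj}$ —
true for near-null effects or very precise exposure GWAS. It is *not*
a good approximation for a strong effect estimated from a moderately
sized exposure GWAS: at $\theta = 0.5$, $n_{exp} = 50{,}000$,
$n_{out} = 400{,}000$ and instrument effects near 0.12, the neglected
exposure-side term ($\approx 0.025$) exceeds the first-order SE
($\approx 0.018$), and simulated CI coverage drops to roughly 85%.
The parameter-recovery checks therefore use `se_method =
"second_order"`, which restores ~95% coverage; under the null the two
coincide and the first-order default is calibrated (the test suite
measures both).

## Harmonization

The two exposure GWAS themselves illustrate why harmonization is
unavoidable: the shared *AHR* instrument rs4410790 is reported against
effect allele T (frequency 0.36) in the plasma-caffeine GWAS and
against C (frequency 0.38) in the intake GWAS. `harmonize()` puts each
exposure/outcome pair on the exposure's effect allele, resolving
swapped alleles (negate the outcome beta, reflect its frequency),
complementary-strand labels (recode), and both at once. Palindromic
(A/T, C/G) variants carry no strand information in their labels; the
default policy infers orientation by comparing effect-allele
frequencies across the two GWAS, and drops the variant whenever either
frequency is within 0.08 of 0.5 (band chosen so that typical
cross-cohort frequency drift of a few percentage points — the caffeine
instruments themselves drift by two — cannot flip the inference; the
analysis' own instruments are non-palindromic, so the policy only
matters for arbitrary inputs). Instruments absent from the outcome GWAS are
reported as missing — no proxy-variant search is attempted, since none
is described for the original analysis. Post-orientation frequency
discrepancies above 0.2 are flagged in the audit but never dropped:
cohorts genuinely differ.

Two invariants pin the implementation down: harmonizing an
already-harmonized pair is a no-op, and jointly flipping the effect
allele of both members of a pair leaves every Wald ratio — and hence
the pooled estimate — unchanged.

## Instrument selection

`assign_loci()` labels variants with gene regions using closed
1-based windows of `[start - 100 kb, end + 100 kb]`; `select_instruments()`
drops variants above the significance threshold (default
$5\times10^{-8}$; no explicit cutoff is conventionally stated for
cis-instrument screens, and the caffeine instruments pass genome-wide
significance comfortably), then keeps the smallest-p variant per
locus. When an LD matrix is supplied, further variants are retained
greedily in ascending p order if their $r^2$ with everything already
kept is below 0.1. Ties break on larger $|\beta|/\mathrm{se}$, then
rsid, so selection is row-order invariant.

## Synthetic data

Two generators make the pipeline testable end to end without any
download.

**Summary-level** (`sim_summary_stats()`): the standard two-sample MR
generative model. True exposure effects are uniform on
$[0.10, 0.15]$ (the range of the caffeine instruments), frequencies
uniform on $[0.2, 0.8]$, SEs from the single-SNP approximation
$\mathrm{se}^2 = 1/(2f(1-f)n)$ for a unit-variance trait, observed
betas normal around their truths, and the outcome beta centered at
$\theta \beta_X + \alpha_j$ with optional pleiotropy
$\alpha_j \sim N(0, \mathrm{sd}^2)$. Default sample sizes are 9,876
(the plasma-caffeine GWAS scale) and 400,000 (kidney-trait consortium
scale). Under the null with valid instruments, the fixed-effect 95% CI
covers zero at its nominal rate and $Q \sim \chi^2_{k-1}$; both are
verified at 10,000 replicates.

**Individual-level** (`sim_cohort()`): a mechanistic formalization of
the metabolizer-compensation explanation for the sign discrepancy
between the plasma and intake analyses. On log scales:

$$c_i = \textstyle\sum_l \delta_l g_{il} + \varepsilon_c,\qquad
I_i = \mu + \kappa c_i + \varepsilon_I,\qquad
P_i = I_i - c_i,\qquad
Y_i = \gamma_p P_i + \gamma_i I_i + \varepsilon_Y.$$

Clearance alleles ($\delta_l > 0$) mark fast metabolizers; $\kappa \in
[0,1]$ is how strongly intake is titrated toward a constant stimulant
effect ($\kappa = 1$: full compensation, plasma decouples from
genotype; $\kappa = 0$: no compensation, intake decouples). The
steady-state identity $P = I - c$ holds exactly row-wise, by
construction. These equations are this package's formalization of a
verbal mechanism — no quantitative estimate of $\kappa$ in real
populations is implied, and the model omits pharmacokinetic
compartments, metabolite panels, and FFQ measurement error entirely;
passing tests show the mechanism is *sufficient* to produce the sign
discrepancy, not that it is the true explanation.

The genotype effects are $\delta(\kappa-1)$ on log plasma,
$\delta\kappa$ on log intake and
$\delta[\gamma_p(\kappa-1)+\gamma_i\kappa]$ on the outcome, so the
Wald estimands are, independently of $\delta$,

$$\theta_{plasma} = \gamma_p + \gamma_i\frac{\kappa}{\kappa-1},
\qquad
\theta_{intake} = \gamma_p\frac{\kappa-1}{\kappa} + \gamma_i,$$

implemented in closed form by `expected_mr_estimates()` and used as
the oracle for the empirical GWAS → MR route. With
$\gamma_p = -0.2,\ \gamma_i = 0,\ \kappa = 0.5$ the estimands are
exactly $-0.2$ and $+0.2$: a harmful plasma effect masquerading as a
protective intake effect, the qualitative pattern of the caffeine
analyses. Defaults: two loci with allele frequencies 0.36 and 0.73
(matching the real instruments), clearance effects 0.15 and 0.20 per
allele, noise SDs 0.3 (clearance, intake) and 1 (outcome) — chosen so
that instrument F-statistics at $n \sim 10^5$ are comfortably strong,
as they are in the real data.

```{r mechanism}
expected_mr_estimates(kappa = 0.5, gamma_p = -0.2, gamma_i = 0)
```

**Phenotype derivations** (`derive_phenotypes()`) reproduce the
kidney-trait constructions used by the outcome GWAS: BUN (mg/dL) is
blood urea (mg/dL) times 2.8; UACR (mg/g) is
$100 \times$ albumin (mg/L) / creatinine (mg/dL); eGFR is winsorized
to $[15, 200]$ mL/min/1.73m$^2$ before log transformation.

## Reproducibility and numerical choices

All generators take one master seed and derive per-component
sub-streams deterministically, so adding a draw to one component never
perturbs another; output is bit-reproducible given (seed, config).
Two-sided p-values computed by generators are floored at the smallest
positive normal double so that extreme associations cannot underflow
to an invalid $p = 0$. Simulation-based checks run at 10,000
replicates (null calibration), 1,000 replicates (parameter recovery),
and a 200,000-individual cohort split into disjoint halves (mechanism
reproduction) — sizes at which Monte-Carlo error is a small fraction
of the tolerances being asserted.

## Auditing printed results

`check_reported_consistency()` recomputes, for each published pooled
estimate shipped in `reference_results()`, the p-value implied by the
printed estimate and 95% CI under the normal approximation, carrying
the rounding interval of every printed digit through the computation
(odds ratios on the log scale). Seven of the eleven reported rows are
internally consistent under this audit; the remaining four carry
apparent typographic errors in their printed intervals (a CI not
bracketing its estimate, reversed bounds, marked asymmetry, or a p
incompatible with the CI by orders of magnitude) and are flagged
`known_typo` so downstream checks can exclude them explicitly rather
than silently.

## Limitations

* The headline numeric estimates for the real kidney outcomes require
  the public consortium outcome GWAS, which are not redistributed
  here; the packaged surface validates the estimator, harmonization,
  and mechanism on synthetic data plus the printed instrument table.
* With two instruments, heterogeneity statistics are nearly
  uninformative and pleiotropy cannot be tested; results inherit the
  cis-instrument validity assumption.
* The compensation simulator is a sufficiency demonstration, not an
  estimate of real-world behavior.
* Findings from European-ancestry GWAS may not transport to other
  populations; nothing in the pipeline addresses trans-ancestry
  generalization.
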