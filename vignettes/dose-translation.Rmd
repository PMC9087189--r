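---
title: "Dose translation from mouse xenograft efficacy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose translation from mouse xenograft efficacy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosetrans)
```

## The problem

A mouse tumor-xenograft study yields an efficacious dose in mg/kg. How close
does a simple interspecies conversion of that dose come to the dose
eventually recommended in patients? `dosetrans` implements the two standard
conversion rules, the retrospective accuracy analysis around them, and a
calibrated simulator of drug-record cohorts so that every stage of the
pipeline can be tested end to end.

## The translation rules

**BSA route.** Dose scaling by body surface area uses fixed species factors
that convert mg/kg to mg/m²: 3 for mouse, 37 for human. The human
equivalent dose (HED) of a mouse dose $D_m$ (mg/kg) is

$$\mathrm{HED} = D_m \times 3 / 37 \;\; \mathrm{mg/kg},$$

i.e. a 37 mg/kg mouse dose maps to exactly 3 mg/kg in human. The package
performs this as the explicit two-step chain (`mgkg_to_mgm2()` then
`mgm2_to_mgkg()`), and `bsa_predict_human_dose()` is defined as that
composition, so the identity holds bit for bit.

**BW route.** For intravascular proteins with molecular weight above
100 kDa, physiology scales closer to body weight and the mg/kg dose carries
over unchanged. `select_method()` encodes the cutoff as a strict
inequality — exactly 100 kDa still uses BSA — which is the literal reading
of the "MW > 100 kDa" convention; a 54.1 kDa bispecific falls on the BSA
side.

**Unit conventions.** All internal arithmetic is in mg/kg; other unit bases
are normalized at the boundary. Absolute mg doses divide by the species
default body weight and mg/m² doses divide by the species BSA factor. We
use 70 kg for the default human body weight, paired with the factor 37;
regulatory conversion tables often pair 37 with 60 kg, but the 70 kg/37
pairing is the convention this analysis was built on and the package keeps
it (a user can register an alternative species profile if desired).
Clinical doses labelled in mg/m² are converted to mg/kg (÷37) before any
fold-error comparison rather than compared in mg/m² space; this is a
documented modelling choice, as accuracy metrics need both doses on one
axis.

**Schedules.** Doses are compared as the total administered over the first
24 h of dosing (`day1_total()`): two 5 mg/kg administrations on Day 1 count
as 10 mg/kg, while a dose given once every four days counts only its Day-1
administration. Differences in intermittent schedules beyond Day 1 are
deliberately not modelled, on either the preclinical or the clinical side.

**Starting dose.** `mrsd_from_hed()` divides the HED by a safety factor
(default 10). It is included for context only; the accuracy analysis never
uses it.

## The drug-record schema and curation rules

Records are curated from the literature, and most curation rules are human
judgments (choice of study, model/route matching, one indication per drug).
Those are represented as schema fields and provenance columns, not
recomputed. Three rules are computable and enforced:

* **Efficacy floor** (`is_efficacious_response()`): tumor stasis or
  regression always qualifies; percent tumor growth inhibition qualifies at
  ≥ 60 (inclusive); other metrics (T/C, survival) rely on a curator flag of
  author-declared significance. TGI above 100 (regressions reported on the
  TGI scale) warns but is accepted.
* **Exclusions** (`apply_exclusions()`): records flagged `mtd_only`
  (efficacy seen only at a maximum tolerated dose, risking a saturated
  response) or `syngeneic_model` (mouse tumor rather than human xenograft)
  are partitioned out with the triggering flag as the reason. Other flags
  annotate without excluding.
* **Clinical ranges** (`recommended_clinical_dose()`): a recommended range
  collapses to the arithmetic mean of its endpoints after each endpoint is
  normalized to mg/kg ("average" is read as the plain arithmetic mean; the
  result is invariant to endpoint order and endpoint units).

Validation is strict and fails loudly naming row and column: unknown
modality classes, missing molecular weight on large-molecule classes,
negative or unparseable doses, and misordered ranges are load errors, never
silently dropped rows.

## The accuracy metric

Per drug, the fold error is $FE = \max(p/c,\, c/p)$ for predicted dose $p$
and clinical dose $c$; it is symmetric, scale invariant, ≥ 1, and undefined
for nonpositive doses (they are rejected). "Within $k\times$" means
$FE \le k$ with an **inclusive** boundary: a drug at exactly 3.0-fold
counts as within 3×. This closed reading makes summary tables
deterministic. Percentages are kept unrounded internally;
`format_pct()` applies the one-decimal display convention used in the
summary tables, so rounding can never hide a mismatch in tests.

`summarize_translation()` tabulates the groups of the retrospective
analysis: small molecules by route (IV, PO, IV + PO) plus the
immune/hormone-targeted subgroup, and large molecules as the antibody + ADC
pool with ADC, antibody (checkpoint inhibitors and bispecifics counted among
the antibodies) and checkpoint-inhibitor subsets. BW columns are reported
for large-molecule groups only. Empty groups are omitted with a warning
rather than shown as spurious zeros. `bootstrap_ci()` adds percentile
bootstrap intervals for the percentages; these go beyond the published
point estimates and report output labels them as additions.

## The fitted object

`dose_translation()` wraps the pipeline as a model fit: validation,
exclusion, evaluation of both routes per drug, selection of a headline
route (`"auto"` = per-drug molecular-weight rule), and a moment fit of the
fold-deviation model below to each route. `summary()` gives the class
table, `coef()` the fitted $(\mu, \sigma)$ per route, `residuals()` the
per-drug $\log_{10}(c/p)$, `predict()` translates new records, `plot()`
draws the log-log scatter with the identity and ±3-fold reference lines,
and `simulate()` draws synthetic cohorts from the fitted error model.

## The synthetic-cohort model

Fold errors on log-log dose axes suggest multiplicative structure, so the
generator models the prediction error as

$$\log_{10}(c/p) = \varepsilon \sim \mathcal{N}(\mu, \sigma^2),$$

giving the analytic within-$k$ probability

$$P(k) = \Phi\!\left(\frac{\log_{10}k - \mu}{\sigma}\right) -
         \Phi\!\left(\frac{-\log_{10}k - \mu}{\sigma}\right).$$

Mouse doses are sampled log-uniformly over 0.1–100 mg/kg by default, a
typical span for xenograft efficacious doses; the span is configurable per
model. Modality class, routes, molecular weights (IgG-scale values for
antibodies and ADCs, sub-kDa for small molecules, ~55 kDa for bispecifics)
and a TGI readout in the efficacious range are filled in solely so the
generated tables pass full schema validation and exercise the grouping and
method-selection code paths; they carry no biological signal. Every
generated record is marked synthetic.

**Calibration.** `calibrate_error_model(p2, p3)` solves $P(2) = p_2$,
$P(3) = p_3$ for $(\mu, \sigma)$. Two numerical points matter:

* $P(k)$ depends on $\mu$ only through $|\mu|$, so the sign of the bias is
  not identifiable from two band probabilities and the Jacobian of the
  2×2 system is singular at $\mu = 0$. The solver therefore nests two
  one-dimensional root finders (inner: $\mu \ge 0$ from $P(3) = p_3$ at
  fixed $\sigma$; outer: $\sigma$ from $P(2) = p_2$), returns the
  nonnegative root by convention, and verifies residuals below $10^{-8}$.
* Not every $(p_2, p_3)$ pair is attainable. With $P(3)$ fixed, $P(2)$ is
  maximal in the unbiased case ($\mu = 0$, where
  $\sigma = \log_{10}3 / \Phi^{-1}((1+p_3)/2)$), which caps the feasible
  within-2× fraction. Empirical fraction pairs from small cohorts can
  exceed that cap — for example (0.567, 0.667) or a pair with
  $p_2 = p_3$ — because real fold-error distributions are not exactly
  log-normal. Such pairs raise an explicit infeasibility error, and
  `calibrate_error_model(NULL, p3)` provides the unbiased closed form
  calibrated to the within-3× fraction alone for exactly these cases.

**What the simulator does not emulate.** Real cohorts have heavy-tailed,
class-correlated errors (target-mediated disposition of biologics,
interspecies bioavailability differences, model–indication mismatches);
the generator is a clean log-normal. Passing pipeline tests on synthetic
cohorts therefore demonstrates correctness of the computation — conversion
constants, counting, grouping, calibration — not predictive validity on
real drugs, which only curated data can show.

## Problem sizes and numerical choices

The test suite verifies the structural identities (round trip, composition,
symmetry, scale invariance, monotonicity, a naive-loop counting oracle on
1,000 random instances) and the stochastic properties at sizes chosen to
keep Monte-Carlo error well below the tolerances used: parameter recovery
at $n = 10{,}000$ (moment-fit error $\lesssim \sigma/\sqrt{n}$), empirical
within-$k$ fractions at $n = 100{,}000$ against 3 binomial standard errors,
and pipeline closure at $n = 20{,}000$. The acceptance script simulates at
the retrospective study's own cohort sizes (90 small molecules, 30 large
molecules, 9 ADCs), so its percentages carry the binomial noise a real
cohort of that size would — about 4–9 percentage points of standard error —
by design.

Degenerate inputs are rejected rather than repaired: negative doses,
nonpositive doses in fold errors, empty row sets for percentages, empty
Day-1 administration lists, safety factors below 1, and bootstrap
resampling below 100 draws are all errors. Built-in species profiles can
never be silently overridden by user configuration.

## Limitations

The package evaluates dose-based translation only: no allometric-exponent
scaling, exposure or PBPK prediction, no per-patient BSA formulas, and no
modelling of schedules beyond the first 24 h. The starting-dose helper is a
labelled convenience, not a safety recommendation. Accuracy estimates on
synthetic cohorts inherit the log-normal assumption discussed above.
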