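---
title: "Elemental-impurity risk assessment: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elemental-impurity risk assessment: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elemrisk)
```

## The problem

Oral supplements taken daily and long-term — effervescent vitamin C
tablets are the motivating product — can carry trace elemental impurities
picked up from raw materials, catalysts, or processing equipment. A
regulatory screening study quantifies a fixed set of elements by ICP-MS
and asks two questions: does chronic intake at the labeled dose pose a
non-carcinogenic hazard, and, for the carcinogenic elements, is the
incremental lifetime cancer risk acceptable? `elemrisk` implements that
assessment end to end: instrument readings to censored matrix
concentrations, concentrations to risk metrics, and a Monte Carlo layer
that propagates the uncertainty in intake, body weight and concentration
through the same equations.

The ten elements covered by the packaged reference set are the ICH Q3D /
USP <232> oral-screening panel: Class 1 (Cd, Pb, As, Hg), Class 2A (Co,
V, Ni) and the Class 3 elements commonly present in oral dosage forms
(Cr, Sb, Sn).

## From instrument signal to concentration

ICP-MS reports solution concentrations in ppb (ng/ml) through a daily
linear calibration, `response = slope * ppb + intercept`, fit by ordinary
least squares (`fit_calibration()`, backed by `stats::lm`). The packaged
curves (`default_calibration_curves()`) are the study's reported lines
for the ten quantification isotopes, with their validity ranges.

Replicates (triplicate by design) are aggregated per sample-by-element
cell by `summarize_replicates()`: mean and sample (n−1) standard
deviation, the conventional estimator for triplicate analytical
chemistry. A cell is *censored* when its replicate **mean** falls below
the element's limit of detection. Two consequences of this rule matter:

* individual sub-LOD replicates are retained in the mean — no LOD/2 or
  zero substitution is applied, because whole cells, not single
  replicates, are the reporting unit;
* censoring is absorbing. A censored cell never yields a numeric
  concentration, EDI, HQ or CR downstream; it is rendered `"NC"` (not
  computable), which is deliberately distinct from zero.

Detected means convert to matrix concentration by the dilution-chain
relation

$$C\ [\mu g/g] = a \cdot \frac{V}{m} \cdot 10^{-3},$$

with `a` the mean reading (ppb), `m` the digested tablet mass (g) and
`V` the effective diluted volume (ml). `V` is always the product of the
printed chain — digest volume times each fold-dilution
(`sample_prep()`): the reference preparation digests 0.4 g into 10 ml and
dilutes 1/4, 1/100 and 1/5, so `V = 10 × 4 × 100 × 5 = 20000` ml. Summary
phrases such as an overall "20000-fold dilution" are never used as
inputs; only the chain product is arithmetically consistent with the
conversion. Standard deviations are propagated by the same linear
scaling; no other SD model is attempted.

## The deterministic risk metrics

For an adult exposure scenario (`exposure_scenario()`) the estimated
daily intake of an element is

$$EDI\ [mg/kg/day] = \frac{EF \cdot ED \cdot IR \cdot C \cdot 10^{-3}}{BW \cdot AT},$$

with defaults IR = 4.5 g/day (one labeled tablet), BW = 70 kg, EF = 365
days/year, ED = 30 years and AT = EF·ED days. The default averaging time
makes the time factors cancel, so EDI reduces to `C·IR·10⁻³/BW`; the full
form is kept so non-chronic scenarios remain expressible.

* **HQ** = EDI / RfD, per element. RfD is the USEPA chronic oral
  reference dose. HQ ≥ 1 flags a hazard (the threshold is inclusive).
  Pb has no established oral RfD: its HQ is *not computable*, reported
  with an explicit `"RfD unavailable"` note rather than silently zero,
  so a detected-Pb input can never pass unexamined.
* **HI** = the sum of defined HQs within a sample; HI ≥ 1 flags
  cumulative hazard. With exactly one detected element HI equals that
  element's HQ; with everything censored HI is `"NC"` with no flag.
* **CR** = EDI × CSF for the five carcinogens (Cd 0.38, Cr 0.5,
  Pb 0.0085, Ni 1.7, As 1.5 (mg/kg/day)⁻¹). Classification follows the
  USEPA convention: below 10⁻⁶ *negligible*, 10⁻⁶–10⁻⁴ *acceptable*,
  above 10⁻⁴ *unacceptable* (the upper bound is a strict inequality).
  Labeling sub-10⁻⁶ risks "negligible" rather than folding them into
  "acceptable" is a presentation choice; the decision boundary that
  matters is 10⁻⁴.
* **PDE screen**: daily elemental intake `C × IR` (µg/day) against the
  oral permitted daily exposure; exceeded only on strict inequality.

Rounding happens exclusively at the reporting layer
(`format_risk_table()`: concentrations to 2 decimals, EDI to 2
significant figures, HQ/HI to 3 decimals, CR to 4 significant figures);
every flag comparison uses full precision.

### The Ni reference dose

Compendial listings of the Ni oral RfD disagree in their units: the same
figure appears both as 20 µg/kg/day and as a raw "20000" with a
mg/kg/day column header. The packaged default adopts 0.02 mg/kg/day (the
µg/kg/day reading, consistent with the values quoted for every other
element) and records the alternate in the reference set's `note` column.
Because reference constants are data, not code (`load_reference_set()`
accepts a YAML override), a user who prefers the other reading can
supply it without a package change. Cr is treated without speciation;
the 0.003 mg/kg/day RfD used for screening is the conservative
(hexavalent) value.

## The probabilistic layer

The deterministic metrics are point estimates at fixed IR, BW and C. The
simulation (`run_simulation()`) re-evaluates HQ and CR over `n` = 10,000
independent draws of the triple (IR, BW, C) and summarizes each metric by
empirical percentiles. Decisions compare the uncertainty upper bound
(P95) and lower bound (P5) with the allowable limits HQ < 1 and
CR < 10⁻⁴.

Distribution choices, all configurable per variable
(`dist_point()`, `dist_uniform()`, `dist_triangular()`):

* **BW** ~ uniform(50, 90) kg, the adult range used in screening-level
  assessments of supplement consumers.
* **IR** ~ uniform(4.5, 9) g/day: one labeled 4.5 g tablet up to two,
  the product mass equivalent to the 2000 mg/day tolerable upper intake
  of vitamin C.
* **C** ~ uniform over the element's detected range in the reference
  panel (Hg 0.25–0.45, Cr 0.55–0.80 µg/g), pooled per element across
  samples; per-sample simulation is available by overriding `c_dist`.

Uniform is the default shape throughout because only ranges, not shapes,
are defensible from the available information; on a bounded interval the
uniform is the maximum-entropy choice and standard in screening-level
Monte Carlo. Inputs are sampled mutually independently — no copulas; a
dependence model between body weight and intake would be speculation
here.

Numerical fixings, chosen so results are bit-stable per seed:

* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), fixed and documented.
* One integer seed governs a run; per-variable substreams are derived
  deterministically (`seed+1` IR, `seed+2` BW, `seed+3` C), so adding or
  re-ordering a variable never perturbs another's draws.
* Sensitivity is reported as Spearman rank correlation between each
  input and each metric with a t-approximation p-value — rank-based
  because HQ is nonlinear (reciprocal) in BW.

Because HQ is monotone in each input, closed-form checks exist for
degenerate configurations: with point IR and C and uniform BW on
\[b₁, b₂\], the q-quantile of HQ is `C·IR·10⁻³/(RfD · BW-quantile(1−q))`.
The test suite verifies the empirical quantiles against these closed
forms within three asymptotic standard errors at n = 10,000, and that
point-mass configurations collapse exactly to the deterministic table.

## What the synthetic generator emulates — and what it does not

`generate_panel()` produces replicate readings with the statistical
structure the analysis assumes: at most one detected element per sample
at a true matrix concentration (the reference design,
`study_spike_plan()`, spikes Hg in four samples at 0.25–0.45 µg/g and Cr
in three at 0.55–0.80 µg/g, leaving five samples clean); triplicate
readings around the exact dilution-chain inversion `a = C·m·10³/V`;
multiplicative truncated-at-zero normal noise with a default relative SD
of 0.3, matching the magnitude of sub-ppb triplicate scatter; and
true-zero cells drawn uniformly on \[0, LOD/2\], which guarantees
censoring while exercising nonzero signal paths. The truncated normal is
sampled by inverse CDF so one seed yields one deterministic stream.

It does **not** emulate instrument drift, internal-standard behavior,
isobaric interference, matrix effects, or correlated replicate errors.
Passing tests on synthetic panels therefore demonstrate that the
*pipeline arithmetic and censoring logic* are correct under the assumed
error model, not that the method is robust to real instrumental
artifacts.

Problem sizes used by the test suite: 12 samples × 10 elements × 3
replicates per panel; 1000 seeded panels for the bias/recovery check at
30% replicate noise (and 300 at 10% for the spread check); 10,000
iterations per simulation. These sizes match the study design and keep
the default test run fast.

## Degenerate inputs and edge behavior

* Calibration fitting refuses fewer than three standards or a
  zero-variance design; back-calculated responses below the intercept
  are flagged censored-at-zero rather than clamped silently.
* A replicate mean exactly at the calibration floor counts as in-range;
  a daily intake exactly at the PDE is not an exceedance; HI exactly 1
  is flagged. Boundary conventions follow the inclusive-hazard /
  strict-exceedance reading of the screening thresholds.
* A spike whose expected reading falls below the LOD is generated with a
  warning — it is a legitimate way to exercise the censoring path.
* Simulation requests that cannot be honored (HQ for Pb, CR for an
  element without a CSF) fail early with a named error instead of
  returning empty summaries.

## Known limitations

* Oral route only; adults only; no age stratification, no dermal or
  inhalation exposure, no Cr speciation.
* The µg/g standard deviations of the reference report are not
  reproducible by linear scaling of the ppb SDs, and no alternative
  propagation reproduces them; the package pins replicate means and
  propagates SDs linearly, reporting means as the comparable quantity.
* Literature-informed concentration distributions (e.g., for a
  worst-case Hg scenario) are not shipped: only the qualitative behavior
  — widening the Hg concentration range pushes the HQ P95 above 1 — is
  demonstrated, with the range left to the user.

## A compact worked example

```{r example}
panel <- generate_panel(study_spike_plan(noise_rel_sd = 0), sample_prep())
conc <- ppb_to_ug_per_g(summarize_replicates(panel), sample_prep())
risk <- assess_risk(conc)
format_risk_table(risk[!risk$censored, ])

res <- run_simulation(simulation_config("Cr", metrics = c("HQ", "CR"),
                                        seed = 1))
res$summary[, c("metric", "P5", "P95", "decision")]
```
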