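---
title: "Indirect-Fick cardiac output and method comparison: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect-Fick cardiac output and method comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fickco)
```

## The model

The indirect Fick method (iFM) estimates cardiac output as

$$\mathrm{CO} = \frac{\dot V O_2}{10 \cdot \mathrm{avDO}_2}, \qquad
\mathrm{avDO}_2 = \mathrm{Hb}\,[\mathrm{g/dL}] \cdot 1.34\,[\mathrm{mL/g}]
\cdot (S_aO_2 - S_vO_2),$$

where $\dot V O_2$ (mL/min) is not measured but approximated from
demographics. The factor 10 converts the per-dL oxygen content to per-L so
that mL/min divided by mL/L yields L/min — the classic unit trap, made
explicit in `compute_fick_co()`'s contract. The Hüfner constant is fixed at
1.34 mL O₂ per g hemoglobin; the 1.36/1.39 variants found elsewhere are
deliberately not offered, because comparability across formulas requires a
single oxygen-capacity convention.

Four $\dot V O_2$ approximations are implemented (`estimate_vo2()`), each
iterated by every "all formulas" operation in the fixed order
`krakau, lafarge, dehmer, bergstra`. Two renderings deserve comment:

* **LaFarge** multiplies the whole bracket — including the heart-rate
  term — by BSA. Heart rate is required only here; a patient without a
  heart-rate measurement simply gets no LaFarge-derived values, while the
  other three formulas are still computed (nothing is imputed).
* **Bergstra** is evaluated with the `+10` as an *additive* male term
  (`BSA·157.3 + 10 − 10.5·ln age + 4.8` for men), not multiplied by BSA.
  Common citations of the original publication fold the male indicator into
  a single sex-pooled equation; we follow the two-row sex-specific
  rendering as our source of record and treat the discrepancy as a known
  ambiguity of the literature, not something to resolve numerically.

Body surface area uses the Dubois & Dubois power law
$0.007184\,H^{0.725}W^{0.425}$ (the canonical 1916 constants — the original
citation does not always print them, but any alternative would break
comparability with clinical calculators). Pulmonary vascular resistance is
the standard $80\,(\mathrm{mPAP}-\mathrm{mPAWP})/\mathrm{CO}$ in
dyn·s/cm⁵.

Saturations are stored internally as fractions. A `saturation_mode =
"percent"` flag divides 0–100 inputs by 100; in fraction mode, values above
1 are rejected rather than silently rescaled (values in $(1, 1.5]$ are
ambiguous between conventions, values above 1.5 are clearly on the percent
scale — the error message says which).

## Agreement statistics

Each comparison of a test series $a$ against a reference $b$ (thermodilution
by convention) uses its own pairwise-complete $n$ — mirroring clinical
tables whose $N$ varies per variable — and reports:

* **Bland–Altman**: mean difference $\bar d$ of $d = a - b$ and limits of
  agreement $\bar d \pm 1.96\,\mathrm{SD}(d)$, with the sample ($n-1$) SD
  throughout, per Bland–Altman convention.
* **Percentage error** (Critchley):
  $100 \cdot m \cdot \mathrm{SD}(d) / \tfrac12(\bar a + \bar b)$ with
  $m = 1.96$ by default and $m = 2.0$ available as a sensitivity switch —
  the two conventions coexist in the literature, and at the 30%
  acceptability boundary they can disagree (an SD-to-mean ratio of 0.153
  gives 29.99% vs 30.6%). The denominator "mean of the two method means"
  equals the mean of the per-pair averages, so the two readings of the
  definition coincide; this is documented, not configurable.
* **Ratio classification**: $a/b < 0.8$ (`under`), $[0.8, 1.2]$
  (`concordant`, boundaries inclusive — a "deviation > 20%" is a strict
  inequality), $> 1.2$ (`over`).
* **Pearson r** with a 95% CI via the Fisher z-transform,
  $\tanh(\mathrm{atanh}\,r \pm 1.96/\sqrt{n-3})$ — chosen because source
  tables report $r$ with a CI but no method, and Fisher z is the default of
  standard software.
* **Cohen's kappa** between two three-category classifications, unweighted,
  $(p_o - p_e)/(1 - p_e)$ with $p_e$ from marginal products. The 95% CI
  uses the asymptotic Fleiss–Cohen–Everitt standard error rather than a
  bootstrap: it matches the CI style of standard statistical packages, and
  the point estimate itself is verified in the test suite against an
  exhaustive definitional computation over *all* 3×3 tables with total
  count ≤ 12. When both raters are constant and identical ($p_e = 1$),
  kappa is undefined; the result carries an explicit `degenerate` flag
  instead of propagating `NaN`.

`compare_all()` produces the full study layout: four formula-vs-reference
reports, three formula-vs-Krakau reports, kappa between the
Krakau-vs-reference classification and each other formula's classification,
a deviation table, and median/quartile summaries of CO, CI and VO₂ per
method. A comparison with fewer than two complete pairs is marked
unavailable rather than failing the run.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` draws a cohort with the marginal structure of a
contemporary adult RHC population: age $N(63, 14.4^2)$ truncated to
$[18, 95]$ years, 30% women, hemoglobin $N(13.7, 1.8^2)$ g/dL, sex-specific
height ($N(176, 7^2)$ / $N(163, 6.5^2)$ cm) and weight ($N(84, 14^2)$ /
$N(72, 14^2)$ kg) chosen to reproduce cohort medians of height ≈ 173 cm,
BSA ≈ 1.9 m² and BMI ≈ 26, heart rate $N(75, 15^2)$, $S_aO_2$
$N(0.96, 0.02^2)$ on $[0.85, 1]$, $S_vO_2$ $N(0.65, 0.07^2)$ on
$[0.30, 0.85]$ and strictly below the patient's $S_aO_2$, and pressures
built as wedge ($N(14, 7^2)$ mm Hg) plus a positive transpulmonary gradient
($N(10, 6^2)$) so mPAP ≥ mPAWP holds by construction and the implied
medians sit near mPAP 22 / mPAWP 13 mm Hg. These values were fixed once,
before any acceptance outcome was observed, and are not tuning knobs.

Out-of-bound draws are redrawn (truncated sampling), never clipped, so no
probability mass piles up at the bounds. Every variable draws from its own
substream of the master seed: adding a variable to the generator never
perturbs previously generated columns, and regeneration with the same seed
is bitwise identical.

The disagreement model is deliberately simple: the latent true CO is the
indirect-Fick CO under a chosen truth formula (Krakau by default), and the
thermodilution reading is $\mathrm{TD} = \mathrm{CO}_{true}\cdot
e^{\beta + \varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$. Multiplicative
log-normal noise keeps CO positive and makes the *ratio* — the comparison
unit of the analysis — exactly $e^{-\beta-\varepsilon}$, so the discordance
probability has the closed form implemented in `expected_discordance()` and
the bias $e^\beta$ is recoverable as the cohort median of TD/Fick.

What the generator does **not** model: correlation among hemoglobin,
saturations and CO (variables are independent); within-patient
thermodilution replicate variability; any real measurement-device error
structure; disease subgroups. A green test against this generator
establishes that the *statistics are computed correctly against a known
construction* — it says nothing about how any formula performs on real
patients, where all four approximations are known to disagree with
thermodilution well beyond the 30% acceptability limit.

## Numerical and interface choices

* Zero-noise recovery is *exact* (percentage error identically 0), not
  approximate: the generator and `derive_all()` share the same arithmetic
  path, and the generator's cohort CSV is serialized with 17 significant
  digits so doubles round-trip bitwise through the file interface. Report
  CSVs round to 4 decimals at serialization; `summary.json` keeps full
  precision. This is the one place we deviate from a blanket
  "4 decimals in CSVs" rule — input data and reports have different
  precision needs.
* The synthetic config file is JSON (read and echoed back verbatim into the
  output directory); named sex-specific parameters serialize as JSON
  objects so the echoed config regenerates the identical cohort.
* Exclusions operate at the comparison level, not the cohort level: a
  patient lacking only a heart rate still contributes to the
  Krakau/Dehmer/Bergstra comparisons, and the run log records per-comparison
  n and exclusion counts with reasons.
* Errors carry condition classes (`fickco_data_error`,
  `fickco_config_error`) that the CLI maps to exit codes 1 and 2; row-level
  validation failures name up to the first five offending patient ids.

## Known limitations

* The asymptotic kappa CI is anti-conservative for very small n; only the
  point estimate is oracle-verified.
* `expected_discordance()` describes the truth formula's ratio only; other
  formulas' ratios against TD additionally carry inter-formula differences,
  which have no closed form here.
* Direct-Fick (measured VO₂), thermodilution curve processing and shunt
  physiology are out of scope by design.
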