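# fickco

Indirect-Fick cardiac output estimation and method-comparison statistics
for right heart catheterization (RHC) data.

## The problem

Cardiac output (CO) in the cath lab is measured either by thermodilution
(TD) or by the *indirect* Fick method (iFM), which replaces measured oxygen
consumption with an approximation formula:

```
CO = VO2 / (10 * avDO2)          [L/min]
avDO2 = Hb * 1.34 * (SaO2 - SvO2)  [mL O2 / dL]
```

with hemoglobin in g/dL, saturations as fractions, and the Hüfner constant
fixed at 1.34 mL/g. Four published VO₂ approximations are implemented
(mL/min; `ln` natural log of age in years, BSA by Dubois & Dubois):

| Formula  | Men | Women |
|----------|-----|-------|
| Krakau   | `BSA·(161 − 0.54·age)` | `BSA·(147.5 − 0.47·age)` |
| LaFarge  | `BSA·(138.1 − 11.49·ln age + 0.378·HR)` | `BSA·(138.1 − 17.04·ln age + 0.378·HR)` |
| Dehmer   | `BSA·125` | `BSA·125` |
| Bergstra | `BSA·157.3 + 10 − 10.5·ln age + 4.8` | `BSA·157.3 − 10.5·ln age + 4.8` |

The agreement module quantifies how well each iFM variant tracks a TD
reference: Bland–Altman mean difference and 95% limits of agreement,
Critchley percentage error `100·1.96·SD(a−b)/mean(a,b)` with the < 30%
acceptability rule, ratio classification (`< 0.8` / `0.8–1.2` / `> 1.2`),
Pearson *r* with a Fisher-z 95% CI, and Cohen's kappa between ratio
classifications. A synthetic-cohort generator with a known-truth
multiplicative disagreement model (`TD-CO = trueCO · e^{β+ε}`,
`ε ~ N(0, σ²)`) makes every statistic testable against construction.

Intended users: cardiology / hemodynamics researchers comparing CO methods,
and anyone needing a tested reference implementation of these formulas.

## Worked example

```r
library(fickco)

syn <- generate_cohort(synth_config(n = 200, seed = 7, noise_sd = 0.15))
derived <- derive_all(syn$records)
cmp <- compare_all(derived)
print(cmp$vs_reference$krakau)
```

```
Agreement: krakau vs td (n = 200)
  mean difference -0.107 L/min, LoA -1.633 to 1.419
  percentage error 32.2% (not acceptable; multiplier 1.96)
  Pearson r 0.924 (95% CI 0.901 to 0.942)
  ratio classes: under 14 (7.0%), concordant 166 (83.0%), over 20 (10.0%)
```

With σ = 0.15 and no bias, the Krakau-derived CO (the generator's truth
formula) disagrees with the simulated TD readings purely through the
log-normal noise: the mean difference is near zero, the percentage error
(32%) sits just above the 30% acceptability cut-off, and 17% of patients
deviate by more than 20% — close to the analytic value
`expected_discordance(0.15) = 0.18`.

Command line:

```sh
Rscript inst/cli/fickco generate --config synth.json --out gen/
Rscript inst/cli/fickco analyze --input gen/cohort.csv --out results/ \
    [--saturation-mode percent] [--pe-multiplier 1.96] [--formulas krakau,dehmer]
```

`analyze` writes `derived.csv`, `method_summary.csv` (median/quartiles of
CO, CI and VO₂ per method), `deviation_table.csv`, one
`bland_altman_<a>_vs_<b>.csv` of plot coordinates per comparison,
`summary.json` (every statistic at full precision) and `run_log.txt`.
Exit codes: 0 success, 1 data error, 2 config error.

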