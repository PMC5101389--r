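# chromdoe

Chemometric development and ICH validation of a HILIC impurity method, as a
reproducible in-silico pipeline.

## The problem

Moxonidine and its four pharmacopoeial impurities (A–D) are weak bases of
near-identical polarity; at acidic pH all five carry a +1 charge, which
defeats conventional reversed-phase separation without ion-pair reagents.
On a bare-silica HILIC column they separate well at high acetonitrile
content, where retention *increases* with the organic fraction. Developing
such a method chemometrically means: screen the mobile-phase factors with a
central composite design (CCD), model the responses with PLS, pick
conditions that satisfy resolution and run-time constraints, and validate
the result against ICH Q2(R1).

chromdoe implements that whole workflow for R users:

- **`ccd_design()`** — rotatable CCDs (`alpha = (2^K)^(1/4)`) with
  coded/actual conversion; the default three-factor design reproduces the
  20-run screening plan (%ACN 70–80, pH 2.8–4.2, ammonium formate
  20–60 mM) exactly.
- **`fit_pls()`** — PLS1 (NIPALS, autoscaled) response-surface models on
  the 9-term quadratic block, with R², leave-one-out Q²
  (`Q2 = 1 − PRESS/TSS`), jackknife 95% coefficient intervals and the
  "error line crosses the axis" significance rule; `print`, `summary`,
  `coef`, `predict`, `residuals` and a coefficient-`plot` method.
- **`optimize_conditions()`** — grid search of the fitted surfaces for
  conditions with both critical resolutions `Rs = 2|ΔtR|/(w1+w2) >= 2`
  inside a 12-minute run.
- **`fit_linearity()`, `lod_loq_from_trace()`, `assess_accuracy()`,
  `assess_precision()`, `robustness_ofat()`, `assess_selectivity()`,
  `assay_tablet()`** — the ICH validation battery with the published
  acceptance windows.
- **`retention_truth()` / `simulate_retention()` / `generate_study()`** — a
  calibrated synthetic retention simulator (quadratic log10 k surfaces,
  Gaussian peaks, seeded noise) that reproduces the critical published
  behaviour: A/B coelution at 70% ACN/pH 2.8 at any buffer level, C/D
  coelution with Rs(A,B) = 10.91 at 75%/pH 4.68/40 mM, and full separation
  within 12 min at 80%/pH 2.8/40 mM.
- **`run_study()`** — the end-to-end seeded study, writing a plain-text
  artifact bundle (CSVs, JSON, md5 manifest) when given an output
  directory.

## Worked example

```r
library(chromdoe)

# one chromatographic run at the optimized conditions
simulate_retention(retention_truth(), method_conditions())
#> ACN 80% / pH 2.8 / 40 mM, 25 C, 1 mL/min, 255 nm
#>    compound      k      tr   width       area     height
#>  moxonidine 2.6002  7.3803 0.29521 2.9142e+06 1.5753e+07
#>        impA 1.0000  4.1000 0.16400 1.2228e+01 1.1899e+02
#>        impB 1.7588  5.6556 0.22622 1.3830e+01 9.7553e+01
#>        impC 3.5003  9.2255 0.36902 1.8181e+01 7.8622e+01
#>        impD 4.6200 11.5210 0.46084 1.1821e+01 4.0934e+01
#> Rs(A,B) = 7.973  Rs(C,D) = 5.532  last peak 11.52 min

# the full study: design -> simulate -> fit -> optimize -> validate
s <- run_study(seed = 1)
s
#> In-silico HILIC method-development study (seed 1 )
#>   20-run design; model Q2: k_M 0.93, k_A 0.99, k_B 0.89, k_C 0.96,
#>                            k_D 0.99, Rs_AB 0.96, Rs_CD 0.92
#>   selected conditions: 80.9% ACN, pH 2.68, 43 mM (min Rs 5.53, 11.8 min)
#>   validation: PASS

summary(s$models$k_A)   # pH dominates impurity A, negatively
#> PLS1 response-surface model: 3 components, 20 runs, 9 terms
#>   R2 = 0.9987   Q2(LOO) = 0.9919   PRESS = 0.01059
#>   ...
#>   acn  +0.078 [ 0.058,  0.098]  significant
#>   ph   -0.288 [-0.300, -0.276]  significant
```

Reading the output: `k` is the retention factor `(tR − t0)/t0`; the two
`Rs` values are the critical-pair resolutions (baseline separation needs
Rs ≥ 2); the last peak at 11.5 min confirms the 12-minute run. The fitted
study recovers the known structure of the simulator: retention of
moxonidine and impurities B–D rises with acetonitrile, impurity A is
governed by pH with a negative coefficient, and the optimizer lands next to
80% ACN / pH 2.8 / 40 mM. The validation report aggregates linearity
(r ≥ 0.997, intercept t-test), S/N-based LOD/LOQ (3:1 and 10:1), recovery
windows, RSD thresholds, OFAT robustness (<5% area, <3% tR and Rs),
selectivity and the tablet assay into one pass/fail table.

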