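# apneascreen

Central sleep apnea (CSA) is common and underdiagnosed in stable heart
failure, and the reference tests — polysomnography or respiratory
polygraphy — are burdensome enough that routine screening rarely happens.
One candidate screen is overnight pulse oximetry from a smartphone-tethered
fingertip oximeter: count oxygen desaturation dips, compute the oxygen
desaturation index (ODI), and call the screen positive when ODI ≥ 15/h.

`apneascreen` implements that screening analysis end to end, for
biostatisticians and sleep researchers evaluating desaturation-based
screens against a polygraph reference:

* **Dip detection and ODI.** A dip is a maximal run of valid samples at or
  below `baseline − 3` percentage points lasting ≥ 10 s (both thresholds
  inclusive); ODI = dips / recording hours. Two baseline conventions are
  supported: a fixed hookup value (polygraph convention) and the mean
  saturation of the 11th minute of recording (app convention).
* **Reference classification.** From a scored respiratory-event list:
  AHI = (apneas + hypopneas) / sleep hours; sleep apnea iff AHI ≥ 15/h;
  CSA iff additionally ≥ 50 % of events are central, otherwise OSA.
* **Paired diagnostic agreement.** 2×2 screen-vs-reference tables
  (a, b, c, d), exact McNemar test
  `p = min(1, 2·P(X ≤ min(b,c)))`, `X ~ Bin(b+c, ½)` (continuity-corrected
  χ² available), sensitivity `a/(a+c)`, specificity `d/(b+d)`, PPV, NPV,
  Bland–Altman limits of agreement `bias ± 1.96·SD`, and the
  paired-proportions sample-size formula
  `n = ⌈(z₁₋α/₂√(p₀₁+p₁₀) + z₁₋β√(p₀₁+p₁₀−(p₀₁−p₁₀)²))² / (p₀₁−p₁₀)²⌉`.
* **Synthetic cohorts with ground truth.** An overnight SpO2 generator
  (Cheyne-Stokes-like periodic desaturation trains for the central
  phenotype, exponentially spaced clusters for the obstructive one, integer
  quantization, sensor noise, dropout artifacts) renders paired 8 Hz
  polygraph and 1 Hz app traces from one shared event plan per patient, so
  the whole pipeline is testable without patient data.

The package also ships a small synthetic per-patient reconstruction of a
22-patient heart-failure screening cohort (plus its 24-patient polygraph
superset), consistent with the four published marginal agreement tables,
so the endpoint statistics can be recomputed exactly.

## Worked example

```r
library(apneascreen)
rep <- replicate_study()
rep
#> Sleep-apnea screening study report (packaged fixture)
#>   cohort prevalence: any SA 58%, CSA 33%, OSA 25%
#>   mobile_csa (a,b,c,d)=(3,7,4,8)  sens 43% spec 53% ppv 30% npv 67%  McNemar p=0.55
#>   mobile_any (a,b,c,d)=(6,4,7,5)  sens 46% spec 56% ppv 60% npv 42%  McNemar p=0.55
#>   poly_csa   (a,b,c,d)=(6,6,1,9)  sens 86% spec 60% ppv 50% npv 90%  McNemar p=0.13
#>   poly_any   (a,b,c,d)=(12,0,1,9)  sens 92% spec 100% ppv 100% npv 90%  McNemar p=1.00
#>   design sample size (paired McNemar): 26 pairs
```

Reading the first line of tables: of 7 reference-CSA patients only 3 screen
positive on the mobile oximeter (sensitivity 43 %), and the exact McNemar
p of 0.55 says the screen's positives and the reference's positives are
statistically interchangeable errors — the mobile ODI is a weak CSA screen.
The polygraph's own ODI, by contrast, is a near-perfect screen for sleep
apnea of *any* etiology (0 false positives, 1 false negative): oximetry
sees desaturations but cannot tell central from obstructive mechanism.

The same analysis on a fully synthetic cohort:

```r
syn <- run_synthetic_study(n_patients = 22, prevalence_csa = 7/22,
                           prevalence_osa = 6/22, seed = 42)
syn$tables$mobile_any
#> <contingency_2x2> n = 22
#>           reference
#> screen     positive negative
#>   positive       13        0
#>   negative        0        9
```

And a single synthetic night through the dip detector:

```r
x <- generate_trace(patient_profile("central", noise_sd = 0), fs = 1, seed = 7)
x$ground_truth
#> <ground_truth> central phenotype: 280 events, AHI 40.0 /h, clean ODI 40.0 /h, diagnosis CSA
nrow(detect_dips(x$trace, baseline = 96))
#> [1] 280
```

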