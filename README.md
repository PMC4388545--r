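# rpewave

Sine-wave quantification of optic disc tilt from circumpapillary OCT
circle scans.

## The problem and who this is for

Optic disc tilt accompanies myopia and distorts both visual-field indices
and peripapillary retinal nerve fiber layer (RNFL) measurements, so
clinicians and reading centres need a tilt metric that is quantitative,
repeatable, and independent of the tilt direction. Classical surrogates —
the ovality ratio of the disc outline, or tilt angles from single
horizontal/vertical OCT sections — miss obliquely tilted discs or
confound disc shape with tilt.

`rpewave` implements a metric that needs nothing beyond the standard
3.4 mm RNFL circle scan. In the unrolled B-image the traced course of the
retinal pigment epithelium (RPE) of a tilted disc rises and falls once
per revolution, so the centred trace $(u_i, v_i)$ is fit by least squares
to

$$v = a \sin(b\,u - c),$$

and the amplitude **a** (pixels) is the tilt metric: flat RPE, untilted
disc, `a ≈ 0`; strongly tilted disc, large `a`, whatever the tilt
meridian. Fit quality is gated at R² > 0.90. The package also provides
the modified ovality ratio (with the 45° vertical/horizontal axis rule),
two-way absolute-agreement intraclass correlation ICC(A,1) with F-based
confidence intervals, Spearman rank correlations, synthetic generators
for traces / B-scan-like band images / cohorts with target rank
correlations, a batch pipeline, and a small CLI (`exec/rpewave`).

## Worked example

Fit one simulated trace (true amplitude 42 px, plotting noise 3 px):

```r
library(rpewave)
tr  <- simulateTrace(aTrue = 42, cTrue = 1.2, noiseSd = 3, nPoints = 64L, seed = 7L)
fit <- fitSine(centerCoordinates(tr))
fit
#> SineFit 'sim': y = 41.968 * sin(0.00611544 * x - 4.3710)
#>   R^2 = 0.9913 (quality pass), RSS = 492.1, n = 64, converged = TRUE
```

The fitted amplitude (41.97 px) recovers the generating value; R² = 0.99
passes the quality gate. Then a full cohort analysis at the study
conditions (126 eyes, amplitude 37.0 ± 17.5 px, exact latent
calibration):

```r
rep <- runCohortAnalysis(simulateCohort(empirical = TRUE, seed = 1L))
rep
#> Cohort analysis report (n = 126 eyes)
#> Summary (mean +/- SD, range):
#>   amplitude               36.91 +/- 17.50  (-15.04 ~ 77.20)  n=126
#>   ovality_ratio            0.89 +/-  0.11  (0.54 ~ 1.17)  n=126
#>   spherical_equivalent    -4.71 +/-  3.41  (-13.18 ~ 4.29)  n=126
#>   axial_length            25.40 +/-  1.50  (21.77 ~ 29.83)  n=126
#>   body_height            167.60 +/-  8.40  (150.87 ~ 187.71)  n=126
#>   ICC Intra (A,1)        0.995 (95% CI 0.993-0.996), p = 5.01e-127
#>   ICC Inter (A,1)        0.954 (95% CI 0.936-0.968), p = 1.2e-67
#> Spearman correlations with amplitude:
#>   ovality_ratio          R = -0.60, p = 1.53e-13, n = 126
#>   spherical_equivalent   R = -0.29, p = 0.000803, n = 126
#>   axial_length           R = +0.14, p = 0.109, n = 126
#>   body_height            R = -0.38, p = 1.51e-05, n = 126
#> Amplitude-ovality correlation by disc axis:
#>   vertical               R = -0.57, p = 1.56e-10, n = 108
#>   horizontal             R = -0.38, p = 0.117, n = 18
```

Amplitude is strongly inversely correlated with the ovality ratio (more
tilt, more elongated disc outline), moderately with refractive error and
body height, and weakly with axial length; rater agreement is excellent.
The analysed amplitude is the mean of the two rater columns. See the
methods vignette (`vignettes/optic-disc-tilt.Rmd`) for the model,
parameter choices, and what the generators do and do not emulate.

The same pipeline runs from the shell:

```sh
rpewave simulate fixtures/ --n-eyes 10 --seed 1
rpewave fit fixtures/traces --out fits.csv
rpewave cohort fixtures/cohort.csv --format json --out report.json
```

Real per-eye tables (CSV or XLSX) are ingested through a user-editable
column-mapping YAML (`readCohort(path, columnMap = "map.yaml")`).

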