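# spectrc

Does it matter where the spheres sit in the NEMA body phantom when you
calibrate quantitative Lu-177 SPECT? This package answers that question in
simulation: it builds voxelized phantoms for arbitrary assignments of the
six sphere diameters to the six ring positions (720 permutations), runs an
analytic SPECT acquisition model (auto-contoured non-circular orbit,
distance-dependent collimator blur, attenuation, an effective scatter
component with triple-energy-window estimation, Poisson noise), reconstructs
with OSEM with and without resolution modeling, and quantifies per-sphere
recovery coefficients, their permutation statistics, recovery-curve fits and
the partial-volume-correction (PVC) factors clinical sites derive from them.

It is aimed at physicists working on SPECT harmonization and dosimetry who
want to understand — and bound — the arrangement-induced variability of
recovery before trusting a single phantom measurement.

## The quantities at the core

* **Recovery coefficient**: `RC = A_image / A_nominal`, the image-based
  activity in a sphere over the activity filled into it; `< 1` under
  partial-volume losses.
* **Spread over permutations**: `theta_RC = (RC_max - RC_min) / mean(RC)`
  per sphere diameter and reconstruction arm.
* **Recovery curve**: `f_RC(d) = 1 / (1 + (beta/d)^gamma)`, fitted per
  permutation with `d` in cm; `beta` is the half-recovery diameter.
* **PVC factor**: `1 / f_RC(d)` at the lesion diameter.
* **Agreement metrics** between two curve sets indexed by the same J
  configurations: `delta(d)`, the mean absolute paired deviation, and
  `Delta(d)`, the mean absolute spread of the reference set about its own
  mean curve.

## Worked example

```r
library(spectrc)

## two sites calibrate PVC from recovery curves measured with different
## sphere arrangements, then correct the same 10 mL (2.67 cm) lesion
ex <- pvc_worked_example(site_a = list(beta = 1.37, gamma = 2.44),
                         site_b = list(beta = 1.27, gamma = 3.21),
                         diameter_cm = 2.67)
str(ex[c("rc_a", "rc_b", "factor_a", "factor_b", "percent_difference")])
#> $ rc_a              : num 0.84
#> $ rc_b              : num 0.92
#> $ factor_a          : num 1.19
#> $ factor_b          : num 1.09
#> $ percent_difference: num 9.2
```

The two sites would report activities differing by 9.2% for the identical
lesion, purely because their calibration phantoms had different sphere
arrangements.

A permutation sweep at the working ("desk") scale:

```r
sw <- run_sweep("NEMA_SPECT", master_seed = 42L)       # ~10 min
an <- subset(sw$rc_table, (arm == "noRR" & updates == 50) |
                          (arm == "RR" & updates == 200))
permutation_stats(an)[, c("arm", "diameter", "mean_rc", "theta_rc")]
#>     arm diameter mean_rc theta_rc
#>    noRR       13   0.206    0.428
#>    noRR       17   0.378    0.231
#>    noRR       22   0.462    0.155
#>    noRR       28   0.558    0.124
#>    noRR       37   0.654    0.064
#>    noRR       60   0.789    0.031
#>      RR       13   0.321    0.253
#>      RR       17   0.568    0.094
#>      RR       22   0.628    0.073
#>      RR       28   0.692    0.071
#>      RR       37   0.765    0.026
#>      RR       60   0.863    0.011
```

The structure mirrors the full-scale study: the spread shrinks with sphere
size, resolution modeling raises recovery and narrows the spread, the
best-recovered position without resolution modeling is the one the detector
approaches closest (the top of the phantom), and with resolution modeling
the extremes are driven by the size of the neighbouring spheres instead.
Absolute RC levels at this coarse desk resolution sit below full-scale
values by construction; conclusions are read structurally. See the numbered
scripts under `analysis/` for the full workflow and
`vignettes/sphere-permutations.Rmd` for the modeling choices.

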