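# divekin

Dive segmentation and kinematic analysis of whale-borne motion-sensor tags.

`divekin` is for movement ecologists working with high-resolution
multi-sensor biologgers on large whales — in particular ram-filtering
balaenids (bowhead and right whales), where the analytical goal is to tell
confirmed feeding dives from travel using kinematics rather than dive shape
alone. The package takes a tag "diary" (tri-axial accelerometer, gyroscope,
magnetometer and depth) from delimited text to:

* zero-phase Butterworth filtering, body orientation (pitch $\varphi$,
  roll, heading), jerk
  $\sqrt{\Delta a_x^2+\Delta a_y^2+\Delta a_z^2}\cdot 9.81 f_s$ (m/s³),
  VeDBA $\|\mathbf{a}_{dyn}\|\cdot 9.81$ (m/s²), and a tag-jiggle swim-speed
  proxy calibrated against orientation-corrected depth rate
  $|\dot d|/|\sin\varphi|$;
* rule-based dive detection (> 5 m, ≥ 10 s, > 10 s surface interval),
  descent/bottom/ascent segmentation and V/U/Square shape classes
  (bottom-time fraction ≤ 20% / 20–50% / ≥ 50%);
* fluke-stroke detection from upward zero-crossings of the 0.08–0.2 Hz
  band-passed pitch-axis gyroscope, stroke frequency and rolling 30-s rate,
  and a linear mixed model testing the shallow/deep gait switch at 23 m;
* hierarchical matching of video-audit behaviour events onto dives
  (Feeding priority, longest-duration fallback, NoVideo at zero coverage);
* a binomial-logit GLMM classifying feeding dives
  ($\mathrm{logit}\,P(\text{feeding}) = X\beta + u_{deployment}$) with
  AIC-based candidate-set comparison;
* a synthetic deployment simulator producing diary + truth table + event
  log with the programmed kinematic signatures of each behaviour, so every
  stage is testable without field data.

## Worked example

Simulate a deployment-like feature table and run the candidate-set
comparison for the feeding classifier:

```r
library(divekin)

feats <- simulate_dive_features(n_dives = 200, p_feeding = 0.5, seed = 42)
cmp <- compare_models(feats, candidate_model_specs())
as.data.frame(cmp)[, c("model", "AIC", "logLik", "dAIC")]
#>             model      AIC     logLik      dAIC
#> 1            null 263.5351 -129.76754   0.00000
#> 2        m1_speed 205.2670  -99.63349  58.26810
#> 3   m2_fluke_rate 250.8933 -122.44663  12.64181
#> 4   m3_linear_tod 143.1831  -64.59155 120.35199
#> 5 m4_circular_tod 114.3650  -49.18251 149.17006
attr(cmp, "winner")
#> [1] "m4_circular_tod"
```

The full model wins by a wide AIC margin (`dAIC` is the AIC drop relative
to the intercept-plus-random-intercept null; larger is better). Its
coefficients carry the expected signs — feeding dives have *slower* bottom
speed and a *positive* speed change after the jerk peak:

```r
attr(cmp, "fits")$m4_circular_tod
#> Feeding GLMM 'm4_circular_tod': n = 200 dives, 10 deployments
#>   logLik -49.2, AIC 114.4, random-intercept SD 0.56
#>                     Estimate Std. Error z value Pr(>|z|)
#> (Intercept)          2.66985    1.23578   2.160 0.030737 *
#> bottom_mean_speed   -2.86865    0.83635  -3.430 0.000604 ***
#> bottom_peak_jerk     3.72129    2.90450   1.281 0.200118
#> bottom_speed_change  9.41202    2.16942   4.338 1.43e-05 ***
#> bottom_mean_roll    -0.19801    0.05239  -3.779 0.000157 ***
#> bottom_mean_pitch   -0.17066    0.04142  -4.120 3.79e-05 ***
#> tod                  0.19198    0.28887   0.665 0.506305
```

The sensor-level pipeline runs the same way from a simulated (or real)
diary:

```r
cfg <- read_sim_config("mixed", seed = 42)   # shipped scenario preset
sim <- simulate_deployment(cfg)
pd  <- process_deployment(sim$diary)          # filter, orient, jerk, speed
dives   <- segment_phases(detect_dives(pd$kin$depth, pd$fs, pd$kin$t),
                          pd$kin$depth, pd$fs, pd$kin$t)
strokes <- detect_fluke_strokes(pd$kin$gyro_y_band, pd$fs, pd$kin$t,
                                pd$kin$depth)
depth_strata_model(pool_strokes(list(sim0042 = strokes)))
#> Depth-strata fluke-frequency model (split 23 m)
#>   deep vs shallow: -1.362 (SE 0.014, p = 0)
#>   medians: shallow 0.192 Hz (n=977), deep 0.151 Hz (n=380)
```

The recovered per-stratum medians match the frequencies the simulator
programmed (0.192 Hz at ≤ 23 m, 0.151 Hz below), and the negative stratum
effect says deep fluking is slower on the standardized scale.

A thin CLI (`exec/divekin`) wraps the main verbs
(`simulate`, `ingest`, `dives`, `flukes`, `strata`, `label`, `compare`)
for shell pipelines.

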