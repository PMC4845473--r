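# mitodiv

Counting, tracking and division-angle measurement for overlapping cell
nuclei in fluorescence time-lapse videos of micropatterned cell clusters.

## The problem

Cells confined on adhesive micropatterns divide under geometric
constraints, and the *orientation* of a division — the angle between the
new daughter–daughter axis and the axis of the two cells that existed
before — is a standard readout for spindle-orientation phenotypes in
RNAi screens. Measuring it at scale requires finding, in each of
thousands of single-cluster videos of H2B-labelled nuclei, the exact
frame where two cells become three, even though the nuclei overlap,
defocus and rotate enough to defeat conventional segmentation-and-track
pipelines.

## The method

Every frame is fitted with two competing penalized Gaussian-mixture
image models. A cluster of K nuclei is modelled as

```
M_K(x) = Σ_k  w_k · exp( −½ (x − μ_k)' S_k⁻¹ (x − μ_k) ),   K ∈ {2, 3}
```

and each fit minimizes, by Powell's derivative-free method,

```
f_global = f_err · (1 + f_loc + f_vol + f_int)
```

where `f_err` is the least-squares residual and the penalties anchor
component centers to the Otsu foreground (`f_loc`, via a distance
transform), component areas to the nucleus area prior `Ā = π d̄²/4`
(`f_vol`, on the covariance determinant) and peak intensities to the
intensity prior `w̄` (`f_int`). Only two parameters — the average nucleus
diameter `d̄` (FWHM, px) and peak intensity `w̄` — need to be set.

Three per-frame features derived from the paired fits — the residual
ratio `F1 = f3/f2`, the minimum 3-component center distance `F2`, and
the intensity variance `F3` sampled between the two closest centers —
jump simultaneously at the two-to-three-cell transition. The product of
their robust-normalized one-frame derivatives peaks at that frame; the
earliest significant peak is the called division frame. There, the two
smallest Gaussian objects are the daughters, and the division angle is
the angle (folded into [0°, 90°]) between the daughter axis and the
2-component axis one frame earlier.

## Worked example

Simulate a ground-truthed cluster video (division at frame 30 at 50°),
fit the paired models, detect the transition and measure the angle:

```r
library(mitodiv)

sc  <- cluster_scenario(n_frames = 60, division_frame = 30,
                        division_angle = 50, overlap_fraction = 0.3,
                        seed = 7)
sim <- simulate_cluster_video(sc)

fit <- fit_nuclei(sim$stack, d_nuc = 10, w_nuc = 0.5, seed = 99)
fit
#> Paired 2-/3-component nucleus mixture fits: 60 frames of 60 x 60 px
#>   priors: d_nuc = 10 px, w_nuc = 0.5
#>   median f_err: 8.67 (K=2), 5.102 (K=3); f3 <= f2 on 32/60 frames

detect_division(fit)
#> Division event at frame 31 (peak 1.07e+03, threshold 283)

measure_division(fit)
#> Division angle: 51.80 deg (daughters 2 & 3, event frame 31)
```

After the division the 3-component model wins on every frame, while on
the two-cell frames before it the two model orders tie to within the
noise floor (hence the roughly even `f3 <= f2` split — the *change* in
their ratio, not its sign, carries the signal). The event is called
within one frame of the programmed division, with the derivative-product
peak nearly four times its significance threshold, and the measured
angle is within 2° of the programmed truth.

For real data: `read_stack()` loads a multi-page TIFF,
`locate_patterns()` / `crop_sequences()` cut a full-field acquisition
into per-pattern videos, and `run_pipeline()` processes a whole batch
into a results table with one row per sequence (event + angle, or an
exclusion reason). `compare_angle_distributions()` runs the two-sample
Kolmogorov–Smirnov comparison between conditions. A thin command-line
front end with `simulate` / `extract` / `fit` / `detect` / `angle` /
`run` / `compare` subcommands lives in `inst/cli/mitodiv.R`.

See the vignette (`vignettes/division-angle-tracking.Rmd`) for the full
model description, the design decisions and the generator's scope.

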