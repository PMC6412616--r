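# qube

Quantitative myocardial blush evaluation for coronary angiograms.

After primary PCI for myocardial infarction, restored flow in the
epicardial artery does not guarantee restored perfusion of the heart
muscle. On an angiogram, tissue perfusion appears as *myocardial
blush* — a faint, diffuse opacification of the myocardium during
contrast passage — and is graded visually on the 0–3 MBG scale. This
package implements QuBE-style quantitative blush scoring, for
researchers studying angiographic perfusion measures and their failure
modes.

## The method

For a grayscale angiographic run at frame rate *f* (default 12.5 Hz),
with a region of interest (ROI) on the distal perfusion territory:

1. invert contrast once per run (`global_max − I`), so contrast
   density is positive;
2. estimate the large-structure background of each frame with a square
   median filter (kernel *k* × *k* px, native *k* = 35; 20 and 50 are
   the standard comparison sizes) and subtract it, clipping negatives;
3. optionally shift the ROI by a per-frame integer panning offset
   (normalized cross-correlation against the first frame, ±20 px
   search box), or use a per-frame ROI track that encodes the motion;
4. the blush value *v<sub>t</sub>* of frame *t* is the mean of the
   *k* brightest 5 × 5-smoothed residual pixels in the ROI, with
   *k* = max(10, ⌈2% · ROI area⌉);
5. the **QuBE score** of the blush curve *v* is

   *score = a + b*, with
   *a* = max<sub>i&lt;j</sub> (v<sub>j</sub> − v<sub>i</sub>) and
   *b* = max<sub>i&lt;j</sub> (v<sub>i</sub> − v<sub>j</sub>)
   (both floored at 0) —

   the maximum rise plus the maximum fall of ROI contrast intensity
   over the run.

Because no labelled angiogram datasets accompany the method, the
package ships a synthetic angiogram simulator
(`simulate_sequence()`, `make_cohort()`) producing runs with a dark
vessel tree under bolus transit, diaphragm, catheter, a blush region
with known gamma-variate kinetics, cardiac motion, panning drift and
noise — plus exact ground truth (true kinetics, per-frame motion, the
perfectly tracked ROI). The statistics used around the score
(Spearman, Kruskal–Wallis, Lin's concordance, Wilcoxon signed-rank,
median/IQR tables) are included with exact small-sample conventions.
See the methods vignette (`vignettes/qube-methods.Rmd`) for the model,
parameter meanings, and design rationale.

## Worked example

```r
library(qube)

params <- simulation_params(blush_amplitude = 40, seed = 1)
sim    <- simulate_sequence(params)

res <- qube_analyze(sim$sequence, params$roi, blush_options())
res
#> <qube_result: score 1.996 = max increase 1.13 + max decrease 0.866 (60 frames)>
glance(res)
#> # A tibble: 1 × 5
#>   score max_increase_a max_decrease_b n_frames frame_rate_hz
#>   <dbl>          <dbl>          <dbl>    <int>         <dbl>
#> 1  2.00           1.13          0.866       60          12.5

# the computed curve tracks the true gamma-variate kinetics
pearson_r(res$curve$value, true_blush_curve(sim$ground_truth)$value)
#> [1] 0.99

# a 20 px kernel swallows most of the 45 px blush: the score drops
qube_analyze(sim$sequence, params$roi, blush_options(kernel = 20))$score
#> [1] 0.739
```

The score decomposes into the rise (*a* = 1.13) and fall (*b* = 0.866)
of ROI contrast around the bolus peak; its absolute scale depends on
blush amplitude, ROI placement and kernel size — the kernel-20 drop
illustrates the filter-scale mechanism that makes the score sensitive
to an essentially arbitrary parameter. `tidy(res)` returns the
per-frame curve with the applied panning offsets; `autoplot(res)`
draws the curve with the scored rise and fall. Cohort-level
experiments follow the same grammar:

```r
cohort <- make_cohort(n_per_grade = 10, mode = "associated", seed = 1)
ke <- kernel_comparison_experiment(cohort, kernels = c(20, 35, 50))
ke$grade_table      # median (IQR) score per MBG grade and kernel
glance(ke)          # Spearman and Kruskal-Wallis per kernel
```

A command-line interface wrapping these functions is installed at
`exec/qube` (`Rscript $(Rscript -e 'cat(system.file("exec","qube",package="qube"))') score --input run/ --roi roi.json --out result.json`),
with `simulate`, `cohort`, `motion` and `experiment kernels`
subcommands.

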