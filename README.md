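# tectodist

Visual detection distance from optic-tectum calcium imaging.

`tectodist` is an analysis pipeline for experiments in which a zebrafish
larva, expressing a genetically encoded calcium indicator (GCaMP) in the
optic tectum, watches an artificial prey-like glyph move back and forth on a
miniature OLED screen while the tectal fluorescence is recorded by
light-sheet microscopy. The package converts the recorded fluorescence into:

* the **visual detection distance (DD)** — the eye-to-stimulus distance at
  the moment each stimulus-locked fluorescence transient begins;
* three **peak-shape response metrics** — transient duration, full width at
  half maximum (FWHM), and the inter-peak interval;
* the **group-comparison statistics** across temperature treatments
  (18, 23, 28 °C): skewness screen, Levene's test, one-way ANOVA with a
  Brown–Forsythe extension, Scheffé / Tamhane T2 post-hocs, and
  Kruskal–Wallis with Dunn's post-hoc.

It is written for experimenters doing stimulus-locked functional imaging who
want the onset-to-distance reconstruction, and for anyone who needs a
self-contained, ground-truthed testbed for transient-detection code: a
synthetic generator reproduces the whole data-generating process (stimulus
kinematics, double-exponential indicator kernel, Gaussian noise, image
stacks with a ring-shaped region of interest), so every estimator in the
package is validated end to end without any recordings.

## The method

The glyph moves along the screen as a triangular wave at constant speed
*v* = 2.1 mm/s (one 0.21 mm pixel pitch per 0.1 s) over a 6.3 mm one-way
track (30 pitches), for ten approach–recede cycles. With the eye a distance
|bc| from the screen, opposite lateral coordinate *b*, the eye-to-stimulus
distance at lateral position *x* is the hypotenuse of a right triangle:

    d(x) = sqrt( (x − b)² + |bc|² )        (|ab|² + |bc|² = |ac|²)

A transient's onset time t₀ is found on the fluorescence trace as the last
upward crossing, before the peak maximum, of the threshold

    F_base + max( k · σ_noise , f · amplitude ),    k = 2, f = 0.005

where F_base is the median inter-peak fluorescence (two-pass estimate) and
σ_noise = 1.4826 · MAD of the inter-peak samples. The detection distance of
the peak is then DD = d(x(t₀)), computed only when t₀ falls on an approach
leg. Duration is t_offset − t_onset, FWHM is the width at half the amplitude
above baseline (linearly interpolated), and the inter-peak interval is the
time from one peak's offset to the next peak's onset. Double-topped peaks
are merged, artifact peaks (single-frame spikes, amplitude outliers,
pre-stimulus onsets) are excluded, and only the first five peaks per trial
enter the statistics.

## Worked example

Simulate one trial with a known detection distance of 5 mm under the study
conditions (motion from t = 10 s, ten 12-s cycles, 2 % noise), then analyse
it:

```r
library(tectodist)
kin   <- stimulus_kinematics(t_move_start = 10)
geo   <- eye_geometry()                       # eye 1 mm from the screen
truth <- synthetic_truth(5, kernel_params(0.05, 0.7, 0.2), noise_sd = 0.02)
sim   <- simulate_trial(truth, kin, geo, seed = 42)
s     <- summarize_trial(sim$trace, kin, geo)
s
#> Trial result: 5 retained peaks ( 10 detected ), status ok
#>   detection distance: 4.996 mm
round(s$detection_distances, 3)
#> 5.004 4.998 4.983 4.997 4.999
```

The five retained peaks each recover the 5 mm ground truth to within one
frame of stimulus travel (2.1 mm/s × 0.05 s ≈ 0.1 mm). The remaining
metrics come from the same object: `s$durations`, `s$fwhms`, `s$intervals`
(≈ 10.6–11 s here: the 12-s cycle minus the ~1.2 s transient),
`s$fmax_fbase` (≈ 1.18–1.24).

A full experiment across the three temperatures, with the generator's
default effect model (DD and decay time falling with temperature):

```r
expm <- simulate_experiment(n_trials_per_temp = 5, kin = kin, geo = geo,
                            seed = 42)
res  <- run_experiment(expm$trials, kin, geo)
res
#> Experiment: 15 trials, 357 peak-level measurements
#>           parameter  value.18   value.23   value.28
#>  detection_distance 5.4710764  5.2212375  4.4655199
#>            duration 2.1810291  1.1172536  0.8576567
#>          fmax_fbase 1.2686832  1.1697372  1.1690203
#>                fwhm 0.9015764  0.5901944  0.4648972
#>            interval 9.7896401 10.8855210 11.1387063
res$stats$detection_distance
#> Group comparison (anova branch)
#>   omnibus one_way_anova : statistic = 21.41 , p = 5.039e-08 (significant)
#>   pairwise (tamhane_t2):
#>     18 vs 23 : p = 0.2367
#>     18 vs 28 : p = 8.166e-06
#>     23 vs 28 : p = 3.798e-05
```

Detection distance and peak duration fall with temperature while the
inter-peak interval rises — the qualitative structure the pipeline is built
to measure. `write_experiment_results(res, "results/")` writes
`results.csv`, `group_means.csv` and `stats.json`.

A thin command-line front end over the same functions lives at
`inst/cli/tectodist.R` (`geometry`, `simulate`, `analyze`, `extract`, `run`
subcommands).

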