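---
title: "Measuring visual detection distance from tectal calcium transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring visual detection distance from tectal calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tectodist)
```

## The measurement problem

A zebrafish larva is immobilised with one eye 1 mm from a miniature OLED
screen. A cross-shaped glyph (5 pixels, 0.63 mm across) moves along the
screen at 2.1 mm/s — one 0.21 mm pixel pitch per 0.1 s jump, modelled as
continuous motion — over a 6.3 mm one-way track, toward and away from the
animal, for ten cycles. Calcium-indicator fluorescence in the optic tectum
is sampled every 50 ms (20 ms exposure + 30 ms gap). Each approach elicits
one fluorescence transient; the question is *how far away the glyph was when
the response began*.

Because the glyph moves laterally along the screen rather than along the
line of sight, the eye-to-glyph distance is the hypotenuse of a right
triangle: if $x$ is the glyph's lateral coordinate and $b$ the screen point
opposite the eye at perpendicular distance $|bc|$,

$$ d(x) = \sqrt{(x-b)^2 + |bc|^2}. $$

The detection distance of a transient is $d(x(t_0))$ evaluated at the
transient's onset time $t_0$. Everything therefore hinges on two
sub-problems: modelling $x(t)$ exactly, and estimating $t_0$ robustly.

## Stimulus trajectory

`stimulus_kinematics()` describes $x(t)$ as a triangular wave: constant at
`start_offset` before `t_move_start`, then `n_cycles` repetitions of
approach leg (slope $-v$), dwell, receding leg (slope $+v$), dwell.

Two conventions needed fixing:

* **Origin and direction.** $x$ is measured along the screen from the
  closest-approach point ($x = 0$ opposite the eye, `eye_opposite_x`
  configurable); an approach is decreasing $x$. Where the track ends
  relative to the eye is not dictated by the hardware, so the default puts
  the near track end directly opposite the eye.
* **Cycle timing.** Ten cycles spanning two minutes imply a 12 s cycle, but
  a 6.3 mm round trip at 2.1 mm/s takes only 6 s. The reconciliation used
  throughout is a 6 s dwell per cycle, split equally between the two track
  ends (`dwell_per_cycle = 6`). Detection distances are unaffected by this
  choice — they depend only on the approach legs — but event spacing and
  therefore inter-peak intervals inherit it.
* **Phase boundaries.** The approach leg includes its right endpoint, so a
  response beginning exactly at closest approach still yields a distance
  (the minimum attainable, $|bc|$). Onsets during dwells or receding legs
  yield `NA`: those peaks keep their shape metrics but contribute no
  distance, since "detection" is only meaningful while the stimulus is
  approaching.

`first_time_within()` inverts the trajectory analytically (no grid search);
a $10^{-4}$ s grid-scan oracle confirms the inversion on random
configurations in the test suite. Angular size and angular speed are
computed from the standard full-angle formulas
($2\arctan(w/2d)$ and $v\,|bc|/(|bc|^2+(x-b)^2)$); both depend strongly on
the instantaneous distance, so the package always reports them at an
explicit time or distance rather than as single nominal values.

## Transient detection

`detect_peaks()` is a two-pass scheme designed so that its estimates are
testable against ground truth:

1. **Provisional pass.** A rolling lower-percentile baseline (20th
   percentile over 4 s blocks, linearly interpolated) absorbs slow drift;
   candidate peaks are local maxima with topographic prominence at least
   `min_prominence` (default $5\sigma$) whose height also clears the
   baseline by `min_height_sd` noise SDs (default 5 — prominence alone
   admits peak-to-trough noise excursions of up to $\sim 7\sigma$, whereas
   a noise maximum itself rarely exceeds $+4\sigma$ over thousands of
   frames), separated by at least `min_separation` (default 1 s, far below
   the 12 s cycle but above noise chatter). Among conflicting maxima the
   higher wins.
2. **Final pass.** The baseline $F_{base}$ is the median of the samples
   outside all provisional peak windows, and the noise scale is
   $\sigma = 1.4826\,\mathrm{MAD}$ of those samples — robust to any
   transients that leaked into the "baseline". Onset and offset are the
   last/first crossings of the threshold
   $$ F_{base} + \max(k\,\sigma,\; f\,(F_{max}-F_{base})), \qquad
      k = 2,\; f = 0.005, $$
   linearly interpolated between frames.

Three numerical choices deserve explanation:

* **The fractional-amplitude floor** $f = 0.005$. With $k\sigma$ alone the
  threshold degenerates to $F_{base}$ exactly on noiseless data, where the
  indicator's sub-threshold decay tails never return to baseline and the
  crossing search drifts into the preceding inter-peak region. A floor of
  0.5 % of each peak's own amplitude keeps the threshold strictly above the
  tails at any noise level while adding a bias far below one frame period
  on realistic rise times.
* **The baseline tail guard.** When computing the final $F_{base}$, samples
  up to three times each peak's maximum-to-offset span beyond the offset
  are also excluded. Below-threshold decay tails otherwise bias the
  inter-peak median upward by a few tenths of a unit; with the guard the
  estimator meets the $3\,\mathrm{sd}/\sqrt{n}$ sampling bound verified by
  Monte-Carlo in the tests.
* **Overlap fallback.** If the signal never returns to threshold between
  two retained maxima, the inter-maximum valley becomes the shared
  onset/offset boundary, keeping the peak list non-overlapping by
  construction.

Onset estimation on a 50 ms frame grid carries an intrinsic resolution
limit: the onset can be located at most one frame early (grid snap) and the
threshold adds at most a fraction of a frame of lateness. The documented
recovery bound is therefore **two frames of stimulus travel**,
$2 v \Delta t = 0.21$ mm at the default speed, and distances within one
frame of travel of the track ends are declared unresolvable. The zero-noise
end-to-end tests hold every retained peak to this bound over 50 random
geometries.

## Peak metrics

* **Duration** $= t_{offset} - t_{onset}$.
* **FWHM**: width between the two crossings of
  $F_{base} + (F_{max}-F_{base})/2$ nearest the maximum, interpolated.
  Half-maximum is measured *above baseline*, not above zero — otherwise the
  metric would depend on the arbitrary fluorescence offset. On analytic
  Gaussian peaks the estimator stays within one frame of
  $2\sqrt{2\ln 2}\,\sigma$.
* **Inter-peak interval** $= t_{onset}^{(i+1)} - t_{offset}^{(i)}$ —
  end-of-one to beginning-of-next, not maximum to maximum.
* **$F_{max}/F_{base}$**: the response-strength ratio, also the score used
  by `select_roi()` to locate the most responsive ring ROI. All other
  metrics are invariant under affine rescaling of the fluorescence; this
  ratio is invariant only under pure scaling, which is why the ROI search
  uses it on raw (offset-free) intensities.

**Double tops** — two maxima closer than `merge_window` (1 s) whose valley
stays above half the lower maximum's amplitude — are merged into one peak;
the operation is idempotent. **Artifacts** are flagged by three
individually switchable rules: duration under 2 frames (single-frame
spikes), amplitude above 5× the median peak amplitude (a robust envelope on
the transient population, applied when ≥ 3 peaks exist), and onset before
stimulus motion. After flagging and merging, only the **first five** peaks
per trial are retained, so a 10-cycle trial contributes at most 5 distances
and 4 intervals.

## Ring ROI

The readout region is a ring (annulus) of 10 µm outer diameter and, by
default, 1 pixel thickness — the diameter is physically meaningful, the
thickness is a choice exposed as a parameter. A pixel belongs to the ring
when its centre distance from the ring centre lies in
$[r - t/2,\, r + t/2]$ with $r$ the radius in pixels; at the default
0.457 µm/px this is a ~72-pixel annulus. `select_roi()` scores every
candidate centre (exhaustive grid by default, stride configurable) by the
$F_{max}/F_{base}$ of its extracted trace and breaks ties by the
lexicographically smallest (row, col) — a deterministic stand-in for the
manual screening of the tectal region that the protocol leaves unspecified.

## The synthetic generator

`simulate_trial()` builds $F(t) = F_{base}(1 + \sum_e h(t - t_e)) +
\varepsilon$, with one event per approach leg at the exact first time the
stimulus comes within the trial's true detection distance, $h$ a
double-exponential kernel
$A\,(1-e^{-t/\tau_r})e^{-t/\tau_d}$ (normalised so its maximum is $A$; peak
time $\tau_r \ln(1+\tau_d/\tau_r)$ in closed form), and
$\varepsilon \sim N(0, \text{noise\_sd}\cdot F_{base})$.
`render_stack()` paints the trace onto a ring of pixels over a flat
background with Gaussian read noise, giving an exact round trip through
`extract_trace()` at zero noise.

The default `temperature_effect_model()` encodes the study conditions as
generator truth, chosen once:

| parameter | 18 °C | 23 °C | 28 °C | rationale |
|---|---|---|---|---|
| mean DD (mm) | 5.5 | 4.9 | 4.2 | decreasing with temperature, SD 0.6, inside the attainable 1–6.38 mm range |
| $\tau_d$ (s) | 1.4 | 1.0 | 0.7 | indicator kinetics slow at low temperature; gives seconds-scale durations |
| amplitude ($\Delta F/F$) | 0.251 | 0.154 | 0.152 | reproduces the reported mean $F_{max}/F_{base}$ ratios 1.251/1.154/1.152 |
| noise sd (rel.) | 0.02 | 0.02 | 0.02 | keeps single-trial transients at ~8–12 $\sigma$ |

$\tau_r = 0.05$ s throughout. Because duration falls with temperature while
the cycle period is fixed, the inter-peak interval rises with temperature —
the three orderings the pipeline is expected to recover emerge from the
model rather than being asserted anywhere downstream.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real recordings: Poisson shot noise (the noise is purely
additive Gaussian), photobleaching and slow drift, motion artifacts,
response-probability failures (every approach responds), neural/indicator
latency (default 0, but exposed: the tests show any added latency biases
the estimated distance downward, a genuine confound of the onset-based
definition), and trial-to-trial kinetic variability within a treatment.

## Statistics battery

`group_stats()` mirrors the decision tree used for this kind of data. Each
group's skewness (adjusted Fisher–Pearson $G_1$, the SPSS convention) is
screened against $|G_1| < 2$; parameters passing go down the ANOVA branch —
Levene's test on mean-centred absolute deviations, one-way ANOVA, plus the
Brown–Forsythe statistic (Satterthwaite df) when Levene rejects — the rest
down Kruskal–Wallis with Dunn's tie-corrected post-hoc (Bonferroni by
default). On the ANOVA branch the conventional default pairs Scheffé with
homogeneous variances and Tamhane T2 (pairwise Welch t, Šidák-adjusted)
with heterogeneous ones; `posthoc_assignment = "as_published"` swaps the
two, reproducing the reversed assignment reported for the original
analysis. Which Tamhane variant (T2) and which Dunn adjustment to use were
open choices; both are parameters. $\alpha = 0.05$.

All omnibus machinery that exists in base R (`oneway.test`,
`kruskal.test`, `p.adjust`) is called, not re-implemented; Brown–Forsythe,
Scheffé, Tamhane T2 and Dunn are authored here and checked in the tests
against permutation/enumeration oracles and independently computed
fixtures.

## Problem sizes and verification scale

The validation suite uses sizes chosen to make the checks statistically
meaningful while staying desk-scale: 100 random configurations for the
trajectory-inversion oracle, 50 for zero-noise distance recovery, 100
seeded replicate experiments at 20 trials per temperature for the
ordering/significance reproduction (the observed fractions are 1.0 against
a ≥ 0.95 requirement), 2000 null datasets for type-I calibration (observed
≈ 0.046–0.048 at $\alpha = 0.05$), and 3000–4000 permutations where p-values
are compared to resampling oracles.

## Known limitations

* The onset-based distance is biased low by any true response latency; with
  no latency correction (the default), reported distances are lower bounds.
* Peaks whose onset falls off an approach leg carry no distance; trials
  where all retained peaks do so produce an explicit empty record rather
  than a value.
* The frame grid limits distance resolution to $2v\Delta t$; speeds or
  frame periods much larger than the defaults proportionally coarsen it.
* The exhaustive ROI search is quadratic in image side length and meant for
  fixture-scale stacks (≤ 256×256); real pipelines would pre-select a
  candidate region.
* `fmax_fbase` is meaningful only for offset-free intensity data; any
  camera offset must be subtracted upstream.
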