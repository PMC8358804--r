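---
title: "Methods: models, parameters and design choices in efferentquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in efferentquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efferentquant)
```

# Scope

`efferentquant` is a desk-scale reimplementation of the quantitative
pipeline used to study temporary noise-induced hearing loss (TTS) and its
modulation by prior electrical activation of the auditory cortex, read out
through the cholinergic medial olivocochlear (MOC) efferent innervation of
outer hair cells. Four experimental arms are modelled: sham controls (SC),
electrically stimulated (ES), acoustic trauma (AT), and stimulation before
trauma (ES_AT). The pipeline has four measuring stages — ABR threshold
calling, cochlear place-frequency mapping, terminal-button morphometry and
densitometry, and immune-cell counting — plus a statistics battery, all
driven by a synthetic-data generator with known ground truth. Animal data
are not distributed with the package; the generator's defaults encode the
study conditions (sample sizes, effect sizes, noise scales) so that every
stage is testable end to end.

# ABR model and threshold criterion

## Waveform model

An averaged click-evoked ABR record is simulated directly at the
post-averaging stage: i.i.d. Gaussian noise per sample (default
`noise_sd = 0.12` µV) plus, at stimulus levels at or above the true
threshold, a small set of biphasic waves. Each wave is a Gabor-like
transient — a Gaussian envelope (0.25 ms SD) on a 1 kHz carrier, so a
negative trough immediately precedes the positive peak — normalized so its
peak-to-peak amplitude is exactly the configured value. Simulating the
average rather than 1,000 individual sweeps is statistically identical for
everything downstream and orders of magnitude faster.

Defaults: sampling at 24.4 samples/ms over 10 ms; levels 10–90 dB SPL in
10-dB steps; four waves with 90-dB latencies 1.9/2.7/3.5/4.3 ms; latency
growing 0.006 ms per dB of level drop; peak-to-peak amplitude
`amplitude_growth` (0.15 µV/dB) times dB above one step below threshold, so
a wave is present with one step's worth of amplitude at threshold itself.
No wave energy occurs before the 1.4-ms conduction delay (the acoustic
travel time through the closed-field tube). The number of waves is
configurable and makes no claim of physiological wave-component fidelity;
threshold calling never identifies individual waves.

## Response criterion

A record is called responsive when at least `min_run` consecutive samples
in the 1.4–5 ms window deviate from the baseline mean by more than
`k = 2` baseline SDs, with baseline statistics (sample SD by default) taken
over the first 1 ms — guaranteed pre-response by the conduction delay. The
exceedance is two-sided: alternating-polarity clicks remove any meaningful
sign convention, and the criterion is stated in terms of a "voltage
change". Both the sidedness and the run length are exposed as parameters
rather than hard-coded.

The `min_run` default is 0.2 ms of consecutive exceedance (5 samples at
the default rate). That value is calibrated analytically, once, against
the false-positive target the threshold caller must meet: a pure-noise
*series* should be censored at least 95% of the time. With an ~88-sample
analysis window, per-sample exceedance probability
$P(|z| > 2) \approx 0.0455$, and 9 levels per series, a 3-sample run
(0.1 ms) yields roughly $9 \times 86 \times 0.0455^3 \approx 7\%$
series-level false calls — too many — while 5 samples drives the rate far
below 1%. A detected response at threshold is unaffected: the rendered
wave exceeds the criterion band for well over 0.2 ms.

The threshold is the lowest responsive level (`policy = "minimal"`,
matching the criterion's wording); `policy = "monotone"` additionally
requires all higher levels to respond, a guard against spurious low-level
calls in real data. A series with no response is *censored* at the maximum
tested level and propagates as censored through shift tables. Wave
latency/amplitude measurement reports local maxima above a prominence
floor of 2 baseline SDs (peak selection is not specified by the bench
protocol; the floor is configurable), with amplitude measured from the
nearest preceding trough to the peak. An optional zero-phase 500–3,000 Hz
Butterworth bandpass is provided for raw inputs and is off by default —
acquisition-grade records are assumed already filtered.

# Cochlear place-frequency mapping

The cochlea is represented by the traced spiral-bundle polyline, apex
first; its Euclidean arc length is the measured cochlear length. Frequency
is assigned by a Greenwood-form map on *fractional* distance from the apex,

$$F(x) = A\,(10^{a x} - k), \qquad x \in [0, 1],$$

with closed-form inverse $x = \log_{10}(f/A + k)/a$. Because $x$ is a
fraction of the measured trace, frequency assignment is scale-invariant:
real cochleae vary around the 9.4-mm reference length, and only the
fraction matters. The default constants ($A = 3.6$ kHz, $a = 1.21$,
$k = 0.85$) are range anchors fitted so the map spans the rat audible
range (≈0.54 kHz at the apex to ≈55 kHz at the base), comfortably
containing the six standard analysis frequencies 2.8, 8, 11.3, 16, 32 and
45.2 kHz. They are deliberately not presented as a published fit — the
mapping plugin used at the bench does not document its constants — and all
three are configurable. Analysis frames are axis-aligned 50-µm squares
centered on the interpolated trace point; polyline interpolation is linear
with exact vertex hits resolved to the earlier segment; coordinates are
0-based µm with y down.

# Morphometry and densitometry

## Segmentation

Terminal buttons are segmented by density thresholding: pixels darker than
the threshold, grouped by 8-connectivity (run-length encoding + union-find,
exact), filtered to areas in [0.5, 50] µm². The automatic threshold is
Otsu's method with a contrast guard: the maximizing split is accepted only
if it explains at least 80% of the total gray variance. A frame with no
dark phase (a pure-background field) fails the guard and yields zero
segments — without the guard, Otsu would split the background noise near
its median and hallucinate foreground. The guard level sits between the
theoretical maximum for a unimodal Gaussian (~0.64) and the values
observed for genuinely bimodal stained fields (>0.95). The bench protocol
does not record its threshold settings, so the automatic default can be
overridden per frame.

Area follows the pixel pitch exactly: at the default 0.2 µm/pixel there
are exactly 25 pixels per µm², and a 25-pixel component measures exactly
1 µm² (the pixels-per-µm² reciprocal is snapped to the implied integer to
keep this identity free of floating-point residue).

## Calibration and normalized OD

Gray levels convert to optical density through a monotone piecewise-linear
interpolant over a stepped-density-filter table (11 levels in the standard
protocol); queries outside the calibrated range clamp to the end values
with a warning. The packaged default follows $OD = \log_{10}(255/g)$
sampled at 11 uniform OD steps from 0 to 1.2 — the geometry of a real
stepped filter — but a measured table, when supplied, is always
authoritative over the analytic formula.

Densitometry converts each button's *mean gray* to OD (matching the bench
definition of button immunoreactivity), not a per-pixel OD average; with a
convex calibration curve the two differ slightly, and the choice is
documented here so results are interpretable. The normalized OD is the
field-referenced z-style statistic

$$\mathrm{nOD} = \frac{OD_\text{button} - \overline{OD}_\text{field}}
                      {SD_\text{field}},$$

where the field is the entire OHC region and its SD uses the population
convention (the field *is* the population). Applying the normalization to
the field's own pixels therefore standardizes them to mean 0, SD 1
exactly — a property the test suite checks to 1e-9. A zero field SD makes
the statistic undefined and is flagged, never returned as an infinity.
The 30-button densitometry sample per frame mirrors the protocol's manual
selection; since manual choice has no reproducible rule, a seeded uniform
sample stands in, and is labelled as such.

## Immune-cell counting

Free cells appear in two classes: large (10–20 µm) intensely stained
macrophages and small (5–10 µm) unstained monocytes. Candidates are
segmented on a 3×3 box-smoothed frame with a cut `k_mad = 4` scaled MADs
below the median of the *non-dark phase* (pixels at or above the Otsu dark
cut) — anchoring the cut to the background keeps faint cells detectable
regardless of how many dark buttons the frame holds. The box filter
dilates dark objects by about a pixel, so the mask is eroded by one pixel
before labeling. Immunoreactivity is decided by a dark core: a component
whose minimum smoothed gray falls below the Otsu cut is immunoreactive.
This is the operational form of the qualitative stained/unstained
distinction; an earlier candidate rule (component mean OD above field mean
+ 1 SD) proved fragile because button-halo components straddle that
boundary. Classes then follow size: immunoreactive 10–20 µm components
are macrophages, non-immunoreactive 5–10 µm components are monocytes, with
a ±1 µm tolerance absorbing the smoothing/erosion bias. Counts normalize
to cells per 1,000 µm of analyzed cochlear length.

# Statistics battery

All tests are two-sided at α = 0.05.

* **Friedman + post hoc** (within-arm threshold trajectories): the
  tie-corrected Friedman chi-square (via `stats::friedman.test`), followed
  by a Dunn-type post hoc on within-subject mean ranks with Bonferroni
  adjustment over all pairs — the procedure major statistical packages run
  under "Friedman with Bonferroni post hoc". The Dunn standard error
  carries the same tie correction as the statistic itself
  ($v_b = ((k^2-1) - \sum_t (t^3-t)/k)/12$ per block;
  $\mathrm{Var}(\bar R_i - \bar R_j) = 2k\,\overline{v}/(n(k-1))$, which
  reduces to the classic $k(k+1)/(6n)$ without ties). This matters here:
  thresholds live on a 10-dB grid and blocks are heavily tied, and the
  no-tie SE visibly overstates the null variance in that regime. Pairwise
  exact Wilcoxon signed-rank tests are available as an alternative post
  hoc, with the caveat (documented in the help page) that at n = 6 and 15
  pairs their Bonferroni floor (15 × 2/64 ≈ 0.47) makes significance
  unreachable. A fully tied table is reported as statistic 0, p = 1.
* **Mann–Whitney** (between-arm comparisons per timepoint): exact for
  combined n ≤ 12 — the study's group sizes — through the standard exact
  algorithm without ties and by full enumeration of group assignments
  (midranks) with ties; the normal approximation with tie and continuity
  correction otherwise.
* **One-way ANOVA** with two post hocs: pooled-SD pairwise t with
  Bonferroni, and Games–Howell for unequal variances (Welch–Satterthwaite
  df, $q = t\sqrt{2}$ referred to the studentized-range distribution via
  `stats::ptukey`; familywise by construction). Degenerate inputs are
  flagged: all-identical values give F = 0, p = 1; zero within-group
  variance with distinct means gives an infinite F with a note.
* **Two-way ANOVA** (arm × frequency region): Type II sums of squares via
  `car::Anova` for unbalanced data (no interaction emphasis is claimed by
  the design); balanced designs reduce to the classical decomposition.
  Empty cells are an error that names the cells.
* **Correlations** (button size vs normalized OD per arm): both Pearson
  and Spearman are always reported, with group n, means and SDs, in the
  layout of the classic correlation table; published tables of this kind
  often leave the coefficient type per row unstated, so the package
  reports both rather than guessing. Zero variance flags the coefficient
  undefined.

# The synthetic study and its defaults

`default_study_effects()` encodes the study conditions: four arms of
n = 6, ABR at protocol days 0/12/13/14/19/26, thresholds drawn
normal-around-the-arm-mean and snapped to the 10-dB grid. The printed
group dispersions are exactly those of grid-valued samples of size six
(e.g. {20,30,30,30,30,40} → 30 ± 6.32 dB), which fixes both n and the
snapping rule. Arm trajectories: SC constant 10 dB; AT 30 ± 6.32 at day
13, 21.66 ± 4.08 at day 14, 13.33 ± 5.16 at day 19, recovered by day 26;
ES and ES_AT transiently 33.33 ± 5.16 at day 12 (right after the last
stimulation session), back at baseline a day later. The emulated conditions give no numeric
day-12 value for the ES arm; the package reuses the ES_AT value, since
the stimulation protocol of the two arms is identical.

Morphometry/densitometry arms carry per-arm (area, normalized OD) means,
SDs and correlations for SC, AT/ES_AT at day 13 and AT/ES_AT at day 26.
Per-button pairs are drawn from a bivariate normal in which the area mean
follows the cochleotopic profile per frequency; the arm's pooled area SD
splits into the between-frequency spread carried by the profile and
within-frame scatter, and the within-frame correlation is inflated by the
ratio of pooled to within SD so the *pooled* per-arm coefficient matches
the configured one. Immune counts are Poisson at per-arm rates over the
analyzed length (default 8,080 µm, a typical measured spiral-bundle
perimeter); the configured rates encode the qualitative pattern —
inflammation peaks one day after trauma, is curbed by prior stimulation,
and resolves by day 26 — the emulated conditions specify the pattern,
not numeric rates, so the rates are the package's own realistic choice.

The image simulator renders 250 × 250-pixel frames (50 × 50 µm at
0.2 µm/pixel): Gaussian background (gray 200 ± 6), dark elliptical buttons
(gray 90 ± 8 between buttons, same pixel noise as background) whose mean
area follows a Gaussian-in-log-frequency profile peaking at 11.3 kHz
(base 8 µm², peak 13.5 µm², width 0.55 octaves, per-button SD 3.5 µm² —
chosen once so the pooled area mean and SD match the sham morphometry
table), at 160 buttons per 10,000 µm² (≈40 per frame). Buttons are
rejection-sampled non-touching with a 4-pixel bounding-circle gap, which
makes count ground truth unambiguous *and* guarantees the smoothed immune
mask cannot bridge neighbours; overlap can be allowed by flag, and
placement raises a generation error after a bounded number of attempts
when a frame cannot hold the requested density. Immune cells render as
disks: macrophages 12–18 µm at gray 70, monocytes 6–9 µm at gray 185
(background contrast only).

By default `simulate_study()` produces the morphometry/densitometry/immune
arms at *measurement level* (draws from the effect distributions) and full
waveforms for the ABR arm; `render_images = TRUE` additionally renders
frames per animal and frequency. The rendered-image path is exercised
separately by the segmentation and profile-recovery validations — routing
replicate whole studies through image rendering would multiply runtime
without adding information to the statistics arm.

## What the generator does not emulate

Uneven illumination and staining gradients, out-of-focus planes and
Z-stack fusion artifacts, touching/overlapping terminals, partial cells at
frame borders, non-Gaussian electrophysiological artifacts (movement,
cardiac), per-animal latency idiosyncrasies, and any acoustic or cochlear
micromechanics. Passing tests therefore demonstrate correctness of the
*measurement and inference machinery* under controlled conditions, not
robustness to every pathology of real bench data. A deep-focus fusion
utility is intentionally out of scope; frames are assumed already fused.

# Validation study sizes

The package's validation suite (the acceptance tests) runs: detection vs
an exhaustive scan on 1,000 random waveforms; threshold recovery on 200
simulated series (truths 20–60 dB) plus 30 series in the vanishing-noise
limit; 200 all-noise series for censoring; 100 rendered frames for count
exactness and rasterized disks of radius ≥ 2 µm for area accuracy; 100
simulated cochleae (six frames each) for recovery of the 11.3-kHz profile
peak; statistics against enumeration/rank/Monte-Carlo oracles (10⁶
studentized-range draws); 1,000-replicate null calibrations per test; and
50 replicate studies at n = 6/arm for the end-to-end qualitative pattern.
These sizes were chosen as the package's own validation budget — large
enough for the stated precision targets, small enough to run routinely.

# Known limitations

* The place-map constants are range anchors, not a measured fit; analyses
  that depend on absolute cochleotopic position should supply constants.
* Normalized OD is relative to each field; absolute staining intensity is
  not comparable across sessions without a shared calibration table.
* The Dunn post hoc uses the normal approximation to the mean-rank
  difference; at very small n its p-values are approximate where the
  Wilcoxon option is exact (but Bonferroni-floored).
* Measurement-level study simulation bypasses segmentation bias; the
  rendered-image path shows that bias is negligible for non-touching
  buttons, but real, touching terminals would be merged or split.
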