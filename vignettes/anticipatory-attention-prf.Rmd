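---
title: "Modeling anticipatory spatial attention with event-related pRF mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling anticipatory spatial attention with event-related pRF mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(anticiprf)
```

## The scientific question

Covert spatial attention changes visual cortical responses before an
attended target ever appears. In a concurrent psychophysics–fMRI protocol,
a central pre-cue directs attention to one of four target locations on the
cardinal meridians at 6° eccentricity (or distributes it over all four), a
task-irrelevant bar mapping stimulus is flashed during the anticipation
period, and the participant finally discriminates the tilt of a cued Gabor.
Because the bar position is randomized trial by trial, the pattern of
responses across bars yields a population receptive field (pRF) per
cortical surface vertex *per attention condition*, and three questions can
be asked of the anticipatory period:

1. **Amplitude**: does focal attention add a stimulus-independent baseline
   shift to the BOLD response, enhancing near the cued location and
   suppressing far from it?
2. **Timing**: is the modulation locked to the cue and sustained until the
   target, or transient, or target-evoked?
3. **Position tuning**: do pRF centers shift toward the attended location?

`anticiprf` implements the full analysis chain — trial design, GLM beta
estimation, coarse-to-fine pRF fitting, polar-angle tuning of the
modulation, latency estimation, and shift quantification — together with a
first-class synthetic-data generator whose known ground truth validates
every stage by parameter recovery.

## The measurement model

Each vertex's time series (1-s TR) is modeled by an event-related GLM with
250 indicator predictors: 5 attention conditions × 49 mapping stimuli
(48 bar positions + 1 blank; 1s spanning the 1 or 2 bar TRs) plus one
Gabor-target predictor per condition (a single 1 at the target TR). All
task predictors are convolved with a hemodynamic response function — by
default the canonical double-gamma, unit-peak, sampled at the TR over
50 s — and per-scan polynomial nuisance regressors (order 2 by default)
absorb drift. Coefficients are converted to percent BOLD by dividing by the
vertex's mean signal intensity. Downstream analyses exclude vertices whose
GLM variance explained is ≤ 5%.

The pRF model is an isotropic 2D Gaussian with center $(x, y)$ and size
$\sigma$ (one SD), all in degrees of visual angle. Its prediction for a
stimulus is the gain times the normalized overlap between the Gaussian and
the binary aperture — the fraction of Gaussian mass inside the aperture, so
the gain is a percent-BOLD quantity independent of grid resolution, and the
blank predicts zero. Fitting minimizes the residual sum of squares over the
49 beta weights per condition by a coarse-to-fine search: an exhaustive
grid (centers at 1° spacing inside the 12.4° stimulus window; $\sigma$
log-spaced over 0.25–8°) with the gain solved in closed form at each point
(the model is linear in gain), then Nelder–Mead refinement of
$(x, y, \log\sigma)$ with gain profiled out, clamped to $|x|,|y| \le 14$°
and $\sigma \in [0.1, 12]$°, and never allowed to end worse than the best
grid point. $R^2 = 1 - RSS/TSS$ is computed in-sample with centered TSS, so
a profile equal to its own mean scores 0; an all-zero profile is flagged
degenerate with undefined $R^2$, as is any profile with fewer than three
observed bar stimuli. Six models are solved per vertex: one per condition
and one for the stimulus-wise mean of the five conditions ("average"),
whose solution anchors vertex positions in all spatial analyses.

Two model choices deserve note. First, the blank beta is included in the
fit with prediction 0 by default (`include_blank`); this routes an additive
offset common to all stimuli into the residual rather than the gain, while
excluding the blank makes fitted centers exactly invariant to such offsets
— both behaviors are tested. Second, the original estimation used
data-driven noise regressors and a participant-specific FIR HRF; this
package keeps the GLM's structure self-contained with the canonical HRF
(a user-supplied sampled HRF is accepted) and per-scan polynomials.

## The synthetic-data generator

`sample_prf_population()` draws vertices uniformly over the stimulus disc
with the canonical linear size–eccentricity relation
($\sigma_0 = 0.3 + \text{slope(map)} \cdot e$, slopes rising from 0.10 in
V1 to 0.30 in LO1) and lognormal gains around 2 %BOLD. Attentional
modulation has two components:

* **Additive baseline shift** — a difference-of-von-Mises profile of the
  polar-angle distance between a vertex's pRF and the attended target
  (`modulation_spec()`): positive at the target, negative far from it,
  scaled so the peak equals a configurable value (default 0.1 %BOLD,
  matching the order of the reported target enhancement). The distributed
  condition carries no offset. In `multiplicative_gain` mode the same
  profile instead scales the stimulus-driven response.
* **Position shift** — under focal attention the effective pRF is the
  normalized product of the baseline Gaussian and a Gaussian attention
  field at the target (`attention_field_transform()`): the center moves
  toward the target by $\sigma_0^2/(\sigma_0^2+\sigma_a^2)$ of the
  distance and the size shrinks. The default $\sigma_a = 8°$ yields
  sub-degree shifts that grow with pRF size, i.e. up the cortical
  hierarchy, as observed. `shift_deg` instead displaces centers by an
  exact amount, giving closed-form recovery targets.

`simulate_bold()` builds the neural predictor from the true betas (bar
boxcars, a target transient) and places the additive component according
to a *temporal account*: `stimulus_locked` folds it into the mapping betas
exactly as the GLM models it (so a noiseless GLM recovers the true betas
to machine precision — the least-squares identity the recovery tests
build on); `sustained` runs from the cue TR through the target TR;
`transient` occupies the cue TR only; `target_evoked` runs from the target
TR to the trial's end. The predictor is HRF-convolved within each scan and
embedded as `baseline × (1 + (signal + drift + noise)/100)`, with the
signal centered per scan so the series mean equals the baseline intensity
and the percent-BOLD conversion is exact. Noise is white Gaussian
(default SD 1 %BOLD per TR — a calibration default for surface-vertex
series, not a measured value) plus per-scan polynomial drift.

Trial schedules follow the protocol's marginals by independent sampling:
80% focal cues (equiprobable over four locations), 75% validity, 10%
blanks, 1- or 2-s bars, jittered ISIs, every trial an integer number of
TRs (4 or 5). Behavior is equal-variance signal detection: evidence
$\mathcal{N}(\pm d'/2, 1)$ with a zero criterion, $d'$ keyed by validity
with defaults at the reported group means (valid 4.00, neutral 1.57,
invalid 0.52), and shifted-lognormal reaction times whose means match the
reported 0.30/0.56/0.56 s. Gaze is 1-kHz Gaussian jitter around fixation
with ~150-ms blink episodes; a configurable cue-locked bias (applied after
each trial's 300-ms fixation period) lets the analysis demonstrate that
the median-of-fixation correction preserves genuine attentional gaze
biases while removing constant calibration error.

What the generator does **not** emulate: spatially correlated noise across
vertices, physiological noise spectra, cortical magnification of vertex
density, eye-movement-induced pRF distortions, or hemodynamic variability
across vertices. Passing recovery tests therefore demonstrate the
correctness and calibration of the estimators under the stated model, not
robustness to every artifact of real surface data.

## Amplitude tuning and spread

Per vertex, the anticipatory modulation is the mean over the 49 stimuli of
(focal − distributed) betas. For maps, modulation is placed at the
average-model pRF center, rotated by $90° - \theta_{target}$ so all four
focal conditions align at the upper vertical meridian, and resampled to a
square grid by cell-mean binning (1° cells) followed by bilinear
interpolation (0.25° output); scattered-triangulation interpolation is not
used. For tuning curves, vertices with eccentricity 4–8° and GLM
$R^2 > 5\%$ are binned by polar-angle distance to the target in 20° steps,
bin centers at the member mean. The four target curves are averaged per
map and fitted with a difference of two von Mises functions sharing one
scalar $S$ and center $\mu$:

$$\hat y(x) = \frac{S e^{\kappa_1 \cos(x-\mu)}}{2\pi I_0(\kappa_1)}
            - \frac{S e^{\kappa_2 \cos(x-\mu)}}{2\pi I_0(\kappa_2)} + B$$

with degrees mapped linearly to radians so the von Mises period matches
the polar circle. Fitting is Levenberg–Marquardt from a multi-start grid
($\mu \in \{-20, 0, 20\}°$, $\kappa_1 \in \{2, 6, 12\}$,
$\kappa_2 \in \{0.3, 1, 3\}$, concentrations on the log scale), best RSS
wins. The attentional spread is the distance between the two x-intercepts,
found by bracketing root search on $[-60°, 0]$ and $[0, 60°]$; peak
enhancement, trough suppression and absolute modulation
(= peak − trough, exactly) come from the fitted curve. A curve without a
sign change in a bracket reports that intercept as missing.

```{r tuning-example}
gen <- modulation_spec(peak = 0.1)
curve <- data.frame(center_deg = seq(-170, 170, by = 20),
                    value = dvm_value(seq(-170, 170, by = 20), gen), n = 30)
fit <- fit_diff_von_mises(curve)
spread <- attentional_spread(fit)
c(peak = spread$peak, trough = spread$trough, width = spread$width)
```

## Latency of the modulation

Event-triggered percent-BOLD series (first-order polynomial projected out
per scan) are extracted per trial, aligned to the cue or to the target,
from trials whose bar overlapped the ROI's target, classed as attend-in /
distributed / attend-out and split by bar duration; the attend-in minus
attend-out trace is the modulation time course. Each limb of the min–max
normalized trace (split at the peak of a lightly smoothed copy) is fitted
with a logistic $f(t) = 1/(1+e^{-m(t-t_{50})})$; the rise latency is the
10%-of-maximum crossing ($t_{10} = t_{50} - \ln 9 / m$) and the fall
latency the 10%-decline crossing ($f = 0.9$ on the falling limb).
Latencies extrapolated more than 2 s outside the sampled window are
flagged as failed fits. Bootstrapping resamples participants, averages
traces, and refits; Bayes factors compare the observed 2-s minus 1-s
differences under mean-0 and mean-1 normal hypotheses, multiplied across
maps.

Three analysis settings matter at simulation scale, all exposed as
arguments. The extraction window defaults to 10 s; fall-limb analyses in
this package use 14 s because the canonical double-gamma HRF peaks and
decays later than participant-optimized FIR responses, leaving the falling
limb incomplete at 10 s. The four target ROIs are pooled (averaged) before
fitting, quadrupling the usable trials. And `stratify_by_bar` balances the
in/out contrast over bar identity, removing the sampling noise caused by
the two classes drawing different bars. Even so, the finite trial count
leaves irreducible "composition" noise — which neighboring trials surround
each selected trial — of roughly ±0.3–0.5 s on group latency differences
at 8 × 2080 trials. The sustained account's signatures (rise difference
≈ 0, fall difference ≈ 1 s cue-locked; rise ≈ −1 s target-locked) resolve
cleanly at that noise level; the transient fall and target-evoked rise
differences do not resolve to ±1 s by confidence-interval exclusion, so
the test suite distinguishes those generators by the statistics that are
robust at this scale — the transient's null differences and the
target-evoked account's delayed absolute rise.

## Position shifts

For shift analyses, vertices must satisfy eccentricity 0.5–5.5° and pRF
$R^2 > 0.25$ in **all five** condition models. Per vertex and target, the
shift statistic is the Euclidean distance change
$\lVert c_{focal} - T\rVert - \lVert c_{distr} - T\rVert$ (negative =
toward the attended target), averaged over vertices within a map and then
over the four conditions. The control refits the entire GLM → pRF chain
after randomly permuting the cue labels across trials; the package runs
one permutation per call, and pooling several calls gives a multi-
permutation null whose spread includes the permutation draw itself.
Directional vector graphs bin vertices by the eccentricity (1° rings from
0.5°) and polar angle (45° sectors) of the pair-averaged center for
opposed cue pairs, restricted to eccentricities below the 6° target
eccentricity, and flag whether each bin's shift component along the pair's
axis is congruent with the attended directions.

## Worked example

A small but complete synthetic run (two maps, 24 vertices, three scans at
64-px aperture resolution — sizes chosen so the example runs in seconds):

```{r pipeline, eval = FALSE}
out <- run_pipeline(pipeline_config(
  seed = 42, maps = c("V1", "hV4"), n_per_map = 12, n_trials = 156,
  resolution = 64,
  mod = modulation_spec(peak = 0.1, account = "stimulus_locked")))
out$shifts$by_map
out$behavior
```

## Numerical and degenerate-input conventions

* Apertures are bit-reproducible: a pixel is lit iff its center lies in
  both the 3°-wide strip and the 12.4° circular window; bar centers are
  1°-spaced and symmetric (−11.5…+11.5°), so adjacent same-orientation
  bars share a 2° band and the 48 bars tile the window. Default grid
  128×128 (the fitting resolution is not dictated by the protocol);
  geometric property tests use ≥512.
* Condition-stimulus cells never observed in a schedule give all-zero
  regressors; their betas are `NA` and pRF fits simply ignore them. Rank
  deficiency among observed regressors is an error naming the columns.
* The d′ correction adds 0.5 to hit and false-alarm counts and (default
  log-linear rule) 1 to the trial counts; the hits-only denominator
  convention is available as `correction = "hits_only"`.
* Percentile bootstrap CIs (1000 × resampling participants, 68% by
  default) are used for all group uncertainty; seeds make every simulated
  quantity reproducible.

## Known limitations

Single isotropic Gaussian pRFs only (no elliptical or
difference-of-Gaussians variants, no compressive summation);
in-sample $R^2$ without cross-validation; no BIDS/NIfTI ingestion — the
entry points take plain matrices and data frames, with TSV read/write for
schedules and pRF tables; the latency composition-noise floor discussed
above.
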