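---
title: "Measuring filter darkening with a lightbox: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring filter darkening with a lightbox: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightboxr)
```

## The measurement problem

Passive filter samplers estimate long-term exposure to light-absorbing
carbon (LAC) from how much a white filter surface darkens as particles
deposit on it. Darkening is quantified photographically: the sampler is
placed in an enclosed, LED-lit lightbox beside an unexposed reference
filter and photographed in 12-bit monochrome, and the mean pixel intensity
(PI, 0 = black … 4095 = white) of a square region of interest (ROI)
centred on each surface is computed, pooling all pixels across a
multi-frame burst. The change in reflectance after exposure time $T$ is the
double difference

$$
\Delta PI_{S,[T-0]} = (PI_{S,T} - PI_{R,T}) - (PI_{S,0} - PI_{R,0}),
$$

with $S$ the exposed sample and $R$ the unexposed reference. The two
subtractions address the two dominant nuisance factors:

* *filter-to-filter baseline differences* — each sampler is compared to its
  own baseline image;
* *session-to-session lighting differences* — any brightness shift common
  to both surfaces in a photo cancels. For an **additive** shift $b$ the
  cancellation is exact (before quantization). A **multiplicative** gain
  drift $g \neq 1$ is *not* cancelled: at zero noise the residual error in
  $\Delta PI$ is exactly $(g-1)(PI_{S,T} - PI_{R,T})$. We document this
  closed form (and assert it in the test suite) rather than invent a gain
  correction the measurement protocol does not define; keeping the lightbox
  illumination stable is what bounds this term in practice.

Darkening is negative by convention ($-4095$ PI $= -100\%$ = white to
black), and values are kept unrounded until report rendering.

## Assumptions and scope

The metric assumes the ROI is fully inside the imaged surface (the default
49 × 49 px ROI sits at the surface centre, avoiding clamp shadows and
handled edges), that one unexposed reference appears in every session
(sessions without one are rejected, not imputed), and that the camera's
12-bit data may arrive padded in 16-bit containers — stored sample depth is
therefore ignored and values are validated against $2^{12}-1$; anything
larger is an error, never silently rescaled. ROIs are addressed by 0-based
centre coordinates and an odd side length in an explicit YAML layout file;
automatic surface detection is out of scope by design (an explicit layout
is reproducible and testable). Conversion of $\Delta PI$ to LAC mass
concentration is also out of scope: no calibration exists, so the package
reports reflectance change only.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| ROI side | 49 | px | large averaging area (~2400 px) without reaching the surface edge |
| frames per session | 20 | — | averages frame-to-frame flicker; any count ≥ 1 is accepted and deviations are QC-flagged |
| measurable-change threshold | 1 (= 41 PI) | % of full scale | the smallest change treated as signal; defines the cohort lower limit of detection |
| saturation `continuing_tolerance` | 41 | PI | continuing samplers within one measurable change of zero count as "stopped darkening" |
| saturation `ratio_threshold` | 10 | — | the replacement sampler must out-darken the continuing ones by an order of magnitude |
| saturation `epsilon` | 1 | PI | floors the ratio denominator when continuing samplers are exactly flat |

The saturation constants deserve a note: the field protocol provides one
worked probe (a replacement sampler darkening tens of times more than its
long-exposed neighbours), not a general rule. The defaults above encode
that instance conservatively and are all configurable arguments of
`assess_saturation()`.

## The synthetic lightbox

Because campaigns of real images are not portable, the package ships a
simulator that generates entire campaigns with known ground truth. Its
darkening model is the simplest monotone form consistent with the two
regimes the analysis must handle — near-linear darkening at low cumulative
dose, and a plateau (saturation) at high dose:

$$
PI(t) = PI_{sat} + (PI_0 - PI_{sat})\, e^{-k D(t)}, \qquad
D(t) = \int_0^t v_d\, C(\tau)\, d\tau ,
$$

with initial darkening rate $k (PI_0 - PI_{sat}) v_d C$. This exponential
form is a modelling stand-in, not a claim about deposition physics; $k$,
$v_d$ and $C$ only ever enter as a product, in arbitrary consistent units,
because no optical/mass calibration exists.

Rendering applies, in order: session gain $g$ (lognormal), per-frame
flicker factor $f_j$, session offset $b$, per-pixel Gaussian noise, then
quantization — round half away from zero (deterministic across platforms)
and clip to $[0, 4095]$. Background pixels carry a mid-gray backdrop so a
mis-specified ROI is immediately visible in tests. Identical configuration
and seed give byte-identical TIFFs.

### Default study conditions

The default `campaign_design()` mirrors a long-term indoor field study in a
solid-fuel-using community: 20 locations × 2 co-located samplers, imaged at
baseline and days 33, 55, 90, 118, 173, 209 and 258, 20 frames per session
at 256 × 256 px, with an optional fresh replacement sampler deployed at the
highest-exposure location on day 118 (the saturation probe).
`lab_study_design()` + `lab_darkening_model()` mirror a smoke-chamber run:
triplicate samplers at 5-minute steps to 85 minutes with an initial rate of
−4.2 PI min⁻¹.

The generator's numeric defaults were fixed once, from the magnitudes such
campaigns report:

* $PI_0 = 3900$, $PI_{sat} = 500$ — white filters image near (not at) full
  scale; the floor leaves heavily loaded filters dark gray rather than
  perfect black;
* median dose rate $0.00155\ \mathrm{d}^{-1}$ — gives a median initial rate
  of $\approx -5.3$ PI d⁻¹ and a median 258-day change of $\approx -1120$
  PI ($-27\%$), the magnitudes a real deployment of this kind produces;
* between-location spread lognormal with $\sigma_{\log} = 1.1$ — locations
  span roughly two orders of magnitude in exposure, so the darkest sites
  approach saturation within the campaign while the slowest stay near the
  detection limit;
* replicate deposition multiplier $\sigma_{\log} = 0.11$ — co-located
  duplicates disagree by ~11% (CV), the reported replicate precision of
  the method, and disagreement scales with the signal as observed;
* noise: session offset sd 15 PI (cancels by construction), session gain sd
  0.002, flicker sd 0.005, pixel sd 8 PI, filter-to-filter baseline sd
  20 PI. The gain term is the one that propagates: its residual is
  $(g-1)(PI_S - PI_R)$, a few PI at these settings.

### What the simulator does not emulate

Real images contain spatial structure the simulator omits: uneven
illumination across the field of view, lens vignetting and distortion,
deposition gradients and speckle within the ROI, filter texture, dust
events, and repositioning error between sessions (surfaces land on exactly
the same pixels every time here). Noise is Gaussian and stationary; real
sensors add fixed-pattern and shot noise. Passing the recovery tests
therefore demonstrates that the *pipeline* is correct and that the metric
behaves as designed under the stated disturbance model — it does not
validate the method's field accuracy, which requires physical collocation
studies.

## Numerical and statistical choices

* **Pooled ROI mean.** All ROI pixels across all frames enter one
  arithmetic mean. For a fixed ROI this is identical to averaging per-frame
  means, so nothing is lost by choosing the simpler pooled form.
* **Quantiles.** Medians and IQRs use the linear-interpolation quantile
  definition (R type 7), the most common reporting convention.
* **CV.** Sample (n−1) standard deviation over the absolute mean — replicate
  counts are 2–3, where the sample form is standard.
* **RMSE vs replicate mean.** Deviations from each set's own mean are pooled
  over sets before taking the root mean square; for a pair this equals
  $|a-b|/2$. The relative version divides by the absolute grand mean
  (positive percentages against negative means).
* **Quintile grouping.** Pairs are ranked by pair-mean $\Delta PI$ and split
  into five equal-count groups; ranking is a stable sort, so ties keep
  input (location) order and group sizes differ by at most one.
* **Positive $\Delta PI$** (reflectance increases) are retained as-is — they
  are measurement uncertainty around small true changes, not errors to be
  truncated.
* **Degenerate inputs** fail loudly with classed conditions: duplicate
  observation times, zero-variance correlation inputs, zero replicate
  means, missing baselines, out-of-bounds ROIs, windows outside a series'
  support. Groups too small for a correlation are reported with `NA`
  coefficients rather than dropped silently.
* **Variability decomposition** excludes the baseline time-point, where
  $\Delta PI \equiv 0$ makes the CV degenerate (0/0); the mean CVs weight
  dates and locations equally, not by n.
* **Replacement series** carry campaign-clock times and start at their
  deployment time with $\Delta PI = 0$; original samplers must start at
  time 0. Both share the invariant that the baseline point is exactly zero.
* **Command surface.** The workflow is exposed as R functions
  (`generate_campaign()`, `measure_campaign()`, `campaign_report()` and the
  module-level functions they compose) plus a thin Rscript wrapper with
  `simulate` / `measure` / `report` subcommands and distinct exit codes.
  Per-sampler series assembly and the statistics have no standalone
  consumers, so they are folded into `report` rather than being separate
  commands.

## Problem sizes

The validation suite runs entirely on simulated data generated at test
time: module tests use compact campaigns (3–5 locations, 96 × 96 px frames,
5 frames per session), while the end-to-end recovery check runs the full
default field design — 320 stacks of twenty 256 × 256 frames — plus two
constructed campaigns for the saturation and detection-limit logic. The
acceptance script re-runs the full field design and the laboratory design
from a user-supplied seed.

## Known limitations

* $\Delta PI$ is a reflectance change, not a mass concentration; comparing
  campaigns requires identical imaging geometry and filter stock.
* Multiplicative lighting drift biases $\Delta PI$ by the closed form above;
  the package quantifies but does not correct it.
* The lower-LOD rule is defined on samplers observed at each candidate
  time; with ragged sampling grids the returned time depends on who was
  imaged when.
* The saturation rule is a heuristic with configurable constants; it
  reports its inputs so a verdict can always be audited.
* Grayscale only: color-channel extensions (distinguishing brown from black
  carbon) are outside the package's scope.
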