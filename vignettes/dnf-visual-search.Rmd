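---
title: "A neural dynamic architecture for visual search and scene working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neural dynamic architecture for visual search and scene working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dnfsearch)
```

## The model

`dnfsearch` simulates visual exploration, scene working memory, search-cue
retention and conjunctive visual search as one autonomous neural dynamic
system. Its building block is the dynamic neural field: an activation
function $u(\mathbf{x}, t)$ over a continuous feature or space dimension
that relaxes under

$$\tau \dot u(\mathbf{x},t) = -u(\mathbf{x},t) + h + s(\mathbf{x},t)
  + \xi(\mathbf{x},t)
  + \int \omega(\mathbf{x}-\mathbf{x}')\,\sigma(u(\mathbf{x}',t))\,
    d\mathbf{x}',$$

with a negative resting level $h$, external input $s$, additive noise
$\xi$, the logistic threshold $\sigma(u) = 1/(1+e^{-\beta u})$, and a
lateral interaction kernel $\omega$ combining local excitation, surround
inhibition and global inhibition. Localized supra-threshold peaks are the
units of representation: they arise in the detection instability when
input pushes activation over threshold, disappear in the reverse
detection instability, and — because local excitation only becomes
effective above threshold — maintaining a peak takes less input than
creating one (hysteresis). Zero-dimensional fields are nodes,
$\tau\dot u = -u + h + s + c\,\sigma(u)$, which latch on and off the same
way.

Depending on its kernel, a field operates in a *detection* regime
(multiple input-driven peaks), a *selection* regime (strong global
inhibition, at most one peak — winner-take-all), or a *sustained* regime
(peaks persist after input removal — working memory).

Fields of different dimensionality are coupled by directional
projections: dimensions present only in the source are marginalized by
integration, dimensions present only in the target receive constant
ridge/slice input, and an attended location enters three-dimensional
space/feature fields as a column — a spatial tube constant along the
feature axis. Homogeneous boosts and deboosts gate which part of the
architecture can form peaks at a given time; inhibitory
condition-of-satisfaction (CoS) and condition-of-dissatisfaction (CoD)
nodes terminate or retry processing steps, which is what turns the
continuous dynamics into discrete, sequential behavior.

## The architecture

A feed-forward frontend converts a raster stimulus frame into three
space/feature maps — hue (circular, degrees), orientation (circular over
180°, from four elongate centre-surround filters), and size (a
centre-surround pyramid with one-way inhibition along scale) — plus their
summed spatial conspicuity, the salience input. On top of it sit:

* the **salience field** (detection regime) and the **spatial selection
  field** (selection regime) implementing attentional selection,
  biased by an **inhibition-of-return trace** of recently attended
  locations, by a sustained, capacity-limited **spatial working memory
  field**, and by **onset/offset transient detectors** (two-layer fields
  whose fast layer fires only while the slow layer has not caught up with
  an input shift);
* per feature dimension, a **scene space/feature selection field**, a
  sustained **memory space/feature map** whose accumulating global
  inhibition sets the working-memory capacity, and a **memory selection
  field** that reads out the stored item at the attended location;
* per feature dimension, sustained **search-cue fields** loaded through
  boosted **retain gates**;
* **overlap fields** combining sub-threshold scene (or memory) input with
  cue ridges, projected into 2-D **guidance fields** that bias the
  selection field during search;
* a **match network**: per dimension an attended, an expected and a
  mismatch-detection field with peak-detector nodes, plus CoS and CoD
  nodes.

Three task modes organize behavior. *Explore* (the default with a visible
scene) selects a salient item, binds its features through the attended
column, commits them to the memory maps, verifies the commitment through
the match network, and releases attention. *Retain* is triggered by the
onset detector when a cue appears: the cue's features are extracted and
latched into the search-cue fields. *Search* repeats guided selection and
match evaluation; a CoD rejects the attended item (destabilizing the
selection and leaving an inhibition-of-return mark), a CoS ends the trial.
The model reaction time is the model time from the condition's clock-start
event to the final CoS.

### Guidance normalization (the n−1 rule)

The scene guidance field's resting level is lowered by a fixed amount per
stored cue feature. With the calibrated weights (`w_overlap = 4`,
`per_cue_drop = 1.4`, `h0 = -0.5`), an item whose position receives
overlap peaks on $m$ of $n$ cued dimensions crosses threshold exactly when
$m \ge \max(1, n-1)$: single-feature search guides complete matches only,
while conjunction search also admits items sharing all but one cued
feature. The memory guidance field uses a steeper drop (3.2 per cued
feature), so only complete matches held in scene memory produce guidance —
this is what makes a memorized target found almost immediately, while
memorized partial matches are net-inhibited through the spatial working
memory pathway and are effectively excluded from examination.

In single-feature search the task cues the color dimension only. All
items (and the cue) share the same vertical orientation, so orientation
carries no search information; cueing it would make every item a
guided n−1 match and erase the qualitative difference between feature
and conjunction search that the normalization mechanism exists to
produce.

### Capacity

The sustained fields use self-excitation at the sampling width — stored
activation latches cell-locally, so peaks neither drift nor spread — and
a shared inhibitory pool that grows with each distinct stored location
(the supra-threshold spatial footprint, pooled across the three feature
maps, contributes one unit per connected component). Because commitment
inputs are calibrated so that only the coincidence of a feature slice and
the attended column crosses threshold, each stored item raises the
threshold for the next; at the calibrated shared gain
(`capacity_gain = 13`) the fifth item can no longer consolidate. The
spatial working memory field uses the same per-location pool and the same
shared gain. `calibrate_capacity()` re-derives the gain by bisection on a
six-item commit sequence.

The offset detector applies a global deboost to the spatial working
memory field whenever salient input vanishes or moves, resetting it; the
memory space/feature maps are not connected to this reset and survive
blanks. This asymmetry is what separates the two preview experiments: with
a continuously visible array the preview's spatial inhibition contributes
to search efficiency, whereas interposed blanks erase it while feature
guidance survives.

## Synthetic stimuli

`generate_array()` reproduces the printed stimulus design: a 5×4 grid of
80×80-pixel tiles centred in a 500×400 display, a reserved black-bordered
cue tile in the middle of the second row, bars of 60×12 pixels in red,
green or blue at 0°, 45°, 90° or 135°. Conjunction arrays contain one
target $(c_t, o_t)$, $(s-2)/2$ distractors of each shared-feature class
$(c_t, o_d)$ and $(c_d, o_t)$, and exactly one distinct distractor
$(c_d, o_d)$ — which keeps the distractor count odd and prevents guessing
the target during a preview. Feature search uses vertical bars in two
colors. Timelines follow the printed schedules (200/800 ms in the
simultaneous-cue experiment; 100/800/100/400/100 ms with the cue shown
alone for 400 ms in the intermittent one), with the reaction-time clock
starting at cue onset or array onset respectively.

What the generator does *not* emulate: anti-aliased rendering aside, there
is no display noise, no luminance calibration, no eccentricity effects,
and no eye movements (all representations share one retinal frame). Tests
passing on these stimuli show that the architecture's mechanisms produce
the right behavioral signatures under the experiments' idealized
conditions; they do not show robustness to natural scenes.

## Numerical choices

* **Integration**: explicit Euler, `dt = 5` ms, field time constants
  40–100 ms (never below `5 dt`). Halving `dt` moves steady-state peaks by
  less than one grid cell.
* **Grids**: space is sampled so that tile centres fall exactly on grid
  points (27×21 at 20 px for the desk-scale configuration, 53×41 at 10 px
  for the standard one); hue in 30° (15°) bins, orientation in 22.5° bins,
  size on five levels. Gaussian kernels are evaluated as row-normalized
  smoothing matrices per axis, wrapped on circular axes.
* **Global inhibition** is mediated by a pool state with its own time
  constant (25 ms), which damps the excitation–inhibition loop; for the
  capacity-limited fields the pool tracks the number of stored locations
  rather than raw output mass, making the capacity independent of how many
  cells a stored peak happens to span.
* **Selection noise**: besides per-step additive noise, the selection
  field carries a per-trial frozen ("quenched") multiplicative noise
  realization on its excitatory drive. Equal inputs are thereby resolved
  by noise — never by cell order — within a realistically short
  competition, and an empty field stays quiet. The excitatory drive
  saturates (clamp 10) so simultaneous-onset bursts cannot ignite the
  whole field. The selection sigmoid is shallower (β = 1.5) than the
  default (β = 4), which makes losing peaks die gradually rather than
  collapsing the whole competition.
* **Readout**: the attended location handed to the space/feature columns
  is the argmax of selection output weighted by salience — the overlap
  that actually drives the downstream projections — which is robust to the
  selection peak's skirt reaching a neighbouring item.
* **Deadlock resolution**: when two or more items remain established for
  more than ~120 ms, a graded deboost lowers all peaks toward the reverse
  detection instability; the weakest die first and the strongest resumes.
* **Event-scoped scheduling**: stimuli are piecewise constant, so the
  feed-forward maps are computed once per timeline segment; the 2-D
  attention subsystem and all nodes are stepped continuously, while the
  3-D operations (feature extraction, memory commitment, overlap/guidance)
  run as event-scoped relaxation episodes. Memory consolidation and match
  verification complete within their own episodes, concurrently with the
  next attentional selection, as they would in the fully parallel system;
  the attentional dwell itself advances the trial clock by the binding
  window (~30–50 ms) plus selection and release times.

## Design choices where the architecture was open

* **Cue localization**: when cue and array appear simultaneously, the
  black-bordered cue tile's position is supplied as an instructed
  localized boost during retention, and the tile is excluded from search
  (its item trivially matches the cue). With an asynchronous cue the onset
  detector finds it on its own.
* **Inhibition-of-return**: build constant 80 ms, decay 20 s. The build
  constant matches the ~250 ms attentional dwell per explored item (three
  items must be committed within the 800-ms preview); the decay covers an
  18-item search at this implementation's cycle times. Within a search,
  rejected items additionally receive a refractory mark so the same
  distractor is not immediately re-examined. The trace builds only while
  the selection field carries a single settled peak, and only around the
  peak's centre.
* **Displacement rule at capacity**: the incoming (fifth) item fails to
  consolidate; stored items are not displaced.
* **Offset reset scope**: global (all spatial working memory peaks), as
  required to explain the intermittent-presentation experiment; the
  inhibition-of-return trace does not reset at offset (config switch
  `ior$reset_at_offset`).
* **Size in matching**: the cue specifies all three dimensions in
  conjunction search; since all bars share their size, the size dimension
  always matches and the outcome is carried by color and orientation.
* **Match tolerances**: half the inter-stimulus feature distance (hue 60°,
  orientation 22.5°), realized by the width of the broadened expected-peak
  inhibition in the mismatch fields; the discrete stimulus sets are then
  always unambiguous. A cued feature that is absent at the attended
  location (an empty or featureless site) counts as a mismatch.

## Problem sizes

The desk-scale configuration used throughout the tests and the
reproduction script runs trials at the 27×21 spatial grid: 16 trials per
set-size cell for the simulated slope comparison (3–6 per cell inside the
test suite), 10³ selection episodes for the uniqueness property, and 10⁵
replicates for the Monte-Carlo serial-search oracle. Simulated RT slopes
carry substantial Monte-Carlo error at these counts — the dominant term is
the serial-position variance of the examined-item count, which is inherent
to serial search — so slope-ratio quantities are reported together with a
propagated standard error, and condition contrasts are run fully paired
(same arrays, same noise streams). The per-trial event logs
(`event_log()`) record every selection, match outcome and task transition
with model timestamps.

## Known limitations

* Gains are calibrated for the two shipped grid resolutions; other
  resolutions need recalibration (the qualitative behaviors are the
  calibration targets, as no published parameter values exist for any
  field).
* The selection field transiently holds more than one supra-threshold
  component during the competition phase (~100–200 ms); uniqueness holds
  for settled states, which is when the architecture reads the field out.
* Reaction times are in model milliseconds; only an affine scaling
  relates them to human data (`fit_rt_scaling()`), and intercept-level
  effects (movement planning, response execution) are outside the model.
* The model does not search in memory without a visible array: search
  mode requires a visible scene, so an intermittent preview yields
  guidance but no early in-memory search.
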