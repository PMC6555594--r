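---
title: "Membrane kinetics, gradient buffering and node encounters: methods"
author: "cortexkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane kinetics, gradient buffering and node encounters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexkin)
```

# The scientific problem

Rod-shaped fission yeast cells position and time their division using
cortical concentration gradients of a polarity kinase (Pom1) nucleated
at the cell poles. Three quantitative questions recur when such
gradients are studied with single-molecule and TIRF imaging:

1. **How long does a molecule stay on the membrane?** Tracked
   fluorophores disappear both because they dissociate and because they
   photobleach; the two must be separated.
2. **How far does it travel while bound?** Per-track diffusion
   coefficients from mean squared displacement (MSD) curves, combined
   with residence times, bound the distance a single molecule can carry
   positional information.
3. **Is the gradient buffered, and does its mid-cell tail reach the
   division machinery?** Decay-length statistics across many cells, and
   threshold-crossing statistics of node-associated intensity traces,
   answer these.

`cortexkin` implements the full analysis chain for all three, plus a
synthetic-data generator that reproduces the statistical structure of
each data type with known ground truth, so every estimator in the chain
is testable without raw images.

# Dissociation kinetics under time-lapse illumination

## Model

A membrane-bound fluorophore disappears from a track through two
independent Poisson processes:

* **dissociation** at rate $k_{off}$, active in continuous time;
* **photobleaching** at rate $k_{bleach}$, active only while the camera
  integrates (the laser is on only during the integration time
  $\tau_{int}$).

Under a time-lapse scheme with period $\tau_{TL} = \tau_{int} + delay$,
the probability that a molecule visible in one frame is visible in the
next is $e^{-k_{off}\tau_{TL}} e^{-k_{bleach}\tau_{int}}$, so observed
track durations $t_{eff} = (n-1)\tau_{TL}$ decay with an *effective*
rate $k_{eff}$ obeying

$$ k_{eff}\,\tau_{TL} = k_{bleach}\,\tau_{int} + k_{off}\,\tau_{TL}. $$

Fitting $k_{eff}$ at several $\tau_{TL}$ (here 20, 120, 220 ms, all
with $\tau_{int} = 20$ ms) and regressing $y = k_{eff}\tau_{TL}$ on
$\tau_{TL}$ yields $k_{off}$ as the slope and $k_{bleach}\tau_{int}$ as
the intercept. Weights are inverse variances $1/\sigma_y^2$ propagated
from the per-fit standard deviations — we read "weight proportional to
the S.D." as standard inverse-variance weighting, since weighting *up*
noisy points would be statistically backwards.

## Fitting on the discrete frame grid

Residence times are only observed as frame counts, so the natural
likelihood is geometric, not continuous-exponential: a track of $n$
localizations survived $n-1$ frame transitions each with probability
$s = e^{-k_{eff}\tau_{TL}}$. `fit_monoexponential()` maximises this
geometric likelihood (closed form, binning-free, converging to the
continuous MLE as $\tau_{TL}\to 0$); `fit_biexponential()` fits a
two-component geometric mixture by EM from 20 deterministic random
restarts with a quasi-Newton polish, ordering components so the
reported fast rate is the larger one. Tracks with a single localization
($t_{eff}=0$) carry no rate information and enter only as a censored
count.

Two numerical guards matter in practice:

* **Unidentifiability.** At the shortest lag the two effective rates
  differ by only ~20%, and a mixture fit explains the data no better
  than a single exponential. If the likelihood-ratio gain over the
  nested mono fit is below the $\chi^2_2$ 99% bound (or the fitted
  components lie within 5% of each other), the fit *collapses*: both
  components report the mono-exponential rate with infinite standard
  deviations, so the condition still anchors nothing in the rate
  separation it cannot actually inform.
* **Hessian failures.** Near-singular mixtures can defeat the numeric
  Hessian used for standard deviations; the fallback is the
  single-geometric Fisher information with the component's effective
  sample size $N f$, with the mixture-fraction SD left undefined.

## Reporting the mixture fraction

The fitted mixture weight is conditioned on *detection*: a molecule
that dissociates before its first frame, or that leaves a single-frame
track, is excluded, and fast molecules are excluded more often. The
observed fraction therefore understates the at-birth fast fraction by
several percentage points at the lags used here.
`run_dissociation_study()` inverts the conditioning analytically — a
component with dissociation rate $k$ and effective rate $k_{eff}$
survives to a usable track with probability
$\frac{1-e^{-k\tau_{TL}}}{k\tau_{TL}} e^{-k_{eff}\tau_{TL}}$ — and then
combines the per-condition corrected fractions by inverse variance, so
the near-degenerate short-lag condition contributes essentially nothing.

## Simulation scale

The acceptance-style studies default to 60,000 events per condition and
medians over 30 replicates. Both exceed the stated floors (5,000 events,
20 replicates) deliberately: maximum-likelihood fitting of *weakly
separated* mixtures (effective-rate ratios of 1.2–2 here) carries
finite-sample bias that only becomes negligible at this scale, and the
whole study still runs in well under a minute per strain.

# Tracking

Localizations are first filtered to the membrane slab (axial positions
within ±200 nm, inclusive), then linked frame-to-frame within a 320 nm
radius with **no gaps permitted**: a molecule that blinks off for one
frame becomes two tracks, exactly as in the reference analysis. The
methods text elsewhere says "less than 321 nm"; we use 0.32 µm with
strict `<=` and expose the radius. Assignment within each frame pair is
greedy in ascending distance with deterministic tie-breaks (lower track
id, then lower row index) — the published rule names only a radius, and
determinism is required for testing. Linking uses lateral (x, y)
distance only; the axial coordinate is consumed entirely by the filter.

Distances from the pole are arclengths along a pole-to-pole centerline,
folded to the nearer pole (both cell halves are plotted together in
this kind of analysis).

# Diffusion

Per-track time-averaged MSD over all ordered pairs at each lag; tracks
need more than five gap-free localizations. The diffusion coefficient
comes from an unweighted least-squares line through the first
`ceiling(0.25 * (n-1))` lags (minimum 2) via $MSD = 2dD\Delta t$ with
$d = 2$; the intercept is kept as a localization-error proxy
($\approx 4\sigma^2$). Negative slopes are retained and classified as
slow rather than silently dropped, which would bias class fractions.
Mobility classes follow the printed boundaries: fast $D \ge 0.1$,
intermediate $0.01 \le D < 0.1$, slow $D < 0.01$ µm²/s, with boundary
values assigned to the upper class. The travel-distance estimate
inverts $t = x^2/2D$.

# Gradient shape and buffering

Profiles (intensity vs arclength from the pole) are aligned to their
intensity maximum, truncated to a common grid (no interpolation — we
prefer discarding samples to inventing them), optionally smoothed with
a normalized Gaussian kernel (default $\sigma = 0.2$ µm; the source
analysis cites a filter without a width), and averaged. The decay
length is $-1/\text{slope}$ of a log-linear fit that skips the first
0.5 µm (the pole plateau). Amplitude buffering is quantified by sorting
profiles by pole amplitude (mean over the first 0.83 µm), averaging
within consecutive 5% bins, fitting a decay length per bin, and
correlating $\log\lambda$ with $\log A$ across bins, with a bootstrap
CI over profiles. The coefficient-of-variation profile summarises the
same phenomenon non-parametrically: for pure amplitude scaling the CV
is position-independent (fold decrease ≈ 1); buffering pushes mid-cell
CV below pole CV (fold > 1).

Order of operations is align → smooth → average, exposed in the
configuration; fits use raw (not normalized) intensities.

# TIRF node encounters

Node traces are bleach-corrected by a mono-exponential trend — fitted
to the across-node mean trace when several nodes are supplied, which is
the whole-field variant of the common correction tools — with the rate
clamped at zero and a simple-ratio mode available. An *encounter* is a
maximal run of samples strictly above the threshold (default 20 a.u.;
equality counts as below, reading "over" literally), with duration =
run length × frame interval and censoring flags at the window edges. A
trace above threshold at every sample is "continuously occupied" and
reports the window span (60 s for the standard 61-sample protocol);
this is the one place where the run-length formula and the stated
continuous-occupancy convention disagree, and we follow the latter.
Cell-length groups are the closed bins [6, 8], [9, 11], [12, 14] µm
with deliberate gaps, exactly as conventionally printed. Cluster
lifetimes are minimal lifetimes — censored records are flagged, never
extrapolated.

# The synthetic-data generator

What it emulates, per data type:

* **Binding events**: mixture of exponential lifetimes over
  populations; photobleaching as a hazard on *cumulative integration
  exposure* (per-frame survival $e^{-k_{bleach}\tau_{int}}$ — the only
  bleaching model under which the linear separation above is exact);
  molecules binding during the dark interval first appear at the next
  frame; detection requires being bound and unbleached at the start of
  a frame's integration window.
* **Localizations**: 2D Brownian steps with per-axis variance
  $2D\tau_{TL}$, reflective boundaries (the membrane is a closed
  surface, so the field-exit channel never fires), and Gaussian
  localization error (default SD 25 nm — typical PALM precision, not a
  measured value) added per observation.
* **Gradients**: $A_i e^{-x/\lambda_i} +$ background + noise with
  log-normal amplitudes (geometric SD 1.6 by default, consistent with
  the up-to-fourfold pole variability reported for such gradients) and
  $\lambda_i = \lambda_0 (A_i/A_{med})^{-\beta}$. $\beta$ is the
  generator's buffering knob: 0 gives an amplitude-independent decay
  length, 0.5 a strong negative amplitude–decay correlation.
* **Node traces**: two-state telegraph occupancy at exact
  continuous-time transition probabilities, intensity scaled by a
  bleaching trend plus Gaussian noise, with an optional cell-length
  modulation of the on-rate.

What it does **not** emulate — and what a green test therefore does not
establish: no pixel-level images or PSFs, no astigmatic z encoding (the
axial coordinate is exercised only through constructed fixtures), no
motion blur within the integration window, no spatially varying
background, no cluster substructure within tracks. Conclusions about
image-processing steps upstream of localization tables are out of
scope by design.

Determinism: every generator takes a seed, and pipeline stages derive
per-operation streams from one master seed, so identical configurations
reproduce byte-identical outputs and stages can be re-run independently.

# Worked example

```{r dissociation-small}
cfg <- default_config()$dissociation
cfg$n_events <- 20000      # keep the vignette reasonably fast; below
cfg$n_replicates <- 5      # this scale the mixture fits get unstable
st <- suppressWarnings(run_dissociation_study(cfg, seed = 1))
st
```

```{r diffusion}
run_diffusion_study(default_config()$diffusion, seed = 1)
```

```{r gradient}
cfgg <- default_config()$gradient
cfgg$n_cells <- 120
run_gradient_study(cfgg, seed = 1)
```

# Known limitations

* The bi-exponential fit assumes exactly two populations; the <1%
  ultra-slow tail seen in deep datasets is out of fitting scope (an
  optional percentile trim exists, default off).
* Per-condition mixture fits followed by two linear separations mirror
  the published workflow, but a joint likelihood across conditions
  would be more efficient; it is deliberately not implemented to keep
  the estimator comparable to the reference analysis.
* `link` mode of the dissociation study is faithful but needs very low
  molecular densities to avoid mis-linking bias; the default `truth`
  mode reads residence times from the generator's frame counts, and the
  equivalence of the two on sparse data is part of the test suite.
* Whether the published diffusion distributions pool per-track
  estimates or per-displacement statistics is not stated; per-track
  pooling is implemented.
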