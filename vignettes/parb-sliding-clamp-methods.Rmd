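---
title: "Models and methods behind parbslide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind parbslide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parbslide)
```

# The biological model

ParB is the centromere-binding component of the bacterial ParABS
chromosome-segregation system. The package implements a three-step
mechanistic picture of its interaction with DNA:

1. **Loading.** A ParB dimer in the open-clamp state binds a 16 bp
   palindromic *parS* site. This step does not require CTP. Each site
   holds at most one open clamp, and *parS*-bound ParB is immobile.
2. **Conversion and sliding.** CTP binding (with Mg^2+^ as cofactor)
   closes the clamp around the DNA and releases it from *parS*. The closed
   clamp then diffuses one-dimensionally along the DNA contour, freeing
   the site for another loading event. The non-hydrolysable analogue
   CTPγS behaves identically — hydrolysis is not part of the sliding
   mechanism. Tightly bound protein roadblocks (catalytically dead EcoRI)
   and, in trapped molecules, the bead-occluded DNA ends reflect sliding
   clamps.
3. **Condensation.** Clamps that populate non-specific DNA can
   self-associate and bridge distal segments, condensing the molecule at
   sub-piconewton forces. No quantitative rate law for this step is
   available, so the package treats condensation phenomenologically (see
   below) rather than mechanistically.

Mutant presets encode the genetics: `R149G` cannot bind *parS* (loading
rate forced to zero) and `R80A` cannot bind CTP (conversion rate forced to
zero); the apo, CDP and EDTA conditions likewise disable conversion.

# Substrate maps

`build_substrate()` returns 0-based half-open coordinate maps of the DNA
constructs. The printed geometry is enforced exactly: the 39× *parS*
construct carries two clusters separated by 1905 bp (the smaller with two
groups of sites, the larger with four), and the EcoRI-flanked version
places the downstream 5× EcoRI group 3613 bp beyond the last *parS*, with
roughly 5 kbp and 1 kbp of DNA protected beyond the two roadblock groups.
Spacings that are *not* published — the distance between palindrome starts
inside a group (default 50 bp), the gap between groups within a cluster
(default 300 bp), and the merged footprint of a 5× EcoRI group (default
60 bp) — are configurable constants and should be read as plausible
placeholders, not measurements. The group sizes of the 39× arrangement
(6+7 and 6+7+6+7) follow from the construct's cloning route, in which the
39× insert arose from 13× and 26× fragments. The λ-DNA control uses the
standard 48 502 bp genome length. All coordinate/optical conversions use a
rise of 0.34 nm per base pair.

# The stochastic simulator

`simulate_parb()` uses fixed-timestep Brownian dynamics. Each state
transition is a per-step exponential clock (`P = 1 − exp(−rate·dt)`);
where two transitions compete (conversion versus unbinding from *parS*)
the event time is drawn from the total rate and the type from the rate
ratio. Sliding clamps take Gaussian steps of variance `2·D·dt` and are
reflected inside the open segment delimited by active roadblocks and/or
the DNA ends (an `absorb` mode lets clamps slide off free ends instead).
The step size is required to satisfy `sqrt(2·D·dt)` ≤ 5% of the contour
length, and the suite checks that halving `dt` changes ensemble occupancy
profiles by well under 2% RMS. Photobleaching runs as an independent clock
once illumination starts; bleached particles turn dark but keep moving and
occupying DNA, which matters for occupancy-based ground truth but not for
rendered images.

Absolute loading, unbinding and bleaching rates are **free parameters**:
none are published. The defaults (0.2 loading events/s per vacant site,
0.5 /s conversion, 0.05 /s clamp unbinding, 0.01 /s *parS* unbinding,
0.15 /s bleaching) were chosen once so that *parS* occupancy is stable
over tens of seconds, non-specific clamps are sparse, and fluorescence
decays over tens of seconds under illumination — the qualitative regime of
the experiments. The diffusion constant default is 0.4 µm²/s, the measured
scale for ParB sliding clamps.

`simulate_clamps()` is the diffusion-measurement generator: pure sliding
clamps with no binding kinetics, produced exactly as reflected Brownian
motion by folding a free Brownian path into the interval (the path-wise
image construction), which makes large ensembles cheap.

# Image synthesis

`render_kymograph()` and `render_scan()` draw Poisson counts around an
expected value built from a Gaussian point-spread function of 250 nm FWHM
sampled on 100 nm pixels with a 0.1 ms dwell, the acquisition geometry of
a dual-trap confocal. Per line, an emitter contributes
`photon_rate × dwell` photons distributed over pixels by the PSF mass, so
total expected counts equal emitter-line-observations × rate × dwell plus
background — a conservation law the tests verify. The PSF is truncated at
±4σ (<0.01% mass lost). Emitter positions are frozen at line start: the
line period (25 ms default) exceeds the pixel dwell by more than two
orders of magnitude, so intra-line motion blur is negligible. Beads are
not rendered; the field spans the DNA contour only. The default photon
rate gives peak pixel counts of order ten per line (the counting regime of
dye-labelled scans); `qd_optics()` raises it five-fold for quantum-dot
emitters, which are much brighter and do not bleach — the label the
tracking experiments use for exactly that reason.

# Tracking and diffusion estimation

Peaks are local maxima above a threshold, refined by three-point parabolic
interpolation and merged within a minimum separation keeping the brighter
peak. Linking is greedy nearest-neighbour between consecutive lines with a
maximum jump and no gap closing; short tracks are discarded. With
quantum-dot optics the empirical localization error is ~20 nm — consistent
with the pixel/√counts scale, and never reported better than that.

The MSD is the single-trajectory, time-averaged, overlapping-pair
estimator, computed after clipping tracks to 2.5 s so that every
trajectory contributes comparable statistics; lags run to 25% of the track
length. The diffusion constant is half the slope of an ordinary
least-squares fit of MSD against lag time, `MSD = 2·D·Δt + offset`, over
lag indices 2–10 by default: the first lag is excluded because
localization noise biases it most, and the window is configurable since no
canonical choice exists. The intercept is the localization-noise offset;
it is positive for rendered data, indistinguishable from zero for
noiseless ground-truth trajectories, and small negative per-track values
are legitimate noise. Negative per-track D estimates are likewise retained
in ensemble means — discarding them would bias the ensemble upward.
Ensembles are summarized as mean ± SEM. A track is classed
immobile/parS-bound when its fitted D falls below 0.05 µm²/s *and* its
mean position lies within a *parS* window widened by 250 nm (the optical
resolution); both constants are configurable.

`recover_diffusion()` wires the whole chain — simulate, render, track,
MSD, fit — against known ground truth. With 200+ tracks of 100 lines the
ensemble mean lands within a few percent of the generating D across
0.1–1.0 µm²/s, with no detectable systematic bias.

# Tethered particle motion

The bead generator is a per-axis stationary Ornstein–Uhlenbeck process
(default correlation time 0.5 s) sampled at 120 Hz for 300 s. In `"auto"`
mode the per-axis amplitude uses the Gaussian-chain estimate
`sigma = sqrt(2·Lp·Lc/3)` (≈139.5 nm for the 1717 bp tether at Lp =
50 nm); the bead-excursion magnitude is phenomenological — no bead-tether
hydrodynamics are modelled, only the "roughly as expected for the tether
length" scale. Drift is applied at 45° so one number sets the stage speed.

Two excursion statistics are provided. The full-trace RMS,
`sqrt(mean((x−x̄)² + (y−ȳ)²))`, uses whole-trace means and is read as a
time average (the windowed statistic's explicit average implies the same
convention). The windowed RMS replaces the means with window-local ones in
a sliding boxcar of span τ (stride one sample, computed in O(n) from
cumulative sums), which filters drift slower than the window. Windows
shorter than the system correlation time bias the variance low, so τ is
floored at 8 s — the calibration finding for this bead-tether geometry —
and the default is 8.3 s; shorter windows require an explicit override and
warn. Note the estimator cost of windowing: for a correlated process the
window-local variance is biased low by roughly `2·t_c/τ`, which the
drift-comparison tests sidestep by always comparing windowed against
windowed.

One quantitative design point: for the 1717 bp tether the drift speed
needed to inflate the *full-trace* RMS by more than 25% follows from
`sqrt(1 + v²T²/12 / (2σ²))`; at σ = 139.5 nm and T = 300 s that requires
v ≳ 2.4 nm/s, so the drift-suppression demonstrations use 3 nm/s (expected
inflation ~1.6×), while the windowed statistic moves by under 0.2% at any
speed in that range. Condensation is declared when the windowed series
drops 30% below its early-trace baseline and stays there for 20 s; both
constants are analysis choices, not measured values.

# Worm-like-chain mechanics

The force-extension law is the classic Marko–Siggia interpolation with
purely entropic elasticity; below 5 pN the enthalpic stretching correction
is far smaller than measurement noise, so no stretch modulus is included.
The inverse (extension at force) is a vectorized monotone bisection to
1e-9 relative tolerance. Fitting minimizes extension residuals over
(Lp, Lc) with Levenberg–Marquardt from a fixed 3×3 multi-start grid, making
the result deterministic; noiseless curves round-trip to well under 1% and
2% multiplicative noise keeps median recovery within 5%. Temperature
defaults to 298 K (kBT = 4.114 pN·nm); it is a parameter because the
experimental temperature is not stated. The contour-length quality filter
discards molecules whose fitted Lc deviates more than 15% from the
expected crystallographic length; "±15%" is read as an inclusive
tolerance. Force calibration from bead excursions uses the
inverted-pendulum equipartition relation `F = kBT·L/⟨x²⟩`.

Condensation time courses and force-extension families are generated
phenomenologically — exponential extension decay to a plateau, or a
condensed branch scaling extension below a chosen force — because the
clamp-density-to-bridging link has no published equations. The analysis
constants (25% extension deficit sustained 30 s) are artifact thresholds.
The `run_pipeline()` magnetic-tweezers archetype uses the same
phenomenology, gating condensation on a licensed preset (loading *and*
conversion possible) and at least 5 *parS* sites, the empirical minimum
under the restraining force of a tweezers assay; the TPM archetype, where
no force is applied, requires only a single site.

# What the synthetic data does and does not show

The generators emulate: *parS*-restricted loading, CTP gating, reflected
1D diffusion with roadblocks, photobleaching, 250 nm optics with Poisson
shot noise, WLC tether mechanics, and drifting TPM beads. They do **not**
emulate ParB–ParB network formation, condensate mechanics, inter-protein
exclusion on DNA (a hard-core mode exists in concept but clamps are point
particles by default, consistent with the sparse occupancy regime),
nucleotide exchange kinetics, bead images, or instrument drift beyond
linear stage drift. Passing tests therefore demonstrate that the analysis
stages recover the parameters of *this* generative model — e.g. that the
kymograph pipeline re-measures the diffusion constant it was fed to within
a few percent — not that the model captures every feature of instrument
data. Conversely, the analysis functions are model-agnostic: they consume
plain TSV/ASCII/TIFF inputs and can be pointed at real exported traces
unchanged.

# Numerical choices and problem sizes

Tolerances and sizes used by the test-suite and the acceptance script are
chosen to make each check statistically decisive at modest cost: diffusion
recovery uses ensembles of 210–300 trajectories of 100 lines each;
occupancy invariance checks use 1000-clamp ensembles; the WLC filter study
uses 100 molecules; TPM statistics use full 300 s × 120 Hz traces. Seeds
are explicit everywhere; identical configurations are bit-reproducible,
and all derived seeds stay within 32-bit integer range.

# Known limitations

* No gap closing, track splitting/merging or super-resolution
  localization; dense fields of crossing emitters will fragment tracks.
* The roadblock is a single merged footprint per EcoRI group; per-site
  detail within a group is not modelled.
* Condensation is detected, never mechanistically predicted; in
  particular the dependence of maximum condensation force on *parS* count
  is an input to the generators, not an output of the model.
* The photon-rate parameters are detector-scale conveniences; no
  excitation-power calibration is attempted.
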