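---
title: "Gas-dynamic characterization of the jet-flow overpressure chamber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas-dynamic characterization of the jet-flow overpressure chamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opcflow)
```

## The problem

The jet-flow overpressure chamber (OPC) is a widely used laboratory
apparatus for blast-mediated traumatic brain injury studies in rodents: a
0.6 m diameter, 1.8 m long steel vessel whose pressurized Driver Section
vents through a 14 cm aperture (sealed by a frangible Mylar diaphragm)
into a closed Test Section, where the specimen sits about 12.7 cm from
the aperture. Although the device is often described as a blast simulator,
careful characterization shows that what reaches the specimen is not a
free-field blast wave (a shock front with ~1 ns rise time followed by a
Friedlander-type static overpressure decay) but a collimated, cold,
high-speed jet whose damaging energy is almost entirely dynamic pressure
("blast wind"), preceded by a weak spherical precursor wavelet and
followed by a slow quasi-static pressurization of the whole vessel.

`opcflow` reproduces this characterization at desk scale. It provides:

* closed-form gas relations (sound speed, Rankine–Hugoniot shock jumps,
  the static/dynamic blast-pressure partition, Friedlander waveforms,
  isentropic cooling, TNT equivalence of a pressurized volume);
* a quasi-one-dimensional compressible finite-volume simulation of the
  venting event;
* a spherically symmetric solver for the precursor wavelet;
* Pitot-static reduction of stagnation/static pressure pairs into Mach
  number, velocity and dynamic pressure;
* free-flight drag loading of a specimen-scale sphere;
* digital diagnostics of pressure records (peak, rise time, impulse,
  quasi-static level, reverberation period, ripple frequency, shock
  classification);
* a seeded synthetic sensor-record generator that emulates the
  apparatus's instrumentation suite so every analysis stage can be tested
  without any measured data.

## The blast partition

For a normal shock moving into still air at ambient pressure
$p_\infty$ (ideal gas, $\gamma = 1.4$), the peak dynamic pressure behind
a front of peak static overpressure $\Delta p_s$ is

$$q \;=\; \frac{\tfrac{5}{2}\,\Delta p_s^2}{7\,p_\infty + \Delta p_s}.$$

This is the key quantitative statement of how blast energy partitions:
at $\Delta p_s = 10$ kPa the blast wind is negligible ($q <$ 0.5 kPa), at
103 kPa it contributes about 33 kPa, and by 480 kPa the two components
are about equal. The package derives $q$ from the full jump conditions
(`shock_mach_from_overpressure()`, `post_shock_state()`) and verifies
that $\tfrac12 \rho_2 u_2^2$ agrees with the closed form to $10^{-6}$
relative. The jet-flow OPC sits at the opposite corner of this map: near
ambient static pressure with extreme dynamic pressure, which is why it
loads a specimen as drag, not as crushing.

## The venting simulation

### Governing equations and numerics

The chamber is modeled by the quasi-1D Euler equations with an axially
varying cross-section $A(x)$, an advected passive scalar marking driver
gas, and reflective end walls. The solver (compiled C++ behind
`solve_quasi1d()` / `solve_euler1d()`) uses minmod-limited linear
reconstruction of primitives, an HLLC approximate Riemann flux, SSP-RK2
time stepping at CFL 0.5, and the $p\,\mathrm{d}A$ momentum source
discretized so that a uniform state at rest is an exact equilibrium.
Mass and energy in the closed domain are conserved to machine precision
once the diaphragm is fully open (the suite asserts $10^{-6}$).

The diaphragm is a time-ramped area restriction at the partition face:
the open fraction grows linearly over the 0.3 ms petaling time, and the
closed fraction contributes a wall-pressure flux on each side, so mass
and energy pass only through the open fraction. The default grid is 720
cells (2.5 mm); halving the cell size changes the quasi-static asymptote
by under 1% and the reverberation period by under 3%.

### The stream-tube geometry

A genuinely open question in reducing this apparatus to one dimension is
what $A(x)$ should be. A literal bore-with-orifice profile dilutes the
vented jet over the full 0.28 m$^2$ cross-section within one cell of the
partition, which is wrong by an order of magnitude at the specimen: the
real jet stays collimated at roughly the aperture diameter for several
diameters downstream (the potential core), and the specimen sits less
than one diameter from the aperture. The package therefore uses a
stream-tube profile: full bore in the driver, a cosine contraction to
the aperture area over 0.07 m (the sink-flow region, about one aperture
radius), a constant-area jet core extending 0.20 m past the partition
(covering the specimen station with margin while staying well inside
typical potential-core lengths of 4–6 diameters), and a cosine expansion
back to the bore over 0.10 m. Driver and Test volumes are integrals of
this same profile, so the lumped two-volume equilibrium and the PDE
asymptote refer to identical volumes; with the 0.20 m driver length the
equilibrium sits at 15.0 kPa gauge for a 138 kPa burst. The driver
length is not published for this apparatus; 0.20 m is the calibrated
choice that reproduces the observed quasi-static level and is exposed in
the configuration.

### Dissipation: what one-dimensional inviscid flow is missing

An inviscid quasi-1D model of a closed vessel never destroys the jet's
kinetic energy: it sloshes indefinitely, depressing the measured static
pressure (Bernoulli) and never settling to the thermodynamic
equilibrium. In the real chamber the dumped jet dissipates turbulently
within a few bore diameters. The package models this the way quasi-1D
duct codes traditionally handle sudden enlargements: a Borda–Carnot
quadratic momentum sink $-\tfrac12 f \rho u |u|$ that leaves total
energy untouched, so the removed kinetic energy reappears as heat.
Three coefficients, all exposed:

* `expansion_loss` — $(1 - A_a/A_c)^2 \approx 0.89$ spread across the
  downstream expansion (the classic sudden-enlargement coefficient);
* `dump_loss` — 4 m$^{-1}$ from the expansion to the end wall (complete
  mixing of the dumped jet within about one bore radius);
* `reverse_loss` — 5 m$^{-1}$ applied to reverse flow along the
  constriction. The collimated core exists only for the forward jet;
  backflow converges from the bore into the orifice and dumps into the
  driver, so reverse neck flow is lossy. This damps the driver/test
  volume-exchange (Helmholtz) oscillation just as separated orifice flow
  does in the real device.

Because the sink is quadratic in velocity it is strong for the ~300 m/s
jet and negligible for the few-m/s longitudinal reverberation wave, so
the acoustics that produce the ~8.5 ms staged convergence survive. The
quasi-static level is insensitive to these coefficients at the
sub-percent level; they chiefly set how fast residual sloshing dies.

### What the default run shows

```{r, eval = FALSE}
h <- solve_quasi1d(chamber_geometry(), burst_model(), t_end = 0.06)
h
jet_front_speed(h)          # ~151 m/s, aperture to specimen
jet_decay_duration(h)       # ~14 ms to settle into the 10% band
diagnose(h$probes$end_wall) # quasi-static ~15 kPa, period ~7.6 ms
```

The vented driver gas cools by expansion to about −69 °C (minimum over
the jet column within the first 10 ms), consistent with isentropic
cooling from 239 kPa absolute to the transient partial-vacuum levels the
static probe records. The specimen-station static trace stays below
20 kPa gauge throughout the jet-decay phase (taken as 2–18 ms, past the
startup transient) with repeated partial-vacuum excursions, while the
stagnation trace follows the driver decay — the signature of jet loading
rather than shock loading. Extremes (minimum temperature, peak speed)
are tracked over the jet column proper, from the aperture plane to the
end of the core segment: the expansion region carries the artificial
mixing loss and is not part of the resolved jet.

### The precursor wavelet

The pressurized volume inside the diaphragm's hemispherical bulge
(radius 0.07 m at 239.3 kPa absolute — an ideal TNT equivalence of about
59 mg) bursts into a weak spherical shock. `solve_spherical_burst()`
solves the same Euler system in spherical symmetry ($A \propto r^2$)
with an instantaneous release. At the specimen range the computed
wavelet has a ~0.23 ms positive phase, but its peak converges (with grid
refinement) to 26–28 kPa, noticeably above the ~20 kPa that full 2D
modeling of the apparatus reports. We attribute the overshoot to the
idealized instantaneous rupture: the real membrane petals over ~0.3 ms,
comparable to the wavelet duration itself, which can only weaken the
front (indeed a true shock front forms in only about 10% of tests). We
report the ideal-burst value rather than introduce an ad hoc release
model.

## Pitot-static reduction

`mach_from_pitot()` inverts the isentropic total-pressure ratio
$p_0/p = (1 + \tfrac{\gamma-1}{2} M^2)^{\gamma/(\gamma-1)}$ and switches
to the Rayleigh–Pitot (normal-shock-corrected) formula whenever the
implied Mach number exceeds 1; the two branches join continuously at the
sonic ratio 1.8929. Round trips are exact to $10^{-8}$ over
$M \in [0, 3]$. Velocity recovery assumes the total temperature equals
ambient (the chamber gas starts at rest at ambient and the flow is
adiabatic); the apparatus did not measure in-chamber temperature, so
this is the natural closure. Samples where the stagnation channel reads
below the static channel — possible with sensor noise, impossible in the
physics — are clamped to $q = 0$ and flagged, never silently dropped.

## Free-flight loading

The 40 mm, 1.1 g/cm³ sphere (36.9 g — Reynolds-matched to a small-rodent
head) obeys the point-mass drag law
$m\,\dot v = \tfrac12 \rho C_d A\,|u - v|(u - v)$ with $C_d = 0.5$
(subcritical sphere; exposed in the spec), driven by the simulated
density and velocity history at the specimen station — the cold jet is
denser than ambient air, which matters for drag. Track analysis
differentiates by central differences (second-order one-sided at the
ends, exact for uniformly accelerated motion); when a track carries
camera pixel noise, the endpoint velocities entering $\Delta v$ come
from quadratic fits over the first and last third of the frames.

Two deliberate reporting choices: the mean acceleration is defined over
the loading interval (motion onset to final velocity), and both mean and
peak acceleration are reported, because the published 270 g figure and
the published 15 m/s-in-5-ms figure imply different means (~306 g); we
do not adjudicate between them.

Driven by the quasi-1D flow history, the simulated sphere reaches only
about 4 m/s in 5 ms — well short of the ~15 m/s observed. This is the
expected signature of the missing ring vortex: the observed impulse
implies a mean dynamic pressure above 200 kPa at the specimen, which the
apparatus's own 2D modeling attributes to vortex-enhanced local
velocities exceeding 450 m/s with partial-vacuum static pressure. A
quasi-1D stream tube cannot generate that enhancement (its specimen
dynamic pressure peaks near 65 kPa), so the free-flight coupling is
reported as an acknowledged lower bound rather than tuned — for example
by inflating $C_d$ — into agreement.

## Signal diagnostics

`diagnose()` reads a gauge record the way the apparatus records are
read, with all conventions fixed and documented:

* baseline from the pre-event window (before the 5% onset crossing), so
  reports are invariant to a constant pre-trigger offset;
* rise time 10%→90% of the first major peak, interpolated between
  samples; records rising faster than 50 µs are classified as shock
  fronts (resolution-aware: a ~1 ns front cannot be resolved at the
  800 kHz acquisition rate, while the ~1.5 ms jet-impingement ramp is
  far slower);
* quasi-static level as the median of the final 20% of the record;
* reverberation period from the first substantial autocorrelation peak
  of the detrended tail. The residual is band-limited first (1 ms
  moving-average low-pass minus a 10 ms moving-average trend) so that
  neither kHz ripple nor the slow convergence trend masks the
  ~8.5 ms mode, and the first local maximum at ≥ 50% of the tallest
  candidate is taken, since beating between nearby duct modes can push
  the global maximum to a later multiple;
* dominant ripple frequency from the spectrum of the decay-phase
  residual within a configured band (0.5–5 kHz by default).

`jet_decay_duration()` applies a 0.5 ms moving average before testing
when the stagnation trace enters (and stays within) 10% of the burst
pressure around the quasi-static asymptote: the band test reads the jet
envelope, and without smoothing sub-millisecond reverberation spikes —
the "stages" of the convergence, not the jet — retrigger it.

## The synthetic-record generator

`gen_opc_record()` produces the three-channel record the analysis
assumes, from fixed defaults that mirror the apparatus's observed
conditions: a 20 kPa / 0.2 ms precursor wavelet from burst time; jet
onset 0.5 ms later, as a one-sample step with probability 0.10 (clean
rupture) or a 1.5 ms ramp otherwise; exponential jet decay with a 6 ms
time constant (so the decay completes over ~18 ms, three time
constants) carrying 3% ripple at 1.3 kHz; staged convergence to a
15 kPa quasi-static level realized as a smoothed step train at the
8.5 ms reverberation period plus a slowly decaying ripple at that
period; a static channel bounded by 20 kPa with a partial-vacuum dip;
a monotone driver decay; Gaussian sensor noise (200 Pa) and optional
linear drift. Records are bit-identical for a given seed, and the
generator restores the caller's RNG state.

The generator emulates the statistical and temporal structure of the
records, not the sensor physics: no piezoresistive transfer function, no
membrane-fragment strikes, no directivity of non-ideal rupture (the
off-axis probe of the real apparatus sees a ~10 kPa wavelet where the
on-axis probe sees ~20 kPa; the spherical model cannot produce that
asymmetry and we record the limitation rather than guess). Parameter
recovery by `diagnose()` within stated tolerances — quasi-static level
to 0.5 kPa, period to 0.5 ms, ripple frequency to a few bins, shock
incidence to binomial error over 200 seeded records — is the backbone
of the test suite; passing it demonstrates the analysis chain is
self-consistent, not that real sensor records obey the generator's
parametric form.

## Problem sizes and runtimes

Default analyses are sized for a desk: 720 cells × 60 ms for the chamber
(about 21,000 time steps, a few seconds of compute), 1500 cells for the
wavelet, 200 kHz probe resampling (the solver step is ~2 µs, so nothing
is lost relative to the 800 kHz acquisition rate), 200 seeded records
for the classification study. The grid-convergence and front-speed
comparisons in the tests use coarser/finer companions (360 and 1440
cells).

## Known limitations

* No ring vortex: the 2D toroidal vortex that locally drives velocities
  past 450 m/s and deepens the static-pressure deficit is out of scope
  for a quasi-1D model; peak dynamic pressure at the specimen, and
  everything downstream of it (sphere impulse, 270 g accelerations), is
  underpredicted.
* The ideal instantaneous spherical burst overpredicts the precursor
  wavelet peak (~26 vs ~20 kPa) because real petaling rupture is as slow
  as the wavelet is long.
* The stream-tube construct keeps a narrow neck after the jet has died,
  exaggerating late-time oscillatory velocities at the specimen station;
  the envelope smoothing in `jet_decay_duration()` and the directional
  reverse loss exist to keep this artifact from contaminating the
  reported observables.
* No membrane mechanics, no fluid–structure interaction, no turbulence
  model beyond the quadratic mixing losses, no humidity or real-gas
  effects.
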