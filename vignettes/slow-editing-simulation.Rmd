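---
title: "Simulating chemical-shift-selective adiabatic refocusing and SLOW J-difference editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating chemical-shift-selective adiabatic refocusing and SLOW J-difference editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowedit)
```

## The method in brief

At 7 T, editing the small J-coupled brain metabolites (GABA, the
oncometabolite 2-hydroxyglutarate, glutamate/glutamine, and
phosphorylethanolamine) with conventional MEGA-type sequences is limited
by SAR, RF peak power, chemical-shift displacement and B1+
inhomogeneity. The approach simulated here replaces the slice-selective
amplitude-modulated refocusing pulse of an EPSI sequence with a
*chemical-shift-selective* adiabatic full-passage pulse pair (a
"2pi-CSAP"): two identical complex hyperbolic-secant pulses whose
nonlinear phase cancels pairwise. Spectral editing ("SLOW" editing) then
follows from running the same double echo twice with two different
refocusing bands:

* **editing-full** refocuses every resonance of the target spin system,
  so scalar coupling evolves freely over the whole echo time and the
  observed multiplet is J-modulated (in-phase amplitude proportional to
  cos(pi J TE));
* **editing-partial** refocuses only the observed part of the system;
  the coupling partner is dephased by the crushers, J evolution is
  refocused, and the observed multiplet comes out in phase at full
  amplitude.

The difference of the two acquisitions isolates the coupled resonance.
Magnetization outside both bands (water at 4.7 ppm, lipids at
0.9–1.3 ppm) is never conjugated by the refocusing pair, survives the
coherence selection with a probability of roughly the *square* of its
single-pulse leakage, and is therefore suppressed by factors of a
thousand and more at zero additional SAR.

This package implements the whole chain as a simulation toolkit: pulse
synthesis, single-spin Bloch response, relaxation-free density-matrix
simulation of the coupled spin systems through the sequence,
figure-of-merit calculators, and a digital phantom for the
B1-homogeneity contrast.

## Pulse model

The adiabatic pulse is the complex secant hyperbolic

$$B_1(t) = \Omega_0\,\mathrm{sech}(\beta t)^{\,1 + i\mu},$$

i.e. a sech amplitude envelope with instantaneous frequency
$-\mu\beta\tanh(\beta t)/2\pi$ Hz sweeping across a band of width
$\mu\beta/\pi$ Hz. The printed specifications of the pulses are duration
and bandwidth only, so `sech_pulse_design()` closes the system with the
edge truncation level:

* `beta = 2 asech(truncation) / duration` — the unique modulation rate
  for which the envelope decays to the stated edge value;
* `mu = pi * bandwidth / beta` — the sweep-width identity.

The default truncation of 0.01 (1% edge amplitude) is the conventional
choice for sech pulses; with it, the reconstructed 24-ms editing pulses
reproduce the printed band geometry of the editing schemes to within a
few hundredths of a ppm (see below). The peak amplitude `omega0`
defaults to **twice** the operational adiabatic threshold, the stated
operating point of the sequence; the threshold itself is defined
operationally by `adiabatic_threshold()` as the smallest B1 scale that
reaches on-carrier Mz <= -0.95, since no numeric criterion is printed.

The excitation pulse is the sinc-Gaussian
$\sin(\pi t f)/\sin(\pi t)\cdot e^{-b^2 t^2}$ with $f = 5500$,
$b = 400$ and $t \in [-3, 3]$ ms. The printed formula is dimensionally
informal; the only reading consistent with its stated 6-ms duration and
5.5-kHz bandwidth takes $t$ in seconds (sinc zeros every $1/f$ s, the
denominator is essentially $\pi t$ on this support, and the Gaussian
edge value is 0.24). `make_sinc_gauss_pulse()` follows that reading and
rescales the envelope to the requested flip angle; its simulated
excitation profile is 5.5 kHz wide, which is what anchors the 5.4%-per-ppm
chemical-shift displacement figure.

## Band geometry of the editing schemes

Three editing schemes are registered (`slow_schemes()`), with the
scheme-2 (GABA/Glx/2HG, TE = 68 ms) parameters carried in full:
carriers 2.90/3.45 ppm, swept bandwidths 0.88/0.56 kHz, and the printed
95%-response passbands 1.6–4.2 ppm (full) and 2.7–4.2 ppm (partial)
with the partial stop band ending at 2.35 ppm. These numbers are
mutually consistent with the sech reconstruction: the Mz = 0 crossings
sit at carrier ± bandwidth/2 (1.42–4.38 and 2.51–4.39 ppm) and the
simulated 95% points fall ≈0.18 ppm inside them, matching the printed
edges. Both printed full-band presets (0.88 kHz from the in vivo pulse
table, 0.81 kHz from the sequence description) are exposed; 0.88 kHz is
the default because it is the value stated for the editing experiments.
For schemes 1 and 3 only carriers and TEs are printed; their ppm edges
are derived from the same transition-inset model and are configurable.

`band_margin()` works from the printed edges, reproducing the safety
margins that justify the method's B0 robustness: 0.3 ppm from the full
lower edge to GABA 1.9, 0.3 ppm from the partial lower edge to GABA
3.0, and 0.45 ppm from the stop band to GABA 1.9.

## Spin dynamics

`run_slow_acquisition()` propagates the density operator of a
J-coupled system (full isotropic coupling, 297 Hz/ppm, reference
3.0 ppm) through excitation, two refocusing pulses and acquisition.
Numerical choices:

* **Piecewise-constant propagation** of the shaped pulses with the
  chemical-shift and J terms active *during* the pulse — at 24 ms the
  pulses occupy most of the echo time, so intra-pulse evolution is not
  negligible. Default 360–400 samples per pulse for dynamics (per-step
  rotations stay well below the Nyquist guard); 4096 samples for
  single-spin profiles where the cost is trivial.
* **Ideal crusher model**: around each refocusing pulse only the
  conjugated coherence pathway survives (-1 after excitation, +1
  between the pulses, -1 at acquisition). This emulates the spoiler
  pairs and is exactly what makes out-of-band magnetization vanish.
* **Symmetric delay split** tau/2 – CSAP – tau – CSAP – tau/2, with
  delays plus pulse durations summing to TE (the split is not printed;
  it is configurable through the timing arithmetic).
* **Ideal 90-degree excitation by default**: the 65-degree Ernst angle
  scales SNR, not editing logic. The shaped sinc-Gaussian pulse can be
  passed instead.
* **Amplitude normalization**: detected FIDs are scaled so one fully
  excited, fully refocused unit-multiplicity proton contributes 1,
  making amplitudes comparable across systems of different size.
* **Processing**: exponential apodization (default 3 Hz), first-point
  halving (to remove the one-sided-DFT baseline so that signed
  integrals are window-robust), zero filling, FFT; acquisition default
  1024 points over a 1.28-kHz sweep.

Spin-system constants (shifts and couplings for GABA, 2HG, glutamate,
glutamine, PE, lactate, creatine, glycine, NAA) are standard literature
values embedded in `mrs_spin_system()`; the source publication of the
method prints none. Glx is simulated as glutamate and glutamine
separately, summed 2:1. PE's phosphorus couplings are ignored (proton
simulator).

### J evolution during long adiabatic pulses

A physical subtlety the simulations expose: while both coupling
partners lie inside the swept band, the sweep inverts them at slightly
different times (when it crosses each one's resonance), and scalar
coupling evolution is effectively time-reversed between those two
crossings. For a 1.1-ppm separation this shortens the effective J
evolution time by ≈2 ms per pulse, which moves the observed
echo modulation from cos(pi J TE) to approximately
cos(pi J (TE − 2Δt)) with Δt the crossing-time gap. The package's tests
verify both this corrected closed form (to 0.03–0.05 in the modulation
for 1.1–1.4 ppm separations; the residual comes from the finite
passage duration) and the textbook cos/sin forms under ideal
instantaneous refocusing (`refocusing = "ideal"`), which is the proper
oracle for the density-matrix engine itself. For close spins the
textbook forms additionally acquire strong-coupling corrections of
order J/Δν, which is why the weak-coupling oracle uses a 3-ppm
separation.

## Editing efficiency and B0 robustness

`editing_efficiency()` is the signed real-part integral of the
difference spectrum over the multiplet window, normalized by the
in-phase integral of the partial spectrum (the fully edited
reference). The *signed* integral matters: antiphase components
integrate to zero over a symmetric window, and — more importantly — a
subtraction artifact from a resonance that fell out of the partial band
enters negatively instead of masquerading as edited signal, which a
magnitude integral cannot distinguish.

`b0_robustness_sweep()` shifts all resonances by a global ΔB0, re-runs
the editing simulation, and evaluates the efficiency in a window that
tracks the shift against the fixed zero-offset reference. For
GABA/scheme 2 the simulated efficiency retention stays above 0.95 for
|ΔB0| ≤ 0.2 ppm and above ~0.85 at ±0.3 ppm, consistent with the band
margins. At ΔB0 = −0.6 ppm the 1.9-ppm partner leaves the full band
*and* the 3.0-ppm multiplet leaves the partial band: the signed metric
goes strongly negative (pure subtraction artifact). At +0.6 ppm the
partner lands on the partial-band crossing and roughly half the editing
contrast survives — a degradation, not a collapse, which is what the
asymmetric band geometry predicts.

## Figure-of-merit calculators

All SAR and peak-power quantities are *ratios* under the standard
scaling model for similarly shaped adiabatic pulses at the same
adiabatic condition: deposited energy ∝ bandwidth, required peak B1
amplitude ∝ sqrt(bandwidth/duration). No absolute W/kg calibration is
attempted — every published number is a ratio. One printed figure
deserves a note: the "15.7%" peak-power comparison equals the *square
root* of the printed formula (0.81 kHz/31 ms)/(5.3 kHz/5 ms) = 2.5%;
i.e. it is the peak *amplitude* ratio, and the complementary "84%"
follows from it. `peak_power_ratio_model()` returns the amplitude ratio
(the published quantity) and attaches the raw power ratio.

The waveform-level cross-checks close the loop: energies of the
reconstructed 0.56- and 0.88-kHz pulses at twice their own thresholds
agree with the bandwidth-proportional model to better than 10%, and
the measured 95%→5% transition width scales as 1/duration (0.45 ppm at
24 ms, 0.35 ppm at 31 ms), slightly wider than the 0.35-ppm
stop-to-pass gap of the printed band geometry because the published
edges use response thresholds rather than the 5/95% convention.

## Digital phantom

`make_phantom()` builds a spherical digital phantom with a
centre-attenuated B1+ map (0.6 at the centre to 1.2 at the rim — the
qualitative transmit pattern of a head coil at 7 T), a smooth ±0.1-ppm
B0 gradient with small random perturbations, and uniform
creatine/water concentrations. It emulates the geometry of the
published phantom experiment, not its exact field maps (which are not
quantified); what the tests show is therefore the *contrast* between
refocusing modes, not absolute map values. Per-voxel signals use the
single-spin pair-transfer model interpolated from a Bloch lookup table
(offset × B1 scale) — full density-matrix runs per voxel would add
nothing to this contrast. With the adiabatic pair driven at twice
threshold, the phantom's whole B1 range rides the adiabatic plateau and
the creatine-window map has a coefficient of variation below 5%; a
conventional amplitude-modulated sinc π pulse, whose refocusing
efficiency falls as roughly the fourth power of sin of the scaled flip
angle, produces a CoV more than three times larger — the simulated
counterpart of the centre-darkened maps seen with the conventional
pulse. The residual-water map uses the 31-ms whole-metabolite pulse
(`csap_epsi_pulse()`), whose refocused range is symmetric about
3.0 ppm, so water (4.7 ppm) and lipid (1.3 ppm) are attenuated equally;
residuals stay below 1e-3 over the phantom's native ±0.13-ppm B0 range.
(Under a ±0.2-ppm shift the water line reaches 4.5 ppm, where the
24–31-ms transition band lets through a few tenths of a percent — the
1e-3 bound is a property of realistic shim ranges, not of arbitrary
ones.)

## Problem sizes and runtimes

The defaults are chosen so the full test suite and the acceptance
script run in a few minutes on one CPU: 4096-sample waveforms for Bloch
profiles, 360-sample waveforms for density-matrix pulses (validated
against 1200-sample runs to three digits), 6-spin GABA as the largest
system (64×64 density matrices; one editing simulation ≈ 1 s), B0
sweeps over 5–7 offsets, and a 24×24×8 phantom grid (a full map well
under a minute).

## Known limitations

* No relaxation (T1/T2), macromolecule baselines, frequency drift or
  eddy currents; the simulator solves the relaxation-free equation of
  motion by design.
* Crushers are ideal coherence-pathway filters; no explicit gradient
  integrals, so diffusion/imperfect-spoiling effects are absent.
* The exact β, μ, Ω0 of the in vivo pulses are not published; all
  pulse-level results are for the reconstruction described above, and
  claims tied to the published profiles (e.g. >90% refocusing at
  4.2 ppm) are checked as bounds the reconstruction must meet.
* Spatial encoding (EPSI readout, k-space, coil combination) and
  spectral fitting are out of scope.
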