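# slowedit

Simulation toolkit for **SLOW J-difference spectral editing** with
chemical-shift-selective adiabatic refocusing pulse pairs (2π-CSAP) in
7 T MR spectroscopic imaging.

## The problem

Editing the low-concentration J-coupled brain metabolites — GABA, the
IDH-glioma oncometabolite 2-hydroxyglutarate (2HG), glutamate/glutamine
(Glx) and phosphorylethanolamine (PE) — at ultra-high field is hard:
MEGA-type editing sequences run into SAR and RF peak-power limits,
large chemical-shift displacement artifacts (CSDA), and B1+
inhomogeneity. Replacing the slice-selective amplitude-modulated
refocusing pulse with a *phase-compensated pair of chemical-shift
selective adiabatic full-passage pulses* — complex hyperbolic-secant
pulses B₁(t) = Ω₀·sech(βt)^(1+iμ) with a narrow swept band and steep
transition bands — solves all four at once, and turns the refocusing
pulses themselves into editing pulses: acquiring once with a band
covering the whole coupled spin system (*editing-full*) and once with a
band covering only the observed resonances (*editing-partial*) makes
the subtraction a J-difference spectrum, while water and lipids outside
both bands are dephased by factors ≥1000 at zero SAR cost.

`slowedit` implements this method end to end as a desk-scale simulator
for sequence designers and MRS physicists:

* **Pulse design** — `sech_pulse_design()`, `make_sech_pulse()`,
  `make_sinc_gauss_pulse()`; β and μ are derived from the published
  duration/bandwidth pairs with β = 2 asech(trunc)/τ, μ = πBW/β, and
  the peak amplitude defaults to twice the operational adiabatic
  threshold.
* **Bloch response** — `bloch_propagate()` (Cayley–Klein SU(2)
  parameters), `inversion_profile()`, `refocusing_profile()`,
  `adiabatic_threshold()`.
* **Spin dynamics** — relaxation-free density-matrix propagation of
  J-coupled systems through the double echo with ideal
  coherence-pathway crushers: `run_slow_acquisition()`,
  `fid_to_spectrum()`, with built-in literature spin systems
  (`mrs_spin_system()`).
* **Editing** — the three published schemes (`slow_schemes()`),
  `simulate_editing()`, `editing_efficiency()`, `band_margin()`,
  `b0_robustness_sweep()`.
* **Figures of merit** — `csda_fraction_per_ppm()`,
  `sar_ratio_bw_model()`, `peak_power_ratio_model()`,
  `suppression_factor()`, `transition_band_width()`,
  `slow_metrics_table()`.
* **Digital phantom** — `make_phantom()`, `simulate_phantom_maps()`,
  `residual_water_map()` for the adiabatic-vs-AM homogeneity contrast.

A thin CLI (`inst/cli/slowedit`) exposes `design-pulse`, `profile`,
`simulate-editing`, `metrics` and `phantom` subcommands.

## Worked example

Reconstruct the scheme-2 (GABA/Glx/2HG, TE = 68 ms) editing-full pulse,
simulate its pair refocusing profile, and edit GABA:

```r
library(slowedit)

sch <- slow_schemes("scheme2")
sch
#> <slow_scheme> scheme2: TE 68 ms
#>   full    2.90 ppm / 880 Hz, passband 1.60..4.20 ppm
#>   partial 3.45 ppm / 560 Hz, passband 2.70..4.20 ppm (stop band < 2.35 ppm)

w <- csap_for_scheme(sch, "full")   # 24 ms, 0.88 kHz, 2x adiabatic threshold
offs <- seq(-700, 700, by = 2) + w$carrier_offset_hz
pr <- refocusing_profile(w, offs, pair = TRUE)

approx(pr$offsets_hz, pr$mz, ppm_to_hz(4.2))$y                    # -0.82
approx(pr$offsets_hz, pr$refocusing_efficiency, ppm_to_hz(4.2))$y #  0.909
suppression_factor(pr, 2.90, 4.7)                                 #  9297

res <- simulate_editing("gaba", sch)
editing_efficiency(res, c(2.8, 3.2))                              #  1.012
```

Reading the numbers: at the 4.2-ppm passband edge the inversion profile
reaches Mz ≈ −0.8 while the refocusing profile still exceeds 90% — the
pair's phase compensation refocuses more than it inverts at the band
edge. Water at 4.7 ppm, only 0.5 ppm further out, is suppressed by a
factor ~9300 relative to the passband centre, because the pair
transfers only |b²|² of the stopband leakage. The edited GABA multiplet
at 3.0 ppm comes out at essentially the full in-phase amplitude of the
partial acquisition (efficiency ≈ 1).

The closed-form figure-of-merit table reproduces the published ratios
(CSDA 23.7%/ppm vs 5.4%/ppm and the 77% reduction; SAR 7.6% of
MEGA-semiLASER's refocusing pulses; peak B1 amplitude 15.7%; 91% SAR
reduction vs a 10-kHz GOIA pulse):

```r
slow_metrics_table()
```

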