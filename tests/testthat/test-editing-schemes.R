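# Scheme registry, band-margin geometry, J-difference editing and the
# B0-robustness sweep.

test_that("scheme registry carries the printed scheme parameters", {
  reg <- slow_schemes()
  expect_named(reg, c("scheme1", "scheme2", "scheme3"))
  s2 <- reg$scheme2
  expect_equal(s2$te_s, 0.068)
  expect_equal(s2$carrier_full_ppm, 2.90)
  expect_equal(s2$carrier_partial_ppm, 3.45)
  expect_equal(s2$passband_full_ppm, c(1.6, 4.2))
  expect_equal(s2$passband_partial_ppm, c(2.7, 4.2))
  expect_equal(s2$stopband_partial_start_ppm, 2.35)
  # partial passband inside the full passband
  expect_gte(s2$passband_partial_ppm[1], s2$passband_full_ppm[1])
  expect_lte(s2$passband_partial_ppm[2], s2$passband_full_ppm[2])
  expect_equal(reg$scheme1$te_s, 0.120)
  expect_equal(reg$scheme1$carrier_full_ppm, 3.00)
  expect_equal(reg$scheme1$carrier_partial_ppm, 2.00)
  expect_equal(reg$scheme3$te_s, 0.090)
  expect_equal(reg$scheme3$carrier_full_ppm, 3.00)
  expect_equal(reg$scheme3$carrier_partial_ppm, 2.60)
  # the alternate 0.81-kHz full-band preset
  alt <- slow_schemes("scheme2", bandwidth_full_hz = 810)
  expect_equal(alt$bandwidth_full_hz, 810)
  expect_error(slow_schemes("scheme9"))
})

test_that("band margins reproduce the scheme-2 editing geometry", {
  s2 <- slow_schemes("scheme2")
  expect_equal(band_margin(s2, 1.9, "full", "lower"), 0.3)
  expect_equal(band_margin(s2, 3.0, "partial", "lower"), 0.3)
  expect_equal(band_margin(s2, 1.9, "stop"), 0.45)
  # sign convention: a resonance below the lower edge has negative margin
  expect_lt(band_margin(s2, 1.4, "full", "lower"), 0)
  expect_error(band_margin(s2, 3.0, "partial", "sideways"))
})

test_that("in-band singlets cancel in the difference spectrum", {
  for (name in c("glycine", "creatine")) {
    res <- simulate_editing(name, "scheme2")
    full_amp <- spectrum_integral(res$full, c(2.8, 4.1), "magnitude")
    diff_amp <- spectrum_integral(res$difference, c(2.8, 4.1), "magnitude")
    expect_lt(diff_amp / full_amp, 0.02)
  }
})

test_that("a singlet inside full but outside partial appears in the difference at full amplitude", {
  # co-editing transparency: structural property of SLOW (unlike MEGA)
  sys <- spin_system("marker", 2.0)   # inside full band, below partial
  res <- simulate_editing(sys, "scheme2")
  d <- spectrum_integral(res$difference, c(1.8, 2.2), "magnitude")
  f <- spectrum_integral(res$full, c(1.8, 2.2), "magnitude")
  expect_equal(d / f, 1, tolerance = 0.03)
})

test_that("GABA scheme-2 editing yields a positive multiplet at 3.0 ppm", {
  res <- simulate_editing("gaba", "scheme2")
  eff <- editing_efficiency(res, c(2.8, 3.2))
  expect_gt(eff, 0.8)
  expect_lt(eff, 1.3)
  # sign flag flips the difference
  res2 <- simulate_editing("gaba", "scheme2",
                           difference = "full_minus_partial")
  expect_equal(res2$difference$intensity, -res$difference$intensity,
               tolerance = 1e-12)
  # all three spectra share one axis
  expect_identical(res$full$ppm, res$partial$ppm)
  expect_identical(res$full$ppm, res$difference$ppm)
})

test_that("AX difference follows the weak-coupling closed form", {
  # partner at 1.9 ppm (inside full, outside partial), observed at
  # 3.0 ppm: difference = in-phase partial - cos-modulated full, with
  # the CSAP sweep-crossing correction to the effective J time
  J <- 7.35
  sys <- ax_system(1.9, 3.0, J)
  sch <- scheme2()
  res <- simulate_editing(sys, sch)
  w <- csap_full(400)
  d <- sech_pulse_design(sch$duration_s, sch$bandwidth_full_hz)
  te_eff <- sch$te_s - 2 * sweep_crossing_gap(w, d, 1.9, 3.0)
  # window wide enough to capture the Lorentzian tails of the multiplet
  eff <- editing_efficiency(res, c(2.6, 3.4))
  expect_lt(abs(eff - (1 - cos(pi * J * te_eff))), 0.03)
})

test_that("editing efficiency: zero difference gives zero, empty window errors", {
  res <- simulate_editing("glycine", "scheme2")
  eff <- editing_efficiency(res, c(3.4, 3.7))
  expect_lt(abs(eff), 0.02)
  expect_error(editing_efficiency(res, c(9.2, 9.4)), "empty")
})

test_that("editing is covariant under a common shift of bands and resonances", {
  J <- 7.35
  shift <- 0.25
  sys1 <- ax_system(1.9, 3.0, J)
  res1 <- simulate_editing(sys1, scheme2())
  sch_shift <- slow_scheme("shifted", 2.90 + shift, 3.45 + shift,
                           880, 560, 0.068)
  sys2 <- ax_system(1.9 + shift, 3.0 + shift, J)
  res2 <- simulate_editing(sys2, sch_shift)
  e1 <- editing_efficiency(res1, c(2.85, 3.15))
  e2 <- editing_efficiency(res2, c(2.85, 3.15) + shift)
  expect_equal(e2, e1, tolerance = 0.02)
})

test_that("edited amplitude follows the J modulation across TE", {
  J <- 7.35
  sys <- ax_system(1.9, 3.0, J)
  ref <- ax_system(1.9, 3.0, 0)
  sch <- scheme2()
  d <- sech_pulse_design(sch$duration_s, sch$bandwidth_full_hz)
  wfull <- csap_full(360)
  wpart <- csap_partial(360)
  gap <- sweep_crossing_gap(wfull, d, 1.9, 3.0)
  tes <- c(0.068, 0.090, 0.120)
  coeff2 <- function(w, system, te) {
    st <- run_slow_acquisition(system, w, te, return_state = TRUE)
    I2m <- st$ops$Ix[[2]] - 1i * st$ops$Iy[[2]]
    op_coefficient(st$rho, I2m)
  }
  for (te in tes) {
    sch_te <- sch; sch_te$te_s <- te
    eff <- editing_efficiency(simulate_editing(sys, sch_te), c(2.6, 3.4))
    # dual route: the spectral metric reproduces the density-matrix
    # in-phase coefficients of the observed spin
    cF <- Re(coeff2(wfull, sys, te) / coeff2(wfull, ref, te))
    cP <- Re(coeff2(wpart, sys, te) / coeff2(wpart, ref, te))
    expect_lt(abs(eff - (cP - cF)), 0.04)
    # and both follow the sweep-corrected J-modulation envelope
    expect_lt(abs(eff - (1 - cos(pi * J * (te - 2 * gap)))), 0.1)
  }
})

test_that("B0-robustness: efficiency retained to 0.2 ppm, collapsing at 0.6 ppm", {
  sweep <- b0_robustness_sweep("gaba", "scheme2",
                               delta_b0_grid_ppm = c(-0.2, 0, 0.2))
  expect_equal(sweep$retention[sweep$delta_b0_ppm == 0], 1)
  expect_true(all(sweep$retention >= 0.9))
  collapse <- b0_robustness_sweep("gaba", "scheme2",
                                  delta_b0_grid_ppm = c(-0.6, 0, 0.6))
  expect_lt(collapse$retention[collapse$delta_b0_ppm == -0.6], 0.5)
  expect_lt(collapse$retention[collapse$delta_b0_ppm == 0.6], 0.75)
  expect_error(b0_robustness_sweep("gaba", "scheme2",
                                   delta_b0_grid_ppm = c(0, 1.0)))
})
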