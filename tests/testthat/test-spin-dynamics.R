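# Density-matrix engine: Hamiltonian structure, unitary evolution,
# shaped-pulse propagation and the closed-form echo-modulation oracles.

test_that("Hamiltonian: reference spin is silent, couplings give the isotropic splitting", {
  # one uncoupled spin at the acquisition reference -> zero Hamiltonian
  s0 <- spin_system("ref", 3.0)
  expect_equal(max(Mod(sys_hamiltonian(s0))), 0)
  # the ppm scale is 297 Hz/ppm: one spin 1 ppm downfield precesses at 297 Hz
  s1 <- spin_system("one", 4.0)
  H <- sys_hamiltonian(s1)
  expect_equal(sort(Re(diag(H))) / (2 * pi), c(-148.5, 148.5))
  # two co-resonant spins, J = 7: isotropic exchange splits singlet from
  # triplet by 2*pi*J (eigenvalues -3/4 J vs +1/4 J in angular units)
  s2 <- spin_system("pair", c(3, 3), 7)
  ev <- sort(eigen(sys_hamiltonian(s2), symmetric = TRUE)$values) / (2 * pi)
  expect_equal(ev, c(-3 / 4 * 7, rep(7 / 4, 3)), tolerance = 1e-10)
  # Hermitian by construction
  sys <- mrs_spin_system("gaba")
  Hg <- sys_hamiltonian(sys)
  expect_lt(max(Mod(Hg - Conj(t(Hg)))), 1e-10)
})

test_that("evolution is unitary: identity at t=0, closed-form precession, spectrum preserved", {
  sys <- spin_system("one", 3.5)
  ops <- spin_operators(sys)
  H <- sys_hamiltonian(sys, ops = ops)
  rho <- ops$Fx
  expect_equal(evolve_rho(rho, H, 0), rho)
  # transverse magnetization precesses by 2*pi*offset*t
  t1 <- 3.1e-3
  r1 <- evolve_rho(rho, H, t1)
  mplus <- sum(diag((ops$Fx + 1i * ops$Fy) %*% r1))
  expect_equal(Arg(mplus), 2 * pi * 0.5 * 297 * t1, tolerance = 1e-9)
  # trace and eigenvalues preserved over 1e4 concatenated steps
  sys2 <- ax_system(1.9, 3.0)
  ops2 <- spin_operators(sys2)
  H2 <- sys_hamiltonian(sys2, ops = ops2)
  U <- NULL
  rho2 <- ops2$Fx + 0.3 * ops2$Fz
  ev0 <- sort(Re(eigen(rho2, symmetric = TRUE)$values))
  step <- 1e-4
  e <- eigen(H2, symmetric = TRUE)
  Ustep <- e$vectors %*% (exp(-1i * e$values * step) * Conj(t(e$vectors)))
  for (k in 1:10000) rho2 <- Ustep %*% rho2 %*% Conj(t(Ustep))
  expect_equal(Re(sum(diag(rho2))), 0, tolerance = 1e-10)
  expect_equal(sort(Re(eigen(rho2, symmetric = TRUE)$values)), ev0,
               tolerance = 1e-10)
})

test_that("shaped pulses: zero amplitude = free evolution, hard pi inverts, stopband untouched", {
  sys <- ax_system(2.5, 3.2, 7)
  ops <- spin_operators(sys)
  H <- sys_hamiltonian(sys, ops = ops)
  rho <- ops$Fx + 0.2 * ops$Fz
  # zero-amplitude pulse of duration tau == evolve(H, tau)
  w0 <- rf_waveform(complex(real = numeric(128)), 1e-4)
  expect_equal(apply_shaped_pulse(rho, sys, w0, H0 = H, ops = ops),
               evolve_rho(rho, H, 128 * 1e-4), tolerance = 1e-8)
  # hard pi pulse inverts z-polarization of an uncoupled spin
  s1 <- spin_system("one", 3.0)
  o1 <- spin_operators(s1)
  n <- 256; dtp <- 1e-6
  wpi <- rf_waveform(rep(complex(real = pi / (n * dtp)), n), dtp)
  rz <- apply_shaped_pulse(o1$Iz[[1]], s1, wpi)
  expect_equal(Re(diag(rz)), c(-0.5, 0.5), tolerance = 1e-6)
  # CSAP leaves a deep-stopband spin's z-polarization within 1% of
  # initial, and agrees with the Bloch inversion profile within 2% even
  # on the stopband shoulder (water, 4.7 ppm)
  w <- csap_full(1024)
  s_deep <- spin_system("far", 5.2)
  odeep <- spin_operators(s_deep)
  rho_deep <- apply_shaped_pulse(odeep$Iz[[1]], s_deep, w)
  expect_gt(2 * Re(sum(diag(odeep$Iz[[1]] %*% rho_deep))), 0.99)
  s_stop <- spin_system("water", 4.7)
  ostop <- spin_operators(s_stop)
  rho_z <- apply_shaped_pulse(ostop$Iz[[1]], s_stop, w)
  mz_dm <- 2 * Re(sum(diag(ostop$Iz[[1]] %*% rho_z)))
  prof <- inversion_profile(w, ppm_to_hz(4.7))
  expect_equal(mz_dm, prof$mz, tolerance = 0.02)
})

test_that("coherence projection keeps exactly the requested order", {
  sys <- ax_system(2.8, 3.1)
  ops <- spin_operators(sys)
  rho <- ops$Fx
  pm1 <- coherence_project(rho, ops$m, -1)
  pp1 <- coherence_project(rho, ops$m, +1)
  expect_equal(pm1 + pp1, rho, tolerance = 1e-12)
  # order -1 part is what F+ detects
  expect_equal(sum(diag(ops$Fplus %*% pm1)), sum(diag(ops$Fplus %*% rho)),
               tolerance = 1e-12)
  expect_equal(Mod(sum(diag(ops$Fplus %*% pp1))), 0, tolerance = 1e-12)
})

test_that("weak-coupling echo modulation follows cos/sin(pi J TE) over the TE grid", {
  J <- 7.35
  sys <- ax_system(1.0, 4.0, J)   # 3 ppm separation: weak coupling
  ref <- ax_system(1.0, 4.0, 0)
  for (te in c(0.034, 0.068, 0.090, 0.120)) {
    st <- run_slow_acquisition(sys, NULL, te, refocusing = "ideal",
                               return_state = TRUE)
    st0 <- run_slow_acquisition(ref, NULL, te, refocusing = "ideal",
                                return_state = TRUE)
    ops <- st$ops
    I1m <- ops$Ix[[1]] - 1i * ops$Iy[[1]]
    anti1 <- 2 * I1m %*% ops$Iz[[2]]
    amp0 <- op_coefficient(st0$rho, I1m)
    inphase <- Re(op_coefficient(st$rho, I1m) / amp0)
    antiphase <- Mod(op_coefficient(st$rho, anti1) / amp0)
    expect_lt(abs(inphase - cos(pi * J * te)), 0.02)
    expect_lt(abs(antiphase - abs(sin(pi * J * te))), 0.02)
  }
})

test_that("CSAP echo modulation matches the sweep-crossing-corrected closed form", {
  # with both spins inside the band, J evolution is reversed between the
  # sweep's two crossing times, shortening the effective J time by twice
  # the crossing gap (two pulses)
  J <- 7.35
  sch <- scheme2()
  w <- csap_full(400)
  d <- sech_pulse_design(sch$duration_s, sch$bandwidth_full_hz)
  # the correction captures the bulk of the effect; the residual from
  # the finite passage duration grows with the spins' separation
  for (case in list(list(ppm = c(1.9, 3.0), tol = 0.03),
                    list(ppm = c(2.2, 3.6), tol = 0.05))) {
    ppms <- case$ppm
    sys <- ax_system(ppms[1], ppms[2], J)
    ref <- ax_system(ppms[1], ppms[2], 0)
    te <- 0.068
    gap <- sweep_crossing_gap(w, d, ppms[1], ppms[2])
    te_eff <- te - 2 * gap
    st <- run_slow_acquisition(sys, w, te, return_state = TRUE)
    st0 <- run_slow_acquisition(ref, w, te, return_state = TRUE)
    ops <- st$ops
    I1m <- ops$Ix[[1]] - 1i * ops$Iy[[1]]
    amp0 <- op_coefficient(st0$rho, I1m)
    inphase <- Re(op_coefficient(st$rho, I1m) / amp0)
    expect_lt(abs(inphase - cos(pi * J * te_eff)), case$tol)
    # and the naive uncorrected form is visibly worse at 1.9/3.0 ppm
    if (ppms[1] == 1.9)
      expect_gt(abs(inphase - cos(pi * J * te)),
                abs(inphase - cos(pi * J * te_eff)))
  }
})

test_that("selective refocusing: partner in the stopband leaves an in-phase doublet at full amplitude", {
  J <- 7.35
  sys <- ax_system(1.9, 3.0, J)        # partner 1.9 outside partial band
  wpart <- csap_partial(400)
  te <- scheme2()$te_s
  st <- run_slow_acquisition(sys, wpart, te, return_state = TRUE)
  # uncoupled single-spin reference at the observed position
  ref <- spin_system("ref", 3.0)
  st0 <- run_slow_acquisition(ref, wpart, te, return_state = TRUE)
  # FID amplitudes are dimension-normalized, so the coupled system's
  # observed spin can be compared against a single-spin reference
  sig <- st$fid$signal[1]
  sig0 <- st0$fid$signal[1]
  expect_equal(Mod(sig / sig0), 1, tolerance = 0.02)
  # and the signal is in phase with the uncoupled reference
  expect_equal(Re(sig / sig0), 1, tolerance = 0.02)
})

test_that("an in-band singlet is refocused identically by full and partial pulses", {
  # the cancellation basis of the difference spectrum: total integrated
  # magnitude of an in-band singlet is scheme-independent within 2%
  sys <- spin_system("cr_ch3", 3.027)
  te <- scheme2()$te_s
  f_full <- run_slow_acquisition(sys, csap_full(400), te)
  f_part <- run_slow_acquisition(sys, csap_partial(400), te)
  a_full <- Mod(f_full$signal[1])
  a_part <- Mod(f_part$signal[1])
  expect_equal(a_full / a_part, 1, tolerance = 0.02)
  # and matches the ideal fully excited, fully refocused reference
  f_ideal <- run_slow_acquisition(sys, NULL, te, refocusing = "ideal")
  expect_equal(a_full / Mod(f_ideal$signal[1]), 1, tolerance = 0.02)
})

test_that("equivalent-spin limit: co-resonant coupled pair equals a doubled singlet", {
  sys <- spin_system("A2", c(2.6, 2.6), 10)
  f <- run_slow_acquisition(sys, NULL, 0.068, refocusing = "ideal")
  sp <- fid_to_spectrum(f, apodization_hz = 2, zero_fill = 4)
  # the coupling is invisible: the spectrum is exactly twice the
  # uncoupled single-spin spectrum, line for line
  ref <- run_slow_acquisition(spin_system("A", 2.6), NULL, 0.068,
                              refocusing = "ideal")
  spr <- fid_to_spectrum(ref, apodization_hz = 2, zero_fill = 4)
  expect_lt(max(Mod(sp$intensity - 2 * spr$intensity)),
            1e-3 * max(Mod(spr$intensity)))
})

test_that("FID-to-spectrum: Lorentzian position/width, DFT identity, Parseval, zero map", {
  dwell <- 1 / 1280
  n <- 1024
  tv <- (0:(n - 1)) * dwell
  off <- ppm_to_hz(3.5)
  f <- fid(exp(1i * 2 * pi * off * tv), dwell)
  lb <- 4
  sp <- fid_to_spectrum(f, apodization_hz = lb, zero_fill = 4)
  y <- Re(sp$intensity)
  expect_equal(sp$ppm[which.max(y)], 3.5, tolerance = 0.01)
  # FWHM of the real part equals the applied line broadening
  hm <- sp$ppm[y >= max(y) / 2]
  expect_equal(diff(range(hm)) * 297, lb, tolerance = 0.15)
  # DFT identity with first-point halving: the spectrum mean equals
  # half the first apodized point (flat zero baseline off resonance)
  sig_ap <- f$signal * exp(-pi * lb * tv)
  expect_equal(mean(sp$intensity), sig_ap[1] / 2 + 0i, tolerance = 1e-9)
  # flat absorption baseline far off resonance (dispersion tails decay
  # only as 1/f and are excluded by taking the real part)
  far <- abs(sp$ppm - 3.5) > 1
  expect_lt(max(abs(Re(sp$intensity[far]))) / max(Re(sp$intensity)), 1e-3)
  # Parseval on the processed (halved first point) signal, no zero fill
  sp1 <- fid_to_spectrum(f, apodization_hz = lb, zero_fill = 1)
  sig_h <- sig_ap; sig_h[1] <- sig_h[1] / 2
  expect_equal(sum(Mod(sp1$intensity)^2) / n, sum(Mod(sig_h)^2),
               tolerance = 1e-9)
  # zero FID -> zero spectrum; invalid processing parameters rejected
  sp0 <- fid_to_spectrum(fid(complex(real = numeric(64)), dwell))
  expect_true(all(Mod(sp0$intensity) == 0))
  expect_error(fid_to_spectrum(f, apodization_hz = -1))
  expect_error(fid_to_spectrum(f, zero_fill = 0))
})

test_that("acquisition timing is enforced", {
  sys <- spin_system("one", 3.0)
  w <- csap_full(400)
  expect_error(run_slow_acquisition(sys, w, 0.040), "timing budget")
  expect_error(run_slow_acquisition(sys, w, 0.068, sweep_hz = 0))
})
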