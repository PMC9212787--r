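# The three SLOW editing schemes: full/partial band definitions, the
# J-difference simulation, editing efficiency and B0-robustness margins.

#' Construct an editing scheme
#'
#' A SLOW scheme is a pair of chemical-shift-selective refocusing bands:
#' editing-full refocuses every resonance of the target spin system,
#' editing-partial only part of it; subtracting the two acquisitions
#' yields the edited J-difference spectrum. Bandwidths are the swept
#' widths of the sech pulses (mu*beta/pi); the ppm passbands are the
#' 95%-response band edges, which sit about 0.18 ppm inside the Mz = 0
#' crossings (carrier +/- bandwidth/2) for the 24-ms pulses.
#'
#' @param name scheme name.
#' @param carrier_full_ppm,carrier_partial_ppm pulse carriers (ppm).
#' @param bandwidth_full_hz,bandwidth_partial_hz swept bandwidths (Hz).
#' @param te_s echo time (s).
#' @param targets named numeric vector of edited resonances (ppm).
#' @param passband_full_ppm,passband_partial_ppm 95%-response band edges
#'   `c(lo, hi)` in ppm; derived from carrier and bandwidth when missing.
#' @param stopband_partial_start_ppm upfield 95%-suppression edge of the
#'   partial band (ppm).
#' @param duration_s CSAP duration (s).
#' @param truncation sech edge truncation for the reconstructed pulses.
#' @return object of class `slow_scheme`.
#' @export
slow_scheme <- function(name, carrier_full_ppm, carrier_partial_ppm,
                        bandwidth_full_hz, bandwidth_partial_hz, te_s,
                        targets = numeric(),
                        passband_full_ppm = NULL,
                        passband_partial_ppm = NULL,
                        stopband_partial_start_ppm = NULL,
                        duration_s = 0.024, truncation = 0.01,
                        hz_per_ppm = 297) {
  if (te_s <= 0 || bandwidth_full_hz <= 0 || bandwidth_partial_hz <= 0)
    stop("TE and bandwidths must be positive")
  inset_ppm <- transition_inset_ppm(duration_s, truncation, hz_per_ppm)
  derive <- function(carrier, bw)
    carrier + c(-1, 1) * (bw / 2 / hz_per_ppm - inset_ppm)
  if (is.null(passband_full_ppm))
    passband_full_ppm <- derive(carrier_full_ppm, bandwidth_full_hz)
  if (is.null(passband_partial_ppm))
    passband_partial_ppm <- derive(carrier_partial_ppm, bandwidth_partial_hz)
  if (is.null(stopband_partial_start_ppm))
    stopband_partial_start_ppm <- passband_partial_ppm[1] - 2 * inset_ppm
  structure(
    list(name = name,
         carrier_full_ppm = carrier_full_ppm,
         carrier_partial_ppm = carrier_partial_ppm,
         bandwidth_full_hz = bandwidth_full_hz,
         bandwidth_partial_hz = bandwidth_partial_hz,
         te_s = te_s, targets = targets,
         passband_full_ppm = passband_full_ppm,
         passband_partial_ppm = passband_partial_ppm,
         stopband_partial_start_ppm = stopband_partial_start_ppm,
         duration_s = duration_s, truncation = truncation),
    class = "slow_scheme")
}

# 95%-response inset from the Mz=0 crossing for a sech pulse: the
# transition steepness is set by beta; the logistic small-signal model
# |b|^2 = 1/(1+exp(pi*(dw - mu*beta)/beta)) puts the 95% point
# ln(19)*beta/pi rad/s inside the crossing.
transition_inset_ppm <- function(duration_s, truncation, hz_per_ppm = 297) {
  beta <- 2 * asech(truncation) / duration_s
  log(19) * beta / pi / (2 * pi) / hz_per_ppm
}

#' @export
print.slow_scheme <- function(x, ...) {
  cat(sprintf(
    "<slow_scheme> %s: TE %.0f ms\n  full    %.2f ppm / %.0f Hz, passband %.2f..%.2f ppm\n  partial %.2f ppm / %.0f Hz, passband %.2f..%.2f ppm (stop band < %.2f ppm)\n",
    x$name, 1e3 * x$te_s, x$carrier_full_ppm, x$bandwidth_full_hz,
    x$passband_full_ppm[1], x$passband_full_ppm[2],
    x$carrier_partial_ppm, x$bandwidth_partial_hz,
    x$passband_partial_ppm[1], x$passband_partial_ppm[2],
    x$stopband_partial_start_ppm))
  invisible(x)
}

#' Registry of the three SLOW editing schemes
#'
#' * scheme1: 2HG at 1.88 ppm, TE = 120 ms, carriers 3.00/2.00 ppm
#'   (in vitro illustration of the working principle only).
#' * scheme2: GABA 3.00, Glx 3.75, 2HG 4.01 ppm; TE = 68 ms, carriers
#'   2.90/3.45 ppm, bandwidths 0.88 (full, alternate preset 0.81) and
#'   0.56 kHz (partial); printed passbands 1.6-4.2 and 2.7-4.2 ppm with
#'   the partial stop band starting at 2.35 ppm.
#' * scheme3: PE 3.26 and Glx 2.11 ppm; TE = 90 ms, carriers
#'   3.00/2.60 ppm.
#'
#' @param name scheme name (`"scheme1"`, `"scheme2"`, `"scheme3"`), or
#'   omit for the full named list.
#' @param bandwidth_full_hz override for the full-band preset (e.g. 810
#'   for the 0.81 kHz scheme-2 preset).
#' @return a [slow_scheme()] or a named list of the three.
#' @export
#' @examples
#' slow_schemes("scheme2")$passband_full_ppm
slow_schemes <- function(name = NULL, bandwidth_full_hz = NULL) {
  reg <- list(
    scheme1 = slow_scheme(
      "scheme1", carrier_full_ppm = 3.00, carrier_partial_ppm = 2.00,
      bandwidth_full_hz = 880, bandwidth_partial_hz = 560, te_s = 0.120,
      targets = c(hg2 = 1.88)),
    scheme2 = slow_scheme(
      "scheme2", carrier_full_ppm = 2.90, carrier_partial_ppm = 3.45,
      bandwidth_full_hz = 880, bandwidth_partial_hz = 560, te_s = 0.068,
      targets = c(gaba = 3.00, glx = 3.75, hg2 = 4.01),
      passband_full_ppm = c(1.6, 4.2),
      passband_partial_ppm = c(2.7, 4.2),
      stopband_partial_start_ppm = 2.35),
    scheme3 = slow_scheme(
      "scheme3", carrier_full_ppm = 3.00, carrier_partial_ppm = 2.60,
      bandwidth_full_hz = 880, bandwidth_partial_hz = 560, te_s = 0.090,
      targets = c(pe = 3.26, glx = 2.11)))
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) stop(sprintf("unknown scheme '%s'", name))
  sch <- reg[[name]]
  if (!is.null(bandwidth_full_hz)) {
    sch <- slow_scheme(sch$name, sch$carrier_full_ppm, sch$carrier_partial_ppm,
                       bandwidth_full_hz, sch$bandwidth_partial_hz, sch$te_s,
                       sch$targets)
  }
  sch
}

#' Build the CSAP waveform of one band of a scheme
#'
#' Reconstructs the sech pulse for the full or partial band: duration
#' and truncation from the scheme, swept bandwidth from the preset, peak
#' amplitude 100% above the operational adiabatic threshold.
#'
#' @param scheme a [slow_scheme()].
#' @param band `"full"` or `"partial"`.
#' @param n_samples waveform samples (4096 for Bloch profiles; a few
#'   hundred suffice for density-matrix runs).
#' @param omega0 peak nutation rate override (rad/s); default 2x the
#'   adiabatic threshold.
#' @return an [rf_waveform] with the band's carrier offset.
#' @export
csap_for_scheme <- function(scheme, band = c("full", "partial"),
                            n_samples = 4096, omega0 = NA_real_,
                            hz_per_ppm = 297, ref_ppm = 3.0) {
  band <- match.arg(band)
  stopifnot(inherits(scheme, "slow_scheme"))
  bw <- if (band == "full") scheme$bandwidth_full_hz else scheme$bandwidth_partial_hz
  carrier <- if (band == "full") scheme$carrier_full_ppm else scheme$carrier_partial_ppm
  d <- sech_pulse_design(scheme$duration_s, bw, scheme$truncation, omega0)
  make_sech_pulse(d, n_samples,
                  carrier_offset_hz = (carrier - ref_ppm) * hz_per_ppm,
                  label = sprintf("%s %s CSAP", scheme$name, band))
}

#' The non-editing whole-metabolite refocusing pulse
#'
#' The 2pi-CSAP used for plain (non-edited) acquisitions: 31 ms duration,
#' 0.81 kHz swept bandwidth, carrier at 3.0 ppm, refocusing the
#' 1.8-4.2 ppm metabolite range while dephasing water (4.7 ppm) and
#' lipids (0.9-1.3 ppm) symmetrically about the carrier.
#'
#' @param n_samples waveform samples.
#' @param omega0 peak nutation rate override (rad/s); default 2x the
#'   adiabatic threshold.
#' @return an [rf_waveform].
#' @export
csap_epsi_pulse <- function(n_samples = 4096, omega0 = NA_real_) {
  d <- sech_pulse_design(0.031, 810, 0.01, omega0)
  make_sech_pulse(d, n_samples, carrier_offset_hz = 0,
                  label = "2pi-CSAP 31ms/0.81kHz @3.0ppm")
}

#' Simulate J-difference editing of a spin system
#'
#' Runs the SLOW acquisition twice (editing-full and editing-partial
#' CSAP pairs) and forms the difference spectrum. `"glx"` sums separate
#' glutamate and glutamine runs with 2:1 weights.
#'
#' @param system a [spin_system()], or a name accepted by
#'   [mrs_spin_system()] (including `"glx"`).
#' @param scheme a [slow_scheme()] or scheme name.
#' @param b0_offset_ppm global B0 offset (ppm).
#' @param difference `"partial_minus_full"` (default; the edited GABA
#'   multiplet at 3.0 ppm comes out positive for scheme 2 at TE = 68 ms)
#'   or `"full_minus_partial"`.
#' @param n_pulse_samples waveform samples for the density-matrix runs.
#' @param apodization_hz,zero_fill spectral processing, see
#'   [fid_to_spectrum()].
#' @param n_points,sweep_hz acquisition grid.
#' @return object of class `edited_result`: list with `full`, `partial`,
#'   `difference` ([mrs_spectrum]s on one axis), `scheme`, `system_name`.
#' @export
simulate_editing <- function(system, scheme, b0_offset_ppm = 0,
                             difference = c("partial_minus_full",
                                            "full_minus_partial"),
                             n_pulse_samples = 360,
                             apodization_hz = 3, zero_fill = 2,
                             n_points = 512, sweep_hz = 1280) {
  difference <- match.arg(difference)
  if (is.character(scheme)) scheme <- slow_schemes(scheme)
  if (is.character(system) && tolower(system) == "glx") {
    glu <- simulate_editing(mrs_spin_system("glutamate"), scheme,
                            b0_offset_ppm, difference, n_pulse_samples,
                            apodization_hz, zero_fill, n_points, sweep_hz)
    gln <- simulate_editing(mrs_spin_system("glutamine"), scheme,
                            b0_offset_ppm, difference, n_pulse_samples,
                            apodization_hz, zero_fill, n_points, sweep_hz)
    mix <- function(a, b) mrs_spectrum(a$ppm, (2 * a$intensity + b$intensity) / 3,
                                       a$meta)
    out <- list(full = mix(glu$full, gln$full),
                partial = mix(glu$partial, gln$partial),
                difference = mix(glu$difference, gln$difference),
                scheme = scheme, system_name = "Glx (glutamate:glutamine 2:1)")
    return(structure(out, class = "edited_result"))
  }
  if (is.character(system)) system <- mrs_spin_system(system)
  wf <- csap_for_scheme(scheme, "full", n_pulse_samples)
  wp <- csap_for_scheme(scheme, "partial", n_pulse_samples)
  meta <- list(scheme = scheme$name, te_s = scheme$te_s,
               system = system$name, b0_offset_ppm = b0_offset_ppm)
  run <- function(w) {
    f <- run_slow_acquisition(system, w, scheme$te_s,
                              b0_offset_ppm = b0_offset_ppm,
                              n_points = n_points, sweep_hz = sweep_hz)
    fid_to_spectrum(f, apodization_hz, zero_fill, meta)
  }
  full <- run(wf)
  partial <- run(wp)
  dy <- if (difference == "partial_minus_full")
    partial$intensity - full$intensity else full$intensity - partial$intensity
  structure(list(full = full, partial = partial,
                 difference = mrs_spectrum(full$ppm, dy, meta),
                 scheme = scheme, system_name = system$name),
            class = "edited_result")
}

#' @export
print.edited_result <- function(x, ...) {
  cat(sprintf("<edited_result> %s with %s (TE %.0f ms)\n",
              x$system_name, x$scheme$name, 1e3 * x$scheme$te_s))
  invisible(x)
}

#' Editing efficiency in a ppm window
#'
#' Signed in-phase integral of the difference spectrum over the window,
#' normalized by the in-phase integral of the reference partial spectrum
#' (the fully edited in-phase amplitude). The signed integral isolates
#' the edited in-phase component: antiphase terms integrate to ~0 and a
#' subtraction artifact from a resonance lost by the partial band comes
#' out negative rather than inflating the metric.
#'
#' @param result an `edited_result` from [simulate_editing()].
#' @param window_ppm `c(lo, hi)` window around the edited multiplet.
#' @param reference optional [mrs_spectrum] used as the fully-edited
#'   in-phase reference (default: the result's own partial spectrum).
#' @param reference_window_ppm window for the reference integral
#'   (default `window_ppm`).
#' @return efficiency scalar (about 1 for ideal editing at TE = 1/2J).
#' @export
editing_efficiency <- function(result, window_ppm, reference = NULL,
                               reference_window_ppm = window_ppm) {
  stopifnot(inherits(result, "edited_result"))
  if (is.null(reference)) reference <- result$partial
  num <- spectrum_integral(result$difference, window_ppm, "signed")
  den <- spectrum_integral(reference, reference_window_ppm, "signed")
  if (abs(den) < .Machine$double.eps) stop("degenerate reference integral")
  num / den
}

#' Distance from a band edge to a resonance
#'
#' Signed ppm distance from the named edge of an editing band to a
#' resonance; positive means the resonance lies inside the band (beyond
#' the edge in the passband direction) for passband edges, and above the
#' stop-band start for the stop band.
#'
#' @param scheme a [slow_scheme()] or name.
#' @param resonance_ppm resonance position (ppm).
#' @param band `"full"`, `"partial"` or `"stop"` (the upfield stop band
#'   of the partial pulse).
#' @param edge `"lower"` or `"upper"` passband edge (ignored for
#'   `"stop"`).
#' @return signed distance in ppm.
#' @export
#' @examples
#' band_margin(slow_schemes("scheme2"), 1.9, "full", "lower")   # 0.3
band_margin <- function(scheme, resonance_ppm,
                        band = c("full", "partial", "stop"),
                        edge = c("lower", "upper")) {
  if (is.character(scheme)) scheme <- slow_schemes(scheme)
  band <- match.arg(band)
  edge <- match.arg(edge)
  if (band == "stop")   # safety margin of an upfield resonance below the
    return(scheme$stopband_partial_start_ppm - resonance_ppm) # stop band
  pb <- if (band == "full") scheme$passband_full_ppm else scheme$passband_partial_ppm
  if (edge == "lower") resonance_ppm - pb[1] else pb[2] - resonance_ppm
}

#' B0-robustness sweep of the editing efficiency
#'
#' Re-runs [simulate_editing()] with a global ppm shift of all
#' resonances and evaluates the editing efficiency in a window that
#' tracks the shift, against the fixed zero-offset reference amplitude.
#'
#' @param system system (as in [simulate_editing()]).
#' @param scheme a [slow_scheme()] or name.
#' @param delta_b0_grid_ppm offsets to evaluate (|offset| <= 0.7 ppm).
#' @param window_ppm edited-multiplet window at zero offset.
#' @param ... passed to [simulate_editing()].
#' @return data.frame with `delta_b0_ppm`, `efficiency`, `retention`
#'   (efficiency relative to the zero-offset value).
#' @export
b0_robustness_sweep <- function(system, scheme,
                                delta_b0_grid_ppm = seq(-0.2, 0.2, by = 0.1),
                                window_ppm = c(2.8, 3.2), ...) {
  if (any(abs(delta_b0_grid_ppm) > 0.7))
    stop("B0 offsets beyond +/-0.7 ppm are outside the model's remit")
  if (is.character(scheme)) scheme <- slow_schemes(scheme)
  base <- simulate_editing(system, scheme, 0, ...)
  ref <- base$partial
  eff <- vapply(delta_b0_grid_ppm, function(db) {
    res <- if (db == 0) base else simulate_editing(system, scheme, db, ...)
    editing_efficiency(res, window_ppm + db, reference = ref,
                       reference_window_ppm = window_ppm)
  }, numeric(1))
  e0 <- if (0 %in% delta_b0_grid_ppm) eff[match(0, delta_b0_grid_ppm)]
        else editing_efficiency(base, window_ppm)
  data.frame(delta_b0_ppm = delta_b0_grid_ppm, efficiency = eff,
             retention = eff / e0)
}
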