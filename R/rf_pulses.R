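# RF waveform container and the two pulse families used by the sequence:
# the complex hyperbolic-secant adiabatic full-passage refocusing pulse
# and the sinc-Gaussian excitation pulse.

#' RF waveform object
#'
#' A uniformly sampled complex RF envelope. Samples are nutation rates in
#' rad/s: the magnitude is gamma*B1(t) and the phase carries the frequency
#' modulation. The carrier offset positions the pulse on the spectral axis
#' relative to the acquisition reference (3.0 ppm by default).
#'
#' @param samples complex vector, nutation rate per time step (rad/s).
#' @param dt sample interval (s).
#' @param carrier_offset_hz offset of the pulse carrier from the
#'   acquisition reference (Hz); positive = downfield.
#' @param label free-text description.
#' @return object of class `rf_waveform` with fields `samples`, `dt`,
#'   `duration`, `carrier_offset_hz`, `label`.
#' @export
rf_waveform <- function(samples, dt, carrier_offset_hz = 0, label = "") {
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  samples <- as.complex(samples)
  if (any(!is.finite(Re(samples))) || any(!is.finite(Im(samples))))
    stop("waveform samples must be finite")
  if (!is.finite(carrier_offset_hz))
    stop("'carrier_offset_hz' must be finite")
  structure(
    list(samples = samples, dt = dt, duration = length(samples) * dt,
         carrier_offset_hz = carrier_offset_hz, label = label),
    class = "rf_waveform")
}

#' @export
print.rf_waveform <- function(x, ...) {
  cat(sprintf(
    "<rf_waveform> %s\n  %d samples, %.3f ms, peak %.1f rad/s (%.1f Hz), carrier %+.1f Hz\n",
    x$label, length(x$samples), 1e3 * x$duration,
    max(Mod(x$samples)), max(Mod(x$samples)) / (2 * pi), x$carrier_offset_hz))
  invisible(x)
}

#' Sample times of a waveform
#'
#' Midpoint sampling, measured from the pulse centre.
#' @param w an [rf_waveform].
#' @return numeric vector of times (s).
#' @export
waveform_times <- function(w) {
  n <- length(w$samples)
  (seq_len(n) - 0.5) * w$dt - w$duration / 2
}

asech <- function(x) acosh(1 / x)

#' Hyperbolic-secant adiabatic pulse design
#'
#' Parameters of the complex secant-hyperbolic full-passage pulse
#' B1(t) = omega0 * sech(beta*t)^(1 + i*mu), whose magnitude envelope is
#' omega0*sech(beta*t) and whose instantaneous frequency sweeps as
#' -mu*beta*tanh(beta*t) (rad/s). The swept bandwidth obeys the design
#' identity `bandwidth_hz = mu * beta / pi`.
#'
#' `beta` and `mu` are derived from the printed pulse specifications
#' (duration, bandwidth) plus the edge truncation level:
#' `beta = 2*asech(truncation)/duration`, `mu = pi*bandwidth_hz/beta`.
#'
#' @param duration pulse length (s).
#' @param bandwidth_hz swept bandwidth (Hz).
#' @param truncation sech value at the pulse edges, in (0, 1);
#'   default 0.01 (1% edge amplitude).
#' @param omega0 peak nutation rate (rad/s), or `NA` to defer; the pulse
#'   builder then operates the pulse 100% above the adiabatic threshold.
#' @return object of class `sech_design` with fields `duration`,
#'   `bandwidth_hz`, `beta`, `mu`, `omega0`, `truncation`.
#' @seealso [make_sech_pulse()], [sech_adiabatic_omega0()]
#' @export
#' @examples
#' d <- sech_pulse_design(0.024, 880)
#' d$mu * d$beta / pi   # = 880
sech_pulse_design <- function(duration, bandwidth_hz, truncation = 0.01,
                              omega0 = NA_real_) {
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be positive")
  if (!is.finite(bandwidth_hz) || bandwidth_hz <= 0)
    stop("'bandwidth_hz' must be positive")
  if (!is.finite(truncation) || truncation <= 0 || truncation >= 1)
    stop("'truncation' must lie strictly between 0 and 1")
  beta <- 2 * asech(truncation) / duration
  mu <- pi * bandwidth_hz / beta
  structure(
    list(duration = duration, bandwidth_hz = bandwidth_hz, beta = beta,
         mu = mu, omega0 = omega0, truncation = truncation),
    class = "sech_design")
}

#' @export
print.sech_design <- function(x, ...) {
  cat(sprintf(
    "<sech_design> %.1f ms, BW %.0f Hz, beta %.1f rad/s, mu %.2f, omega0 %s\n",
    1e3 * x$duration, x$bandwidth_hz, x$beta, x$mu,
    if (is.na(x$omega0)) "(2x adiabatic threshold)" else sprintf("%.0f rad/s", x$omega0)))
  invisible(x)
}

#' Build the sech adiabatic waveform
#'
#' Samples the complex secant-hyperbolic pulse on a uniform grid. When the
#' design leaves `omega0` unset, the peak amplitude is placed 100% above
#' the operational adiabatic threshold (see [adiabatic_threshold()]).
#'
#' @param design a [sech_pulse_design()].
#' @param n_samples number of samples (>= 256); the default 4096 resolves
#'   the fastest sweep by more than two orders of magnitude.
#' @param carrier_offset_hz carrier position relative to the acquisition
#'   reference (Hz).
#' @param label optional label; default derived from the design.
#' @return an [rf_waveform].
#' @export
make_sech_pulse <- function(design, n_samples = 4096, carrier_offset_hz = 0,
                            label = NULL) {
  stopifnot(inherits(design, "sech_design"))
  if (n_samples < 256) stop("'n_samples' must be at least 256")
  omega0 <- design$omega0
  if (is.na(omega0))
    omega0 <- 2 * sech_adiabatic_omega0(design)
  if (!is.finite(omega0) || omega0 <= 0) stop("'omega0' must be positive")
  dt <- design$duration / n_samples
  # Nyquist guard on the frequency sweep
  fmax <- design$mu * design$beta / (2 * pi)
  if (dt * fmax > 0.5)
    stop("n_samples too small to resolve the frequency sweep (Nyquist)")
  t <- (seq_len(n_samples) - 0.5) * dt - design$duration / 2
  amp <- omega0 / cosh(design$beta * t)
  # sech(beta t)^(1+i mu): phase = -mu*log(cosh(beta t)), the integral of
  # the instantaneous frequency sweep -mu*beta*tanh(beta t)
  phase <- -design$mu * log(cosh(design$beta * t))
  if (is.null(label))
    label <- sprintf("sech %gms/%gHz", 1e3 * design$duration, design$bandwidth_hz)
  rf_waveform(amp * exp(1i * phase), dt, carrier_offset_hz, label)
}

#' Peak amplitude at the adiabatic threshold of a sech design
#'
#' Operational threshold: the smallest peak nutation rate that achieves
#' on-carrier inversion Mz <= `criterion_mz` (default -0.95), located by
#' bisection on a Bloch simulation of the unit-amplitude pulse.
#'
#' @param design a [sech_pulse_design()].
#' @param criterion_mz on-carrier inversion criterion.
#' @param n_samples samples used for the search waveform.
#' @param tol relative bisection tolerance.
#' @return threshold peak nutation rate (rad/s).
#' @export
sech_adiabatic_omega0 <- function(design, criterion_mz = -0.95,
                                  n_samples = 1024, tol = 1e-3) {
  d <- design; d$omega0 <- 1
  w <- make_sech_pulse(d, n_samples = n_samples)
  mz_at <- function(scale) {
    r <- bloch_propagate(w, offset_hz = 0, b1_scale = scale)
    1 - 2 * Mod(r$b)^2
  }
  # bracket: sqrt(mu)*beta is the textbook scale of the threshold
  hi <- sqrt(d$mu) * d$beta
  it <- 0
  while (mz_at(hi) > criterion_mz) {
    hi <- hi * 2; it <- it + 1
    if (it > 20) stop("adiabatic threshold criterion not reached")
  }
  lo <- hi / 2
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (mz_at(mid) <= criterion_mz) hi <- mid else lo <- mid
  }
  hi
}

#' Sinc-Gaussian excitation pulse design
#'
#' The slice-selective excitation pulse
#' B1(t) ∝ sin(pi*t*f)/sin(pi*t) * exp(-b^2*t^2) with t in seconds on a
#' symmetric support. With f = 5500 and b = 400 on t in \[-3, 3\] ms this
#' reproduces the 6-ms, 5.5-kHz excitation used alongside the adiabatic
#' pair. The removable singularity at t = 0 takes its limit value f.
#'
#' @param f sinc frequency parameter (zeros every 1/f s); equals the
#'   excitation bandwidth in Hz.
#' @param b Gaussian width parameter (1/s).
#' @param t_range symmetric support `c(-T/2, T/2)` in seconds.
#' @param flip_deg nominal on-resonance flip angle in degrees, in (0, 180].
#' @return object of class `sinc_gauss_design`.
#' @export
sinc_gauss_design <- function(f = 5500, b = 400, t_range = c(-3e-3, 3e-3),
                              flip_deg = 65) {
  if (length(t_range) != 2L || abs(t_range[1] + t_range[2]) > 1e-12)
    stop("'t_range' must be symmetric about zero")
  if (flip_deg <= 0 || flip_deg > 180) stop("'flip_deg' must be in (0, 180]")
  if (max(abs(t_range)) >= 1)
    stop("support includes non-removable singularities of sin(pi*t)")
  structure(list(f = f, b = b, t_range = t_range, flip_deg = flip_deg),
            class = "sinc_gauss_design")
}

#' Build the sinc-Gaussian excitation waveform
#'
#' @param design a [sinc_gauss_design()].
#' @param n_samples number of samples.
#' @param carrier_offset_hz carrier position (Hz, relative to reference).
#' @return an [rf_waveform], scaled so the on-resonance flip angle
#'   (time integral of the nutation rate) equals `flip_deg`.
#' @export
make_sinc_gauss_pulse <- function(design, n_samples = 4096,
                                  carrier_offset_hz = 0) {
  stopifnot(inherits(design, "sinc_gauss_design"))
  dur <- diff(design$t_range)
  dt <- dur / n_samples
  t <- (seq_len(n_samples) - 0.5) * dt + design$t_range[1]
  ratio <- ifelse(abs(t) < 1e-12, design$f,
                  sin(pi * t * design$f) / sin(pi * t))
  env <- ratio * exp(-design$b^2 * t^2)
  flip_rad <- design$flip_deg * pi / 180
  env <- env * flip_rad / (sum(env) * dt)
  rf_waveform(env, dt, carrier_offset_hz,
              sprintf("sinc-gauss %gms/%gHz", 1e3 * dur, design$f))
}

#' Waveform energy
#'
#' Time integral of the squared nutation rate, `sum(|samples|^2) * dt`
#' (rad^2/s). Additive over concatenation and quadratic in amplitude;
#' the relative SAR of two pulses on the same coil/load is the ratio of
#' their energies.
#'
#' @param w an [rf_waveform].
#' @return energy-like scalar (rad^2/s).
#' @export
pulse_energy <- function(w) {
  stopifnot(inherits(w, "rf_waveform"))
  sum(Mod(w$samples)^2) * w$dt
}

#' Waveform peak power
#'
#' Maximum squared nutation rate, `max(|samples|^2)` (rad^2/s^2).
#'
#' @param w an [rf_waveform].
#' @return peak power scalar (rad^2/s^2).
#' @export
peak_power <- function(w) {
  stopifnot(inherits(w, "rf_waveform"))
  max(Mod(w$samples)^2)
}

#' Unwrapped phase and instantaneous frequency of a waveform
#'
#' @param w an [rf_waveform].
#' @return data.frame with `t` (s from pulse centre), `phase` (rad,
#'   unwrapped) and `freq_hz` (central-difference instantaneous frequency).
#' @export
waveform_phase <- function(w) {
  ph <- Arg(w$samples)
  dp <- diff(ph)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  ph <- cumsum(c(ph[1], dp))
  t <- waveform_times(w)
  n <- length(ph)
  freq <- rep(NA_real_, n)
  if (n > 2) freq[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / (2 * w$dt) / (2 * pi)
  data.frame(t = t, phase = ph, freq_hz = freq)
}
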