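# Density-matrix simulation of J-coupled spin systems through the SLOW
# double-echo sequence: ideal (or shaped) excitation, a pair of identical
# chemical-shift-selective adiabatic refocusing pulses with ideal
# coherence-pathway (crusher) selection, and analytic acquisition.
# Relaxation-free throughout.

pauli_half <- function() {
  list(x = matrix(c(0, 0.5, 0.5, 0), 2),
       y = matrix(c(0, 0.5i, -0.5i, 0), 2),
       z = matrix(c(0.5, 0, 0, -0.5), 2))
}

#' Product-operator basis for an n-spin system
#'
#' Single-spin Cartesian operators Ix, Iy, Iz in the 2^n-dimensional
#' Zeeman product basis, plus the totals Fx, Fy, Fz and the raising
#' operator F+ weighted by signal multiplicities.
#'
#' @param system a [spin_system()] (or a spin count).
#' @return list with per-spin operator lists and totals; cached fields
#'   `m` (Zeeman quantum numbers, diagonal of Fz) used for coherence
#'   filtering.
#' @export
spin_operators <- function(system) {
  n <- if (inherits(system, "spin_system")) length(system$shifts_ppm)
       else as.integer(system)
  mult <- if (inherits(system, "spin_system")) system$multiplicities
          else rep(1, n)
  s <- pauli_half()
  id <- diag(2)
  kr <- function(ops) Reduce(kronecker, ops)
  one <- function(k, op) kr(lapply(seq_len(n), function(j) if (j == k) op else id))
  Ix <- lapply(seq_len(n), one, op = s$x)
  Iy <- lapply(seq_len(n), one, op = s$y)
  Iz <- lapply(seq_len(n), one, op = s$z)
  Fx <- Reduce(`+`, Ix); Fy <- Reduce(`+`, Iy); Fz <- Reduce(`+`, Iz)
  Fplus <- Reduce(`+`, lapply(seq_len(n), function(k)
    mult[k] * (Ix[[k]] + 1i * Iy[[k]])))
  list(n = n, Ix = Ix, Iy = Iy, Iz = Iz, Fx = Fx, Fy = Fy, Fz = Fz,
       Fplus = Fplus, m = Re(diag(Fz)))
}

#' Rotating-frame Hamiltonian of a spin system
#'
#' H = sum_k 2*pi*(shift_k + b0 - ref)*hz_per_ppm * Ikz
#'   + sum_(k<l) 2*pi*J_kl * (Ik . Il)
#' in rad/s, with the full (strong-coupling) scalar product.
#'
#' @param system a [spin_system()].
#' @param b0_offset_ppm global B0 offset applied to all spins (ppm).
#' @param ops optional precomputed [spin_operators()].
#' @param hz_per_ppm,ref_ppm frequency scale (see [slow_constants()]).
#' @return Hermitian complex matrix (rad/s).
#' @export
sys_hamiltonian <- function(system, b0_offset_ppm = 0, ops = NULL,
                            hz_per_ppm = 297, ref_ppm = 3.0) {
  stopifnot(inherits(system, "spin_system"))
  if (is.null(ops)) ops <- spin_operators(system)
  n <- ops$n
  H <- matrix(0i, 2^n, 2^n)
  off <- 2 * pi * (system$shifts_ppm + b0_offset_ppm - ref_ppm) * hz_per_ppm
  for (k in seq_len(n)) H <- H + off[k] * ops$Iz[[k]]
  if (n > 1) {
    for (k in seq_len(n - 1)) for (l in (k + 1):n) {
      J <- system$j_hz[k, l]
      if (J != 0)
        H <- H + 2 * pi * J * (ops$Ix[[k]] %*% ops$Ix[[l]] +
                               ops$Iy[[k]] %*% ops$Iy[[l]] +
                               ops$Iz[[k]] %*% ops$Iz[[l]])
    }
  }
  H
}

expm_herm <- function(H, t) {
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% (exp(-1i * e$values * t) * Conj(t(e$vectors)))
}

#' Unitary evolution of a density operator
#'
#' rho -> U rho U' with U = exp(-i H t); trace, Hermiticity and the
#' eigenvalue spectrum are preserved.
#'
#' @param rho density operator (complex matrix).
#' @param H Hermitian Hamiltonian (rad/s).
#' @param t evolution time (s), >= 0 allowed 0.
#' @return evolved density operator.
#' @export
evolve_rho <- function(rho, H, t) {
  if (!all(dim(rho) == dim(H))) stop("dimension mismatch")
  if (t == 0) return(rho)
  U <- expm_herm(H, t)
  U %*% rho %*% Conj(t(U))
}

#' Coherence-order projection (ideal crusher model)
#'
#' Retains only the density-operator elements of total coherence order
#' `p` (difference of Zeeman quantum numbers). Emulates ideal spoiler
#' selection of one coherence pathway.
#'
#' @param rho density operator.
#' @param m Zeeman quantum numbers (diagonal of Fz).
#' @param p coherence order to keep.
#' @return filtered density operator.
#' @export
coherence_project <- function(rho, m, p) {
  rho * (abs(outer(m, m, `-`) - p) < 1e-9)
}

#' Apply a shaped RF pulse to a density operator
#'
#' Piecewise-constant propagation including the chemical-shift and J
#' terms during the pulse (the adiabatic pulses span a large fraction of
#' the echo time, so intra-pulse evolution matters). The pulse carrier
#' offset is folded into the sample phases; time runs over the pulse's
#' own support.
#'
#' @param rho density operator.
#' @param system a [spin_system()].
#' @param w an [rf_waveform].
#' @param b1_scale nutation-rate scale.
#' @param H0 optional precomputed [sys_hamiltonian()].
#' @param ops optional precomputed [spin_operators()].
#' @return evolved density operator.
#' @seealso [shaped_pulse_propagator()] to reuse the propagator.
#' @export
apply_shaped_pulse <- function(rho, system, w, b1_scale = 1, H0 = NULL,
                               ops = NULL) {
  U <- shaped_pulse_propagator(system, w, b1_scale, H0, ops)
  U %*% rho %*% Conj(t(U))
}

#' Total propagator of a shaped pulse for a spin system
#'
#' @inheritParams apply_shaped_pulse
#' @return unitary complex matrix.
#' @export
shaped_pulse_propagator <- function(system, w, b1_scale = 1, H0 = NULL,
                                    ops = NULL, hz_per_ppm = 297,
                                    ref_ppm = 3.0) {
  stopifnot(inherits(w, "rf_waveform"))
  if (is.null(ops)) ops <- spin_operators(system)
  if (is.null(H0)) H0 <- sys_hamiltonian(system, 0, ops, hz_per_ppm, ref_ppm)
  # Nyquist guard: per-step rotation must stay well under half a turn
  fmax <- (max(Mod(w$samples)) * b1_scale + max(Mod(diag(H0))) +
           2 * pi * abs(w$carrier_offset_hz)) / (2 * pi)
  if (w$dt * fmax > 0.45)
    stop("pulse waveform too coarsely sampled for this spin system (Nyquist)")
  tvec <- waveform_times(w) + w$duration / 2 # time from pulse start
  s <- w$samples * b1_scale * exp(1i * 2 * pi * w$carrier_offset_hz * tvec)
  U <- diag(nrow(H0))
  for (k in seq_along(s)) {
    Hk <- H0 + Re(s[k]) * ops$Fx + Im(s[k]) * ops$Fy
    U <- expm_herm(Hk, w$dt) %*% U
  }
  U
}

#' Free induction decay container
#'
#' @param signal complex time-domain samples.
#' @param dwell dwell time (s).
#' @param ref_ppm chemical shift mapped to 0 Hz offset.
#' @return object of class `fid`.
#' @export
fid <- function(signal, dwell, ref_ppm = 3.0) {
  if (!is.finite(dwell) || dwell <= 0) stop("dwell must be positive")
  if (any(!is.finite(Mod(signal)))) stop("FID samples must be finite")
  structure(list(signal = as.complex(signal), dwell = dwell,
                 ref_ppm = ref_ppm), class = "fid")
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("<fid> %d points, dwell %.4g s (sweep %.0f Hz)\n",
              length(x$signal), x$dwell, 1 / x$dwell))
  invisible(x)
}

# analytic FID: rho expressed in the H0 eigenbasis evolves with phase
# factors exp(-i(l_i - l_j)t); the detected signal collects the order -1
# coefficients. Chunked to bound memory for 6-7 spin systems.
# The raw trace grows with the Hilbert-space dimension (the partner
# spins' identity factors); amplitudes are normalized so one fully
# excited, fully refocused unit-multiplicity proton contributes 1,
# making amplitudes comparable across systems of different size.
acquire_fid <- function(rho, H0, ops, n_points, dwell, ref_ppm = 3.0) {
  norm <- 2^(2 - ops$n)
  e <- eigen(H0, symmetric = TRUE)
  V <- e$vectors
  rt <- Conj(t(V)) %*% rho %*% V
  Ft <- Conj(t(V)) %*% ops$Fplus %*% V
  C <- t(Ft) * rt                       # c_ij = F+[j,i] * rho[i,j]
  keep <- which(Mod(C) > 1e-12, arr.ind = TRUE)
  if (nrow(keep) == 0)
    return(fid(complex(real = numeric(n_points)), dwell, ref_ppm))
  co <- C[keep]
  fr <- -(e$values[keep[, 1]] - e$values[keep[, 2]])  # rad/s
  tv <- (seq_len(n_points) - 1) * dwell
  sig <- complex(real = numeric(n_points))
  chunk <- max(1L, floor(2e6 / length(co)))
  for (i0 in seq(1L, n_points, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n_points)
    sig[idx] <- as.vector(crossprod(exp(outer(fr, tv[idx], function(f, tt)
      1i * f * tt)), co))
  }
  fid(sig * norm, dwell, ref_ppm)
}

#' Run the SLOW double-echo acquisition
#'
#' Sequence: 90-degree excitation -> tau/2 -> CSAP -> tau -> CSAP ->
#' tau/2 -> acquire, with tau = (TE - 2*Tp)/2 so that delays plus pulse
#' durations fill the echo time and the echo tops at acquisition start.
#' Ideal coherence-pathway filtering is applied around each refocusing
#' pulse (order -1 after excitation, +1 between the pulses, -1 at
#' acquisition), emulating the spoiler pairs; unrefocused magnetization
#' is thereby dephased, which is the mechanism of the implicit water and
#' lipid suppression.
#'
#' @param system a [spin_system()].
#' @param pulse the CSAP [rf_waveform] (used for both refocusing pulses),
#'   or `NULL` with `refocusing = "ideal"`.
#' @param te_s total echo time (s).
#' @param b1_scale nutation-rate scale applied to the refocusing pulses.
#' @param excitation `"ideal"` (instantaneous 90 degrees, the default) or
#'   an [rf_waveform] such as the sinc-Gaussian pulse.
#' @param refocusing `"csap"` (shaped pulse with intra-pulse evolution)
#'   or `"ideal"` (instantaneous 180 degrees; used by the closed-form
#'   J-modulation oracles).
#' @param b0_offset_ppm global B0 offset (ppm).
#' @param n_points,sweep_hz acquisition grid (defaults 1024 points,
#'   1.28 kHz).
#' @param return_state also return the density operator at acquisition
#'   start (field `rho`).
#' @return an [fid]; with `return_state = TRUE` a list with `fid`, `rho`,
#'   `H0`, `ops`.
#' @export
run_slow_acquisition <- function(system, pulse, te_s, b1_scale = 1,
                                 excitation = "ideal",
                                 refocusing = c("csap", "ideal"),
                                 b0_offset_ppm = 0,
                                 n_points = 1024, sweep_hz = 1280,
                                 return_state = FALSE,
                                 hz_per_ppm = 297, ref_ppm = 3.0) {
  refocusing <- match.arg(refocusing)
  stopifnot(inherits(system, "spin_system"))
  if (n_points < 1 || sweep_hz <= 0) stop("invalid acquisition window")
  ops <- spin_operators(system)
  H0 <- sys_hamiltonian(system, b0_offset_ppm, ops, hz_per_ppm, ref_ppm)
  tp <- if (refocusing == "csap") {
    stopifnot(inherits(pulse, "rf_waveform"))
    pulse$duration
  } else 0
  tau <- (te_s - 2 * tp) / 2
  if (tau < 0) stop("timing budget violated: TE shorter than the two pulses")
  # excitation
  rho <- ops$Fz
  if (identical(excitation, "ideal")) {
    U <- expm_herm(ops$Fy, pi / 2)
    rho <- U %*% rho %*% Conj(t(U))
  } else {
    stopifnot(inherits(excitation, "rf_waveform"))
    rho <- apply_shaped_pulse(rho, system, excitation, 1, H0, ops)
  }
  rho <- coherence_project(rho, ops$m, -1)
  Up <- if (refocusing == "csap") {
    shaped_pulse_propagator(system, pulse, b1_scale, H0, ops,
                            hz_per_ppm, ref_ppm)
  } else expm_herm(ops$Fx, pi)
  rho <- evolve_rho(rho, H0, tau / 2)
  rho <- Up %*% rho %*% Conj(t(Up))
  rho <- coherence_project(rho, ops$m, +1)
  rho <- evolve_rho(rho, H0, tau)
  rho <- Up %*% rho %*% Conj(t(Up))
  rho <- coherence_project(rho, ops$m, -1)
  rho <- evolve_rho(rho, H0, tau / 2)
  out <- acquire_fid(rho, H0, ops, n_points, 1 / sweep_hz, ref_ppm)
  if (return_state) list(fid = out, rho = rho, H0 = H0, ops = ops) else out
}

#' Spectrum container
#'
#' @param ppm ppm axis (strictly monotone, stored descending for
#'   conventional display).
#' @param intensity complex spectral intensity, same length as `ppm`.
#' @param meta named list of metadata (scheme, TE, system, ...).
#' @return object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(ppm, intensity, meta = list()) {
  if (length(ppm) != length(intensity)) stop("axis/intensity length mismatch")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  if (d[1] > 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(ppm = ppm, intensity = as.complex(intensity), meta = meta),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, %.2f..%.2f ppm\n",
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Fourier transform an FID to a spectrum
#'
#' Exponential apodization, first-point halving, zero filling and DFT;
#' the frequency axis is mapped to ppm with 0 Hz at the acquisition
#' reference. Halving the first point removes the constant baseline a
#' one-sided DFT otherwise spreads across all bins, so absorption lines
#' sit on a flat zero baseline; the DFT identity then reads
#' mean(spectrum) = (apodized first FID point) / 2.
#'
#' @param x an [fid].
#' @param apodization_hz exponential line broadening (Lorentzian FWHM
#'   added to every line), >= 0.
#' @param zero_fill integer zero-filling factor >= 1.
#' @param meta metadata list passed to the spectrum.
#' @return an [mrs_spectrum].
#' @export
fid_to_spectrum <- function(x, apodization_hz = 3, zero_fill = 2,
                            meta = list(), hz_per_ppm = 297) {
  stopifnot(inherits(x, "fid"))
  if (apodization_hz < 0) stop("'apodization_hz' must be >= 0")
  if (zero_fill < 1) stop("'zero_fill' must be >= 1")
  n <- length(x$signal)
  tv <- (seq_len(n) - 1) * x$dwell
  sig <- x$signal * exp(-pi * apodization_hz * tv)
  sig[1] <- sig[1] / 2
  N <- n * as.integer(zero_fill)
  sig <- c(sig, complex(real = numeric(N - n)))
  sp <- stats::fft(sig)
  f <- ((seq_len(N) - 1 + N %/% 2) %% N - N %/% 2) / (N * x$dwell)
  ord <- order(f)
  mrs_spectrum(x$ref_ppm + f[ord] / hz_per_ppm, sp[ord], meta)
}

#' Integrate a spectrum over a ppm window
#'
#' @param spec an [mrs_spectrum].
#' @param window_ppm `c(lo, hi)` window.
#' @param mode `"signed"` (sum of real parts, the in-phase integral) or
#'   `"magnitude"`.
#' @return scalar integral (per-bin sum; bins are uniform).
#' @export
spectrum_integral <- function(spec, window_ppm,
                              mode = c("signed", "magnitude")) {
  mode <- match.arg(mode)
  if (length(window_ppm) != 2L) stop("window must be c(lo, hi)")
  lo <- min(window_ppm); hi <- max(window_ppm)
  i <- spec$ppm >= lo & spec$ppm <= hi
  if (!any(i)) stop("empty integration window")
  if (mode == "signed") sum(Re(spec$intensity[i]))
  else sum(Mod(spec$intensity[i]))
}
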