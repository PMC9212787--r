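# Single spin-1/2 response of a waveform: SU(2) propagation over offset
# and B1-scale grids, inversion/refocusing profiles, adiabatic threshold.

#' Propagate a waveform for a single spin-1/2
#'
#' Piecewise-constant solution of the Bloch/Schroedinger equation in the
#' rotating frame. The net rotation is returned as Cayley-Klein (SU(2))
#' parameters (a, b) with |a|^2 + |b|^2 = 1. Starting from equilibrium,
#' the longitudinal response is Mz = 1 - 2|b|^2; a refocusing pulse
#' transfers the fraction |b^2| of transverse magnetization to the
#' conjugate coherence.
#'
#' @param w an [rf_waveform].
#' @param offset_hz frequency offset(s) of the spin relative to the
#'   acquisition reference (Hz); may be a vector.
#' @param b1_scale multiplicative nutation-rate factor (dimensionless).
#' @return object of class `spin_rotation`: list with complex vectors
#'   `a`, `b` (one element per offset) and the input grids.
#' @export
bloch_propagate <- function(w, offset_hz, b1_scale = 1) {
  stopifnot(inherits(w, "rf_waveform"))
  if (any(!is.finite(offset_hz)) || !is.finite(b1_scale))
    stop("offsets and b1_scale must be finite")
  wx <- Re(w$samples) * b1_scale
  wy <- Im(w$samples) * b1_scale
  dz <- 2 * pi * (offset_hz - w$carrier_offset_hz)
  dt <- w$dt
  a <- rep(1 + 0i, length(offset_hz))
  b <- rep(0 + 0i, length(offset_hz))
  for (k in seq_along(wx)) {
    Om <- sqrt(wx[k]^2 + wy[k]^2 + dz^2)
    phi <- Om * dt
    sinc2 <- ifelse(Om > 0, sin(phi / 2) / Om, dt / 2)
    ak <- cos(phi / 2) - 1i * dz * sinc2
    bk <- -1i * (wx[k] + 1i * wy[k]) * sinc2
    anew <- ak * a - Conj(bk) * b
    b <- bk * a + Conj(ak) * b
    a <- anew
  }
  structure(list(a = a, b = b, offset_hz = offset_hz, b1_scale = b1_scale),
            class = "spin_rotation")
}

#' @export
print.spin_rotation <- function(x, ...) {
  cat(sprintf("<spin_rotation> %d offset(s), b1_scale %.3g\n",
              length(x$a), x$b1_scale))
  invisible(x)
}

new_response_profile <- function(offsets_hz, b1_scales, mz, efficiency,
                                 pair_transfer = NULL, pair_phase = NULL) {
  if (is.unsorted(offsets_hz, strictly = TRUE))
    stop("offset grid must be strictly increasing")
  structure(list(offsets_hz = offsets_hz, b1_scales = b1_scales, mz = mz,
                 refocusing_efficiency = efficiency,
                 pair_transfer = pair_transfer, pair_phase = pair_phase),
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("<response_profile> %d offsets x %d B1 scale(s)\n",
              length(x$offsets_hz), length(x$b1_scales)))
  invisible(x)
}

#' Inversion profile of a waveform
#'
#' Longitudinal response Mz(offset) starting from +z,
#' Mz = 1 - 2|b(offset)|^2.
#'
#' @param w an [rf_waveform].
#' @param offsets_hz strictly increasing offset grid (Hz, relative to the
#'   acquisition reference).
#' @param b1_scale nutation-rate scale factor.
#' @return a `response_profile` with `mz` filled (matrix offsets x scales
#'   when `b1_scale` is a vector, otherwise a vector).
#' @export
inversion_profile <- function(w, offsets_hz, b1_scale = 1) {
  vals <- sapply(b1_scale, function(s) {
    r <- bloch_propagate(w, offsets_hz, s)
    1 - 2 * Mod(r$b)^2
  })
  if (length(b1_scale) == 1L) vals <- drop(vals)
  new_response_profile(offsets_hz, b1_scale, mz = vals,
                       efficiency = NULL)
}

#' Refocusing profile of a waveform or phase-compensated pair
#'
#' Per-pulse refocusing efficiency |b(offset)^2| (the fraction of
#' transverse magnetization conjugated by one pulse). For `pair = TRUE`
#' the profile additionally carries the fraction transferred by the
#' identical two-pulse pair through ideal crusher selection,
#' `pair_transfer = |b^2|^2`, and the net refocusing phase of the pair,
#' which the phase compensation drives to zero across the passband.
#'
#' @param w an [rf_waveform].
#' @param offsets_hz strictly increasing offset grid (Hz).
#' @param b1_scale nutation-rate scale factor (scalar).
#' @param pair compute pair quantities as well.
#' @return a `response_profile` with `refocusing_efficiency` (and for
#'   pairs `pair_transfer`, `pair_phase`) plus `mz`.
#' @export
refocusing_profile <- function(w, offsets_hz, b1_scale = 1, pair = TRUE) {
  r <- bloch_propagate(w, offsets_hz, b1_scale)
  b2 <- r$b^2
  eff <- Mod(b2)
  pt <- pp <- NULL
  if (pair) {
    # pair transfer: M+ -> Conj(b2)*Conj(M+) applied twice -> Conj(b2)*b2*M+
    amp <- Conj(b2) * b2
    pt <- Mod(amp)
    pp <- Arg(amp)
  }
  new_response_profile(offsets_hz, b1_scale, mz = 1 - 2 * Mod(r$b)^2,
                       efficiency = eff, pair_transfer = pt, pair_phase = pp)
}

#' Operational adiabatic threshold of a refocusing waveform
#'
#' Smallest B1 scale on a grid for which the on-carrier inversion reaches
#' `criterion_mz`. The pulse amplitude is "100% above the adiabatic
#' threshold" when driven at twice the returned scale.
#'
#' @param w an [rf_waveform].
#' @param criterion_mz on-carrier Mz criterion (default -0.95).
#' @param scale_grid increasing grid of candidate B1 scales.
#' @return the smallest passing scale (same units as `scale_grid`).
#' @export
adiabatic_threshold <- function(w, criterion_mz = -0.95,
                                scale_grid = seq(0.05, 4, by = 0.05)) {
  if (is.unsorted(scale_grid)) stop("'scale_grid' must be increasing")
  mz <- vapply(scale_grid, function(s) {
    r <- bloch_propagate(w, 0, s)
    1 - 2 * Mod(r$b)^2
  }, numeric(1))
  ok <- which(mz <= criterion_mz)
  if (!length(ok))
    stop("inversion criterion not reached on the supplied scale grid")
  scale_grid[ok[1]]
}

#' Export a response profile as long-format CSV
#'
#' Columns: offset_hz, b1_scale, mz, efficiency, pair_transfer.
#' @param profile a `response_profile`.
#' @param path output file.
#' @return the data.frame, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "response_profile"))
  grid <- expand.grid(offset_hz = profile$offsets_hz,
                      b1_scale = profile$b1_scales)
  df <- data.frame(
    offset_hz = grid$offset_hz, b1_scale = grid$b1_scale,
    mz = as.vector(profile$mz),
    efficiency = if (is.null(profile$refocusing_efficiency)) NA_real_
                 else as.vector(profile$refocusing_efficiency),
    pair_transfer = if (is.null(profile$pair_transfer)) NA_real_
                    else as.vector(profile$pair_transfer))
  write_num_csv(df, path)
  invisible(df)
}

#' Plot a response profile to a PNG file
#'
#' @param profile a `response_profile`.
#' @param path output PNG path.
#' @param what `"mz"` or `"efficiency"`.
#' @return `path`, invisibly.
#' @export
plot_profile_png <- function(profile, path, what = c("mz", "efficiency")) {
  what <- match.arg(what)
  y <- if (what == "mz") profile$mz else profile$refocusing_efficiency
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::plot(profile$offsets_hz, y, type = "l",
                 xlab = "offset (Hz)", ylab = what)
  graphics::abline(h = 0, lty = 3)
  invisible(path)
}
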