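# Shared fixtures: reconstructed scheme-2 pulses are expensive to design
# (adiabatic-threshold bisection), so they are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

scheme2 <- function() slow_schemes("scheme2")

csap_full <- function(n_samples = 4096) {
  cached(paste0("full", n_samples),
         csap_for_scheme(scheme2(), "full", n_samples))
}

csap_partial <- function(n_samples = 4096) {
  cached(paste0("partial", n_samples),
         csap_for_scheme(scheme2(), "partial", n_samples))
}

# pair refocusing profile of the full band over the metabolite range
full_pair_profile <- function() {
  cached("full_profile", {
    w <- csap_full()
    offs <- seq(-700, 700, by = 2) + w$carrier_offset_hz
    refocusing_profile(w, offs, b1_scale = 1, pair = TRUE)
  })
}

profile_at_ppm <- function(profile, ppm, what = "refocusing_efficiency") {
  stats::approx(profile$offsets_hz, profile[[what]], ppm_to_hz(ppm))$y
}

# coefficient of a product operator in rho under the trace inner product
op_coefficient <- function(rho, op) {
  sum(diag(Conj(t(op)) %*% rho)) / sum(diag(Conj(t(op)) %*% op))
}

# two-spin AX system
ax_system <- function(ppm_a, ppm_x, j_hz = 7.35) {
  spin_system("AX", c(ppm_a, ppm_x), j_hz)
}

# J-evolution reversal interval of a CSAP for two resonances: the time
# between the sweep's crossings of the two offsets (per pulse)
sweep_crossing_gap <- function(w, design, ppm1, ppm2) {
  tt <- function(ppm) {
    x <- 2 * pi * (ppm_to_hz(ppm) - w$carrier_offset_hz) /
      (design$mu * design$beta)
    atanh(max(min(x, 1 - 1e-12), -1 + 1e-12)) / design$beta
  }
  abs(tt(ppm1) - tt(ppm2))
}
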