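#' Field constants for 7 T proton MRS
#'
#' All frequency/ppm conversions in the package use a proton ppm scale
#' anchored at the acquisition reference of 3.0 ppm, with 1 ppm = 297 Hz
#' at B0 = 7 T. Positive frequency offsets are downfield (higher ppm).
#'
#' @return Named list with `hz_per_ppm` (297), `ref_ppm` (3.0) and the
#'   default acquisition settings (`sweep_hz` = 1280, `n_points` = 1024).
#' @export
#' @examples
#' slow_constants()$hz_per_ppm
slow_constants <- function() {
  list(hz_per_ppm = 297, ref_ppm = 3.0, sweep_hz = 1280, n_points = 1024)
}

#' Convert a chemical shift to a frequency offset
#'
#' @param ppm chemical shift(s) on the proton scale.
#' @param hz_per_ppm Hz per ppm (297 at 7 T).
#' @param ref_ppm acquisition reference shift (0 Hz offset).
#' @return offset(s) in Hz; positive = downfield of the reference.
#' @export
ppm_to_hz <- function(ppm, hz_per_ppm = 297, ref_ppm = 3.0) {
  (ppm - ref_ppm) * hz_per_ppm
}

#' @rdname ppm_to_hz
#' @param hz frequency offset(s) in Hz relative to the reference.
#' @export
hz_to_ppm <- function(hz, hz_per_ppm = 297, ref_ppm = 3.0) {
  ref_ppm + hz / hz_per_ppm
}
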