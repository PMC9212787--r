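# J-coupled spin systems of the edited brain metabolites.
# Chemical shifts (ppm) and scalar couplings (Hz) are standard literature
# values for the proton spin systems; heteronuclear couplings (e.g. the
# 31P couplings of phosphorylethanolamine) are not modelled.

#' Construct a spin system
#'
#' @param name metabolite or system name.
#' @param shifts_ppm per-spin chemical shifts (ppm, proton scale).
#' @param j_hz symmetric scalar-coupling matrix (Hz) with zero diagonal;
#'   a single number is accepted for two-spin systems.
#' @param multiplicities per-spin signal multiplicity (number of
#'   magnetically equivalent protons represented by the spin); used only
#'   to scale detected amplitudes of uncoupled groups.
#' @return object of class `spin_system`.
#' @export
#' @examples
#' ax <- spin_system("AX", c(1.9, 3.0), 7.35)
spin_system <- function(name, shifts_ppm, j_hz = NULL,
                        multiplicities = NULL) {
  n <- length(shifts_ppm)
  if (n < 1 || n > 8) stop("spin systems with 1..8 spins are supported")
  if (any(shifts_ppm < 0 | shifts_ppm > 10))
    stop("chemical shifts must lie in [0, 10] ppm")
  if (is.null(j_hz)) j_hz <- matrix(0, n, n)
  if (length(j_hz) == 1L && n == 2L)
    j_hz <- matrix(c(0, j_hz, j_hz, 0), 2, 2)
  j_hz <- as.matrix(j_hz)
  if (!all(dim(j_hz) == c(n, n))) stop("coupling matrix dimension mismatch")
  if (any(abs(j_hz - t(j_hz)) > 1e-9)) stop("coupling matrix must be symmetric")
  if (any(abs(diag(j_hz)) > 0)) stop("coupling matrix must have zero diagonal")
  if (is.null(multiplicities)) multiplicities <- rep(1, n)
  structure(list(name = name, shifts_ppm = as.numeric(shifts_ppm),
                 j_hz = j_hz, multiplicities = multiplicities),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %s: %d spin(s) at %s ppm\n", x$name,
              length(x$shifts_ppm),
              paste(sprintf("%.2f", x$shifts_ppm), collapse = ", ")))
  invisible(x)
}

sym_j <- function(n, ...) {
  J <- matrix(0, n, n)
  for (e in list(...)) {
    J[e[1], e[2]] <- e[3]; J[e[2], e[1]] <- e[3]
  }
  J
}

#' Built-in metabolite spin systems
#'
#' Registry of the proton spin systems relevant to the three editing
#' schemes: GABA, 2-hydroxyglutarate (2HG), glutamate, glutamine,
#' phosphorylethanolamine (PE), lactate, creatine, glycine and NAA.
#' "glx" is not a single system: use [simulate_editing()] which sums
#' glutamate and glutamine 2:1.
#'
#' @param name system name (case-insensitive); omit for the full list of
#'   available names.
#' @return a [spin_system()], or a character vector of names.
#' @export
#' @examples
#' mrs_spin_system("gaba")
#' mrs_spin_system()
mrs_spin_system <- function(name = NULL) {
  reg <- list(
    gaba = spin_system(
      "GABA",
      c(3.0128, 3.0128, 1.8890, 1.8890, 2.2840, 2.2840),
      sym_j(6, c(1, 2, -12.021), c(1, 3, 5.372), c(1, 4, 7.127),
            c(2, 3, 10.578), c(2, 4, 6.982), c(3, 4, -13.121),
            c(3, 5, 7.755), c(3, 6, 7.432), c(4, 5, 6.173),
            c(4, 6, 7.933), c(5, 6, -10.744))),
    hg2 = spin_system(
      "2HG",
      c(4.0130, 1.8250, 1.9770, 2.2210, 2.2720),
      sym_j(5, c(1, 2, 7.83), c(1, 3, 4.13), c(2, 3, -14.28),
            c(2, 4, 5.30), c(2, 5, 10.58), c(3, 4, 10.85),
            c(3, 5, 6.06), c(4, 5, -15.00))),
    glutamate = spin_system(
      "glutamate",
      c(3.7433, 2.0375, 2.1200, 2.3378, 2.3520),
      sym_j(5, c(1, 2, 7.331), c(1, 3, 4.651), c(2, 3, -14.849),
            c(2, 4, 6.413), c(2, 5, 8.406), c(3, 4, 8.478),
            c(3, 5, 6.875), c(4, 5, -15.915))),
    glutamine = spin_system(
      "glutamine",
      c(3.7570, 2.1290, 2.1090, 2.4320, 2.4540),
      sym_j(5, c(1, 2, 5.847), c(1, 3, 6.500), c(2, 3, -14.504),
            c(2, 4, 9.165), c(2, 5, 6.347), c(3, 4, 6.324),
            c(3, 5, 9.209), c(4, 5, -15.371))),
    pe = spin_system(
      "PE",
      c(3.9765, 3.9765, 3.2157, 3.2157),
      sym_j(4, c(1, 2, -14.560), c(1, 3, 6.716), c(1, 4, 7.088),
            c(2, 3, 7.088), c(2, 4, 6.716), c(3, 4, -16.260))),
    lactate = spin_system(
      "lactate", c(4.0974, 1.3142), 6.933, multiplicities = c(1, 3)),
    creatine = spin_system(
      "creatine", c(3.0270, 3.9130), multiplicities = c(3, 2)),
    glycine = spin_system("glycine", 3.5480, multiplicities = 2),
    naa = spin_system(
      "NAA",
      c(2.0080, 4.3817, 2.6727, 2.4863),
      sym_j(4, c(2, 3, 3.861), c(2, 4, 9.821), c(3, 4, -15.592)),
      multiplicities = c(3, 1, 1, 1))
  )
  if (is.null(name)) return(names(reg))
  key <- tolower(name)
  if (key %in% c("2hg", "hg")) key <- "hg2"
  if (key %in% c("glu")) key <- "glutamate"
  if (key %in% c("gln")) key <- "glutamine"
  if (key %in% c("cr")) key <- "creatine"
  if (key %in% c("gly")) key <- "glycine"
  if (key %in% c("lac")) key <- "lactate"
  if (!key %in% names(reg))
    stop(sprintf("unknown spin system '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")))
  reg[[key]]
}

#' Shift all resonances of a system
#'
#' Applies a global B0-type frequency offset in ppm.
#' @param system a [spin_system()].
#' @param delta_ppm shift added to every resonance.
#' @return the shifted [spin_system()].
#' @export
shift_system <- function(system, delta_ppm) {
  system$shifts_ppm <- system$shifts_ppm + delta_ppm
  system
}
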