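#' Physical constants and unit system
#'
#' The package works throughout in the AKMA-style unit system commonly used by
#' biomolecular simulation codes: lengths in Angstrom, time in picoseconds,
#' energies in kcal/mol and masses in Dalton (g/mol).
#'
#' * `kBoltzmann`: Boltzmann constant, 1.987204e-3 kcal/mol/K.
#' * `accUnit`: conversion factor from (kcal/mol/A)/Da to A/ps^2. It equals
#'   4184 J/kcal * 1e3 (g/kg) * 1e-4 (m^2/s^2 per A^2/ps^2) = 418.4 exactly
#'   (thermochemical calorie).
#' * `coulombConst`: Coulomb constant in kcal*A/(mol*e^2), 332.0637.
#'
#' @name constants
#' @format `kBoltzmann` and `accUnit` are numeric scalars.
#' @aliases kBoltzmann accUnit
#' @export kBoltzmann accUnit
NULL

kBoltzmann <- 1.987204e-3
accUnit <- 418.4
coulombConst <- 332.0637

#' Default nucleotide masses (Da)
#'
#' Per-nucleotide masses used for the beads; each bead carries the mass of its
#' whole nucleotide. The table is configurable wherever masses enter.
#'
#' @return Named numeric vector for A, C, G, T.
#' @export
#' @examples
#' defaultMasses()
defaultMasses <- function() {
  c(A = 331.2, C = 307.2, G = 347.2, T = 322.2)
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcompChars <- function(x) {
  paste(rev(DNA_COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")
}
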