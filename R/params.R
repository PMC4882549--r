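#' Solvent-model parameters with standard defaults
#'
#' Constructs a [SolventModelParams-class]. Defaults follow common implicit
#' solvent practice for MM/GBSA analyses of membrane-protein binding pockets:
#' interior dielectric 1, solvent dielectric 80, 0.15 M monovalent salt (the
#' physiological ionic strength the simulations emulate), a 1.4 Angstrom water
#' probe, the 0.09 Angstrom intrinsic-radius offset of the
#' Hawkins-Cramer-Truhlar Generalized Born model, and a surface coefficient of
#' 0.0072 kcal/mol/Angstrom^2 for the LCPO-based nonpolar term.
#'
#' Salt enters the polar term as Debye-Hueckel screening
#' `exp(-kappa * f_GB)` on the solvent contribution, with
#' `kappa = 0.329 * sqrt(saltConc)` in 1/Angstrom.
#'
#' @param epsIn interior dielectric (>= 1).
#' @param epsOut solvent dielectric (> epsIn).
#' @param saltConc monovalent salt concentration, mol/L.
#' @param probeRadius solvent probe radius, Angstrom.
#' @param gbOffset intrinsic Born radius offset, Angstrom.
#' @param gammaNonpolar surface coefficient, kcal/mol/Angstrom^2.
#' @param coulombConst electrostatic constant, kcal Angstrom/mol/e^2.
#' @param temperature temperature for thermodynamic conversions, Kelvin.
#' @return a validated [SolventModelParams-class] object.
#' @examples
#' p <- solventParams()
#' p@gammaNonpolar   # 0.0072
#' @export
solventParams <- function(epsIn = 1.0, epsOut = 80.0, saltConc = 0.15,
                          probeRadius = 1.4, gbOffset = 0.09,
                          gammaNonpolar = 0.0072, coulombConst = 332.0636,
                          temperature = 298.15) {
  new("SolventModelParams", epsIn = epsIn, epsOut = epsOut,
      saltConc = saltConc, probeRadius = probeRadius, gbOffset = gbOffset,
      gammaNonpolar = gammaNonpolar, coulombConst = coulombConst,
      temperature = temperature)
}

#' Debye screening constant of a parameter set
#'
#' @param params a [SolventModelParams-class].
#' @return kappa in 1/Angstrom (0 for salt-free solvent).
#' @export
debyeKappa <- function(params) 0.329 * sqrt(params@saltConc)
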