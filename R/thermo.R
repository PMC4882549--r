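# Thermodynamic conversions between inhibition constants, binding free
# energies, relative free energies and potency fold-changes, plus the
# validation statistics used to compare calculated and experimental panels.

#' @keywords internal
.GAS_CONSTANT <- 1.9872e-3   # kcal / (mol K)

.rt <- function(temperature) .GAS_CONSTANT * temperature

#' Binding free energy from an inhibition constant
#'
#' `dG = RT ln(Ki)` with `Ki` converted from nM to mol/L, R = 1.9872e-3
#' kcal/(mol K). The default 298.15 K is the standard temperature of the
#' experimental affinity literature; printed free-energy tables derived from
#' Ki values reproduce at this temperature.
#'
#' @param kiNm inhibition constant, nM (> 0); vectorised.
#' @param temperature Kelvin.
#' @return kcal/mol (negative for sub-molar Ki).
#' @examples
#' dgFromKi(1.60)   # -12.00 at two decimals
#' @export
dgFromKi <- function(kiNm, temperature = 298.15) {
  if (any(kiNm <= 0)) stop("Ki must be positive", call. = FALSE)
  .rt(temperature) * log(kiNm * 1e-9)
}

#' Inhibition constant from a binding free energy
#'
#' Exact inverse of [dgFromKi()]: `Ki = exp(dG / RT)` in mol/L, reported
#' in nM.
#'
#' @param dg kcal/mol; vectorised.
#' @param temperature Kelvin.
#' @return Ki in nM.
#' @export
kiFromDg <- function(dg, temperature = 298.15)
  exp(dg / .rt(temperature)) * 1e9

#' Relative binding free energies against a reference ligand
#'
#' `ddG_ligand = dG_ligand - dG_reference`; the reference maps to 0.
#'
#' @param dg named numeric of free energies, kcal/mol.
#' @param reference name of the reference ligand (must be present).
#' @return named numeric of the same length.
#' @export
ddgVsReference <- function(dg, reference) {
  if (!reference %in% names(dg))
    stop("reference ligand ", sQuote(reference), " not found", call. = FALSE)
  dg - dg[[reference]]
}

#' Convert between relative free energy and potency fold-change
#'
#' `ddG = RT ln(FC)` and `FC = exp(ddG / RT)`: exact mutual inverses. A
#' loss-of-potency mutation (higher Ki) has FC > 1 and ddG > 0.
#'
#' @param value ddG (kcal/mol) or fold-change, per `direction`; vectorised.
#' @param direction `"ddg_to_fc"` or `"fc_to_ddg"`.
#' @param temperature Kelvin.
#' @return the converted value.
#' @examples
#' fcDdgConvert(514.09, "fc_to_ddg")   # 3.70 at two decimals
#' fcDdgConvert(-0.31, "ddg_to_fc")    # 0.59 at two decimals
#' @export
fcDdgConvert <- function(value, direction = c("ddg_to_fc", "fc_to_ddg"),
                         temperature = 298.15) {
  direction <- match.arg(direction)
  if (direction == "fc_to_ddg") {
    if (any(value <= 0)) stop("fold-change must be positive", call. = FALSE)
    .rt(temperature) * log(value)
  } else {
    exp(value / .rt(temperature))
  }
}

#' Classify a mutation's sensitivity from its potency fold-change
#'
#' A mutation is "sensitive" when the fold-change in potency reaches the
#' threshold in either direction: `max(FC, 1/FC) >= threshold` (inclusive),
#' so both loss- and gain-of-potency mutations qualify. The conventional
#' threshold is 5-fold.
#'
#' @param fc fold-change (> 0); vectorised.
#' @param threshold fold threshold (default 5).
#' @return character vector, `"sensitive"` or `"non-sensitive"`.
#' @export
classifySensitivity <- function(fc, threshold = 5) {
  if (any(fc <= 0)) stop("fold-change must be positive", call. = FALSE)
  ifelse(pmax(fc, 1 / fc) >= threshold, "sensitive", "non-sensitive")
}

#' Squared Pearson correlation
#'
#' `r^2` between two numeric vectors; errors on fewer than 3 points or zero
#' variance (where the correlation is undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return r-squared in `[0, 1]`.
#' @export
pearsonR2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(x, y)^2
}

#' Affinity comparison table
#'
#' Builds the standard calculated-vs-experimental panel: experimental free
#' energies from Ki, relative free energies against a reference ligand for
#' both the experimental and calculated columns, and two-decimal report
#' strings.
#'
#' @param ligand character ligand names.
#' @param kiNm experimental inhibition constants, nM.
#' @param dgCalc calculated binding free energies, kcal/mol.
#' @param dgCalcSem optional standard errors for `dgCalc`.
#' @param reference reference ligand for the relative columns.
#' @param temperature Kelvin.
#' @return data.frame with `ligand`, `ki_nm`, `dg_exp`, `ddg_exp`,
#'   `dg_calc`, `ddg_calc` and a formatted `dg_calc_fmt` column.
#' @export
affinityTable <- function(ligand, kiNm, dgCalc, dgCalcSem = NULL,
                          reference = ligand[length(ligand)],
                          temperature = 298.15) {
  dgExp <- dgFromKi(kiNm, temperature)
  names(dgExp) <- names(dgCalc) <- ligand
  fmt <- if (is.null(dgCalcSem)) vapply(dgCalc, formatEnergy, character(1))
  else mapply(formatEnergy, dgCalc, dgCalcSem)
  data.frame(
    ligand = ligand, ki_nm = kiNm,
    dg_exp = unname(dgExp),
    ddg_exp = unname(ddgVsReference(dgExp, reference)),
    dg_calc = unname(dgCalc),
    ddg_calc = unname(ddgVsReference(dgCalc, reference)),
    dg_calc_fmt = unname(fmt))
}

#' Mutation sensitivity table
#'
#' For each mutant system: the calculated relative free energy
#' (`dG_mutant - dG_wild`), its fold-change equivalent, the experimental
#' relative free energy derived from the measured fold-change (with optional
#' min/max range), and the sensitivity class of the calculated fold-change.
#'
#' @param system character labels (e.g. "atomoxetine F323Y").
#' @param dgWild,dgMutant calculated free energies, kcal/mol; alternatively
#'   pass `ddgCalc` directly.
#' @param ddgCalc optional precomputed relative free energies.
#' @param fcExp experimental fold-change (mid value).
#' @param fcExpMin,fcExpMax optional experimental range.
#' @param threshold sensitivity fold threshold.
#' @param temperature Kelvin.
#' @return data.frame with calculated and experimental columns plus
#'   `sensitivity`.
#' @export
mutationTable <- function(system, dgWild = NULL, dgMutant = NULL,
                          ddgCalc = NULL, fcExp = NA_real_,
                          fcExpMin = NA_real_, fcExpMax = NA_real_,
                          threshold = 5, temperature = 298.15) {
  if (is.null(ddgCalc)) ddgCalc <- dgMutant - dgWild
  fcCalc <- fcDdgConvert(ddgCalc, "ddg_to_fc", temperature)
  ddgExp <- ifelse(is.na(fcExp), NA_real_,
                   fcDdgConvert(fcExp, "fc_to_ddg", temperature))
  data.frame(
    system = system,
    ddg_calc = ddgCalc, fc_calc = fcCalc,
    fc_exp = fcExp, fc_exp_min = fcExpMin, fc_exp_max = fcExpMax,
    ddg_exp = ddgExp,
    sensitivity = classifySensitivity(fcCalc, threshold))
}
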