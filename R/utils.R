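# internal helpers shared across modules

# half-away-from-zero rounding, used only when formatting report values so
# printed tables match the convention of the experimental literature
#' Round half away from zero
#'
#' Unlike [base::round()] (banker's rounding), ties go away from zero:
#' `roundHalfAway(2.345, 2)` is 2.35. Applied only at report time; internal
#' energies are never rounded.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
roundHalfAway <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format an energy as "mean +/- sem"
#'
#' Two-decimal report string in the style of binding free-energy tables,
#' e.g. `"-41.42 ± 0.13"`.
#'
#' @param mean,sem numeric scalars (kcal/mol); `sem = NA` drops the spread.
#' @export
formatEnergy <- function(mean, sem = NA_real_) {
  fmt <- function(v) sprintf("%.2f", roundHalfAway(v, 2))
  if (is.na(sem)) fmt(mean) else paste0(fmt(mean), " \u00b1 ", fmt(sem))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# squared-distance matrix between two coordinate blocks (rows are atoms)
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.frame_matrix <- function(frame, n) {
  f <- as.matrix(frame)
  if (nrow(f) != n || ncol(f) != 3)
    stop("frame must be an nAtoms x 3 coordinate matrix", call. = FALSE)
  storage.mode(f) <- "double"
  unname(f)
}

.new_breakdown <- function(evdw, eele, gpol, gnonpol)
  new("EnergyBreakdown", evdw = evdw, eele = eele, gpol = gpol,
      gnonpol = gnonpol, total = evdw + eele + gpol + gnonpol)
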