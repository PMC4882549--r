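#' @rdname MolecularSystem-class
#' @export
setMethod("atoms", "MolecularSystem", function(x) x@atoms)

#' @rdname Ensemble-class
#' @export
setMethod("atoms", "Ensemble", function(x) x@system@atoms)

#' @rdname MolecularSystem-class
#' @export
setMethod("residues", "MolecularSystem", function(x) {
  a <- x@atoms
  idx <- !duplicated(a$resid)
  data.frame(resid = a$resid[idx], resname = a$resname[idx],
             segment = a$segment[idx], row.names = NULL)
})

#' @rdname MolecularSystem-class
#' @export
setMethod("ligandLabel", "MolecularSystem", function(x) x@ligandLabel)

#' @rdname MolecularSystem-class
#' @export
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))

#' @rdname Ensemble-class
#' @export
setMethod("nAtoms", "Ensemble", function(x) nrow(x@system@atoms))

#' Coordinates stored on the system itself
#'
#' @return an nAtoms x 3 numeric matrix (Angstrom).
#' @rdname MolecularSystem-class
#' @export
setMethod("referenceFrame", "MolecularSystem", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname Ensemble-class
#' @export
setMethod("frames", "Ensemble", function(x) x@frames)

#' @rdname Ensemble-class
#' @export
setMethod("nFrames", "Ensemble", function(x) length(x@frames))

#' @rdname EnergyBreakdown-class
#' @export
setMethod("energyComponents", "EnergyBreakdown", function(x)
  c(evdw = x@evdw, eele = x@eele, gpol = x@gpol, gnonpol = x@gnonpol,
    total = x@total))

#' @rdname EnergyMatrix-class
#' @export
setMethod("values", "EnergyMatrix", function(x) x@values)

#' @rdname ResidueProfile-class
#' @export
setMethod("values", "ResidueProfile", function(x) x@values)

#' @rdname GeometrySeries-class
#' @export
setMethod("values", "GeometrySeries", function(x) x@values)

#' Summary statistics of a geometry series
#'
#' @param object a \linkS4class{GeometrySeries}.
#' @param ... ignored.
#' @return named numeric with `mean`, `sd`, `min`, `max` (sd is `NA` for a
#'   single frame).
#' @rdname GeometrySeries-class
#' @export
setMethod("summary", "GeometrySeries", function(object, ...) {
  v <- object@values
  c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
    min = min(v), max = max(v))
})

setMethod("show", "MolecularSystem", function(object) {
  a <- object@atoms
  cat("MolecularSystem:", sum(a$segment == "receptor"), "receptor atoms in",
      length(unique(a$resid[a$segment == "receptor"])), "residues;",
      sum(a$segment == "ligand"), "ligand atoms (",
      object@ligandLabel, ")\n")
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble of", length(object@frames), "frames over ")
  show(object@system)
})

setMethod("show", "EnergyBreakdown", function(object) {
  v <- energyComponents(object)
  cat("EnergyBreakdown (kcal/mol):\n")
  print(round(v, 4))
})

setMethod("show", "EnergyStats", function(object) {
  cat("EnergyStats over", object@nFrames, "frames (kcal/mol):\n")
  m <- energyComponents(object@mean)
  for (k in names(m))
    cat(sprintf("  %-8s %s\n", k, formatEnergy(m[[k]], object@sem[[k]])))
})

setMethod("show", "ResidueProfile", function(object) {
  cat("ResidueProfile over", nrow(object@values), "receptor residues",
      "(kcal/mol); strongest contributors:\n")
  ord <- order(object@values[, "total"])
  head <- ord[seq_len(min(5, length(ord)))]
  print(round(object@values[head, , drop = FALSE], 3))
})

setMethod("show", "EnergyMatrix", function(object) {
  cat("EnergyMatrix:", nrow(object@values), "residues x",
      ncol(object@values), "ligands (kcal/mol)\n")
})

setMethod("show", "ClusterTree", function(object) {
  cat("ClusterTree over", length(object@labels), "leaves;",
      "merge heights in [", round(min(object@height), 4), ",",
      round(max(object@height), 4), "]\n")
})

setMethod("show", "GeometrySeries", function(object) {
  s <- summary(object)
  cat("GeometrySeries", sQuote(object@label), ":", length(object@values),
      sprintf("frames, mean %.3f, sd %.3f A\n", s[["mean"]], s[["sd"]]))
})
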