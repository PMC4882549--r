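#' @rdname MolecularSystem-class
#' @param x,object a \linkS4class{MolecularSystem} or \linkS4class{Ensemble}.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname MolecularSystem-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname MolecularSystem-class
#' @export
setGeneric("ligandLabel", function(x) standardGeneric("ligandLabel"))

#' @rdname MolecularSystem-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname MolecularSystem-class
#' @export
setGeneric("referenceFrame", function(x) standardGeneric("referenceFrame"))

#' @rdname Ensemble-class
#' @param x an \linkS4class{Ensemble}.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname Ensemble-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname EnergyBreakdown-class
#' @param x an \linkS4class{EnergyBreakdown} (or object carrying one).
#' @export
setGeneric("energyComponents", function(x) standardGeneric("energyComponents"))

#' @rdname EnergyMatrix-class
#' @param x an object with a numeric payload (energy matrix, residue profile,
#'   geometry series).
#' @export
setGeneric("values", function(x) standardGeneric("values"))
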