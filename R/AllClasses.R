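#' @import methods
NULL

#' Implicit-solvent and force-field model parameters
#'
#' Container for the constants of the MM/GBSA energy model: dielectric
#' constants, ionic strength, solvent probe radius, the intrinsic-radius
#' offset of the Generalized Born model, the surface-tension coefficient of
#' the nonpolar term, the electrostatic constant and the temperature used in
#' thermodynamic conversions.
#'
#' @slot epsIn interior (solute) dielectric constant, unitless.
#' @slot epsOut solvent dielectric constant, unitless.
#' @slot saltConc monovalent salt concentration, mol/L.
#' @slot probeRadius solvent probe radius, Angstrom.
#' @slot gbOffset offset subtracted from intrinsic Born radii, Angstrom.
#' @slot gammaNonpolar surface coefficient of the nonpolar solvation term,
#'   kcal/mol/Angstrom^2.
#' @slot coulombConst electrostatic conversion constant, kcal Angstrom / mol e^2.
#' @slot temperature absolute temperature, Kelvin.
#'
#' @seealso [solventParams()] for the user-facing constructor with defaults.
#' @exportClass SolventModelParams
setClass("SolventModelParams",
  representation(
    epsIn = "numeric", epsOut = "numeric", saltConc = "numeric",
    probeRadius = "numeric", gbOffset = "numeric", gammaNonpolar = "numeric",
    coulombConst = "numeric", temperature = "numeric"
  )
)

setValidity("SolventModelParams", function(object) {
  msg <- character()
  if (object@epsIn < 1) msg <- c(msg, "epsIn must be >= 1")
  if (object@epsOut <= object@epsIn)
    msg <- c(msg, "epsOut must exceed epsIn")
  if (object@probeRadius < 0) msg <- c(msg, "probeRadius must be >= 0")
  if (object@gammaNonpolar <= 0) msg <- c(msg, "gammaNonpolar must be > 0")
  if (object@saltConc < 0) msg <- c(msg, "saltConc must be >= 0")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (length(msg)) msg else TRUE
})

#' A parameterised receptor-ligand system
#'
#' Atoms with coordinates and per-atom force-field/solvation parameters,
#' partitioned into a receptor and a single ligand, grouped into residues.
#' The `atoms` slot is a data.frame with one row per atom and columns
#' `serial`, `name`, `resid`, `resname`, `segment` ("receptor" or "ligand"),
#' `x`, `y`, `z` (Angstrom), `charge` (e), `lj_rmin_half` (Angstrom),
#' `lj_epsilon` (kcal/mol), `gb_radius` (Angstrom), `gb_screen` (unitless),
#' `sasa_radius` (Angstrom) and LCPO weights `p1`..`p4`.
#'
#' @slot atoms data.frame as described above.
#' @slot ligandLabel display name of the ligand.
#' @exportClass MolecularSystem
setClass("MolecularSystem",
  representation(atoms = "data.frame", ligandLabel = "character")
)

.atomColumns <- c(
  "serial", "name", "resid", "resname", "segment", "x", "y", "z",
  "charge", "lj_rmin_half", "lj_epsilon", "gb_radius", "gb_screen",
  "sasa_radius", "p1", "p2", "p3", "p4"
)

setValidity("MolecularSystem", function(object) {
  a <- object@atoms
  msg <- character()
  missing <- setdiff(.atomColumns, names(a))
  if (length(missing))
    return(paste("atoms is missing columns:", paste(missing, collapse = ", ")))
  if (nrow(a) < 2) msg <- c(msg, "need at least two atoms")
  if (!all(a$segment %in% c("receptor", "ligand")))
    msg <- c(msg, "segment must be 'receptor' or 'ligand'")
  if (!any(a$segment == "receptor") || !any(a$segment == "ligand"))
    msg <- c(msg, "need at least one receptor and one ligand atom")
  if (anyDuplicated(a$serial)) msg <- c(msg, "atom serials must be unique")
  if (any(a$lj_epsilon < 0)) msg <- c(msg, "lj_epsilon must be >= 0")
  if (any(a$gb_radius <= 0)) msg <- c(msg, "gb_radius must be > 0")
  if (any(a$sasa_radius < 0)) msg <- c(msg, "sasa_radius must be >= 0")
  # a residue may not straddle the receptor/ligand partition
  seg <- tapply(a$segment, a$resid, function(s) length(unique(s)))
  if (any(seg > 1)) msg <- c(msg, "a residue spans both segments")
  if (length(msg)) msg else TRUE
})

#' A snapshot ensemble over one system
#'
#' An ordered list of coordinate frames (each an n_atoms x 3 matrix, Angstrom)
#' sharing a single [MolecularSystem-class] topology; frames typically come
#' from the equilibrated window of a molecular-dynamics trajectory, or from
#' [jitterEnsemble()].
#'
#' @slot system the shared [MolecularSystem-class].
#' @slot frames list of numeric matrices, each `nAtoms(system)` x 3.
#' @exportClass Ensemble
setClass("Ensemble",
  representation(system = "MolecularSystem", frames = "list")
)

setValidity("Ensemble", function(object) {
  n <- nrow(object@system@atoms)
  if (length(object@frames) < 1) return("need at least one frame")
  ok <- vapply(object@frames, function(f)
    is.matrix(f) && is.numeric(f) && nrow(f) == n && ncol(f) == 3, logical(1))
  if (!all(ok)) return("every frame must be an nAtoms x 3 numeric matrix")
  TRUE
})

#' Binding-energy breakdown of one snapshot
#'
#' The four MM/GBSA components of a single-trajectory binding energy and
#' their sum (kcal/mol): intermolecular van der Waals (`evdw`) and
#' electrostatic (`eele`) energies, the Generalized Born polar solvation
#' change on binding (`gpol`) and the surface-area nonpolar term (`gnonpol`).
#'
#' @slot evdw,eele,gpol,gnonpol,total numeric scalars, kcal/mol.
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
  representation(evdw = "numeric", eele = "numeric", gpol = "numeric",
                 gnonpol = "numeric", total = "numeric")
)

setValidity("EnergyBreakdown", function(object) {
  s <- object@evdw + object@eele + object@gpol + object@gnonpol
  if (abs(s - object@total) > 1e-9)
    return("total must equal the sum of the four components (1e-9 kcal/mol)")
  TRUE
})

#' Per-residue energy decomposition
#'
#' Receptor-residue contributions to the binding energy: a matrix with one
#' row per receptor residue and columns `evdw`, `eele`, `gpol`, `gnonpol`,
#' `total` (kcal/mol). Pairwise terms (vdW, electrostatic, GB cross terms)
#' sum over residues to the corresponding intermolecular system totals.
#'
#' @slot values numeric matrix, rownames = residue indices, columns as above.
#' @slot resnames residue names aligned with the rows.
#' @exportClass ResidueProfile
setClass("ResidueProfile",
  representation(values = "matrix", resnames = "character")
)

setValidity("ResidueProfile", function(object) {
  cols <- c("evdw", "eele", "gpol", "gnonpol", "total")
  if (!identical(colnames(object@values), cols))
    return(paste("columns must be", paste(cols, collapse = ", ")))
  if (length(object@resnames) != nrow(object@values))
    return("resnames must align with rows")
  TRUE
})

#' Residue-by-ligand energy matrix
#'
#' Per-residue total energy contributions (kcal/mol) across a panel of
#' ligands: residues as rows, ligands as columns, both uniquely labelled.
#'
#' @slot values numeric matrix with unique dimnames.
#' @exportClass EnergyMatrix
setClass("EnergyMatrix", representation(values = "matrix"))

setValidity("EnergyMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry residue rownames and ligand colnames")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    return("row and column labels must be unique")
  if (any(!is.finite(v))) return("entries must be finite")
  TRUE
})

#' Agglomerative cluster tree
#'
#' Result of Ward clustering: `merge` and `height` follow the
#' [stats::hclust()] convention (negative entries of `merge` are leaves,
#' positive entries refer to earlier merges).
#'
#' @slot merge integer matrix (n-1) x 2.
#' @slot height numeric merge heights, non-decreasing for Ward linkage.
#' @slot labels leaf labels.
#' @exportClass ClusterTree
setClass("ClusterTree",
  representation(merge = "matrix", height = "numeric", labels = "character")
)

setValidity("ClusterTree", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L)
    return("a tree over n leaves must have exactly n-1 merges")
  if (any(object@height < -1e-12)) return("merge heights must be non-negative")
  TRUE
})

#' Ensemble energy summary
#'
#' Frame-averaged MM/GBSA components with standard errors of the mean
#' (sample sd / sqrt(n) per term). With a single frame the SEM is `NA`.
#'
#' @slot mean an [EnergyBreakdown-class] of frame means.
#' @slot sem named numeric of per-term standard errors.
#' @slot nFrames number of snapshots averaged.
#' @exportClass EnergyStats
setClass("EnergyStats",
  representation(mean = "EnergyBreakdown", sem = "numeric", nFrames = "integer")
)

setValidity("EnergyStats", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (any(object@sem < 0, na.rm = TRUE)) return("sem must be >= 0")
  TRUE
})

#' Per-frame geometry series
#'
#' A scalar geometric observable (distance, RMSD, ...) evaluated on every
#' frame of an ensemble, with its mean and standard deviation.
#'
#' @slot values per-frame values, Angstrom.
#' @slot label description of the observable.
#' @exportClass GeometrySeries
setClass("GeometrySeries",
  representation(values = "numeric", label = "character")
)

setValidity("GeometrySeries", function(object) {
  if (length(object@values) < 1) return("need at least one frame")
  TRUE
})
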