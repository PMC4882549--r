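# Snapshot-ensemble statistics, geometry monitors and differential
# per-residue comparison between systems.

#' Construct an ensemble
#'
#' @param system a [MolecularSystem-class].
#' @param frames list of nAtoms x 3 coordinate matrices.
#' @return an [Ensemble-class].
#' @export
ensemble <- function(system, frames) {
  frames <- lapply(frames, .frame_matrix, n = nrow(system@atoms))
  new("Ensemble", system = system, frames = frames)
}

#' Select atoms of a system
#'
#' Returns atom indices matching all supplied filters. `name` matches PDB
#' atom names; `heavyOnly` drops hydrogens, identified by the atom-name
#' convention (first alphabetic character of the name is "H").
#'
#' @param system a [MolecularSystem-class].
#' @param resid residue indices to keep.
#' @param name atom names to keep.
#' @param segment `"receptor"` or `"ligand"`.
#' @param serial atom serials to keep.
#' @param heavyOnly drop hydrogens.
#' @return integer atom indices.
#' @export
selectAtoms <- function(system, resid = NULL, name = NULL, segment = NULL,
                        serial = NULL, heavyOnly = FALSE) {
  a <- system@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(segment)) keep <- keep & a$segment %in% segment
  if (!is.null(serial)) keep <- keep & a$serial %in% serial
  if (heavyOnly) keep <- keep & !.is_hydrogen(a$name)
  which(keep)
}

.is_hydrogen <- function(names) {
  first <- sub("^[0-9]*", "", names)
  toupper(substr(first, 1, 1)) == "H"
}

.single_atom <- function(system, sel) {
  idx <- do.call(selectAtoms, c(list(system), sel))
  if (length(idx) != 1)
    stop("selector must resolve to exactly one atom (matched ",
         length(idx), ")", call. = FALSE)
  idx
}

#' Frame-averaged MM/GBSA energy with standard errors
#'
#' Runs [mmgbsaSnapshot()] on every frame and reports per-term means and
#' standard errors of the mean (sample standard deviation with the n-1
#' denominator, divided by `sqrt(n)`). With a single frame the SEM is
#' reported as `NA`.
#'
#' @param ens an [Ensemble-class].
#' @param params a [SolventModelParams-class].
#' @return an [EnergyStats-class].
#' @export
ensembleEnergyStats <- function(ens, params = solventParams()) {
  per <- vapply(ens@frames, function(f)
    energyComponents(mmgbsaSnapshot(ens@system, f, params)), numeric(5))
  n <- ncol(per)
  m <- rowMeans(per)
  sem <- if (n > 1) apply(per, 1, stats::sd) / sqrt(n)
  else stats::setNames(rep(NA_real_, 5), rownames(per))
  new("EnergyStats",
      mean = .new_breakdown(m[["evdw"]], m[["eele"]], m[["gpol"]],
                            m[["gnonpol"]]),
      sem = sem, nFrames = as.integer(n))
}

#' Frame-averaged per-residue decomposition
#'
#' Arithmetic mean of [decomposeSnapshot()] over all frames; by linearity the
#' pairwise-term conservation of the single-frame decomposition carries over
#' to the average.
#'
#' @inheritParams ensembleEnergyStats
#' @param depth icosahedral subdivision depth for the nonpolar term.
#' @return a [ResidueProfile-class] of frame means.
#' @export
ensembleDecomposition <- function(ens, params = solventParams(), depth = 3L) {
  profs <- lapply(ens@frames, function(f)
    decomposeSnapshot(ens@system, f, params, depth))
  vals <- Reduce(`+`, lapply(profs, function(p) p@values)) / length(profs)
  new("ResidueProfile", values = vals, resnames = profs[[1]]@resnames)
}

# optimal proper rotation (Kabsch, via SVD) mapping moving onto fixed,
# both already centred
.kabsch <- function(fixed, moving) {
  s <- svd(crossprod(moving, fixed))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superposition RMSD over an atom selection
#'
#' Each frame is least-squares superposed onto the reference frame over the
#' selection (optimal proper rotation from the SVD of the cross-covariance,
#' with the determinant correction that excludes reflections), then the RMSD
#' over the selection is reported per frame.
#'
#' @param ens an [Ensemble-class].
#' @param selection integer atom indices (e.g. from [selectAtoms()]).
#' @param reference index of the reference frame (default 1).
#' @param label description used in reports.
#' @return a [GeometrySeries-class] of per-frame RMSD values (Angstrom).
#' @export
superposeRMSD <- function(ens, selection, reference = 1L,
                          label = "RMSD") {
  if (length(selection) < 3)
    stop("superposition needs at least 3 selected atoms", call. = FALSE)
  ref <- ens@frames[[reference]][selection, , drop = FALSE]
  refc <- scale(ref, scale = FALSE)
  vals <- vapply(ens@frames, function(f) {
    mov <- f[selection, , drop = FALSE]
    movc <- scale(mov, scale = FALSE)
    rot <- movc %*% .kabsch(refc, movc)
    sqrt(mean(rowSums((rot - refc)^2)))
  }, numeric(1))
  new("GeometrySeries", values = vals, label = label)
}

#' Binding-site residues within a cutoff of the ligand
#'
#' Receptor residues with at least one heavy atom within `cutoff` of any
#' ligand heavy atom (hydrogens excluded on both sides); the boundary is
#' inclusive.
#'
#' @param system a [MolecularSystem-class].
#' @param frame coordinate matrix (defaults to the system's own).
#' @param cutoff distance cutoff, Angstrom (default 5.0).
#' @return integer vector of residue indices.
#' @export
pocketResidues <- function(system, frame = referenceFrame(system),
                           cutoff = 5.0) {
  stopifnot(cutoff > 0)
  a <- system@atoms
  f <- .frame_matrix(frame, nrow(a))
  ri <- selectAtoms(system, segment = "receptor", heavyOnly = TRUE)
  li <- selectAtoms(system, segment = "ligand", heavyOnly = TRUE)
  d <- .cross_dist(f[ri, , drop = FALSE], f[li, , drop = FALSE])
  near <- apply(d, 1, min) <= cutoff
  sort(unique(a$resid[ri][near]))
}

#' Interatomic distance along an ensemble
#'
#' @param ens an [Ensemble-class].
#' @param atomA,atomB selector lists passed to [selectAtoms()] (e.g.
#'   `list(resid = 75, name = "OD1")`); each must resolve to one atom.
#' @param label description used in reports.
#' @return a [GeometrySeries-class] of per-frame distances (Angstrom).
#' @export
distanceSeries <- function(ens, atomA, atomB, label = "distance") {
  ia <- .single_atom(ens@system, atomA)
  ib <- .single_atom(ens@system, atomB)
  vals <- vapply(ens@frames, function(f)
    sqrt(sum((f[ia, ] - f[ib, ])^2)), numeric(1))
  new("GeometrySeries", values = vals, label = label)
}

#' Hydrogen-bond occupancy along an ensemble
#'
#' Fraction of frames in which the donor-acceptor distance is at most
#' `distCutoff` and the donor-hydrogen-acceptor angle at least `angleCutoff`
#' (degrees). The same machinery monitors salt bridges with
#' `angleCutoff = 0` and a 4.0 Angstrom cutoff on the charged-atom pair.
#'
#' @param ens an [Ensemble-class].
#' @param donor,hydrogen,acceptor selector lists (see [distanceSeries()]);
#'   `hydrogen = NULL` skips the angle criterion.
#' @param distCutoff donor-acceptor cutoff, Angstrom.
#' @param angleCutoff minimum D-H-A angle, degrees.
#' @return occupancy fraction in `[0, 1]`.
#' @export
hbondOccupancy <- function(ens, donor, acceptor, hydrogen = NULL,
                           distCutoff = 3.5, angleCutoff = 135) {
  id <- .single_atom(ens@system, donor)
  ia <- .single_atom(ens@system, acceptor)
  ih <- if (!is.null(hydrogen)) .single_atom(ens@system, hydrogen)
  ok <- vapply(ens@frames, function(f) {
    dda <- sqrt(sum((f[id, ] - f[ia, ])^2))
    if (dda > distCutoff) return(FALSE)
    if (is.null(ih)) return(TRUE)
    v1 <- f[id, ] - f[ih, ]
    v2 <- f[ia, ] - f[ih, ]
    ang <- acos(.clamp(sum(v1 * v2) /
                         sqrt(sum(v1^2) * sum(v2^2)), -1, 1)) * 180 / pi
    ang >= angleCutoff
  }, logical(1))
  mean(ok)
}

#' Residues whose contributions differ between two systems
#'
#' Compares the per-residue totals of two profiles (e.g. two enantiomers, or
#' wild type vs mutant) and flags residues with an absolute difference of at
#' least `threshold` kcal/mol, sorted by decreasing magnitude. Swapping the
#' inputs negates every difference.
#'
#' @param profileA,profileB [ResidueProfile-class] objects sharing residue
#'   indexing (compared over the intersection; disjoint sets are an error).
#' @param threshold minimum absolute difference, kcal/mol (default 0.5).
#' @return data.frame with `resid`, `resname`, `totalA`, `totalB`, `delta`.
#' @export
differentialResidues <- function(profileA, profileB, threshold = 0.5) {
  ra <- rownames(profileA@values)
  rb <- rownames(profileB@values)
  shared <- intersect(ra, rb)
  if (!length(shared))
    stop("profiles share no residues; cannot align", call. = FALSE)
  ta <- profileA@values[shared, "total"]
  tb <- profileB@values[shared, "total"]
  delta <- ta - tb
  keep <- abs(delta) >= threshold
  out <- data.frame(
    resid = as.integer(shared[keep]),
    resname = profileA@resnames[match(shared[keep], ra)],
    totalA = unname(ta[keep]), totalB = unname(tb[keep]),
    delta = unname(delta[keep]))
  out[order(-abs(out$delta)), , drop = FALSE]
}
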