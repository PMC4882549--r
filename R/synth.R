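# Seeded synthetic generators: toy pocket-ligand complexes with physically
# plausible per-atom parameters, Gaussian-jittered snapshot ensembles (a
# stand-in for an equilibrated trajectory window), and residue-by-ligand
# energy matrices with planted group structure.

# built-in parameter classes: AMBER-style Lennard-Jones minima, mbondi
# intrinsic Born radii with HCT descreening factors, and published LCPO
# weights for singly-bonded heavy atoms
.atomClasses <- data.frame(
  class = c("C", "N", "O"),
  lj_rmin_half = c(1.9080, 1.8240, 1.6612),
  lj_epsilon = c(0.1094, 0.1700, 0.2100),
  gb_radius = c(1.70, 1.55, 1.50),
  gb_screen = c(0.72, 0.79, 0.85),
  sasa_radius = c(1.70, 1.65, 1.60),
  p1 = c(0.78870, 0.78602, 0.77914),
  p2 = c(-0.28063, -0.29198, -0.25262),
  p3 = c(-0.0012968, -0.0006537, -0.0016056),
  p4 = c(0.00039328, 0.00036247, 0.00035071),
  stringsAsFactors = FALSE
)

.class_params <- function(cls) {
  .atomClasses[match(cls, .atomClasses$class), -1, drop = FALSE]
}

.rand_unit <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a toy pocket-ligand complex
#'
#' A small synthetic receptor-ligand system for exercising the full MM/GBSA
#' pipeline: ligand atoms clustered near the origin (the first, an amine-like
#' nitrogen `N1`, carries a +1 e charge), and three-atom pocket residues
#' placed on a shell 6-10 Angstrom from the origin. The first pocket residue
#' is an aspartate-like residue whose carboxylate oxygen (`OD1`, -1 e) points
#' at the ligand nitrogen at salt-bridge range (~2.8 Angstrom); all other
#' charges are drawn uniformly from \[-0.5, 0.5\] e. Lennard-Jones, Born and
#' LCPO parameters come from a built-in table of physically plausible
#' heavy-atom classes. Deterministic under `seed`.
#'
#' @param nPocketResidues number of receptor residues (>= 1).
#' @param nLigandAtoms number of ligand atoms (>= 1).
#' @param seed RNG seed.
#' @return a [MolecularSystem-class] carrying its reference coordinates.
#' @export
toyComplex <- function(nPocketResidues, nLigandAtoms, seed = 1) {
  stopifnot(nPocketResidues >= 1, nLigandAtoms >= 1)
  set.seed(seed)
  rows <- list()
  serial <- 0L
  addAtom <- function(name, resid, resname, segment, xyz, charge, cls) {
    serial <<- serial + 1L
    p <- .class_params(cls)
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, resid = resid, resname = resname,
      segment = segment, x = xyz[1], y = xyz[2], z = xyz[3],
      charge = charge, p, stringsAsFactors = FALSE)
  }
  resnamePool <- c("ALA", "SER", "VAL", "TYR", "PHE", "MET")
  for (r in seq_len(nPocketResidues)) {
    centre <- .rand_unit()[1, ] * stats::runif(1, 6, 10)
    resname <- if (r == 1) "ASP" else sample(resnamePool, 1)
    addAtom("CA", r, resname, "receptor", centre,
            stats::runif(1, -0.5, 0.5), "C")
    addAtom("CB", r, resname, "receptor",
            centre + .rand_unit()[1, ] * 1.5,
            stats::runif(1, -0.5, 0.5), "C")
    if (r == 1) {
      # carboxylate oxygen on the ligand-facing side, salt-bridge range
      od <- centre * (1 - 2.8 / sqrt(sum(centre^2)))
      addAtom("OD1", r, resname, "receptor", od, -1.0, "O")
    } else {
      addAtom("OG", r, resname, "receptor",
              centre + .rand_unit()[1, ] * 1.4,
              stats::runif(1, -0.5, 0.5), "O")
    }
  }
  lig <- nPocketResidues + 1L
  pos <- c(0, 0, 0)
  for (k in seq_len(nLigandAtoms)) {
    if (k == 1) {
      addAtom("N1", lig, "LIG", "ligand", pos, 1.0, "N")
    } else {
      pos <- pos + .rand_unit()[1, ] * 1.5
      addAtom(paste0("C", k), lig, "LIG", "ligand", pos,
              stats::runif(1, -0.5, 0.5), "C")
    }
  }
  atoms <- do.call(rbind, rows)
  new("MolecularSystem", atoms = atoms, ligandLabel = "toy-ligand")
}

#' Gaussian-jittered snapshot ensemble
#'
#' Adds i.i.d. Gaussian displacements (sd `sigma` per coordinate) to a base
#' frame, emulating the thermal scatter of an equilibrated trajectory window.
#' Deterministic under `seed`.
#'
#' @param system a [MolecularSystem-class].
#' @param frame base coordinates (default: the system's own).
#' @param nFrames number of snapshots.
#' @param sigma displacement standard deviation, Angstrom (default 0.3).
#' @param seed RNG seed.
#' @return an [Ensemble-class].
#' @export
jitterEnsemble <- function(system, frame = referenceFrame(system),
                           nFrames = 10, sigma = 0.3, seed = 1) {
  stopifnot(sigma >= 0, nFrames >= 1)
  f <- .frame_matrix(frame, nrow(system@atoms))
  set.seed(seed)
  frames <- lapply(seq_len(nFrames), function(i)
    f + matrix(stats::rnorm(length(f), 0, sigma), nrow(f), 3))
  ensemble(system, frames)
}

#' Residue-by-ligand energy matrix with planted group structure
#'
#' Emulates the statistical shape of a per-residue energy panel: a few
#' groups of residues whose ligand vectors scatter (sd `withinSd`) around
#' group mean energies -- typically one strongly favourable group shared
#' across ligands, weaker groups, and a few weakly unfavourable residues --
#' plus a block of exact-zero residues that exercise the nonzero-contribution
#' filter. Deterministic under `seed`.
#'
#' @param groupSizes integer vector (>= 2 groups), residues per group.
#' @param groupMeans numeric vector of group mean energies, kcal/mol.
#' @param withinSd within-group standard deviation, kcal/mol (>= 0).
#' @param nLigands number of ligand columns.
#' @param zeroFraction fraction of rows that are exact zeros.
#' @param seed RNG seed.
#' @return list with `matrix` (an [EnergyMatrix-class] including the zero
#'   rows) and `labels` (named truth labels; 0 marks zero rows).
#' @export
plantedMatrix <- function(groupSizes, groupMeans, withinSd = 0.1,
                          nLigands = 4, zeroFraction = 0, seed = 1) {
  stopifnot(length(groupSizes) == length(groupMeans),
            length(groupSizes) >= 2, withinSd >= 0,
            zeroFraction >= 0, zeroFraction < 1)
  set.seed(seed)
  nPlanted <- sum(groupSizes)
  nZero <- round(nPlanted * zeroFraction / (1 - zeroFraction))
  labels <- c(rep(seq_along(groupSizes), groupSizes), rep(0L, nZero))
  n <- length(labels)
  m <- matrix(0, n, nLigands,
              dimnames = list(paste0("R", seq_len(n)),
                              paste0("L", seq_len(nLigands))))
  for (i in seq_len(n)) {
    if (labels[i] > 0)
      m[i, ] <- stats::rnorm(nLigands, groupMeans[labels[i]], withinSd)
  }
  names(labels) <- rownames(m)
  list(matrix = new("EnergyMatrix", values = m), labels = labels)
}
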