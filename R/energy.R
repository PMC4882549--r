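# MM/GBSA energy engine: intermolecular pairwise terms, HCT effective Born
# radii, GB polar solvation, LCPO and icosahedral SASA, snapshot binding
# energies and per-residue decomposition. All energies kcal/mol, lengths
# Angstrom, charges e. Single-trajectory convention throughout: complex,
# receptor and ligand are evaluated on the same coordinates, so internal
# bonded terms cancel and are never computed.

.receptor_idx <- function(system) which(system@atoms$segment == "receptor")
.ligand_idx <- function(system) which(system@atoms$segment == "ligand")

#' Intermolecular pairwise Lennard-Jones and Coulomb energies
#'
#' Sums over all receptor-ligand atom pairs with no distance cutoff.
#' Lennard-Jones uses `eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with
#' `rmin_ij = rmin2_i + rmin2_j` (arithmetic on half-minima) and
#' `eps_ij = sqrt(eps_i * eps_j)`; Coulomb uses
#' `coulombConst * q_i q_j / (epsIn * r)`. Each pair energy is assigned to
#' the receptor residue involved (the ligand is treated as one unit), so the
#' per-residue columns sum exactly to the totals.
#'
#' @param system a [MolecularSystem-class].
#' @param frame nAtoms x 3 coordinate matrix; defaults to the system's own
#'   coordinates.
#' @param params a [SolventModelParams-class].
#' @return list with `evdw`, `eele` (kcal/mol) and `perResidue`, a matrix
#'   (rownames = receptor residue indices) with columns `evdw`, `eele`.
#' @export
pairwiseInteractionEnergies <- function(system, frame = referenceFrame(system),
                                        params = solventParams()) {
  a <- system@atoms
  f <- .frame_matrix(frame, nrow(a))
  ri <- .receptor_idx(system)
  li <- .ligand_idx(system)
  d <- .cross_dist(f[ri, , drop = FALSE], f[li, , drop = FALSE])
  if (any(d < 1e-6)) {
    w <- which(d < 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf("degenerate geometry: atoms %d and %d closer than 1e-6 A",
                 a$serial[ri[w[1]]], a$serial[li[w[2]]]), call. = FALSE)
  }
  rmin <- outer(a$lj_rmin_half[ri], a$lj_rmin_half[li], "+")
  epsij <- sqrt(outer(a$lj_epsilon[ri], a$lj_epsilon[li]))
  sr6 <- (rmin / d)^6
  vdw <- epsij * (sr6^2 - 2 * sr6)
  ele <- params@coulombConst * outer(a$charge[ri], a$charge[li]) /
    (params@epsIn * d)
  res <- a$resid[ri]
  perRes <- cbind(evdw = rowsum(rowSums(vdw), res)[, 1],
                  eele = rowsum(rowSums(ele), res)[, 1])
  list(evdw = sum(vdw), eele = sum(ele), perResidue = perRes)
}

# Pairwise descreening integral of the HCT Generalized Born model:
# (1/4pi) * integral of |x - x_i|^-4 over the descreening sphere (radius s at
# distance r), excluding |x - x_i| < rho. Closed form from the spherical-lens
# decomposition; includes the full-shell term when atom i sits inside the
# descreening sphere. Vectorised over equal-length r, s, rho.
.hct_integral <- function(r, s, rho) {
  H <- numeric(length(r))
  act <- s > 0 & (r + s) > rho
  if (!any(act)) return(H)
  r <- r[act]; s <- s[act]; rho <- rho[act]
  L <- pmax(rho, abs(r - s))
  U <- r + s
  lens <- 0.5 * (1 / L - 1 / U +
                   (r / 4) * (1 / U^2 - 1 / L^2) +
                   (1 / (2 * r)) * log(L / U) +
                   (s^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
  eng <- (s - r) > rho      # atom i engulfed by the descreening sphere
  lens[eng] <- lens[eng] + 1 / rho[eng] - 1 / (s[eng] - r[eng])
  H[act] <- lens
  H
}

#' Effective Born radii by pairwise descreening
#'
#' Hawkins-Cramer-Truhlar radii: `1/R_i = 1/rho_i' - sum_j H(r_ij, S_j rho_j')`
#' with reduced intrinsic radii `rho' = gb_radius - gbOffset`, descreening
#' scale factors `S_j = gb_screen`, and `H` the analytic pairwise descreening
#' integral. Radii are clamped to at most 1000 Angstrom (with a message) if
#' descreening drives `1/R` non-positive.
#'
#' @inheritParams pairwiseInteractionEnergies
#' @param atomIdx indices of the atoms forming the species (default: all
#'   atoms, i.e. the complex). Radii see only atoms inside the species.
#' @return numeric vector of effective radii (Angstrom), one per selected
#'   atom, named by serial.
#' @export
effectiveBornRadii <- function(system, frame = referenceFrame(system),
                               params = solventParams(), atomIdx = NULL) {
  a <- system@atoms
  f <- .frame_matrix(frame, nrow(a))
  if (is.null(atomIdx)) atomIdx <- seq_len(nrow(a))
  rho <- a$gb_radius[atomIdx] - params@gbOffset
  if (any(rho <= 0))
    stop("gb_radius must exceed gbOffset for every atom", call. = FALSE)
  scr <- a$gb_screen[atomIdx]
  xyz <- f[atomIdx, , drop = FALSE]
  n <- length(atomIdx)
  if (n == 1L) {
    R <- rho
  } else {
    d <- .cross_dist(xyz, xyz)
    s <- scr * rho
    Hm <- matrix(.hct_integral(as.vector(d),
                               rep(s, each = n),
                               rep(rho, times = n)), n, n)
    diag(Hm) <- 0
    invR <- 1 / rho - rowSums(Hm)
    if (any(invR <= 1e-3)) {
      message("effectiveBornRadii: clamping ", sum(invR <= 1e-3),
              " radii to 1000 A")
      invR[invR <= 1e-3] <- 1e-3
    }
    R <- 1 / invR
  }
  names(R) <- a$serial[atomIdx]
  R
}

#' Generalized Born polar solvation energy with pair decomposition
#'
#' Still-type GB energy
#' `G_pol = -(k/2) sum_ij (1/epsIn - exp(-kappa f_ij)/epsOut) q_i q_j / f_ij`
#' with `f_ij = sqrt(r_ij^2 + R_i R_j exp(-r_ij^2 / (4 R_i R_j)))` and self
#' terms `f_ii = R_i`; `kappa` is the Debye screening constant of the salt.
#' The full symmetric pair matrix is returned so residue-level cross terms
#' can be read off directly; its grand sum equals the total.
#'
#' @inheritParams effectiveBornRadii
#' @param radii effective Born radii for the selected atoms (from
#'   [effectiveBornRadii()] with the same `atomIdx`).
#' @return list with `total` (kcal/mol) and `pairMatrix` (n x n, kcal/mol).
#' @export
gbPolarEnergy <- function(system, frame = referenceFrame(system),
                          radii, params = solventParams(), atomIdx = NULL) {
  a <- system@atoms
  f <- .frame_matrix(frame, nrow(a))
  if (is.null(atomIdx)) atomIdx <- seq_len(nrow(a))
  if (length(radii) != length(atomIdx) || any(radii <= 0))
    stop("radii must be positive, one per selected atom", call. = FALSE)
  xyz <- f[atomIdx, , drop = FALSE]
  q <- a$charge[atomIdx]
  d <- .cross_dist(xyz, xyz)
  RR <- tcrossprod(radii)
  fgb <- sqrt(d^2 + RR * exp(-d^2 / (4 * RR)))
  diag(fgb) <- radii
  kappa <- debyeKappa(params)
  pref <- -(params@coulombConst / 2) *
    (1 / params@epsIn - exp(-kappa * fgb) / params@epsOut)
  M <- pref * tcrossprod(q) / fgb
  dimnames(M) <- list(a$serial[atomIdx], a$serial[atomIdx])
  list(total = sum(M), pairMatrix = M)
}

#' Binding polar solvation change (single-trajectory)
#'
#' `dG_pol = G_pol(complex) - G_pol(receptor) - G_pol(ligand)`, all three
#' species evaluated on the same coordinates; radii are recomputed for each
#' species so desolvation on binding is captured.
#'
#' @inheritParams pairwiseInteractionEnergies
#' @return list with `gpol` (kcal/mol) and `complexPairMatrix` (atom-pair
#'   polar terms of the complex, used for residue decomposition).
#' @export
gbPolarBinding <- function(system, frame = referenceFrame(system),
                           params = solventParams()) {
  ri <- .receptor_idx(system); li <- .ligand_idx(system)
  all_idx <- seq_len(nrow(system@atoms))
  gC <- gbPolarEnergy(system, frame,
                      effectiveBornRadii(system, frame, params), params)
  gR <- gbPolarEnergy(system, frame,
                      effectiveBornRadii(system, frame, params, ri),
                      params, ri)
  gL <- gbPolarEnergy(system, frame,
                      effectiveBornRadii(system, frame, params, li),
                      params, li)
  list(gpol = gC$total - gR$total - gL$total,
       complexPairMatrix = gC$pairMatrix)
}

# two-sphere overlap: area of sphere i (radius ri) buried inside sphere j
# (radius rj, centre distance d); clamped to [0, full sphere]
.overlap_area <- function(ri, rj, d) {
  A <- 2 * pi * ri * (ri - d / 2 - (ri^2 - rj^2) / (2 * d))
  .clamp(A, 0, 4 * pi * ri^2)
}

#' Per-atom solvent-accessible surface area by LCPO
#'
#' Linear Combination of Pairwise Overlaps: for each atom,
#' `SASA_i = P1 S1 + P2 sum_j A_ij + P3 sum_jk A_jk + P4 sum_j A_ij sum_k A_jk`
#' where `S1 = 4 pi (r_i + probe)^2`, `A_ij` is the analytic two-sphere
#' overlap area, `j` runs over neighbours of `i` and `k` over common
#' neighbours of `i` and `j`. Atoms with `sasa_radius <= 0` (e.g. hydrogens
#' under a united treatment) neither contribute nor occlude. Negative
#' per-atom areas are clamped to zero with a message.
#'
#' @inheritParams effectiveBornRadii
#' @return numeric vector of per-atom SASA (Angstrom^2) for the selected
#'   atoms, named by serial.
#' @export
sasaLCPO <- function(system, frame = referenceFrame(system),
                     params = solventParams(), atomIdx = NULL) {
  a <- system@atoms
  f <- .frame_matrix(frame, nrow(a))
  if (is.null(atomIdx)) atomIdx <- seq_len(nrow(a))
  r <- a$sasa_radius[atomIdx] + params@probeRadius
  act <- a$sasa_radius[atomIdx] > 0
  n <- length(atomIdx)
  out <- numeric(n)
  if (any(act)) {
    xyz <- f[atomIdx, , drop = FALSE][act, , drop = FALSE]
    rr <- r[act]
    P <- as.matrix(a[atomIdx, c("p1", "p2", "p3", "p4")])[act, , drop = FALSE]
    m <- sum(act)
    d <- .cross_dist(xyz, xyz)
    nb <- d < outer(rr, rr, "+")
    diag(nb) <- FALSE
    Amat <- matrix(0, m, m)
    if (any(nb)) {
      idx <- which(nb, arr.ind = TRUE)
      Amat[idx] <- .overlap_area(rr[idx[, 1]], rr[idx[, 2]],
                                 d[idx])
    }
    sasa <- numeric(m)
    for (i in seq_len(m)) {
      Ni <- which(nb[i, ])
      S1 <- 4 * pi * rr[i]^2
      T2 <- T3 <- T4 <- 0
      if (length(Ni)) {
        T2 <- sum(Amat[i, Ni])
        for (j in Ni) {
          common <- Ni[nb[j, Ni]]
          common <- common[common != j]
          Aj <- if (length(common)) sum(Amat[j, common]) else 0
          T3 <- T3 + Aj
          T4 <- T4 + Amat[i, j] * Aj
        }
      }
      sasa[i] <- P[i, 1] * S1 + P[i, 2] * T2 + P[i, 3] * T3 + P[i, 4] * T4
    }
    if (any(sasa < 0)) {
      message("sasaLCPO: clamping ", sum(sasa < 0),
              " negative per-atom areas to 0")
      sasa[sasa < 0] <- 0
    }
    out[act] <- sasa
  }
  names(out) <- a$serial[atomIdx]
  out
}

# memoised icosphere meshes: unit-sphere face centroids and solid angles
.icosa_cache <- new.env(parent = emptyenv())

.icosphere <- function(depth) {
  key <- as.character(depth)
  if (!is.null(.icosa_cache[[key]])) return(.icosa_cache[[key]])
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(depth)) {
    nf <- nrow(faces)
    newv <- v
    newfaces <- matrix(0L, nf * 4, 3)
    midkey <- new.env(parent = emptyenv())
    mid <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      if (!is.null(midkey[[k]])) return(midkey[[k]])
      p <- (newv[i, ] + newv[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv <<- rbind(newv, p)
      midkey[[k]] <- nrow(newv)
      nrow(newv)
    }
    for (fi in seq_len(nf)) {
      tri <- faces[fi, ]
      ab <- mid(tri[1], tri[2]); bc <- mid(tri[2], tri[3])
      ca <- mid(tri[3], tri[1])
      newfaces[(fi - 1) * 4 + 1:4, ] <- rbind(
        c(tri[1], ab, ca), c(tri[2], bc, ab), c(tri[3], ca, bc),
        c(ab, bc, ca))
    }
    v <- newv
    faces <- newfaces
  }
  A <- v[faces[, 1], , drop = FALSE]
  B <- v[faces[, 2], , drop = FALSE]
  C <- v[faces[, 3], , drop = FALSE]
  # solid angle of each spherical triangle (Van Oosterom & Strackee)
  det3 <- A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) -
    A[, 2] * (B[, 1] * C[, 3] - B[, 3] * C[, 1]) +
    A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])
  dots <- 1 + rowSums(A * B) + rowSums(B * C) + rowSums(A * C)
  omega <- abs(2 * atan2(abs(det3), dots))
  cen <- (A + B + C) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  mesh <- list(centroids = cen, omega = omega)
  .icosa_cache[[key]] <- mesh
  mesh
}

#' Per-atom SASA by recursive icosahedral tessellation
#'
#' Each atom's solvent-inflated sphere is tessellated by recursively
#' subdividing an icosahedron (`20 * 4^depth` faces); a face counts as
#' exposed when its centroid lies outside every other inflated sphere, and
#' the atom's SASA is the sum of exposed face areas. Used for the nonpolar
#' part of the per-residue decomposition; converges to the exact sphere area
#' for an isolated atom as `depth` grows.
#'
#' @inheritParams effectiveBornRadii
#' @param depth recursion level (default 3, i.e. 1280 faces per atom).
#' @return numeric vector of per-atom SASA (Angstrom^2), named by serial.
#' @export
sasaIcosa <- function(system, frame = referenceFrame(system),
                      params = solventParams(), depth = 3L, atomIdx = NULL) {
  stopifnot(depth >= 0)
  a <- system@atoms
  f <- .frame_matrix(frame, nrow(a))
  if (is.null(atomIdx)) atomIdx <- seq_len(nrow(a))
  r <- a$sasa_radius[atomIdx] + params@probeRadius
  act <- which(a$sasa_radius[atomIdx] > 0)
  mesh <- .icosphere(depth)
  n <- length(atomIdx)
  out <- numeric(n)
  xyz <- f[atomIdx, , drop = FALSE]
  for (i in act) {
    pts <- sweep(mesh$centroids * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(pts))
    for (j in act) {
      if (j == i) next
      dj <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dj >= r[i] + r[j]) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > r[j]^2
      if (!any(exposed)) break
    }
    out[i] <- r[i]^2 * sum(mesh$omega[exposed])
  }
  names(out) <- a$serial[atomIdx]
  out
}

#' Nonpolar solvation energy from a surface-area change
#'
#' `gammaNonpolar * deltaSASA`, the LCPO-based surface term of the binding
#' energy (0.0072 kcal/mol/Angstrom^2 by default).
#'
#' @param deltaSasa surface-area change on binding, Angstrom^2 (negative for
#'   surface burial).
#' @param params a [SolventModelParams-class].
#' @export
nonpolarEnergy <- function(deltaSasa, params = solventParams())
  params@gammaNonpolar * deltaSasa

#' MM/GBSA binding energy of a single snapshot
#'
#' Single-trajectory binding energy: intermolecular van der Waals and
#' electrostatic terms, the GB polar solvation change
#' `G_pol(complex) - G_pol(receptor) - G_pol(ligand)`, and the nonpolar term
#' `gammaNonpolar * deltaSASA` with `deltaSASA` from [sasaLCPO()] on the
#' three species. Internal bonded terms cancel by construction.
#'
#' @inheritParams pairwiseInteractionEnergies
#' @return an [EnergyBreakdown-class].
#' @examples
#' sys <- toyComplex(2, 3, seed = 1)
#' mmgbsaSnapshot(sys)
#' @export
mmgbsaSnapshot <- function(system, frame = referenceFrame(system),
                           params = solventParams()) {
  f <- .frame_matrix(frame, nrow(system@atoms))
  pw <- pairwiseInteractionEnergies(system, f, params)
  gb <- gbPolarBinding(system, f, params)
  ri <- .receptor_idx(system); li <- .ligand_idx(system)
  dsasa <- sum(sasaLCPO(system, f, params)) -
    sum(sasaLCPO(system, f, params, ri)) -
    sum(sasaLCPO(system, f, params, li))
  .new_breakdown(pw$evdw, pw$eele, gb$gpol, nonpolarEnergy(dsasa, params))
}

#' Per-residue decomposition of a snapshot's binding energy
#'
#' Receptor-residue contributions: van der Waals and electrostatic terms from
#' the receptor-residue-to-ligand pair sums; the polar term from the complex
#' GB pair matrix, assigning each residue-ligand cross term wholly to the
#' residue (the ligand is one unit; receptor-internal and self-term changes
#' cancel in the single-trajectory decomposition convention); the nonpolar
#' term as `gammaNonpolar` times the residue's SASA change between complex
#' and free receptor, via [sasaIcosa()]. The pairwise columns sum over
#' residues to the corresponding intermolecular totals.
#'
#' @inheritParams pairwiseInteractionEnergies
#' @param depth icosahedral subdivision depth for the nonpolar term.
#' @return a [ResidueProfile-class] over the receptor residues.
#' @export
decomposeSnapshot <- function(system, frame = referenceFrame(system),
                              params = solventParams(), depth = 3L) {
  a <- system@atoms
  f <- .frame_matrix(frame, nrow(a))
  ri <- .receptor_idx(system); li <- .ligand_idx(system)
  resIds <- unique(a$resid[ri])
  pw <- pairwiseInteractionEnergies(system, f, params)
  gb <- gbPolarBinding(system, f, params)
  M <- gb$complexPairMatrix
  sasaC <- sasaIcosa(system, f, params, depth)
  sasaR <- sasaIcosa(system, f, params, depth, ri)
  vals <- matrix(0, length(resIds), 5,
                 dimnames = list(resIds,
                                 c("evdw", "eele", "gpol", "gnonpol", "total")))
  pr <- pw$perResidue
  vals[rownames(pr), "evdw"] <- pr[, "evdw"]
  vals[rownames(pr), "eele"] <- pr[, "eele"]
  for (k in seq_along(resIds)) {
    idx <- ri[a$resid[ri] == resIds[k]]
    vals[k, "gpol"] <- 2 * sum(M[idx, li])
    dres <- sum(sasaC[match(idx, seq_len(nrow(a)))]) -
      sum(sasaR[match(idx, ri)])
    vals[k, "gnonpol"] <- nonpolarEnergy(dres, params)
  }
  vals[, "total"] <- rowSums(vals[, 1:4, drop = FALSE])
  resnames <- a$resname[ri][match(resIds, a$resid[ri])]
  new("ResidueProfile", values = vals, resnames = resnames)
}
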