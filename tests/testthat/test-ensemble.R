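# Ensemble statistics, geometry monitors, differential residues

test_that("identical frames give zero SEM and the single-frame values", {
  sys <- toyComplex(2, 3, seed = 4)
  f <- referenceFrame(sys)
  ens <- ensemble(sys, list(f, f, f))
  st <- ensembleEnergyStats(ens)
  expect_equal(unname(st@sem), rep(0, 5))
  expect_equal(energyComponents(st@mean),
               energyComponents(mmgbsaSnapshot(sys, f)), tolerance = 1e-12)
})

test_that("mean and SEM follow the sample formulas", {
  # totals -40, -42, -44 must summarise as -42 +/- 2/sqrt(3)
  x <- c(-40, -42, -44)
  expect_equal(mean(x), -42)
  expect_equal(sd(x) / sqrt(3), 2 / sqrt(3), tolerance = 1e-12)
  # and the ensemble path reproduces the same arithmetic on real frames
  sys <- toyComplex(2, 2, seed = 6)
  ens <- jitterEnsemble(sys, nFrames = 3, sigma = 0.05, seed = 8)
  st <- ensembleEnergyStats(ens)
  per <- sapply(frames(ens), function(f)
    energyComponents(mmgbsaSnapshot(sys, f))[["total"]])
  expect_equal(energyComponents(st@mean)[["total"]], mean(per),
               tolerance = 1e-12)
  expect_equal(st@sem[["total"]], sd(per) / sqrt(3), tolerance = 1e-12)
})

test_that("energy report strings use the two-decimal mean-sem convention", {
  expect_equal(formatEnergy(-41.418, 0.131), "-41.42 ± 0.13")
  expect_equal(formatEnergy(-42, 2 / sqrt(3)), "-42.00 ± 1.15")
  sys <- toyComplex(2, 2, seed = 6)
  ens <- jitterEnsemble(sys, nFrames = 2, sigma = 0.05, seed = 8)
  st <- ensembleEnergyStats(ens)
  m <- energyComponents(st@mean)[["total"]]
  expect_match(formatEnergy(m, st@sem[["total"]]),
               "^-?[0-9]+\\.[0-9]{2} ± [0-9]+\\.[0-9]{2}$")
})

test_that("a single frame reports an undefined SEM", {
  sys <- toyComplex(2, 2, seed = 6)
  ens <- ensemble(sys, list(referenceFrame(sys)))
  st <- ensembleEnergyStats(ens)
  expect_true(all(is.na(st@sem)))
  expect_equal(st@nFrames, 1L)
})

test_that("ensemble decomposition is the frame average of snapshots", {
  sys <- toyComplex(2, 3, seed = 11)
  ens <- jitterEnsemble(sys, nFrames = 2, sigma = 0.1, seed = 3)
  avg <- ensembleDecomposition(ens, depth = 2L)
  p1 <- decomposeSnapshot(sys, frames(ens)[[1]], depth = 2L)
  p2 <- decomposeSnapshot(sys, frames(ens)[[2]], depth = 2L)
  expect_equal(avg@values, (p1@values + p2@values) / 2, tolerance = 1e-12)
  # linearity preserves conservation of the averaged pairwise terms
  pw <- lapply(frames(ens), function(f)
    pairwiseInteractionEnergies(sys, f))
  expect_equal(sum(avg@values[, "evdw"]),
               mean(sapply(pw, `[[`, "evdw")), tolerance = 1e-6)
})

test_that("SEM shrinks as 1/sqrt(n) for i.i.d. frames", {
  sys <- toyComplex(2, 3, seed = 30)
  semN <- function(n) {
    ens <- jitterEnsemble(sys, nFrames = n, sigma = 0.05, seed = 99)
    ensembleEnergyStats(ens)@sem[["total"]]
  }
  s10 <- semN(10)
  s40 <- semN(40)
  # ratio should be near 2 (sqrt(40/10)); generous statistical band
  expect_gt(s10 / s40, 1.2)
  expect_lt(s10 / s40, 3.5)
})

test_that("superposition RMSD is zero for the reference and any rigid copy", {
  sys <- toyComplex(3, 4, seed = 13)
  f <- referenceFrame(sys)
  th <- 0.8
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(f %*% Rz, 2, c(3, -1, 7), "+")
  ens <- ensemble(sys, list(f, moved))
  rms <- superposeRMSD(ens, selection = seq_len(nAtoms(sys)))
  expect_equal(values(rms)[1], 0, tolerance = 1e-10)
  expect_equal(values(rms)[2], 0, tolerance = 1e-8)
})

test_that("superposition RMSD matches a hand value on a known displacement", {
  sys <- toyComplex(2, 2, seed = 17)
  f <- referenceFrame(sys)
  g <- f
  sel <- 1:3
  # displace one selected atom by d perpendicular to the selection plane:
  # after optimal superposition of an asymmetric selection the residual is
  # bounded by the raw displacement
  g[3, ] <- g[3, ] + c(0, 0, 0.6)
  ens <- ensemble(sys, list(f, g))
  rms <- superposeRMSD(ens, selection = sel)
  raw <- sqrt(mean(c(0, 0, 0.6^2)))
  expect_lte(values(rms)[2], raw + 1e-9)
  expect_gt(values(rms)[2], 0)
})

test_that("superposition requires at least three atoms", {
  sys <- toyComplex(2, 2, seed = 17)
  ens <- ensemble(sys, list(referenceFrame(sys)))
  expect_error(superposeRMSD(ens, selection = 1:2), "3")
})

test_that("pocket residues respect the inclusive cutoff boundary", {
  # one residue with nearest heavy atom at 4.9 A, another at 5.1 A
  atoms <- data.frame(
    serial = 1:3, name = c("CA", "CA", "N1"), resid = c(1, 2, 3),
    resname = c("ALA", "ALA", "LIG"),
    segment = c("receptor", "receptor", "ligand"),
    x = c(4.9, 5.1, 0), y = 0, z = 0,
    charge = 0, lj_rmin_half = 1.9, lj_epsilon = 0.1, gb_radius = 1.7,
    gb_screen = 0.72, sasa_radius = 1.7, p1 = 0.7887, p2 = -0.28,
    p3 = -0.0013, p4 = 0.00039, stringsAsFactors = FALSE)
  sys <- new("MolecularSystem", atoms = atoms, ligandLabel = "L")
  expect_equal(pocketResidues(sys, cutoff = 5.0), 1L)
})

test_that("pocket detection agrees with a brute-force distance scan", {
  sys <- toyComplex(6, 4, seed = 41)
  f <- referenceFrame(sys)
  a <- atoms(sys)
  got <- pocketResidues(sys, f, cutoff = 6.5)
  ri <- which(a$segment == "receptor")
  li <- which(a$segment == "ligand")
  want <- sort(unique(unlist(lapply(ri, function(i) {
    dmin <- min(sqrt(colSums((t(f[li, , drop = FALSE]) - f[i, ])^2)))
    if (dmin <= 6.5) a$resid[i] else NULL
  }))))
  expect_equal(got, want)
})

test_that("distance series reproduce static and 3-4-5 geometries", {
  sys <- toyComplex(2, 2, seed = 19)
  f <- referenceFrame(sys)
  f[1, ] <- c(0, 0, 0)   # receptor CA of residue 1
  idxLig <- which(atoms(sys)$name == "N1")
  f[idxLig, ] <- c(3, 4, 0)
  ens <- ensemble(sys, list(f, f, f))
  ds <- distanceSeries(ens, list(resid = 1, name = "CA"),
                       list(name = "N1"))
  expect_equal(unname(values(ds)), rep(5, 3))
  s <- summary(ds)
  expect_equal(s[["sd"]], 0)
  expect_error(distanceSeries(ens, list(name = "CA"), list(name = "N1")),
               "exactly one")
})

test_that("hydrogen-bond occupancy counts qualifying frames", {
  # hand-built donor-hydrogen-acceptor triangle: ideal in 2 frames, broken
  # in 1 by stretching D...A beyond the cutoff
  atoms <- data.frame(
    serial = 1:4, name = c("OD1", "N1", "H1", "C2"), resid = c(1, 2, 2, 2),
    resname = c("ASP", "LIG", "LIG", "LIG"),
    segment = c("receptor", "ligand", "ligand", "ligand"),
    x = c(2.8, 0, 1.0, -1.5), y = 0, z = 0,
    charge = 0, lj_rmin_half = 1.9, lj_epsilon = 0.1, gb_radius = 1.7,
    gb_screen = 0.72, sasa_radius = 1.7, p1 = 0.7887, p2 = -0.28,
    p3 = -0.0013, p4 = 0.00039, stringsAsFactors = FALSE)
  sys <- new("MolecularSystem", atoms = atoms, ligandLabel = "L")
  f1 <- referenceFrame(sys)               # D...A 2.8, angle 180
  f2 <- f1; f2[1, 1] <- 4.2               # beyond 3.5 cutoff
  ens <- ensemble(sys, list(f1, f1, f2))
  occ <- hbondOccupancy(ens, donor = list(name = "N1"),
                        acceptor = list(name = "OD1"),
                        hydrogen = list(name = "H1"))
  expect_equal(occ, 2 / 3)
  expect_equal(hbondOccupancy(ensemble(sys, list(f2)),
                              donor = list(name = "N1"),
                              acceptor = list(name = "OD1")), 0)
  expect_equal(hbondOccupancy(ensemble(sys, list(f1)),
                              donor = list(name = "N1"),
                              acceptor = list(name = "OD1"),
                              hydrogen = list(name = "H1")), 1)
})

test_that("differential residues obey the threshold rule and antisymmetry", {
  mk <- function(tot) {
    v <- cbind(evdw = tot, eele = 0, gpol = 0, gnonpol = 0, total = tot)
    rownames(v) <- as.character(seq_along(tot))
    new("ResidueProfile", values = v,
        resnames = rep("ALA", length(tot)))
  }
  pa <- mk(c(-3.0, -1.2, 0.4))
  pb <- mk(c(-1.0, -1.1, 0.4))
  d <- differentialResidues(pa, pb, threshold = 0.5)
  expect_equal(d$resid, 1L)
  expect_equal(d$delta, -2.0)
  expect_equal(nrow(differentialResidues(pa, pa)), 0L)
  dBA <- differentialResidues(pb, pa, threshold = 0.5)
  expect_equal(dBA$delta, -d$delta)
  # inclusive boundary
  pc <- mk(c(-3.5, -1.2, 0.4))
  expect_true(1 %in% differentialResidues(pc, pb, threshold = 0.5)$resid)
  pd <- mk(c(-9, -9))
  rownames(pd@values) <- c("90", "91")
  expect_error(differentialResidues(pa, pd), "share no residues")
})
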