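# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit double loops, numerical quadrature and
# point-sampling surface areas.

# explicit double loop over all receptor-ligand pairs
bruteForcePairEnergies <- function(system, frame = referenceFrame(system),
                                   params = solventParams()) {
  a <- atoms(system)
  ri <- which(a$segment == "receptor")
  li <- which(a$segment == "ligand")
  evdw <- eele <- 0
  perRes <- list()
  for (i in ri) for (j in li) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    v <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    e <- params@coulombConst * a$charge[i] * a$charge[j] / (params@epsIn * r)
    evdw <- evdw + v
    eele <- eele + e
    key <- as.character(a$resid[i])
    old <- perRes[[key]]
    if (is.null(old)) old <- c(evdw = 0, eele = 0)
    perRes[[key]] <- old + c(evdw = v, eele = e)
  }
  list(evdw = evdw, eele = eele, perResidue = perRes)
}

# Shrake-Rupley numerical SASA: near-uniform golden-spiral points per sphere
shrakeRupleySasa <- function(coords, radii, probe = 1.4, nPoints = 960) {
  k <- seq_len(nPoints) - 0.5
  phi <- acos(1 - 2 * k / nPoints)
  theta <- pi * (1 + sqrt(5)) * k
  unitPts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  r <- radii + probe
  act <- which(radii > 0)
  sasa <- numeric(length(radii))
  for (i in act) {
    pts <- sweep(unitPts * r[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, nPoints)
    for (j in act) {
      if (j == i) next
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      exposed <- exposed & d2 > r[j]^2
    }
    sasa[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  sasa
}

# 3-D grid quadrature of the descreening integral: (1/4pi) * integral of
# |x - xi|^-4 over the sphere of radius s at distance d, excluding
# |x - xi| < rho
numericalDescreenIntegral <- function(d, s, rho, h = 0.02) {
  g <- seq(-s, s, by = h)
  gx <- rep(g, times = length(g)^2)
  gy <- rep(rep(g, each = length(g)), times = length(g))
  gz <- rep(g, each = length(g)^2)
  inside <- gx^2 + gy^2 + gz^2 <= s^2
  # descreening sphere centred at (d, 0, 0) relative to atom i
  r2 <- (gx[inside] + d)^2 + gy[inside]^2 + gz[inside]^2
  keep <- r2 > rho^2
  sum(1 / r2[keep]^2) * h^3 / (4 * pi)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# a small random parameterised system built independently of toyComplex,
# for oracle comparisons where we want full control of every parameter
randomSystem <- function(nRec, nLig, seed, spread = 4) {
  set.seed(seed)
  n <- nRec + nLig
  repeat {
    xyz <- matrix(runif(n * 3, -spread, spread), n, 3)
    if (min(dist(xyz)) > 1.0) break
  }
  atoms <- data.frame(
    serial = seq_len(n),
    name = paste0("X", seq_len(n)),
    resid = c(rep(seq_len(ceiling(nRec / 2)), each = 2)[seq_len(nRec)],
              rep(ceiling(nRec / 2) + 1, nLig)),
    resname = "UNK",
    segment = c(rep("receptor", nRec), rep("ligand", nLig)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = runif(n, -0.8, 0.8),
    lj_rmin_half = runif(n, 1.5, 2.0),
    lj_epsilon = runif(n, 0.05, 0.25),
    gb_radius = runif(n, 1.2, 1.8),
    gb_screen = runif(n, 0.7, 0.9),
    sasa_radius = runif(n, 1.4, 1.9),
    p1 = 0.7887, p2 = -0.28063, p3 = -0.0012968, p4 = 0.00039328,
    stringsAsFactors = FALSE)
  new("MolecularSystem", atoms = atoms, ligandLabel = "rnd")
}

# single-atom-per-call Born-style system builder for closed-form GB checks
ionSystem <- function(charges, coords, gbRadius, screen = 0.8) {
  n <- length(charges)
  atoms <- data.frame(
    serial = seq_len(n), name = paste0("I", seq_len(n)),
    resid = c(1, rep(2, max(0, n - 1))), resname = "ION",
    segment = c("receptor", rep("ligand", max(0, n - 1))),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = charges, lj_rmin_half = 1.7, lj_epsilon = 0.1,
    gb_radius = gbRadius, gb_screen = screen, sasa_radius = 1.7,
    p1 = 0.7887, p2 = -0.28063, p3 = -0.0012968, p4 = 0.00039328,
    stringsAsFactors = FALSE)
  new("MolecularSystem", atoms = atoms, ligandLabel = "ion")
}
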