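# Energy matrix assembly, Ward/Manhattan clustering, groups, fractions,
# colour scale and Newick export

.profileFromTotals <- function(tot, resids = seq_along(tot)) {
  v <- cbind(evdw = tot, eele = 0, gpol = 0, gnonpol = 0, total = tot)
  rownames(v) <- as.character(resids)
  new("ResidueProfile", values = v, resnames = rep("RES", length(tot)))
}

test_that("matrix assembly drops only residues below eps everywhere", {
  pa <- .profileFromTotals(c(-2.0, 0, -0.01, 0.002))
  pb <- .profileFromTotals(c(-1.5, 0, 0, 0.001))
  m <- buildEnergyMatrix(list(ligA = pa, ligB = pb), eps = 0.005)
  expect_equal(rownames(values(m)), c("RES1", "RES3"))
  expect_equal(colnames(values(m)), c("ligA", "ligB"))
  expect_error(buildEnergyMatrix(list(pa, pb)), "named")
  expect_error(buildEnergyMatrix(list(x = pa, x = pb)), "named")
})

test_that("the nonzero filter reproduces its boundary behaviour on a matrix", {
  m <- rbind(a = c(-0.01, 0), b = c(0.004, 0.004), c = c(0, 0))
  colnames(m) <- c("L1", "L2")
  kept <- rownames(values(buildEnergyMatrix(m, eps = 0.005)))
  expect_equal(kept, "a")
})

test_that("Manhattan distance satisfies its definition and the triangle inequality", {
  expect_equal(manhattanDistance(c(1, 2), c(1, 2)), 0)
  expect_equal(manhattanDistance(c(-3.67, -2.0, 0, 1), c(0, 0, 0, 0)), 6.67)
  expect_error(manhattanDistance(1:3, 1:4), "length")
  set.seed(101)
  for (i in 1:1000) {
    a <- rnorm(4); b <- rnorm(4); c <- rnorm(4)
    expect_lte(manhattanDistance(a, c),
               manhattanDistance(a, b) + manhattanDistance(b, c) + 1e-12)
  }
})

test_that("two rows merge once at their Manhattan distance", {
  m <- rbind(r1 = c(-2, -1), r2 = c(0, 0.5))
  colnames(m) <- c("L1", "L2")
  tr <- wardTree(m)
  expect_equal(length(tr@height), 1L)
  expect_equal(tr@height, manhattanDistance(m[1, ], m[2, ]))
  expect_error(wardTree(m[1, , drop = FALSE]), "2 rows")
})

test_that("well-separated pairs merge before the pairs join", {
  m <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 10), d = c(10.1, 10))
  colnames(m) <- c("L1", "L2")
  tr <- wardTree(m)
  first2 <- tr@merge[1:2, ]
  leafPairs <- apply(first2, 1, function(r) sort(-as.numeric(r)))
  pairsFound <- list(leafPairs[, 1], leafPairs[, 2])
  expect_true(any(vapply(pairsFound, identical, logical(1), c(1, 2))))
  expect_true(any(vapply(pairsFound, identical, logical(1), c(3, 4))))
})

test_that("Ward heights are monotone and invariant to row order", {
  set.seed(7)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("r", 1:10), paste0("L", 1:4)))
  tr <- wardTree(m)
  expect_true(all(diff(tr@height) >= -1e-9))
  perm <- sample(10)
  tr2 <- wardTree(m[perm, ])
  expect_equal(sort(tr@height), sort(tr2@height), tolerance = 1e-9)
  # groupings agree up to relabelling
  g1 <- cutGroups(tr, 3)
  g2 <- cutGroups(tr2, 3)
  expect_equal(adjustedRand(g1[rownames(m)], g2[rownames(m)]), 1)
})

test_that("authored Ward linkage reproduces hclust ward.D on the same distances", {
  set.seed(17)
  m <- matrix(rnorm(60), 15, 4,
              dimnames = list(paste0("r", 1:15), paste0("L", 1:4)))
  tr <- wardTree(m)
  hc <- hclust(dist(m, method = "manhattan"), method = "ward.D")
  expect_equal(tr@height, hc$height, tolerance = 1e-9)
  for (k in c(2, 4, 7)) {
    g1 <- cutGroups(tr, k)
    g2 <- cutree(hc, k)
    expect_equal(adjustedRand(g1[rownames(m)], g2[rownames(m)]), 1)
  }
})

test_that("cutting recovers planted groups exactly", {
  pm <- plantedMatrix(groupSizes = c(10, 10, 10, 10),
                      groupMeans = c(-2.5, -0.8, -0.2, 0.1),
                      withinSd = 0.02, seed = 5)
  tr <- wardTree(pm$matrix)
  g <- cutGroups(tr, 4, pm$matrix)
  expect_equal(adjustedRand(g[names(pm$labels)], pm$labels), 1)
  # strength-ordered labels: group A must hold the -2.5 residues
  expect_true(all(g[names(pm$labels)[pm$labels == 1]] == "A"))
})

test_that("trivial cuts return one group and all singletons", {
  set.seed(3)
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("r", 1:6), paste0("L", 1:4)))
  tr <- wardTree(m)
  expect_equal(length(unique(cutGroups(tr, 1))), 1L)
  expect_equal(length(unique(cutGroups(tr, 6))), 6L)
  expect_error(cutGroups(tr, 0), "k")
  expect_error(cutGroups(tr, 7), "k")
})

test_that("hot-spot filter applies the inclusive 0.5 kcal/mol rule", {
  m <- rbind(r1 = c(-1.97, -0.3), r2 = c(-0.49, -0.49),
             r3 = c(-0.5, 0), r4 = c(0.6, 0.2))
  colnames(m) <- c("L1", "L2")
  hs <- hotspotFilter(m, 0.5)
  expect_equal(hs$L1, c("r1", "r3", "r4"))
  expect_equal(hs$L2, character(0))
  prof <- .profileFromTotals(c(-1.97, -0.49, -0.5))
  expect_equal(hotspotFilter(prof), c("1", "3"))
  expect_error(hotspotFilter(m, 0), "threshold")
})

test_that("group fractions are hand-checkable percentages", {
  m <- rbind(r1 = c(-20, -10), r2 = c(-12, -6), r3 = c(-8, -4))
  colnames(m) <- c("L1", "L2")
  groups <- c(r1 = "A", r2 = "A", r3 = "B")
  ref <- c(L1 = -40, L2 = -40)
  fr <- groupFractions(m, groups, ref)
  expect_equal(fr["A", "L1"], 80)
  expect_equal(fr["A", "L2"], 40)
  expect_equal(fr["B", "L1"], 20)
  # all residues summing to the reference give 100%
  expect_equal(groupFractions(m, c(r1 = "A", r2 = "A", r3 = "A"),
                              c(L1 = -40, L2 = -20))["A", ],
               c(L1 = 100, L2 = 100))
  expect_error(groupFractions(m, groups, c(L1 = 0, L2 = -40)), "zero")
})

test_that("colour intensities anchor at the extremes and clamp beyond", {
  m <- rbind(r1 = c(-3.91, 0), r2 = c(0.20, -1.955))
  colnames(m) <- c("L1", "L2")
  cv <- colorValues(m, redAnchor = -3.91, blueAnchor = 0.20)
  expect_equal(cv["r1", "L1"], -1.0)
  expect_equal(cv["r1", "L2"], 0)
  expect_equal(cv["r2", "L1"], 1.0)
  expect_equal(cv["r2", "L2"], -0.5)
  # beyond-anchor clamping
  cv2 <- colorValues(m, redAnchor = -1, blueAnchor = 0.1)
  expect_equal(cv2["r1", "L1"], -1.0)
  expect_equal(cv2["r2", "L1"], 1.0)
  expect_error(colorValues(m, redAnchor = 1, blueAnchor = 2), "redAnchor")
})

test_that("Newick output round-trips through ape", {
  pm <- plantedMatrix(groupSizes = c(4, 4), groupMeans = c(-2, -0.5),
                      withinSd = 0.05, seed = 9)
  tr <- wardTree(pm$matrix)
  nw <- treeToNewick(tr)
  ph <- ape::read.tree(text = nw)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, rownames(values(pm$matrix)))
  # topology preserved: cutting the parsed tree into 2 recovers the groups
  g <- cutGroups(tr, 2, pm$matrix)
  dists <- ape::cophenetic.phylo(ph)
  within <- max(dists[names(g)[g == "A"], names(g)[g == "A"]])
  across <- min(dists[names(g)[g == "A"], names(g)[g == "B"]])
  expect_lt(within, across)
  # two-leaf convention: "(A:h/2,B:h/2);"
  m2 <- rbind(a = c(0, 0), b = c(4, 0))
  colnames(m2) <- c("L1", "L2")
  t2 <- wardTree(m2)
  p2 <- ape::read.tree(text = treeToNewick(t2))
  expect_equal(sort(p2$edge.length), c(2, 2))
  expect_error(treeToNewick(t2, labels = "onlyone"), "labels")
})

test_that("the binding-mode report splits the dominant group into subgroups", {
  pm <- plantedMatrix(groupSizes = c(3, 3, 6, 8),
                      groupMeans = c(-3.2, -2.6, -1.0, 0.5),
                      withinSd = 0.05, seed = 33)
  ref <- c(L1 = -40, L2 = -41, L3 = -39, L4 = -38)
  rep <- bindingModeReport(pm$matrix, k = 3, referenceTotals = ref)
  # with k = 3 the two strong planted groups merge into A; its split must
  # recover them as A1 (strong) and A2 (relatively strong)
  g <- rep$groups
  lab <- pm$labels
  expect_true(all(g[names(lab)[lab %in% c(1, 2)]] == "A"))
  expect_setequal(rep$subgroups$A1, names(lab)[lab == 1])
  expect_setequal(rep$subgroups$A2, names(lab)[lab == 2])
  expect_equal(dim(rep$fractions), c(3L, 4L))
  # fractions of a partition add up to the all-residue share
  total <- colSums(values(pm$matrix)) / ref * 100
  expect_equal(colSums(rep$fractions), total, tolerance = 1e-9)
  expect_type(rep$newick, "character")
})
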