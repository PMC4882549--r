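# Residue-by-ligand energy matrices, Ward clustering on Manhattan distances,
# hot-spot groups, fractions, colour scales and Newick export.

#' Assemble a residue-by-ligand energy matrix
#'
#' Rows are residues, columns ligands, entries per-residue total energies.
#' Residues contributing to no ligand are dropped: a residue is kept when its
#' absolute energy reaches `eps` for at least one ligand. The default
#' `eps = 0.005` is the rounding precision of a two-decimal report, i.e. the
#' operational meaning of "nonzero contribution".
#'
#' @param profiles named list of [ResidueProfile-class] objects, one per
#'   ligand (names become column labels and must be unique); alternatively an
#'   already-assembled [EnergyMatrix-class] or labelled matrix, to which only
#'   the retention filter is applied.
#' @param eps retention threshold, kcal/mol.
#' @return an [EnergyMatrix-class].
#' @export
buildEnergyMatrix <- function(profiles, eps = 0.005) {
  if (is(profiles, "EnergyMatrix") || is.matrix(profiles)) {
    m <- if (is(profiles, "EnergyMatrix")) profiles@values else profiles
    keep <- apply(abs(m) >= eps, 1, any)
    return(new("EnergyMatrix", values = m[keep, , drop = FALSE]))
  }
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop("profiles must be uniquely named by ligand", call. = FALSE)
  resids <- rownames(profiles[[1]]@values)
  resnames <- profiles[[1]]@resnames
  for (p in profiles)
    if (!identical(rownames(p@values), resids))
      stop("profiles must share residue indexing", call. = FALSE)
  m <- vapply(profiles, function(p) p@values[, "total"],
              numeric(length(resids)))
  rownames(m) <- paste0(resnames, resids)
  keep <- apply(abs(m) >= eps, 1, any)
  new("EnergyMatrix", values = m[keep, , drop = FALSE])
}

#' Manhattan distance between energy vectors
#'
#' `sum_i |a_i - b_i|`: the city-block similarity used to compare residues'
#' energy-contribution vectors across the ligand panel.
#'
#' @param a,b numeric vectors of equal length (kcal/mol).
#' @return the distance, kcal/mol.
#' @export
manhattanDistance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  sum(abs(a - b))
}

# smallest original leaf id contained in each active cluster, used for the
# deterministic tie-break
#' Ward agglomerative clustering of residue energy vectors
#'
#' Hierarchical clustering of the rows of an energy matrix on their pairwise
#' Manhattan distances, with Ward's minimum-variance linkage via the
#' Lance-Williams update
#' `d(k, ij) = [(n_i+n_k) d(k,i) + (n_j+n_k) d(k,j) - n_k d(i,j)] / (n_i+n_j+n_k)`.
#' Distances enter as given (not squared), the classic behaviour of Ward
#' clustering applied to a precomputed non-Euclidean distance matrix. Ties
#' are broken deterministically: among equally close candidate pairs, the one
#' with the lexicographically smallest (min leaf id, max leaf id) merges
#' first. Ward heights are monotone non-decreasing.
#'
#' @param mat an [EnergyMatrix-class] (or plain matrix with rownames).
#' @return a [ClusterTree-class].
#' @export
wardTree <- function(mat) {
  v <- if (is(mat, "EnergyMatrix")) mat@values else mat
  n <- nrow(v)
  if (n < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  D <- as.matrix(stats::dist(v, method = "manhattan"))
  size <- rep(1L, n)
  minleaf <- seq_len(n)           # smallest leaf id in each active cluster
  id <- -seq_len(n)               # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    Dsub <- D[act, act, drop = FALSE]
    diag(Dsub) <- Inf
    dmin <- min(Dsub)
    cand <- which(Dsub - dmin <= 1e-12 * max(1, dmin), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keyA <- pmin(minleaf[act[cand[, 1]]], minleaf[act[cand[, 2]]])
    keyB <- pmax(minleaf[act[cand[, 1]]], minleaf[act[cand[, 2]]])
    pick <- order(keyA, keyB)[1]
    i <- act[cand[pick, 1]]; j <- act[cand[pick, 2]]
    pair <- sort(c(id[i], id[j]))
    # hclust orders singleton entries (negative) before cluster references
    merge[step, ] <- if (pair[1] < 0 && pair[2] < 0) pair else
      if (id[i] < 0) c(id[i], id[j]) else if (id[j] < 0) c(id[j], id[i]) else
        c(min(id[i], id[j]), max(id[i], id[j]))
    height[step] <- D[i, j]
    ni <- size[i]; nj <- size[j]
    for (k in act) {
      if (k == i || k == j) next
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[k, i] + (nj + nk) * D[k, j] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active[j] <- FALSE
  }
  new("ClusterTree", merge = merge, height = height, labels = rownames(v))
}

# ClusterTree -> base hclust object (for ape interop and plotting)
.as_hclust <- function(tree) {
  n <- length(tree@labels)
  # leaf ordering by in-order traversal of the merge structure
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) ord <<- c(ord, -node)
    else { walk(tree@merge[node, 1]); walk(tree@merge[node, 2]) }
  }
  walk(n - 1L)
  structure(list(merge = tree@merge, height = tree@height, order = ord,
                 labels = tree@labels, method = "ward.D",
                 dist.method = "manhattan"),
            class = "hclust")
}

#' Cut a cluster tree into k groups
#'
#' Undoes the last `k - 1` merges. When `mat` is supplied, groups are
#' labelled `A`, `B`, ... in descending order of the group's mean absolute
#' energy across ligands (so `A` is the energetically dominant group);
#' otherwise integer group ids are returned.
#'
#' @param tree a [ClusterTree-class].
#' @param k number of groups, `1 <= k <=` number of leaves.
#' @param mat optional [EnergyMatrix-class] whose rows match the tree's
#'   leaves, used for group labelling.
#' @return named vector (leaf label -> group) of letters, or integers when
#'   `mat` is `NULL`.
#' @export
cutGroups <- function(tree, k, mat = NULL) {
  n <- length(tree@labels)
  if (k < 1 || k > n) stop("k must be in [1, n_leaves]", call. = FALSE)
  gr <- stats::cutree(.as_hclust(tree), k = k)
  names(gr) <- tree@labels
  if (is.null(mat)) return(gr)
  v <- if (is(mat, "EnergyMatrix")) mat@values else mat
  strength <- vapply(split(rownames(v), gr[rownames(v)]),
                     function(rows) mean(abs(v[rows, , drop = FALSE])),
                     numeric(1))
  ranks <- rank(-strength, ties.method = "first")
  relabel <- stats::setNames(LETTERS[ranks], names(strength))
  stats::setNames(unname(relabel[as.character(gr)]), names(gr))
}

#' Hot-spot residues per ligand
#'
#' Residues whose absolute energy contribution reaches `threshold`
#' (inclusive) for a given ligand; the conventional cutoff is 0.5 kcal/mol.
#'
#' @param mat an [EnergyMatrix-class] (or a [ResidueProfile-class], in which
#'   case totals are used and a single set is returned).
#' @param threshold kcal/mol, > 0.
#' @return for a matrix, a named list (ligand -> character vector of residue
#'   labels); for a profile, a character vector.
#' @export
hotspotFilter <- function(mat, threshold = 0.5) {
  stopifnot(threshold > 0)
  if (is(mat, "ResidueProfile")) {
    tot <- mat@values[, "total"]
    return(rownames(mat@values)[abs(tot) >= threshold])
  }
  v <- if (is(mat, "EnergyMatrix")) mat@values else mat
  lapply(stats::setNames(colnames(v), colnames(v)),
         function(l) rownames(v)[abs(v[, l]) >= threshold])
}

#' Share of the binding energy carried by each residue group
#'
#' For each ligand, the summed energy of a group divided by that ligand's
#' reference total (conventionally its total MM/GBSA binding free energy),
#' in percent.
#'
#' @param mat an [EnergyMatrix-class].
#' @param groups named group assignment from [cutGroups()].
#' @param referenceTotals named numeric, ligand -> total energy (kcal/mol,
#'   nonzero).
#' @return matrix groups x ligands of percentages.
#' @export
groupFractions <- function(mat, groups, referenceTotals) {
  v <- if (is(mat, "EnergyMatrix")) mat@values else mat
  if (any(referenceTotals == 0)) stop("zero reference total", call. = FALSE)
  ref <- referenceTotals[colnames(v)]
  if (any(is.na(ref)))
    stop("referenceTotals must cover every ligand", call. = FALSE)
  gs <- rowsum(v, groups[rownames(v)])
  sweep(gs, 2, ref, "/") * 100
}

#' Signed colour intensities for a residue-energy heat scale
#'
#' Maps favourable (negative) energies linearly onto the red side `[-1, 0)`
#' and unfavourable (positive) energies onto the blue side `(0, 1]`, with 0
#' at white; values beyond the anchors clamp to full intensity. Defaults
#' anchor at the data extremes, mirroring the convention of colouring the
#' strongest contributor as standard red and the strongest unfavourable
#' residue as standard blue.
#'
#' @param mat an [EnergyMatrix-class] or numeric matrix.
#' @param redAnchor negative energy mapped to -1 (default: data minimum).
#' @param blueAnchor positive energy mapped to +1 (default: data maximum).
#' @return matrix of intensities in `[-1, 1]` with the input's dimnames.
#' @export
colorValues <- function(mat, redAnchor = NULL, blueAnchor = NULL) {
  v <- if (is(mat, "EnergyMatrix")) mat@values else mat
  if (is.null(redAnchor)) redAnchor <- min(v, -1e-12)
  if (is.null(blueAnchor)) blueAnchor <- max(v, 1e-12)
  if (!(redAnchor < 0 && blueAnchor > 0))
    stop("need redAnchor < 0 < blueAnchor", call. = FALSE)
  out <- v
  neg <- v < 0
  out[neg] <- -.clamp(v[neg] / redAnchor, 0, 1)
  out[!neg] <- .clamp(v[!neg] / blueAnchor, 0, 1)
  out
}

#' Newick serialisation of a cluster tree
#'
#' Converts the dendrogram to an ultrametric phylogram (leaf depth = half
#' the merge height, the standard dendrogram-to-phylogeny convention) and
#' writes Newick text via \pkg{ape}.
#'
#' @param tree a [ClusterTree-class].
#' @param labels optional replacement leaf labels (same length and order as
#'   `tree@labels`).
#' @return a single Newick string.
#' @export
treeToNewick <- function(tree, labels = NULL) {
  hc <- .as_hclust(tree)
  if (!is.null(labels)) {
    if (length(labels) != length(tree@labels))
      stop("labels must match the number of leaves", call. = FALSE)
    hc$labels <- labels
  }
  ape::write.tree(ape::as.phylo(hc))
}

# leaf sets under every internal node, in merge order
.merge_leafsets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    pick <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- c(pick(merge[i, 1]), pick(merge[i, 2]))
  }
  sets
}

#' Shared binding-mode report
#'
#' The full hot-spot analysis over a ligand panel: Ward/Manhattan clustering
#' of the energy matrix, a `k`-group cut labelled by energetic strength,
#' hot-spot sets per ligand, per-group energy fractions of each ligand's
#' reference total, the colour scale, and the split of the dominant group
#' into two subgroups (`A1` strong, `A2` relatively strong) obtained by
#' undoing the top group's last internal merge.
#'
#' @param mat an [EnergyMatrix-class].
#' @param k number of residue groups (default 4).
#' @param referenceTotals named numeric, ligand -> total binding energy.
#' @param hotspotThreshold kcal/mol (default 0.5).
#' @return list with `tree`, `groups`, `hotspots`, `fractions`,
#'   `subgroups` (residues of the top group split into `A1`/`A2`),
#'   `subgroupFractions`, `colors` and `newick`.
#' @export
bindingModeReport <- function(mat, k = 4, referenceTotals,
                              hotspotThreshold = 0.5) {
  v <- mat@values
  tree <- wardTree(mat)
  groups <- cutGroups(tree, k, mat)
  topRows <- names(groups)[groups == "A"]
  subgroups <- NULL
  subFrac <- NULL
  if (length(topRows) >= 2) {
    sets <- .merge_leafsets(tree@merge)
    leafIdx <- sort(match(topRows, tree@labels))
    nodeA <- which(vapply(sets, function(s)
      identical(sort(s), leafIdx), logical(1)))[1]
    kids <- tree@merge[nodeA, ]
    leaves <- function(x) tree@labels[if (x < 0) -x else sets[[x]]]
    s1 <- leaves(kids[1]); s2 <- leaves(kids[2])
    m1 <- mean(abs(v[s1, , drop = FALSE]))
    m2 <- mean(abs(v[s2, , drop = FALSE]))
    subgroups <- if (m1 >= m2) list(A1 = s1, A2 = s2) else
      list(A1 = s2, A2 = s1)
    subAssign <- stats::setNames(
      rep(names(subgroups), lengths(subgroups)), unlist(subgroups))
    subFrac <- groupFractions(
      new("EnergyMatrix", values = v[names(subAssign), , drop = FALSE]),
      subAssign, referenceTotals)
  }
  list(tree = tree,
       groups = groups,
       hotspots = hotspotFilter(mat, hotspotThreshold),
       fractions = groupFractions(mat, groups, referenceTotals),
       subgroups = subgroups,
       subgroupFractions = subFrac,
       colors = colorValues(mat),
       newick = treeToNewick(tree))
}
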