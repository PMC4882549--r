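# File formats and run configuration: multi-model PDB (via bio3d), the
# per-atom parameter TSV, energy-matrix CSV, report bundles and YAML config.

.paramColumns <- c("serial", "charge", "lj_rmin_half", "lj_epsilon",
                   "gb_radius", "gb_screen", "sasa_radius",
                   "p1", "p2", "p3", "p4")

#' Read a system and its snapshot ensemble
#'
#' Parses a (multi-model) PDB file with \pkg{bio3d} -- MODEL/ENDMDL blocks
#' become frames -- and joins per-atom force-field/solvation parameters from
#' a TSV with columns `serial`, `charge`, `lj_rmin_half`, `lj_epsilon`,
#' `gb_radius`, `gb_screen`, `sasa_radius`, `p1`..`p4`, matched by atom
#' serial. Atoms without a parameter row are a hard error listing the
#' offending serials. The ligand is identified by chain id or by residue
#' name; everything else is receptor.
#'
#' @param pdbPath path to the PDB file.
#' @param paramPath path to the parameter TSV.
#' @param ligandChain chain identifier of the ligand, or `NULL`.
#' @param ligandResname ligand residue name, used when `ligandChain` is
#'   `NULL`.
#' @param ligandLabel display name (defaults to the resname or chain).
#' @return list with `system` (a [MolecularSystem-class], coordinates from
#'   the first frame) and `ensemble` (an [Ensemble-class] over all frames).
#' @export
readSystem <- function(pdbPath, paramPath, ligandChain = NULL,
                       ligandResname = NULL, ligandLabel = NULL) {
  if (is.null(ligandChain) && is.null(ligandResname))
    stop("specify the ligand by chain or residue name", call. = FALSE)
  pdb <- bio3d::read.pdb(pdbPath, multi = TRUE)
  at <- pdb$atom
  seg <- if (!is.null(ligandChain)) {
    ifelse(at$chain %in% ligandChain, "ligand", "receptor")
  } else {
    ifelse(at$resid %in% ligandResname, "ligand", "receptor")
  }
  par <- utils::read.table(paramPath, header = TRUE, sep = "\t")
  missingCols <- setdiff(.paramColumns, names(par))
  if (length(missingCols))
    stop("parameter table is missing columns: ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  hit <- match(at$eleno, par$serial)
  if (anyNA(hit))
    stop("no parameters for atom serials: ",
         paste(at$eleno[is.na(hit)], collapse = ", "), call. = FALSE)
  par <- par[hit, ]
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, resid = at$resno,
    resname = at$resid, segment = seg,
    x = at$x, y = at$y, z = at$z,
    charge = par$charge, lj_rmin_half = par$lj_rmin_half,
    lj_epsilon = par$lj_epsilon, gb_radius = par$gb_radius,
    gb_screen = par$gb_screen, sasa_radius = par$sasa_radius,
    p1 = par$p1, p2 = par$p2, p3 = par$p3, p4 = par$p4,
    stringsAsFactors = FALSE)
  if (is.null(ligandLabel))
    ligandLabel <- if (!is.null(ligandResname)) ligandResname[1]
      else paste("chain", ligandChain[1])
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  atoms[, c("x", "y", "z")] <- frames[[1]]
  system <- new("MolecularSystem", atoms = atoms, ligandLabel = ligandLabel)
  list(system = system, ensemble = ensemble(system, frames))
}

#' Write a system (and optional ensemble) to PDB + parameter TSV
#'
#' The inverse of [readSystem()]: a multi-model PDB (one MODEL per frame,
#' written with \pkg{bio3d}; receptor atoms on chain A, ligand on chain B)
#' and the per-atom parameter TSV.
#'
#' @param system a [MolecularSystem-class].
#' @param pdbPath,paramPath output paths.
#' @param ens optional [Ensemble-class]; defaults to the single reference
#'   frame.
#' @return invisibly, the two paths.
#' @export
writeSystem <- function(system, pdbPath, paramPath, ens = NULL) {
  a <- system@atoms
  frames <- if (is.null(ens)) list(referenceFrame(system)) else ens@frames
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(file = pdbPath, xyz = xyz, eleno = a$serial,
                   elety = a$name, resno = a$resid, resid = a$resname,
                   chain = ifelse(a$segment == "ligand", "B", "A"))
  utils::write.table(a[, .paramColumns], paramPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(pdb = pdbPath, params = paramPath))
}

#' Write/read a residue-by-ligand energy matrix as CSV
#'
#' First column `residue`, remaining columns one per ligand.
#'
#' @param mat an [EnergyMatrix-class].
#' @param path CSV path.
#' @return `writeEnergyMatrix` invisibly returns `path`;
#'   `readEnergyMatrix` returns an [EnergyMatrix-class].
#' @export
writeEnergyMatrix <- function(mat, path) {
  df <- data.frame(residue = rownames(mat@values), mat@values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnergyMatrix
#' @export
readEnergyMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new("EnergyMatrix", values = m)
}

#' Validated run configuration
#'
#' Central container for the analysis thresholds and settings, serialisable
#' to YAML: the hot-spot and differential-residue cutoffs (kcal/mol), pocket
#' cutoff (Angstrom), nonzero-contribution epsilon (kcal/mol), sensitivity
#' fold threshold, conversion temperature (K), cluster count and RNG seed,
#' plus any [solventParams()] overrides.
#'
#' @param hotspotThreshold,differentialThreshold kcal/mol (default 0.5).
#' @param pocketCutoff Angstrom (default 5.0).
#' @param eps nonzero-contribution threshold, kcal/mol (default 0.005).
#' @param sensitivityFold fold-change threshold (default 5).
#' @param temperature Kelvin (default 298.15).
#' @param clusterK residue groups to cut (default 4).
#' @param seed RNG seed.
#' @param solvent named list of [solventParams()] overrides.
#' @return a validated list of class `"gbsaRunConfig"`.
#' @export
runConfig <- function(hotspotThreshold = 0.5, differentialThreshold = 0.5,
                      pocketCutoff = 5.0, eps = 0.005, sensitivityFold = 5,
                      temperature = 298.15, clusterK = 4, seed = 1,
                      solvent = list()) {
  cfg <- list(hotspotThreshold = hotspotThreshold,
              differentialThreshold = differentialThreshold,
              pocketCutoff = pocketCutoff, eps = eps,
              sensitivityFold = sensitivityFold, temperature = temperature,
              clusterK = clusterK, seed = seed, solvent = solvent)
  num <- cfg[c("hotspotThreshold", "differentialThreshold", "pocketCutoff",
               "eps", "sensitivityFold", "temperature", "clusterK")]
  if (any(unlist(num) <= 0))
    stop("all thresholds must be positive", call. = FALSE)
  do.call(solventParams, c(solvent, list(temperature = temperature)))
  structure(cfg, class = "gbsaRunConfig")
}

#' @rdname runConfig
#' @param path YAML path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @param cfg a run configuration.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$solvent)) raw$solvent <- list()
  do.call(runConfig, raw)
}

#' Write a report bundle
#'
#' Serialises the results of a pipeline run into `outDir`: an energy table
#' CSV with two-decimal "mean ± sem" strings, per-residue decomposition
#' CSVs, the residue-by-ligand matrix CSV, the dendrogram as Newick, a JSON
#' report (groups, hot spots, fractions, colour values) and a plain-text log
#' echoing the configuration and seed.
#'
#' @param results list with any of: `energyTable` (data.frame),
#'   `profiles` (named list of [ResidueProfile-class]), `matrix`
#'   (an [EnergyMatrix-class]), `bindingMode` (from [bindingModeReport()]),
#'   `config` (from [runConfig()]).
#' @param outDir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(results, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(results$energyTable)) {
    p <- file.path(outDir, "energy_table.csv")
    utils::write.csv(results$energyTable, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (lig in names(results$profiles)) {
    p <- file.path(outDir, paste0("residues_", lig, ".csv"))
    prof <- results$profiles[[lig]]
    utils::write.csv(data.frame(resid = rownames(prof@values),
                                resname = prof@resnames, prof@values),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results$matrix))
    paths <- c(paths, writeEnergyMatrix(results$matrix,
                                        file.path(outDir, "energy_matrix.csv")))
  bm <- results$bindingMode
  if (!is.null(bm)) {
    nw <- file.path(outDir, "tree.newick")
    writeLines(bm$newick, nw)
    js <- file.path(outDir, "report.json")
    jsonlite::write_json(list(
      groups = as.list(bm$groups),
      hotspots = bm$hotspots,
      fractions = as.data.frame(bm$fractions),
      subgroups = bm$subgroups,
      colors = as.data.frame(bm$colors)), js, auto_unbox = TRUE,
      digits = NA)
    paths <- c(paths, nw, js)
  }
  lg <- file.path(outDir, "run.log")
  cfg <- results$config
  writeLines(c(
    paste("gbsaHotspots report,", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(cfg)) paste0("config: ", yaml::as.yaml(unclass(cfg)))
    else "config: defaults"), lg)
  invisible(c(paths, lg))
}
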