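# Synthetic ground-truth generators: a toy protein with disulfides at
# designed burial, an overdamped probe-diffusion simulator with an optional
# attractive surface patch, conformer generation for real probe molecules,
# and a synthetic MS peak table. The simulator's purpose is contact
# statistics with known ground truth, not physical kinetics: probes are
# single centre-of-mass beads performing seeded random walks with hard-core
# rejection against the protein and a Metropolis bias toward the patch.

.PROBE_MASSES <- c(TCEP = 250.19, DTT = 154.25)
.PROBE_SMILES <- c(TCEP = "OC(=O)CCP(CCC(O)=O)CCC(O)=O",
                   DTT = "SCC(O)C(O)CS")

#' Specification of a toy disulfide-bearing protein
#'
#' @param nResidues total residue count (backbone N/CA/C beads; cysteines
#'   additionally carry CB and SG).
#' @param disulfides list of bonds, each \code{list(exposure = "surface")}
#'   or \code{list(exposure = "buried")}.
#' @param outerRadius,innerRadius shell radii (nm) of the two-layer globule.
#' @return list with class \code{"ToyProteinSpec"}.
#' @export
toyProteinSpec <- function(nResidues = 80,
                           disulfides = list(list(exposure = "surface"),
                                             list(exposure = "surface"),
                                             list(exposure = "buried")),
                           outerRadius = 1.2, innerRadius = 0.55) {
  exposures <- vapply(disulfides, function(d) d$exposure, character(1))
  if (!all(exposures %in% c("surface", "buried"))) {
    stop("disulfide exposure must be 'surface' or 'buried'")
  }
  if (sum(exposures == "buried") > 1) {
    stop("the two-shell template supports at most one buried bond")
  }
  if (nResidues < 2 * length(disulfides) + 20) {
    stop("too few residues to build the requested globule")
  }
  structure(list(nResidues = nResidues, disulfides = disulfides,
                 outerRadius = outerRadius, innerRadius = innerRadius),
            class = "ToyProteinSpec")
}

# n roughly even directions on the unit sphere (deterministic)
.fibonacciDirections <- function(n) {
  .spherePoints(n)
}

# two orthonormal tangent vectors for a unit direction u
.tangentBasis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
          u[1] * a[2] - u[2] * a[1])
  t1 <- t1 / sqrt(sum(t1 * t1))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

#' Build a toy protein with disulfides at designed burial
#'
#' A two-shell globule: most residues sit on an outer shell, a smaller set
#' on an inner shell, and a buried cystine (when requested) at the centre
#' so it is occluded by both shells. Surface cystines sit on the outer
#' shell with their sulfurs pointing outward. All placements are
#' deterministic given the seed (used only for small coordinate jitter).
#'
#' @param spec a \code{\link{toyProteinSpec}}.
#' @param seed integer RNG seed.
#' @return a \code{MolecularStructure} centred at the origin, non-periodic.
#' @export
buildToyProtein <- function(spec = toyProteinSpec(), seed = 1) {
  set.seed(seed)
  exposures <- vapply(spec$disulfides, function(d) d$exposure, character(1))
  nSurf <- sum(exposures == "surface")
  nBuried <- sum(exposures == "buried")
  nCys <- 2 * (nSurf + nBuried)
  nInner <- max(8, round(0.25 * (spec$nResidues - nCys)))
  nOuter <- spec$nResidues - nCys - nInner

  atoms <- list()
  resno <- 0
  addResidue <- function(resname, sites) {
    resno <<- resno + 1
    for (nm in names(sites)) {
      p <- sites[[nm]] + stats::rnorm(3, sd = 0.004)
      el <- substr(nm, 1, 1)
      atoms[[length(atoms) + 1]] <<- data.frame(
        name = nm, element = el, resname = resname, resno = resno,
        chain = "A", x = p[1], y = p[2], z = p[3],
        stringsAsFactors = FALSE)
    }
  }
  plainResidue <- function(u, r) {
    tb <- .tangentBasis(u)
    ca <- r * u
    addResidue("ALA", list(N = ca + 0.123 * tb$t1, CA = ca,
                           C = ca - 0.123 * tb$t1))
  }
  cystinePair <- function(u, r, outward) {
    tb <- .tangentBasis(u)
    for (sgn in c(-1, 1)) {
      ca <- r * u + sgn * 0.275 * tb$t1
      cb <- ca + 0.153 * outward * u
      sg <- (r + outward * 0.25) * u + sgn * 0.1025 * tb$t1
      addResidue("CYS", list(N = ca + 0.123 * tb$t2, CA = ca,
                             C = ca - 0.123 * tb$t2, CB = cb, SG = sg))
    }
  }

  # buried cystine at the centre, sulfurs toward the origin
  if (nBuried) cystinePair(c(0, 0, 1), 0.28, outward = -1)

  # surface cystines claim well-separated outer-shell directions
  outerDirs <- .fibonacciDirections(nOuter + nSurf)
  surfSlots <- if (nSurf > 0) {
    round(seq(1, nOuter + nSurf, length.out = nSurf + 2))[2:(nSurf + 1)]
  } else {
    integer(0)
  }
  for (k in surfSlots) {
    cystinePair(outerDirs[k, ], spec$outerRadius, outward = 1)
  }
  innerDirs <- .fibonacciDirections(nInner)
  for (k in seq_len(nInner)) {
    plainResidue(innerDirs[k, ], spec$innerRadius)
  }
  for (k in setdiff(seq_len(nOuter + nSurf), surfSlots)) {
    plainResidue(outerDirs[k, ], spec$outerRadius)
  }

  molecularStructure(do.call(rbind, atoms), box = NULL,
                     title = "synthetic two-shell toy protein")
}

#' Configuration of the probe-diffusion simulator
#'
#' Defaults emulate the study conditions of the proximity method: a cubic
#' 7.9 nm box with 100 probe molecules per protein, 10 ps between saved
#' frames. The patch bias is a Metropolis acceptance on the potential
#' U(r) = -patchStrength * s(r), with s the rational switching function of
#' range \code{patchRange} around the patched bond's COM; strength is in
#' kT units.
#'
#' @param box numeric(3) box lengths, nm.
#' @param nProbes probe molecule count.
#' @param probeKind \code{"TCEP"} or \code{"DTT"} (sets the bead mass).
#' @param stepSize random-walk step scale per frame, nm.
#' @param nFrames frames to simulate.
#' @param frameInterval ps between frames.
#' @param seed integer; fixes the full trajectory.
#' @param patchBond label of the bond carrying the attractive patch, or
#'   NULL.
#' @param patchStrength dimensionless attraction (kT units), >= 0.
#' @param patchRange switching-function range of the patch, nm.
#' @param excludedRadius hard-core exclusion distance from protein atoms,
#'   nm.
#' @param startExclusion minimum initial probe distance from every bond
#'   COM, nm (probes start in the bulk).
#' @param stopWithin stop the simulation at the first frame in which a
#'   probe COM comes within this distance of any bond COM (the reduction
#'   protocol stops a trajectory at the event), or NULL to run all frames.
#' @return list with class \code{"SimulatorConfig"}.
#' @export
simulatorConfig <- function(box = c(7.9, 7.9, 7.9), nProbes = 100L,
                            probeKind = c("TCEP", "DTT"), stepSize = 0.12,
                            nFrames = 1000L, frameInterval = 10,
                            seed = 1L, patchBond = NULL, patchStrength = 4,
                            patchRange = 2.0, excludedRadius = 0.45,
                            startExclusion = 2.0, stopWithin = NULL) {
  probeKind <- match.arg(probeKind)
  stopifnot(nProbes >= 1, stepSize > 0, nFrames >= 1, patchStrength >= 0,
            excludedRadius > 0)
  structure(list(box = box, nProbes = as.integer(nProbes),
                 probeKind = probeKind, stepSize = stepSize,
                 nFrames = as.integer(nFrames),
                 frameInterval = frameInterval, seed = as.integer(seed),
                 patchBond = patchBond, patchStrength = patchStrength,
                 patchRange = patchRange, excludedRadius = excludedRadius,
                 startExclusion = startExclusion, stopWithin = stopWithin),
            class = "SimulatorConfig")
}

#' Simulate probe diffusion around a static protein
#'
#' Probes are single beads on a seeded random walk with periodic wrapping,
#' hard-core rejection within \code{excludedRadius} of any protein atom,
#' and (optionally) a Metropolis bias toward the patched bond's COM. The
#' protein is held static at the box centre.
#'
#' @param protein a \code{MolecularStructure} (non-periodic, centred at the
#'   origin; it is translated to the box centre).
#' @param cfg a \code{\link{simulatorConfig}}.
#' @return a \code{Trajectory} whose topology is protein plus probe beads;
#'   probes carry the probe residue name so \code{\link{selectProbes}}
#'   finds them.
#' @export
simulateProbeDiffusion <- function(protein, cfg = simulatorConfig()) {
  set.seed(cfg$seed)
  box <- cfg$box
  P <- sweep(coords(protein), 2, box / 2, "+")
  if (any(P < 0) || any(sweep(P, 2, box) > 0)) {
    stop("protein does not fit in the simulation box")
  }
  freeVol <- prod(box) - (4 / 3) * pi * (max(sqrt(rowSums(
    sweep(P, 2, box / 2)^2))) + cfg$excludedRadius)^3
  if (freeVol < cfg$nProbes * 0.05) {
    stop("box too small for the requested probe count at this excluded ",
         "volume")
  }
  proteinShifted <- setCoords(protein, P)
  bonds <- detectDisulfides(proteinShifted)
  bondComs <- if (nrow(bonds)) {
    t(vapply(seq_len(nrow(bonds)), function(i) {
      massWeightedCom(P, c(bonds$sg1[i], bonds$sg2[i]),
                      protein@atoms$mass, box)
    }, numeric(3)))
  } else {
    matrix(numeric(0), ncol = 3)
  }
  patchCom <- NULL
  if (!is.null(cfg$patchBond) && cfg$patchStrength > 0) {
    hit <- match(cfg$patchBond, bonds$label)
    if (is.na(hit)) stop("patch bond ", cfg$patchBond, " not found")
    patchCom <- bondComs[hit, ]
  }
  sw <- switchingParams(r0 = cfg$patchRange, n = 6, m = 12)

  # initial placement: bulk solvent, outside the protein core and away
  # from every bond COM
  pos <- matrix(NA_real_, cfg$nProbes, 3)
  placed <- 0
  while (placed < cfg$nProbes) {
    cand <- matrix(stats::runif(3 * 2 * cfg$nProbes,
                                max = rep(box, each = 2 * cfg$nProbes)),
                   ncol = 3)
    ok <- rowSums(.pairDistances(cand, P, box) < cfg$excludedRadius) == 0
    if (nrow(bondComs)) {
      ok <- ok & rowSums(.pairDistances(cand, bondComs, box) <
                           cfg$startExclusion) == 0
    }
    cand <- cand[ok, , drop = FALSE]
    take <- min(nrow(cand), cfg$nProbes - placed)
    if (take > 0) {
      pos[(placed + 1):(placed + take), ] <- cand[seq_len(take), ,
                                                  drop = FALSE]
      placed <- placed + take
    }
  }

  frames <- vector("list", cfg$nFrames)
  nAtomsTotal <- nrow(P) + cfg$nProbes
  lastFrame <- cfg$nFrames
  patchR <- if (is.null(patchCom)) NULL else {
    minImageDistance(pos, matrix(patchCom, 1), box)
  }
  for (f in seq_len(cfg$nFrames)) {
    prop <- pos + matrix(stats::rnorm(3 * cfg$nProbes, sd = cfg$stepSize),
                         ncol = 3)
    prop <- .wrapIntoBox(prop, box)
    ok <- rowSums(.pairDistances(prop, P, box) < cfg$excludedRadius) == 0
    if (!is.null(patchCom)) {
      rNew <- minImageDistance(prop, matrix(patchCom, 1), box)
      dU <- -cfg$patchStrength *
        (switchingValue(rNew, sw) - switchingValue(patchR, sw))
      ok <- ok & (stats::runif(cfg$nProbes) < exp(-dU))
      patchR[ok] <- rNew[ok]
    }
    pos[ok, ] <- prop[ok, , drop = FALSE]
    frames[[f]] <- rbind(P, pos)
    if (!is.null(cfg$stopWithin) && nrow(bondComs)) {
      if (min(.pairDistances(pos, bondComs, box)) < cfg$stopWithin) {
        lastFrame <- f
        break
      }
    }
  }
  frames <- frames[seq_len(lastFrame)]

  probeAtoms <- data.frame(
    name = "C1", element = "C", mass = .PROBE_MASSES[[cfg$probeKind]],
    resname = cfg$probeKind,
    resno = max(protein@atoms$resno) + seq_len(cfg$nProbes),
    chain = "P", x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE)
  topo <- molecularStructure(rbind(proteinShifted@atoms, probeAtoms),
                             box = box, title = "probe diffusion")
  trajectory(topo, frames,
             times = (seq_len(lastFrame) - 1) * cfg$frameInterval)
}

#' Run a multi-trajectory lability experiment on synthetic data
#'
#' Simulates \code{nTrajectories} independent probe-diffusion trajectories
#' (seeds \code{baseSeed + 1 ... + nTrajectories}), applies the distance
#' criterion to each and aggregates the calls.
#'
#' @param protein toy protein structure.
#' @param cfg a \code{\link{simulatorConfig}}; its seed field is replaced
#'   per trajectory.
#' @param nTrajectories number of independent trajectories.
#' @param baseSeed base RNG seed.
#' @param proximity a \code{\link{proximityConfig}}.
#' @return list with \code{report} (\code{LabilityReport}) and
#'   \code{calls}.
#' @export
runLabilityExperiment <- function(protein, cfg = simulatorConfig(),
                                  nTrajectories = 20, baseSeed = 1,
                                  proximity = proximityConfig()) {
  calls <- vector("list", nTrajectories)
  labels <- NULL
  for (i in seq_len(nTrajectories)) {
    cfgI <- cfg
    cfgI$seed <- as.integer(baseSeed + i)
    if (is.null(cfgI$stopWithin)) {
      cfgI$stopWithin <- proximity$contactCutoff
    }
    traj <- simulateProbeDiffusion(protein, cfgI)
    bonds <- detectDisulfides(traj@topology)
    labels <- bonds$label
    probes <- selectProbes(traj@topology)
    calls[[i]] <- scanDistanceCriterion(traj, bonds, probes, proximity,
                                        trajectoryId = paste0("traj", i))
  }
  list(report = aggregateLability(calls, bondLabels = labels),
       calls = calls)
}

#' Write a canonical ground-truth fixture bundle
#'
#' Builds the default toy protein (two surface bonds, one buried), places
#' the attractive patch on the first surface bond, simulates
#' \code{nTrajectories} trajectories, and writes: the protein and the full
#' topology as PDB, every trajectory as multi-model PDB, a synthetic MS
#' peak table whose designed reduction fractions single out the patched
#' bond, and a JSON manifest with the ground truth.
#'
#' @param dir output directory (created if needed).
#' @param seed base seed.
#' @param nTrajectories number of trajectories.
#' @param nFrames frames per trajectory (trajectories stop early at the
#'   first contact).
#' @param patchStrength patch attraction, kT units.
#' @return invisible list: \code{dir}, \code{protein}, \code{patchedBond},
#'   \code{trajectoryFiles}, \code{peakTableFile}, \code{manifestFile}.
#' @export
knownAnswerBundle <- function(dir = tempfile("bundle"), seed = 1,
                              nTrajectories = 20, nFrames = 300,
                              patchStrength = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  protein <- buildToyProtein(seed = seed)
  bonds <- detectDisulfides(protein)
  sasa <- shrakeRupleySasa(protein, nPoints = 240L)
  exposure <- vapply(seq_len(nrow(bonds)), function(i) {
    disulfideSasa(protein, bonds[i, ], sasa = sasa)
  }, numeric(1))
  surface <- bonds$label[which.max(exposure)]
  writeStructurePDB(protein, file.path(dir, "protein.pdb"))
  cfg <- simulatorConfig(nFrames = nFrames, patchBond = surface,
                         patchStrength = patchStrength, stopWithin = 0.8)
  trajFiles <- character(nTrajectories)
  for (i in seq_len(nTrajectories)) {
    cfgI <- cfg
    cfgI$seed <- as.integer(seed + i)
    traj <- simulateProbeDiffusion(protein, cfgI)
    if (i == 1) {
      writeStructurePDB(traj@topology, file.path(dir, "topology.pdb"))
    }
    trajFiles[i] <- file.path(dir, sprintf("traj_%02d.pdb", i))
    writeTrajectoryPDB(traj, trajFiles[i])
  }
  truth <- stats::setNames(rep(0.05, nrow(bonds)), bonds$label)
  truth[surface] <- 0.8
  peak <- syntheticPeakTable(trueReduction = truth, seed = seed)
  peakFile <- file.path(dir, "peak_areas.csv")
  writePeakTable(peak, peakFile)
  manifest <- list(
    seed = seed, nTrajectories = nTrajectories,
    patchedBond = surface, patchStrength = patchStrength,
    bonds = bonds$label, designedReduction = as.list(truth),
    simulator = cfg[c("box", "nProbes", "probeKind", "stepSize", "nFrames",
                      "frameInterval", "excludedRadius", "startExclusion",
                      "patchRange")])
  manifestFile <- file.path(dir, "manifest.json")
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             manifestFile)
  invisible(list(dir = dir, protein = protein, patchedBond = surface,
                 trajectoryFiles = trajFiles, peakTableFile = peakFile,
                 manifestFile = manifestFile))
}

#' Synthetic MS peak-area table with designed reduction fractions
#'
#' Each cysteine peptide's treated-sample area is its fully-reduced area
#' scaled by the designed fraction; every (sample, replicate) carries a
#' shared lognormal loading factor (which control normalisation must
#' cancel) and every area carries independent lognormal noise.
#'
#' @param trueReduction named numeric vector of designed reduction
#'   fractions in [0, ~1], one per cysteine label.
#' @param controlReduction designed fraction(s) in the untreated control
#'   sample (scalar or named like \code{trueReduction}).
#' @param nControls number of control peptides.
#' @param nReplicates replicates per sample.
#' @param noiseCv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @return a validated peak table (data.frame).
#' @export
syntheticPeakTable <- function(trueReduction, controlReduction = 0.02,
                               nControls = 4, nReplicates = 3,
                               noiseCv = 0.05, seed = 1) {
  stopifnot(length(trueReduction) >= 1, !is.null(names(trueReduction)))
  set.seed(seed)
  if (length(controlReduction) == 1) {
    controlReduction <- stats::setNames(
      rep(controlReduction, length(trueReduction)), names(trueReduction))
  }
  sdlog <- sqrt(log(1 + noiseCv^2))
  noise <- function(n) stats::rlnorm(n, meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog)
  cysBase <- stats::rlnorm(length(trueReduction), meanlog = log(1e6),
                           sdlog = 0.4)
  ctrlBase <- stats::rlnorm(nControls, meanlog = log(2e6), sdlog = 0.4)
  samples <- c("control", "treated", "fully_reduced")
  loading <- matrix(stats::rlnorm(length(samples) * nReplicates,
                                  meanlog = 0, sdlog = 0.25),
                    nrow = length(samples),
                    dimnames = list(samples, NULL))
  rows <- list()
  for (si in seq_along(samples)) {
    for (r in seq_len(nReplicates)) {
      frac <- switch(samples[si],
                     control = controlReduction,
                     treated = trueReduction,
                     fully_reduced = stats::setNames(
                       rep(1, length(trueReduction)),
                       names(trueReduction)))
      for (ci in seq_along(trueReduction)) {
        rows[[length(rows) + 1]] <- data.frame(
          peptide_id = paste0("pep_", names(trueReduction)[ci]),
          cysteine_label = names(trueReduction)[ci],
          sample = samples[si], replicate_id = paste0("rep", r),
          precursor_area = cysBase[ci] * frac[[ci]] *
            loading[si, r] * noise(1),
          stringsAsFactors = FALSE)
      }
      for (ki in seq_len(nControls)) {
        rows[[length(rows) + 1]] <- data.frame(
          peptide_id = paste0("ctrl_", ki), cysteine_label = "",
          sample = samples[si], replicate_id = paste0("rep", r),
          precursor_area = ctrlBase[ki] * loading[si, r] * noise(1),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .validatePeakTable(out)
  out
}

.parseSdfCoords <- function(sdf) {
  ln <- strsplit(sdf, "\n")[[1]]
  n <- as.integer(substr(ln[4], 1, 3))
  rows <- ln[4 + seq_len(n)]
  xyz <- cbind(as.numeric(substr(rows, 1, 10)),
               as.numeric(substr(rows, 11, 20)),
               as.numeric(substr(rows, 21, 30))) / 10  # Angstrom -> nm
  el <- trimws(substr(rows, 32, 34))
  list(xyz = xyz, element = el)
}

#' Generate 3D conformers of a reducing probe
#'
#' Builds energy-reasonable gas-phase conformers of TCEP or DTT with
#' OpenBabel (through the ChemmineOB bindings) and returns them as
#' structures, e.g. for radius-of-gyration characterisation of the probes.
#' The conformer search is stochastic, so for a stable size estimate
#' average \code{\link{radiusOfGyration}} over several conformers.
#'
#' @param kind \code{"TCEP"} or \code{"DTT"}.
#' @param nConformers how many independent conformers to generate.
#' @return list of \code{MolecularStructure}s.
#' @export
probeConformer <- function(kind = c("TCEP", "DTT"), nConformers = 1) {
  kind <- match.arg(kind)
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("probeConformer needs the ChemmineOB package")
  }
  smi <- .PROBE_SMILES[[kind]]
  lapply(seq_len(nConformers), function(i) {
    sdf <- ChemmineOB::convertFormat(
      "SMI", "SDF", source = paste0(smi, " ", kind),
      options = data.frame(names = "gen3d", args = "best"))
    p <- .parseSdfCoords(sdf)
    molecularStructure(data.frame(
      name = paste0(p$element, seq_along(p$element)), element = p$element,
      resname = kind, resno = 1L, chain = "A",
      x = p$xyz[, 1], y = p$xyz[, 2], z = p$xyz[, 3],
      stringsAsFactors = FALSE), title = paste(kind, "conformer"))
  })
}

#' Three-bead probe mimic
#'
#' A minimal multi-atom probe model (three beads sharing the probe's total
#' mass) for exercising centre-of-mass code paths on multi-atom molecules.
#'
#' @param kind \code{"TCEP"} or \code{"DTT"}.
#' @param centre numeric(3) position of the middle bead, nm.
#' @param spacing bead spacing, nm.
#' @return a \code{MolecularStructure} with three atoms.
#' @export
threeBeadProbe <- function(kind = c("TCEP", "DTT"), centre = c(0, 0, 0),
                           spacing = 0.15) {
  kind <- match.arg(kind)
  m <- .PROBE_MASSES[[kind]] / 3
  molecularStructure(data.frame(
    name = c("B1", "B2", "B3"), element = "C", mass = m,
    resname = kind, resno = 1L, chain = "A",
    x = centre[1] + c(-spacing, 0, spacing), y = centre[2], z = centre[3],
    stringsAsFactors = FALSE), title = paste(kind, "three-bead mimic"))
}
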