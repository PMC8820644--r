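#' @import methods
NULL

#' MolecularStructure: atoms, coordinates and an optional periodic box
#'
#' The central static container. Atoms are stored as a data frame with one
#' row per atom (columns \code{name}, \code{element}, \code{mass},
#' \code{resname}, \code{resno}, \code{chain}, \code{x}, \code{y}, \code{z});
#' coordinates are in nm. The box, when present, is an orthorhombic cell
#' given by its three edge lengths in nm (all the systems this package
#' targets use cubic cells; triclinic input is rejected at read time).
#'
#' @slot atoms data.frame of per-atom records, coordinates in nm.
#' @slot box numeric(3) orthorhombic box lengths in nm, or numeric(0) for a
#'   non-periodic system.
#' @slot title character(1) free-text title.
#' @slot excludedBonds integer matrix with two columns; covalent bonds
#'   (atom index pairs) that distance-based topology inference must not
#'   recreate. Populated by \code{\link{reduceDisulfide}}.
#' @export
setClass("MolecularStructure",
  representation(atoms = "data.frame", box = "numeric", title = "character",
                 excludedBonds = "matrix"),
  prototype(atoms = data.frame(), box = numeric(0), title = "",
            excludedBonds = matrix(integer(0), ncol = 2)))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  need <- c("name", "element", "mass", "resname", "resno", "chain",
            "x", "y", "z")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a) > 0) {
    if (any(!is.finite(a$mass)) || any(a$mass <= 0)) {
      return("all atom masses must be finite and > 0")
    }
    if (any(!is.finite(c(a$x, a$y, a$z)))) {
      return("all atom coordinates must be finite")
    }
  }
  if (length(object@box) > 0) {
    if (length(object@box) != 3) return("box must have 3 edge lengths")
    if (any(!is.finite(object@box)) || any(object@box <= 0)) {
      return("box lengths must be finite and > 0")
    }
  }
  if (ncol(object@excludedBonds) != 2) {
    return("excludedBonds must have two columns")
  }
  TRUE
})

#' Trajectory: an ordered stack of frames over a fixed topology
#'
#' @slot topology a \code{MolecularStructure} giving atom identities; its own
#'   coordinates are the reference/first-frame coordinates.
#' @slot coords numeric array of dim (nFrames, nAtoms, 3), nm.
#' @slot times numeric vector of frame times in ps, strictly increasing.
#' @slot boxes numeric matrix (nFrames x 3) of per-frame box lengths in nm,
#'   or a 0-row matrix when the system is non-periodic.
#' @export
setClass("Trajectory",
  representation(topology = "MolecularStructure", coords = "array",
                 times = "numeric", boxes = "matrix"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3) {
    return("coords must be an (nFrames x nAtoms x 3) array")
  }
  if (d[1] < 1) return("a trajectory must contain at least one frame")
  if (d[2] != nrow(object@topology@atoms)) {
    return("frame atom count must equal the topology atom count")
  }
  if (length(object@times) != d[1]) {
    return("times must have one entry per frame")
  }
  if (d[1] > 1 && any(diff(object@times) <= 0)) {
    return("frame times must be strictly increasing")
  }
  if (nrow(object@boxes) > 0 &&
      (nrow(object@boxes) != d[1] || ncol(object@boxes) != 3)) {
    return("boxes must be an (nFrames x 3) matrix or empty")
  }
  TRUE
})

#' ProbeGroup: reducing-probe molecules selected from a structure
#'
#' @slot kind one of \code{"TCEP"}, \code{"DTT"}, \code{"custom"}.
#' @slot molecules list of integer vectors, one per probe molecule, giving
#'   atom indices (1-based) into the parent structure; disjoint, non-empty.
#' @export
setClass("ProbeGroup",
  representation(kind = "character", molecules = "list"))

setValidity("ProbeGroup", function(object) {
  if (!object@kind %in% c("TCEP", "DTT", "custom")) {
    return("kind must be TCEP, DTT or custom")
  }
  if (length(object@molecules) > 0) {
    if (any(vapply(object@molecules, length, 1L) == 0)) {
      return("every probe molecule must contain at least one atom")
    }
    all_idx <- unlist(object@molecules)
    if (anyDuplicated(all_idx)) return("probe molecules must be disjoint")
  }
  TRUE
})

#' ForceField: parameters of the simplified vacuum potential
#'
#' A deliberately small self-contained potential (harmonic bonds and angles,
#' Lennard-Jones, Coulomb truncated at \code{cutoff}) used by the
#' distance+energy criterion to compare the minimised energies of a structure
#' before and after disulfide cleavage. It is a desk-scale potential, not a
#' biomolecular force field; externally computed energies can be supplied
#' through the pluggable backend of \code{\link{energyCheck}}.
#'
#' @slot bondTable data.frame with columns \code{pair} (sorted element pair,
#'   e.g. "C-S"), \code{k} (kJ/mol/nm^2), \code{req} (nm).
#' @slot angleK numeric(1) harmonic angle constant, kJ/mol/rad^2.
#' @slot angleTheta0 numeric(1) equilibrium angle, degrees.
#' @slot ljTable data.frame with columns \code{element}, \code{sigma} (nm),
#'   \code{epsilon} (kJ/mol).
#' @slot cutoff numeric(1) nonbonded cutoff in nm.
#' @export
setClass("ForceField",
  representation(bondTable = "data.frame", angleK = "numeric",
                 angleTheta0 = "numeric", ljTable = "data.frame",
                 cutoff = "numeric"))

setValidity("ForceField", function(object) {
  if (!all(c("pair", "k", "req") %in% names(object@bondTable))) {
    return("bondTable needs columns pair, k, req")
  }
  if (!all(c("element", "sigma", "epsilon") %in% names(object@ljTable))) {
    return("ljTable needs columns element, sigma, epsilon")
  }
  if (any(object@ljTable$sigma <= 0)) return("all LJ sigma must be > 0")
  if (any(object@ljTable$epsilon < 0)) return("all LJ epsilon must be >= 0")
  if (object@cutoff <= 0) return("cutoff must be > 0")
  TRUE
})

#' LabilityReport: ensemble reduction probabilities per disulfide bond
#'
#' @slot probabilities named numeric vector; fraction of trajectories whose
#'   reduction call landed on each bond.
#' @slot nTrajectories integer(1).
#' @slot noCallFraction numeric(1); fraction of trajectories with no call.
#' @slot criterion character(1), \code{"distance"} or
#'   \code{"distance_energy"}.
#' @export
setClass("LabilityReport",
  representation(probabilities = "numeric", nTrajectories = "integer",
                 noCallFraction = "numeric", criterion = "character"))

setValidity("LabilityReport", function(object) {
  tot <- sum(object@probabilities) + object@noCallFraction
  if (abs(tot - 1) > 1e-9) {
    return("per-bond probabilities plus the no-call fraction must sum to 1")
  }
  if (any(object@probabilities < 0) || object@noCallFraction < 0) {
    return("probabilities must be non-negative")
  }
  TRUE
})

setMethod("show", "MolecularStructure", function(object) {
  a <- object@atoms
  nres <- if (nrow(a)) nrow(unique(a[, c("chain", "resno")])) else 0L
  cat("MolecularStructure:", sQuote(object@title), "\n")
  cat(" ", nrow(a), "atoms,", nres, "residues\n")
  if (length(object@box)) {
    cat("  box:", paste(format(object@box, digits = 4), collapse = " x "),
        "nm\n")
  } else {
    cat("  non-periodic\n")
  }
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "frames x", d[2], "atoms\n")
  cat("  time:", object@times[1], "to", object@times[d[1]], "ps\n")
})

setMethod("show", "ProbeGroup", function(object) {
  cat("ProbeGroup:", length(object@molecules), object@kind, "molecules\n")
})

setMethod("show", "LabilityReport", function(object) {
  cat("LabilityReport (", object@criterion, " criterion, ",
      object@nTrajectories, " trajectories)\n", sep = "")
  p <- sort(object@probabilities, decreasing = TRUE)
  for (b in names(p)) {
    cat(sprintf("  %-22s %6.1f%%\n", b, 100 * p[[b]]))
  }
  cat(sprintf("  %-22s %6.1f%%\n", "(no call)", 100 * object@noCallFraction))
})
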