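# Trajectory conformational analytics: radius of gyration, hydrogen-bond
# counts, SASA and backbone-RMSD time series, Daura clustering, the
# representative (most sampled) conformation and per-residue deviation maps.

.BACKBONE_NAMES <- c("N", "CA", "C")

.backboneIndices <- function(s) {
  which(s@atoms$name %in% .BACKBONE_NAMES)
}

#' Mass-weighted radius of gyration
#'
#' Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i ).
#'
#' @param x a \code{MolecularStructure}, or an (n x 3) coordinate matrix
#'   (nm) with \code{masses} supplied.
#' @param masses per-atom masses (amu); taken from the structure when
#'   \code{x} is one.
#' @param indices optional atom subset.
#' @return Rg in nm.
#' @export
radiusOfGyration <- function(x, masses = NULL, indices = NULL) {
  if (is(x, "MolecularStructure")) {
    masses <- x@atoms$mass
    x <- coords(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 3)
  if (is.null(indices)) indices <- seq_len(nrow(x))
  m <- masses[indices]
  if (length(m) == 0 || sum(m) <= 0) stop("zero total mass")
  p <- x[indices, , drop = FALSE]
  com <- colSums(p * m) / sum(m)
  sq <- rowSums(sweep(p, 2, com)^2)
  sqrt(sum(m * sq) / sum(m))
}

# Kabsch superposition of mob onto ref (n x 3 matrices) via bio3d
.superpose <- function(ref, mob) {
  inds <- seq_len(3 * nrow(ref))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)), mobile = as.vector(t(mob)),
                   fixed.inds = inds, mobile.inds = inds))
  matrix(fitted, ncol = 3, byrow = TRUE)
}

#' Backbone RMSD after optimal superposition
#'
#' Kabsch least-squares superposition of the selected atoms, then the RMSD
#' over the same selection. Symmetric in its arguments.
#'
#' @param a,b \code{MolecularStructure}s or (n x 3) coordinate matrices, nm.
#' @param selection atom indices to fit and measure on (applied to both);
#'   defaults to backbone N, CA, C atoms when structures are given, or all
#'   rows for bare matrices.
#' @return RMSD in nm.
#' @export
backboneRmsd <- function(a, b, selection = NULL) {
  getm <- function(x) if (is(x, "MolecularStructure")) coords(x) else x
  if (is.null(selection)) {
    selection <- if (is(a, "MolecularStructure")) .backboneIndices(a)
                 else seq_len(nrow(getm(a)))
  }
  A <- getm(a)[selection, , drop = FALSE]
  B <- getm(b)[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection sizes differ between frames")
  Bf <- .superpose(A, B)
  sqrt(mean(rowSums((A - Bf)^2)))
}

#' Donor/hydrogen/acceptor sets for hydrogen-bond counting
#'
#' Donors are N/O atoms covalently bonded to a hydrogen (one entry per D-H
#' pair); acceptors are all N/O atoms.
#'
#' @param s a \code{MolecularStructure}.
#' @param topology optional precomputed \code{\link{buildTopology}} result.
#' @return list with integer vectors \code{donors}, \code{hydrogens}
#'   (parallel) and \code{acceptors}.
#' @export
hydrogenBondParticipants <- function(s, topology = NULL) {
  if (is.null(topology)) topology <- buildTopology(s)
  el <- .normalizeElement(s@atoms$element)
  dh <- topology$bonds[
    (el[topology$bonds[, 1]] %in% c("N", "O") &
       el[topology$bonds[, 2]] == "H") |
    (el[topology$bonds[, 2]] %in% c("N", "O") &
       el[topology$bonds[, 1]] == "H"), , drop = FALSE]
  if (nrow(dh)) {
    flip <- el[dh[, 1]] == "H"
    donors <- ifelse(flip, dh[, 2], dh[, 1])
    hydrogens <- ifelse(flip, dh[, 1], dh[, 2])
  } else {
    donors <- integer(0); hydrogens <- integer(0)
  }
  list(donors = as.integer(donors), hydrogens = as.integer(hydrogens),
       acceptors = which(el %in% c("N", "O")))
}

#' Count intramolecular hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor distance at most \code{dCut} and
#' H-D-A angle at most \code{angleCut} (a standard trajectory-analysis
#' default).
#'
#' @param xyz (n x 3) coordinate matrix, nm.
#' @param donors,hydrogens parallel integer vectors of D-H pairs.
#' @param acceptors integer vector of acceptor atoms.
#' @param dCut donor-acceptor distance cutoff, nm.
#' @param angleCut H-D-A angle cutoff, degrees.
#' @return integer count.
#' @export
hydrogenBondCount <- function(xyz, donors, hydrogens, acceptors,
                              dCut = 0.35, angleCut = 30) {
  if (length(donors) == 0 || length(acceptors) == 0) return(0L)
  if (length(donors) != length(hydrogens)) {
    stop("donors and hydrogens must be parallel vectors")
  }
  D <- .pairDistances(xyz[donors, , drop = FALSE],
                      xyz[acceptors, , drop = FALSE], NULL)
  # a donor cannot bond to itself
  self <- outer(donors, acceptors, "==")
  cand <- which(D <= dCut & !self, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0L)
  cnt <- 0L
  for (r in seq_len(nrow(cand))) {
    di <- donors[cand[r, 1]]; hi <- hydrogens[cand[r, 1]]
    ai <- acceptors[cand[r, 2]]
    u <- xyz[hi, ] - xyz[di, ]
    v <- xyz[ai, ] - xyz[di, ]
    ct <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
    ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
    if (ang <= angleCut) cnt <- cnt + 1L
  }
  cnt
}

#' Per-frame Rg / hydrogen-bond / SASA / RMSD time series
#'
#' @param traj a \code{Trajectory}.
#' @param reference structure (or coordinate matrix) the backbone RMSD is
#'   measured against; defaults to the first frame.
#' @param selection atom indices for the RMSD fit; defaults to backbone
#'   N, CA, C.
#' @param sasaPoints Shrake-Rupley points per atom for the SASA series (a
#'   coarser default than the static table, since it runs per frame).
#' @param hbond compute the hydrogen-bond series (needs hydrogens in the
#'   topology; set FALSE for heavy-atom-only models).
#' @return data.frame with columns \code{time} (ps), \code{rg} (nm),
#'   \code{hbCount}, \code{sasa} (nm^2), \code{rmsd} (nm).
#' @export
trajectoryTimeSeries <- function(traj, reference = NULL, selection = NULL,
                                 sasaPoints = 120L, hbond = TRUE) {
  s <- traj@topology
  masses <- s@atoms$mass
  if (is.null(selection)) selection <- .backboneIndices(s)
  if (is.null(reference)) reference <- frameCoords(traj, 1)
  refM <- if (is(reference, "MolecularStructure")) coords(reference)
          else reference
  hb <- if (hbond) hydrogenBondParticipants(s) else NULL
  nf <- nFrames(traj)
  rg <- numeric(nf); hbn <- integer(nf); sas <- numeric(nf)
  rms <- numeric(nf)
  for (i in seq_len(nf)) {
    xyz <- frameCoords(traj, i)
    rg[i] <- radiusOfGyration(xyz, masses)
    hbn[i] <- if (is.null(hb)) NA_integer_ else {
      hydrogenBondCount(xyz, hb$donors, hb$hydrogens, hb$acceptors)
    }
    sas[i] <- sum(shrakeRupleySasa(setCoords(s, xyz),
                                   nPoints = sasaPoints)) / 100  # A^2->nm^2
    rms[i] <- backboneRmsd(refM, xyz, selection = selection)
  }
  data.frame(time = traj@times, rg = rg, hbCount = hbn, sasa = sas,
             rmsd = rms)
}

# pairwise fitted-RMSD matrix over frames (selection rows only)
.rmsdMatrix <- function(traj, selection) {
  nf <- nFrames(traj)
  sel <- lapply(seq_len(nf), function(i) {
    frameCoords(traj, i)[selection, , drop = FALSE]
  })
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      Bf <- .superpose(sel[[i]], sel[[j]])
      M[i, j] <- M[j, i] <- sqrt(mean(rowSums((sel[[i]] - Bf)^2)))
    }
  }
  M
}

#' Greedy neighbour-count (Daura) clustering of trajectory frames
#'
#' Frames are neighbours when their fitted RMSD over the selection is below
#' the cutoff. Iteratively, the frame with the most neighbours (ties broken
#' by lowest frame index) becomes a cluster centroid; it and its neighbours
#' are removed and the procedure repeats. Cluster 1 is always the largest
#' and sizes are non-increasing.
#'
#' @param traj a \code{Trajectory}.
#' @param selection atom indices (default backbone N, CA, C).
#' @param cutoff neighbour RMSD cutoff, nm (0.2 is the standard backbone
#'   choice).
#' @return list with \code{assignments} (cluster id per frame),
#'   \code{clusterSizes}, \code{centroidFrames}, \code{cutoff},
#'   \code{selection}.
#' @export
dauraCluster <- function(traj, selection = NULL, cutoff = 0.2) {
  s <- traj@topology
  if (is.null(selection)) selection <- .backboneIndices(s)
  nf <- nFrames(traj)
  M <- .rmsdMatrix(traj, selection)
  nbr <- M < cutoff
  diag(nbr) <- TRUE
  remaining <- rep(TRUE, nf)
  assignments <- integer(nf)
  centroids <- integer(0)
  sizes <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(nbr[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    centre <- which.max(counts)  # ties: lowest index
    members <- which(nbr[centre, ] & remaining)
    assignments[members] <- cl
    centroids <- c(centroids, centre)
    sizes <- c(sizes, length(members))
    remaining[members] <- FALSE
  }
  list(assignments = assignments, clusterSizes = sizes,
       centroidFrames = centroids, cutoff = cutoff, selection = selection)
}

#' Most sampled conformation of the equilibrated trajectory
#'
#' Discards the first \code{discardPs} of simulated time, clusters the
#' remaining frames and returns the centroid frame of the largest cluster
#' (as an index into the full trajectory).
#'
#' @param traj a \code{Trajectory}.
#' @param discardPs equilibration time to discard, ps; must be shorter than
#'   the trajectory.
#' @param selection atom indices (default backbone N, CA, C).
#' @param cutoff neighbour RMSD cutoff, nm.
#' @return frame index of the representative conformation.
#' @export
representativeFrame <- function(traj, discardPs = 0, selection = NULL,
                                cutoff = 0.2) {
  span <- traj@times[nFrames(traj)] - traj@times[1]
  if (discardPs >= span) {
    stop("discard window (", discardPs, " ps) is not shorter than the ",
         "trajectory (", span, " ps)")
  }
  keep <- which(traj@times >= traj@times[1] + discardPs)
  sub <- trajectory(traj@topology,
                    traj@coords[keep, , , drop = FALSE],
                    times = traj@times[keep])
  res <- dauraCluster(sub, selection = selection, cutoff = cutoff)
  keep[res$centroidFrames[1]]
}

#' Per-residue deviation between two conformations
#'
#' After superposing structure B onto structure A on their alpha-carbons -
#' either the whole structure at once or each configured domain separately -
#' the displacement of each residue's alpha-carbon is reported. This is the
#' numerical counterpart of structure-similarity colouring: small values
#' mean locally preserved structure, large values mark regions that moved.
#'
#' @param repA,repB \code{MolecularStructure}s with matching residue
#'   sequences.
#' @param mode \code{"whole"} or \code{"per_domain"}.
#' @param domains for \code{per_domain}: list of numeric ranges
#'   \code{c(firstResno, lastResno)}; residues outside every range form one
#'   implicit remainder domain.
#' @return data.frame with \code{chain}, \code{resno}, \code{resname},
#'   \code{deviation} (nm); alignment mode in attribute
#'   \code{"alignmentMode"}.
#' @export
perResidueDeviation <- function(repA, repB, mode = c("whole", "per_domain"),
                                domains = NULL) {
  mode <- match.arg(mode)
  caA <- which(repA@atoms$name == "CA")
  caB <- which(repB@atoms$name == "CA")
  if (length(caA) != length(caB)) {
    stop("structures have different numbers of residues")
  }
  aA <- repA@atoms[caA, ]; aB <- repB@atoms[caB, ]
  if (!all(aA$resname == aB$resname) || !all(aA$resno == aB$resno)) {
    stop("residue sequences do not match between the two structures")
  }
  A <- coords(repA)[caA, , drop = FALSE]
  B <- coords(repB)[caB, , drop = FALSE]
  n <- nrow(A)
  dev <- numeric(n)
  groups <- if (mode == "whole") list(seq_len(n)) else {
    if (is.null(domains)) stop("per_domain mode needs domain ranges")
    gs <- lapply(domains, function(rg) {
      which(aA$resno >= rg[1] & aA$resno <= rg[2])
    })
    rest <- setdiff(seq_len(n), unlist(gs))
    if (length(rest)) gs <- c(gs, list(rest))
    gs[vapply(gs, length, 1L) > 0]
  }
  for (g in groups) {
    if (length(g) < 3) {
      # too few points for a meaningful fit; measure unfitted displacement
      dev[g] <- sqrt(rowSums((A[g, , drop = FALSE] -
                                B[g, , drop = FALSE])^2))
      next
    }
    Bf <- .superpose(A[g, , drop = FALSE], B[g, , drop = FALSE])
    dev[g] <- sqrt(rowSums((A[g, , drop = FALSE] - Bf)^2))
  }
  out <- data.frame(chain = aA$chain, resno = aA$resno,
                    resname = aA$resname, deviation = dev,
                    stringsAsFactors = FALSE)
  attr(out, "alignmentMode") <- mode
  out
}
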