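# The distance+energy criterion: cleave the candidate disulfide in the
# event-frame structure, minimise both forms and accept the reduction only
# when the cleaved form ends up strictly lower in energy.

.SH_BOND_LENGTH <- 0.134  # nm, capping S-H along the former S-S axis

#' Break a disulfide bond and cap the sulfurs
#'
#' Removes the S-S bonded term (recorded in the structure's excluded-bond
#' list so topology inference will not recreate it) and adds one hydrogen
#' per SG at 0.134 nm along the former S-S axis, pointing outward. All other
#' atoms are untouched; the two caps are appended, so the atom count grows
#' by exactly 2.
#'
#' @param s a \code{MolecularStructure}.
#' @param bond one row of a \code{\link{detectDisulfides}} table.
#' @return the modified structure.
#' @export
reduceDisulfide <- function(s, bond) {
  sg1 <- bond$sg1; sg2 <- bond$sg2
  a <- s@atoms
  ok <- !is.na(sg1) && !is.na(sg2) && sg1 >= 1 && sg2 >= 1 &&
    sg1 <= nrow(a) && sg2 <= nrow(a) &&
    a$name[sg1] == "SG" && a$name[sg2] == "SG"
  if (!ok) stop("bond ", bond$label, " is not present in the structure")
  if (nrow(s@excludedBonds)) {
    key <- paste(pmin(s@excludedBonds[, 1], s@excludedBonds[, 2]),
                 pmax(s@excludedBonds[, 1], s@excludedBonds[, 2]))
    if (paste(min(sg1, sg2), max(sg1, sg2)) %in% key) {
      stop("bond ", bond$label, " has already been reduced")
    }
  }
  xyz <- coords(s)
  axis <- xyz[sg1, ] - xyz[sg2, ]
  nrm <- sqrt(sum(axis * axis))
  if (nrm < 1e-9) stop("degenerate S-S geometry for bond ", bond$label)
  axis <- axis / nrm
  h1 <- xyz[sg1, ] + .SH_BOND_LENGTH * axis
  h2 <- xyz[sg2, ] - .SH_BOND_LENGTH * axis
  caps <- data.frame(
    name = "HG", element = "H", mass = elementMass("H"),
    resname = a$resname[c(sg1, sg2)], resno = a$resno[c(sg1, sg2)],
    chain = a$chain[c(sg1, sg2)],
    x = c(h1[1], h2[1]), y = c(h1[2], h2[2]), z = c(h1[3], h2[3]),
    stringsAsFactors = FALSE)
  s@atoms <- rbind(a, caps)
  rownames(s@atoms) <- NULL
  s@excludedBonds <- rbind(s@excludedBonds,
                           c(min(sg1, sg2), max(sg1, sg2)))
  s
}

#' Energy backend that accepts every reduction
#'
#' Passing this as \code{backend} turns the distance+energy scan into a pure
#' distance scan (useful as an equivalence check and for criterion-logic
#' tests decoupled from any potential).
#'
#' @param intact,reduced ignored.
#' @param ff,minCfg ignored.
#' @return list with \code{Ein = 1}, \code{Efin = 0}.
#' @export
alwaysAcceptBackend <- function(intact, reduced, ff, minCfg) {
  list(Ein = 1, Efin = 0)
}

.defaultEnergyBackend <- function(intact, reduced, ff, minCfg) {
  args <- utils::modifyList(list(step0 = 0.01, fmaxTol = 50,
                                 maxSteps = 300), minCfg)
  Ein <- steepestDescent(intact, ff, step0 = args$step0,
                         fmaxTol = args$fmaxTol,
                         maxSteps = args$maxSteps)$energy
  Efin <- steepestDescent(reduced, ff, step0 = args$step0,
                          fmaxTol = args$fmaxTol,
                          maxSteps = args$maxSteps)$energy
  list(Ein = Ein, Efin = Efin)
}

#' The energy acceptance check of the distance+energy criterion
#'
#' Minimises the event-frame structure intact (E_in) and after cleaving the
#' candidate disulfide (E_fin); the reduction is accepted only when
#' E_fin < E_in, strictly. The comparison is a pure function of the
#' event-frame structure: rerunning yields an identical result.
#'
#' @param sEvent event-frame \code{MolecularStructure} (protein atoms).
#' @param bond one row of a \code{\link{detectDisulfides}} table (indices
#'   into \code{sEvent}).
#' @param ff a \code{ForceField}.
#' @param minCfg list of minimiser settings (\code{step0}, \code{fmaxTol},
#'   \code{maxSteps}).
#' @param backend optional function \code{(intact, reduced, ff, minCfg)}
#'   returning \code{list(Ein, Efin)}; replaces the built-in minimiser so
#'   externally computed energies (e.g. from an MD engine) can be used.
#' @return list with \code{Ein}, \code{Efin} (kJ/mol) and \code{accepted}.
#' @export
energyCheck <- function(sEvent, bond, ff = defaultForceField(),
                        minCfg = list(), backend = NULL) {
  reduced <- reduceDisulfide(sEvent, bond)
  fn <- if (is.null(backend)) .defaultEnergyBackend else backend
  en <- fn(sEvent, reduced, ff, minCfg)
  structure(list(Ein = en$Ein, Efin = en$Efin,
                 accepted = en$Efin < en$Ein),
            class = "EnergyCheckResult")
}

#' First-passage scan of the distance+energy criterion
#'
#' Iterates proximity events in time order (within a frame: by increasing
#' distance, then bond order). The first event whose energy check accepts
#' yields the call. A failed check marks that (bond, probe) pair refractory
#' for \code{refractoryTime} ps and the scan continues; the number of failed
#' checks is recorded on the call.
#'
#' @inheritParams scanDistanceCriterion
#' @param ff a \code{ForceField}.
#' @param minCfg minimiser settings passed to \code{\link{energyCheck}}.
#' @param refractoryTime ps for which a failed (bond, probe) contact is not
#'   re-tested.
#' @param backend optional energy backend (see \code{\link{energyCheck}}).
#' @return a \code{TrajectoryCall} with criterion
#'   \code{"distance_energy"}.
#' @export
scanDistanceEnergyCriterion <- function(traj, bonds, probes,
                                        cfg = proximityConfig(),
                                        ff = defaultForceField(),
                                        minCfg = list(),
                                        refractoryTime = 100,
                                        backend = NULL,
                                        trajectoryId = "traj") {
  if (length(probes@molecules) == 0) stop("probe group is empty")
  s <- traj@topology
  masses <- s@atoms$mass
  bondIdx <- .bondComIndices(s, bonds, cfg$bondComMode)
  probeAtoms <- unlist(probes@molecules)
  proteinIdx <- setdiff(seq_len(nAtoms(s)), probeAtoms)
  map <- integer(nAtoms(s)); map[proteinIdx] <- seq_along(proteinIdx)
  refractoryUntil <- new.env(parent = emptyenv())
  nFailed <- 0L
  for (i in seq(1, nFrames(traj), by = cfg$frameStride)) {
    xyz <- frameCoords(traj, i)
    box <- frameBox(traj, i)
    if (length(box) == 0) box <- NULL
    pC <- .frameComs(xyz, probes@molecules, masses, box)
    bC <- .frameComs(xyz, bondIdx, masses, box)
    D <- .pairDistances(pC, bC, box)
    ev <- .frameEvents(D, cfg$contactCutoff, bonds, i, traj@times[i])
    if (is.null(ev)) next
    for (r in seq_len(nrow(ev))) {
      e <- ev[r, ]
      key <- paste(e$bondIndex, e$probeIndex)
      until <- refractoryUntil[[key]]
      if (!is.null(until) && e$time < until) next
      sEvent <- subsetAtoms(setCoords(s, xyz), proteinIdx)
      bEvent <- bonds[e$bondIndex, ]
      for (col in c("sg1", "sg2", "ca1", "ca2", "cb1", "cb2")) {
        v <- bEvent[[col]]
        bEvent[[col]] <- if (is.na(v)) NA_integer_ else map[v]
      }
      chk <- energyCheck(sEvent, bEvent, ff, minCfg, backend)
      if (chk$accepted) {
        return(.trajectoryCall(
          trajectoryId, e$bond, "distance_energy",
          list(frameIndex = e$frameIndex, time = e$time, bond = e$bond,
               probeIndex = e$probeIndex, distance = e$distance),
          energyChecksFailed = nFailed))
      }
      nFailed <- nFailed + 1L
      refractoryUntil[[key]] <- e$time + refractoryTime
    }
  }
  .trajectoryCall(trajectoryId, NA_character_, "distance_energy", NULL,
                  energyChecksFailed = nFailed)
}
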