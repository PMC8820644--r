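# Probe-disulfide proximity statistics, the distance-based reduction
# criterion and ensemble aggregation into per-bond lability probabilities.

#' Parameters of the rational switching function
#'
#' The smooth contact function s(r) = (1-(r/r0)^n) / (1-(r/r0)^m) used for
#' coordination numbers. Defaults r0 = 3 nm, n = 6, m = 12.
#'
#' @param r0 reference distance, nm.
#' @param n,m positive integer exponents with n < m.
#' @return a list with class \code{"SwitchingParams"}.
#' @export
switchingParams <- function(r0 = 3, n = 6L, m = 12L) {
  stopifnot(r0 > 0, n >= 1, m >= 1)
  if (!(n < m)) stop("switching exponents must satisfy n < m")
  structure(list(r0 = r0, n = as.integer(n), m = as.integer(m)),
            class = "SwitchingParams")
}

#' Evaluate the rational switching function
#'
#' Monotone non-increasing in r, with s(0) = 1 and the removable singularity
#' at r = r0 evaluated as its limit n/m.
#'
#' @param r distances, nm (vectorised).
#' @param p a \code{\link{switchingParams}} object.
#' @return values in [0, 1].
#' @export
switchingValue <- function(r, p = switchingParams()) {
  stopifnot(all(r >= 0))
  x <- r / p$r0
  out <- numeric(length(x))
  sing <- abs(x - 1) < 1e-9
  out[sing] <- p$n / p$m
  xr <- x[!sing]
  out[!sing] <- (1 - xr^p$n) / (1 - xr^p$m)
  out
}

#' Coordination number between two groups of points
#'
#' Double sum of the switching function over all A-B pairs at their
#' minimum-image distances.
#'
#' @param comsA,comsB (n x 3) matrices of positions (typically centres of
#'   mass), nm.
#' @param p a \code{\link{switchingParams}} object.
#' @param box numeric(3) box lengths (nm) or NULL.
#' @return a single coordination number in [0, nA * nB].
#' @export
coordinationNumber <- function(comsA, comsB, p = switchingParams(),
                               box = NULL) {
  if (!is.matrix(comsA)) comsA <- matrix(comsA, ncol = 3)
  if (!is.matrix(comsB)) comsB <- matrix(comsB, ncol = 3)
  if (nrow(comsA) == 0 || nrow(comsB) == 0) {
    stop("both groups must be non-empty")
  }
  D <- .pairDistances(comsA, comsB, box)
  sum(switchingValue(as.vector(D), p))
}

#' Configuration of the proximity criterion
#'
#' @param contactCutoff probe-COM-to-bond-COM contact cutoff, nm. The
#'   defaults in the field are 0.8 nm for TCEP and 0.6 nm for the smaller
#'   DTT probe.
#' @param bondComMode \code{"SG_only"} (centre of mass of the two sulfurs;
#'   default) or \code{"cystine_residues"} (all atoms of both cysteines).
#' @param frameStride evaluate every \code{frameStride}-th frame.
#' @param switching \code{\link{switchingParams}} for the soft coordination
#'   count.
#' @return a list with class \code{"ProximityConfig"}.
#' @export
proximityConfig <- function(contactCutoff = 0.8,
                            bondComMode = c("SG_only", "cystine_residues"),
                            frameStride = 1L,
                            switching = switchingParams()) {
  stopifnot(contactCutoff > 0, frameStride >= 1)
  bondComMode <- match.arg(bondComMode)
  structure(list(contactCutoff = contactCutoff, bondComMode = bondComMode,
                 frameStride = as.integer(frameStride),
                 switching = switching),
            class = "ProximityConfig")
}

#' Default contact cutoff for a probe kind
#'
#' @param kind \code{"TCEP"}, \code{"DTT"} or \code{"custom"}.
#' @return cutoff in nm (0.8 for TCEP/custom, 0.6 for DTT).
#' @export
defaultContactCutoff <- function(kind) {
  if (identical(kind, "DTT")) 0.6 else 0.8
}

# atom-index sets over which each bond's COM is taken
.bondComIndices <- function(s, bonds, mode) {
  lapply(seq_len(nrow(bonds)), function(i) {
    b <- bonds[i, ]
    if (mode == "SG_only") {
      c(b$sg1, b$sg2)
    } else {
      a <- s@atoms
      which((a$chain == b$chain1 & a$resno == b$res1) |
            (a$chain == b$chain2 & a$resno == b$res2))
    }
  })
}

# (nProbes x 3) and (nBonds x 3) COM matrices for one frame
.frameComs <- function(xyz, indexSets, masses, box) {
  t(vapply(indexSets, function(idx) {
    massWeightedCom(xyz, idx, masses, box)
  }, numeric(3)))
}

#' Per-frame probe-to-disulfide distance statistics
#'
#' For every evaluated frame and every bond, the COM-to-COM distances from
#' all probe molecules are summarised as the per-frame mean and minimum
#' distance, the hard count of probes within the contact cutoff, and the
#' soft coordination number under the switching function. Five-number
#' (boxplot) summaries per bond and statistic are attached.
#'
#' @param traj a \code{Trajectory}.
#' @param bonds disulfide table from \code{\link{detectDisulfides}}.
#' @param probes a \code{ProbeGroup} (non-empty).
#' @param cfg a \code{\link{proximityConfig}}.
#' @return list with \code{$perFrame} (long data.frame: bond, frame, time,
#'   meanDist, minDist, countWithin, cnSoft) and \code{$summary}
#'   (bond x statistic five-number table).
#' @export
distanceStats <- function(traj, bonds, probes, cfg = proximityConfig()) {
  if (length(probes@molecules) == 0) stop("probe group is empty")
  if (nrow(bonds) == 0) stop("no disulfide bonds supplied")
  s <- traj@topology
  masses <- s@atoms$mass
  bondIdx <- .bondComIndices(s, bonds, cfg$bondComMode)
  framesToUse <- seq(1, nFrames(traj), by = cfg$frameStride)
  recs <- vector("list", length(framesToUse))
  for (k in seq_along(framesToUse)) {
    i <- framesToUse[k]
    xyz <- frameCoords(traj, i)
    box <- frameBox(traj, i)
    if (length(box) == 0) box <- NULL
    pC <- .frameComs(xyz, probes@molecules, masses, box)
    bC <- .frameComs(xyz, bondIdx, masses, box)
    D <- .pairDistances(pC, bC, box)        # probes x bonds
    recs[[k]] <- data.frame(
      bond = bonds$label, frame = i, time = traj@times[i],
      meanDist = colMeans(D),
      minDist = apply(D, 2, min),
      countWithin = colSums(D < cfg$contactCutoff),
      cnSoft = colSums(matrix(switchingValue(as.vector(D), cfg$switching),
                              nrow = nrow(D))),
      stringsAsFactors = FALSE)
  }
  perFrame <- do.call(rbind, recs)
  rownames(perFrame) <- NULL
  sumRows <- list()
  for (b in bonds$label) {
    sub <- perFrame[perFrame$bond == b, ]
    for (stat in c("meanDist", "minDist", "countWithin", "cnSoft")) {
      q <- stats::quantile(sub[[stat]], c(0, 0.25, 0.5, 0.75, 1),
                           names = FALSE)
      sumRows[[length(sumRows) + 1]] <- data.frame(
        bond = b, statistic = stat, min = q[1], q1 = q[2], median = q[3],
        q3 = q[4], max = q[5], stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, sumRows)
  rownames(summary) <- NULL
  list(perFrame = perFrame, summary = summary)
}

.trajectoryCall <- function(trajectoryId, calledBond, criterion, event,
                            energyChecksFailed = 0L) {
  structure(list(trajectoryId = trajectoryId, calledBond = calledBond,
                 criterion = criterion, event = event,
                 energyChecksFailed = as.integer(energyChecksFailed)),
            class = "TrajectoryCall")
}

#' @export
print.TrajectoryCall <- function(x, ...) {
  cat("TrajectoryCall [", x$criterion, "] ", x$trajectoryId, ": ",
      if (is.na(x$calledBond)) "no call" else x$calledBond, sep = "")
  if (!is.null(x$event)) {
    cat(sprintf(" (frame %d, t = %g ps, probe %d, d = %.3f nm)",
                x$event$frameIndex, x$event$time, x$event$probeIndex,
                x$event$distance))
  }
  if (x$energyChecksFailed > 0) {
    cat(" [", x$energyChecksFailed, "energy checks failed ]")
  }
  cat("\n")
  invisible(x)
}

# all contact events of one frame, ordered by increasing distance then bond
.frameEvents <- function(D, cutoff, bonds, frameIndex, time) {
  hit <- which(D < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  ev <- data.frame(frameIndex = frameIndex, time = time,
                   bond = bonds$label[hit[, 2]],
                   bondIndex = hit[, 2], probeIndex = hit[, 1],
                   distance = D[hit], stringsAsFactors = FALSE)
  ev[order(ev$distance, ev$bondIndex, ev$probeIndex), , drop = FALSE]
}

#' First-passage scan of the distance criterion
#'
#' Scans frames in time order; a disulfide is called reduced at the first
#' (frame, bond, probe) with probe-COM-to-bond-COM distance below the
#' contact cutoff. Ties inside one frame are broken by smallest distance,
#' then bond order. At most one call is made per trajectory (the physical
#' protocol stops a simulation at the reduction event). No contact yields a
#' no-call record.
#'
#' @inheritParams distanceStats
#' @param trajectoryId identifier carried into the call record.
#' @return a \code{TrajectoryCall}.
#' @export
scanDistanceCriterion <- function(traj, bonds, probes,
                                  cfg = proximityConfig(),
                                  trajectoryId = "traj") {
  if (length(probes@molecules) == 0) stop("probe group is empty")
  s <- traj@topology
  masses <- s@atoms$mass
  bondIdx <- .bondComIndices(s, bonds, cfg$bondComMode)
  for (i in seq(1, nFrames(traj), by = cfg$frameStride)) {
    xyz <- frameCoords(traj, i)
    box <- frameBox(traj, i)
    if (length(box) == 0) box <- NULL
    pC <- .frameComs(xyz, probes@molecules, masses, box)
    bC <- .frameComs(xyz, bondIdx, masses, box)
    D <- .pairDistances(pC, bC, box)
    ev <- .frameEvents(D, cfg$contactCutoff, bonds, i, traj@times[i])
    if (!is.null(ev)) {
      e <- ev[1, ]
      return(.trajectoryCall(trajectoryId, e$bond, "distance",
                             list(frameIndex = e$frameIndex, time = e$time,
                                  bond = e$bond, probeIndex = e$probeIndex,
                                  distance = e$distance)))
    }
  }
  .trajectoryCall(trajectoryId, NA_character_, "distance", NULL)
}

#' Aggregate per-trajectory calls into lability probabilities
#'
#' The probability assigned to each bond is the fraction of trajectories
#' whose call landed on it; the no-call fraction completes the total to 1.
#'
#' @param calls list of \code{TrajectoryCall} records sharing one criterion.
#' @param bondLabels optional full set of bond labels so uncalled bonds
#'   appear with probability 0.
#' @return a \code{LabilityReport}.
#' @export
aggregateLability <- function(calls, bondLabels = NULL) {
  if (length(calls) == 0) stop("at least one trajectory call is required")
  crit <- unique(vapply(calls, function(cl) cl$criterion, character(1)))
  if (length(crit) != 1) {
    stop("cannot aggregate calls from mixed criteria: ",
         paste(crit, collapse = ", "))
  }
  called <- vapply(calls, function(cl) cl$calledBond, character(1))
  n <- length(calls)
  labels <- unique(c(bondLabels, called[!is.na(called)]))
  p <- vapply(labels, function(b) sum(called == b, na.rm = TRUE) / n,
              numeric(1))
  names(p) <- labels
  new("LabilityReport", probabilities = p, nTrajectories = as.integer(n),
      noCallFraction = sum(is.na(called)) / n, criterion = crit)
}
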