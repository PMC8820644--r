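# Simplified vacuum potential used by the distance+energy criterion:
# harmonic bonds and angles, Lennard-Jones and Coulomb truncated at the
# nonbonded cutoff (default 1.2 nm). The criterion's logic (compare the
# minimised energies of the intact and cleaved structures) is what matters;
# externally computed energies can be injected via the backend argument of
# energyCheck() for replication against an MD engine.

.COULOMB_K <- 138.935458  # kJ mol^-1 nm e^-2

#' Default parameters of the simplified potential
#'
#' Harmonic bond classes are keyed by the sorted element pair; any pair not
#' listed raises an error at energy evaluation. LJ parameters are
#' per-element with Lorentz-Berthelot combination.
#'
#' @param cutoff nonbonded cutoff, nm.
#' @return a \code{ForceField} object.
#' @export
defaultForceField <- function(cutoff = 1.2) {
  bondTable <- data.frame(
    pair = c("C-C", "C-N", "C-O", "C-S", "C-H", "H-N", "H-O", "S-S", "H-S",
             "C-P", "H-P"),
    k = c(rep(250000, 2), 280000, 220000, rep(300000, 3), 170000, 280000,
          200000, 280000),
    req = c(0.153, 0.147, 0.143, 0.181, 0.109, 0.101, 0.096, 0.204, 0.134,
            0.184, 0.142),
    stringsAsFactors = FALSE)
  ljTable <- data.frame(
    element = c("H", "C", "N", "O", "S", "P"),
    sigma = c(0.240, 0.340, 0.325, 0.296, 0.356, 0.374),
    epsilon = c(0.066, 0.360, 0.710, 0.880, 1.046, 0.840),
    stringsAsFactors = FALSE)
  new("ForceField", bondTable = bondTable, angleK = 420,
      angleTheta0 = 109.47, ljTable = ljTable, cutoff = cutoff)
}

.pairClass <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2), sep = "-")
}

#' Infer covalent topology from geometry
#'
#' Bonds are assigned where the interatomic distance is below
#' \code{scale} times the sum of covalent radii (H-H pairs never bond);
#' pairs recorded in the structure's \code{excludedBonds} slot (broken
#' disulfides) are removed. Angles are every connected i-j-k triple, and
#' nonbonded exclusions are all 1-2 and 1-3 pairs.
#'
#' @param s a \code{MolecularStructure}.
#' @param scale tolerance factor on covalent radii sums.
#' @return list with \code{bonds} (2-col matrix), \code{angles} (3-col
#'   matrix, centre atom second) and \code{excluded} (2-col matrix of
#'   nonbonded exclusions).
#' @export
buildTopology <- function(s, scale = 1.2) {
  n <- nAtoms(s)
  xyz <- coords(s)
  el <- .normalizeElement(s@atoms$element)
  rc <- .elementCovalentRadius(el) / 10  # nm
  D <- .pairDistances(xyz, xyz, NULL)
  thr <- outer(rc, rc, "+") * scale
  isH <- el == "H"
  mask <- D < thr & upper.tri(D)
  mask[isH, isH] <- FALSE
  bonds <- which(mask, arr.ind = TRUE)
  if (nrow(s@excludedBonds)) {
    exKey <- paste(pmin(s@excludedBonds[, 1], s@excludedBonds[, 2]),
                   pmax(s@excludedBonds[, 1], s@excludedBonds[, 2]))
    bKey <- paste(pmin(bonds[, 1], bonds[, 2]),
                  pmax(bonds[, 1], bonds[, 2]))
    bonds <- bonds[!(bKey %in% exKey), , drop = FALSE]
  }
  # adjacency for angles
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  angles <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      angles[[length(angles) + 1]] <-
        cbind(cmb[1, ], j, cmb[2, ], deparse.level = 0)
    }
  }
  angles <- if (length(angles)) do.call(rbind, angles)
            else matrix(integer(0), ncol = 3)
  excl <- rbind(bonds,
                if (nrow(angles)) angles[, c(1, 3), drop = FALSE]
                else NULL)
  list(bonds = bonds, angles = angles, excluded = excl)
}

.ljParams <- function(s, ff) {
  el <- .normalizeElement(s@atoms$element)
  idx <- match(el, .normalizeElement(ff@ljTable$element))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no LJ parameters for atom ", bad, " (element ",
         s@atoms$element[bad], ")")
  }
  list(sigma = ff@ljTable$sigma[idx], epsilon = ff@ljTable$epsilon[idx])
}

.bondParams <- function(s, ff, bonds) {
  if (nrow(bonds) == 0) {
    return(list(k = numeric(0), req = numeric(0)))
  }
  el <- .normalizeElement(s@atoms$element)
  cls <- .pairClass(el[bonds[, 1]], el[bonds[, 2]])
  idx <- match(cls, ff@bondTable$pair)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no bond parameters for class ", cls[bad], " (atoms ",
         bonds[bad, 1], "-", bonds[bad, 2], ")")
  }
  list(k = ff@bondTable$k[idx], req = ff@bondTable$req[idx])
}

# nonbonded pair list: all pairs minus exclusions
.nonbondedPairs <- function(n, excluded) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  all <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (nrow(excluded)) {
    exKey <- paste(pmin(excluded[, 1], excluded[, 2]),
                   pmax(excluded[, 1], excluded[, 2]))
    key <- paste(all[, 1], all[, 2])
    all <- all[!(key %in% exKey), , drop = FALSE]
  }
  all
}

#' Potential energy under the simplified force field
#'
#' @param s a \code{MolecularStructure}.
#' @param ff a \code{ForceField}.
#' @param topology optional precomputed \code{\link{buildTopology}} result.
#' @param charges optional per-atom partial charges (e); defaults to zero
#'   (the vacuum criterion is dominated by the bonded and LJ terms).
#' @return list with components \code{total}, \code{bonds}, \code{angles},
#'   \code{lj}, \code{coulomb}, kJ/mol.
#' @export
potentialEnergy <- function(s, ff = defaultForceField(), topology = NULL,
                            charges = NULL) {
  if (is.null(topology)) topology <- buildTopology(s)
  n <- nAtoms(s)
  xyz <- coords(s)
  box <- if (length(s@box)) s@box else NULL
  if (is.null(charges)) charges <- numeric(n)

  eBond <- 0
  bp <- .bondParams(s, ff, topology$bonds)
  if (nrow(topology$bonds)) {
    d <- .minImageDisp(xyz[topology$bonds[, 1], , drop = FALSE] -
                       xyz[topology$bonds[, 2], , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    eBond <- sum(0.5 * bp$k * (r - bp$req)^2)
  }

  eAngle <- 0
  if (nrow(topology$angles)) {
    th <- .angleValues(xyz, topology$angles, box)
    th0 <- ff@angleTheta0 * pi / 180
    eAngle <- sum(0.5 * ff@angleK * (th - th0)^2)
  }

  eLJ <- 0; eCoul <- 0
  nb <- .nonbondedPairs(n, topology$excluded)
  if (nrow(nb)) {
    lj <- .ljParams(s, ff)
    d <- .minImageDisp(xyz[nb[, 1], , drop = FALSE] -
                       xyz[nb[, 2], , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    within <- r < ff@cutoff
    if (any(within)) {
      i <- nb[within, 1]; j <- nb[within, 2]; rw <- r[within]
      sig <- (lj$sigma[i] + lj$sigma[j]) / 2
      eps <- sqrt(lj$epsilon[i] * lj$epsilon[j])
      sr6 <- (sig / rw)^6
      eLJ <- sum(4 * eps * (sr6 * sr6 - sr6))
      qq <- charges[i] * charges[j]
      eCoul <- sum(.COULOMB_K * qq / rw)
    }
  }

  list(total = eBond + eAngle + eLJ + eCoul, bonds = eBond,
       angles = eAngle, lj = eLJ, coulomb = eCoul)
}

.angleValues <- function(xyz, angles, box) {
  u <- .minImageDisp(xyz[angles[, 1], , drop = FALSE] -
                     xyz[angles[, 2], , drop = FALSE], box)
  v <- .minImageDisp(xyz[angles[, 3], , drop = FALSE] -
                     xyz[angles[, 2], , drop = FALSE], box)
  cu <- sqrt(rowSums(u * u)); cv <- sqrt(rowSums(v * v))
  ct <- rowSums(u * v) / (cu * cv)
  acos(pmin(1, pmax(-1, ct)))
}

# analytic gradient of the potential, (n x 3) matrix, kJ/mol/nm
.energyGradient <- function(s, ff, topology, charges = NULL) {
  n <- nAtoms(s)
  xyz <- coords(s)
  box <- if (length(s@box)) s@box else NULL
  if (is.null(charges)) charges <- numeric(n)
  g <- matrix(0, n, 3)

  bp <- .bondParams(s, ff, topology$bonds)
  if (nrow(topology$bonds)) {
    i <- topology$bonds[, 1]; j <- topology$bonds[, 2]
    d <- .minImageDisp(xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    coef <- bp$k * (r - bp$req) / r
    gi <- d * coef
    for (k in 1:3) {
      g[, k] <- g[, k] + tabulate2(i, gi[, k], n) - tabulate2(j, gi[, k], n)
    }
  }

  if (nrow(topology$angles)) {
    A <- topology$angles
    u <- .minImageDisp(xyz[A[, 1], , drop = FALSE] -
                       xyz[A[, 2], , drop = FALSE], box)
    v <- .minImageDisp(xyz[A[, 3], , drop = FALSE] -
                       xyz[A[, 2], , drop = FALSE], box)
    cu <- sqrt(rowSums(u * u)); cv <- sqrt(rowSums(v * v))
    uh <- u / cu; vh <- v / cv
    ct <- rowSums(uh * vh)
    ct <- pmin(1, pmax(-1, ct))
    st <- sqrt(pmax(1 - ct * ct, 1e-12))
    th <- acos(ct)
    dV <- ff@angleK * (th - ff@angleTheta0 * pi / 180)
    # dtheta/dri and dtheta/drk
    gi <- (uh * ct - vh) / (cu * st) * dV
    gk <- (vh * ct - uh) / (cv * st) * dV
    gj <- -(gi + gk)
    for (k in 1:3) {
      g[, k] <- g[, k] + tabulate2(A[, 1], gi[, k], n) +
        tabulate2(A[, 2], gj[, k], n) + tabulate2(A[, 3], gk[, k], n)
    }
  }

  nb <- .nonbondedPairs(n, topology$excluded)
  if (nrow(nb)) {
    lj <- .ljParams(s, ff)
    i <- nb[, 1]; j <- nb[, 2]
    d <- .minImageDisp(xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    within <- r < ff@cutoff
    if (any(within)) {
      i <- i[within]; j <- j[within]
      d <- d[within, , drop = FALSE]; r <- r[within]
      sig <- (lj$sigma[i] + lj$sigma[j]) / 2
      eps <- sqrt(lj$epsilon[i] * lj$epsilon[j])
      sr6 <- (sig / r)^6
      # dV/dr for LJ and Coulomb
      dV <- (-24 * eps * (2 * sr6 * sr6 - sr6) / r) -
        .COULOMB_K * charges[i] * charges[j] / r^2
      gi <- d * (dV / r)
      for (k in 1:3) {
        g[, k] <- g[, k] + tabulate2(i, gi[, k], n) -
          tabulate2(j, gi[, k], n)
      }
    }
  }
  g
}

# sum values into bins (like tabulate, but weighted)
tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
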