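# Shrake-Rupley solvent-accessible surface area. Implemented here because
# no installed package in this stack computes SASA. Sample points are
# placed on each atom's solvent-expanded sphere with a deterministic golden
# spiral; a point is accessible when no neighbouring expanded sphere covers
# it. SASA is reported in Angstrom^2 (the convention of structure tables),
# while coordinates come in as nm.

# n roughly evenly distributed unit vectors (golden-spiral construction)
.spherePoints <- function(n) {
  k <- seq_len(n)
  phi <- (1 + sqrt(5)) / 2
  z <- (2 * k - 1) / n - 1
  theta <- 2 * pi * k / phi
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param s a \code{MolecularStructure} (treated as a single molecule; no
#'   periodic images).
#' @param probeRadius solvent probe radius, Angstrom (water: 1.4).
#' @param nPoints sample points per atom sphere; the quadrature error
#'   shrinks roughly as 1/nPoints.
#' @param radiiOverrides named numeric vector (Angstrom) of van der Waals
#'   radii taking precedence over the built-in table; required for elements
#'   the table lacks.
#' @return numeric vector of per-atom accessible areas, Angstrom^2.
#' @export
shrakeRupleySasa <- function(s, probeRadius = 1.4, nPoints = 960L,
                             radiiOverrides = NULL) {
  n <- nAtoms(s)
  if (n == 0) return(numeric(0))
  xyz <- coords(s) * 10  # nm -> Angstrom
  rad <- .elementVdwRadius(s@atoms$element, overrides = radiiOverrides) +
    probeRadius
  pts <- .spherePoints(nPoints)
  out <- numeric(n)
  # neighbour search radius: two largest expanded spheres can touch
  maxR <- max(rad)
  D <- .pairDistances(xyz, xyz, NULL)
  for (i in seq_len(n)) {
    nbr <- which(D[i, ] < rad[i] + rad & seq_len(n) != i)
    if (length(nbr) == 0) {
      out[i] <- 4 * pi * rad[i]^2
      next
    }
    P <- pts * rad[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nbr) {
      if (!any(free)) break
      dj <- sweep(P[free, , drop = FALSE], 2, xyz[j, ], "-")
      free[free] <- rowSums(dj * dj) > rad[j]^2
    }
    out[i] <- 4 * pi * rad[i]^2 * sum(free) / nPoints
  }
  out
}

#' Solvent accessibility of one disulfide bond
#'
#' Default mode sums the accessible areas of the two sulfur atoms; the
#' whole-cystine mode sums over every atom of both cysteine residues.
#'
#' @param s a \code{MolecularStructure}.
#' @param bond one row of a \code{\link{detectDisulfides}} table.
#' @param mode \code{"SG_only"} or \code{"cystine"}.
#' @param sasa optional precomputed per-atom SASA from
#'   \code{\link{shrakeRupleySasa}} (computed on the full structure
#'   otherwise).
#' @param ... passed on to \code{\link{shrakeRupleySasa}}.
#' @return accessible area in Angstrom^2.
#' @export
disulfideSasa <- function(s, bond, mode = c("SG_only", "cystine"),
                          sasa = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(sasa)) sasa <- shrakeRupleySasa(s, ...)
  if (mode == "SG_only") {
    return(sasa[bond$sg1] + sasa[bond$sg2])
  }
  a <- s@atoms
  idx <- which((a$chain == bond$chain1 & a$resno == bond$res1) |
               (a$chain == bond$chain2 & a$resno == bond$res2))
  sum(sasa[idx])
}
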