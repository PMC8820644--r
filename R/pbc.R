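# Periodic-geometry primitives (orthorhombic cells only).

# minimum-image displacement(s); d may be a vector or an (n x 3) matrix
.minImageDisp <- function(d, box = NULL) {
  if (is.null(box) || length(box) == 0) return(d)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

#' Minimum-image distance between points in an orthorhombic cell
#'
#' @param a,b numeric(3) positions, or (n x 3) matrices of positions, nm.
#'   When both are matrices they are paired row-wise.
#' @param box numeric(3) box lengths (nm), or NULL for plain Euclidean
#'   distance.
#' @return numeric vector of distances, nm.
#' @export
minImageDistance <- function(a, b, box = NULL) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 3)
  if (!is.matrix(b)) b <- matrix(b, ncol = 3)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  d <- .minImageDisp(a - b, box)
  sqrt(rowSums(d * d))
}

# all pairwise minimum-image distances between rows of A (n x 3) and B (m x 3)
.pairDistances <- function(A, B, box = NULL) {
  n <- nrow(A); m <- nrow(B)
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (!is.null(box) && length(box) == 3) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Mass-weighted centre of mass with minimum-image unwrapping
#'
#' For a molecule split across the periodic boundary each atom is first
#' shifted by whole box vectors to the image nearest the first atom of the
#' set (reference-atom unwrapping), then the mass-weighted mean position is
#' taken and wrapped back into the primary cell.
#'
#' @param xyz (nAtoms x 3) coordinate matrix, nm.
#' @param indices atom indices of the molecule (non-empty).
#' @param masses per-atom masses for the full coordinate set (amu).
#' @param box numeric(3) box lengths (nm) or NULL.
#' @return numeric(3) centre-of-mass position, nm.
#' @export
massWeightedCom <- function(xyz, indices, masses, box = NULL) {
  if (length(indices) == 0) stop("indices must be non-empty")
  m <- masses[indices]
  if (sum(m) <= 0) stop("zero total mass")
  p <- xyz[indices, , drop = FALSE]
  if (!is.null(box) && length(box) == 3) {
    ref <- p[1, ]
    for (k in 1:3) {
      p[, k] <- p[, k] - box[k] * round((p[, k] - ref[k]) / box[k])
    }
  }
  com <- colSums(p * m) / sum(m)
  if (!is.null(box) && length(box) == 3) {
    com <- com - box * floor(com / box)
  }
  com
}

# wrap positions into [0, box)
.wrapIntoBox <- function(xyz, box) {
  if (is.null(box) || length(box) == 0) return(xyz)
  for (k in 1:3) xyz[, k] <- xyz[, k] - box[k] * floor(xyz[, k] / box[k])
  xyz
}
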