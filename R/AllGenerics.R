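#' Accessors for the core containers
#'
#' \code{atoms} returns the per-atom data frame; \code{coords} the coordinate
#' matrix (nm); \code{nAtoms}/\code{nFrames} counts; \code{boxLengths} the
#' orthorhombic box edge lengths (numeric(0) when non-periodic);
#' \code{frameTimes} the per-frame times in ps; \code{frameCoords} one
#' frame's (nAtoms x 3) coordinate matrix.
#'
#' @param x a \code{MolecularStructure} or \code{Trajectory}.
#' @param i frame index for \code{frameCoords}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname accessors
#' @export
setMethod("atoms", "MolecularStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)
#' @rdname accessors
#' @export
setMethod("coords", "MolecularStructure", function(x) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})
#' @rdname accessors
#' @export
setMethod("nAtoms", "MolecularStructure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
#' @export
setMethod("boxLengths", "MolecularStructure", function(x) x@box)
#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= dim(x@coords)[1])
  m <- x@coords[i, , , drop = TRUE]
  dim(m) <- c(dim(x@coords)[2], 3)
  m
})

#' Box lengths of a trajectory frame
#'
#' @param x a Trajectory.
#' @param i frame index.
#' @return numeric(3) box lengths in nm, or numeric(0) if non-periodic.
#' @export
frameBox <- function(x, i) {
  if (nrow(x@boxes) == 0) return(x@topology@box)
  x@boxes[i, ]
}

#' Construct a MolecularStructure
#'
#' @param atoms data.frame with columns name, element, resname, resno, chain,
#'   x, y, z (nm); a \code{mass} column is optional and otherwise filled from
#'   the built-in element table.
#' @param box numeric(3) orthorhombic box lengths (nm) or NULL.
#' @param title character title.
#' @param massOverrides named numeric vector of element masses taking
#'   precedence over the built-in table.
#' @return a \code{MolecularStructure}.
#' @export
molecularStructure <- function(atoms, box = NULL, title = "",
                               massOverrides = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$mass)) {
    atoms$mass <- elementMass(atoms$element, overrides = massOverrides)
  }
  atoms <- atoms[, c("name", "element", "mass", "resname", "resno", "chain",
                     "x", "y", "z")]
  rownames(atoms) <- NULL
  new("MolecularStructure", atoms = atoms,
      box = if (is.null(box)) numeric(0) else as.numeric(box),
      title = title,
      excludedBonds = matrix(integer(0), ncol = 2))
}

#' Construct a Trajectory
#'
#' @param topology a \code{MolecularStructure}.
#' @param coords (nFrames x nAtoms x 3) array, or a list of (nAtoms x 3)
#'   matrices, nm.
#' @param times per-frame times, ps; defaults to 0, 1, 2, ...
#' @param boxes optional (nFrames x 3) matrix of per-frame box lengths (nm);
#'   defaults to the topology box for every frame.
#' @return a \code{Trajectory}.
#' @export
trajectory <- function(topology, coords, times = NULL, boxes = NULL) {
  if (is.list(coords)) {
    nf <- length(coords)
    if (nf == 0) stop("a trajectory must contain at least one frame")
    na <- nrow(coords[[1]])
    arr <- array(NA_real_, dim = c(nf, na, 3))
    for (i in seq_len(nf)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (is.null(boxes)) {
    boxes <- if (length(topology@box)) {
      matrix(topology@box, nrow = nf, ncol = 3, byrow = TRUE)
    } else {
      matrix(numeric(0), nrow = 0, ncol = 3)
    }
  }
  new("Trajectory", topology = topology, coords = coords,
      times = as.numeric(times), boxes = boxes)
}

#' Replace the coordinates of a structure
#'
#' @param s a \code{MolecularStructure}.
#' @param xyz (nAtoms x 3) matrix, nm.
#' @return the structure with new coordinates.
#' @export
setCoords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nAtoms(s), ncol(xyz) == 3)
  s@atoms$x <- xyz[, 1]
  s@atoms$y <- xyz[, 2]
  s@atoms$z <- xyz[, 3]
  s
}

#' Extract a subset of atoms as a new structure
#'
#' @param s a \code{MolecularStructure}.
#' @param idx integer vector of atom indices to keep.
#' @return a \code{MolecularStructure} with the selected atoms (in the given
#'   order); excluded-bond bookkeeping is remapped and entries referring to
#'   dropped atoms are removed.
#' @export
subsetAtoms <- function(s, idx) {
  out <- s
  out@atoms <- s@atoms[idx, , drop = FALSE]
  rownames(out@atoms) <- NULL
  if (nrow(s@excludedBonds)) {
    map <- integer(nAtoms(s))
    map[idx] <- seq_along(idx)
    eb <- s@excludedBonds
    keep <- map[eb[, 1]] > 0 & map[eb[, 2]] > 0
    out@excludedBonds <- cbind(map[eb[keep, 1]], map[eb[keep, 2]])
  }
  out
}
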