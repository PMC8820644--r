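# Trajectory I/O. Multi-model PDB is the portable text format used for all
# fixtures; DCD binaries are read through bio3d. XTC/TRR have no installed
# reader in this stack and are rejected with a clear message.

#' Read a multi-frame trajectory
#'
#' @param path file path.
#' @param topology a \code{MolecularStructure} with the same atom count as
#'   every frame.
#' @param format \code{"auto"} (by extension), \code{"multiPDB"} or
#'   \code{"DCD"}. \code{"XTC"} and \code{"TRR"} are recognised but
#'   unsupported.
#' @param times optional per-frame times (ps); defaults to
#'   0, frameInterval, ... .
#' @param frameInterval spacing (ps) used when \code{times} is NULL.
#' @return a \code{Trajectory}.
#' @export
readTrajectory <- function(path, topology,
                           format = c("auto", "multiPDB", "DCD", "XTC",
                                      "TRR"),
                           times = NULL, frameInterval = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "multiPDB", dcd = "DCD", xtc = "XTC", trr = "TRR",
                     stop("cannot infer trajectory format from extension of ",
                          path))
  }
  if (format %in% c("XTC", "TRR")) {
    stop(format, " trajectories are not supported by this installation; ",
         "convert to multi-model PDB or DCD")
  }
  frames <- if (format == "multiPDB") {
    .readPdbStructure(path, multi = TRUE)$frames
  } else {
    dcd <- suppressMessages(bio3d::read.dcd(path, verbose = FALSE))
    lapply(seq_len(nrow(dcd)), function(i) {
      matrix(dcd[i, ], ncol = 3, byrow = TRUE) / 10
    })
  }
  if (length(frames) == 0) stop("trajectory contains zero frames: ", path)
  na <- nrow(frames[[1]])
  if (na != nAtoms(topology)) {
    stop("atom-count mismatch: trajectory frames have ", na,
         " atoms but the topology has ", nAtoms(topology))
  }
  if (is.null(times)) times <- (seq_along(frames) - 1) * frameInterval
  trajectory(topology, frames, times = times)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a \code{Trajectory}.
#' @param path output path.
#' @param stride keep every \code{stride}-th frame.
#' @return the path, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path, stride = 1) {
  s <- traj@topology
  keep <- seq(1, nFrames(traj), by = stride)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(s@box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      s@box[1] * 10, s@box[2] * 10, s@box[3] * 10, 90, 90, 90), con)
  }
  for (i in keep) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(.pdbAtomLines(s, xyz = frameCoords(traj, i)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
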