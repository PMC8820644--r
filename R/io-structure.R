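# Structure I/O. PDB files are read through bio3d; GRO files (for which no
# installed reader exists) are parsed from their fixed-column layout here.
# PDB coordinates are Angstrom on disk and converted to nm at the boundary;
# GRO files are already nm.

.parseCryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(numeric(0))
  cl <- cl[1]
  abc <- suppressWarnings(as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                                       substr(cl, 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(cl, 34, 40), substr(cl, 41, 47),
                                       substr(cl, 48, 54))))
  if (anyNA(abc)) return(numeric(0))
  # a 1x1x1 cell with 90-degree angles is the PDB convention for "no cell"
  if (all(abc == 1)) return(numeric(0))
  if (!anyNA(ang) && any(abs(ang - 90) > 1e-3)) {
    stop("triclinic cells are not supported (CRYST1 angles must be 90)")
  }
  abc / 10
}

.readPdbStructure <- function(path, massOverrides = NULL, multi = FALSE) {
  lines <- readLines(path, warn = FALSE)
  # light validation so malformed coordinate records fail by line number
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  for (i in rec) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz)) {
      stop("malformed ATOM/HETATM record at line ", i, " of ", path)
    }
  }
  box <- .parseCryst1(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi,
                                          verbose = FALSE))
  a <- pdb$atom
  element <- trimws(a$elesy)
  noelem <- is.na(element) | element == ""
  if (any(noelem)) {
    warning("PDB file lacks element symbols for ", sum(noelem),
            " atoms; falling back on atom-name heuristics")
    element[noelem] <- .guessElement(a$elety[noelem])
  }
  atoms <- data.frame(
    name = trimws(a$elety), element = element,
    resname = trimws(a$resid), resno = a$resno,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    x = a$x / 10, y = a$y / 10, z = a$z / 10,
    stringsAsFactors = FALSE)
  atoms$mass <- elementMass(atoms$element, overrides = massOverrides)
  s <- molecularStructure(atoms, box = if (length(box)) box else NULL,
                          title = basename(path))
  if (multi) {
    nf <- nrow(pdb$xyz)
    frames <- vector("list", nf)
    for (i in seq_len(nf)) {
      frames[[i]] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
    }
    return(list(structure = s, frames = frames))
  }
  s
}

.readGroStructure <- function(path, massOverrides = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("not a valid GRO file: ", path)
  title <- trimws(lines[1])
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1) stop("malformed atom count at line 2 of ", path)
  if (length(lines) < 2 + n + 1) {
    stop("GRO file truncated: expected ", n, " atom lines plus a box line")
  }
  rec <- lines[3:(2 + n)]
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(rec, a, b)))
    if (anyNA(v)) {
      stop("malformed GRO record at line ", 2 + which(is.na(v))[1],
           " of ", path)
    }
    v
  }
  resno <- as.integer(num(1, 5))
  resname <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  x <- num(21, 28); y <- num(29, 36); z <- num(37, 44)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + n + 1]),
                                               "\\s+")[[1]]))
  if (length(boxv) > 3 && any(abs(boxv[4:length(boxv)]) > 1e-9)) {
    stop("triclinic cells are not supported (off-diagonal GRO box entries)")
  }
  box <- boxv[1:3]
  if (anyNA(box) || all(box == 0)) box <- NULL
  element <- .guessElement(name)
  atoms <- data.frame(name = name, element = element, resname = resname,
                      resno = resno, chain = "A", x = x, y = y, z = z,
                      stringsAsFactors = FALSE)
  atoms$mass <- elementMass(element, overrides = massOverrides)
  molecularStructure(atoms, box = box, title = title)
}

#' Read a molecular structure from a PDB or GRO file
#'
#' Coordinates are converted to the package-internal nm unit (PDB files are
#' Angstrom on disk). Masses are assigned from the built-in element table;
#' PDB files without element columns fall back on atom-name heuristics with
#' a warning. Orthorhombic cells only; triclinic input is rejected.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"PDB"} or \code{"GRO"}.
#' @param massOverrides named numeric vector (amu) for exotic elements.
#' @return a \code{MolecularStructure}.
#' @export
readStructure <- function(path, format = c("auto", "PDB", "GRO"),
                          massOverrides = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "PDB", ent = "PDB", gro = "GRO",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "PDB") .readPdbStructure(path, massOverrides)
  else .readGroStructure(path, massOverrides)
}

#' Write a structure as a PDB file
#'
#' @param s a \code{MolecularStructure}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStructurePDB <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(s@box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      s@box[1] * 10, s@box[2] * 10, s@box[3] * 10, 90, 90, 90), con)
  }
  writeLines(.pdbAtomLines(s), con)
  writeLines("END", con)
  invisible(path)
}

.pdbAtomLines <- function(s, xyz = NULL) {
  a <- s@atoms
  if (is.null(xyz)) xyz <- coords(s)
  name4 <- vapply(a$name, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4)
    else sprintf(" %-3s", nm)
  }, character(1), USE.NAMES = FALSE)
  el <- toupper(a$element)
  el[el == "NA2"] <- "NA"; el[el == "CA2"] <- "CA"
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          (seq_len(nrow(a)) - 1L) %% 100000L,
          name4, substr(a$resname, 1, 4), substr(a$chain, 1, 1),
          a$resno %% 10000L,
          xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10, 1, 0, el)
}

#' Write a structure as a GRO file
#'
#' @param s a \code{MolecularStructure}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStructureGRO <- function(s, path) {
  a <- s@atoms
  xyz <- coords(s)
  lines <- c(
    if (nzchar(s@title)) s@title else "written by redoxscan",
    sprintf("%5d", nrow(a)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            a$resno %% 100000L, substr(a$resname, 1, 5),
            substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    if (length(s@box)) sprintf("%10.5f%10.5f%10.5f",
                               s@box[1], s@box[2], s@box[3])
    else sprintf("%10.5f%10.5f%10.5f", 0, 0, 0))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize structure metadata as JSON
#'
#' Writes counts, box, title and the residue table (no coordinates) so a
#' structure's identity can be recorded alongside numeric reports.
#'
#' @param s a \code{MolecularStructure}.
#' @param path output path; when NULL the JSON string is returned.
#' @return the path (or the JSON string), invisibly.
#' @export
structureMetadataJSON <- function(s, path = NULL) {
  a <- s@atoms
  res <- unique(a[, c("chain", "resno", "resname")])
  meta <- list(title = s@title, nAtoms = nrow(a), nResidues = nrow(res),
               box_nm = if (length(s@box)) s@box else NULL,
               residues = res)
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}
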