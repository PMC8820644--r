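# Built-in per-element tables. Internal length unit throughout the package is
# nm; radii tables are kept in Angstrom because that is how SASA is reported.

.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA2 = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA2 = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904
)

# van der Waals radii (Bondi), Angstrom; used by the Shrake-Rupley sampler.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, SE = 1.90, BR = 1.85, I = 1.98, NA2 = 2.27, K = 2.75,
  MG = 1.73, CA2 = 2.31, ZN = 1.39, FE = 2.00, MN = 2.00, CU = 1.40,
  NI = 1.63, CO = 2.00
)

# single-bond covalent radii, Angstrom; used for distance-based bond inference
.COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  CL = 1.02, SE = 1.20, BR = 1.20, I = 1.39, NA2 = 1.66, K = 2.03,
  MG = 1.41, CA2 = 1.76, ZN = 1.22, FE = 1.32, MN = 1.39, CU = 1.32,
  NI = 1.24, CO = 1.26
)

.normalizeElement <- function(element) {
  el <- toupper(trimws(element))
  # NA (sodium) and CA (calcium) collide with R's NA and the CA atom name;
  # they are keyed as NA2/CA2 in the tables and normalised here.
  el[el == "NA"] <- "NA2"
  el[el == "CA" ] <- "CA2"
  el
}

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols.
#' @param overrides optional named numeric vector (amu) taking precedence over
#'   the built-in table; names are element symbols.
#' @return numeric vector of masses in amu.
#' @export
elementMass <- function(element, overrides = NULL) {
  el <- .normalizeElement(element)
  m <- unname(.ATOMIC_MASSES[el])
  if (!is.null(overrides)) {
    names(overrides) <- .normalizeElement(names(overrides))
    hit <- el %in% names(overrides)
    m[hit] <- unname(overrides[el[hit]])
  }
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element(s) with no mass override: ",
         paste(bad, collapse = ", "))
  }
  m
}

.elementVdwRadius <- function(element, overrides = NULL) {
  el <- .normalizeElement(element)
  r <- unname(.VDW_RADII[el])
  if (!is.null(overrides)) {
    names(overrides) <- .normalizeElement(names(overrides))
    hit <- el %in% names(overrides)
    r[hit] <- unname(overrides[el[hit]])
  }
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  r
}

.elementCovalentRadius <- function(element) {
  el <- .normalizeElement(element)
  r <- unname(.COVALENT_RADII[el])
  r[is.na(r)] <- 1.5  # generous fallback so exotic atoms still bond
  r
}

# atom-name -> element heuristic for PDB records lacking element columns:
# strip digits/primes, try the two-letter prefix then the first letter.
.guessElement <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9'\"]", "", toupper(trimws(nm)))
    if (nchar(s) >= 2 && substr(s, 1, 2) %in% c("CL", "BR", "SE", "FE",
                                                "ZN", "MG", "MN")) {
      return(substr(s, 1, 2))
    }
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}
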