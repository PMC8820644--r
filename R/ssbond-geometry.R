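# Static disulfide geometry: alpha-carbon distance, the five chi dihedrals
# of the cystine and the 20-class conformation taxonomy, plus the per-bond
# table combining them with solvent accessibility.

#' Alpha-carbon distance of a disulfide bond
#'
#' Plain Euclidean distance (single molecule, no periodic images), reported
#' in Angstrom as structure tables conventionally do.
#'
#' @param s a \code{MolecularStructure}.
#' @param bond one row of a \code{\link{detectDisulfides}} table.
#' @return distance in Angstrom.
#' @export
calphaDistance <- function(s, bond) {
  if (is.na(bond$ca1) || is.na(bond$ca2)) {
    stop("missing CA atom for bond ", bond$label)
  }
  xyz <- coords(s)
  10 * sqrt(sum((xyz[bond$ca1, ] - xyz[bond$ca2, ])^2))
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking down the b2 = p3 - p2 axis, the angle is
#' positive for a clockwise rotation of the far bond; range (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric(3) positions.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' The five chi dihedrals of a cystine
#'
#' chi1 = N-CA-CB-SG, chi2 = CA-CB-SG-SG', chi3 = CB-SG-SG'-CB', with chi2'
#' and chi1' mirrored on the partner cysteine. Degrees, IUPAC signs.
#'
#' @param s a \code{MolecularStructure}.
#' @param bond one row of a \code{\link{detectDisulfides}} table.
#' @return named numeric vector (chi1, chi2, chi3, chi2p, chi1p), degrees.
#' @export
chiDihedrals <- function(s, bond) {
  xyz <- coords(s)
  need <- function(chain, resno, name) {
    i <- .residueAtom(s, chain, resno, name)
    if (is.na(i)) {
      stop("missing atom ", name, " in residue ", chain, ":", resno,
           " for bond ", bond$label)
    }
    xyz[i, ]
  }
  n1 <- need(bond$chain1, bond$res1, "N")
  ca1 <- need(bond$chain1, bond$res1, "CA")
  cb1 <- need(bond$chain1, bond$res1, "CB")
  sg1 <- need(bond$chain1, bond$res1, "SG")
  n2 <- need(bond$chain2, bond$res2, "N")
  ca2 <- need(bond$chain2, bond$res2, "CA")
  cb2 <- need(bond$chain2, bond$res2, "CB")
  sg2 <- need(bond$chain2, bond$res2, "SG")
  c(chi1 = dihedralAngle(n1, ca1, cb1, sg1),
    chi2 = dihedralAngle(ca1, cb1, sg1, sg2),
    chi3 = dihedralAngle(cb1, sg1, sg2, cb2),
    chi2p = dihedralAngle(ca2, cb2, sg2, sg1),
    chi1p = dihedralAngle(n2, ca2, cb2, sg2))
}

.conformationTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "disulfide_conformations.csv",
                          package = "redoxscan")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = "character")
    }
    cache
  }
})

#' Classify a disulfide conformation from its chi signs
#'
#' The 32 sign vectors of (chi1, chi2, chi3, chi2', chi1') map onto the 20
#' named disulfide conformations: handedness (RH/LH) follows the sign of
#' chi3; the Spiral/Hook/Staple shape and the -/+ prefixes follow the signs
#' of the remaining four angles. The mapping ships as a data table
#' (\code{inst/extdata/disulfide_conformations.csv}) so it can be audited
#' directly.
#'
#' @param dihedrals named numeric vector from \code{\link{chiDihedrals}}.
#' @return list with \code{label} (e.g. \code{"-RHStaple"}) and
#'   \code{signVector} (character(5) of "+"/"-"); a chi of exactly 0 yields
#'   label \code{"unclassifiable"}.
#' @export
classifyConformation <- function(dihedrals) {
  d <- dihedrals[c("chi1", "chi2", "chi3", "chi2p", "chi1p")]
  if (anyNA(d)) stop("dihedral set must contain chi1, chi2, chi3, chi2p, chi1p")
  if (any(d == 0)) {
    return(list(label = "unclassifiable",
                signVector = ifelse(d > 0, "+", ifelse(d < 0, "-", "0"))))
  }
  sv <- ifelse(d > 0, "+", "-")
  tab <- .conformationTable()
  hit <- tab$chi1 == sv[1] & tab$chi2 == sv[2] & tab$chi3 == sv[3] &
    tab$chi2p == sv[4] & tab$chi1p == sv[5]
  list(label = tab$label[hit][1], signVector = unname(sv))
}

#' Per-bond geometry table
#'
#' One record per detected disulfide: solvent accessibility (sum of the two
#' SG atoms by default), alpha-carbon distance, the five chi dihedrals and
#' the conformation class.
#'
#' @param s a \code{MolecularStructure}.
#' @param bonds optional precomputed \code{\link{detectDisulfides}} table.
#' @param sasaMode \code{"SG_only"} or \code{"cystine"}.
#' @param nPoints Shrake-Rupley sample points per atom.
#' @param probeRadius solvent probe radius, Angstrom.
#' @return data.frame with columns \code{bond}, \code{sasa_A2},
#'   \code{ca_dist_A}, \code{chi1}..\code{chi1p}, \code{conformation}.
#' @export
geometryTable <- function(s, bonds = NULL, sasaMode = "SG_only",
                          nPoints = 960L, probeRadius = 1.4) {
  if (is.null(bonds)) bonds <- detectDisulfides(s)
  if (nrow(bonds) == 0) {
    return(data.frame(bond = character(0), sasa_A2 = numeric(0),
                      ca_dist_A = numeric(0), chi1 = numeric(0),
                      chi2 = numeric(0), chi3 = numeric(0),
                      chi2p = numeric(0), chi1p = numeric(0),
                      conformation = character(0),
                      stringsAsFactors = FALSE))
  }
  sasa <- shrakeRupleySasa(s, probeRadius = probeRadius, nPoints = nPoints)
  rows <- lapply(seq_len(nrow(bonds)), function(i) {
    b <- bonds[i, ]
    ch <- chiDihedrals(s, b)
    cls <- classifyConformation(ch)
    data.frame(bond = b$label,
               sasa_A2 = disulfideSasa(s, b, mode = sasaMode, sasa = sasa),
               ca_dist_A = calphaDistance(s, b),
               chi1 = ch[["chi1"]], chi2 = ch[["chi2"]], chi3 = ch[["chi3"]],
               chi2p = ch[["chi2p"]], chi1p = ch[["chi1p"]],
               conformation = cls$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
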