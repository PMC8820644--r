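# Disulfide detection and probe selection.

.CYS_NAMES <- c("CYS", "CYX", "CYS2")
.TCEP_NAMES <- c("TCEP", "TCP")
.DTT_NAMES <- c("DTT", "DTTX")

#' Detect disulfide bonds from sulfur geometry
#'
#' Pairs cysteine SG atoms whose minimum-image distance is at most
#' \code{sgCutoff} (default 0.25 nm, comfortably covering the ~0.205 nm S-S
#' bond). Pairing is greedy nearest-first, so each SG joins at most one
#' bond; an SG within the cutoff of two partners triggers a warning and is
#' assigned to its nearest partner. Bonds are returned sorted by the first
#' residue id, with the lower residue number first within each bond, so the
#' result is invariant to atom order in the input.
#'
#' @param s a \code{MolecularStructure} containing cysteine residues.
#' @param sgCutoff SG-SG detection cutoff, nm.
#' @return data.frame with one row per bond: \code{label}
#'   ("CysA-CysB" in input residue numbering), residue ids/chains, and atom
#'   indices of the SG, CA and CB atoms of both cysteines (NA when absent).
#' @export
detectDisulfides <- function(s, sgCutoff = 0.25) {
  a <- s@atoms
  box <- if (length(s@box)) s@box else NULL
  sg <- which(a$resname %in% .CYS_NAMES & a$name == "SG")
  if (length(sg) < 2) {
    return(.emptyBondTable())
  }
  P <- coords(s)[sg, , drop = FALSE]
  D <- .pairDistances(P, P, box)
  diag(D) <- Inf
  cand <- which(D <= sgCutoff & upper.tri(D), arr.ind = TRUE)
  if (nrow(cand) == 0) return(.emptyBondTable())
  # multi-partner ambiguity warning before greedy resolution
  within <- rowSums(D <= sgCutoff)
  if (any(within > 1)) {
    amb <- sg[within > 1]
    warning("SG atom(s) within cutoff of more than one partner (atom index ",
            paste(amb, collapse = ", "), "); using nearest-partner pairing")
  }
  ord <- order(D[cand])
  cand <- cand[ord, , drop = FALSE]
  used <- logical(length(sg))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    pairs[[length(pairs) + 1]] <- c(sg[i], sg[j])
  }
  rows <- lapply(pairs, function(p) .bondRow(s, p[1], p[2]))
  out <- do.call(rbind, rows)
  out <- out[order(out$res1, out$res2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyBondTable <- function() {
  data.frame(label = character(0), res1 = integer(0), res2 = integer(0),
             chain1 = character(0), chain2 = character(0),
             sg1 = integer(0), sg2 = integer(0), ca1 = integer(0),
             ca2 = integer(0), cb1 = integer(0), cb2 = integer(0),
             stringsAsFactors = FALSE)
}

.residueAtom <- function(s, chain, resno, name) {
  a <- s@atoms
  i <- which(a$chain == chain & a$resno == resno & a$name == name)
  if (length(i) == 0) NA_integer_ else i[1]
}

.bondRow <- function(s, sgA, sgB) {
  a <- s@atoms
  # lower residue number first (ties broken by chain) for a stable label
  if (a$resno[sgB] < a$resno[sgA] ||
      (a$resno[sgB] == a$resno[sgA] && a$chain[sgB] < a$chain[sgA])) {
    tmp <- sgA; sgA <- sgB; sgB <- tmp
  }
  r1 <- a$resno[sgA]; r2 <- a$resno[sgB]
  c1 <- a$chain[sgA]; c2 <- a$chain[sgB]
  data.frame(
    label = paste0("Cys", r1, "-Cys", r2),
    res1 = r1, res2 = r2, chain1 = c1, chain2 = c2,
    sg1 = sgA, sg2 = sgB,
    ca1 = .residueAtom(s, c1, r1, "CA"), ca2 = .residueAtom(s, c2, r2, "CA"),
    cb1 = .residueAtom(s, c1, r1, "CB"), cb2 = .residueAtom(s, c2, r2, "CB"),
    stringsAsFactors = FALSE)
}

#' Select reducing-probe molecules by residue name
#'
#' Groups atoms into probe molecules by (chain, residue id, residue name).
#' The probe kind is inferred from the residue names (TCEP/DTT synonyms),
#' otherwise \code{"custom"}.
#'
#' @param s a \code{MolecularStructure}.
#' @param residueNames residue names to select
#'   (default all TCEP/DTT synonyms).
#' @return a \code{ProbeGroup}; empty when nothing matches.
#' @export
selectProbes <- function(s, residueNames = c(.TCEP_NAMES, .DTT_NAMES)) {
  a <- s@atoms
  hit <- which(a$resname %in% residueNames)
  if (length(hit) == 0) {
    return(new("ProbeGroup", kind = "custom", molecules = list()))
  }
  key <- paste(a$chain[hit], a$resno[hit], a$resname[hit], sep = "|")
  mols <- split(hit, factor(key, levels = unique(key)))
  names(mols) <- NULL
  seen <- unique(a$resname[hit])
  kind <- if (all(seen %in% .TCEP_NAMES)) "TCEP"
          else if (all(seen %in% .DTT_NAMES)) "DTT"
          else "custom"
  new("ProbeGroup", kind = kind, molecules = mols)
}
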