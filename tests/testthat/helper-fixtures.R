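# Shared fixture builders and independent oracles. Fixtures are built in
# code; no binary data.

# minimal structure from parallel vectors
makeStructure <- function(name, element, resname, resno, xyz, chain = "A",
                          box = NULL, mass = NULL) {
  df <- data.frame(name = name, element = element, resname = resname,
                   resno = resno, chain = chain, x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3], stringsAsFactors = FALSE)
  if (!is.null(mass)) df$mass <- mass
  molecularStructure(df, box = box)
}

# a cystine fragment (N/CA/CB/SG for two CYS residues) with ~ideal geometry,
# dihedral signs controlled by the z-offsets of the N atoms
makeCystine <- function() {
  xyz <- rbind(
    c(-0.35,  0.12,  0.08),  # N   res1
    c(-0.30,  0.05,  0.00),  # CA  res1
    c(-0.15,  0.00,  0.00),  # CB  res1
    c(-0.10, -0.10,  0.12),  # SG  res1
    c( 0.35,  0.25, -0.08),  # N   res2
    c( 0.30,  0.15,  0.00),  # CA  res2
    c( 0.15,  0.15,  0.05),  # CB  res2
    c( 0.05, -0.02,  0.15))  # SG  res2
  makeStructure(
    name = rep(c("N", "CA", "CB", "SG"), 2),
    element = rep(c("N", "C", "C", "S"), 2),
    resname = "CYS", resno = rep(1:2, each = 4), xyz = xyz)
}

# two-cysteine system with a chosen SG-SG distance
makeSgPair <- function(d, box = NULL) {
  xyz <- rbind(c(0.5, 0.5, 0.5), c(0.5 + d, 0.5, 0.5))
  makeStructure(name = c("SG", "SG"), element = c("S", "S"),
                resname = "CYS", resno = 1:2, xyz = xyz, box = box)
}

# 27-image brute-force distance oracle
bruteMinImageDistance <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    bb <- b + c(i, j, k) * box
    best <- min(best, sqrt(sum((a - bb)^2)))
  }
  best
}

# independent Gram-Schmidt dihedral oracle: project the two outer bonds
# onto the plane perpendicular to the central bond and measure the signed
# angle between the projections
gramSchmidtDihedral <- function(p1, p2, p3, p4) {
  b2 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u <- (p1 - p2) - sum((p1 - p2) * b2) * b2
  v <- (p4 - p3) - sum((p4 - p3) * b2) * b2
  u <- u / sqrt(sum(u * u)); v <- v / sqrt(sum(v * v))
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sum(cr * b2), sum(u * v)) * 180 / pi
}

# quaternion-based superposition RMSD oracle (Horn's method)
quaternionRmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  S <- t(Bc) %*% Ac
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lmax) / nrow(A)
  sqrt(max(msd, 0))
}

# random rigid transform of an (n x 3) coordinate set
randomRigidTransform <- function(X) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
  X %*% t(R) + matrix(rnorm(3), nrow(X), 3, byrow = TRUE)
}

# a protein-plus-probes trajectory built frame by frame from explicit probe
# positions (list of (nProbes x 3) matrices); protein static
makeProbeTrajectory <- function(protein, probePositions, box,
                                probeKind = "TCEP", frameInterval = 1) {
  np <- nrow(probePositions[[1]])
  probeAtoms <- data.frame(
    name = "C1", element = "C", mass = 250.19, resname = probeKind,
    resno = max(protein@atoms$resno) + seq_len(np), chain = "P",
    x = probePositions[[1]][, 1], y = probePositions[[1]][, 2],
    z = probePositions[[1]][, 3], stringsAsFactors = FALSE)
  pa <- protein@atoms
  pa$mass <- protein@atoms$mass
  topo <- molecularStructure(rbind(pa, probeAtoms), box = box)
  P <- coords(protein)
  frames <- lapply(probePositions, function(pp) rbind(P, pp))
  trajectory(topo, frames,
             times = (seq_along(frames) - 1) * frameInterval)
}

# strained four-membered ring whose cleavage relieves angle strain
makeStrainedRing <- function() {
  makeStructure(
    name = c("C1", "SG", "SG", "C2"), element = c("C", "S", "S", "C"),
    resname = "CYS", resno = c(1, 1, 2, 2),
    xyz = rbind(c(0, 0, 0), c(0.181, 0, 0), c(0.181, 0.204, 0),
                c(0, 0.153, 0)))
}
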