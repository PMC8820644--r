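# Simplified potential, steepest-descent minimiser, disulfide cleavage and
# the E_fin < E_in acceptance logic.

# two carbons far enough apart not to bond covalently
.ljDimer <- function(r) {
  makeStructure(name = c("C1", "C2"), element = c("C", "C"),
                resname = "LIG", resno = 1:2,
                xyz = rbind(c(0, 0, 0), c(r, 0, 0)))
}

test_that("LJ dimer at its minimum has pair energy -epsilon", {
  ff <- defaultForceField()
  sig <- ff@ljTable$sigma[ff@ljTable$element == "C"]
  eps <- ff@ljTable$epsilon[ff@ljTable$element == "C"]
  e <- potentialEnergy(.ljDimer(2^(1 / 6) * sig), ff)
  expect_equal(e$lj, -eps, tolerance = 1e-12)
  expect_equal(e$bonds, 0)
  expect_equal(e$total, e$lj)
})

test_that("harmonic bond at its equilibrium length contributes zero", {
  s <- makeStructure(name = c("C1", "C2"), element = c("C", "C"),
                     resname = "LIG", resno = 1:2,
                     xyz = rbind(c(0, 0, 0), c(0.153, 0, 0)))
  e <- potentialEnergy(s)
  expect_equal(e$bonds, 0, tolerance = 1e-12)
  expect_equal(e$lj, 0)  # 1-2 pairs are excluded from nonbonded terms
})

test_that("a 5-atom toy matches a term-by-term hand sum", {
  # methanethiol-like: C bonded to S and 2 H, S bonded to H
  xyz <- rbind(c(0, 0, 0),          # C
               c(0.181, 0, 0),      # S
               c(0.181 + 0.04, 0.128, 0),  # HS
               c(-0.04, 0.10, 0),   # H1
               c(-0.04, -0.10, 0))  # H2
  s <- makeStructure(name = c("C", "S", "HS", "H1", "H2"),
                     element = c("C", "S", "H", "H", "H"),
                     resname = "LIG", resno = 1, xyz = xyz)
  ff <- defaultForceField()
  topo <- buildTopology(s)
  e <- potentialEnergy(s, ff, topo)

  # independent hand sum
  bondE <- function(i, j, k, req) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2)); 0.5 * k * (r - req)^2
  }
  angE <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    0.5 * 420 * (th - 109.47 * pi / 180)^2
  }
  ljE <- function(i, j, si, sj, ei, ej) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sg <- (si + sj) / 2; ep <- sqrt(ei * ej)
    4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  handBonds <- bondE(1, 2, 220000, 0.181) + bondE(2, 3, 280000, 0.134) +
    bondE(1, 4, 300000, 0.109) + bondE(1, 5, 300000, 0.109)
  handAngles <- angE(1, 2, 3) +                  # C-S-HS
    angE(2, 1, 4) + angE(2, 1, 5) + angE(4, 1, 5)  # around C
  # nonbonded: only pairs separated by >2 bonds: HS-H1, HS-H2, H1 etc.
  # exclusions: 1-2 bonds and 1-3 (C..HS via S; S..H1,H2 via C; H1..H2 via C)
  handLJ <- ljE(3, 4, 0.24, 0.24, 0.066, 0.066) +
    ljE(3, 5, 0.24, 0.24, 0.066, 0.066)
  expect_equal(e$bonds, handBonds, tolerance = 1e-9)
  expect_equal(e$angles, handAngles, tolerance = 1e-9)
  expect_equal(e$lj, handLJ, tolerance = 1e-9)
  expect_equal(e$total, handBonds + handAngles + handLJ, tolerance = 1e-9)
})

test_that("the potential is invariant under rigid motion", {
  s <- makeCystine()
  topo <- buildTopology(s)
  e0 <- potentialEnergy(s, topology = topo)$total
  set.seed(5)
  for (i in 1:5) {
    s2 <- setCoords(s, randomRigidTransform(coords(s)))
    e1 <- potentialEnergy(s2, topology = topo)$total
    expect_equal(e1, e0, tolerance = 1e-8 * max(1, abs(e0)))
  }
})

test_that("missing parameters raise errors naming the offender", {
  s <- makeStructure(name = c("FE", "C1"), element = c("FE", "C"),
                     resname = "LIG", resno = 1:2,
                     xyz = rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_error(potentialEnergy(s), "FE|LJ")
})

test_that("steepest descent relaxes a stretched bond to equilibrium", {
  s <- makeStructure(name = c("C1", "C2"), element = c("C", "C"),
                     resname = "LIG", resno = 1:2,
                     xyz = rbind(c(0, 0, 0), c(0.173, 0, 0)))
  res <- steepestDescent(s, fmaxTol = 1)
  expect_true(res$converged)
  r <- sqrt(sum((coords(res$finalStructure)[1, ] -
                   coords(res$finalStructure)[2, ])^2))
  expect_equal(r, 0.153, tolerance = 1e-4)
  expect_lt(res$energy, 1e-5)
  expect_true(all(diff(res$trace) <= 0))
  expect_lt(res$maxForce, 1)
})

test_that("a system already at its minimum converges in zero steps", {
  ff <- defaultForceField()
  sig <- ff@ljTable$sigma[ff@ljTable$element == "C"]
  res <- steepestDescent(.ljDimer(2^(1 / 6) * sig), ff)
  expect_true(res$converged)
  expect_equal(res$nSteps, 0L)
})

test_that("an LJ dimer minimises to the closed-form separation", {
  ff <- defaultForceField()
  sig <- ff@ljTable$sigma[ff@ljTable$element == "C"]
  res <- steepestDescent(.ljDimer(1.5 * sig), ff, fmaxTol = 0.5,
                         maxSteps = 2000)
  r <- sqrt(sum((coords(res$finalStructure)[1, ] -
                   coords(res$finalStructure)[2, ])^2))
  expect_equal(r, 2^(1 / 6) * sig, tolerance = 1e-3)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("disulfide cleavage caps both sulfurs and cannot run twice", {
  s <- makeCystine()
  bond <- detectDisulfides(s)[1, ]
  red <- reduceDisulfide(s, bond)
  expect_equal(nAtoms(red), nAtoms(s) + 2)
  xyz <- coords(red)
  h <- (nAtoms(s) + 1):(nAtoms(s) + 2)
  d1 <- sqrt(sum((xyz[bond$sg1, ] - xyz[h[1], ])^2))
  d2 <- sqrt(sum((xyz[bond$sg2, ] - xyz[h[2], ])^2))
  expect_equal(d1, 0.134, tolerance = 1e-6)
  expect_equal(d2, 0.134, tolerance = 1e-6)
  # caps point outward: each H is farther from the partner sulfur
  expect_gt(sqrt(sum((xyz[bond$sg2, ] - xyz[h[1], ])^2)), d1)
  # the original atoms are untouched
  expect_equal(xyz[seq_len(nAtoms(s)), ], coords(s), ignore_attr = TRUE)
  expect_error(reduceDisulfide(red, bond), "already been reduced")
  # the broken bond is gone from the inferred topology
  topo <- buildTopology(red)
  key <- paste(topo$bonds[, 1], topo$bonds[, 2])
  expect_false(paste(min(bond$sg1, bond$sg2),
                     max(bond$sg1, bond$sg2)) %in% key)
})

test_that("cleaving a strained ring is energetically accepted", {
  ring <- makeStrainedRing()
  bond <- detectDisulfides(ring)[1, ]
  chk <- energyCheck(ring, bond)
  expect_true(chk$accepted)
  expect_lt(chk$Efin, chk$Ein)
  # purity: identical result on rerun
  chk2 <- energyCheck(ring, bond)
  expect_identical(chk, chk2)
})

test_that("the acceptance inequality is strict and backend-injectable", {
  ring <- makeStrainedRing()
  bond <- detectDisulfides(ring)[1, ]
  equalBackend <- function(intact, reduced, ff, minCfg) {
    list(Ein = 5, Efin = 5)
  }
  expect_false(energyCheck(ring, bond, backend = equalBackend)$accepted)
  worseBackend <- function(intact, reduced, ff, minCfg) {
    list(Ein = 5, Efin = 6)
  }
  expect_false(energyCheck(ring, bond, backend = worseBackend)$accepted)
  expect_true(energyCheck(ring, bond,
                          backend = alwaysAcceptBackend)$accepted)
})

# a two-bond protein with probes steered frame by frame
.twoEventTrajectory <- function() {
  protein <- buildToyProtein(
    toyProteinSpec(disulfides = list(list(exposure = "surface"),
                                     list(exposure = "surface"))),
    seed = 8)
  box <- c(7.9, 7.9, 7.9)
  protein <- setCoords(protein, sweep(coords(protein), 2, box / 2, "+"))
  bonds <- detectDisulfides(protein)
  masses <- protein@atoms$mass
  com <- function(i) massWeightedCom(coords(protein),
                                     c(bonds$sg1[i], bonds$sg2[i]),
                                     masses, box)
  outward <- function(i) {
    v <- com(i) - box / 2; v / sqrt(sum(v^2))
  }
  # frame 1: probe 1 touches bond 1; frame 2: probe 2 touches bond 2
  frames <- list(
    rbind(com(1) + 0.6 * outward(1), com(2) + 2.0 * outward(2)),
    rbind(com(1) + 2.0 * outward(1), com(2) + 0.6 * outward(2)))
  list(traj = makeProbeTrajectory(protein, frames, box = box),
       bonds = bonds)
}

test_that("with an always-accepting backend the two criteria agree", {
  fx <- .twoEventTrajectory()
  bonds <- detectDisulfides(fx$traj@topology)
  probes <- selectProbes(fx$traj@topology)
  d <- scanDistanceCriterion(fx$traj, bonds, probes, proximityConfig())
  de <- scanDistanceEnergyCriterion(fx$traj, bonds, probes,
                                    proximityConfig(),
                                    backend = alwaysAcceptBackend)
  expect_equal(de$calledBond, d$calledBond)
  expect_equal(de$event$frameIndex, d$event$frameIndex)
  expect_equal(de$event$distance, d$event$distance)
  expect_equal(de$energyChecksFailed, 0L)
})

test_that("a failed check defers the call to a later passing event", {
  fx <- .twoEventTrajectory()
  bonds <- detectDisulfides(fx$traj@topology)
  probes <- selectProbes(fx$traj@topology)
  firstLabel <- bonds$label[1]
  # reject any check whose cleaved bond belongs to the first bond's
  # residues (the caps carry the cysteine resno)
  pickyBackend <- function(intact, reduced, ff, minCfg) {
    capResno <- utils::tail(reduced@atoms$resno, 2)
    target <- detectDisulfides(intact)
    first <- target$label == firstLabel &
      all(capResno %in% c(target$res1[target$label == firstLabel],
                          target$res2[target$label == firstLabel]))
    if (any(first)) list(Ein = 1, Efin = 2) else list(Ein = 2, Efin = 1)
  }
  call <- scanDistanceEnergyCriterion(fx$traj, bonds, probes,
                                      proximityConfig(),
                                      backend = pickyBackend)
  expect_equal(call$calledBond, bonds$label[2])
  expect_equal(call$event$frameIndex, 2)
  expect_equal(call$energyChecksFailed, 1L)
})

test_that("when every event fails the scan reports all failed checks", {
  fx <- .twoEventTrajectory()
  bonds <- detectDisulfides(fx$traj@topology)
  probes <- selectProbes(fx$traj@topology)
  rejectAll <- function(intact, reduced, ff, minCfg) {
    list(Ein = 1, Efin = 2)
  }
  call <- scanDistanceEnergyCriterion(fx$traj, bonds, probes,
                                      proximityConfig(),
                                      backend = rejectAll)
  expect_true(is.na(call$calledBond))
  expect_equal(call$energyChecksFailed, 2L)
})
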