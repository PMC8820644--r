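# Rg, superposition RMSD, hydrogen-bond counting, Daura clustering,
# representative frames and per-residue deviation maps.

test_that("radius of gyration matches symmetry cases", {
  expect_equal(radiusOfGyration(matrix(c(1, 2, 3), 1), masses = 5), 0)
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(radiusOfGyration(two, masses = c(3, 3)), 0.5)
  # unequal masses shift the COM but Rg still follows the definition
  m <- c(1, 3)
  com <- 3 / 4
  expect_equal(radiusOfGyration(two, masses = m),
               sqrt((1 * com^2 + 3 * (1 - com)^2) / 4))
  expect_error(radiusOfGyration(two, masses = c(0, 0)), "zero total mass")
})

test_that("RMSD is zero for identical and rigidly moved frames", {
  set.seed(31)
  A <- matrix(rnorm(60), 20, 3)
  expect_equal(backboneRmsd(A, A), 0, tolerance = 1e-12)
  B <- randomRigidTransform(A)
  expect_lt(backboneRmsd(A, B), 1e-9)
  expect_equal(backboneRmsd(A, B), backboneRmsd(B, A), tolerance = 1e-9)
  expect_error(backboneRmsd(A, B[1:10, ], selection = 1:20),
               "sizes differ|subscript")
})

test_that("RMSD agrees with a quaternion-method oracle", {
  set.seed(37)
  for (i in 1:20) {
    A <- matrix(rnorm(45), 15, 3)
    B <- A + matrix(rnorm(45, sd = 0.1), 15, 3)
    expect_equal(backboneRmsd(A, B), quaternionRmsd(A, B),
                 tolerance = 1e-9)
  }
  # single displaced atom in an otherwise rigid set
  A <- matrix(rnorm(300), 100, 3)
  B <- A; B[1, ] <- B[1, ] + c(0.3, 0, 0)
  expect_equal(backboneRmsd(A, B), quaternionRmsd(A, B), tolerance = 1e-9)
})

.hbFixture <- function(bendDeg = 0, dNO = 0.29) {
  # donor N with its H, acceptor O; bend rotates the acceptor away from
  # the N-H axis while keeping the N-O distance
  th <- bendDeg * pi / 180
  xyz <- rbind(c(0, 0, 0),                       # N
               c(0.101, 0, 0),                   # H on N
               c(dNO * cos(th), dNO * sin(th), 0))  # O
  makeStructure(name = c("N", "H", "O"), element = c("N", "H", "O"),
                resname = "GLY", resno = 1, xyz = xyz)
}

test_that("hydrogen bonds follow the distance-angle criterion", {
  lin <- .hbFixture(0)
  expect_equal(hydrogenBondCount(coords(lin), donors = 1L, hydrogens = 2L,
                                 acceptors = c(1L, 3L)), 1L)
  bent <- .hbFixture(45)
  expect_equal(hydrogenBondCount(coords(bent), donors = 1L,
                                 hydrogens = 2L, acceptors = c(1L, 3L)), 0L)
  far <- .hbFixture(0, dNO = 0.4)
  expect_equal(hydrogenBondCount(coords(far), donors = 1L, hydrogens = 2L,
                                 acceptors = c(1L, 3L)), 0L)
})

test_that("hydrogen-bond counts match a triple-loop brute force", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 12
    xyz <- matrix(runif(3 * n, max = 0.9), n, 3)
    donors <- 1:4
    hydrogens <- 5:8
    acceptors <- 9:12
    mine <- hydrogenBondCount(xyz, donors, hydrogens, acceptors)
    brute <- 0L
    for (k in seq_along(donors)) {
      for (a in acceptors) {
        if (a == donors[k]) next
        dDA <- sqrt(sum((xyz[donors[k], ] - xyz[a, ])^2))
        if (dDA > 0.35) next
        u <- xyz[hydrogens[k], ] - xyz[donors[k], ]
        v <- xyz[a, ] - xyz[donors[k], ]
        ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
        if (ang <= 30) brute <- brute + 1L
      }
    }
    expect_equal(mine, brute)
  }
})

test_that("donor/acceptor discovery finds covalent D-H pairs", {
  s <- .hbFixture(0)
  hb <- hydrogenBondParticipants(s)
  expect_equal(hb$donors, 1L)
  expect_equal(hb$hydrogens, 2L)
  expect_setequal(hb$acceptors, c(1L, 3L))
})

# a rigid backbone triangle wrapped in a trajectory, with a deformed state
.twoStateTrajectory <- function(nA, nB, jitter = 0.001, seed = 51) {
  set.seed(seed)
  base <- makeStructure(
    name = rep(c("N", "CA", "C"), 4), element = rep(c("N", "C", "C"), 4),
    resname = "ALA", resno = rep(1:4, each = 3),
    xyz = matrix(rnorm(36, sd = 0.4), 12, 3))
  alt <- coords(base)
  alt[1:6, ] <- alt[1:6, ] + 0.5  # displaced sub-block: a distinct state
  frames <- c(
    lapply(seq_len(nA), function(i) {
      randomRigidTransform(coords(base)) + rnorm(36, sd = jitter)
    }),
    lapply(seq_len(nB), function(i) {
      randomRigidTransform(alt) + rnorm(36, sd = jitter)
    }))
  ord <- sample(length(frames))
  list(traj = trajectory(base, frames[ord]),
       stateA = which(ord <= nA))
}

test_that("identical frames collapse into a single cluster", {
  fx <- .twoStateTrajectory(6, 0, jitter = 0)
  res <- dauraCluster(fx$traj)
  expect_equal(length(res$clusterSizes), 1)
  expect_equal(res$clusterSizes, 6)
  expect_true(all(res$assignments == 1))
})

test_that("two well-separated conformers give two clusters", {
  fx <- .twoStateTrajectory(5, 3, jitter = 0)
  res <- dauraCluster(fx$traj, cutoff = 0.2)
  expect_equal(length(res$clusterSizes), 2)
  expect_equal(res$clusterSizes, c(5, 3))
  expect_true(all(diff(res$clusterSizes) <= 0))
  # members of the designed majority state share a cluster
  expect_equal(length(unique(res$assignments[fx$stateA])), 1)
})

test_that("clustering matches a brute-force neighbour-count oracle", {
  set.seed(61)
  base <- makeStructure(
    name = rep(c("N", "CA", "C"), 3), element = rep(c("N", "C", "C"), 3),
    resname = "ALA", resno = rep(1:3, each = 3),
    xyz = matrix(rnorm(27, sd = 0.3), 9, 3))
  frames <- lapply(1:30, function(i) {
    coords(base) + matrix(rnorm(27, sd = 0.08), 9, 3)
  })
  traj <- trajectory(base, frames)
  cutoff <- 0.12
  res <- dauraCluster(traj, cutoff = cutoff)

  # independent re-implementation
  n <- 30
  M <- matrix(0, n, n)
  sel <- which(base@atoms$name %in% c("N", "CA", "C"))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- quaternionRmsd(frames[[i]][sel, ],
                                         frames[[j]][sel, ])
  }
  nbr <- M < cutoff; diag(nbr) <- TRUE
  remaining <- rep(TRUE, n)
  assign2 <- integer(n); cl <- 0
  while (any(remaining)) {
    cl <- cl + 1
    cnt <- vapply(1:n, function(k) {
      if (!remaining[k]) -1L else sum(nbr[k, ] & remaining)
    }, integer(1))
    centre <- which.max(cnt)
    mem <- which(nbr[centre, ] & remaining)
    assign2[mem] <- cl
    remaining[mem] <- FALSE
  }
  expect_equal(res$assignments, assign2)
  expect_equal(sum(res$clusterSizes), 30)
})

test_that("the representative frame comes from the dominant state", {
  fx <- .twoStateTrajectory(16, 4)
  rep <- representativeFrame(fx$traj, discardPs = 0)
  expect_true(rep %in% fx$stateA)
  # discarding also discards candidate frames
  expect_error(representativeFrame(fx$traj, discardPs = 1e6),
               "not shorter")
})

test_that("the discard window excludes early frames", {
  fx <- .twoStateTrajectory(10, 5)
  rep <- representativeFrame(fx$traj, discardPs = 4)
  expect_gte(rep, 5)
})

test_that("time series are rigid-motion invariant frame by frame", {
  s <- buildToyProtein(
    toyProteinSpec(disulfides = list(list(exposure = "surface"))),
    seed = 71)
  set.seed(71)
  f1 <- coords(s)
  f2 <- randomRigidTransform(f1)
  traj <- trajectory(s, list(f1, f2))
  ts <- trajectoryTimeSeries(traj, sasaPoints = 60L, hbond = FALSE)
  expect_equal(ts$rg[1], ts$rg[2], tolerance = 1e-9)
  # SASA invariance holds only to quadrature resolution (fixed point grid)
  expect_equal(ts$sasa[1], ts$sasa[2], tolerance = 5e-3)
  expect_lt(ts$rmsd[2], 1e-9)
  expect_equal(nrow(ts), 2)
})

.hingeFixture <- function() {
  # a large static domain and a small domain rotating about the origin;
  # the asymmetry makes the whole-structure fit anchor on the static part
  set.seed(81)
  nA <- 20; nB <- 6
  xyzA <- cbind(runif(nA, -0.9, -0.2), runif(nA, 0, 0.5),
                runif(nA, 0, 0.5))
  xyzB <- cbind(runif(nB, 0.3, 0.7), runif(nB, 0, 0.4),
                runif(nB, 0, 0.4))
  mk <- function(xyz2) {
    makeStructure(name = rep("CA", nA + nB), element = "C",
                  resname = "ALA", resno = seq_len(nA + nB),
                  xyz = rbind(xyzA, xyz2))
  }
  th <- 60 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  list(a = mk(xyzB), b = mk(xyzB %*% R), nA = nA, nB = nB)
}

test_that("identical structures give an all-zero deviation map", {
  fx <- .hingeFixture()
  dev <- perResidueDeviation(fx$a, fx$a)
  expect_true(all(dev$deviation < 1e-12))
  expect_equal(nrow(dev), fx$nA + fx$nB)
})

test_that("a hinge rotation is localised by per-domain alignment", {
  fx <- .hingeFixture()
  domains <- list(c(1, fx$nA), c(fx$nA + 1, fx$nA + fx$nB))
  byDomain <- perResidueDeviation(fx$a, fx$b, mode = "per_domain",
                                  domains = domains)
  expect_true(all(byDomain$deviation < 1e-9))
  whole <- perResidueDeviation(fx$a, fx$b, mode = "whole")
  moved <- whole$deviation[(fx$nA + 1):(fx$nA + fx$nB)]
  still <- whole$deviation[1:fx$nA]
  expect_gt(mean(moved), mean(still))
  expect_gt(max(moved), 0.1)
})

test_that("mismatched residue sequences are rejected", {
  fx <- .hingeFixture()
  b2 <- fx$b
  b2@atoms$resname[1] <- "GLY"
  expect_error(perResidueDeviation(fx$a, b2), "do not match")
})
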