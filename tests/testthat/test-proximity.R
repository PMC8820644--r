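# Switching function, coordination numbers, per-frame distance statistics,
# the distance criterion and lability aggregation.

test_that("switching function reproduces its closed forms", {
  p <- switchingParams(r0 = 3, n = 6, m = 12)
  expect_equal(switchingValue(0, p), 1)
  expect_equal(switchingValue(3, p), 0.5)            # limit n/m at r0
  expect_equal(switchingValue(6, p), 63 / 4095, tolerance = 1e-12)
})

test_that("switching function is continuous at r0 and monotone", {
  p <- switchingParams(r0 = 2, n = 6, m = 12)
  eps <- 1e-7
  expect_equal(switchingValue(2 - eps, p), 0.5, tolerance = 1e-5)
  expect_equal(switchingValue(2 + eps, p), 0.5, tolerance = 1e-5)
  grid <- switchingValue(seq(0, 10, by = 0.005), p)
  expect_true(all(diff(grid) <= 1e-12))
  expect_true(all(grid >= 0 & grid <= 1))
  expect_error(switchingParams(n = 12, m = 6), "n < m")
})

test_that("coordination number equals the pairwise brute-force sum", {
  p <- switchingParams(r0 = 1.5, n = 6, m = 12)
  one <- coordinationNumber(c(0, 0, 0), c(1.5, 0, 0), p)
  expect_equal(one, 0.5)
  far <- coordinationNumber(c(0, 0, 0), c(40, 0, 0), p, box = NULL)
  expect_lt(far, 1e-8)
  set.seed(11)
  A <- matrix(runif(9, max = 4), 3, 3)
  B <- matrix(runif(6, max = 4), 2, 3)
  box <- c(4, 4, 4)
  brute <- 0
  for (i in 1:3) for (j in 1:2) {
    brute <- brute + switchingValue(
      bruteMinImageDistance(A[i, ], B[j, ], box), p)
  }
  expect_equal(coordinationNumber(A, B, p, box), brute, tolerance = 1e-12)
  expect_error(coordinationNumber(matrix(numeric(0), ncol = 3), B, p),
               "non-empty")
})

# one bond at the box centre, probes placed explicitly per frame
.fixedProbeSetup <- function(probeOffsets, box = c(6, 6, 6)) {
  protein <- makeSgPair(0.205)
  com <- massWeightedCom(coords(protein), 1:2, protein@atoms$mass)
  protein <- setCoords(protein,
                       sweep(coords(protein), 2, box / 2 - com, "+"))
  frames <- lapply(probeOffsets, function(off) {
    matrix(box / 2 + off, ncol = 3, byrow = TRUE)
  })
  traj <- makeProbeTrajectory(protein, frames, box = box)
  list(traj = traj, bonds = detectDisulfides(traj@topology),
       probes = selectProbes(traj@topology))
}

test_that("distance statistics match a constructed single-probe geometry", {
  # one probe exactly 0.5 nm from the bond COM, every frame
  fx <- .fixedProbeSetup(list(c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5)))
  st <- distanceStats(fx$traj, fx$bonds, fx$probes, proximityConfig())
  expect_equal(st$perFrame$meanDist, rep(0.5, 3), tolerance = 1e-9)
  expect_equal(st$perFrame$minDist, rep(0.5, 3), tolerance = 1e-9)
  expect_equal(st$perFrame$countWithin, rep(1L, 3), ignore_attr = TRUE)
  # probe outside the cutoff never counts
  fx2 <- .fixedProbeSetup(list(c(0.9, 0, 0)))
  st2 <- distanceStats(fx2$traj, fx2$bonds, fx2$probes, proximityConfig())
  expect_equal(st2$perFrame$countWithin, 0L, ignore_attr = TRUE)
  expect_true(all(st$perFrame$minDist <= st$perFrame$meanDist + 1e-12))
  med <- st$summary[st$summary$statistic == "countWithin", "median"]
  expect_equal(med, 1)
})

test_that("hard counts agree with brute-force pair enumeration", {
  set.seed(21)
  protein <- buildToyProtein(seed = 4)
  box <- c(7.9, 7.9, 7.9)
  protein <- setCoords(protein, sweep(coords(protein), 2, box / 2, "+"))
  frames <- lapply(1:3, function(i) matrix(runif(30, max = 7.9), 10, 3))
  traj <- makeProbeTrajectory(protein, frames, box = box)
  bonds <- detectDisulfides(traj@topology)
  probes <- selectProbes(traj@topology)
  cfg <- proximityConfig(contactCutoff = 2.0)
  st <- distanceStats(traj, bonds, probes, cfg)
  masses <- traj@topology@atoms$mass
  for (f in 1:3) {
    xyz <- frameCoords(traj, f)
    for (bi in seq_len(nrow(bonds))) {
      bcom <- massWeightedCom(xyz, c(bonds$sg1[bi], bonds$sg2[bi]),
                              masses, box)
      cnt <- 0
      for (m in probes@molecules) {
        pcom <- massWeightedCom(xyz, m, masses, box)
        if (bruteMinImageDistance(pcom, bcom, box) < 2.0) cnt <- cnt + 1
      }
      got <- st$perFrame[st$perFrame$frame == f &
                           st$perFrame$bond == bonds$label[bi], ]
      expect_equal(got$countWithin, cnt, ignore_attr = TRUE)
    }
  }
})

test_that("distance criterion is first-passage with documented tie-breaks", {
  # contact with the bond at frame 3 only
  fx <- .fixedProbeSetup(list(c(2, 0, 0), c(1.2, 0, 0), c(0.55, 0, 0)))
  call <- scanDistanceCriterion(fx$traj, fx$bonds, fx$probes,
                                proximityConfig())
  expect_equal(call$calledBond, fx$bonds$label[1])
  expect_equal(call$event$frameIndex, 3)
  # no contact ever: no call
  none <- .fixedProbeSetup(list(c(2, 0, 0), c(1.5, 0, 0)))
  c2 <- scanDistanceCriterion(none$traj, none$bonds, none$probes,
                              proximityConfig())
  expect_true(is.na(c2$calledBond))
  expect_null(c2$event)
})

test_that("simultaneous contacts resolve by smallest distance then bond order", {
  # two bonds; in one frame probe 1 is at 0.79 nm from bond A and probe 2
  # at 0.60 nm from bond B: B wins on distance
  protein <- buildToyProtein(
    toyProteinSpec(disulfides = list(list(exposure = "surface"),
                                     list(exposure = "surface"))),
    seed = 5)
  box <- c(7.9, 7.9, 7.9)
  protein <- setCoords(protein, sweep(coords(protein), 2, box / 2, "+"))
  bonds <- detectDisulfides(protein)
  masses <- protein@atoms$mass
  comA <- massWeightedCom(coords(protein),
                          c(bonds$sg1[1], bonds$sg2[1]), masses, box)
  comB <- massWeightedCom(coords(protein),
                          c(bonds$sg1[2], bonds$sg2[2]), masses, box)
  outA <- comA - box / 2; outA <- outA / sqrt(sum(outA^2))
  outB <- comB - box / 2; outB <- outB / sqrt(sum(outB^2))
  frames <- list(rbind(comA + 0.79 * outA, comB + 0.60 * outB))
  traj <- makeProbeTrajectory(protein, frames, box = box)
  call <- scanDistanceCriterion(traj, detectDisulfides(traj@topology),
                                selectProbes(traj@topology),
                                proximityConfig())
  expect_equal(call$calledBond, bonds$label[2])
  expect_equal(call$event$probeIndex, 2)
  expect_equal(call$event$distance, 0.6, tolerance = 1e-6)
})

test_that("the scan equals an exhaustive oracle and ignores probe order", {
  set.seed(31)
  protein <- buildToyProtein(seed = 6)
  box <- c(7.9, 7.9, 7.9)
  cfg <- simulatorConfig(nFrames = 200, nProbes = 30, seed = 99,
                         startExclusion = 1.1)
  traj <- simulateProbeDiffusion(protein, cfg)
  bonds <- detectDisulfides(traj@topology)
  probes <- selectProbes(traj@topology)
  pcfg <- proximityConfig(contactCutoff = 1.0)
  call <- scanDistanceCriterion(traj, bonds, probes, pcfg)

  # exhaustive frame x bond x probe oracle
  masses <- traj@topology@atoms$mass
  oracle <- NULL
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    best <- NULL
    for (bi in seq_len(nrow(bonds))) {
      bcom <- massWeightedCom(xyz, c(bonds$sg1[bi], bonds$sg2[bi]),
                              masses, box)
      for (pi in seq_along(probes@molecules)) {
        pcom <- massWeightedCom(xyz, probes@molecules[[pi]], masses, box)
        d <- bruteMinImageDistance(pcom, bcom, box)
        if (d < 1.0 && (is.null(best) || d < best$d)) {
          best <- list(bond = bonds$label[bi], d = d, frame = f)
        }
      }
    }
    if (!is.null(best)) { oracle <- best; break }
  }
  expect_false(is.null(oracle))
  expect_equal(call$calledBond, oracle$bond)
  expect_equal(call$event$frameIndex, oracle$frame)
  expect_equal(call$event$distance, oracle$d, tolerance = 1e-9)

  # probe order must not matter: reverse the probe molecule list
  probesRev <- probes
  probesRev@molecules <- rev(probes@molecules)
  callRev <- scanDistanceCriterion(traj, bonds, probesRev, pcfg)
  expect_equal(callRev$calledBond, call$calledBond)
  expect_equal(callRev$event$frameIndex, call$event$frameIndex)
  expect_equal(callRev$event$distance, call$event$distance)
})

test_that("lability aggregation is simple proportion arithmetic", {
  mk <- function(bond, id) {
    structure(list(trajectoryId = id, calledBond = bond,
                   criterion = "distance",
                   event = if (is.na(bond)) NULL else list(frameIndex = 1),
                   energyChecksFailed = 0L), class = "TrajectoryCall")
  }
  calls <- c(lapply(1:14, function(i) mk("A", i)),
             lapply(15:20, function(i) mk(NA_character_, i)))
  rep <- aggregateLability(calls)
  expect_equal(unname(rep@probabilities["A"]), 0.7)
  expect_equal(rep@noCallFraction, 0.3)

  calls2 <- c(lapply(1:10, function(i) mk("A", i)),
              lapply(11:15, function(i) mk("B", i)),
              lapply(16:20, function(i) mk(NA_character_, i)))
  rep2 <- aggregateLability(calls2)
  expect_equal(unname(rep2@probabilities[c("A", "B")]), c(0.5, 0.25))
  expect_equal(rep2@noCallFraction, 0.25)
  expect_equal(sum(rep2@probabilities) + rep2@noCallFraction, 1)

  allNone <- lapply(1:5, function(i) mk(NA_character_, i))
  rep3 <- aggregateLability(allNone, bondLabels = c("A", "B"))
  expect_equal(unname(rep3@probabilities), c(0, 0))
  expect_equal(rep3@noCallFraction, 1)

  # permutation invariance over trajectory order
  set.seed(3)
  rep4 <- aggregateLability(sample(calls2))
  expect_equal(sort(rep4@probabilities), sort(rep2@probabilities))

  bad <- calls2
  bad[[1]]$criterion <- "distance_energy"
  expect_error(aggregateLability(bad), "mixed criteria")
})
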