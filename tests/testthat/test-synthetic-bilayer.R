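test_that("generation is bitwise deterministic given the seed", {
  tr <- syntheticTruth(nPopc = 8, nXan = 1, nWater = 10, seed = 42)
  g1 <- generateBilayer(tr, duration = 40)
  g2 <- generateBilayer(tr, duration = 40)
  expect_identical(g1$trajectory@coords, g2$trajectory@coords)
  expect_identical(g1$truth$bondingOn, g2$truth$bondingOn)
  g3 <- generateBilayer(syntheticTruth(nPopc = 8, nXan = 1, nWater = 10,
                                       seed = 43), duration = 40)
  expect_false(identical(g1$trajectory@coords, g3$trajectory@coords))
  bm1 <- generateEventMatrix(5, 0.01, 0.01, 100, seed = 7)
  bm2 <- generateEventMatrix(5, 0.01, 0.01, 100, seed = 7)
  expect_identical(eventMatrix(bm1), eventMatrix(bm2))
})

test_that("generated trajectories validate and round-trip through GRO", {
  tr <- syntheticTruth(nPopc = 8, nXan = 2, nWater = 12, seed = 5)
  g <- generateBilayer(tr, duration = 10)
  expect_true(methods::validObject(g$trajectory))
  expect_identical(checkMoleculesWhole(g$trajectory), character(0))
  f <- tempfile(fileext = ".gro")
  writeTrajectory(g$trajectory, f)
  rt <- readTrajectory(f)
  expect_lt(max(abs(rt@coords - g$trajectory@coords)), 0.01)
  expect_identical(atoms(rt)$name, atoms(g$trajectory)$name)
})

test_that("frozen kinetics yield zero hopping transitions; off telegraph yields all-ones", {
  tr <- syntheticTruth(nPopc = 8, nXan = 2, nWater = 0,
                       epsRates = c(0, 0), seed = 10)
  g <- generateBilayer(tr, duration = 2000, spacing = 2)
  tor <- extractTorsions(g$trajectory, defaultClassMap(),
                         defaultTorsionSpecs()$eps)
  hop <- countHopping(tor, defaultTorsionStates("eps"))
  expect_equal(hop$total_transitions, 0L)
  bm <- generateEventMatrix(4, kOn = 0.01, kOff = 0, duration = 200,
                            seed = 2)
  expect_true(all(eventMatrix(bm)))
})

test_that("the bonding telegraph is recovered exactly by the contact detector", {
  cm <- defaultClassMap()
  tr <- syntheticTruth(nPopc = 16, nXan = 2, nWater = 30, seed = 3)
  g <- generateBilayer(tr, duration = 250)
  bem <- buildEventMatrix(g$trajectory, cm, "hbond", partners = "water")
  ev <- eventMatrix(bem)
  pairs <- pairInfo(bem)
  truth <- g$truth$bondingOn
  expect_equal(nrow(pairs), sum(colSums(truth) > 0))
  for (r in seq_len(nrow(pairs))) {
    col <- match(pairs$oh_id[r], colnames(truth))
    expect_identical(unname(ev[r, ]), unname(truth[, col]))
  }
})

test_that("telegraph stationary mean is recovered within 3 sigma by the summary", {
  cm <- defaultClassMap()
  p <- 0.3
  tr <- syntheticTruth(nPopc = 16, nXan = 4, nWater = 30,
                       bondingRates = c(0.003, 0.007), seed = 23)
  g <- generateBilayer(tr, duration = 4000)
  bem <- buildEventMatrix(g$trajectory, cm, "hbond", partners = "water")
  sm <- summarizeContacts(bem)
  m <- weighted.mean(sm$mean[sm$partner_class == "water"],
                     sm$n[sm$partner_class == "water"])
  # 8 chains decorrelating over 1/(kOn+kOff) = 100 ps
  neff <- 8 * 4000 / (2 * 100)
  expect_lt(abs(m - p), 3 * sqrt(p * (1 - p) / neff))
  # and the measured mean equals the realised truth exactly
  mids <- colnames(g$truth$bondingOn)
  got <- vapply(mids, function(id) {
    r <- which(pairInfo(bem)$oh_id == id)
    if (length(r)) mean(eventMatrix(bem)[r, ]) else 0
  }, numeric(1))
  expect_equal(unname(got), unname(colMeans(g$truth$bondingOn)))
})

test_that("infeasible geometry is rejected", {
  expect_error(syntheticTruth(rodLength = 90, box = 80), "fit")
  expect_error(syntheticTruth(nPopc = 7), "nPopc")
})

test_that("analytic reference curve fits recover the printed time constants", {
  ref <- referenceDecayParameters()
  p <- ref[ref$system == "LUT_V_eps", ]
  cur <- generateDecayCurve(as.numeric(p[c("A1", "A2", "A3", "A4")]),
                            as.numeric(p[c("T1", "T2", "T3", "T4")]),
                            C0 = 100, lag = 5000)
  ft <- fitMultiExp(cur)
  expect_equal(ft@T[2], p$T2, tolerance = 0.01)
  # single exponential shortcut
  cur1 <- generateDecayCurve(100, 10, C0 = 1, lag = 100)
  expect_equal(cur1@counts, exp(-cur1@lags / 10), tolerance = 1e-12)
})

test_that("end-to-end truth sweep: every prescribed quantity is recovered", {
  cm <- defaultClassMap()
  tr <- syntheticTruth(nPopc = 16, nXan = 2, nWater = 20,
                       betaRates = c(0.004, 0.008),
                       bondingRates = c(0.007, 0.003),
                       thetaMode = "ramp", thetaRate = 0.05, seed = 99)
  g <- generateBilayer(tr, duration = 3000)
  traj <- g$trajectory
  # torsion occupancy: stationary fraction of the +30 state = k21/(k12+k21)
  tor <- extractTorsions(traj, cm, defaultTorsionSpecs()$beta)
  st <- assignStates(tor$angle[tor$molecule_id == "LUT17"],
                     tor$time[tor$molecule_id == "LUT17"],
                     defaultTorsionStates("beta"))
  occTruth <- mean(g$truth$stateBeta[, 1] == 1L)
  occ <- sum(st$labels == "B30") / sum(st$labels != "unassigned")
  expect_lt(abs(occ - occTruth), 0.05)
  # transition count close to the realised chain's switch count
  sw <- sum(diff(g$truth$stateBeta[, 1]) != 0)
  expect_lt(abs(nrow(st$transitions) - sw) / sw, 0.25)
  # orientation: all vertical, no events
  o <- classifyAllOrientations(traj, cm, smoothing = 100)
  expect_true(all(o$perMolecule[["LUT17"]]$data$label == "V"))
  # contacts equal the telegraph truth (checked via means)
  bem <- buildEventMatrix(traj, cm, "hbond", partners = "water")
  expect_equal(mean(eventMatrix(bem)[pairInfo(bem)$oh_id == "LUT17:beta", ]),
               mean(g$truth$bondingOn[, "LUT17:beta"]))
  # theta ramp recovered
  th <- thetaRotation(traj, cm, o, stride = 100)
  th1 <- th[th$molecule_id == "LUT17", ]
  expect_equal(diff(th1$theta_unwrapped[c(1, nrow(th1))]),
               0.05 * 3000, tolerance = 1e-6)
  # structural scalars
  expect_equal(molecularLength(traj, cm)$mean, 28.3, tolerance = 1e-9)
  expect_lt(abs(hydrophobicWidth(traj, cm)$mean - 30.3), 0.1)
})
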