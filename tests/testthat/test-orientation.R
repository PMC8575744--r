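slabTrajectory <- function(nLip = 8, pZ = 20, ogZ = 15, noise = 0,
                           shift = 0, nFrames = 3, seed = 1) {
  set.seed(seed)
  top <- do.call(rbind, lapply(seq_len(nLip), function(i)
    data.frame(name = c("P", "O21", "O31", "O22", "O32"), resname = "POPC",
               resid = i)))
  nat <- nrow(top)
  co <- array(0, c(nat, 3L, nFrames))
  sg <- rep(c(1, -1), length.out = nLip)
  for (f in seq_len(nFrames)) {
    xyz <- matrix(runif(nat * 3, 0, 60), nat, 3)
    z0 <- rep(sg, each = 5) * c(pZ, ogZ, ogZ, ogZ + 0.15, ogZ + 0.15)
    xyz[, 3] <- z0 + rnorm(nat, 0, noise) + shift
    co[, , f] <- xyz
  }
  newTrajectory(top, co, c(60, 60, 90))
}

test_that("interface references recover constructed planes and translate covariantly", {
  cm <- defaultClassMap()
  tr <- slabTrajectory()
  ref <- interfaceReference(tr, cm)
  expect_equal(ref$p_upper, rep(20, 3))
  expect_equal(ref$p_lower, rep(-20, 3))
  expect_equal(ref$og_upper, rep(15, 3))
  expect_equal(ref$centre, rep(0, 3))
  ref2 <- interfaceReference(slabTrajectory(shift = 3), cm)
  expect_equal(ref2$p_upper, ref$p_upper + 3)
  expect_equal(ref2$centre, ref$centre + 3)
})

test_that("noisy interface references stay within the CLT bound", {
  cm <- defaultClassMap()
  nLip <- 100
  tr <- slabTrajectory(nLip = nLip, noise = 1, nFrames = 20, seed = 3)
  ref <- interfaceReference(tr, cm)
  # per-frame leaflet mean of nLip/2 P atoms: sd = 1/sqrt(50); time mean tighter
  expect_lt(abs(mean(ref$p_upper) - 20), 3 / sqrt(nLip / 2 * 20))
  expect_lt(abs(mean(ref$og_lower) + 15), 3 / sqrt(nLip * 20))
})

test_that("orientation labels follow the slab geometry", {
  ref <- data.frame(time = 0:99, p_upper = 20, p_lower = -20,
                    og_upper = 15, og_lower = -15, centre = 0)
  # vertical: rings in opposite slabs
  o <- classifyOrientation(rep(17, 100), rep(-17, 100), ref, smoothing = 5)
  expect_true(all(o$data$label == "V"))
  expect_equal(nrow(o$events), 0L)
  # horizontal: both rings in the same slab
  o2 <- classifyOrientation(rep(16, 100), rep(18, 100), ref, smoothing = 5)
  expect_true(all(o2$data$label == "H"))
  # H -> V ramp produces one event ending at ramp completion
  zb <- rep(16, 100)
  ze <- c(rep(16, 40), seq(16, -17, length.out = 20), rep(-17, 40))
  o3 <- classifyOrientation(zb, ze, ref, smoothing = 5)
  expect_equal(nrow(o3$events), 1L)
  expect_equal(o3$events$from, "H")
  expect_equal(o3$events$to, "V")
  expect_lt(abs(o3$events$end - 59), 5 + 1)
})

test_that("classification is invariant under z translation and mirror", {
  ref <- data.frame(time = 0:49, p_upper = 20, p_lower = -20,
                    og_upper = 15, og_lower = -15, centre = 0)
  set.seed(4)
  zb <- c(rep(17, 25), rep(16, 25)) + rnorm(50, 0, 0.3)
  ze <- c(rep(-17, 25), rep(18, 25)) + rnorm(50, 0, 0.3)
  o <- classifyOrientation(zb, ze, ref, smoothing = 3)
  sh <- 7
  refs <- ref; refs[, c("p_upper", "p_lower", "og_upper", "og_lower",
                        "centre")] <-
    refs[, c("p_upper", "p_lower", "og_upper", "og_lower", "centre")] + sh
  oT <- classifyOrientation(zb + sh, ze + sh, refs, smoothing = 3)
  expect_identical(oT$data$label, o$data$label)
  refm <- ref
  refm$p_upper <- 20; refm$p_lower <- -20  # symmetric refs: mirror swaps leaflets
  oM <- classifyOrientation(-zb, -ze, refm, smoothing = 3)
  expect_identical(oM$data$label, o$data$label)
})

test_that("scheduled reorientation is detected within smoothing plus stride", {
  cm <- defaultClassMap()
  set.seed(77)
  for (rep in 1:8) {
    flip <- sample(seq(1200, 2400, by = 100), 1)
    tr <- syntheticTruth(nPopc = 16, nXan = 1, nWater = 0,
                         orientation = "H", flipTime = flip,
                         transitDuration = 400, seed = 100 + rep)
    g <- generateBilayer(tr, duration = 3200, spacing = 2)
    o <- classifyAllOrientations(g$trajectory, cm, smoothing = 100)
    ev <- o$perMolecule[[1]]$events
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$to, "V")
    expect_lt(abs(ev$end - flip), 100 + 2)
  }
})

test_that("vertical molecules have opposite-signed ring z on nearly all V frames", {
  cm <- defaultClassMap()
  tr <- syntheticTruth(nPopc = 16, nXan = 2, nWater = 0, seed = 6)
  g <- generateBilayer(tr, duration = 400)
  o <- classifyAllOrientations(g$trajectory, cm, smoothing = 50)
  for (id in names(o$perMolecule)) {
    d <- o$perMolecule[[id]]$data
    v <- d$label == "V"
    frac <- mean(sign(d$z_beta[v] - o$ref$centre[v]) !=
                   sign(d$z_eps[v] - o$ref$centre[v]))
    expect_gte(frac, 0.99)
  }
})

test_that("plane orientation recovers the generator truth and mirrors correctly", {
  cm <- defaultClassMap()
  for (ps in c(1, -1)) for (leaf in c(1, -1)) {
    tr <- syntheticTruth(nPopc = 16, nXan = 1, nWater = 0,
                         orientation = "H", seed = 9)
    tr$xan$planeSign <- ps
    tr$xan$leaflet <- leaf
    g <- generateBilayer(tr, duration = 300)
    o <- classifyAllOrientations(g$trajectory, cm, smoothing = 50)
    po <- planeOrientation(g$trajectory, cm, o)
    expect_equal(po$label, g$truth$planeLabel[1])
    expect_equal(po$label, if (ps * leaf > 0) "beta_up" else "beta_down")
  }
  # calling on an all-vertical system is a usage error
  trV <- syntheticTruth(nPopc = 16, nXan = 1, nWater = 0, seed = 9)
  gV <- generateBilayer(trV, duration = 100)
  oV <- classifyAllOrientations(gV$trajectory, cm, smoothing = 50)
  expect_error(planeOrientation(gV$trajectory, cm, oV), "horizontal")
})

test_that("theta sweeps one full turn for a 10 degree-per-sample rotation and freezes when frozen", {
  cm <- defaultClassMap()
  tr <- syntheticTruth(nPopc = 8, nXan = 1, nWater = 0,
                       thetaMode = "ramp", thetaRate = 0.1, seed = 12)
  g <- generateBilayer(tr, duration = 3600, spacing = 10)
  th <- thetaRotation(g$trajectory, cm, stride = 100, fixedLabel = "V")
  sweep <- th$theta_unwrapped[nrow(th)] - th$theta_unwrapped[1]
  expect_equal(sweep, 360, tolerance = 1e-6)
  trF <- syntheticTruth(nPopc = 8, nXan = 1, nWater = 0,
                        thetaMode = "frozen", seed = 12)
  gF <- generateBilayer(trF, duration = 1000, spacing = 10)
  thF <- thetaRotation(gF$trajectory, cm, stride = 100, fixedLabel = "V")
  expect_lt(diff(range(thF$theta_unwrapped)), 1e-6)
})

test_that("diffusive theta follows the Brownian mean-square law", {
  cm <- defaultClassMap()
  D <- 0.5; Tspan <- 400
  dsq <- numeric(60)
  for (r in seq_along(dsq)) {
    tr <- syntheticTruth(nPopc = 2, nXan = 1, nWater = 0,
                         thetaMode = "diffusion", thetaD = D,
                         seed = 400 + r)
    g <- generateBilayer(tr, duration = Tspan, spacing = 25)
    th <- thetaRotation(g$trajectory, cm, stride = 100, fixedLabel = "V")
    dsq[r] <- (th$theta_unwrapped[nrow(th)] - th$theta_unwrapped[1])^2
  }
  msd <- mean(dsq)
  expected <- 2 * D * Tspan
  se <- expected * sqrt(2 / length(dsq))
  expect_lt(abs(msd - expected), 3 * se)
})

test_that("molecular length and width match construction and are rotation invariant", {
  cm <- defaultClassMap()
  tr <- syntheticTruth(nPopc = 16, nXan = 2, nWater = 0, seed = 13)
  g <- generateBilayer(tr, duration = 60)
  ml <- molecularLength(g$trajectory, cm)
  expect_equal(ml$mean, 28.3, tolerance = 1e-9)
  expect_equal(ml$sd, 0, tolerance = 1e-9)
  hw <- hydrophobicWidth(g$trajectory, cm)
  expect_lt(abs(hw$mean - 30.3), 0.3)
  # rigid rotation invariance: H molecule gives the same rod length
  trH <- syntheticTruth(nPopc = 16, nXan = 1, nWater = 0,
                        orientation = "H", seed = 13)
  gH <- generateBilayer(trH, duration = 60)
  expect_equal(molecularLength(gH$trajectory, cm)$mean, 28.3,
               tolerance = 1e-9)
})

test_that("aggregation episodes require persistence", {
  cm <- defaultClassMap()
  # two rods far apart: no episodes
  tr <- syntheticTruth(nPopc = 16, nXan = 2, nWater = 0, seed = 14)
  g <- generateBilayer(tr, duration = 30)
  expect_equal(nrow(checkAggregation(g$trajectory, cm, cutoff = 5,
                                     minFrames = 5)), 0L)
  # hand-built overlap for 10 frames
  top <- rbind(data.frame(name = c("C3", "C3P"), resname = "LUT", resid = 1L),
               data.frame(name = c("C3", "C3P"), resname = "LUT", resid = 2L))
  nf <- 30
  co <- array(0, c(4, 3, nf))
  co[1, , ] <- 0; co[2, 1, ] <- 5
  co[3, 1, ] <- 20; co[4, 1, ] <- 25
  co[3, 1, 11:20] <- 2; co[4, 1, 11:20] <- 7   # overlap frames 11..20
  trj <- newTrajectory(top, co, c(60, 60, 60))
  ep <- checkAggregation(trj, cm, cutoff = 5, minFrames = 5)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$n_frames, 10L)
  # 1-frame transient contacts are not episodes
  co[3, 1, ] <- 20; co[4, 1, ] <- 25
  co[3, 1, c(5, 15, 25)] <- 2
  trj2 <- newTrajectory(top, co, c(60, 60, 60))
  expect_equal(nrow(checkAggregation(trj2, cm, cutoff = 5, minFrames = 5)),
               0L)
})
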