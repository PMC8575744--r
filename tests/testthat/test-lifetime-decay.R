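test_that("decay curve reproduces hand counts and the brute-force recount", {
  # single pair bonded at frames 0 and 1 only, one origin at 0
  M <- matrix(FALSE, 1, 20); M[1, 1:2] <- TRUE
  dc <- decayCurve(M, lag = 5, originStride = 100, times = 0:19)
  expect_equal(dc@counts, c(1, 1, 0, 0, 0, 0))
  # all pairs always bonded: C(tau) = pair count
  M2 <- matrix(TRUE, 4, 30)
  dc2 <- decayCurve(M2, lag = 10, originStride = 5, times = 0:29)
  expect_true(all(dc2@counts == 4))
  # exhaustive brute force on random small matrices
  set.seed(33)
  for (r in 1:10) {
    M3 <- matrix(runif(5 * 200) < runif(1, 0.2, 0.8), 5, 200)
    dc3 <- decayCurve(M3, lag = 40, originStride = 25, times = 0:199)
    origins <- seq(1, 200 - 40, by = 25)
    expect_equal(dc3@counts, bruteDecay(M3, origins, 40))
  }
  expect_error(decayCurve(matrix(TRUE, 1, 5), lag = 100, times = 0:4),
               "span")
})

test_that("telegraph decay follows the two-state closed form", {
  kOn <- 0.004; kOff <- 0.006
  p <- kOn / (kOn + kOff)
  bem <- generateEventMatrix(1000, kOn, kOff, duration = 3000, seed = 11)
  dc <- decayCurve(bem, lag = 500, originStride = 100)
  pred <- dc@counts[1] * (p + (1 - p) * exp(-(kOn + kOff) * dc@lags))
  # Monte-Carlo band: 1000 pair indicators, conservatively 1 effective origin
  band <- 3 * sqrt(0.25 * 1000)
  expect_lt(max(abs(dc@counts - pred)), band)
  expect_lt(mean(abs(dc@counts - pred)), band / 4)
  expect_equal(dc@counts[1], sum(eventMatrix(bem)[, seq(1, 2501, 100)]) /
                 length(seq(1, 2501, 100)))
})

test_that("decay curve is robust to the origin-set choice for stationary input", {
  bem <- generateEventMatrix(400, 0.005, 0.005, duration = 4000, seed = 7)
  d1 <- decayCurve(bem, lag = 300, originStride = 100)
  d2 <- decayCurve(bem, lag = 300, originStride = 350)
  expect_lt(max(abs(d1@counts / d1@counts[1] - d2@counts / d2@counts[1])),
            0.1)
})

test_that("single-exponential input is recovered exactly", {
  cur <- generateDecayCurve(100, 10, C0 = 1, lag = 200)
  ft <- fitMultiExp(cur, n = 1)
  expect_equal(ft@A, 100, tolerance = 1e-6)
  expect_equal(ft@T, 10, tolerance = 1e-6)
  expect_equal(ft@C0, 1, tolerance = 1e-6)
})

test_that("random admissible four-exponential curves round-trip within 1 percent", {
  set.seed(61)
  for (r in 1:20) {
    # well-separated time constants (ratio >= 4) and non-trivial amplitudes
    T0 <- sort(exp(runif(1, 0, 0.8) + cumsum(runif(4, log(4), log(8)))))
    A0 <- runif(4, 0.5, 1); A0 <- 100 * A0 / sum(A0)
    cur <- generateDecayCurve(A0, T0, C0 = 100,
                              lag = min(20000, ceiling(4 * max(T0))))
    ft <- fitMultiExp(cur, n = 4, restarts = 12, seed = r)
    expect_lt(max(abs(ft@A - A0) / A0), 0.01)
    expect_lt(max(abs(ft@T - T0) / T0), 0.01)
    expect_equal(sum(ft@A), 100, tolerance = 1e-6)
    expect_false(ft@degenerate)
  }
})

test_that("fitted amplitudes are sorted with T and stable across restart seeds", {
  p <- referenceDecayParameters()[4, ]   # vertical-lutein eps-ring row
  cur <- generateDecayCurve(as.numeric(p[c("A1", "A2", "A3", "A4")]),
                            as.numeric(p[c("T1", "T2", "T3", "T4")]))
  f1 <- fitMultiExp(cur, seed = 1)
  f2 <- fitMultiExp(cur, seed = 99)
  expect_true(all(diff(f1@T) > 0))
  expect_equal(f1@A, f2@A, tolerance = 1e-4)
  expect_equal(f1@T, f2@T, tolerance = 1e-4)
})

test_that("residual diagnostics flag noise level and structured misfit", {
  p <- referenceDecayParameters()[1, ]
  A <- as.numeric(p[c("A1", "A2", "A3", "A4")])
  T0 <- as.numeric(p[c("T1", "T2", "T3", "T4")])
  cur <- generateDecayCurve(A, T0, C0 = 100, lag = 5000)
  ft <- fitMultiExp(cur)
  r0 <- fitResiduals(ft)
  expect_lt(r0$maxAbsRelative, 1e-6)
  # injected white noise: residual sd within 20 percent of sigma
  sig <- 0.5
  curN <- generateDecayCurve(A, T0, C0 = 100, lag = 5000, noiseSd = sig,
                             seed = 4)
  ftN <- fitMultiExp(curN)
  rN <- fitResiduals(ftN)
  expect_lt(abs(rN$residualSd - sig) / sig, 0.2)
  # a 3-exponential signal fitted with n = 2 leaves structured residuals
  cur3 <- generateDecayCurve(c(40, 35, 25), c(5, 80, 1500), C0 = 100,
                             lag = 5000)
  ft2 <- fitMultiExp(cur3, n = 2)
  r2 <- fitResiduals(ft2)
  expect_gt(abs(r2$runs$z), 3)
  expect_lt(r2$runs$p, 0.01)
})

test_that("every published reference row round-trips noiselessly within 1 percent", {
  ref <- referenceDecayParameters()
  for (i in seq_len(nrow(ref))) {
    A <- as.numeric(ref[i, c("A1", "A2", "A3", "A4")])
    T0 <- as.numeric(ref[i, c("T1", "T2", "T3", "T4")])
    lag <- if (max(T0) > 5000) 30000 else 5000
    cur <- generateDecayCurve(A, T0, C0 = 100, lag = lag)
    ft <- fitMultiExp(cur)
    expect_lt(max(abs(ft@A - 100 * A / sum(A)) / A), 0.01)
    expect_lt(max(abs(ft@T - T0) / T0), 0.01)
  }
})

test_that("noisy analytic curves are still recovered within 5 percent", {
  A <- c(100); T0 <- 10
  cur <- generateDecayCurve(A, T0, C0 = 1, lag = 100, noiseSd = 0.01,
                            seed = 3)
  ft <- fitMultiExp(cur, n = 1)
  expect_lt(abs(ft@T - 10) / 10, 0.05)
  # a two-population telegraph mixture resolves two relaxation rates
  bem <- generateEventMatrix(800, kOn = c(rep(0.02, 400), rep(0.002, 400)),
                             kOff = c(rep(0.08, 400), rep(0.008, 400)),
                             duration = 4000, seed = 13)
  dc <- decayCurve(bem, lag = 800, originStride = 200)
  # subtract the stationary plateau before fitting pure exponentials
  p <- 0.2
  plateau <- dc@counts[1] * p
  cur2 <- new("DecayCurve", lags = dc@lags, counts = dc@counts - plateau,
              nOrigins = dc@nOrigins, type = "mixture", spacing = dc@spacing)
  ft2 <- fitMultiExp(cur2, n = 2, restarts = 24)
  expect_lt(abs(ft2@T[1] - 10) / 10, 0.35)
  expect_lt(abs(ft2@T[2] - 100) / 100, 0.35)
})

test_that("generateDecayCurve validates parameters", {
  expect_error(generateDecayCurve(c(50, 40), c(10, 100)), "sum to 100")
  expect_error(generateDecayCurve(100, -5), "invalid")
})
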