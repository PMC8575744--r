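# minimal single-frame builder: named atoms at given positions
frameTraj <- function(spec, box = 30) {
  top <- do.call(rbind, lapply(spec, function(s)
    data.frame(name = s$name, resname = s$resname, resid = s$resid)))
  co <- array(t(vapply(spec, function(s) s$xyz, numeric(3))),
              c(length(spec), 3L, 1L))
  newTrajectory(top, co, rep(box, 3))
}

at <- function(name, resname, resid, xyz)
  list(name = name, resname = resname, resid = resid, xyz = xyz)

test_that("hydrogen-bond detection honours distance and angle criteria", {
  # collinear O-H...A at 2.8 A: bonded
  tr <- frameTraj(list(
    at("O3", "LUT", 1, c(0, 0, 0)), at("H3O", "LUT", 1, c(0.96, 0, 0)),
    at("O13", "POPC", 2, c(2.8, 0, 0))))
  hb <- detectHBonds(tr, 1, defaultClassMap())
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$partner_class, "Op")
  # acceptor beyond the cutoff: not bonded
  tr2 <- frameTraj(list(
    at("O3", "LUT", 1, c(0, 0, 0)), at("H3O", "LUT", 1, c(0.96, 0, 0)),
    at("O13", "POPC", 2, c(0, 4, 0))))
  expect_equal(nrow(detectHBonds(tr2, 1, defaultClassMap())), 0L)
  # within distance but bent below the angle cutoff: not bonded
  tr3 <- frameTraj(list(
    at("O3", "LUT", 1, c(0, 0, 0)), at("H3O", "LUT", 1, c(0.96, 0, 0)),
    at("O13", "POPC", 2, c(0, 2.8, 0))))
  expect_equal(nrow(detectHBonds(tr3, 1, defaultClassMap())), 0L)
  # hydroxyl without hydrogen is a configuration error
  tr4 <- frameTraj(list(at("O3", "LUT", 1, c(0, 0, 0)),
                        at("O13", "POPC", 2, c(2.8, 0, 0))))
  expect_error(detectHBonds(tr4, 1, defaultClassMap()), "hydrogen")
})

test_that("detectors match the brute-force 27-image oracle on random frames", {
  crit <- hbondCriteria()
  cp <- chargePairCriteria()
  cm <- defaultClassMap()
  tr <- randomContactTrajectory(nFrames = 500, nWater = 5, box = 12,
                                seed = 55)
  top <- atoms(tr)
  ohs <- xanmem:::.ohGroups(tr, cm)
  for (f in seq_len(nFrames(tr))) {
    xyz <- coords(tr, f)
    box <- boxLengths(tr, f)
    hb <- detectHBonds(tr, f, cm)
    got <- sort(paste(hb$oh_id, hb$partner_id, hb$direction))
    want <- character()
    for (g in seq_len(nrow(ohs))) {
      xo <- xyz[ohs$o_idx[g], ]; xh <- xyz[ohs$h_idx[g], ]
      for (cl in c("Op", "O22", "O32", "water")) {
        pa <- xanmem:::.partnerAtoms(tr, cm, cl)
        for (k in seq_len(nrow(pa))) {
          xa <- xyz[pa$atom_idx[k], ]
          if (bruteHbondPair(xo, xh, xa, box, crit$maxDistance,
                             crit$minAngle))
            want <- c(want, paste(ohs$oh_id[g], pa$partner_id[k],
                                  "oh_donor"))
          if (cl == "water") {
            wres <- top$resid[pa$atom_idx[k]]
            hIdx <- which(top$resname == "SOL" & top$resid == wres &
                          top$name %in% c("HW1", "HW2"))
            for (h in hIdx)
              if (bruteHbondPair(xa, xyz[h, ], xo, box, crit$maxDistance,
                                 crit$minAngle)) {
                want <- c(want, paste(ohs$oh_id[g], pa$partner_id[k],
                                      "water_donor"))
                break
              }
          }
        }
      }
    }
    expect_identical(got, sort(unique(want)))
    # charge pairs against a brute double loop
    cpq <- detectChargePairs(tr, f, cm, cp)
    choIdx <- which(top$resname == "POPC" &
                    top$name %in% c("N", "C13", "C14", "C15"))
    wantCp <- character()
    for (g in seq_len(nrow(ohs))) {
      dmin <- min(vapply(choIdx, function(j)
        bruteMinImage(xyz[ohs$o_idx[g], ], xyz[j, ], box), numeric(1)))
      if (dmin <= cp$maxDistance)
        wantCp <- c(wantCp, paste0(ohs$oh_id[g], "|POPC2"))
    }
    got <- if (nrow(cpq)) sort(paste0(cpq$oh_id, "|", cpq$partner_id))
           else character(0)
    expect_identical(got, sort(wantCp))
  }
})

test_that("water bridges require both hydrogen bonds and count pairs once", {
  cm <- defaultClassMap()
  # OH - water - Op chain, all collinear at 2.8 A steps
  base <- list(
    at("O3", "LUT", 1, c(0, 0, 0)), at("H3O", "LUT", 1, c(0.96, 0, 0)),
    at("OW", "SOL", 3, c(2.8, 0, 0)), at("HW1", "SOL", 3, c(3.76, 0, 0)),
    at("HW2", "SOL", 3, c(2.56, 0.93, 0)),
    at("O13", "POPC", 2, c(5.6, 0, 0)))
  tr <- frameTraj(base)
  br <- detectWaterBridges(tr, 1, cm)
  expect_equal(nrow(br), 1L)
  expect_equal(br$partner_class, "Op")
  expect_equal(br$n_waters, 1L)
  # water bonded to the OH only: no bridge
  base2 <- base; base2[[6]]$xyz <- c(15, 0, 0)
  expect_equal(nrow(detectWaterBridges(frameTraj(base2), 1, cm)), 0L)
  # two waters bridging the same (OH, Op): still one bridge row
  base3 <- c(base, list(
    at("OW", "SOL", 4, c(2.8, 1.2, 0)), at("HW1", "SOL", 4, c(3.76, 1.2, 0)),
    at("HW2", "SOL", 4, c(2.56, 2.13, 0))))
  # place the second water so it H-bonds both ends too
  base3[[7]]$xyz <- c(2.8, 0.4, 0); base3[[8]]$xyz <- c(3.76, 0.4, 0)
  base3[[9]]$xyz <- c(2.33, 1.23, 0)
  tr3 <- frameTraj(base3)
  br3 <- detectWaterBridges(tr3, 1, cm)
  expect_equal(nrow(br3), 1L)
  expect_equal(br3$n_waters, 2L)
  # bridge endpoints are a subset of OH/PC atoms with a water H-bond
  hb <- detectHBonds(tr3, 1, cm, partners = "water")
  expect_true(all(br3$oh_id %in% hb$oh_id))
})

test_that("event matrix columns equal per-frame detector counts and episodes conserve", {
  cm <- defaultClassMap()
  tr <- randomContactTrajectory(nFrames = 60, nWater = 4, box = 10,
                                seed = 77)
  bem <- buildEventMatrix(tr, cm, "hbond")
  ev <- eventMatrix(bem)
  for (f in seq_len(60)) {
    hb <- detectHBonds(tr, f, cm)
    expect_equal(sum(ev[, f]),
                 length(unique(paste(hb$oh_id, hb$partner_id))))
  }
  ep <- bondEpisodes(bem)
  expect_equal(sum(ep$n_frames), sum(ev))
  # alternating on/off gives episodes of length 1
  m <- matrix(rep(c(TRUE, FALSE), 10), 1)
  bem2 <- newBondEventMatrix("hbond", data.frame(pair_id = "p1"),
                             m, seq_len(20) - 1)
  ep2 <- bondEpisodes(bem2)
  expect_true(all(ep2$n_frames == 1L))
  expect_equal(nrow(ep2), 10L)
})

test_that("contact counts are invariant under rigid translation (PBC correctness)", {
  cm <- defaultClassMap()
  tr <- randomContactTrajectory(nFrames = 25, nWater = 4, box = 10,
                                seed = 88)
  sh <- c(7.3, -4.1, 12.9)
  tr2 <- tr
  tr2@coords <- sweep(tr@coords, 2, sh, "+")
  for (f in seq_len(25)) {
    a <- detectHBonds(tr, f, cm)
    b <- detectHBonds(tr2, f, cm)
    expect_identical(sort(paste(a$oh_id, a$partner_id, a$direction)),
                     sort(paste(b$oh_id, b$partner_id, b$direction)))
  }
})

test_that("contact summaries average correctly and All equals the sum of parts", {
  pairs <- data.frame(
    pair_id = c("a|Op", "a|O22", "a|w"),
    oh_id = "a", molecule_id = "LUT1", ring = c("beta", "beta", "beta"),
    partner_class = c("Op", "O22", "water"),
    partner_id = c("POPC2:O13", "POPC2:O22", "SOL3"))
  ev <- rbind(rep(TRUE, 10),
              rep(c(TRUE, FALSE), 5),
              rep(FALSE, 10))
  bem <- newBondEventMatrix("hbond", pairs, ev, 0:9)
  sm <- summarizeContacts(bem)
  expect_equal(sm$mean[sm$partner_class == "Op"], 1.0)
  expect_equal(sm$sd[sm$partner_class == "Op"], 0.0)
  expect_equal(sm$mean[sm$partner_class == "O22"], 0.5)
  expect_equal(sm$sd[sm$partner_class == "O22"],
               stats::sd(rep(c(1, 0), 5)))
  expect_equal(sm$mean[sm$partner_class == "All"], 1.5)
  # All = Op + O22 + O32 exactly, frame by frame construction
  expect_equal(sm$mean[sm$partner_class == "All"],
               sm$mean[sm$partner_class == "Op"] +
                 sm$mean[sm$partner_class == "O22"])
})

test_that("telegraph stationary on-probability is recovered by the summary", {
  kOn <- 0.003; kOff <- 0.007   # p = 0.3
  bem <- generateEventMatrix(200, kOn, kOff, duration = 2000, seed = 19)
  m <- mean(eventMatrix(bem))
  # effective sample count: chains decorrelate over 1/(kOn+kOff) = 100 ps
  neff <- 200 * 2000 / (2 * 100)
  expect_lt(abs(m - 0.3), 3 * sqrt(0.3 * 0.7 / neff))
})
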