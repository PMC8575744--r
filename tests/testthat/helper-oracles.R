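# Independent brute-force oracles: deliberately coded by different routes
# than the package internals (explicit 27-image searches instead of
# nearest-image rounding; the projection form of the dihedral instead of
# the normal-vector form).

imageShifts <- function(box) {
  g <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  cbind(g$i * box[1], g$j * box[2], g$k * box[3])
}

bruteMinImage <- function(a, b, box) {
  sh <- imageShifts(box)
  min(sqrt(rowSums((sweep(sh, 2, b - a, "+"))^2)))
}

# nearest periodic image of point b relative to a (27-image search)
bruteNearestImage <- function(a, b, box) {
  sh <- imageShifts(box)
  cand <- sweep(sh, 2, b, "+")
  cand[which.min(rowSums(sweep(cand, 2, a)^2)), ]
}

bruteDihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  atan2(sum(cr(b1, v) * w), sum(v * w)) * 180 / pi
}

# brute H-bond check for one donor triplet against one acceptor
bruteHbondPair <- function(xD, xH, xA, box, maxDist, minAngle) {
  xAim <- bruteNearestImage(xD, xA, box)
  if (sqrt(sum((xAim - xD)^2)) > maxDist) return(FALSE)
  xDim <- bruteNearestImage(xH, xD, box)
  xAim <- bruteNearestImage(xH, xA, box)
  vD <- xDim - xH; vA <- xAim - xH
  ang <- acos(min(1, max(-1, sum(vD * vA) /
                           sqrt(sum(vD^2) * sum(vA^2))))) * 180 / pi
  ang >= minAngle
}

# brute decay: naive double loop over origins and pairs
bruteDecay <- function(M, origins, lagFrames) {
  sapply(0:lagFrames, function(k)
    mean(sapply(origins, function(o) sum(M[, o] * M[, o + k]))))
}

# minimal hand-built trajectory for contact tests: one xanthophyll OH pair
# set, a few PC oxygens, a few waters, random coordinates each frame
randomContactTrajectory <- function(nFrames, nWater = 6, box = 12,
                                    seed = 1) {
  set.seed(seed)
  top <- rbind(
    data.frame(name = c("O3", "H3O", "O3P", "H3P", "C3", "C3P"),
               resname = "LUT", resid = 1L),
    data.frame(name = c("P", "O13", "O14", "O22", "O32", "N",
                        "C13", "C14", "C15"),
               resname = "POPC", resid = 2L),
    do.call(rbind, lapply(seq_len(nWater), function(k)
      data.frame(name = c("OW", "HW1", "HW2"), resname = "SOL",
                 resid = 2L + k))))
  nat <- nrow(top)
  co <- array(runif(nat * 3 * nFrames, 0, box), c(nat, 3L, nFrames))
  # keep each O-H at a fixed 0.96 A offset from its oxygen
  hAfterO <- which(top$name %in% c("H3O", "H3P", "HW1", "HW2"))
  for (h in hAfterO) {
    o <- if (top$name[h] == "HW2") h - 2L else h - 1L
    d <- matrix(rnorm(3 * nFrames), 3)
    d <- sweep(d, 2, sqrt(colSums(d^2)), "/") * 0.96
    co[h, , ] <- co[o, , ] + d
  }
  newTrajectory(top, co, rep(box, 3))
}
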