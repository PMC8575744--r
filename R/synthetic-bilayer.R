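#' @include xan-topology.R trajectory-class.R atom-class-map.R event-matrix.R
NULL

#' Ground-truth parameter set for the synthetic bilayer generator
#'
#' Defines the statistical structure a generated trajectory realises:
#' composition (default 188 POPC, 6 xanthophylls, ~8,500 waters), leaflet
#' reference planes (P at +-20 A, glycerol O at +-15 A, carbonyl O at
#' +-15.15 A, i.e. hydrophobic width 30.3 A), a rigid 28.3 A xanthophyll
#' rod, per-molecule orientation schedules with interpolated flips,
#' two-state Markov ring-torsion kinetics, OH-water bonding telegraph
#' processes and long-axis rotation dynamics.  Every quantity is
#' recoverable by the matching analysis stage; the generator is a
#' statistical-structure emulator, not an MD substitute.
#'
#' @param nPopc number of POPC pseudo-lipids (split over two leaflets).
#' @param nXan number of xanthophyll rods.
#' @param nWater total water count (bulk slabs + dedicated bonding waters).
#' @param species xanthophyll residue name (`"LUT"` or `"ZEA"`).
#' @param box cubic box edge, Angstrom.
#' @param pZ,ogZ,ocZ leaflet plane heights of P, glycerol O and carbonyl O
#'   atoms, Angstrom.
#' @param interfaceNoise per-frame Gaussian jitter sd of lipid atoms, A.
#' @param rodLength C3 to C3' distance, Angstrom.
#' @param orientation initial orientation for all xanthophylls (`"V"` or
#'   `"H"`); refine per molecule via the returned `$xan` table.
#' @param flipTime time (ps) at which an H molecule completes its
#'   reorientation to V (`NA` = never); the transit spans
#'   `[flipTime - transitDuration, flipTime]`.
#' @param transitDuration reorientation transit length, ps (default 20 ns).
#' @param epsRates,betaRates length-2 rates (per ps) of the ring-torsion
#'   two-state chains, `c(k12, k21)`; eps default `c(0, 0)` (no hopping),
#'   beta default `c(0.002, 0.004)` (frequent, 2:1 occupancy of +30).
#' @param torsionNoise angular sd about the state centre, degrees.
#' @param bondingRates length-2 `c(kOn, kOff)` per ps of the OH-water
#'   telegraph (default `c(0.007, 0.003)`, stationary on-probability 0.7).
#' @param thetaMode long-axis rotation of vertical molecules:
#'   `"diffusion"` (Brownian), `"frozen"`, or `"ramp"` (constant rate).
#' @param thetaD rotational diffusion coefficient, degrees^2/ps.
#' @param thetaRate ramp rate, degrees/ps (used by `thetaMode = "ramp"`).
#' @param seed integer seed; generation is bitwise deterministic given it.
#' @return list of class `SyntheticTruth`.
#' @export
syntheticTruth <- function(nPopc = 188, nXan = 6, nWater = 8500,
                           species = "LUT", box = 80,
                           pZ = 20, ogZ = 15, ocZ = 15.15,
                           interfaceNoise = 0.5, rodLength = 28.3,
                           orientation = "V", flipTime = NA,
                           transitDuration = 20000,
                           epsRates = c(0, 0), betaRates = c(0.002, 0.004),
                           torsionNoise = 8,
                           bondingRates = c(0.007, 0.003),
                           thetaMode = c("diffusion", "frozen", "ramp"),
                           thetaD = 0.1, thetaRate = 0.1, seed = 1) {
  thetaMode <- match.arg(thetaMode)
  stopifnot(nPopc >= 2, nPopc %% 2 == 0, nXan >= 0, nWater >= 0,
            all(epsRates >= 0), all(betaRates >= 0), all(bondingRates >= 0),
            thetaD >= 0, rodLength > 0, box > 0)
  if (rodLength + 2 * 3.8 > box - 2)
    stop("configuration error: rod (plus hydroxyls) does not fit the box")
  if (!pZ > ogZ || ogZ <= 0)
    stop("interface planes must satisfy pZ > ogZ > 0")
  xan <- if (nXan > 0) data.frame(
    id = seq_len(nXan),
    orientation = rep(orientation, nXan),
    leaflet = rep(c(1, -1), length.out = nXan),
    flipTime = rep(flipTime, nXan),
    transitDuration = rep(transitDuration, nXan),
    planeSign = rep(c(1, -1), length.out = nXan),
    theta0 = rep(0, nXan)) else
    data.frame(id = integer(), orientation = character(),
               leaflet = numeric(), flipTime = numeric(),
               transitDuration = numeric(), planeSign = numeric(),
               theta0 = numeric())
  structure(list(
    nPopc = nPopc, nXan = nXan, nWater = nWater, species = species,
    box = box, pZ = pZ, ogZ = ogZ, ocZ = ocZ,
    interfaceNoise = interfaceNoise, rodLength = rodLength,
    xan = xan, epsRates = epsRates, betaRates = betaRates,
    torsionNoise = torsionNoise, bondingRates = bondingRates,
    thetaMode = thetaMode, thetaD = thetaD, thetaRate = thetaRate,
    seed = seed,
    epsCentres = c(130, -50), betaCentres = c(30, -30)),
    class = "SyntheticTruth")
}

# two-state Markov chain on a uniform grid; states 1/2, rates per ps
.twoStateChain <- function(n, k12, k21, dt, init = NA) {
  p12 <- 1 - exp(-k12 * dt)
  p21 <- 1 - exp(-k21 * dt)
  s <- integer(n)
  if (is.na(init)) {
    pi1 <- if (k12 + k21 > 0) k21 / (k12 + k21) else 1
    s[1] <- if (stats::runif(1) < pi1) 1L else 2L
  } else s[1] <- as.integer(init)
  if (n > 1) {
    u <- stats::runif(n - 1)
    for (t in 2:n)
      s[t] <- if (s[t - 1] == 1L) (if (u[t - 1] < p12) 2L else 1L)
              else (if (u[t - 1] < p21) 1L else 2L)
  }
  s
}

# one leaflet-anchored POPC pseudo-lipid at xy site, leaflet sign sg
.lipidTemplate <- function(x, y, sg, truth) {
  nm <- c("N", "C13", "C14", "C15", "P", "O13", "O14", "O11", "O12",
          "O21", "O31", "O22", "O32", "C23", "C24", "C33", "C34")
  chZ <- truth$pZ + 2.5
  xyz <- rbind(
    c(x + 0.3, y, sg * chZ),
    c(x + 1.3, y, sg * (chZ + 0.5)), c(x - 0.7, y, sg * (chZ + 0.5)),
    c(x + 0.3, y + 1.0, sg * (chZ + 0.5)),
    c(x, y, sg * truth$pZ),
    c(x + 0.8, y, sg * (truth$pZ + 0.6)), c(x - 0.8, y, sg * (truth$pZ + 0.6)),
    c(x, y + 0.8, sg * (truth$pZ - 0.6)), c(x, y - 0.8, sg * (truth$pZ - 0.6)),
    c(x + 0.8, y, sg * truth$ogZ), c(x - 0.8, y, sg * truth$ogZ),
    c(x + 0.8, y, sg * truth$ocZ), c(x - 0.8, y, sg * truth$ocZ),
    c(x + 0.8, y, sg * 10), c(x + 0.8, y, sg * 6),
    c(x - 0.8, y, sg * 10), c(x - 0.8, y, sg * 6))
  list(names = nm, xyz = xyz)
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' Builds a slab of leaflet-anchored POPC pseudo-lipids (jittered about
#' their reference planes each frame), rigid xanthophyll rods placed per
#' the orientation schedule (horizontal-to-vertical flips interpolated over
#' the transit window), ring torsions realised by moving the off-axis
#' C5/C5' atoms to the Markov-chain angle series, long-axis rotation
#' realised as rigid spin, and waters: bulk slabs plus one dedicated water
#' per hydroxyl placed at collinear 2.8 A O...O geometry while its
#' telegraph is "on" and displaced to 6 A while "off".
#'
#' @param truth a [syntheticTruth()] parameter set.
#' @param duration trajectory length, ps.
#' @param spacing frame spacing, ps (default 1).
#' @return list with `trajectory` (a [Trajectory]) and `truth` (realised
#'   series: torsion angles and states, bonding telegraph, theta, plane
#'   labels, flip schedule, and the input parameters).
#' @export
generateBilayer <- function(truth, duration, spacing = 1) {
  stopifnot(inherits(truth, "SyntheticTruth"), duration >= 0)
  times <- seq(0, duration, by = spacing)
  nf <- length(times)
  if (any(!is.na(truth$xan$flipTime)) &&
      any(truth$xan$flipTime[!is.na(truth$xan$flipTime)] > duration))
    warning("a scheduled flip lies beyond the trajectory span")
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(truth$seed)
  half <- truth$box / 2
  # --- lipid sites: square grid per leaflet; xan sites at cell centres ----
  perLeaf <- truth$nPopc / 2
  nxy <- ceiling(sqrt(max(perLeaf, 1)))
  sGrid <- truth$box / nxy
  gx <- (rep(seq_len(nxy), nxy) - 0.5) * sGrid
  gy <- (rep(seq_len(nxy), each = nxy) - 0.5) * sGrid
  lipTop <- list(); lipBase <- list()
  rid <- 0L
  for (sg in c(1, -1)) for (k in seq_len(perLeaf)) {
    rid <- rid + 1L
    lt <- .lipidTemplate(gx[k], gy[k], sg, truth)
    lipTop[[rid]] <- data.frame(name = lt$names, resname = "POPC",
                                resid = rid, stringsAsFactors = FALSE)
    lipBase[[rid]] <- lt$xyz
  }
  lipBase <- do.call(rbind, lipBase)
  lipBase[, 3] <- lipBase[, 3] + half        # z origin -> box centre
  lipTop <- do.call(rbind, lipTop)
  nLip <- nrow(lipBase)
  # xan xy at cell-centre offsets of spread-out cells (max distance from
  # lipid sites, so no accidental contacts)
  if (truth$nXan > 0) {
    cells <- unique(round(seq(1, nxy * nxy, length.out = truth$nXan)))
    while (length(cells) < truth$nXan)
      cells <- unique(c(cells, sample.int(nxy * nxy, 1)))
    # cell corners: diagonal offset s/2 from every lipid site (min xy
    # separation s/sqrt(2)), so xanthophylls never graze lipid oxygens
    xanXY <- cbind((((cells - 1) %% nxy) * sGrid + sGrid) %% truth$box,
                   (((cells - 1) %/% nxy) * sGrid + sGrid) %% truth$box)
  }
  # --- xanthophyll schedules ---------------------------------------------
  calib <- .ringCalibration(truth$rodLength)
  interfaceZ <- (truth$pZ + truth$ogZ) / 2
  xanTop <- list(); xanTemplates <- list()
  sched <- list()
  torsB <- matrix(NA_real_, nf, truth$nXan)
  torsE <- matrix(NA_real_, nf, truth$nXan)
  stateB <- matrix(NA_integer_, nf, truth$nXan)
  stateE <- matrix(NA_integer_, nf, truth$nXan)
  theta <- matrix(NA_real_, nf, truth$nXan)
  for (i in seq_len(truth$nXan)) {
    x <- truth$xan[i, ]
    resid <- truth$nPopc + i
    tmpl <- .xanLocalCoords(0, 0, x$planeSign, truth$rodLength)
    xanTop[[i]] <- data.frame(name = tmpl$name, resname = truth$species,
                              resid = resid, stringsAsFactors = FALSE)
    xanTemplates[[i]] <- as.matrix(tmpl[, c("x", "y", "z")])
    # torsion chains
    stateB[, i] <- .twoStateChain(nf, truth$betaRates[1], truth$betaRates[2],
                                  spacing)
    stateE[, i] <- .twoStateChain(nf, truth$epsRates[1], truth$epsRates[2],
                                  spacing)
    torsB[, i] <- wrapAngle(truth$betaCentres[stateB[, i]] +
                            stats::rnorm(nf, 0, truth$torsionNoise))
    torsE[, i] <- wrapAngle(truth$epsCentres[stateE[, i]] +
                            stats::rnorm(nf, 0, truth$torsionNoise))
    # orientation schedule
    gamma <- numeric(nf); cz <- numeric(nf); spin <- numeric(nf)
    th <- rep(NA_real_, nf)
    if (x$orientation == "V") {
      gamma[] <- 0; cz[] <- 0
      th <- switch(truth$thetaMode,
        diffusion = x$theta0 + cumsum(c(0, stats::rnorm(nf - 1, 0,
                      sqrt(2 * truth$thetaD * spacing)))),
        ramp = x$theta0 + truth$thetaRate * times,
        frozen = rep(x$theta0, nf))
      spin <- th + 90
    } else {
      tf <- x$flipTime; ttr <- x$transitDuration
      if (is.na(tf)) {
        gamma[] <- 90; cz[] <- x$leaflet * interfaceZ; spin[] <- 90
      } else {
        pre <- times <= tf - ttr
        mid <- times > tf - ttr & times < tf
        post <- times >= tf
        frac <- (times[mid] - (tf - ttr)) / ttr
        gamma[pre] <- 90; gamma[mid] <- 90 * (1 - frac); gamma[post] <- 0
        cz[pre] <- x$leaflet * interfaceZ
        cz[mid] <- x$leaflet * interfaceZ * (1 - frac)
        cz[post] <- 0
        spin[pre | mid] <- 90
        nPost <- sum(post)
        if (nPost) {
          thp <- switch(truth$thetaMode,
            diffusion = x$theta0 + cumsum(c(0, stats::rnorm(nPost - 1, 0,
                          sqrt(2 * truth$thetaD * spacing)))),
            ramp = x$theta0 + truth$thetaRate *
              (times[post] - times[post][1]),
            frozen = rep(x$theta0, nPost))
          th[post] <- thp
          spin[post] <- thp + 90
        }
      }
    }
    theta[, i] <- th
    sched[[i]] <- list(gamma = gamma, cz = cz, spin = spin,
                       centreXY = xanXY[i, ])
  }
  # --- bonding telegraph per hydroxyl ------------------------------------
  nOH <- 2 * truth$nXan
  haveTelegraph <- truth$nWater >= nOH && nOH > 0
  bondOn <- matrix(FALSE, nf, nOH)
  ohIds <- character(nOH)
  if (truth$nXan > 0) {
    for (i in seq_len(truth$nXan)) {
      resid <- truth$nPopc + i
      ohIds[2 * i - 1] <- paste0(truth$species, resid, ":beta")
      ohIds[2 * i] <- paste0(truth$species, resid, ":eps")
      # state 2 = "on": 1->2 at kOn, 2->1 at kOff
      if (haveTelegraph) for (j in c(2 * i - 1, 2 * i))
        bondOn[, j] <- .twoStateChain(nf, truth$bondingRates[1],
                                      truth$bondingRates[2], spacing) == 2L
    }
    colnames(bondOn) <- ohIds
  }
  # --- waters ------------------------------------------------------------
  nTele <- if (haveTelegraph) nOH else 0L
  nBulk <- max(0L, truth$nWater - nTele)
  wSpace <- 2.75
  nwxy <- max(1L, floor(truth$box / wSpace))
  perLayer <- nwxy * nwxy
  bulkO <- matrix(0, nBulk, 3)
  placed <- 0L; layer <- 0L
  while (placed < nBulk) {
    zAbs <- 24 + wSpace * (layer %/% 2)
    if (zAbs > half - 1.5)
      stop("configuration error: nWater exceeds bulk slab capacity")
    sg <- if (layer %% 2 == 0) 1 else -1
    nHere <- min(perLayer, nBulk - placed)
    k <- seq_len(nHere)
    bulkO[placed + k, ] <- cbind(((k - 1) %% nwxy + 0.5) * wSpace,
                                 ((k - 1) %/% nwxy + 0.5) * wSpace,
                                 sg * zAbs + half)
    placed <- placed + nHere
    layer <- layer + 1L
  }
  waterTop <- list()
  wrid <- truth$nPopc + truth$nXan
  mkWater <- function(rid) data.frame(name = c("OW", "HW1", "HW2"),
                                      resname = "SOL", resid = rid,
                                      stringsAsFactors = FALSE)
  nWaterAll <- nBulk + nTele
  if (nWaterAll > 0)
    waterTop <- lapply(seq_len(nWaterAll), function(k) mkWater(wrid + k))
  # --- assemble topology --------------------------------------------------
  top <- rbind(lipTop,
               if (truth$nXan > 0) do.call(rbind, xanTop),
               if (nWaterAll > 0) do.call(rbind, waterTop))
  rownames(top) <- NULL
  nat <- nrow(top)
  xanRows <- if (truth$nXan > 0)
    lapply(seq_len(truth$nXan), function(i)
      which(top$resname == truth$species & top$resid == truth$nPopc + i))
    else list()
  waterStart <- nLip + if (truth$nXan > 0) sum(lengths(xanRows)) else 0L
  co <- array(0, c(nat, 3L, nf))
  hw1 <- c(0.96, 0, 0); hw2 <- c(-0.24, 0.93, 0)
  for (f in seq_len(nf)) {
    xyz <- matrix(0, nat, 3)
    xyz[seq_len(nLip), ] <- lipBase +
      matrix(stats::rnorm(nLip * 3, 0, truth$interfaceNoise), nLip, 3)
    ohPos <- matrix(0, nOH, 3); ohDir <- matrix(0, nOH, 3)
    for (i in seq_len(truth$nXan)) {
      az <- .azimuthFor(torsB[f, i], torsE[f, i], calib)
      T <- xanTemplates[[i]]
      nm <- xanTop[[i]]$name
      iC5 <- which(nm == "C5"); iC5P <- which(nm == "C5P")
      T[iC5, 1:2] <- 1.3 * c(cos(az["beta"] * pi / 180),
                             sin(az["beta"] * pi / 180))
      T[iC5P, 1:2] <- 1.3 * c(cos(az["eps"] * pi / 180),
                              sin(az["eps"] * pi / 180))
      sc <- sched[[i]]
      R <- .rotY(sc$gamma[f]) %*% .rotZ(sc$spin[f])
      centre <- c(sc$centreXY, sc$cz[f] + half)
      pos <- T %*% t(R)
      pos <- sweep(pos, 2, centre, "+")
      xyz[xanRows[[i]], ] <- pos
      iO3 <- which(nm == "O3"); iH3 <- which(nm == "H3O")
      iO3P <- which(nm == "O3P"); iH3P <- which(nm == "H3P")
      ohPos[2 * i - 1, ] <- pos[iO3, ]
      ohDir[2 * i - 1, ] <- (pos[iH3, ] - pos[iO3, ]) / 0.96
      ohPos[2 * i, ] <- pos[iO3P, ]
      ohDir[2 * i, ] <- (pos[iH3P, ] - pos[iO3P, ]) / 0.96
    }
    if (nBulk > 0) {
      rows <- waterStart + 3 * (seq_len(nBulk) - 1L)
      xyz[rows + 1L, ] <- bulkO
      xyz[rows + 2L, ] <- sweep(bulkO, 2, hw1, "+")
      xyz[rows + 3L, ] <- sweep(bulkO, 2, hw2, "+")
    }
    if (nTele > 0) {
      for (j in seq_len(nOH)) {
        d <- if (bondOn[f, j]) 2.8 else 6.0
        ow <- ohPos[j, ] + d * ohDir[j, ]
        rows <- waterStart + 3 * (nBulk + j - 1L)
        xyz[rows + 1L, ] <- ow
        xyz[rows + 2L, ] <- ow + hw1
        xyz[rows + 3L, ] <- ow + hw2
      }
    }
    co[, , f] <- xyz
  }
  traj <- newTrajectory(top, co, rep(truth$box, 3), times)
  planeLabel <- if (truth$nXan > 0)
    ifelse(truth$xan$orientation == "H",
           ifelse(truth$xan$leaflet * truth$xan$planeSign > 0,
                  "beta_up", "beta_down"), NA_character_) else character()
  list(trajectory = traj,
       truth = list(times = times, torsionBeta = torsB, torsionEps = torsE,
                    stateBeta = stateB, stateEps = stateE,
                    bondingOn = bondOn, ohIds = ohIds, theta = theta,
                    xan = truth$xan, planeLabel = planeLabel,
                    params = truth))
}

#' Geometry-free telegraph bond-event matrix
#'
#' Draws binary bonding rows directly from two-state telegraph processes
#' (stationary initial state), bypassing coordinates -- the fast path for
#' stress-testing the lifetime-decay stage.
#'
#' @param nPairs number of pairs.
#' @param kOn,kOff rates per ps (may be vectors of length `nPairs`).
#' @param duration span, ps.
#' @param spacing frame spacing, ps.
#' @param seed integer seed.
#' @return a [BondEventMatrix] of type `"telegraph"`.
#' @export
generateEventMatrix <- function(nPairs, kOn, kOff, duration, spacing = 1,
                                seed = 1) {
  kOn <- rep_len(kOn, nPairs); kOff <- rep_len(kOff, nPairs)
  times <- seq(0, duration, by = spacing)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)
  ev <- matrix(FALSE, nPairs, length(times))
  for (p in seq_len(nPairs))
    ev[p, ] <- .twoStateChain(length(times), kOn[p], kOff[p], spacing) == 2L
  pairs <- data.frame(pair_id = paste0("pair", seq_len(nPairs)),
                      oh_id = NA_character_, molecule_id = NA_character_,
                      ring = NA_character_, partner_class = "telegraph",
                      partner_id = NA_character_, stringsAsFactors = FALSE)
  newBondEventMatrix("telegraph", pairs, ev, times)
}
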