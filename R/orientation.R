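#' @include geometry.R atom-class-map.R
NULL

#' Per-frame interface reference planes
#'
#' Mean z of the phosphate P atoms and of the glycerol O atoms in each
#' leaflet, plus the bilayer centre (midpoint of the leaflet P means).
#' Leaflets are assigned by the sign of z minus the instantaneous centre.
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @return data.frame with `time`, `p_upper`, `p_lower`, `og_upper`,
#'   `og_lower`, `centre` (Angstrom).
#' @export
interfaceReference <- function(traj, classmap) {
  pIdx <- selectAtoms(traj, classmap, "P", require = TRUE)
  ogIdx <- selectAtoms(traj, classmap, "glycerol_O", require = TRUE)
  nf <- nFrames(traj)
  out <- data.frame(time = frameTimes(traj), p_upper = NA_real_,
                    p_lower = NA_real_, og_upper = NA_real_,
                    og_lower = NA_real_, centre = NA_real_)
  for (f in seq_len(nf)) {
    pz <- traj@coords[pIdx, 3, f]
    c0 <- mean(pz)                       # provisional centre
    up <- pz > c0
    if (!any(up) || all(up))
      stop("configuration error: all P atoms in one leaflet")
    pu <- mean(pz[up]); pl <- mean(pz[!up])
    centre <- (pu + pl) / 2
    oz <- traj@coords[ogIdx, 3, f]
    ou <- oz > centre
    if (!any(ou) || all(ou))
      stop("configuration error: all glycerol O atoms in one leaflet")
    out$p_upper[f] <- pu; out$p_lower[f] <- pl
    out$og_upper[f] <- mean(oz[ou]); out$og_lower[f] <- mean(oz[!ou])
    out$centre[f] <- centre
  }
  out
}

#' Ring centre-of-mass z trajectories of the xanthophylls
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @return data.frame with `molecule_id`, `time`, `z_beta`, `z_eps`
#'   (mass-weighted ring-COM z, Angstrom).
#' @export
ringComSeries <- function(traj, classmap) {
  mols <- xanMolecules(traj, classmap)
  if (!nrow(mols)) stop("no xanthophyll molecules found")
  bNames <- classmap@roles$ring_beta_atoms$atoms
  eNames <- classmap@roles$ring_eps_atoms$atoms
  out <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    bi <- .residueAtoms(traj, mols$resname[i], mols$resid[i], bNames)
    ei <- .residueAtoms(traj, mols$resname[i], mols$resid[i], eNames)
    if (!length(bi) || !length(ei))
      stop("ring atoms missing for ", mols$molecule_id[i])
    out[[i]] <- data.frame(molecule_id = mols$molecule_id[i],
                           time = frameTimes(traj),
                           z_beta = .comZSeries(traj, bi),
                           z_eps = .comZSeries(traj, ei),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.runningMajority <- function(labels, w) {
  if (w <= 1) return(labels)
  lv <- c("H", "V", "transit")
  ind <- sapply(lv, function(l) as.numeric(labels == l))
  k <- rep(1, w)
  sums <- apply(ind, 2, function(v)
    as.numeric(stats::filter(v, k, sides = 2)))
  out <- labels
  ok <- stats::complete.cases(sums)
  best <- lv[max.col(sums[ok, , drop = FALSE], ties.method = "first")]
  # keep the raw label on ties
  mx <- apply(sums[ok, , drop = FALSE], 1, max)
  tie <- rowSums(sums[ok, , drop = FALSE] == mx) > 1
  best[tie] <- labels[ok][tie]
  out[ok] <- best
  out
}

#' Classify xanthophyll orientation (horizontal / vertical / transit)
#'
#' A ring lies in a leaflet's interfacial slab when its COM z is between
#' that leaflet's glycerol-O and P reference planes, padded by `tol`.
#' Vertical (V): the two rings occupy opposite slabs; horizontal (H): both
#' occupy the same slab; otherwise transit.  Labels are smoothed by a
#' running majority window and runs of H/V shorter than `smoothing` are
#' demoted to transit; a reorientation event is a maximal transit run
#' bounded by two different stable labels, its end time being the start of
#' the new stable label.
#'
#' @param zBeta,zEps ring-COM z series (Angstrom).
#' @param ref output of [interfaceReference()] (aligned in time).
#' @param times frame times (ps); defaults to `ref$time`.
#' @param smoothing majority window, ps (default 1000 = 1 ns).
#' @param tol slab padding, Angstrom (default 2).
#' @return list with `data` (data.frame `time`, `z_beta`, `z_eps`, `label`)
#'   and `events` (data.frame `start`, `end`, `from`, `to`).
#' @export
classifyOrientation <- function(zBeta, zEps, ref, times = ref$time,
                                smoothing = 1000, tol = 2) {
  stopifnot(length(zBeta) == nrow(ref), length(zEps) == nrow(ref))
  inUpper <- function(z) z >= ref$og_upper - tol & z <= ref$p_upper + tol
  inLower <- function(z) z >= ref$p_lower - tol & z <= ref$og_lower + tol
  ub <- inUpper(zBeta); lb <- inLower(zBeta)
  ue <- inUpper(zEps); le <- inLower(zEps)
  label <- rep("transit", length(zBeta))
  label[(ub & le) | (lb & ue)] <- "V"
  label[(ub & ue) | (lb & le)] <- "H"
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  w <- max(1L, round(smoothing / dt))
  if (w %% 2 == 0) w <- w + 1L
  sm <- .runningMajority(label, min(w, length(label)))
  # stability: H/V runs shorter than the smoothing window become transit
  r <- rle(sm)
  short <- r$values != "transit" & r$lengths * dt < smoothing
  r$values[short] <- "transit"
  sm <- inverse.rle(r)
  r <- rle(sm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  events <- data.frame(start = numeric(), end = numeric(),
                       from = character(), to = character(),
                       stringsAsFactors = FALSE)
  addEvent <- function(ev, s, e, from, to)
    rbind(ev, data.frame(start = s, end = e, from = from, to = to,
                         stringsAsFactors = FALSE))
  for (k in seq_along(r$values)) {
    if (r$values[k] == "transit") {
      prev <- if (k > 1) r$values[k - 1] else NA
      nxt <- if (k < length(r$values)) r$values[k + 1] else NA
      if (!is.na(prev) && !is.na(nxt) && prev != nxt)
        events <- addEvent(events, times[starts[k]],
                           times[min(ends[k] + 1L, length(times))],
                           prev, nxt)
    } else if (k > 1 && r$values[k - 1] != "transit" &&
               r$values[k - 1] != r$values[k]) {
      # direct switch without transit frames
      events <- addEvent(events, times[starts[k]], times[starts[k]],
                         r$values[k - 1], r$values[k])
    }
  }
  list(data = data.frame(time = times, z_beta = zBeta, z_eps = zEps,
                         label = sm, stringsAsFactors = FALSE),
       events = events)
}

#' Orientation classification for every xanthophyll in a trajectory
#'
#' Convenience wrapper: [interfaceReference()] + [ringComSeries()] +
#' [classifyOrientation()] per molecule.
#'
#' @inheritParams classifyOrientation
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @return list with `ref` and `perMolecule` (named list of
#'   [classifyOrientation()] results).
#' @export
classifyAllOrientations <- function(traj, classmap, smoothing = 1000,
                                    tol = 2) {
  ref <- interfaceReference(traj, classmap)
  rc <- ringComSeries(traj, classmap)
  ids <- unique(rc$molecule_id)
  per <- lapply(ids, function(id) {
    d <- rc[rc$molecule_id == id, ]
    classifyOrientation(d$z_beta, d$z_eps, ref, d$time, smoothing, tol)
  })
  names(per) <- ids
  list(ref = ref, perMolecule = per)
}

#' Polyene-plane orientation (beta-up / beta-down) of horizontal molecules
#'
#' For a horizontal molecule the polyene-chain plane stands perpendicular
#' to the bilayer surface and the methyl (MET) groups of the two chain
#' halves point in opposite directions along the normal.  The molecule is
#' `beta_up` when the beta-half MET mean z is on the water side of the
#' eps-half MET mean z (the beta-ring OH points to water), mirrored in the
#' lower leaflet; else `beta_down`.
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @param orientation output of [classifyAllOrientations()].
#' @return data.frame with one row per molecule that has stable H frames:
#'   `molecule_id`, `label`, `z_met_beta`, `z_met_eps`, `leaflet`,
#'   `n_frames`.
#' @export
planeOrientation <- function(traj, classmap, orientation) {
  mols <- xanMolecules(traj, classmap)
  bNames <- classmap@roles$met_beta$atoms
  eNames <- classmap@roles$met_eps$atoms
  rows <- list()
  for (i in seq_len(nrow(mols))) {
    id <- mols$molecule_id[i]
    oc <- orientation$perMolecule[[id]]
    hIdx <- which(oc$data$label == "H")
    if (!length(hIdx)) next
    bi <- .residueAtoms(traj, mols$resname[i], mols$resid[i], bNames)
    ei <- .residueAtoms(traj, mols$resname[i], mols$resid[i], eNames)
    if (!length(bi) || !length(ei))
      stop("MET atoms missing for ", id)
    zb <- mean(traj@coords[bi, 3, hIdx])
    ze <- mean(traj@coords[ei, 3, hIdx])
    zc <- mean(orientation$ref$centre[hIdx])
    zmol <- mean(c(oc$data$z_beta[hIdx], oc$data$z_eps[hIdx]))
    leaflet <- if (zmol > zc) "upper" else "lower"
    up <- if (leaflet == "upper") zb > ze else zb < ze
    rows[[length(rows) + 1L]] <- data.frame(
      molecule_id = id, label = if (up) "beta_up" else "beta_down",
      z_met_beta = zb, z_met_eps = ze, leaflet = leaflet,
      n_frames = length(hIdx), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("plane orientation is defined only for horizontally oriented molecules; none found")
  do.call(rbind, rows)
}

#' Long-axis rotation angle theta
#'
#' For vertical molecules theta is the angle between the MET-to-C13 bond
#' projected on the x-y plane and the x axis; for horizontal molecules it
#' is the angle between the bond and the z axis within the vertical plane
#' containing the long axis.  Sampled every `stride` ps; an unwrapped
#' cumulative angle (nearest-image steps) is also returned.
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @param orientation output of [classifyAllOrientations()], or `NULL` to
#'   force the label in `fixedLabel` for all frames.
#' @param stride sampling interval, ps (default 100).
#' @param fixedLabel optional label ("H" or "V") overriding classification.
#' @return data.frame with `molecule_id`, `time`, `label`, `theta`
#'   (degrees, `[0, 360)`; `NA` on transit frames or degenerate
#'   projections) and `theta_unwrapped`.
#' @export
thetaRotation <- function(traj, classmap, orientation = NULL, stride = 100,
                          fixedLabel = NULL) {
  mols <- xanMolecules(traj, classmap)
  times <- frameTimes(traj)
  dt <- frameSpacing(traj)
  step <- max(1L, round(stride / dt))
  sample <- seq(1L, nFrames(traj), by = step)
  metName <- classmap@roles$met_theta$atoms
  out <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    id <- mols$molecule_id[i]
    met <- .residueAtoms(traj, mols$resname[i], mols$resid[i], metName)
    c13 <- .residueAtoms(traj, mols$resname[i], mols$resid[i],
                         classmap@roles$C13$atoms)
    c3 <- .residueAtoms(traj, mols$resname[i], mols$resid[i],
                        classmap@roles$C3$atoms)
    c3p <- .residueAtoms(traj, mols$resname[i], mols$resid[i],
                         classmap@roles$C3prime$atoms)
    if (length(met) != 1 || length(c13) != 1)
      stop("MET-C13 pairing undefined for ", id)
    labs <- if (!is.null(fixedLabel)) rep(fixedLabel, length(sample))
            else orientation$perMolecule[[id]]$data$label[sample]
    theta <- rep(NA_real_, length(sample))
    for (s in seq_along(sample)) {
      f <- sample[s]
      b <- traj@coords[c13, , f] - traj@coords[met, , f]
      if (labs[s] == "V") {
        if (sum(b[1:2]^2) < 1e-12) next   # degenerate projection
        theta[s] <- (atan2(b[2], b[1]) * 180 / pi) %% 360
      } else if (labs[s] == "H") {
        u <- traj@coords[c3p, , f] - traj@coords[c3, , f]
        u[3] <- 0
        nu <- sqrt(sum(u^2))
        if (nu < 1e-12) next
        u <- u / nu
        comp <- c(sum(b * u), b[3])
        if (sum(comp^2) < 1e-12) next
        theta[s] <- (atan2(comp[1], comp[2]) * 180 / pi) %% 360
      }
    }
    unwrapped <- rep(NA_real_, length(theta))
    prev <- NA_real_; acc <- NA_real_
    for (s in seq_along(theta)) {
      if (is.na(theta[s])) next
      if (is.na(prev)) acc <- theta[s]
      else acc <- acc + wrapAngle(theta[s] - prev)
      unwrapped[s] <- acc
      prev <- theta[s]
    }
    out[[i]] <- data.frame(molecule_id = id, time = times[sample],
                           label = labs, theta = theta,
                           theta_unwrapped = unwrapped,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Apparent molecular length (C3 to C3')
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @return list with `series` (data.frame `molecule_id`, `time`, `length`
#'   in Angstrom), `mean` and `sd`.
#' @export
molecularLength <- function(traj, classmap) {
  mols <- xanMolecules(traj, classmap)
  if (!nrow(mols)) stop("no xanthophyll molecules found")
  out <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    c3 <- .residueAtoms(traj, mols$resname[i], mols$resid[i],
                        classmap@roles$C3$atoms)
    c3p <- .residueAtoms(traj, mols$resname[i], mols$resid[i],
                         classmap@roles$C3prime$atoms)
    if (length(c3) != 1 || length(c3p) != 1)
      stop("C3/C3' atoms missing for ", mols$molecule_id[i])
    len <- vapply(seq_len(nFrames(traj)), function(f)
      minImageDistance(traj@coords[c3, , f], traj@coords[c3p, , f],
                       boxLengths(traj, f)), numeric(1))
    out[[i]] <- data.frame(molecule_id = mols$molecule_id[i],
                           time = frameTimes(traj), length = len,
                           stringsAsFactors = FALSE)
  }
  series <- do.call(rbind, out)
  list(series = series, mean = mean(series$length), sd = stats::sd(series$length))
}

#' Hydrophobic width of the bilayer
#'
#' Distance along z between the leaflet mean carbonyl-oxygen (Oc) planes;
#' `method = "acyl"` switches to the acyl-carbon planes.
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @param method `"carbonyl"` (default) or `"acyl"`.
#' @return list with `series` (data.frame `time`, `width` in Angstrom),
#'   `mean` and `sd`.
#' @export
hydrophobicWidth <- function(traj, classmap, method = c("carbonyl", "acyl")) {
  method <- match.arg(method)
  role <- if (method == "carbonyl") "Oc" else "acyl_C"
  idx <- selectAtoms(traj, classmap, role, require = TRUE)
  pIdx <- selectAtoms(traj, classmap, "P", require = TRUE)
  nf <- nFrames(traj)
  width <- numeric(nf)
  for (f in seq_len(nf)) {
    centre <- mean(traj@coords[pIdx, 3, f])
    z <- traj@coords[idx, 3, f]
    up <- z > centre
    width[f] <- mean(z[up]) - mean(z[!up])
  }
  series <- data.frame(time = frameTimes(traj), width = width)
  list(series = series, mean = mean(width), sd = stats::sd(width))
}

#' Xanthophyll-xanthophyll contact (aggregation) episodes
#'
#' Reports episodes where the minimum heavy-atom minimum-image distance
#' between two xanthophylls stays below `cutoff` for at least `minFrames`
#' consecutive frames; transient single-frame contacts are not episodes.
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @param cutoff distance cutoff, Angstrom (default 5).
#' @param minFrames minimum consecutive frames (default 5).
#' @return data.frame with `mol_a`, `mol_b`, `start`, `end` (ps),
#'   `n_frames`, `min_distance`.
#' @export
checkAggregation <- function(traj, classmap, cutoff = 5, minFrames = 5) {
  mols <- xanMolecules(traj, classmap)
  if (nrow(mols) < 2) stop("need at least 2 xanthophyll molecules")
  top <- atoms(traj)
  heavy <- lapply(seq_len(nrow(mols)), function(i) {
    idx <- .residueAtoms(traj, mols$resname[i], mols$resid[i])
    idx[top$element[idx] != "H"]
  })
  nf <- nFrames(traj)
  episodes <- list()
  for (i in seq_len(nrow(mols))) for (j in seq_len(i - 1L)) {
    dmin <- vapply(seq_len(nf), function(f) {
      A <- traj@coords[heavy[[i]], , f, drop = FALSE]; dim(A) <- c(length(heavy[[i]]), 3L)
      B <- traj@coords[heavy[[j]], , f, drop = FALSE]; dim(B) <- c(length(heavy[[j]]), 3L)
      min(.pbcDistMatrix(A, B, boxLengths(traj, f)))
    }, numeric(1))
    r <- rle(dmin < cutoff)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= minFrames)
    for (k in keep)
      episodes[[length(episodes) + 1L]] <- data.frame(
        mol_a = mols$molecule_id[j], mol_b = mols$molecule_id[i],
        start = frameTimes(traj)[starts[k]],
        end = frameTimes(traj)[ends[k]], n_frames = r$lengths[k],
        min_distance = min(dmin[starts[k]:ends[k]]),
        stringsAsFactors = FALSE)
  }
  if (!length(episodes))
    return(data.frame(mol_a = character(), mol_b = character(),
                      start = numeric(), end = numeric(),
                      n_frames = integer(), min_distance = numeric()))
  do.call(rbind, episodes)
}
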