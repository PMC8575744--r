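#' @include geometry.R atom-class-map.R
NULL

#' Torsion specification
#'
#' @param name label for the torsion (e.g. `"eps_ring"`).
#' @param atomNames four atom names, in bonded order, looked up within each
#'   xanthophyll residue.
#' @return a list of class `torsionSpec`.
#' @export
torsionSpec <- function(name, atomNames) {
  stopifnot(length(atomNames) == 4, !anyDuplicated(atomNames))
  structure(list(name = name, atoms = as.character(atomNames)),
            class = "torsionSpec")
}

#' Ring-torsion specifications for the two hopping rotations
#'
#' The epsilon-ring torsion is C5'-C6'-C7'-C8' (primed atoms carry a `P`
#' suffix); the beta-ring torsion is C5-C6-C7-C8.
#'
#' @return named list of [torsionSpec()] objects (`eps`, `beta`).
#' @export
defaultTorsionSpecs <- function() {
  list(eps = torsionSpec("eps_ring", c("C5P", "C6P", "C7P", "C8P")),
       beta = torsionSpec("beta_ring", c("C5", "C6", "C7", "C8")))
}

# vectorised dihedral over frames for fixed four atoms; xi are nF x 3
.dihedralSeries <- function(x1, x2, x3, x4) {
  b1 <- x2 - x1; b2 <- x3 - x2; b3 <- x4 - x3
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  nb2 <- sqrt(rowSums(b2 * b2))
  m1 <- cr(n1, b2 / nb2)
  ang <- -atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Extract per-molecule torsion-angle time series
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap] (identifies the xanthophyll residues).
#' @param spec a [torsionSpec()].
#' @return data.frame with columns `molecule_id`, `time` (ps), `angle`
#'   (degrees, (-180, 180]), `spec`.
#' @export
extractTorsions <- function(traj, classmap, spec) {
  mols <- xanMolecules(traj, classmap)
  if (!nrow(mols)) stop("no xanthophyll molecules found")
  nf <- nFrames(traj)
  out <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    idx <- vapply(spec$atoms, function(a) {
      j <- .residueAtoms(traj, mols$resname[i], mols$resid[i], a)
      if (length(j) != 1L)
        stop("torsion atom '", a, "' not found (or not unique) in ",
             mols$molecule_id[i])
      j
    }, integer(1))
    getxyz <- function(j) {
      m <- traj@coords[j, , , drop = FALSE]
      dim(m) <- c(3L, nf)
      t(m)
    }
    ang <- .dihedralSeries(getxyz(idx[1]), getxyz(idx[2]),
                           getxyz(idx[3]), getxyz(idx[4]))
    out[[i]] <- data.frame(molecule_id = mols$molecule_id[i],
                           time = frameTimes(traj), angle = ang,
                           spec = spec$name, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Normalised circular population histogram of torsion angles
#'
#' Densities, not counts, so trajectories of different length compare;
#' `sum(density) * binWidth == 1`.
#'
#' @param angles angles in degrees (any wrap).
#' @param binWidth bin width in degrees; must divide 360 (default 5).
#' @return data.frame with `mid`, `lower`, `upper`, `count`, `density`.
#' @export
torsionHistogram <- function(angles, binWidth = 5) {
  if (!length(angles)) stop("empty angle series")
  if (abs(360 / binWidth - round(360 / binWidth)) > 1e-9)
    stop("binWidth must divide 360")
  a <- wrapAngle(angles)
  breaks <- seq(-180, 180, by = binWidth)
  # (-180, 180] binning: right-closed
  cnt <- as.integer(table(cut(a, breaks, right = TRUE,
                              include.lowest = FALSE)))
  data.frame(mid = breaks[-1] - binWidth / 2,
             lower = breaks[-length(breaks)], upper = breaks[-1],
             count = cnt, density = cnt / (length(a) * binWidth))
}

#' Default two-state definitions for the ring torsions
#'
#' Epsilon ring: states centred at 130 and -50 degrees (half-width 40,
#' covering the observed 100..150 oscillation band); beta ring: 30 and -30
#' degrees (half-width 25, keeping the windows disjoint).
#'
#' @param ring `"eps"` or `"beta"`.
#' @return data.frame with `label`, `centre`, `halfWidth` (degrees).
#' @export
defaultTorsionStates <- function(ring = c("eps", "beta")) {
  ring <- match.arg(ring)
  if (ring == "eps")
    data.frame(label = c("E130", "E50"), centre = c(130, -50),
               halfWidth = c(40, 40), stringsAsFactors = FALSE)
  else
    data.frame(label = c("B30", "Bm30"), centre = c(30, -30),
               halfWidth = c(25, 25), stringsAsFactors = FALSE)
}

.checkStatesDisjoint <- function(states) {
  n <- nrow(states)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    sep <- abs(wrapAngle(states$centre[i] - states$centre[j]))
    if (sep <= states$halfWidth[i] + states$halfWidth[j])
      stop("state windows overlap: ", states$label[i], " / ", states$label[j])
  }
}

#' Assign torsion angles to discrete states and count transitions
#'
#' A frame is labelled with the state whose circular window
#' `centre +/- halfWidth` contains the angle, else `"unassigned"`.  A
#' transition between assigned states is recorded when the new state
#' persists for at least `minDwell` ps; shorter excursions are ignored
#' (with `minDwell = 0` every label change between assigned states counts).
#'
#' @param angles angles in degrees.
#' @param times frame times in ps (same length).
#' @param states state definition data.frame ([defaultTorsionStates()]).
#' @param minDwell minimum persistence in ps (default 0).
#' @return list with `labels` (character per frame), `transitions`
#'   (data.frame `time`, `from`, `to`) and `dwells` (data.frame `state`,
#'   `start`, `duration` — one row per maximal run of an assigned label).
#' @export
assignStates <- function(angles, times, states, minDwell = 0) {
  stopifnot(length(angles) == length(times))
  .checkStatesDisjoint(states)
  a <- wrapAngle(angles)
  labels <- rep("unassigned", length(a))
  for (i in seq_len(nrow(states))) {
    inwin <- abs(wrapAngle(a - states$centre[i])) <= states$halfWidth[i]
    labels[inwin] <- states$label[i]
  }
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  assigned <- r$values != "unassigned"
  dwells <- data.frame(state = r$values[assigned],
                       start = times[starts[assigned]],
                       duration = r$lengths[assigned] * dt,
                       stringsAsFactors = FALSE)
  transitions <- data.frame(time = numeric(), from = character(),
                            to = character(), stringsAsFactors = FALSE)
  cur <- NA_character_
  for (k in seq_along(r$values)) {
    st <- r$values[k]
    if (st == "unassigned") next
    if (is.na(cur)) { cur <- st; next }
    if (st != cur) {
      if (r$lengths[k] * dt >= minDwell) {
        transitions <- rbind(transitions, data.frame(
          time = times[starts[k]], from = cur, to = st,
          stringsAsFactors = FALSE))
        cur <- st
      }
    }
  }
  list(labels = labels, transitions = transitions, dwells = dwells)
}

#' Hopping-rotation summary over all molecules
#'
#' Applies [assignStates()] per molecule and reports per-molecule and
#' pooled transition counts, as rates per microsecond, plus the dwell-time
#' table.  Zero-transition molecules are reported as such.
#'
#' @param torsions output of [extractTorsions()].
#' @param states state definitions.
#' @param minDwell minimum persistence in ps.
#' @return list with `perMolecule` (data.frame `molecule_id`,
#'   `n_transitions`, `span_ps`, `rate_per_us`), `transitions`, `dwells`
#'   (both pooled, with a `molecule_id` column) and `total_transitions`.
#' @export
countHopping <- function(torsions, states, minDwell = 0) {
  ids <- unique(torsions$molecule_id)
  if (!length(ids)) stop("no torsion traces supplied")
  per <- vector("list", length(ids))
  trs <- list(); dws <- list()
  for (i in seq_along(ids)) {
    d <- torsions[torsions$molecule_id == ids[i], ]
    st <- assignStates(d$angle, d$time, states, minDwell)
    span <- diff(range(d$time))
    per[[i]] <- data.frame(molecule_id = ids[i],
                           n_transitions = nrow(st$transitions),
                           span_ps = span,
                           rate_per_us = if (span > 0)
                             nrow(st$transitions) / (span / 1e6) else NA_real_,
                           stringsAsFactors = FALSE)
    if (nrow(st$transitions)) {
      st$transitions$molecule_id <- ids[i]
      trs[[length(trs) + 1L]] <- st$transitions
    }
    if (nrow(st$dwells)) {
      st$dwells$molecule_id <- ids[i]
      dws[[length(dws) + 1L]] <- st$dwells
    }
  }
  perMolecule <- do.call(rbind, per)
  list(perMolecule = perMolecule,
       transitions = if (length(trs)) do.call(rbind, trs) else
         data.frame(time = numeric(), from = character(), to = character(),
                    molecule_id = character()),
       dwells = if (length(dws)) do.call(rbind, dws) else
         data.frame(state = character(), start = numeric(),
                    duration = numeric(), molecule_id = character()),
       total_transitions = sum(perMolecule$n_transitions))
}
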