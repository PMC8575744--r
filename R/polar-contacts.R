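#' @include geometry.R atom-class-map.R
NULL

#' Geometric hydrogen-bond criteria
#'
#' Defaults: donor-acceptor oxygen distance <= 3.25 Angstrom and
#' donor-H...acceptor angle (vertex at the hydrogen) >= 135 degrees.  The
#' criteria are always carried along in summaries; cutoffs are never
#' implicit.
#'
#' @param maxDistance donor-acceptor distance cutoff, Angstrom.
#' @param minAngle minimum D-H...A angle, degrees, in (0, 180].
#' @return list of class `hbondCriteria`.
#' @export
hbondCriteria <- function(maxDistance = 3.25, minAngle = 135) {
  stopifnot(maxDistance > 0, minAngle > 0, minAngle <= 180)
  structure(list(maxDistance = maxDistance, minAngle = minAngle),
            class = "hbondCriteria")
}

#' Charge-pair criteria
#'
#' A hydroxyl oxygen and a choline group form a charge pair when the
#' minimum-image distance from the oxygen to any choline methyl carbon or
#' the nitrogen is within the cutoff.
#'
#' @param maxDistance cutoff, Angstrom (default 4.0).
#' @return list of class `chargePairCriteria`.
#' @export
chargePairCriteria <- function(maxDistance = 4.0) {
  stopifnot(maxDistance > 0)
  structure(list(maxDistance = maxDistance), class = "chargePairCriteria")
}

# xanthophyll hydroxyl groups: O3 (beta ring) / O3P (eps ring) with their H
.ohGroups <- function(traj, classmap) {
  mols <- xanMolecules(traj, classmap)
  top <- atoms(traj)
  rows <- list()
  for (i in seq_len(nrow(mols))) {
    for (ring in c("beta", "eps")) {
      oName <- if (ring == "beta") "O3" else "O3P"
      hName <- if (ring == "beta") "H3O" else "H3P"
      o <- .residueAtoms(traj, mols$resname[i], mols$resid[i], oName)
      if (!length(o)) next
      h <- .residueAtoms(traj, mols$resname[i], mols$resid[i], hName)
      if (length(h) != 1L)
        stop("configuration error: hydroxyl oxygen ", oName, " of ",
             mols$molecule_id[i], " has no hydrogen in the topology")
      rows[[length(rows) + 1L]] <- data.frame(
        oh_id = paste0(mols$molecule_id[i], ":", ring),
        molecule_id = mols$molecule_id[i], ring = ring,
        o_idx = o, h_idx = h, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no xanthophyll OH groups found")
  do.call(rbind, rows)
}

# partner atoms for a PC-oxygen class or water oxygens
.partnerAtoms <- function(traj, classmap, class) {
  top <- atoms(traj)
  if (class == "water") {
    idx <- selectAtoms(traj, classmap, "water_O")
    if (!length(idx)) return(NULL)
    return(data.frame(atom_idx = idx,
                      partner_id = paste0(top$resname[idx], top$resid[idx]),
                      stringsAsFactors = FALSE))
  }
  role <- if (class == "Op") "Op" else "Oc"
  idx <- selectAtoms(traj, classmap, role)
  if (class %in% c("O22", "O32")) idx <- idx[top$name[idx] == class]
  if (!length(idx)) return(NULL)
  data.frame(atom_idx = idx,
             partner_id = paste0(top$resname[idx], top$resid[idx], ":",
                                 top$name[idx]),
             stringsAsFactors = FALSE)
}

# D-H...A angles (degrees, vertex at H) for acceptor coordinate rows A
.dhaAngles <- function(xyzD, xyzH, A, box) {
  vD <- .pbcDiff(matrix(xyzD, 1, 3), xyzH, box)
  vA <- .pbcDiff(A, xyzH, box)
  nD <- sqrt(sum(vD * vD))
  cosv <- (vA %*% t(vD)) / (sqrt(rowSums(vA * vA)) * nD)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' A donor-acceptor pair is bonded when the minimum-image O...A distance is
#' within the cutoff and the D-H...A angle meets the minimum.  Xanthophyll
#' OH groups are evaluated as donors towards PC oxygens and water, and as
#' acceptors from water (both directions for OH/water).
#'
#' @param traj a [Trajectory].
#' @param frame frame index.
#' @param classmap an [AtomClassMap].
#' @param criteria an [hbondCriteria()].
#' @param partners partner classes to scan (default Op, O22, O32, water).
#' @return data.frame with `oh_id`, `molecule_id`, `ring`, `partner_class`,
#'   `partner_id`, `direction` (`"oh_donor"` or `"water_donor"`).
#' @export
detectHBonds <- function(traj, frame, classmap, criteria = hbondCriteria(),
                         partners = c("Op", "O22", "O32", "water")) {
  ohs <- .ohGroups(traj, classmap)
  box <- boxLengths(traj, frame)
  xyz <- coords(traj, frame)
  top <- atoms(traj)
  waterH <- selectAtoms(traj, classmap, "water_H")
  out <- list()
  for (cl in partners) {
    pa <- .partnerAtoms(traj, classmap, cl)
    if (is.null(pa)) next
    A <- xyz[pa$atom_idx, , drop = FALSE]
    for (g in seq_len(nrow(ohs))) {
      xo <- xyz[ohs$o_idx[g], ]; xh <- xyz[ohs$h_idx[g], ]
      d <- sqrt(rowSums(.pbcDiff(A, xo, box)^2))
      cand <- which(d <= criteria$maxDistance)
      if (length(cand)) {
        ang <- .dhaAngles(xo, xh, A[cand, , drop = FALSE], box)
        hit <- cand[ang >= criteria$minAngle]
        for (k in hit)
          out[[length(out) + 1L]] <- data.frame(
            oh_id = ohs$oh_id[g], molecule_id = ohs$molecule_id[g],
            ring = ohs$ring[g], partner_class = cl,
            partner_id = pa$partner_id[k], direction = "oh_donor",
            stringsAsFactors = FALSE)
      }
      if (cl == "water" && length(cand)) {
        # water as donor towards the hydroxyl oxygen
        for (k in cand) {
          wresid <- top$resid[pa$atom_idx[k]]
          wh <- waterH[top$resid[waterH] == wresid &
                       top$resname[waterH] == top$resname[pa$atom_idx[k]]]
          if (!length(wh)) next
          ow <- xyz[pa$atom_idx[k], ]
          bonded <- FALSE
          for (hidx in wh) {
            ang <- .dhaAngles(ow, xyz[hidx, ], matrix(xo, 1, 3), box)
            if (ang >= criteria$minAngle) { bonded <- TRUE; break }
          }
          if (bonded)
            out[[length(out) + 1L]] <- data.frame(
              oh_id = ohs$oh_id[g], molecule_id = ohs$molecule_id[g],
              ring = ohs$ring[g], partner_class = "water",
              partner_id = pa$partner_id[k], direction = "water_donor",
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(oh_id = character(), molecule_id = character(),
                      ring = character(), partner_class = character(),
                      partner_id = character(), direction = character()))
  unique(do.call(rbind, out))
}

# water-donor H-bonds from water oxygens to PC oxygens of given classes;
# returns data.frame(water_id, partner_class, partner_id)
.waterPcHbonds <- function(traj, frame, classmap, criteria,
                           pcClasses = c("Op", "O22", "O32")) {
  box <- boxLengths(traj, frame)
  xyz <- coords(traj, frame)
  top <- atoms(traj)
  wO <- selectAtoms(traj, classmap, "water_O")
  wH <- selectAtoms(traj, classmap, "water_H")
  out <- list()
  for (cl in pcClasses) {
    pa <- .partnerAtoms(traj, classmap, cl)
    if (is.null(pa)) next
    A <- xyz[pa$atom_idx, , drop = FALSE]
    for (wi in wO) {
      xo <- xyz[wi, ]
      d <- sqrt(rowSums(.pbcDiff(A, xo, box)^2))
      cand <- which(d <= criteria$maxDistance)
      if (!length(cand)) next
      wh <- wH[top$resid[wH] == top$resid[wi] &
               top$resname[wH] == top$resname[wi]]
      ok <- rep(FALSE, length(cand))
      for (hidx in wh) {
        ang <- .dhaAngles(xo, xyz[hidx, ], A[cand, , drop = FALSE], box)
        ok <- ok | (ang >= criteria$minAngle)
      }
      for (k in cand[ok])
        out[[length(out) + 1L]] <- data.frame(
          water_id = paste0(top$resname[wi], top$resid[wi]),
          partner_class = cl, partner_id = pa$partner_id[k],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(water_id = character(), partner_class = character(),
                      partner_id = character()))
  unique(do.call(rbind, out))
}

#' Detect water bridges in one frame
#'
#' A hydroxyl group and a PC oxygen are bridged when some water molecule is
#' simultaneously H-bonded (either direction) to the hydroxyl and H-bonded
#' to the PC oxygen in the same frame.  Multiplicity is counted once per
#' (OH, PC-oxygen) pair: two waters bridging the same pair are one bridge.
#'
#' @inheritParams detectHBonds
#' @param pcClasses PC-oxygen classes eligible as the far end.
#' @return data.frame with `oh_id`, `molecule_id`, `ring`, `partner_class`,
#'   `partner_id`, `n_waters`.
#' @export
detectWaterBridges <- function(traj, frame, classmap,
                               criteria = hbondCriteria(),
                               pcClasses = c("Op", "O22", "O32")) {
  ohw <- detectHBonds(traj, frame, classmap, criteria, partners = "water")
  empty <- data.frame(oh_id = character(), molecule_id = character(),
                      ring = character(), partner_class = character(),
                      partner_id = character(), n_waters = integer())
  if (!nrow(ohw)) return(empty)
  wpc <- .waterPcHbonds(traj, frame, classmap, criteria, pcClasses)
  if (!nrow(wpc)) return(empty)
  m <- merge(unique(ohw[, c("oh_id", "molecule_id", "ring", "partner_id")]),
             wpc, by.x = "partner_id", by.y = "water_id")
  if (!nrow(m)) return(empty)
  agg <- stats::aggregate(list(n_waters = m$partner_id),
                          by = list(oh_id = m$oh_id,
                                    molecule_id = m$molecule_id,
                                    ring = m$ring,
                                    partner_class = m$partner_class,
                                    partner_id = m$partner_id.y),
                          FUN = length)
  agg[, c("oh_id", "molecule_id", "ring", "partner_class", "partner_id",
          "n_waters")]
}

#' Detect choline charge pairs in one frame
#'
#' @inheritParams detectHBonds
#' @param criteria a [chargePairCriteria()].
#' @return data.frame with `oh_id`, `molecule_id`, `ring`, `partner_class`
#'   (`"choline"`), `partner_id` (lipid), `min_distance`.
#' @export
detectChargePairs <- function(traj, frame, classmap,
                              criteria = chargePairCriteria()) {
  ohs <- .ohGroups(traj, classmap)
  box <- boxLengths(traj, frame)
  xyz <- coords(traj, frame)
  top <- atoms(traj)
  cho <- c(selectAtoms(traj, classmap, "choline_N", require = TRUE),
           selectAtoms(traj, classmap, "choline_CH3"))
  lipid <- paste0(top$resname[cho], top$resid[cho])
  A <- xyz[cho, , drop = FALSE]
  out <- list()
  for (g in seq_len(nrow(ohs))) {
    d <- sqrt(rowSums(.pbcDiff(A, xyz[ohs$o_idx[g], ], box)^2))
    dmin <- tapply(d, lipid, min)
    hit <- names(dmin)[dmin <= criteria$maxDistance]
    for (lp in hit)
      out[[length(out) + 1L]] <- data.frame(
        oh_id = ohs$oh_id[g], molecule_id = ohs$molecule_id[g],
        ring = ohs$ring[g], partner_class = "choline", partner_id = lp,
        min_distance = unname(dmin[lp]), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(oh_id = character(), molecule_id = character(),
                      ring = character(), partner_class = character(),
                      partner_id = character(), min_distance = numeric()))
  do.call(rbind, out)
}
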