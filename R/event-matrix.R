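#' @include polar-contacts.R
NULL

#' Boolean pair-by-frame record of firm bonding
#'
#' Each row tracks one interaction pair (a xanthophyll OH group and a
#' specific partner: PC oxygen atom, water molecule or choline group);
#' entry `[p, f]` is `TRUE` when the pair satisfies the geometric criteria
#' at frame `f` ("firm bonding").
#'
#' @slot type interaction type: `"hbond"`, `"water_bridge"` or
#'   `"charge_pair"` (or `"telegraph"` for synthetic matrices).
#' @slot pairs data.frame with `pair_id`, `oh_id`, `molecule_id`, `ring`,
#'   `partner_class`, `partner_id`.
#' @slot events logical matrix, pairs x frames.
#' @slot times frame times, ps.
#' @export
setClass("BondEventMatrix",
  representation(type = "character", pairs = "data.frame",
                 events = "matrix", times = "numeric"))

setValidity("BondEventMatrix", function(object) {
  msgs <- character()
  if (!is.logical(object@events))
    msgs <- c(msgs, "events must be a logical matrix")
  if (nrow(object@events) != nrow(object@pairs))
    msgs <- c(msgs, "pair table and event matrix disagree in pair count")
  if (ncol(object@events) != length(object@times))
    msgs <- c(msgs, "event matrix and times disagree in frame count")
  if (anyDuplicated(object@pairs$pair_id))
    msgs <- c(msgs, "pair ids must be unique")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BondEventMatrix", function(object) {
  cat("BondEventMatrix (", object@type, "): ", nrow(object@pairs),
      " pairs x ", length(object@times), " frames; fill ",
      sprintf("%.3f", mean(object@events)), "\n", sep = "")
})

#' @rdname pairInfo
#' @export
setMethod("pairInfo", "BondEventMatrix", function(x) x@pairs)

#' @rdname eventMatrix
#' @export
setMethod("eventMatrix", "BondEventMatrix", function(x) x@events)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "BondEventMatrix", function(x) x@times)

#' Construct a BondEventMatrix from raw parts
#'
#' @param type interaction type string.
#' @param pairs pair table (see class slots); missing descriptive columns
#'   are filled with `NA`.
#' @param events logical pairs x frames matrix.
#' @param times frame times, ps.
#' @return a [BondEventMatrix].
#' @export
newBondEventMatrix <- function(type, pairs, events, times) {
  for (col in c("pair_id", "oh_id", "molecule_id", "ring", "partner_class",
                "partner_id"))
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_character_
  new("BondEventMatrix", type = type, pairs = as.data.frame(pairs),
      events = events, times = as.numeric(times))
}

#' Build the firm-bonding matrix over a trajectory
#'
#' Runs the frame-level detector for the chosen interaction type on every
#' frame (at `stride` ps) and assembles the boolean pair x frame matrix;
#' any pair bonded in at least one frame gets a row.
#'
#' @param traj a [Trajectory] with uniform frame spacing.
#' @param classmap an [AtomClassMap].
#' @param type `"hbond"`, `"water_bridge"` or `"charge_pair"`.
#' @param criteria [hbondCriteria()] (or [chargePairCriteria()] for charge
#'   pairs); `NULL` uses the defaults.
#' @param partners partner classes for H-bonds.
#' @param stride sampling interval, ps (default 1: every recorded frame).
#' @return a [BondEventMatrix].
#' @export
buildEventMatrix <- function(traj, classmap,
                             type = c("hbond", "water_bridge", "charge_pair"),
                             criteria = NULL,
                             partners = c("Op", "O22", "O32", "water"),
                             stride = 1) {
  type <- match.arg(type)
  dt <- frameSpacing(traj)
  step <- if (is.na(dt)) 1L else max(1L, round(stride / dt))
  frames <- seq(1L, nFrames(traj), by = step)
  if (is.null(criteria))
    criteria <- if (type == "charge_pair") chargePairCriteria()
                else hbondCriteria()
  det <- switch(type,
    hbond = function(f) detectHBonds(traj, f, classmap, criteria, partners),
    water_bridge = function(f) detectWaterBridges(traj, f, classmap, criteria),
    charge_pair = function(f) detectChargePairs(traj, f, classmap, criteria))
  hits <- lapply(frames, det)
  allPairs <- unique(do.call(rbind, lapply(hits, function(h)
    h[, c("oh_id", "molecule_id", "ring", "partner_class", "partner_id")])))
  if (is.null(allPairs) || !nrow(allPairs)) {
    return(newBondEventMatrix(type,
      data.frame(pair_id = character(), oh_id = character(),
                 molecule_id = character(), ring = character(),
                 partner_class = character(), partner_id = character()),
      matrix(logical(), 0, length(frames)), frameTimes(traj)[frames]))
  }
  allPairs$pair_id <- paste(allPairs$oh_id, allPairs$partner_id, sep = "|")
  allPairs <- allPairs[!duplicated(allPairs$pair_id), ]
  rownames(allPairs) <- NULL
  ev <- matrix(FALSE, nrow(allPairs), length(frames))
  for (k in seq_along(hits)) {
    h <- hits[[k]]
    if (!nrow(h)) next
    ids <- unique(paste(h$oh_id, h$partner_id, sep = "|"))
    ev[match(ids, allPairs$pair_id), k] <- TRUE
  }
  newBondEventMatrix(type, allPairs, ev, frameTimes(traj)[frames])
}

#' Time-and-ensemble contact summary (table shape of the per-ps counts)
#'
#' Per ring (eps/beta) and partner class: the mean and sd over all
#' (OH group, frame) combinations of the per-frame bonded-pair count of
#' that OH group.  With orientation labels supplied, rows are further split
#' by the molecule's H/V label at the frame; transit frames are excluded.
#' An `All` row sums the PC-oxygen classes (Op + O22 + O32) before
#' averaging, so `All = sum of the parts` exactly.
#'
#' @param bem a [BondEventMatrix].
#' @param orientation optional output of [classifyAllOrientations()].
#' @return data.frame with `ring`, `partner_class`, `orientation`, `mean`,
#'   `sd`, `n` (number of OH-frame observations).
#' @export
summarizeContacts <- function(bem, orientation = NULL) {
  pairs <- pairInfo(bem)
  ev <- eventMatrix(bem)
  nf <- length(frameTimes(bem))
  ohs <- unique(pairs[, c("oh_id", "molecule_id", "ring")])
  classes <- unique(pairs$partner_class)
  pcClasses <- intersect(c("Op", "O22", "O32"), classes)
  labelOf <- function(mol) {
    if (is.null(orientation)) return(rep("all", nf))
    oc <- orientation$perMolecule[[mol]]
    if (is.null(oc)) return(rep(NA_character_, nf))
    # align orientation frames to matrix frames by time
    oc$data$label[match(frameTimes(bem), oc$data$time)]
  }
  rows <- list()
  addObs <- function(ring, cls, counts, labs) {
    for (lab in unique(labs[!is.na(labs) & labs != "transit"])) {
      sel <- which(labs == lab)
      rows[[length(rows) + 1L]] <<- data.frame(
        ring = ring, partner_class = cls, orientation = lab,
        obs_sum = sum(counts[sel]), obs_sq = sum(counts[sel]^2),
        n = length(sel), stringsAsFactors = FALSE)
    }
  }
  for (g in seq_len(nrow(ohs))) {
    labs <- labelOf(ohs$molecule_id[g])
    perClass <- list()
    for (cls in classes) {
      rowsSel <- pairs$oh_id == ohs$oh_id[g] & pairs$partner_class == cls
      counts <- if (any(rowsSel))
        colSums(ev[rowsSel, , drop = FALSE]) else rep(0, nf)
      perClass[[cls]] <- counts
      addObs(ohs$ring[g], cls, counts, labs)
    }
    if (length(pcClasses))
      addObs(ohs$ring[g], "All",
             Reduce(`+`, perClass[pcClasses]), labs)
  }
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(d[, c("obs_sum", "obs_sq", "n")],
                          by = d[, c("ring", "partner_class", "orientation")],
                          FUN = sum)
  agg$mean <- agg$obs_sum / agg$n
  v <- pmax(0, agg$obs_sq / agg$n - agg$mean^2)
  agg$sd <- sqrt(v * agg$n / pmax(1, agg$n - 1))
  agg[, c("ring", "partner_class", "orientation", "mean", "sd", "n")]
}

#' Firm-bonding episodes per pair (duration panels)
#'
#' Maximal runs of consecutive bonded frames per tracked pair -- the
#' dot-raster information of per-partner bonding history panels.
#'
#' @param bem a [BondEventMatrix].
#' @return data.frame with `pair_id`, `oh_id`, `partner_id`,
#'   `partner_class`, `start`, `end` (ps), `n_frames`.
#' @export
bondEpisodes <- function(bem) {
  pairs <- pairInfo(bem)
  ev <- eventMatrix(bem)
  times <- frameTimes(bem)
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    r <- rle(ev[p, ])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep)
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[p], oh_id = pairs$oh_id[p],
        partner_id = pairs$partner_id[p],
        partner_class = pairs$partner_class[p],
        start = times[starts[k]], end = times[ends[k]],
        n_frames = r$lengths[k], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(pair_id = character(), oh_id = character(),
                      partner_id = character(), partner_class = character(),
                      start = numeric(), end = numeric(),
                      n_frames = integer()))
  do.call(rbind, out)
}
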