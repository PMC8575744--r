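#' @include AllGenerics.R
NULL

# standard atomic masses (amu) used when a topology carries no masses
.ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

.elementFromName <- function(name) {
  # strip digits/primes, take the leading element symbol; two-letter symbols
  # are not needed for POPC/XAN/water chemistry
  el <- sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
  toupper(el)
}

#' Trajectory of named atoms with an orthorhombic box
#'
#' The central container: an atom topology shared by all frames, a stack of
#' coordinates in Angstrom, per-frame orthorhombic box lengths and time
#' stamps in ps.  All analysis stages consume this class.
#'
#' @slot topology data.frame with columns `index` (0-based), `name`,
#'   `resname`, `resid`, `element`, `mass` (amu).
#' @slot coords numeric array, atoms x 3 x frames, Angstrom.
#' @slot box numeric matrix, frames x 3, Angstrom; all entries positive.
#' @slot times numeric vector of frame times, ps, strictly increasing.
#'
#' @seealso [readTrajectory()], [writeTrajectory()], [newTrajectory()]
#' @export
setClass("Trajectory",
  representation(topology = "data.frame", coords = "array",
                 box = "matrix", times = "numeric"))

setValidity("Trajectory", function(object) {
  msgs <- character()
  top <- object@topology
  need <- c("index", "name", "resname", "resid", "element", "mass")
  if (!all(need %in% names(top)))
    msgs <- c(msgs, paste("topology must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(top$index))
      msgs <- c(msgs, "atom indices must be unique")
    if (any(!is.finite(top$mass)) || any(top$mass <= 0))
      msgs <- c(msgs, "atom masses must be positive")
  }
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msgs <- c(msgs, "coords must be an atoms x 3 x frames array")
  else {
    if (d[1] != nrow(top))
      msgs <- c(msgs, "coords atom count does not match topology")
    if (d[3] != length(object@times))
      msgs <- c(msgs, "frame count does not match times")
    if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
      msgs <- c(msgs, "box must be a frames x 3 matrix")
    else if (any(object@box <= 0))
      msgs <- c(msgs, "box lengths must be positive")
  }
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "frame times must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Trajectory
#'
#' @param topology data.frame with at least `name`, `resname`, `resid`;
#'   `index`, `element` and `mass` are filled in when absent (element from
#'   the leading letter of the atom name, mass from standard atomic masses).
#' @param coords atoms x 3 x frames array (Angstrom), or an atoms x 3 matrix
#'   for a single frame.
#' @param box frames x 3 matrix or length-3 vector recycled to all frames
#'   (Angstrom).
#' @param times frame times in ps; defaults to `0:(nframes-1)` (1 ps spacing).
#' @return a [Trajectory].
#' @export
newTrajectory <- function(topology, coords, box, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(topology$index)) topology$index <- seq_len(nrow(topology)) - 1L
  topology$resid <- as.integer(topology$resid)
  if (is.null(topology$element)) topology$element <- .elementFromName(topology$name)
  if (is.null(topology$mass)) {
    m <- .ELEMENT_MASSES[topology$element]
    if (any(is.na(m)))
      stop("unknown element(s): ",
           paste(unique(topology$element[is.na(m)]), collapse = ", "))
    topology$mass <- unname(m)
  }
  if (!is.matrix(box)) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  new("Trajectory", topology = as.data.frame(topology), coords = coords,
      box = box, times = as.numeric(times))
}

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology)

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, frame = NULL) {
  if (is.null(frame)) return(x@coords)
  x@coords[, , frame, drop = FALSE][, , 1]
})

#' @rdname boxLengths
#' @export
setMethod("boxLengths", "Trajectory", function(x, frame = NULL) {
  if (is.null(frame)) return(x@box)
  x@box[frame, ]
})

setMethod("show", "Trajectory", function(object) {
  nf <- nFrames(object)
  cat("Trajectory:", nAtoms(object), "atoms,", nf, "frames\n")
  cat("  residues:",
      paste(utils::head(unique(object@topology$resname), 6), collapse = " "),
      "\n")
  cat(sprintf("  time span: %.6g .. %.6g ps\n",
              object@times[1], object@times[nf]))
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A\n",
              object@box[1, 1], object@box[1, 2], object@box[1, 3]))
})

#' Frame spacing of a uniformly sampled trajectory
#'
#' @param traj a [Trajectory] with at least 2 frames.
#' @param tol relative non-uniformity tolerated (1e-6).
#' @return spacing in ps.
#' @export
frameSpacing <- function(traj, tol = 1e-6) {
  if (nFrames(traj) < 2) return(NA_real_)
  dt <- diff(frameTimes(traj))
  if (diff(range(dt)) > tol * max(dt))
    stop("trajectory is not uniformly sampled")
  dt[1]
}

#' Subset frames of a trajectory
#'
#' @param traj a [Trajectory].
#' @param frames integer frame indices (1-based, increasing).
#' @return a [Trajectory] restricted to those frames.
#' @export
subsetFrames <- function(traj, frames) {
  new("Trajectory", topology = traj@topology,
      coords = traj@coords[, , frames, drop = FALSE],
      box = traj@box[frames, , drop = FALSE],
      times = traj@times[frames])
}
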