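#' @include AllGenerics.R
NULL

#' Number of atoms in a topology-bearing object
#'
#' @param x an object with an atom topology, typically a [Trajectory].
#' @return integer scalar.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#'
#' @param x a [Trajectory] or other frame-indexed object.
#' @return integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame time stamps (ps)
#'
#' @param x a frame-indexed object.
#' @return numeric vector of times in ps.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Atom table of a trajectory
#'
#' @param x a [Trajectory].
#' @return data.frame with columns `index`, `name`, `resname`, `resid`,
#'   `element`, `mass`.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Coordinates of one frame or the whole stack
#'
#' @param x a [Trajectory].
#' @param frame frame index (1-based); `NULL` returns the full
#'   atoms x 3 x frames array.
#' @return numeric matrix (atoms x 3, Angstrom) or 3-d array.
#' @export
setGeneric("coords", function(x, frame = NULL) standardGeneric("coords"))

#' Box lengths (Angstrom)
#'
#' @param x a [Trajectory].
#' @param frame frame index; `NULL` returns the frames x 3 matrix.
#' @return numeric length-3 vector or matrix.
#' @export
setGeneric("boxLengths", function(x, frame = NULL) standardGeneric("boxLengths"))

#' Interaction pair table of a bond-event matrix
#'
#' @param x a [BondEventMatrix].
#' @return data.frame describing each tracked pair.
#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))

#' Boolean bonding matrix (pairs x frames)
#'
#' @param x a [BondEventMatrix].
#' @return logical matrix.
#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))

#' Fitted multi-exponential parameters
#'
#' @param x a [MultiExpFit].
#' @return data.frame with one row per component: `A` (percent), `T` (ps)
#'   and their standard errors.
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))
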