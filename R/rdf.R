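#' @include geometry.R atom-class-map.R
NULL

#' Minimum-image radial distribution function between two selections
#'
#' Pair-distance histogram under the minimum-image convention, normalised
#' by the ideal-gas expectation from the instantaneous box volume and the
#' target number density, averaged over frames.  Normalisation uses the
#' full orthorhombic box volume (not a slab-corrected density); the curves
#' are meant for comparative peak analysis.
#'
#' @param traj a [Trajectory].
#' @param selRef integer atom indices of the reference selection.
#' @param selTarget integer atom indices of the target selection.
#' @param rMax cutoff radius, Angstrom (default 10); must not exceed half
#'   the smallest box length.
#' @param binWidth bin width, Angstrom (default 0.1).
#' @param frames frame indices to average over (default all).
#' @return data.frame of class `rdfResult` with `r` (bin centres), `g`,
#'   and attributes `rMax`, `binWidth`, `nFrames`.
#' @export
computeRDF <- function(traj, selRef, selTarget, rMax = 10, binWidth = 0.1,
                       frames = seq_len(nFrames(traj))) {
  if (!length(selRef) || !length(selTarget))
    stop("empty selection in computeRDF")
  selfPairs <- length(intersect(selRef, selTarget)) > 0
  nbin <- ceiling(rMax / binWidth - 1e-9)
  counts <- numeric(nbin)
  norm <- numeric(nbin)
  shell <- 4 / 3 * pi * ((seq_len(nbin) * binWidth)^3 -
                         ((seq_len(nbin) - 1) * binWidth)^3)
  for (f in frames) {
    box <- boxLengths(traj, f)
    if (rMax > min(box) / 2)
      stop("rMax exceeds half the smallest box length (", min(box) / 2, " A)")
    A <- traj@coords[selRef, , f, drop = FALSE]; dim(A) <- c(length(selRef), 3L)
    B <- traj@coords[selTarget, , f, drop = FALSE]; dim(B) <- c(length(selTarget), 3L)
    D <- .pbcDistMatrix(A, B, box)
    if (selfPairs) {
      same <- outer(selRef, selTarget, "==")
      D[same] <- Inf
    }
    d <- D[D < rMax]
    if (length(d))
      counts <- counts + tabulate(pmin(nbin, floor(d / binWidth) + 1L), nbin)
    # ideal-gas expectation: target density x shell volume, per reference atom
    nTargetEff <- length(selTarget) - if (selfPairs) 1 else 0
    rho <- nTargetEff / prod(box)
    norm <- norm + length(selRef) * rho * shell
  }
  g <- ifelse(norm > 0, counts / norm, 0)
  out <- data.frame(r = (seq_len(nbin) - 0.5) * binWidth, g = g)
  attr(out, "rMax") <- rMax
  attr(out, "binWidth") <- binWidth
  attr(out, "nFrames") <- length(frames)
  class(out) <- c("rdfResult", "data.frame")
  out
}
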