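#' @include trajectory-class.R
NULL

#' Minimum-image distance under an orthorhombic box
#'
#' @param a,b numeric length-3 coordinates (Angstrom).
#' @param box length-3 positive box lengths (Angstrom).
#' @return the minimum-image Euclidean distance (Angstrom).
#' @export
minImageDistance <- function(a, b, box) {
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# vectorised minimum-image displacement: A (n x 3) minus b (length 3),
# or A minus B row-wise
.pbcDiff <- function(A, b, box) {
  D <- sweep(A, 2, b)
  D - sweep(round(sweep(D, 2, box, "/")), 2, box, "*")
}

# all minimum-image distances between rows of A (n x 3) and rows of B (m x 3):
# returns n x m matrix
.pbcDistMatrix <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: the eclipsed (cis) arrangement is 0 degrees, the
#' anti (trans) arrangement 180 degrees; result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom).
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1 * n1) < 1e-12 || sum(n2 * n2) < 1e-12)
    stop("undefined dihedral: collinear bond geometry")
  b2u <- b2 / sqrt(sum(b2 * b2))
  m1 <- .cross3(n1, b2u)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Wrap angles into (-180, 180]
#'
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrapAngle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Mass-weighted centre of mass of an atom selection
#'
#' No unwrapping across the periodic box is performed: molecules are assumed
#' whole within the cell (the synthetic generator guarantees this; see the
#' methods vignette for the caveat on real input).
#'
#' @param traj a [Trajectory].
#' @param selection integer atom indices (1-based).
#' @param frame frame index.
#' @return numeric length-3 centre of mass (Angstrom).
#' @export
centerOfMass <- function(traj, selection, frame) {
  if (!length(selection)) stop("empty selection in centerOfMass")
  m <- atoms(traj)$mass[selection]
  xyz <- traj@coords[selection, , frame, drop = FALSE][, , 1, drop = FALSE]
  dim(xyz) <- c(length(selection), 3L)
  colSums(xyz * m) / sum(m)
}

# per-frame z of the COM of a selection, whole trajectory (vectorised)
.comZSeries <- function(traj, selection) {
  m <- atoms(traj)$mass[selection]
  z <- traj@coords[selection, 3, , drop = FALSE]
  dim(z) <- c(length(selection), nFrames(traj))
  as.numeric(colSums(z * m) / sum(m))
}

#' Warn when a molecule appears split across the periodic boundary
#'
#' Flags any residue whose internal coordinate extent exceeds half the box
#' in some direction on the first frame; centre-of-mass results for such
#' molecules would be wrong without unwrapping.
#'
#' @param traj a [Trajectory].
#' @return invisibly, character vector of suspect residue labels.
#' @export
checkMoleculesWhole <- function(traj) {
  top <- atoms(traj)
  box <- boxLengths(traj, 1)
  xyz <- coords(traj, 1)
  key <- paste(top$resname, top$resid)
  bad <- character()
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    ext <- apply(xyz[rows, , drop = FALSE], 2, function(v) diff(range(v)))
    if (any(ext > box / 2)) bad <- c(bad, k)
  }
  if (length(bad))
    warning("residue(s) may be split across the periodic boundary: ",
            paste(utils::head(bad, 5), collapse = ", "))
  invisible(bad)
}
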