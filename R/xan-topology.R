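#' @include geometry.R
NULL

# ---- rigid pseudo-xanthophyll template ------------------------------------
#
# Local frame: long axis along z, C3 (beta end) at z = -L/2, C3' (primed,
# "eps" end) at +L/2.  The hydroxyls extend past the rod ends along the
# axis; the ring-torsion-defining atoms C5/C8 (and primed) sit off-axis so
# the C5-C6-C7-C8 dihedral is set by the azimuth of C5; MET methyl carbons
# sit off-axis on opposite sides of the two chain halves so the polyene
# plane has a well-defined up/down.

#' Pseudo-atom template of a rigid xanthophyll rod
#'
#' @param rodLength C3 to C3' distance, Angstrom (default 28.3).
#' @return data.frame with `name`, `x`, `y`, `z` (local frame) for the
#'   reference geometry (ring torsions at azimuth 0, plane sign +1).
#' @export
xanTopology <- function(rodLength = 28.3) {
  .xanLocalCoords(0, 0, +1, rodLength)
}

.xanLocalCoords <- function(azBeta, azEps, planeSign, L) {
  h <- L / 2
  p <- planeSign
  df <- function(name, x, y, z) data.frame(name = name, x = x, y = y, z = z,
                                           stringsAsFactors = FALSE)
  rows <- rbind(
    # beta end
    df("C3", 0, 0, -h),
    df("O3", 0, 0, -h - 1.4),
    df("H3O", 0, 0, -h - 2.36),
    df("C1", 1.2, 0.4, -h + 0.4),
    df("C2", 0.9, -0.6, -h + 0.2),
    df("C4", -0.9, 0.6, -h + 0.3),
    df("C6", 0, 0, -h + 0.9),
    df("C5", 1.3 * cos(azBeta * pi / 180), 1.3 * sin(azBeta * pi / 180),
       -h + 0.6),
    df("C7", 0, 0, -h + 2.3),
    df("C8", 1.3, 0, -h + 2.8),
    # polyene (beta half), MET methyls off-axis at +p on local y
    df("C9", 0, 0, -h + 5.0),
    df("C19", 0, p * 1.5, -h + 5.0),
    df("C11", 0, 0, -5.0),
    df("C13", 0, 0, -3.0),
    df("C20", 0, p * 1.5, -3.0),
    df("C15", 0, 0, -0.5),
    # eps (primed) end, mirrored; MET methyls at -p on local y
    df("C15P", 0, 0, 0.5),
    df("C11P", 0, 0, 5.0),
    df("C20P", 0, -p * 1.5, 3.0),
    df("C9P", 0, 0, h - 5.0),
    df("C19P", 0, -p * 1.5, h - 5.0),
    df("C8P", 1.3, 0, h - 2.8),
    df("C7P", 0, 0, h - 2.3),
    df("C5P", 1.3 * cos(azEps * pi / 180), 1.3 * sin(azEps * pi / 180),
       h - 0.6),
    df("C6P", 0, 0, h - 0.9),
    df("C4P", -0.9, 0.6, h - 0.3),
    df("C2P", 0.9, -0.6, h - 0.2),
    df("C1P", 1.2, 0.4, h - 0.4),
    df("C3P", 0, 0, h),
    df("O3P", 0, 0, h + 1.4),
    df("H3P", 0, 0, h + 2.36))
  rows
}

# azimuth -> measured dihedral is affine with slope +-1; calibrate once
.ringCalibration <- function(L = 28.3) {
  measure <- function(azB, azE) {
    m <- .xanLocalCoords(azB, azE, +1, L)
    rownames(m) <- m$name
    xyz <- function(nm) as.numeric(m[nm, c("x", "y", "z")])
    c(beta = dihedralAngle(xyz("C5"), xyz("C6"), xyz("C7"), xyz("C8")),
      eps = dihedralAngle(xyz("C5P"), xyz("C6P"), xyz("C7P"), xyz("C8P")))
  }
  d0 <- measure(0, 0)
  d1 <- measure(20, 20)
  slope <- sign(wrapAngle(d1 - d0))
  list(offset = d0, slope = slope)
}

# azimuths that realise the requested torsion angles (degrees)
.azimuthFor <- function(betaAngle, epsAngle, calib) {
  c(beta = unname(wrapAngle((betaAngle - calib$offset[["beta"]]) *
                              calib$slope[["beta"]])),
    eps = unname(wrapAngle((epsAngle - calib$offset[["eps"]]) *
                             calib$slope[["eps"]])))
}

.rotY <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}

.rotZ <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

# lab-frame coordinates of one xanthophyll at one frame.
# gamma: tilt from vertical (0 = transmembrane, 90 = horizontal, about lab y)
# spin: rotation about the molecular long axis (degrees)
# centre: lab position of the rod midpoint
.xanFrameCoords <- function(betaAngle, epsAngle, planeSign, gamma, spin,
                            centre, L, calib) {
  az <- .azimuthFor(betaAngle, epsAngle, calib)
  loc <- .xanLocalCoords(az["beta"], az["eps"], planeSign, L)
  R <- .rotY(gamma) %*% .rotZ(spin)
  xyz <- as.matrix(loc[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, centre, "+")
  list(names = loc$name, xyz = xyz)
}
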