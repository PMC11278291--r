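# Local cardiac coordinate frames (circumferential / radial / longitudinal)
# and conversion of tensor eigenvectors to helix, transverse, and sheetlet
# (|E2A|) angles under fixed sign conventions:
#   HA = atan2(e1.z_hat, e1.c_hat)  — 0 deg at circumferential, +90 at longitudinal
#   TA = atan2(e1.r_hat, e1.c_hat)  — positive toward the outward radial
#   |E2A| = |atan2(e2.r_hat, e2.t_hat)|, t_hat = normalized(r_hat x e1)

# Per-slice centroid of a mask (cavity preferred); falls back to wall.
.sliceCentroids <- function(primary, fallback) {
  d <- dim(primary)
  out <- matrix(NA_real_, d[3], 2)
  for (k in seq_len(d[3])) {
    m <- primary[, , k]
    if (!any(m)) m <- fallback[, , k]
    if (!any(m)) next
    idx <- which(m, arr.ind = TRUE)
    out[k, ] <- colMeans(idx)
  }
  out
}

# Per-slice Euclidean distance (in voxels) from every voxel to the nearest
# voxel of `target`, via EBImage's distance transform.
.sliceDistanceTo <- function(target) {
  d <- dim(target)
  out <- array(Inf, dim = d)
  for (k in seq_len(d[3])) {
    m <- target[, , k]
    if (!any(m)) next
    # distmap gives, for each non-zero pixel, the distance to the nearest
    # zero pixel; so zero out the target region.
    out[, , k] <- EBImage::distmap(1 - m * 1, metric = "euclidean")
  }
  out
}

#' Build per-voxel cardiac coordinate frames
#'
#' The longitudinal direction is the (given) long axis, apex to base; the
#' radial direction points outward from the per-slice cavity centroid
#' (\code{method = "centroid"}, exact for annular geometry) or along the
#' in-slice gradient of the transmural-depth field
#' (\code{method = "gradient"}, for non-cylindrical walls); the
#' circumferential direction completes the right-handed triad
#' c_hat = z_hat x r_hat. Transmural depth is computed from dual per-slice
#' Euclidean distance transforms: TD = 100 * d_endo / (d_endo + d_epi).
#'
#' @param wall,endo,epi Logical arrays: wall annulus, cavity, exterior.
#' @param affine 4x4 voxel-to-world affine (isotropic in-plane voxels
#'   assumed for the distance transform scaling).
#' @param longAxis Unit long-axis vector (default +z, apex to base).
#' @param method Radial-direction construction, "centroid" or "gradient".
#' @return A \linkS4class{CardiacFrameField}.
#' @export
buildFrames <- function(wall, endo, epi, affine = diag(4),
                        longAxis = c(0, 0, 1),
                        method = c("centroid", "gradient")) {
  method <- match.arg(method)
  d <- dim(wall)
  for (k in which(apply(wall, 3, any))) {
    if (!any(endo[, , k]) || !any(epi[, , k]))
      stop("endo and epi surfaces must be non-empty on every analyzed slice (slice ",
           k, ")")
  }
  zhat <- longAxis / sqrt(sum(longAxis^2))

  # distmap measures to the nearest surface-voxel *center*; the tissue
  # boundary lies half a voxel closer, so subtract 0.5 voxel from each side
  dEndo <- pmax(.sliceDistanceTo(endo) - 0.5, 0)
  dEpi <- pmax(.sliceDistanceTo(epi) - 0.5, 0)
  denom <- dEndo + dEpi
  valid <- wall & is.finite(denom) & denom > 0
  td <- array(NA_real_, dim = d)
  td[valid] <- 100 * dEndo[valid] / denom[valid]
  td[valid] <- pmin(pmax(td[valid], 0), 100)

  n3 <- prod(d)
  radial <- array(0, dim = c(d, 3L))
  if (method == "centroid") {
    cen <- .sliceCentroids(endo, wall)
    ijk <- which(array(TRUE, d), arr.ind = TRUE)
    dx <- ijk[, 1] - cen[ijk[, 3], 1]
    dy <- ijk[, 2] - cen[ijk[, 3], 2]
    rmat <- cbind(dx, dy, 0)
  } else {
    # in-slice central differences of TD, NA-tolerant at the wall border
    tdFill <- td
    tdFill[!valid] <- NA
    gx <- array(NA_real_, d); gy <- array(NA_real_, d)
    tdp <- tdFill[c(2:d[1], d[1]), , , drop = FALSE]
    tdm <- tdFill[c(1, 1:(d[1] - 1)), , , drop = FALSE]
    gx <- ifelse(is.na(tdp) | is.na(tdm), NA, (tdp - tdm) / 2)
    tdp <- tdFill[, c(2:d[2], d[2]), , drop = FALSE]
    tdm <- tdFill[, c(1, 1:(d[2] - 1)), , drop = FALSE]
    gy <- ifelse(is.na(tdp) | is.na(tdm), NA, (tdp - tdm) / 2)
    rmat <- cbind(as.vector(gx), as.vector(gy), 0)
    bad <- !is.finite(rmat[, 1]) | !is.finite(rmat[, 2])
    rmat[bad, ] <- 0
    valid <- valid & array(!bad, d)
  }
  # project out any longitudinal component, then normalize
  rmat <- rmat - outer(c(rmat %*% zhat), zhat)
  nrm <- rowNorms(rmat)
  degenerate <- nrm < 1e-12
  rmat[!degenerate, ] <- rmat[!degenerate, , drop = FALSE] / nrm[!degenerate]
  valid <- valid & array(!degenerate, d)

  lmat <- matrix(zhat, n3, 3, byrow = TRUE)
  cmat <- rowCross(lmat, rmat)

  new("CardiacFrameField",
      circ = array(cmat, c(d, 3L)), radial = array(rmat, c(d, 3L)),
      longit = array(lmat, c(d, 3L)), td = td, wall = wall,
      valid = valid, affine = affine)
}

# Dot product of the per-voxel vector field (X,Y,Z,3) with a frame field.
.fieldDot <- function(a, b) {
  am <- matrix(a, ncol = 3L); bm <- matrix(b, ncol = 3L)
  rowSums(am * bm)
}

#' Sign-fix eigenvectors against the cardiac frame
#'
#' The raw eigendecomposition sign is arbitrary. e1 is flipped so its
#' circumferential component is >= 0 (tie-break: if |e1 . c_hat| < 1e-8, flip
#' so the longitudinal component is >= 0); e2 is flipped so e2 . r_hat >= 0;
#' e3 is recomputed as e1 x e2. Idempotent.
#'
#' @param field A \linkS4class{DiffusionTensorField}.
#' @param frames A \linkS4class{CardiacFrameField} on the same grid.
#' @return The field with sign-fixed eigenvectors.
#' @export
orientEigenvectors <- function(field, frames) {
  d <- dim(field@S0)
  e1 <- matrix(field@evecs[, , , , 1], ncol = 3L)
  e2 <- matrix(field@evecs[, , , , 2], ncol = 3L)
  cdot <- .fieldDot(field@evecs[, , , , 1], frames@circ)
  zdot <- .fieldDot(field@evecs[, , , , 1], frames@longit)
  flip1 <- ifelse(abs(cdot) < 1e-8, zdot < 0, cdot < 0)
  e1[flip1, ] <- -e1[flip1, , drop = FALSE]
  rdot <- .fieldDot(field@evecs[, , , , 2], frames@radial)
  flip2 <- rdot < 0
  e2[flip2, ] <- -e2[flip2, , drop = FALSE]
  e3 <- rowCross(e1, e2)
  field@evecs[, , , , 1] <- array(e1, c(d, 3L))
  field@evecs[, , , , 2] <- array(e2, c(d, 3L))
  field@evecs[, , , , 3] <- array(e3, c(d, 3L))
  field
}

#' Helix angle map
#'
#' HA = atan2(e1 . z_hat, e1 . c_hat) in degrees: the signed angle of e1's
#' projection onto the wall-tangent (circumferential-longitudinal) plane,
#' measured from circumferential, positive toward the base. Voxels whose
#' tangent-plane projection is below 1e-8 in norm are flagged invalid.
#'
#' @param e1 X x Y x Z x 3 sign-fixed primary eigenvector array (or a
#'   \linkS4class{DiffusionTensorField}, whose e1 is used).
#' @param frames A \linkS4class{CardiacFrameField}.
#' @return List with \code{angle} (degrees array) and \code{valid} mask.
#' @export
helixAngle <- function(e1, frames) {
  if (is(e1, "DiffusionTensorField")) e1 <- e1@evecs[, , , , 1]
  d <- dim(frames@td)
  cdot <- .fieldDot(e1, frames@circ)
  zdot <- .fieldDot(e1, frames@longit)
  proj <- sqrt(cdot^2 + zdot^2)
  ok <- array(proj >= 1e-8, d) & frames@valid
  ang <- array(NA_real_, d)
  ang[ok] <- rad2deg(atan2(zdot, cdot))[ok]
  list(angle = ang, valid = ok)
}

#' Transverse angle map
#'
#' TA = atan2(e1 . r_hat, e1 . c_hat) in degrees: the signed angle of e1's
#' projection onto the short-axis (circumferential-radial) plane from
#' circumferential, positive toward the outward radial.
#'
#' @inheritParams helixAngle
#' @return List with \code{angle} and \code{valid}.
#' @export
transverseAngle <- function(e1, frames) {
  if (is(e1, "DiffusionTensorField")) e1 <- e1@evecs[, , , , 1]
  d <- dim(frames@td)
  cdot <- .fieldDot(e1, frames@circ)
  rdot <- .fieldDot(e1, frames@radial)
  proj <- sqrt(cdot^2 + rdot^2)
  ok <- array(proj >= 1e-8, d) & frames@valid
  ang <- array(NA_real_, d)
  ang[ok] <- rad2deg(atan2(rdot, cdot))[ok]
  list(angle = ang, valid = ok)
}

#' Absolute secondary eigenvector (sheetlet) angle map
#'
#' |E2A| = |atan2(e2 . r_hat, e2 . t_hat)| in [0, 90] degrees, where
#' t_hat = normalized(r_hat x e1) is the cross-myocyte wall-tangent
#' direction: 0 when the sheetlet plane lies in the wall, 90 when e2 is
#' wall-normal. Voxels with ||r_hat x e1|| < 1e-8 are flagged.
#'
#' @param e2,e1 X x Y x Z x 3 sign-fixed eigenvector arrays.
#' @param frames A \linkS4class{CardiacFrameField}.
#' @return List with \code{angle} and \code{valid}.
#' @export
e2aAngle <- function(e2, e1, frames) {
  d <- dim(frames@td)
  rm_ <- matrix(frames@radial, ncol = 3L)
  e1m <- matrix(e1, ncol = 3L)
  e2m <- matrix(e2, ncol = 3L)
  tvec <- rowCross(rm_, e1m)
  tn <- rowNorms(tvec)
  ok <- array(tn >= 1e-8, d) & frames@valid
  tvec[tn > 0, ] <- tvec[tn > 0, , drop = FALSE] / tn[tn > 0]
  rdot <- rowSums(e2m * rm_)
  tdot <- rowSums(e2m * tvec)
  ang <- array(NA_real_, d)
  a <- abs(rad2deg(atan2(rdot, tdot)))
  a[a > 90] <- 180 - a[a > 90]          # fold to [0, 90]
  ang[ok] <- a[ok]
  list(angle = ang, valid = ok)
}

#' Compute all angle maps from a fitted tensor field
#'
#' Sign-fixes the eigenvectors against the frames and evaluates the helix,
#' transverse, and absolute sheetlet angle maps.
#'
#' @param field A \linkS4class{DiffusionTensorField}.
#' @param frames A \linkS4class{CardiacFrameField} on the same grid.
#' @return An \linkS4class{AngleMaps}.
#' @export
angleMaps <- function(field, frames) {
  field <- orientEigenvectors(field, frames)
  e1 <- field@evecs[, , , , 1]
  e2 <- field@evecs[, , , , 2]
  ha <- helixAngle(e1, frames)
  ta <- transverseAngle(e1, frames)
  e2a <- e2aAngle(e2, e1, frames)
  valid <- ha$valid & ta$valid & e2a$valid &
    field@mask & field@flags != 2L
  new("AngleMaps", ha = ha$angle, ta = ta$angle, e2a = e2a$angle,
      valid = valid, affine = frames@affine)
}
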