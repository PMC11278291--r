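#' @import methods
NULL

#' Diffusion gradient table
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions defining the
#' diffusion encoding of a 4D acquisition. b-values below \code{b0Threshold}
#' are treated as b = 0 volumes and may carry a zero direction vector.
#'
#' @slot bvals Numeric vector of b-values, one per volume.
#' @slot bvecs 3 x N matrix of gradient directions (columns), unit-norm for
#'   non-b0 volumes, zero permitted for b0 volumes.
#' @slot b0Threshold b-values at or below this are treated as b0.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix", b0Threshold = "numeric"),
  prototype(b0Threshold = 10))

setValidity("GradientTable", function(object) {
  if (ncol(object@bvecs) != length(object@bvals))
    return("number of bvec columns must equal number of bvals")
  if (nrow(object@bvecs) != 3L)
    return("bvecs must have 3 rows")
  if (any(!is.finite(object@bvals)) || any(object@bvals < 0))
    return("bvals must be finite and non-negative")
  nb0 <- object@bvals > object@b0Threshold
  if (any(nb0)) {
    nrm <- sqrt(colSums(object@bvecs[, nb0, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      return("non-b0 gradient directions must be unit-norm (within 1e-6)")
  }
  TRUE
})

#' Construct a gradient table
#'
#' @param bvals Numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x N matrix (or N x 3, auto-transposed) of directions.
#' @param b0Threshold b-values at or below this count as b0 (default 10).
#' @param normalize Renormalize non-b0 columns to unit length before
#'   validation (default TRUE).
#' @return A \linkS4class{GradientTable}.
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 10, normalize = TRUE) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (normalize) {
    nb0 <- bvals > b0Threshold
    nrm <- sqrt(colSums(bvecs^2))
    fix <- nb0 & nrm > 0
    bvecs[, fix] <- sweep(bvecs[, fix, drop = FALSE], 2, nrm[fix], "/")
  }
  new("GradientTable", bvals = as.numeric(bvals), bvecs = bvecs,
      b0Threshold = b0Threshold)
}

#' Image volume with world affine
#'
#' A 3D or 4D voxel array together with the 4x4 voxel-to-world (mm) affine
#' and an intent tag describing what the volume holds.
#'
#' @slot data Numeric array, 3D or 4D.
#' @slot affine 4x4 voxel-to-world affine (0-based voxel indices to mm).
#' @slot intent One of \code{"dwi"}, \code{"ce"}, \code{"mask"}, \code{"map"}.
#' @export
setClass("ImageVolume",
  representation(data = "array", affine = "matrix", intent = "character"))

setValidity("ImageVolume", function(object) {
  nd <- length(dim(object@data))
  if (!(nd %in% c(3L, 4L))) return("data must be a 3D or 4D array")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine)) < .Machine$double.eps)
    return("affine must be invertible")
  if (!object@intent %in% c("dwi", "ce", "mask", "map"))
    return("intent must be one of dwi, ce, mask, map")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D or 4D array.
#' @param affine 4x4 voxel-to-world affine; default builds a diagonal affine
#'   from \code{voxelSize}.
#' @param intent Intent tag (\code{"map"} by default).
#' @param voxelSize Isotropic voxel edge in mm used when \code{affine} is NULL.
#' @return An \linkS4class{ImageVolume}.
#' @export
imageVolume <- function(data, affine = NULL, intent = "map", voxelSize = 1) {
  if (is.null(affine)) affine <- diag(c(rep(voxelSize, 3), 1))
  new("ImageVolume", data = data, affine = affine, intent = intent)
}

#' Fitted diffusion tensor field
#'
#' Per-voxel symmetric diffusion tensor with its eigen-system, the estimated
#' b0 signal, and per-voxel fit-quality flags. Tensor components are stored in
#' the order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s).
#'
#' Flags: 0 = clean fit; 1 = negative eigenvalue clamped to 1e-12;
#' 2 = invalid (non-positive signal or outside mask).
#'
#' @slot tensors X x Y x Z x 6 array of tensor components.
#' @slot S0 X x Y x Z array of estimated b0 signal.
#' @slot evals X x Y x Z x 3 array, eigenvalues sorted descending.
#' @slot evecs X x Y x Z x 3 x 3 array; \code{evecs[,,,,i]} holds the i-th
#'   unit eigenvector's xyz components.
#' @slot mask Logical X x Y x Z array of fitted voxels.
#' @slot flags Integer X x Y x Z array of fit-quality flags.
#' @slot affine 4x4 voxel-to-world affine.
#' @export
setClass("DiffusionTensorField",
  representation(tensors = "array", S0 = "array", evals = "array",
                 evecs = "array", mask = "array", flags = "array",
                 affine = "matrix"))

setValidity("DiffusionTensorField", function(object) {
  d <- dim(object@S0)
  if (!all(dim(object@tensors) == c(d, 6L))) return("tensors must be X x Y x Z x 6")
  if (!all(dim(object@evals) == c(d, 3L))) return("evals must be X x Y x Z x 3")
  if (!all(dim(object@evecs) == c(d, 3L, 3L))) return("evecs must be X x Y x Z x 3 x 3")
  ok <- which(object@mask & object@flags != 2L)
  if (length(ok)) {
    ev <- matrix(object@evals, ncol = 3L)[ok, , drop = FALSE]
    if (any(ev[, 1] + 1e-15 < ev[, 2] | ev[, 2] + 1e-15 < ev[, 3]))
      return("eigenvalues must be sorted descending")
  }
  TRUE
})

#' Per-voxel local cardiac coordinate frames
#'
#' Orthonormal circumferential / radial / longitudinal unit triad and the
#' transmural depth (percent, 0 at endocardium to 100 at epicardium) on the
#' left-ventricular wall.
#'
#' @slot circ,radial,longit X x Y x Z x 3 arrays of unit vectors.
#' @slot td X x Y x Z array of transmural depth in percent.
#' @slot wall Logical wall mask.
#' @slot valid Logical mask of voxels with a well-defined frame.
#' @slot affine 4x4 voxel-to-world affine.
#' @export
setClass("CardiacFrameField",
  representation(circ = "array", radial = "array", longit = "array",
                 td = "array", wall = "array", valid = "array",
                 affine = "matrix"))

setValidity("CardiacFrameField", function(object) {
  idx <- which(object@valid)
  if (length(idx)) {
    n <- prod(dim(object@td))
    cm <- matrix(object@circ, ncol = 3)[idx, , drop = FALSE]
    rm_ <- matrix(object@radial, ncol = 3)[idx, , drop = FALSE]
    lm <- matrix(object@longit, ncol = 3)[idx, , drop = FALSE]
    if (max(abs(rowSums(cm * rm_))) > 1e-6 ||
        max(abs(rowSums(cm * lm))) > 1e-6 ||
        max(abs(rowSums(rm_ * lm))) > 1e-6)
      return("frame triad must be orthonormal within 1e-6")
    if (max(abs(rowCross(lm, rm_) - cm)) > 1e-6)
      return("circumferential must equal longitudinal x radial")
  }
  TRUE
})

#' Helix / transverse / sheetlet angle maps
#'
#' Per-voxel helix angle (HA), transverse angle (TA), both signed in
#' [-90, +90] degrees, and the absolute secondary eigenvector angle |E2A| in
#' [0, 90] degrees, with a validity mask marking voxels where the angles are
#' defined.
#'
#' @slot ha,ta,e2a X x Y x Z arrays in degrees.
#' @slot valid Logical mask.
#' @slot affine 4x4 voxel-to-world affine.
#' @export
setClass("AngleMaps",
  representation(ha = "array", ta = "array", e2a = "array",
                 valid = "array", affine = "matrix"))

setValidity("AngleMaps", function(object) {
  v <- which(object@valid)
  if (length(v)) {
    if (any(abs(object@ha[v]) > 90 + 1e-9) || any(abs(object@ta[v]) > 90 + 1e-9))
      return("HA and TA must lie in [-90, 90] degrees")
    if (any(object@e2a[v] < -1e-9 | object@e2a[v] > 90 + 1e-9))
      return("|E2A| must lie in [0, 90] degrees")
  }
  TRUE
})

#' Region labels derived from contrast-enhanced intensities
#'
#' Voxel labels for background / remote / scar / graft / other wall tissue,
#' plus a provenance record of how they were derived (threshold, remote
#' statistics, region-growing seeds and tolerance).
#'
#' Label coding: 0 background, 1 remote, 2 scar, 3 graft, 4 other wall.
#'
#' @slot labels Integer X x Y x Z array.
#' @slot provenance Named list recording thresholds, statistics and seeds.
#' @slot affine 4x4 voxel-to-world affine.
#' @export
setClass("RegionLabels",
  representation(labels = "array", provenance = "list", affine = "matrix"))

setValidity("RegionLabels", function(object) {
  if (!all(object@labels %in% 0:4)) return("labels must be coded 0..4")
  TRUE
})

.REGION_LEVELS <- c(background = 0L, remote = 1L, scar = 2L, graft = 3L,
                    otherwall = 4L)

#' Synthetic left-ventricle phantom
#'
#' Container holding the synthetic DWI acquisition, contrast-enhanced volume,
#' masks, gradient table, and the ground-truth fields used by recovery tests:
#' true tensors, helix/transverse angles, transmural depth and region labels.
#'
#' @slot spec The \linkS4class{PhantomSpec} that generated it.
#' @slot dwi X x Y x Z x N array of diffusion-weighted signal.
#' @slot ce X x Y x Z contrast-enhanced volume.
#' @slot gtab \linkS4class{GradientTable}.
#' @slot wall,endo,epi Logical masks (wall annulus, cavity, exterior).
#' @slot tdTrue,haTrue,taTrue Ground-truth maps (percent / degrees).
#' @slot e1True X x Y x Z x 3 true primary eigenvector field.
#' @slot tensorTrue X x Y x Z x 6 true tensor components (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz).
#' @slot labelsTrue Integer array, coding as \linkS4class{RegionLabels}.
#' @slot affine 4x4 voxel-to-world affine.
#' @export
setClass("LVPhantom",
  representation(spec = "list", dwi = "array", ce = "array",
                 gtab = "GradientTable", wall = "array", endo = "array",
                 epi = "array", tdTrue = "array", haTrue = "array",
                 taTrue = "array", e1True = "array", tensorTrue = "array",
                 labelsTrue = "array", affine = "matrix"))

#' Streamline set from deterministic tractography
#'
#' @slot points List of n_i x 3 matrices of world-mm coordinates.
#' @slot seeds Integer matrix of seed voxel indices (one row per streamline).
#' @slot reasons Character vector of termination reasons, the two ends joined
#'   as "backward|forward" (each one of fa-stop, angle-stop, mask-exit,
#'   length-cap).
#' @slot step Step size in mm.
#' @slot affine Reference voxel-to-world affine.
#' @export
setClass("StreamlineSet",
  representation(points = "list", seeds = "matrix", reasons = "character",
                 step = "numeric", affine = "matrix"))
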