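#' @rdname GradientTable-class
#' @param object A \linkS4class{GradientTable}.
#' @export
setGeneric("bvals", function(object) standardGeneric("bvals"))

#' @rdname GradientTable-class
#' @export
setGeneric("bvecs", function(object) standardGeneric("bvecs"))

#' @rdname GradientTable-class
#' @export
setGeneric("isB0", function(object) standardGeneric("isB0"))

#' @rdname GradientTable-class
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))

#' @rdname DiffusionTensorField-class
#' @param object A \linkS4class{DiffusionTensorField}.
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname DiffusionTensorField-class
#' @param which Eigenvector index (1 = primary).
#' @export
setGeneric("eigenvectors", function(object, which = 1L) standardGeneric("eigenvectors"))

#' @rdname DiffusionTensorField-class
#' @export
setGeneric("fitFlags", function(object) standardGeneric("fitFlags"))

#' Extract the voxel array of an object
#' @param object An object holding a voxel array.
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' Extract the voxel-to-world affine of an object
#' @param object An object with an affine slot.
#' @export
setGeneric("worldAffine", function(object) standardGeneric("worldAffine"))

#' @rdname RegionLabels-class
#' @param object A \linkS4class{RegionLabels}.
#' @param region Region name: "background", "remote", "scar", "graft",
#'   "otherwall", or "wall" for all non-background voxels.
#' @export
setGeneric("regionMask", function(object, region) standardGeneric("regionMask"))

#' @rdname CardiacFrameField-class
#' @param object A \linkS4class{CardiacFrameField}.
#' @export
setGeneric("transmuralDepth", function(object) standardGeneric("transmuralDepth"))

setMethod("bvals", "GradientTable", function(object) object@bvals)
setMethod("bvecs", "GradientTable", function(object) object@bvecs)
setMethod("isB0", "GradientTable", function(object) object@bvals <= object@b0Threshold)
setMethod("nVolumes", "GradientTable", function(object) length(object@bvals))

setMethod("eigenvalues", "DiffusionTensorField", function(object) object@evals)
setMethod("eigenvectors", "DiffusionTensorField",
          function(object, which = 1L) object@evecs[, , , , which, drop = TRUE])
setMethod("fitFlags", "DiffusionTensorField", function(object) object@flags)

setMethod("voxelData", "ImageVolume", function(object) object@data)
setMethod("voxelData", "RegionLabels", function(object) object@labels)

setMethod("worldAffine", "ImageVolume", function(object) object@affine)
setMethod("worldAffine", "DiffusionTensorField", function(object) object@affine)
setMethod("worldAffine", "CardiacFrameField", function(object) object@affine)
setMethod("worldAffine", "AngleMaps", function(object) object@affine)
setMethod("worldAffine", "RegionLabels", function(object) object@affine)
setMethod("worldAffine", "LVPhantom", function(object) object@affine)

setMethod("regionMask", "RegionLabels", function(object, region) {
  if (region == "wall") return(object@labels > 0L)
  code <- .REGION_LEVELS[region]
  if (is.na(code)) stop("unknown region '", region, "'")
  object@labels == code
})

setMethod("transmuralDepth", "CardiacFrameField", function(object) object@td)

setMethod("show", "GradientTable", function(object) {
  b0 <- isB0(object)
  cat("GradientTable:", nVolumes(object), "volumes (", sum(b0), "b0,",
      sum(!b0), "diffusion ), b =",
      paste(unique(round(object@bvals[!b0])), collapse = "/"), "s/mm^2\n")
})

setMethod("show", "ImageVolume", function(object) {
  cat("ImageVolume [", object@intent, "]:",
      paste(dim(object@data), collapse = " x "), "voxels, voxel size",
      paste(round(sqrt(colSums(object@affine[1:3, 1:3]^2)), 4), collapse = " x "),
      "mm\n")
})

setMethod("show", "DiffusionTensorField", function(object) {
  n <- sum(object@mask)
  cat("DiffusionTensorField:", paste(dim(object@S0), collapse = " x "),
      "grid,", n, "fitted voxels;",
      sum(object@flags == 1L), "clamped,", sum(object@flags == 2L), "invalid\n")
})

setMethod("show", "CardiacFrameField", function(object) {
  cat("CardiacFrameField:", sum(object@wall), "wall voxels,",
      sum(object@valid), "with valid frames; TD range",
      paste(round(range(object@td[object@valid & object@wall]), 1), collapse = "-"),
      "%\n")
})

setMethod("show", "AngleMaps", function(object) {
  v <- object@valid
  cat("AngleMaps:", sum(v), "valid voxels; HA",
      paste(round(range(object@ha[v]), 1), collapse = ".."), "deg, TA",
      paste(round(range(object@ta[v]), 1), collapse = ".."), "deg, |E2A|",
      paste(round(range(object@e2a[v]), 1), collapse = ".."), "deg\n")
})

setMethod("show", "RegionLabels", function(object) {
  counts <- vapply(names(.REGION_LEVELS), function(r)
    sum(object@labels == .REGION_LEVELS[r]), integer(1))
  cat("RegionLabels:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LVPhantom", function(object) {
  cat("LVPhantom:", paste(dim(object@ce), collapse = " x "), "grid,",
      nVolumes(object@gtab), "DWI volumes,", sum(object@wall), "wall voxels\n")
})

setMethod("show", "StreamlineSet", function(object) {
  npts <- vapply(object@points, nrow, integer(1))
  cat("StreamlineSet:", length(object@points), "streamlines, step",
      object@step, "mm, mean", round(mean(npts), 1), "points\n")
})

#' Number of streamlines
#' @param x A \linkS4class{StreamlineSet}.
#' @export
setMethod("length", "StreamlineSet", function(x) length(x@points))

#' Streamline lengths in mm
#' @param object A \linkS4class{StreamlineSet}.
#' @export
setGeneric("streamlineLengths", function(object) standardGeneric("streamlineLengths"))

setMethod("streamlineLengths", "StreamlineSet", function(object) {
  vapply(object@points, function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
})
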