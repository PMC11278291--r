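# NIfTI and FSL gradient-table I/O, plus resampling of the contrast-enhanced
# volume onto the DWI grid. World coordinates follow the NIfTI affine
# convention throughout; all internal geometry is in world mm.

#' Read a NIfTI volume
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param intent Intent tag to attach ("dwi", "ce", "mask" or "map").
#' @return An \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path, intent = "map") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  dat <- array(as.numeric(img), dim = dim(img))
  if (intent != "mask" && any(!is.finite(dat)))
    stop("non-finite values in ", path)
  imageVolume(dat, matrix(aff, 4, 4), intent)
}

#' Write a NIfTI volume
#'
#' Integer-valued mask volumes are written as int16 so the round trip is
#' bitwise; float maps are written as float64.
#'
#' @param vol An \linkS4class{ImageVolume}.
#' @param path Output path (.nii or .nii.gz).
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path) {
  datatype <- if (vol@intent == "mask") "int16" else "double"
  img <- RNifti::asNifti(vol@data)
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read an FSL-style gradient table
#'
#' \code{bvals} is one row of b-values; \code{bvecs} is three rows (x, y, z)
#' of direction components, one column per volume. Directions are
#' renormalized to unit length; b-values below 10 s/mm^2 are treated as b0.
#'
#' @param bvalPath,bvecPath Paths to the two text files.
#' @return A \linkS4class{GradientTable}.
#' @export
readGradientTable <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecRows <- readLines(bvecPath)
  bvecRows <- bvecRows[nzchar(trimws(bvecRows))]
  if (length(bvecRows) != 3L)
    stop("bvec file must have 3 rows, found ", length(bvecRows))
  bvecs <- do.call(rbind, lapply(bvecRows, function(l)
    scan(text = l, quiet = TRUE)))
  if (ncol(bvecs) != length(bvals))
    stop("gradient table mismatch: ", length(bvals), " bvals but ",
         ncol(bvecs), " bvec columns")
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("non-finite values in gradient table")
  gradientTable(bvals, bvecs)
}

#' Write an FSL-style gradient table
#'
#' @param gtab A \linkS4class{GradientTable}.
#' @param bvalPath,bvecPath Output paths.
#' @return Invisibly, NULL.
#' @export
writeGradientTable <- function(gtab, bvalPath, bvecPath) {
  writeLines(paste(format(bvals(gtab), scientific = FALSE, trim = TRUE),
                   collapse = " "), bvalPath)
  writeLines(apply(bvecs(gtab), 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")), bvecPath)
  invisible(NULL)
}

#' Read a DWI acquisition
#'
#' Reads the 4D volume and its gradient table, validating that the volume
#' count matches the table length.
#'
#' @param niftiPath Path to the 4D NIfTI.
#' @param bvalPath,bvecPath Paths to the FSL gradient-table files.
#' @return List with \code{volume} (\linkS4class{ImageVolume}, intent "dwi")
#'   and \code{gtab} (\linkS4class{GradientTable}).
#' @export
readDWI <- function(niftiPath, bvalPath, bvecPath) {
  vol <- readVolume(niftiPath, intent = "dwi")
  if (length(dim(vol@data)) != 4L)
    stop("DWI volume must be 4D, got ", length(dim(vol@data)), "D")
  gtab <- readGradientTable(bvalPath, bvecPath)
  if (dim(vol@data)[4] != nVolumes(gtab))
    stop("DWI has ", dim(vol@data)[4], " volumes but gradient table has ",
         nVolumes(gtab))
  list(volume = vol, gtab = gtab)
}

#' Resample a CE volume onto the DWI grid
#'
#' Maps each DWI voxel center through the (given, not estimated) CE-to-DWI
#' world affine back into CE voxel space and interpolates: trilinear for
#' intensities, nearest-neighbour for label volumes. Voxels that map outside
#' the source volume are returned as NA and excluded from downstream
#' statistics.
#'
#' @param ce Source \linkS4class{ImageVolume}.
#' @param dwi Target-grid \linkS4class{ImageVolume} (3D or 4D; only the grid
#'   and affine are used).
#' @param affineCEtoDWI 4x4 world-to-world affine taking CE coordinates to
#'   DWI coordinates (identity by default, as for phantom runs).
#' @param method "trilinear" (default) or "nearest".
#' @return An \linkS4class{ImageVolume} on the DWI grid, intent "ce".
#' @export
resampleToDWI <- function(ce, dwi, affineCEtoDWI = diag(4),
                          method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (abs(det(affineCEtoDWI)) < .Machine$double.eps)
    stop("singular CE-to-DWI affine")
  dTarget <- dim(dwi@data)[1:3]
  idx <- as.matrix(expand.grid(i = seq_len(dTarget[1]),
                               j = seq_len(dTarget[2]),
                               k = seq_len(dTarget[3])))
  worldDWI <- voxelToWorld(idx, dwi@affine)
  worldCE <- t(solve(affineCEtoDWI) %*% rbind(t(worldDWI), 1))[, 1:3]
  voxCE <- worldToVoxel(worldCE, ce@affine)
  vals <- if (method == "trilinear") interpTrilinear(ce@data, voxCE)
          else interpNearest(ce@data, voxCE)
  imageVolume(array(vals, dim = dTarget), dwi@affine, "ce")
}
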