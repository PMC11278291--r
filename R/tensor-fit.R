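# Log-linear least-squares diffusion tensor estimation and scalar maps.

# 7-column design matrix for ln S = ln S0 - b g' D g:
# columns (lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
.dtiDesign <- function(gtab) {
  b <- bvals(gtab); g <- t(bvecs(gtab))
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves ln S = ln S0 - b g' D g per voxel by ordinary least squares on the
#' 7-parameter design (all b0 volumes enter the design; averaging is implicit
#' in the LS solution), then eigendecomposes each tensor. Negative
#' eigenvalues are clamped to 1e-12 and the voxel flagged (flag 1); voxels
#' with any non-positive signal are flagged invalid (flag 2) and excluded,
#' not fatal.
#'
#' @param dwi 4D signal array or an \linkS4class{ImageVolume} with intent
#'   "dwi".
#' @param gtab A \linkS4class{GradientTable} with at least one b0 volume and
#'   at least 6 unique non-b0 directions.
#' @param mask Logical array of voxels to fit.
#' @param affine Voxel-to-world affine; taken from \code{dwi} when it is an
#'   \linkS4class{ImageVolume}.
#' @return A \linkS4class{DiffusionTensorField}.
#' @export
fitTensorLLS <- function(dwi, gtab, mask, affine = NULL) {
  if (is(dwi, "ImageVolume")) {
    if (is.null(affine)) affine <- dwi@affine
    dwi <- dwi@data
  }
  if (is.null(affine)) affine <- diag(4)
  d <- dim(dwi)[1:3]
  stopifnot(dim(dwi)[4] == nVolumes(gtab), all(dim(mask) == d))
  b0 <- isB0(gtab)
  if (!any(b0)) stop("configuration error: gradient table has no b0 volume")
  uniqDirs <- unique(round(t(bvecs(gtab)[, !b0, drop = FALSE]), 6))
  if (nrow(uniqDirs) < 6L)
    stop("configuration error: need >= 6 unique non-b0 directions, have ",
         nrow(uniqDirs))
  X <- .dtiDesign(gtab)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("configuration error: rank-deficient diffusion design matrix")

  idx <- which(mask)
  nvox <- length(idx)
  sig <- matrix(dwi, ncol = dim(dwi)[4])[idx, , drop = FALSE]
  bad <- rowSums(sig <= 0) > 0
  flagsV <- integer(nvox)
  flagsV[bad] <- 2L

  tensors <- array(0, dim = c(d, 6L))
  S0 <- array(0, dim = d)
  evals <- array(0, dim = c(d, 3L))
  evecs <- array(0, dim = c(d, 3L, 3L))
  flags <- array(0L, dim = d)

  good <- which(!bad)
  if (length(good)) {
    beta <- qr.coef(qrX, t(log(sig[good, , drop = FALSE])))  # 7 x n
    S0v <- exp(beta[1, ])
    dcomp <- t(beta[2:7, , drop = FALSE])                    # n x 6
    evM <- matrix(0, length(good), 3)
    e1M <- matrix(0, length(good), 3)
    e2M <- matrix(0, length(good), 3)
    e3M <- matrix(0, length(good), 3)
    clamped <- logical(length(good))
    for (q in seq_along(good)) {
      dc <- dcomp[q, ]
      Dm <- matrix(c(dc[1], dc[4], dc[5],
                     dc[4], dc[2], dc[6],
                     dc[5], dc[6], dc[3]), 3, 3)
      es <- eigen(Dm, symmetric = TRUE)      # descending eigenvalues
      ev <- es$values
      if (any(ev < 0)) {
        ev[ev < 0] <- 1e-12
        clamped[q] <- TRUE
      }
      evM[q, ] <- ev
      e1M[q, ] <- es$vectors[, 1]
      e2M[q, ] <- es$vectors[, 2]
      e3M[q, ] <- es$vectors[, 3]
    }
    gi <- idx[good]
    n3 <- prod(d)
    for (cc in 1:6) tensors[gi + (cc - 1) * n3] <- dcomp[, cc]
    S0[gi] <- S0v
    for (cc in 1:3) {
      evals[gi + (cc - 1) * n3] <- evM[, cc]
      evecs[gi + (cc - 1) * n3] <- e1M[, cc]            # eigenvector 1
      evecs[gi + (cc - 1) * n3 + 3L * n3] <- e2M[, cc]  # eigenvector 2
      evecs[gi + (cc - 1) * n3 + 6L * n3] <- e3M[, cc]  # eigenvector 3
    }
    flagsV[good][clamped] <- 1L
  }
  flags[idx] <- flagsV
  new("DiffusionTensorField", tensors = tensors, S0 = S0, evals = evals,
      evecs = evecs, mask = mask, flags = flags, affine = affine)
}

#' Fractional anisotropy map
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, zero for
#' isotropic or all-zero eigenvalue triples (all-zero voxels are excluded
#' from the validity mask).
#'
#' @param field A \linkS4class{DiffusionTensorField}.
#' @return An \linkS4class{ImageVolume} (intent "map") whose array holds FA
#'   in [0, 1], NA outside the valid fit mask.
#' @export
computeFA <- function(field) {
  d <- dim(field@S0)
  ok <- field@mask & field@flags != 2L
  ev <- matrix(field@evals, ncol = 3L)[which(ok), , drop = FALSE]
  fa <- array(NA_real_, dim = d)
  fa[ok] <- faFromEvals(ev)
  allZero <- array(rowSums(abs(matrix(field@evals, ncol = 3L))) == 0, dim = d)
  fa[ok & allZero] <- NA_real_
  imageVolume(fa, field@affine, "map")
}

#' Mean diffusivity map
#'
#' MD = (lambda1 + lambda2 + lambda3) / 3 = trace(D) / 3.
#'
#' @param field A \linkS4class{DiffusionTensorField}.
#' @return An \linkS4class{ImageVolume} (intent "map") in mm^2/s, NA outside
#'   the valid fit mask.
#' @export
computeMD <- function(field) {
  d <- dim(field@S0)
  ok <- field@mask & field@flags != 2L
  md <- array(NA_real_, dim = d)
  md[ok] <- rowMeans(matrix(field@evals, ncol = 3L)[which(ok), , drop = FALSE])
  imageVolume(md, field@affine, "map")
}

# Eigenvalue triple of one symmetric tensor given as 6 components.
.tensorEigen <- function(dc) {
  eigen(matrix(c(dc[1], dc[4], dc[5],
                 dc[4], dc[2], dc[6],
                 dc[5], dc[6], dc[3]), 3, 3), symmetric = TRUE)
}
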