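# Deterministic fixed-step Euler streamline tracking of the primary
# eigenvector field, with per-step eigenvector re-orientation, and TCK
# (MRtrix) streamline file I/O.

# Interpolate the 6 tensor components at world-mm points and return the
# eigen-system at each (list of evals n x 3, e1 n x 3). Rows with any NA
# component come back as NA.
.tensorAtPoints <- function(field, pts) {
  vox <- worldToVoxel(pts, field@affine)
  comp <- sapply(1:6, function(cc)
    interpTrilinear(field@tensors[, , , cc], vox))
  comp <- matrix(comp, ncol = 6L)
  n <- nrow(comp)
  evals <- matrix(NA_real_, n, 3)
  e1 <- matrix(NA_real_, n, 3)
  ok <- rowSums(is.na(comp)) == 0
  for (q in which(ok)) {
    es <- .tensorEigen(comp[q, ])
    evals[q, ] <- pmax(es$values, 0)
    e1[q, ] <- es$vectors[, 1]
  }
  list(evals = evals, e1 = e1)
}

# Track one direction from a start point; returns points (excluding start)
# and a termination reason.
.trackOneWay <- function(field, maskArr, start, dir0, step, faMin,
                         maxTurnDeg, maxLen, startLen = 0) {
  cosMax <- cos(deg2rad(maxTurnDeg))
  pts <- matrix(numeric(0), 0, 3)
  pos <- start
  dir <- dir0
  len <- startLen
  repeat {
    cand <- pos + step * dir
    vox <- worldToVoxel(matrix(cand, 1), field@affine)
    inMask <- !is.na(interpNearest(maskArr, vox)) &&
      interpNearest(maskArr, vox) > 0
    if (!inMask) return(list(points = pts, reason = "mask-exit"))
    ts <- .tensorAtPoints(field, matrix(cand, 1))
    if (any(is.na(ts$e1[1, ]))) return(list(points = pts, reason = "mask-exit"))
    fa <- faFromEvals(ts$evals)[1]
    if (fa < faMin) return(list(points = pts, reason = "fa-stop"))
    newDir <- ts$e1[1, ]
    if (sum(newDir * dir) < 0) newDir <- -newDir   # re-orient to previous step
    if (sum(newDir * dir) < cosMax)
      return(list(points = pts, reason = "angle-stop"))
    pos <- cand
    dir <- newDir
    pts <- rbind(pts, pos)
    len <- len + step
    if (len >= maxLen) return(list(points = pts, reason = "length-cap"))
  }
}

#' Longest chord of an ROI bounding box
#'
#' The world-mm diagonal of the ROI's voxel bounding box — the least
#' restrictive reading of capping tract length at the maximum length of the
#' ROI.
#'
#' @param mask Logical ROI array.
#' @param affine Voxel-to-world affine.
#' @return Length in mm.
#' @export
roiMaxChord <- function(mask, affine) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty ROI")
  lo <- voxelToWorld(matrix(apply(idx, 2, min), 1), affine)
  hi <- voxelToWorld(matrix(apply(idx, 2, max), 1), affine)
  vx <- sqrt(colSums(affine[1:3, 1:3]^2))
  sqrt(sum((hi - lo + vx)^2))   # include the voxel extent itself
}

#' Deterministic streamline tractography
#'
#' Bidirectional fixed-step Euler integration of the primary eigenvector
#' field from every seed voxel center. At each step the tensor components
#' are trilinearly interpolated, eigendecomposed, and the new direction
#' sign-aligned with the previous step. A branch stops when FA falls below
#' \code{faMin}, the turning angle exceeds \code{maxTurn}, the tracking mask
#' is exited, or the cumulative (two-branch) length reaches \code{maxLen}.
#' Tracking is fully deterministic: identical inputs give identical
#' streamlines and termination reasons.
#'
#' @param field A \linkS4class{DiffusionTensorField}.
#' @param seedMask Logical array of seed voxels.
#' @param trackMask Logical array constraining tracking (e.g. the wall).
#' @param step Step size in mm (default 0.15, half a 0.3 mm voxel).
#' @param faMin FA stopping threshold (default 0.1).
#' @param maxTurn Maximum per-step turning angle in degrees (default 60).
#' @param maxLen Maximum streamline length in mm; \code{NULL} caps at the
#'   seed-ROI bounding-box diagonal (the ROI-length cap used for graft
#'   runs), \code{Inf} disables the cap.
#' @return A \linkS4class{StreamlineSet}.
#' @export
trackStreamlines <- function(field, seedMask, trackMask, step = 0.15,
                             faMin = 0.1, maxTurn = 60, maxLen = NULL) {
  stopifnot(step > 0, faMin >= 0, maxTurn > 0)
  if (!any(seedMask)) stop("empty seed mask")
  if (is.null(maxLen)) maxLen <- roiMaxChord(seedMask, field@affine)
  maskArr <- array(as.numeric(trackMask), dim = dim(trackMask))
  seeds <- which(seedMask, arr.ind = TRUE)
  pts <- voxelToWorld(seeds, field@affine)
  t0 <- .tensorAtPoints(field, pts)
  points <- vector("list", nrow(seeds))
  reasons <- character(nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    if (any(is.na(t0$e1[s, ]))) {
      points[[s]] <- matrix(pts[s, ], 1)
      reasons[s] <- "fa-stop|fa-stop"
      next
    }
    fa0 <- faFromEvals(matrix(t0$evals[s, ], 1))[1]
    if (fa0 < faMin) {
      points[[s]] <- matrix(pts[s, ], 1)
      reasons[s] <- "fa-stop|fa-stop"
      next
    }
    dir <- t0$e1[s, ]
    fwd <- .trackOneWay(field, maskArr, pts[s, ], dir, step, faMin,
                        maxTurn, maxLen / 2)
    bwd <- .trackOneWay(field, maskArr, pts[s, ], -dir, step, faMin,
                        maxTurn, maxLen / 2)
    track <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
                   matrix(pts[s, ], 1),
                   fwd$points)
    rownames(track) <- NULL
    points[[s]] <- track
    reasons[s] <- paste(bwd$reason, fwd$reason, sep = "|")
  }
  new("StreamlineSet", points = points, seeds = seeds, reasons = reasons,
      step = step, affine = field@affine)
}

#' Write streamlines to a TCK file
#'
#' MRtrix track format: a text header, then little-endian float32 xyz
#' triplets in world mm, streamlines separated by a NaN triplet and the
#' stream terminated by an Inf triplet.
#'
#' @param streamlines A \linkS4class{StreamlineSet} (or list of n x 3
#'   matrices).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTCK <- function(streamlines, path) {
  tracks <- if (is(streamlines, "StreamlineSet")) streamlines@points
            else streamlines
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           paste0("count: ", length(tracks)),
           "file: . 0",
           "END")
  # fixed point: the stated data offset must equal the header's own length
  offset <- 0L
  repeat {
    hdr[4] <- paste0("file: . ", offset)
    size <- sum(nchar(hdr, type = "bytes")) + length(hdr)  # + newlines
    if (size == offset) break
    offset <- size
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  for (tr in tracks) {
    if (nrow(tr))
      writeBin(as.numeric(t(tr)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK file
#'
#' @param path Path to a TCK file written by \code{\link{writeTCK}} or any
#'   MRtrix-compatible tool (Float32LE data).
#' @return List of n x 3 matrices of world-mm points.
#' @export
readTCK <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  endPat <- charToRaw("\nEND\n")
  endAt <- NA_integer_
  for (q in seq_len(min(length(bytes) - 4L, 4096L))) {
    if (identical(bytes[q:(q + 4L)], endPat)) { endAt <- q + 4L; break }
  }
  if (is.na(endAt)) stop("malformed TCK header")
  hdr <- strsplit(rawToChar(bytes[1:endAt]), "\n", fixed = TRUE)[[1]]
  if (!identical(hdr[1], "mrtrix tracks")) stop("not a TCK file")
  fileLine <- grep("^file:", hdr, value = TRUE)
  offset <- as.integer(sub("^file: \\. ", "", fileLine))
  raw <- readBin(bytes[(offset + 1L):length(bytes)], "numeric",
                 n = length(bytes), size = 4L, endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  tracks <- list()
  cur <- matrix(numeric(0), 0, 3)
  for (q in seq_len(nrow(m))) {
    row <- m[q, ]
    if (all(is.infinite(row))) break
    if (all(is.nan(row))) {
      tracks[[length(tracks) + 1L]] <- cur
      cur <- matrix(numeric(0), 0, 3)
    } else {
      cur <- rbind(cur, row)
    }
  }
  lapply(tracks, function(t) { rownames(t) <- NULL; t })
}
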