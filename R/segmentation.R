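# Scar / graft / remote segmentation from the contrast-enhanced volume:
# sector-based remote definition, the 5-standard-deviation hyperenhancement
# rule, and seeded running-mean region growing for the graft pocket.

# In-slice angle (degrees in [0, 360)) of every voxel about the per-slice
# cavity centroid.
.sliceAngles <- function(wall, endo) {
  d <- dim(wall)
  cen <- .sliceCentroids(endo, wall)
  ijk <- which(array(TRUE, d), arr.ind = TRUE)
  th <- atan2(ijk[, 2] - cen[ijk[, 3], 2], ijk[, 1] - cen[ijk[, 3], 1])
  array(rad2deg(th) %% 360, d)
}

#' Define the remote myocardium sector
#'
#' Remote tissue is the set of wall voxels whose in-slice angle about the
#' cavity centroid falls within the given angular span — a simplified
#' mid-cavity sector model in which the default 120-degree span stands in
#' for the two standard mid-ventricular reference segments (inferoseptal +
#' inferior), anchored at a configurable reference angle.
#'
#' @param wall Logical wall mask.
#' @param endo Logical cavity mask (for per-slice centroids).
#' @param sectorDeg Angular span c(start, end) in degrees, counter-clockwise,
#'   wrap-around allowed; default c(210, 330).
#' @return Logical remote mask.
#' @export
defineRemote <- function(wall, endo, sectorDeg = c(210, 330)) {
  lo <- sectorDeg[1] %% 360; hi <- sectorDeg[2] %% 360
  if (isTRUE(all.equal(lo, hi)))
    stop("remote sector span is empty")
  th <- .sliceAngles(wall, endo)
  inSec <- if (lo < hi) th >= lo & th < hi else th >= lo | th < hi
  remote <- wall & inSec
  if (!any(remote)) stop("remote sector contains no wall voxels")
  remote
}

#' Segment scar by the 5-SD hyperenhancement rule
#'
#' Scar is every wall voxel whose contrast-enhanced intensity exceeds the
#' remote mean plus 5 remote sample standard deviations (n - 1 denominator).
#' The threshold and remote statistics are recorded for provenance.
#'
#' @param ce CE intensity array on the analysis grid (NA allowed for voxels
#'   excluded by resampling).
#' @param remote Logical remote mask.
#' @param wall Logical wall mask.
#' @param nSD Number of SDs above the remote mean (default 5).
#' @return List with \code{mask} (logical scar mask) and \code{provenance}
#'   (threshold, remote mean/SD/n).
#' @export
segmentScar <- function(ce, remote, wall, nSD = 5) {
  vals <- ce[remote]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) stop("remote region too small for statistics")
  m <- mean(vals); s <- stats::sd(vals)
  if (s == 0) stop("degenerate remote statistics: zero variance")
  thr <- m + nSD * s
  mask <- wall & !is.na(ce) & ce > thr
  list(mask = mask,
       provenance = list(threshold = thr, remote_mean = m, remote_sd = s,
                         remote_n = length(vals), n_sd = nSD))
}

# 26-connected neighbour offsets.
.neighbours26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Grow the graft mask by seeded region growing
#'
#' 26-connected flood fill from the seed voxels: a neighbour is accepted when
#' its intensity differs from the running mean of the accepted region by at
#' most \code{tolerance}, constrained to the wall. Accepted voxels are meant
#' to be removed from the scar label by the caller (see
#' \code{\link{segmentRegions}}).
#'
#' @param ce CE intensity array.
#' @param wall Logical wall mask constraining growth.
#' @param seeds Integer matrix (n x 3) of seed voxel indices (1-based).
#' @param tolerance Intensity tolerance (> 0).
#' @return List with \code{mask} (logical graft mask) and \code{provenance}
#'   (seeds, tolerance, final region mean, voxel count).
#' @export
growGraft <- function(ce, wall, seeds, tolerance) {
  if (!(tolerance > 0)) stop("tolerance must be positive")
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  d <- dim(ce)
  lin <- function(ijk) ijk[, 1] + d[1] * (ijk[, 2] - 1) +
    d[1] * d[2] * (ijk[, 3] - 1)
  sLin <- lin(seeds)
  if (any(!wall[sLin])) stop("region-growing seed outside the wall mask")
  accepted <- logical(prod(d))
  accepted[sLin] <- TRUE
  total <- sum(ce[sLin]); count <- length(sLin)
  queue <- sLin
  wallV <- as.vector(wall); ceV <- as.vector(ce)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    i <- ((cur - 1) %% d[1]) + 1
    j <- (((cur - 1) %/% d[1]) %% d[2]) + 1
    k <- ((cur - 1) %/% (d[1] * d[2])) + 1
    nb <- sweep(.neighbours26, 2, c(i, j, k), "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbLin <- lin(nb[keep, , drop = FALSE])
    nbLin <- nbLin[!accepted[nbLin] & wallV[nbLin] & is.finite(ceV[nbLin])]
    if (!length(nbLin)) next
    ok <- abs(ceV[nbLin] - total / count) <= tolerance
    add <- nbLin[ok]
    if (length(add)) {
      accepted[add] <- TRUE
      total <- total + sum(ceV[add]); count <- count + length(add)
      queue <- c(queue, add)
    }
  }
  mask <- array(accepted, d)
  if (sum(mask) > 0.5 * sum(wall))
    warning("region growing reached more than half the wall: ",
            "tolerance is probably too loose")
  list(mask = mask,
       provenance = list(seeds = seeds, tolerance = tolerance,
                         region_mean = total / count, n_voxels = count))
}

#' Full region labelling from a CE volume
#'
#' Applies \code{\link{defineRemote}}, \code{\link{segmentScar}} and
#' (optionally) \code{\link{growGraft}}, carves the graft out of the scar
#' label, and labels the rest of the wall as other-wall tissue.
#'
#' @param ce CE intensity array on the analysis grid.
#' @param wall,endo Logical masks.
#' @param sectorDeg Remote sector span (degrees), default c(210, 330).
#' @param graftSeeds Optional n x 3 integer matrix of graft seeds.
#' @param graftTolerance Region-growing tolerance (required with seeds).
#' @param affine Voxel-to-world affine for the result.
#' @return A \linkS4class{RegionLabels}.
#' @export
segmentRegions <- function(ce, wall, endo, sectorDeg = c(210, 330),
                           graftSeeds = NULL, graftTolerance = NULL,
                           affine = diag(4)) {
  remote <- defineRemote(wall, endo, sectorDeg)
  scar <- segmentScar(ce, remote, wall)
  labels <- array(0L, dim = dim(ce))
  labels[wall] <- .REGION_LEVELS[["otherwall"]]
  labels[remote] <- .REGION_LEVELS[["remote"]]
  labels[scar$mask] <- .REGION_LEVELS[["scar"]]
  prov <- list(scar = scar$provenance, remote_sector = sectorDeg)
  if (!is.null(graftSeeds)) {
    if (is.null(graftTolerance))
      stop("graftTolerance is required when graftSeeds are given")
    graft <- growGraft(ce, wall, graftSeeds, graftTolerance)
    labels[graft$mask] <- .REGION_LEVELS[["graft"]]
    prov$graft <- graft$provenance
  }
  new("RegionLabels", labels = labels, provenance = prov, affine = affine)
}

#' Per-region summary statistics of scalar maps
#'
#' For each region and each supplied map: number of valid voxels, mean,
#' sample SD (n - 1) and SEM. Empty regions yield a row with n = 0 and NA
#' statistics; single-voxel regions have NA SD and are flagged by n = 1.
#'
#' @param labels A \linkS4class{RegionLabels} (or integer label array).
#' @param maps Named list of scalar arrays (or \linkS4class{ImageVolume}s)
#'   on the same grid, e.g. \code{list(FA = fa, MD = md)}.
#' @param regions Regions to summarize (default remote, scar, graft).
#' @return data.frame with columns region, metric, n, mean, sd, sem.
#' @export
regionSummary <- function(labels, maps,
                          regions = c("remote", "scar", "graft")) {
  lab <- if (is(labels, "RegionLabels")) labels@labels else labels
  rows <- list()
  for (r in regions) {
    idx <- lab == .REGION_LEVELS[[r]]
    for (m in names(maps)) {
      arr <- maps[[m]]
      if (is(arr, "ImageVolume")) arr <- arr@data
      v <- arr[idx]
      v <- v[is.finite(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, metric = m, n = n,
        mean = if (n > 0) mean(v) else NA_real_,
        sd = if (n > 1) stats::sd(v) else NA_real_,
        sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
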