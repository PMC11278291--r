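# Scalar structural summaries: transmural helix-angle profile and
# transmurality (HAT), handedness class fractions, and transverse-angle
# dispersion as an alignment marker.

# Extract matched finite (HA, TD) vectors over an ROI.
.anglePairs <- function(ha, td, roi) {
  if (is(ha, "AngleMaps")) {
    roi <- roi & ha@valid
    ha <- ha@ha
  }
  keep <- roi & is.finite(ha) & is.finite(td)
  list(ha = ha[keep], td = td[keep])
}

#' Binned transmural helix-angle profile
#'
#' Voxels with transmural depth outside the retained window (default: the
#' first 15 percent and the last 25 percent of the wall are omitted, because
#' grafts localize to the mid-myocardium and the borders suffer
#' partial-volume effects) are discarded; the rest are assigned to contiguous
#' 15-percent bins, half-open at the low edge with the final bin closed at
#' the window top: [15,30), [30,45), [45,60), [60,75].
#'
#' @param ha HA array in degrees (or an \linkS4class{AngleMaps}).
#' @param td Transmural-depth array in percent.
#' @param roi Logical mask of voxels to profile.
#' @param window Retained TD window in percent, default c(15, 75).
#' @param binWidth Bin width in percent TD, default 15.
#' @return data.frame with td_lo, td_hi, n, mean_ha, sd_ha per bin.
#' @export
binHAProfile <- function(ha, td, roi, window = c(15, 75), binWidth = 15) {
  p <- .anglePairs(ha, td, roi)
  keep <- p$td >= window[1] & p$td <= window[2]
  if (!any(keep)) stop("all voxels fall outside the retained TD window")
  haK <- p$ha[keep]; tdK <- p$td[keep]
  edges <- seq(window[1], window[2], by = binWidth)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  bin <- findInterval(tdK, edges, rightmost.closed = TRUE)
  out <- lapply(seq_len(length(edges) - 1L), function(b) {
    v <- haK[bin == b]
    data.frame(td_lo = edges[b], td_hi = edges[b + 1L], n = length(v),
               mean_ha = if (length(v)) mean(v) else NA_real_,
               sd_ha = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' Helix-angle transmurality (HAT)
#'
#' Ordinary least-squares fit of per-voxel helix angle on transmural depth
#' over the retained window, reported as slope (degrees per percent TD),
#' intercept, Pearson r of the same pairs, voxel count, and the binned
#' profile. A config switch fits the bin means instead of per-voxel pairs.
#'
#' @inheritParams binHAProfile
#' @param useBinMeans Fit the binned means (weighted by bin count) instead
#'   of per-voxel pairs (default FALSE).
#' @return List of class \code{"HATResult"}: slope, intercept, pearson_r,
#'   n_voxels, bin_profile.
#' @export
fitHAT <- function(ha, td, roi, window = c(15, 75), binWidth = 15,
                   useBinMeans = FALSE) {
  p <- .anglePairs(ha, td, roi)
  keep <- p$td >= window[1] & p$td <= window[2]
  if (!any(keep)) stop("all voxels fall outside the retained TD window")
  haK <- p$ha[keep]; tdK <- p$td[keep]
  if (length(unique(tdK)) < 2L)
    stop("constant transmural depth: HAT slope is undefined")
  profile <- binHAProfile(ha, td, roi, window, binWidth)
  if (useBinMeans) {
    pf <- profile[profile$n > 0, ]
    mid <- (pf$td_lo + pf$td_hi) / 2
    fit <- stats::lm(pf$mean_ha ~ mid, weights = pf$n)
    r <- stats::cov.wt(cbind(mid, pf$mean_ha), wt = pf$n, cor = TRUE)$cor[1, 2]
    n <- sum(pf$n)
  } else {
    fit <- stats::lm(haK ~ tdK)
    r <- if (stats::sd(haK) > 0) stats::cor(tdK, haK) else 0
    n <- length(haK)
  }
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              pearson_r = r, n_voxels = n, bin_profile = profile)
  class(out) <- "HATResult"
  out
}

#' @export
print.HATResult <- function(x, ...) {
  cat(sprintf("HAT: slope %.3f deg/%%TD, intercept %.1f deg, r = %.3f (n = %d)\n",
              x$slope, x$intercept, x$pearson_r, x$n_voxels))
  invisible(x)
}

#' Helix-angle handedness class fractions
#'
#' Classifies voxels as right-handed (HA in (+30, +90]), circumferential
#' (HA in [-30, +30]) or left-handed (HA in [-90, -30)); the +/-30 degree
#' boundaries are assigned to the circumferential class (documented
#' tie-break). Fractions are over valid voxels and sum to 1.
#'
#' @param ha HA array in degrees (or an \linkS4class{AngleMaps}).
#' @param roi Logical mask.
#' @return Named numeric vector c(rh, circumferential, lh).
#' @export
classifyHandedness <- function(ha, roi) {
  if (is(ha, "AngleMaps")) {
    roi <- roi & ha@valid
    ha <- ha@ha
  }
  v <- ha[roi]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no valid voxels in ROI")
  n <- length(v)
  c(rh = sum(v > 30) / n,
    circumferential = sum(v >= -30 & v <= 30) / n,
    lh = sum(v < -30) / n)
}

#' Transverse-angle dispersion (alignment marker)
#'
#' Sample standard deviation (n - 1) of the signed transverse angle over the
#' ROI; low dispersion indicates well-aligned myocytes. Angles within 5
#' degrees of +/-90 are counted and reported with a warning, since the
#' linear SD ignores wrap-around there.
#'
#' @param ta TA array in degrees (or an \linkS4class{AngleMaps}).
#' @param roi Logical mask.
#' @return SD of TA in degrees.
#' @export
taAlignment <- function(ta, roi) {
  if (is(ta, "AngleMaps")) {
    roi <- roi & ta@valid
    ta <- ta@ta
  }
  v <- ta[roi]
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least 2 valid voxels for TA dispersion")
  nearWrap <- sum(abs(v) > 85)
  if (nearWrap > 0)
    warning(nearWrap, " TA values within 5 degrees of +/-90; ",
            "linear SD ignores wrap-around there")
  stats::sd(v)
}

#' One-row structural summary of an ROI
#'
#' Convenience wrapper producing the per-region metric row used in report
#' tables: FA/MD mean and SD, HAT slope and r, TA dispersion, and handedness
#' fractions.
#'
#' @param angles An \linkS4class{AngleMaps}.
#' @param td Transmural-depth array (percent).
#' @param fa,md Scalar arrays or \linkS4class{ImageVolume}s.
#' @param roi Logical mask.
#' @param region Region name for the row.
#' @param window Retained TD window for HAT.
#' @return One-row data.frame.
#' @export
structureSummary <- function(angles, td, fa, md, roi, region = "roi",
                             window = c(15, 75)) {
  if (is(fa, "ImageVolume")) fa <- fa@data
  if (is(md, "ImageVolume")) md <- md@data
  hat <- fitHAT(angles, td, roi, window = window)
  hand <- classifyHandedness(angles, roi)
  fav <- fa[roi]; fav <- fav[is.finite(fav)]
  mdv <- md[roi]; mdv <- mdv[is.finite(mdv)]
  data.frame(region = region,
             n = sum(roi & angles@valid),
             fa_mean = mean(fav), fa_sd = stats::sd(fav),
             md_mean = mean(mdv), md_sd = stats::sd(mdv),
             hat_slope = hat$slope, hat_r = hat$pearson_r,
             ta_sd = taAlignment(angles, roi),
             frac_rh = unname(hand["rh"]),
             frac_circ = unname(hand["circumferential"]),
             frac_lh = unname(hand["lh"]))
}
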