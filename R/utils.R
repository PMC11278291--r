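# Internal numeric helpers shared across modules.

# Row-wise Euclidean norms of an n x 3 matrix.
rowNorms <- function(m) sqrt(rowSums(m * m))

# Normalize rows of an n x 3 matrix; zero rows are left as zero.
normalizeRows <- function(m) {
  n <- rowNorms(m)
  ok <- n > 0
  m[ok, ] <- m[ok, , drop = FALSE] / n[ok]
  m
}

# Cross product of rows of two n x 3 matrices.
rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dice similarity coefficient of two masks
#'
#' @param a,b Logical arrays (or arrays coercible to logical) of identical
#'   dimension.
#' @return Dice coefficient in \code{[0, 1]}; 1 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Voxel (1-based index) -> world mm coordinates under a NIfTI-style affine
# (which maps 0-based indices to world).
voxelToWorld <- function(idx, affine) {
  idx <- rbind(t(idx - 1), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

worldToVoxel <- function(xyz, affine) {
  xyz <- rbind(t(xyz), 1)
  t(solve(affine) %*% xyz)[, 1:3, drop = FALSE] + 1
}

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates (n x 3 matrix). Points outside the grid return NA.
interpTrilinear <- function(arr, coords) {
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  inside <- x0 >= 1 & y0 >= 1 & z0 >= 1 &
    x0 + 1 <= d[1] & y0 + 1 <= d[2] & z0 + 1 <= d[3]
  # points exactly on the upper face are still inside
  onFaceX <- x == d[1] & x0 == d[1]
  x0[onFaceX] <- d[1] - 1
  onFaceY <- y == d[2] & y0 == d[2]
  y0[onFaceY] <- d[2] - 1
  onFaceZ <- z == d[3] & z0 == d[3]
  z0[onFaceZ] <- d[3] - 1
  inside <- inside | ((x0 >= 1 & y0 >= 1 & z0 >= 1 &
                         x0 + 1 <= d[1] & y0 + 1 <= d[2] & z0 + 1 <= d[3]) &
                        (onFaceX | onFaceY | onFaceZ))
  out <- rep(NA_real_, nrow(coords))
  if (!any(inside)) return(out)
  x0 <- x0[inside]; y0 <- y0[inside]; z0 <- z0[inside]
  fx <- x[inside] - x0; fy <- y[inside] - y0; fz <- z[inside] - z0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[inside] <- v
  out
}

# Nearest-neighbour lookup at continuous 1-based voxel coordinates.
interpNearest <- function(arr, coords) {
  d <- dim(arr)
  idx <- round(coords)
  inside <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= d[1] & idx[, 2] <= d[2] & idx[, 3] <= d[3]
  out <- rep(NA_real_, nrow(coords))
  out[inside] <- arr[idx[inside, , drop = FALSE]]
  out
}

# Closed-form FA from an n x 3 eigenvalue matrix.
faFromEvals <- function(ev) {
  m <- rowMeans(ev)
  num <- sqrt(rowSums((ev - m)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- sqrt(1.5) * ifelse(den > 0, num / den, 0)
  pmin(pmax(fa, 0), 1)
}

# Run an expression with a temporarily-set RNG seed, restoring prior state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
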