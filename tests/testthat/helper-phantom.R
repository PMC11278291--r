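# Small fast phantom for unit tests: 32 x 32 x 8 grid, thin wall, and the
# same region / acquisition defaults as the full-size phantom.
smallSpec <- function(...) {
  phantomSpec(gridShape = c(32L, 32L, 8L), endoRadius = 1.8, epiRadius = 3.9,
              ...)
}

# Noiseless, dispersion-free small phantom used by exact-recovery tests.
noiselessPhantom <- function(...) {
  simulatePhantom(smallSpec(snrB0 = Inf, taSDTrue = 0, ...))
}

# Independent scalar FA implementation (oracle for the array code path).
faScalar <- function(ev) {
  m <- mean(ev)
  sqrt(3 / 2) * sqrt(sum((ev - m)^2)) / sqrt(sum(ev^2))
}

# Rotate tensor components (n x 6, order xx,yy,zz,xy,xz,yz) by a rotation A.
rotateTensors <- function(tc, A) {
  t(apply(tc, 1, function(v) {
    D <- matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3)
    Dr <- A %*% D %*% t(A)
    c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3])
  }))
}

# Uniform anisotropic tensor field along a given axis on a slab grid.
slabField <- function(d = c(21L, 7L, 7L), axis = c(1, 0, 0),
                      evals = c(1.8e-3, 0.6e-3, 0.5e-3), voxel = 1) {
  axis <- axis / sqrt(sum(axis^2))
  basis <- diag(3)
  e2 <- basis[, which.min(abs(axis))]
  e2 <- e2 - axis * sum(e2 * axis); e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(axis[2] * e2[3] - axis[3] * e2[2],
          axis[3] * e2[1] - axis[1] * e2[3],
          axis[1] * e2[2] - axis[2] * e2[1])
  D <- evals[1] * outer(axis, axis) + evals[2] * outer(e2, e2) +
    evals[3] * outer(e3, e3)
  comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  tensors <- array(rep(comp, each = prod(d)), c(d, 6))
  methods::new("DiffusionTensorField", tensors = tensors,
      S0 = array(1000, d), evals = array(rep(evals, each = prod(d)), c(d, 3)),
      evecs = array(0, c(d, 3, 3)), mask = array(TRUE, d),
      flags = array(0L, d), affine = diag(c(voxel, voxel, voxel, 1)))
}

randomRotation <- function() {
  A <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  A
}
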