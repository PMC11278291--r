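test_that("LLS fit inverts the noiseless forward model exactly", {
  ph <- noiselessPhantom()
  field <- fitTensorLLS(ph@dwi, ph@gtab, ph@wall, affine = ph@affine)
  sel <- rep(as.vector(ph@wall), 6)
  relErr <- max(abs(field@tensors - ph@tensorTrue)[sel]) / max(ph@tensorTrue)
  expect_lt(relErr, 1e-8)
  expect_true(all(field@flags[ph@wall] == 0L))
  # eigen-system: values to 1e-9 relative, e1 to 1e-6 rad up to sign
  ev <- matrix(eigenvalues(field), ncol = 3)[which(ph@wall), ]
  evTrue <- ph@spec$regionEvals$remote
  remoteIdx <- which(as.vector(ph@labelsTrue) == 1L)
  evR <- matrix(eigenvalues(field), ncol = 3)[remoteIdx, ]
  expect_lt(max(abs(sweep(evR, 2, evTrue)) / evTrue[1]), 1e-9)
  e1 <- matrix(eigenvectors(field, 1), ncol = 3)[which(ph@wall), ]
  e1True <- matrix(ph@e1True, ncol = 3)[which(ph@wall), ]
  ang <- acos(pmin(abs(rowSums(e1 * e1True)), 1))
  expect_lt(max(ang), 1e-6)
})

test_that("pseudo-inverse oracle agrees with the QR solve path", {
  # independent route: explicit Moore-Penrose solve of the same log-linear
  # system at a handful of voxels
  ph <- noiselessPhantom()
  X <- cardioDTI:::.dtiDesign(ph@gtab)
  pinv <- solve(t(X) %*% X) %*% t(X)
  field <- fitTensorLLS(ph@dwi, ph@gtab, ph@wall, affine = ph@affine)
  idx <- which(ph@wall, arr.ind = TRUE)[c(1, 101, 501), , drop = FALSE]
  for (q in seq_len(nrow(idx))) {
    s <- ph@dwi[idx[q, 1], idx[q, 2], idx[q, 3], ]
    beta <- pinv %*% log(s)
    expect_equal(field@tensors[idx[q, 1], idx[q, 2], idx[q, 3], ],
                 as.numeric(beta[2:7]), tolerance = 1e-10)
    expect_equal(field@S0[idx[q, 1], idx[q, 2], idx[q, 3]],
                 exp(beta[1]), tolerance = 1e-10)
  }
})

test_that("degenerate designs and signals are handled as specified", {
  ph <- noiselessPhantom()
  b0only <- gradientTable(rep(0, 5), matrix(0, 3, 5))
  expect_error(fitTensorLLS(ph@dwi[, , , 1:5], b0only, ph@wall),
               "configuration error")
  few <- gradientTable(c(0, rep(700, 3)),
                       cbind(c(0, 0, 0), diag(3)))
  expect_error(fitTensorLLS(ph@dwi[, , , 1:4], few, ph@wall),
               "6 unique")
  # a voxel with a non-positive signal is flagged invalid, not fatal
  dwi <- ph@dwi
  vox <- which(ph@wall, arr.ind = TRUE)[1, ]
  dwi[vox[1], vox[2], vox[3], 7] <- 0
  field <- fitTensorLLS(dwi, ph@gtab, ph@wall, affine = ph@affine)
  expect_equal(field@flags[vox[1], vox[2], vox[3]], 2L)
  expect_true(is.na(computeFA(field)@data[vox[1], vox[2], vox[3]]))
})

test_that("FA limits and closed form; MD is the trace identity", {
  mkField <- function(ev) {
    d <- c(1L, 1L, 1L)
    new("DiffusionTensorField",
        tensors = array(c(ev, 0, 0, 0), c(d, 6)),
        S0 = array(1, d), evals = array(ev, c(d, 3)),
        evecs = array(diag(3), c(d, 3, 3)),
        mask = array(TRUE, d), flags = array(0L, d), affine = diag(4))
  }
  expect_equal(computeFA(mkField(c(1, 1, 1)))@data[1, 1, 1], 0)
  expect_equal(computeFA(mkField(c(1, 0, 0)))@data[1, 1, 1], 1)
  expect_equal(computeFA(mkField(c(1.8e-3, 0.6e-3, 0.6e-3)))@data[1, 1, 1],
               0.6030227, tolerance = 1e-7)
  expect_equal(computeMD(mkField(c(1.8e-3, 0.6e-3, 0.6e-3)))@data[1, 1, 1],
               1.0e-3, tolerance = 1e-12)
  # MD equals trace(D)/3 for random SPD tensors (independent of eigen route)
  set.seed(3)
  for (q in 1:100) {
    B <- matrix(rnorm(9), 3)
    D <- B %*% t(B) + diag(3) * 0.1
    es <- eigen(D, symmetric = TRUE)
    f <- mkField(es$values)
    expect_equal(computeMD(f)@data[1, 1, 1], sum(diag(D)) / 3,
                 tolerance = 1e-12)
  }
})

test_that("FA and MD are rotation-invariant under joint refitting", {
  spec <- phantomSpec(gridShape = c(16, 16, 4), endoRadius = 0.9,
                      epiRadius = 2.1, snrB0 = Inf, taSDTrue = 0)
  geom <- buildGeometry(spec)
  fib <- buildFiberField(spec, geom)
  tens <- assignTensors(fib$e1True, buildRegionLabels(spec, geom), spec, geom)
  gtab <- phantomGradientTable(spec)
  dwi <- simulateDWI(tens, 1000, gtab, Inf, 1, geom$wall)
  f1 <- fitTensorLLS(dwi, gtab, geom$wall)
  fa1 <- computeFA(f1)@data; md1 <- computeMD(f1)@data
  set.seed(11)
  A <- randomRotation()
  w <- which(geom$wall); n3 <- prod(dim(geom$wall))
  tcr <- rotateTensors(matrix(tens, ncol = 6)[w, , drop = FALSE], A)
  tensR <- array(0, dim = dim(tens))
  for (cc in 1:6) tensR[w + (cc - 1) * n3] <- tcr[, cc]
  dwiR <- simulateDWI(tensR, 1000, gradientTable(bvals(gtab), A %*% bvecs(gtab)),
                      Inf, 1, geom$wall)
  f2 <- fitTensorLLS(dwiR, gradientTable(bvals(gtab), A %*% bvecs(gtab)),
                     geom$wall)
  expect_lt(max(abs(computeFA(f2)@data - fa1)[geom$wall]), 1e-8)
  expect_lt(max(abs(computeMD(f2)@data - md1)[geom$wall]) / max(md1[geom$wall]),
            1e-8)
})

test_that("FA error at SNR 25 stays within the Monte-Carlo band", {
  # full-size acquisition geometry; tolerance established by pre-build
  # simulation of the same conditions
  ph <- simulatePhantom(phantomSpec(snrB0 = 25, seed = 1))
  field <- fitTensorLLS(ph@dwi, ph@gtab, ph@wall, affine = ph@affine)
  fa <- computeFA(field)@data
  faTrue <- faScalar(ph@spec$regionEvals$remote)
  err <- abs(fa - faTrue)[ph@labelsTrue == 1L]
  expect_lt(median(err, na.rm = TRUE), 0.03)
})
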