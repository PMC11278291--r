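test_that("geometry gives the analytic annulus and transmural depth", {
  spec <- smallSpec()
  geom <- buildGeometry(spec)
  r <- geom$radius
  expect_true(all((r >= spec$endoRadius & r <= spec$epiRadius)[geom$wall]))
  expect_false(any(geom$wall & geom$endo) || any(geom$wall & geom$epi))
  # TD is the exact linear function of radius, clipped to [0, 100]
  tdExpect <- pmin(pmax(
    100 * (r - spec$endoRadius) / (spec$epiRadius - spec$endoRadius), 0), 100)
  expect_equal(geom$tdTrue, tdExpect)
  # voxels inside the cavity are outside the wall mask
  expect_true(all(!geom$wall[r < spec$endoRadius]))
})

test_that("degenerate radii are rejected", {
  expect_error(phantomSpec(endoRadius = 4, epiRadius = 3), "endoRadius")
  expect_error(phantomSpec(haEndo = 120), "-90")
  expect_error(phantomSpec(snrB0 = 0), "snrB0")
})

test_that("fiber field follows the linear helix rule and injected dispersion", {
  spec <- smallSpec(snrB0 = Inf, taSDTrue = 0)
  geom <- buildGeometry(spec)
  fib <- buildFiberField(spec, geom)
  expect_equal(fib$haTrue,
               spec$haEndo + (spec$haEpi - spec$haEndo) * geom$tdTrue / 100)
  expect_true(all(fib$taTrue == 0))
  # midpoint of the transmural course is exactly 0 degrees
  mid <- abs(geom$tdTrue - 50) < 1e-9
  expect_true(all(abs(fib$haTrue[mid]) < 1e-9))
  # e1 recovers both injected angles under the package conventions
  fr <- cardioDTI:::.cylinderFrames(geom)
  e1 <- matrix(fib$e1True, ncol = 3)
  haRec <- atan2(rowSums(e1 * fr$longit), rowSums(e1 * fr$circ)) * 180 / pi
  expect_lt(max(abs(haRec - as.vector(fib$haTrue))[as.vector(geom$wall)]), 1e-9)
  # ground-truth HA regressed on TD recovers the generating slope exactly
  hat <- fitHAT(fib$haTrue, geom$tdTrue, geom$wall, window = c(0, 100))
  expect_equal(hat$slope, (spec$haEpi - spec$haEndo) / 100, tolerance = 1e-9)
})

test_that("transverse-angle dispersion is injected at the requested SD", {
  spec <- smallSpec(taSDTrue = 12)
  geom <- buildGeometry(spec)
  fib <- buildFiberField(spec, geom)
  expect_equal(sd(fib$taTrue[geom$wall]), 12, tolerance = 0.05 * 12)
  fr <- cardioDTI:::.cylinderFrames(geom)
  e1 <- matrix(fib$e1True, ncol = 3)
  taRec <- atan2(rowSums(e1 * fr$radial), rowSums(e1 * fr$circ)) * 180 / pi
  expect_lt(max(abs(taRec - as.vector(fib$taTrue))[as.vector(geom$wall)]), 1e-9)
})

test_that("assigned tensors have the region closed-form FA and MD", {
  ph <- noiselessPhantom()
  tc <- matrix(ph@tensorTrue, ncol = 6)
  for (reg in c(remote = 1L, scar = 2L, graft = 3L)) {
    ev <- ph@spec$regionEvals[[c("remote", "scar", "graft")[reg]]]
    idx <- which(ph@labelsTrue == reg)[1:25]
    for (q in idx) {
      es <- cardioDTI:::.tensorEigen(tc[q, ])
      expect_equal(es$values, ev, tolerance = 1e-12)
    }
    # MD equals the eigenvalue mean, FA the independent scalar closed form
    md <- (tc[idx, 1] + tc[idx, 2] + tc[idx, 3]) / 3
    expect_equal(md, rep(mean(ev), length(idx)), tolerance = 1e-12)
  }
  # isotropic eigenvalues give D = d I regardless of e1
  spec <- smallSpec(regionEvals = list(remote = c(1e-3, 1e-3, 1e-3),
                                       scar = c(1e-3, 1e-3, 1e-3),
                                       graft = c(1e-3, 1e-3, 1e-3)))
  geom <- buildGeometry(spec)
  fib <- buildFiberField(spec, geom)
  tens <- assignTensors(fib$e1True, buildRegionLabels(spec, geom), spec, geom)
  tcI <- matrix(tens, ncol = 6)[which(geom$wall), ]
  expect_equal(max(abs(tcI[, 1:3] - 1e-3)), 0, tolerance = 1e-15)
  expect_equal(max(abs(tcI[, 4:6])), 0, tolerance = 1e-15)
})

test_that("unlabeled wall voxels are rejected by tensor assignment", {
  spec <- smallSpec()
  geom <- buildGeometry(spec)
  fib <- buildFiberField(spec, geom)
  labels <- buildRegionLabels(spec, geom)
  labels[which(geom$wall)[1]] <- 0L
  expect_error(assignTensors(fib$e1True, labels, spec, geom), "unlabeled")
})

test_that("forward DWI model matches scalar physics and is b0-exact", {
  ph <- noiselessPhantom()
  b0 <- which(isB0(ph@gtab))
  wallIdx <- which(ph@wall, arr.ind = TRUE)[1:50, ]
  for (v in b0) {
    expect_equal(ph@dwi[cbind(wallIdx, v)], rep(ph@spec$S0, 50))
  }
  # along e1 at b = 700 with lambda1 = 1.8e-3: S/S0 = exp(-1.26) = 0.283654
  spec1 <- smallSpec(regionEvals = list(remote = c(1.8e-3, 0.6e-3, 0.6e-3),
                                        scar = c(1.8e-3, 0.6e-3, 0.6e-3),
                                        graft = c(1.8e-3, 0.6e-3, 0.6e-3)),
                     snrB0 = Inf, taSDTrue = 0)
  geom <- buildGeometry(spec1)
  fib <- buildFiberField(spec1, geom)
  tens <- assignTensors(fib$e1True, buildRegionLabels(spec1, geom), spec1, geom)
  vox <- which(geom$wall, arr.ind = TRUE)[1, , drop = FALSE]
  e1 <- fib$e1True[vox[1], vox[2], vox[3], ]
  gtab <- gradientTable(c(0, 700), cbind(c(0, 0, 0), e1))
  sig <- simulateDWI(tens, 1000, gtab, Inf, 1, geom$wall)
  expect_equal(sig[vox[1], vox[2], vox[3], 2] / 1000, 0.283654,
               tolerance = 1e-6)
  # isotropic tensor: identical signal in every direction
  specI <- smallSpec(regionEvals = list(remote = c(1e-3, 1e-3, 1e-3),
                                        scar = c(1e-3, 1e-3, 1e-3),
                                        graft = c(1e-3, 1e-3, 1e-3)),
                     snrB0 = Inf)
  phI <- simulatePhantom(specI)
  dwSig <- phI@dwi[cbind(vox[rep(1, 30), , drop = FALSE][, 1], vox[2], vox[3],
                         which(!isB0(phI@gtab)))]
  expect_equal(dwSig, rep(1000 * exp(-700 * 1e-3), 30), tolerance = 1e-9)
})

test_that("noiseless signals are invariant under joint rotation", {
  spec <- phantomSpec(gridShape = c(16, 16, 4), endoRadius = 0.9,
                      epiRadius = 2.1, snrB0 = Inf, taSDTrue = 0)
  geom <- buildGeometry(spec)
  fib <- buildFiberField(spec, geom)
  tens <- assignTensors(fib$e1True, buildRegionLabels(spec, geom), spec, geom)
  gtab <- phantomGradientTable(spec)
  s1 <- simulateDWI(tens, 1000, gtab, Inf, 1, geom$wall)
  w <- which(geom$wall)
  n3 <- prod(dim(geom$wall))
  sel <- array(FALSE, dim(s1))
  for (v in seq_len(nVolumes(gtab))) sel[, , , v] <- geom$wall
  set.seed(7)
  for (q in 1:5) {
    A <- randomRotation()
    tcr <- rotateTensors(matrix(tens, ncol = 6)[w, , drop = FALSE], A)
    tensR <- array(0, dim = dim(tens))
    for (cc in 1:6) tensR[w + (cc - 1) * n3] <- tcr[, cc]
    s2 <- simulateDWI(tensR, 1000, gradientTable(bvals(gtab), A %*% bvecs(gtab)),
                      Inf, 1, geom$wall)
    expect_lt(max(abs(s2[sel] - s1[sel]) / s1[sel]), 1e-10)
  }
})

test_that("Rician noise is unbiased at high SNR and seed-deterministic", {
  spec <- phantomSpec(gridShape = c(8, 8, 4), endoRadius = 0.3,
                      epiRadius = 1.05, snrB0 = 50, taSDTrue = 0)
  geom <- buildGeometry(spec)
  fib <- buildFiberField(spec, geom)
  tens <- assignTensors(fib$e1True, buildRegionLabels(spec, geom), spec, geom)
  gtab <- gradientTable(0, matrix(0, 3, 1))
  vox <- which(geom$wall, arr.ind = TRUE)[1, ]
  draws <- vapply(1:300, function(s)
    simulateDWI(tens, 1000, gtab, 50, s, geom$wall)[vox[1], vox[2], vox[3], 1],
    numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1000), 3 * se + 1000 / 50^2 / 2)
  # determinism
  s1 <- simulateDWI(tens, 1000, gtab, 50, 123, geom$wall)
  s2 <- simulateDWI(tens, 1000, gtab, 50, 123, geom$wall)
  expect_identical(s1, s2)
})

test_that("CE simulation separates regions by construction and is seeded", {
  spec <- smallSpec()
  geom <- buildGeometry(spec)
  labels <- buildRegionLabels(spec, geom)
  ce1 <- simulateCE(labels, spec$ceParams, seed = 9)
  ce2 <- simulateCE(labels, spec$ceParams, seed = 9)
  expect_identical(ce1, ce2)
  # scar mean 8 SD above remote: essentially all scar above the 5-SD line
  thr <- spec$ceParams$remote[["mean"]] + 5 * spec$ceParams$remote[["sd"]]
  expect_gt(mean(ce1[labels == 2L] > thr), 0.99)
  expect_gt(mean(ce1[labels == 3L] < thr), 0.99)
  badCe <- spec$ceParams
  badCe$scar <- c(mean = 120, sd = 5)
  expect_error(expect_warning(simulateCE(labels, badCe, 1), "5 remote SDs"),
               "6 remote SDs")
  badCe$scar <- c(mean = 140, sd = 5)
  badCe$graft <- c(mean = 150, sd = 5)
  expect_error(simulateCE(labels, badCe, 1), "attenuated")
})

test_that("gradient scheme is well-spread and reproducible", {
  d1 <- generateDirections(30, seed = 5)
  d2 <- generateDirections(30, seed = 5)
  expect_identical(d1, d2)
  expect_equal(sqrt(rowSums(d1^2)), rep(1, 30), tolerance = 1e-12)
  # minimum pairwise angle (antipodally symmetric) is reasonably large
  g <- abs(d1 %*% t(d1))
  diag(g) <- 0
  minAngle <- min(acos(pmin(apply(g, 1, max), 1))) * 180 / pi
  expect_gt(minAngle, 15)
})
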