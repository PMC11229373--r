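test_that("superposition recovers rigidly scattered copies and guards chirality", {
  set.seed(4)
  base <- idealBDNABeads("ACGTACGTAC")
  fr <- array(0, c(20, 3, 8))
  for (f in 1:8) fr[, , f] <- randomRigid(base)
  sup <- superposeRMSD(fr)
  expect_lt(max(sup$rmsd), 1e-8)

  # two-point toy, hand arithmetic: collinear points a = {0, 2}, b = {0, 4};
  # after centering a = {-1, +1}, b = {-2, +2}, so the optimal rigid fit
  # leaves residuals {-1, +1} -> RMSD exactly 1
  a <- rbind(c(0, 0, 0), c(2, 0, 0))
  b <- rbind(c(0, 5, 0), c(4, 5, 0))       # plus an arbitrary translation
  expect_equal(kabsch(b, a)$rmsd, 1, tolerance = 1e-9)

  # mirror image: only proper rotations allowed, so RMSD stays large
  m <- base; m[, 1] <- -m[, 1]
  expect_gt(kabsch(m, base)$rmsd, 1)
  expect_equal(det(kabsch(m, base)$rotation), 1, tolerance = 1e-9)
})

test_that("essential modes are orthonormal with non-increasing eigenvalues", {
  ens <- synthEnsemble("ACGTACGTAC", nFrames = 120, seed = 3)
  em <- essentialModes(ens, nModes = 10)
  expect_equal(crossprod(em$modes), diag(10), tolerance = 1e-8)
  expect_true(all(diff(em$eigenvalues) <= 1e-12))
})

test_that("RMSIP: identity, orthogonality, and the random-subspace expectation", {
  ens <- synthEnsemble("ACGTACGTAC", nFrames = 120, seed = 3)
  em <- essentialModes(ens, nModes = 12)
  expect_equal(rmsip(em, em, 10), 1, tolerance = 1e-9)
  # orthogonal complements overlap zero
  a <- em$modes[, 1:5]
  b <- em$modes[, 6:10]
  expect_equal(rmsip(a, b, 5), 0, tolerance = 1e-9)
  # random n-subspaces in dimension d: E[rmsip^2] = n/d
  set.seed(9)
  d <- 24; nm <- 4
  r2 <- replicate(400, {
    A <- qr.Q(qr(matrix(rnorm(d * nm), d)))
    B <- qr.Q(qr(matrix(rnorm(d * nm), d)))
    rmsip(A, B, nm)^2
  })
  expect_lt(abs(mean(r2) - nm / d) / (nm / d), 0.1)
})

test_that("end-to-end distance uses terminal bp midpoints", {
  ens <- trajectoryEnsemble(idealBDNABeads(SEQ18),
                            buildDuplexTopology(SEQ18))
  ee <- endToEnd(ens)
  expect_equal(ee$mean, 17 * 3.38, tolerance = 1e-9)
  expect_equal(ee$sd, 0)
  expect_match(ee$definition, "midpoint")
  circ <- buildMinicircle(strrep("ACGT", 4))
  expect_error(endToEnd(trajectoryEnsemble(circ$coords, circ$topology)),
               "linear")
})

test_that("persistence length: straight-chain sentinel and WLC recovery", {
  straight <- array(cbind(0, 0, (0:100) * 3.38), c(101, 3, 1))
  expect_identical(persistenceLength(straight, window = 1)$pl, Inf)

  w <- sampleWLC(nSteps = 250, nFrames = 2500, persistenceLength = 50,
                 seed = 4)
  pl1 <- persistenceLength(w, window = 1)$pl
  expect_lt(abs(pl1 - 50) / 50, 0.10)
  # doubling the contour length leaves the estimate unchanged within error
  w2 <- sampleWLC(nSteps = 500, nFrames = 1250, persistenceLength = 50,
                  seed = 5)
  pl2 <- persistenceLength(w2, window = 1)$pl
  expect_lt(abs(pl2 - pl1) / pl1, 0.12)
})

test_that("gyration shape descriptors match closed-form geometries", {
  n <- 200
  phi <- (0:(n - 1)) * 2 * pi / n
  ring <- array(c(30 * cos(phi), 30 * sin(phi), rep(0, n)), c(n, 3, 1))
  sd <- shapeDescriptors(ring)
  expect_equal(sd$rg, 30, tolerance = 1e-6)

  rod <- array(cbind(0, 0, seq(0, 100, length.out = 400)), c(400, 3, 1))
  expect_equal(shapeDescriptors(rod)$rg, 100 / sqrt(12), tolerance = 1e-2)

  set.seed(2)
  cloud <- array(rnorm(3000 * 3), c(3000, 3, 1))
  expect_lt(abs(shapeDescriptors(cloud)$aspect - 1), 0.1)
})

test_that("bending profiles: straight chain, ring arc angle, soft-segment peak", {
  straight <- array(cbind(0, 0, (0:60) * 3.38), c(61, 3, 1))
  bp <- bendingProfile(straight, window = 10)
  expect_equal(length(bp$position), 61 - 10)
  expect_lt(max(abs(bp$mean)), 1e-6)

  n <- 72
  phi <- (0:(n - 1)) * 2 * pi / n
  ring <- array(c(40 * cos(phi), 40 * sin(phi), rep(0, n)), c(n, 3, 1))
  bpr <- bendingProfile(ring, window = 12, circular = TRUE)
  # chords to +-w/2: the deviation from straight is 180 * w / n degrees
  expect_equal(bpr$mean, rep(180 * 12 / n, n), tolerance = 1e-9)

  # a flexible segment inside a stiff chain shows up as the profile maximum
  set.seed(6)
  nst <- 80
  mkChain <- function() {
    t <- c(0, 0, 1); p <- c(0, 0, 0)
    out <- matrix(0, nst + 1, 3)
    for (s in 1:nst) {
      sdv <- if (s >= 38 && s <= 42) 0.35 else 0.02
      ax <- cgdna:::unitVec(rnorm(3))
      ax <- cgdna:::unitVec(ax - sum(ax * t) * t)
      t <- as.numeric(t %*% rotationMatrix(ax, rnorm(1, 0, sdv)))
      p <- p + 3.38 * t
      out[s + 1, ] <- p
    }
    out
  }
  fr <- array(0, c(nst + 1, 3, 60))
  for (f in 1:60) fr[, , f] <- mkChain()
  prof <- bendingProfile(fr, window = 10)
  peak <- prof$position[which.max(prof$mean)]
  expect_true(peak >= 36 && peak <= 46)
})

test_that("writhe: planar circle, refinement convergence, rigid invariance", {
  n <- 100
  phi <- (0:(n - 1)) * 2 * pi / n
  ring <- cbind(50 * cos(phi), 50 * sin(phi), 0)
  expect_lt(abs(writhe(ring)), 1e-3)

  f8 <- function(m) {
    tt <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
    cbind(sin(2 * tt), 2 * cos(tt), 0.5 * sin(tt))
  }
  w80 <- writhe(f8(80))
  w320 <- writhe(f8(320))
  expect_lt(abs(w80 - w320), 5e-3)      # refinement-converged oracle

  set.seed(3)
  curve <- f8(60)
  expect_equal(writhe(randomRigid(curve)), writhe(curve), tolerance = 1e-6)
})

test_that("cross-RMSD matrices are symmetric with block structure", {
  set.seed(8)
  a <- synthEnsemble("ACGTACGTAC", nFrames = 6, seed = 1)
  shifted <- a
  # second conformer family: strongly bent copies
  for (f in 1:6) {
    x <- a@frames[, , f]
    bend <- x
    bend[x[, 3] > 15, 1] <- bend[x[, 3] > 15, 1] + 12
    shifted@frames[, , f] <- bend
  }
  cm <- crossRMSDMatrix(a, shifted)
  expect_true(isSymmetric(cm$rmsd))
  expect_true(all(diag(cm$rmsd) == 0))
  expect_equal(cm$blocks, c(6L, 6L))
  within <- c(cm$rmsd[1:6, 1:6][upper.tri(diag(6))],
              cm$rmsd[7:12, 7:12][upper.tri(diag(6))])
  between <- as.vector(cm$rmsd[1:6, 7:12])
  expect_lt(mean(within), mean(between))
  # identical ensembles: zero diagonal blocks
  cm2 <- crossRMSDMatrix(a, a)
  expect_lt(max(abs(cm2$rmsd[1:6, 7:12][cbind(1:6, 1:6)])), 1e-10)
})

test_that("mechanics estimators are invariant to rigid motion of the frames", {
  set.seed(10)
  ens <- synthEnsemble("ACGTACGTACGT", nFrames = 30, seed = 2)
  moved <- ens
  for (f in 1:30) moved@frames[, , f] <- randomRigid(ens@frames[, , f])
  expect_equal(endToEnd(moved)$series, endToEnd(ens)$series,
               tolerance = 1e-9)
  expect_equal(shapeDescriptors(moved)$rg, shapeDescriptors(ens)$rg,
               tolerance = 1e-9)
  expect_equal(bendingProfile(moved, 4)$mean, bendingProfile(ens, 4)$mean,
               tolerance = 1e-8)
  expect_equal(superposeRMSD(moved)$rmsd, superposeRMSD(ens)$rmsd,
               tolerance = 1e-8)
})

test_that("Kabsch superposition agrees with an independent implementation", {
  set.seed(14)
  a <- idealBDNABeads("ACGTACGTAC") + matrix(rnorm(60, 0, 0.6), 20, 3)
  b <- randomRigid(idealBDNABeads("ACGTACGTAC") +
                   matrix(rnorm(60, 0, 0.6), 20, 3))
  ours <- kabsch(b, a)$rmsd
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})
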