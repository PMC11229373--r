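dimerRun <- function(K2 = 2, K4 = 0, temperature = 300, friction = 1,
                     nSteps = 100000L, stride = 50L, logEvery = 0L,
                     v0 = NULL, seed = 42) {
  bonds <- cbind(i = 1, j = 2, K2 = K2, K3 = 0, K4 = K4, x0 = 5, channel = 1)
  noAng <- matrix(numeric(0), 0, 7)
  m <- c(322.2, 322.2)
  x0 <- rbind(c(0, 0, 0), c(5, 0, 0))
  set.seed(seed)
  if (is.null(v0)) v0 <- initializeVelocities(m, temperature)
  cgdna:::cpp_run_langevin(x0, v0, m, bonds, noAng, FALSE, remoteSettings(),
                           c(1L, 100L), 2L, FALSE, 0.1, friction,
                           temperature, as.integer(nSteps), as.integer(stride),
                           as.integer(logEvery))
}

test_that("Maxwell-Boltzmann initialization is correct and deterministic", {
  expect_true(all(initializeVelocities(rep(300, 5), 0) == 0))
  m <- rep(defaultMasses(), length.out = 10000)
  v <- initializeVelocities(m, 300, seed = 1)
  expect_lt(abs(kineticTemperature(v, m, dof = 3 * length(m) - 3) - 300) / 300,
            0.02)
  expect_identical(initializeVelocities(m, 300, seed = 7),
                   initializeVelocities(m, 300, seed = 7))
  # center-of-mass velocity removed
  expect_lt(max(abs(colSums(v * m))), 1e-8)
})

test_that("a free particle moves uniformly at gamma = 0, T = 0", {
  noBonds <- matrix(numeric(0), 0, 7)
  noAng <- matrix(numeric(0), 0, 7)
  x0 <- matrix(c(0, 0, 0), 1, 3)
  v0 <- matrix(c(0.3, -0.1, 0.2), 1, 3)
  res <- cgdna:::cpp_run_langevin(x0, v0, 322.2, noBonds, noAng, FALSE,
                                  remoteSettings(), 1L, 1L, FALSE,
                                  0.1, 0, 0, 1000L, 100L, 0L)
  expect_equal(res$coords[1, ], v0[1, ] * 100, tolerance = 1e-12)
  expect_equal(res$velocities, v0, tolerance = 1e-13)
})

test_that("microcanonical harmonic motion shows no secular energy drift", {
  res <- dimerRun(K2 = 2, temperature = 0, friction = 0, nSteps = 100000L,
                  logEvery = 100L,
                  v0 = rbind(c(0.2, 0, 0), c(-0.2, 0, 0)))
  tot <- res$energyLog[, "total"]
  # the shadow energy oscillates at O((omega dt)^2); the secular drift is the
  # regression slope over the run
  fit <- stats::lm.fit(cbind(1, seq_along(tot)), tot)
  drift <- abs(fit$coefficients[2] * length(tot)) / abs(mean(tot))
  expect_lt(drift, 1e-4)
})

test_that("harmonic dimer reaches the Boltzmann variance and bath temperature", {
  res <- dimerRun(K2 = 2, temperature = 300, nSteps = 400000L, stride = 50L,
                  logEvery = 200L)
  fr <- res$frames
  l <- sqrt(colSums((fr[2, , ] - fr[1, , ])^2))
  l <- l[-(1:500)]
  expect_lt(abs(var(l) - kBoltzmann * 300 / (2 * 2)) / (kBoltzmann * 300 / 4),
            0.05)
  kin <- res$energyLog[-(1:100), "kinetic"]
  tKin <- mean(kin) * 2 / (kBoltzmann * 6)
  expect_lt(abs(tKin - 300) / 300, 0.02)
})

test_that("langevinStep and runSimulation are deterministic under a fixed seed", {
  lib <- fittedLib18()
  topo <- buildDuplexTopology(SEQ18)
  ss <- dynamicsSettings(nSteps = 2000L, saveStride = 100L, seed = 31L)
  a <- runSimulation(topo, lib, ss)
  b <- runSimulation(topo, lib, ss)
  expect_identical(a@frames, b@frames)
  expect_identical(a@provenance$energyLog, b@provenance$energyLog)
  # zero-step run returns only the initial frame
  z <- runSimulation(topo, lib, dynamicsSettings(nSteps = 0L, seed = 1L))
  expect_equal(dim(z@frames)[3], 1L)
  expect_equal(z@frames[, , 1], idealBDNABeads(topo), ignore_attr = TRUE)
  # a single langevinStep advances the state reproducibly
  model <- buildModel(duplexSequence(SEQ18), lib)
  st <- list(coords = idealBDNABeads(topo),
             velocities = initializeVelocities(topo@masses, 300, seed = 3))
  set.seed(11); s1 <- langevinStep(st, model, ss)
  set.seed(11); s2 <- langevinStep(st, model, ss)
  expect_identical(s1$coords, s2$coords)
  expect_equal(s1$step, 1L)
})

test_that("an 18-mer run holds the bath temperature within 2 percent", {
  lib <- fittedLib18()
  topo <- buildDuplexTopology(SEQ18)
  sim <- runSimulation(topo, lib,
                       dynamicsSettings(nSteps = 100000L, saveStride = 500L,
                                        seed = 9L, logInterval = 100L))
  el <- sim@provenance$energyLog
  kin <- el[-(1:200), "kinetic"]
  tKin <- mean(kin) * 2 / (kBoltzmann * 3 * 36)
  expect_lt(abs(tKin - 300) / 300, 0.02)
})

test_that("trajectories stay finite at a 500 K bath", {
  lib <- fittedLib18()
  topo <- buildDuplexTopology(SEQ18)
  sim <- runSimulation(topo, lib,
                       dynamicsSettings(nSteps = 20000L, temperature = 500,
                                        saveStride = 500L, seed = 13L))
  expect_true(all(is.finite(sim@frames)))
})

test_that("a diverging integration aborts with the offending step index", {
  # absurd stiffness at dt = 0.1 ps makes the integrator blow up fast
  bonds <- cbind(i = 1, j = 2, K2 = 1e7, K3 = 0, K4 = 1e6, x0 = 1,
                 channel = 1)
  noAng <- matrix(numeric(0), 0, 7)
  x0 <- rbind(c(0, 0, 0), c(5, 0, 0))
  v0 <- matrix(0, 2, 3)
  expect_error(
    cgdna:::cpp_run_langevin(x0, v0, c(322.2, 322.2), bonds, noAng, FALSE,
                             remoteSettings(), c(1L, 100L), 2L, FALSE,
                             0.1, 1, 300, 1000L, 10L, 0L),
    "step [0-9]+")
})
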