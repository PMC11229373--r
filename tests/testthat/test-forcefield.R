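test_that("bonded term energy follows the truncated quartic polynomial", {
  expect_equal(bondedEnergy(5, bondedTerm(3, -1, 0.5, x0 = 5)), 0)
  expect_equal(bondedEnergy(7, bondedTerm(1, 0, 0, x0 = 5)), 4)
  # independent Horner-scheme oracle on a grid of displacements
  horner <- function(d, k2, k3, k4) ((k4 * d + k3) * d + k2) * d^2
  trm <- bondedTerm(1, -0.5, 0.25, x0 = 2.2)
  for (x in seq(0.5, 4.5, by = 0.37))
    expect_equal(bondedEnergy(x, trm), horner(x - 2.2, 1, -0.5, 0.25))
  # bounded below when K4 > 0 (coarse displacement grid)
  grid <- bondedEnergy(seq(-40, 50, by = 0.5), bondedTerm(1, -0.9, 0.05, x0 = 5))
  expect_true(all(is.finite(grid)))
  expect_gt(grid[1], 0); expect_gt(grid[length(grid)], 0)
})

test_that("sequential energy vanishes at equilibrium and is local", {
  lib <- uniformLib(SEQ18)
  model <- buildModel(duplexSequence(SEQ18), lib)
  xyz <- idealBDNABeads(SEQ18)
  model0 <- relaxedModelAt(model, xyz)
  e <- sequentialEnergy(xyz, model0)
  expect_equal(unname(e$total), 0, tolerance = 1e-12)
  expect_true(all(abs(e$channels) < 1e-12))

  # single active stacking instance: total equals that one bondedEnergy
  m1 <- model0
  keep <- which(m1$bonds[, "channel"] == 1)[3]
  m1$bonds[, "K2"] <- 0; m1$bonds[, "K3"] <- 0; m1$bonds[, "K4"] <- 0
  m1$angles[, c("K2", "K3", "K4")] <- 0
  m1$bonds[keep, c("K2", "K4")] <- c(2, 0.3)
  x2 <- xyz
  x2[m1$bonds[keep, "j"], ] <- x2[m1$bonds[keep, "j"], ] + c(0.7, 0, 0)
  d <- sqrt(sum((x2[m1$bonds[keep, "j"], ] - x2[m1$bonds[keep, "i"], ])^2))
  e2 <- sequentialEnergy(x2, m1)
  expect_equal(unname(e2$total),
               unname(bondedEnergy(d, c(2, 0, 0.3, m1$bonds[keep, "x0"]))))
  expect_equal(unname(e2$channels["stacking"]), unname(e2$total))
})

test_that("sequential energy equals the instance-walk oracle on random 8-bp conformations", {
  set.seed(42)
  seqs <- "GCATTCGA"
  lib <- uniformLib(seqs, K2 = 1.5, K3 = -0.2, K4 = 0.2)
  topo <- buildDuplexTopology(seqs)
  tab <- enumerateInteractions(topo)
  model <- resolveParameters(tab, lib)
  for (rep in 1:3) {
    x <- idealBDNABeads(seqs) + matrix(rnorm(48, 0, 0.5), 16, 3)
    e <- sequentialEnergy(x, model)
    orc <- oracleSequential(x, tab, lib)
    expect_equal(unname(e$channels[c("stacking", "pairing", "fan",
                                     "distant", "angle")]),
                 unname(orc), tolerance = 1e-10)
    expect_equal(unname(e$total), unname(sum(orc)), tolerance = 1e-10)
  }
})

test_that("remote energy reproduces closed forms and the pairwise oracle", {
  # LJ root at r = sigma
  s <- remoteSettings(sigma = 10, epsLJ = 0.59, kappa = 0, epsR = 1)
  x <- rbind(c(0, 0, 0), c(10, 0, 0))
  e <- remoteEnergy(x, s)
  expect_equal(unname(e$channels["LJ"]), 0, tolerance = 1e-12)
  # unscreened Coulomb at r = 1 A equals the Coulomb constant
  s2 <- remoteSettings(sigma = 0.1, epsLJ = 0, kappa = 0, epsR = 1,
                       cutoff = 5)
  e2 <- remoteEnergy(rbind(c(0, 0, 0), c(1, 0, 0)), s2)
  expect_equal(unname(e2$channels["electrostatic"]), 332.0637)

  # 30-bead random cloud vs O(N^2) oracle, with and without the exclusion
  set.seed(7)
  cloud <- matrix(runif(90, 0, 40), 30, 3)
  s3 <- remoteSettings()
  e3 <- remoteEnergy(cloud, s3)
  expect_equal(unname(e3$channels), unname(oracleRemote(cloud, s3)),
               tolerance = 1e-10)
  seqs <- "ACGTACGTACGTACG"
  topo <- buildDuplexTopology(seqs)
  xyz <- idealBDNABeads(seqs) * 0.4          # compressed: pairs inside cutoff
  e4 <- remoteEnergy(xyz, s3, topology = topo)
  e4o <- oracleRemote(xyz, s3, excluded = remoteExclusionMask(topo))
  expect_equal(unname(e4$channels), unname(e4o), tolerance = 1e-10)

  # overlapping beads are a hard error
  expect_error(remoteEnergy(rbind(c(0, 0, 0), c(0, 0, 0)), s3),
               "overlapping")
})

test_that("neighbor-list remote evaluation equals the direct double loop", {
  set.seed(11)
  cloud <- matrix(runif(150, 0, 60), 50, 3)
  s <- remoteSettings()
  d <- remoteEnergy(cloud, s, method = "direct")
  l <- remoteEnergy(cloud, s, method = "list")
  expect_identical(d$channels, l$channels)
})

test_that("analytic forces match central finite differences and conserve momentum", {
  set.seed(3)
  lib <- fittedLib18()
  model <- buildModel(duplexSequence(SEQ18), lib)
  x <- idealBDNABeads(SEQ18) + matrix(rnorm(108, 0, 0.3), 36, 3)
  f <- totalForces(x, model)
  h <- 1e-5
  scale <- max(abs(f))
  for (i in sample(36, 8)) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    fd <- -(energyBreakdown(xp, model)$total -
            energyBreakdown(xm, model)$total) / (2 * h)
    expect_lt(abs(fd - f[i, d]) / scale, 1e-4)
  }
  # Newton's third law accounting: zero net force and net torque
  expect_lt(max(abs(colSums(f))), 1e-9 * scale)
  torque <- colSums(cbind(x[, 2] * f[, 3] - x[, 3] * f[, 2],
                          x[, 3] * f[, 1] - x[, 1] * f[, 3],
                          x[, 1] * f[, 2] - x[, 2] * f[, 1]))
  expect_lt(max(abs(torque)), 1e-7 * scale * max(abs(x)))

  # zero force at a strict equilibrium with remote off
  x0 <- idealBDNABeads(SEQ18)
  m0 <- relaxedModelAt(model, x0)
  f0 <- totalForces(x0, m0, remote = FALSE)
  expect_lt(max(abs(f0)), 1e-10)
})

test_that("every energy channel is invariant under rigid motion", {
  set.seed(12)
  lib <- fittedLib18()
  model <- buildModel(duplexSequence(SEQ18), lib)
  x <- idealBDNABeads(SEQ18) + matrix(rnorm(108, 0, 0.2), 36, 3)
  e0 <- energyBreakdown(x, model)
  for (rep in 1:5) {
    e1 <- energyBreakdown(randomRigid(x), model)
    expect_equal(e1$channels, e0$channels, tolerance = 1e-8)
  }
})
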