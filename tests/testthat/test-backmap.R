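seqBM <- "ACGTACGTACGTAC"   # 14 bp: 5 sliding windows

trainPair <- function(nFrames, seed) synthAtomisticEnsemble(seqBM,
                                                            nFrames = nFrames,
                                                            seed = seed)

test_that("training on a zero-fluctuation ensemble reproduces it exactly", {
  fl0 <- fluctuationSpec(0, 0, 0, persistenceLength = Inf)
  tr <- synthAtomisticEnsemble(seqBM, fluct = fl0, nFrames = 3, seed = 1)
  mdl <- trainBackmap(tr$beads, tr$atoms, rank = 1)
  rec <- reconstructAtomistic(tr$beads, mdl)
  expect_lt(max(abs(rec@xyz - tr$atoms@xyz)), 1e-3)
})

test_that("held-out reconstruction is accurate and shrinks with training size", {
  te <- trainPair(12, seed = 99)
  errAt <- function(nTrain, seed) {
    tr <- trainPair(nTrain, seed)
    mdl <- trainBackmap(tr$beads, tr$atoms, rank = 30)
    rec <- reconstructAtomistic(te$beads, mdl)
    mean(sapply(seq_len(12), function(f)
      sqrt(mean(rowSums((rec@xyz[, , f] - te$atoms@xyz[, , f])^2)))))
  }
  e1 <- errAt(40, 4); e2 <- errAt(90, 4); e3 <- errAt(200, 4)
  # error per bp below 0.3 A (here even the whole-structure RMSD is)
  expect_lt(e3, 0.3)
  expect_lt(e3 / 14, 0.3)
  # monotone improvement over three training sizes
  expect_lt(e2, e1)
  expect_lt(e3, e2)
})

test_that("model serialization round-trips to bit-identical reconstructions", {
  tr <- trainPair(60, seed = 7)
  mdl <- trainBackmap(tr$beads, tr$atoms, rank = 20)
  f <- tempfile(fileext = ".json")
  writeBackmapModel(mdl, f)
  mdl2 <- readBackmapModel(f)
  te <- trainPair(3, seed = 123)
  r1 <- reconstructAtomistic(te$beads, mdl)
  r2 <- reconstructAtomistic(te$beads, mdl2)
  expect_identical(r1@xyz, r2@xyz)
})

test_that("reconstruction is rigid-motion equivariant", {
  tr <- trainPair(60, seed = 7)
  mdl <- trainBackmap(tr$beads, tr$atoms, rank = 20)
  te <- trainPair(3, seed = 5)
  rec <- reconstructAtomistic(te$beads, mdl)
  set.seed(2)
  rot <- cgdna:::randomRotation(); tv <- c(12, -7, 31)
  moved <- te$beads
  for (f in 1:3)
    moved@frames[, , f] <- sweep(te$beads@frames[, , f] %*% rot, 2, tv, `+`)
  rec2 <- reconstructAtomistic(moved, mdl)
  for (f in 1:3)
    expect_lt(max(abs(sweep(rec@xyz[, , f] %*% rot, 2, tv, `+`) -
                      rec2@xyz[, , f])), 1e-3)
})

test_that("window bookkeeping: 47 blended windows for a 56-mer, seams reported", {
  tr <- trainPair(60, seed = 7)
  mdl <- trainBackmap(tr$beads, tr$atoms, rank = 20)
  seq56 <- strrep("ACGTACGT", 7)
  topo56 <- buildDuplexTopology(seq56)
  beads56 <- trajectoryEnsemble(idealBDNABeads(seq56), topo56)
  rec <- reconstructAtomistic(beads56, mdl)
  expect_equal(rec@provenance$nWindows, 56 - 10 + 1)
  expect_true(all(is.finite(rec@provenance$seamMean)))
  expect_gte(rec@provenance$seamMean[1], 0)
  expect_lt(rec@provenance$c1MaxDev, 0.5)
})

test_that("minicircle bead trajectories reconstruct through wraparound windows", {
  tr <- trainPair(60, seed = 7)
  mdl <- trainBackmap(tr$beads, tr$atoms, rank = 20)
  mc <- buildMinicircle(strrep("ACGT", 15), deltaLk = 0)  # 60 bp circle
  beads <- trajectoryEnsemble(mc$coords, mc$topology)
  # a tightly curved circle is far outside the linear training set, so the
  # C1'-fidelity warning may fire; the reconstruction must still complete
  rec <- suppressWarnings(reconstructAtomistic(beads, mdl))
  expect_equal(rec@provenance$nWindows, 60L)
  expect_equal(dim(rec@xyz)[1], nrow(rec@atoms))
  expect_true(all(is.finite(rec@xyz)))
  # circular atom table has no 5'-terminal truncation
  expect_equal(sum(rec@atoms$atom == "P"), 120L)
})

test_that("training rejects underdetermined regressions with advice", {
  tr <- trainPair(10, seed = 3)
  expect_error(trainBackmap(tr$beads, tr$atoms),
               "more frames|rank reduction")
  expect_error(trainBackmap(tr$beads, tr$atoms, window = 20),
               "shorter than the training window")
})

test_that("clash relaxation separates planted clashes and fixes nothing else", {
  # clash-free structure is unchanged
  st <- idealBDNAAtomistic("ACGTACGT")
  rl <- relaxClashes(st)
  expect_lt(max(abs(rl@xyz - st@xyz)), 1e-6)

  # two atoms planted at 0.8 A in sequence-distant residues separate
  atoms <- data.frame(res = c(1L, 5L), strand = c(1L, 1L), bp = c(1L, 5L),
                      base = c("A", "A"), atom = c("C1'", "C1'"))
  xyz <- array(rbind(c(0, 0, 0), c(0.8, 0, 0)), c(2, 3, 1))
  toy <- new("AtomisticStructure", atoms = atoms, xyz = xyz,
             sequence = duplexSequence("AAAAA"), provenance = list())
  rl2 <- relaxClashes(toy, threshold = 1.7)
  expect_gte(sqrt(sum((rl2@xyz[2, , 1] - rl2@xyz[1, , 1])^2)), 1.7 - 1e-6)

  # mild planted clash in a real structure: bounded displacements
  st2 <- idealBDNAAtomistic("ACGTACGT")
  i <- which(st2@atoms$atom == "N1")[1]
  j <- which(st2@atoms$strand == 2L & st2@atoms$bp == st2@atoms$bp[i] &
             st2@atoms$atom == "N1")[1]   # facing residue on the other strand
  mid <- (st2@xyz[i, , 1] + st2@xyz[j, , 1]) / 2
  st2@xyz[i, , 1] <- mid + c(0.4, 0, 0)
  st2@xyz[j, , 1] <- mid - c(0.4, 0, 0)
  rl3 <- relaxClashes(st2)
  disp <- sqrt(rowSums((rl3@xyz[, , 1] - st2@xyz[, , 1])^2))
  expect_lte(max(disp), 1.0 + 1e-9)
  expect_lt(mean(disp), 0.5)
  expect_equal(rl3@provenance$relaxation$potential,
               "soft-sphere (not a force field)")
})
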