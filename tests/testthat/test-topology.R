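test_that("duplex topology has 2 beads per bp with reverse-complement pairing", {
  topo <- buildDuplexTopology(SEQ18)
  expect_equal(nbp(topo), 18L)
  expect_length(topo@masses, 36L)
  expect_equal(topo@masses[1:4],
               unname(defaultMasses()[c("A", "C", "G", "T")]))

  # "ACGT": Watson strand position p pairs Crick strand position n + 1 - p
  t4 <- buildDuplexTopology("ACGT")
  for (p in 1:4)
    expect_equal(t4@pairedBead[beadIndex(t4, 1L, p)],
                 beadIndex(t4, 2L, 4L + 1L - p))
  expect_equal(t4@pairedBead[t4@pairedBead], seq_len(8L))  # involution

  # custom masses are honored
  tm <- buildDuplexTopology("ACGT", masses = c(A = 1, C = 2, G = 3, T = 4))
  expect_equal(tm@masses, c(1, 2, 3, 4, 4, 3, 2, 1))
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(buildDuplexTopology("ACGXACGT"), "position 4")
  expect_error(duplexSequence("ACGTACG", circular = TRUE), ">= 12")
  expect_error(duplexSequence("ACA"), ">= 4")
})

test_that("circular 339-bp duplex has 678 beads and no chain ends", {
  seqc <- duplexSequence(substr(strrep("ACGT", 85), 1, 339), circular = TRUE)
  topo <- buildDuplexTopology(seqc)
  expect_equal(length(topo@masses), 678L)
  tab <- enumerateInteractions(topo)
  # every bead has two sequence neighbors: n stacking steps per strand
  st <- tab@bonds[tab@bonds$kind == "stacking", ]
  expect_equal(nrow(st), 2L * 339L)
  deg <- table(c(st$i, st$j))
  expect_true(all(deg == 2L))
})

test_that("interaction counts match a brute-force window walk for n = 4..12", {
  for (n in 4:12) {
    seqs <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    tab <- enumerateInteractions(buildDuplexTopology(seqs))
    expect_equal(tableCounts(tab), oracleCounts(n), ignore_attr = TRUE,
                 label = sprintf("n = %d", n))
  }
})

test_that("circular interaction counts are exactly nbp x per-window counts", {
  seqc <- duplexSequence(strrep("ACGGT", 4), circular = TRUE)  # 20 bp
  tab <- enumerateInteractions(buildDuplexTopology(seqc))
  n <- 20L
  cnt <- tableCounts(tab)
  # per window: 2 stacking (1 context each), 2 pairing (2 contexts), 8 fan
  # (2 contexts), 4 angles (2 contexts); distant: 6 offsets per bp
  expect_equal(unname(cnt["stacking"]), 2L * n)
  expect_equal(unname(cnt["pairing"]), n)
  expect_equal(unname(cnt["fan"]), 4L * n)
  expect_equal(unname(cnt["angle"]), 2L * n)
  expect_equal(unname(cnt["distant"]), 6L * n)
  # no instance with a truncated (fallback) context
  allCtx <- unlist(c(tab@bonds$contexts, tab@angles$contexts))
  expect_false(any(startsWith(allCtx, "AVG/")))
})

test_that("each interior tetramer window carries exactly 8 fan terms (eq5)", {
  tab <- enumerateInteractions(buildDuplexTopology(SEQ18))
  fanCtx <- unlist(tab@bonds$contexts[tab@bonds$kind == "fan"])
  tetCtx <- fanCtx[!startsWith(fanCtx, "AVG/")]
  # 15 windows, 8 fan context slots each; the first and last windows each
  # lose one slot whose offset leaves the duplex (boundary truncation)
  expect_equal(length(tetCtx), 8L * 15L - 2L)
  # spot-check one interior window: its class occurs on 8 fan slots
  expect_equal(sum(grepl("^CGTA/fan\\.", fanCtx)),
               8L * sum(vapply(1:15, function(t)
                 canonicalTetramer(substr(SEQ18, t, t + 3))$class == "CGTA",
                 logical(1))))
})

test_that("an interior bead sees 11 cross-strand partners", {
  tab <- enumerateInteractions(buildDuplexTopology(SEQ18))
  b <- tab@bonds[tab@bonds$kind %in% c("pairing", "fan", "distant"), ]
  i <- 9L
  expect_equal(sum(b$i == i | b$j == i), 11L)
})

test_that("out-of-range offsets are silently dropped on a 4-bp duplex", {
  tab <- enumerateInteractions(buildDuplexTopology("ACGT"))
  d <- tab@bonds[tab@bonds$kind == "distant", ]
  expect_true(all(abs(d$offset) == 3L))    # +-4, +-5 never fit in 4 bp
  expect_equal(tableCounts(tab), oracleCounts(4L), ignore_attr = TRUE)
})

test_that("the fig1 scheme moves fan +-3 to the tetramer level", {
  tab <- enumerateInteractions(buildDuplexTopology(SEQ18), scheme = "fig1")
  expect_true(any(abs(tab@bonds$offset[tab@bonds$kind == "fan"]) == 3L))
  expect_true(all(abs(tab@bonds$offset[tab@bonds$kind == "distant"]) >= 4L))
  expect_setequal(unique(grep("^fan", tetramerRoles("fig1"), value = TRUE)),
                  as.vector(outer(c("w2", "w3"), c(-3, -2, -1, 1, 2, 3),
                                  function(a, b) sprintf("fan.%s.%d", a, b))))
  expect_error(enumerateInteractions(buildDuplexTopology("ACGT"), "bogus"),
               "eq5, fig1")
})

test_that("remote exclusion mask is the 5-bp criterion, circular-aware", {
  topo <- buildDuplexTopology(SEQ18)
  m <- remoteExclusionMask(topo)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m)))
  expect_true(m[1, 19])                       # same bp
  expect_true(m[1, 6])                        # 5 bp apart -> excluded
  expect_false(m[1, 7])                       # 6 bp apart -> included
  expect_false(m[3, 19 + 9])                  # cross-strand, 6 bp apart

  # 20-bp circle: brute-force circular-distance check over all pairs
  seqc <- duplexSequence(strrep("ACGTT", 4), circular = TRUE)
  tc <- buildDuplexTopology(seqc)
  mc <- remoteExclusionMask(tc)
  for (a in seq_len(40L)) for (b in seq_len(40L)) {
    d <- abs(tc@bpPos[a] - tc@bpPos[b])
    d <- min(d, 20L - d)
    expect_identical(mc[a, b], d <= 5L)
  }
  expect_true(mc[1, 18])                      # positions 1 and 18: sep 3
})

test_that("reverse-complement canonicalization picks the smaller tetramer", {
  cc <- canonicalTetramer(c("AAAA", "TTTT", "AATT", "GGGG", "ACGT"))
  expect_equal(cc$class, c("AAAA", "AAAA", "AATT", "CCCC", "ACGT"))
  expect_equal(cc$flipped, c(FALSE, TRUE, FALSE, TRUE, FALSE))
})
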