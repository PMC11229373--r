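# Shared fixtures and independent oracles. Everything is generated in code at
# test time; the cache avoids refitting the same library across test files.

.cache <- new.env(parent = emptyenv())

SEQ18 <- "ACGTACGTACGTACGTAC"

# synthetic reference + baseline + harmonic tetramer refinement, cached
fittedLib18 <- function() {
  if (is.null(.cache$lib18)) {
    ens <- synthEnsemble(SEQ18, nFrames = 1500, seed = 5)
    obs <- extractObservables(ens)
    lib <- fitBaseline(obs)
    .cache$obs18 <- obs
    .cache$ref18 <- ens
    .cache$lib18 <- refineTetramers(lib, obs)$lib
  }
  .cache$lib18
}

refObs18 <- function() { fittedLib18(); .cache$obs18 }

# independent window-walk oracle: interaction counts for a linear duplex
# under the "eq5" scheme, enumerated bead-pair-wise from first principles
oracleCounts <- function(n) {
  stack <- 2 * (n - 1)                     # every step, both strands
  pair <- n
  fan <- 0
  for (p in seq_len(n)) for (k in c(-2L, -1L, 1L, 2L))
    if (p + k >= 1 && p + k <= n) fan <- fan + 1
  dist <- 0
  for (p in seq_len(n)) for (k in c(-5L, -4L, -3L, 3L, 4L, 5L))
    if (p + k >= 1 && p + k <= n) dist <- dist + 1
  ang <- if (n >= 3) 2 * (n - 2) else 0
  c(stacking = stack, pairing = pair, fan = fan, distant = dist, angle = ang)
}

tableCounts <- function(tab) {
  k <- table(tab@bonds$kind)
  c(stacking = unname(k["stacking"]), pairing = unname(k["pairing"]),
    fan = unname(k["fan"]),
    distant = if ("distant" %in% names(k)) unname(k["distant"]) else 0L,
    angle = nrow(tab@angles))
}

# O(N^2) remote energy oracle in R
oracleRemote <- function(coords, s, excluded = NULL) {
  n <- nrow(coords)
  lj <- ele <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.null(excluded) && excluded[i, j]) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (r >= s$cutoff) next
    sr6 <- (s$sigma / r)^6
    lj <- lj + 4 * s$epsLJ * (sr6^2 - sr6)
    ele <- ele + 332.0637 * s$q^2 * exp(-s$kappa * r) / (s$epsR * r)
  }
  c(LJ = lj, electrostatic = ele)
}

# instance-walk oracle: sequential energy by explicit loops over the table
oracleSequential <- function(coords, tab, lib) {
  model <- resolveParameters(tab, lib)
  tot <- c(stacking = 0, pairing = 0, fan = 0, distant = 0, angle = 0)
  b <- model$bonds
  for (r in seq_len(nrow(b))) {
    d <- sqrt(sum((coords[b[r, "j"], ] - coords[b[r, "i"], ])^2))
    ch <- c("stacking", "pairing", "fan", "distant")[b[r, "channel"]]
    dd <- d - b[r, "x0"]
    tot[ch] <- tot[ch] + b[r, "K2"] * dd^2 + b[r, "K3"] * dd^3 + b[r, "K4"] * dd^4
  }
  a <- model$angles
  for (r in seq_len(nrow(a))) {
    u <- coords[a[r, "i"], ] - coords[a[r, "j"], ]
    v <- coords[a[r, "k"], ] - coords[a[r, "j"], ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    dd <- th - a[r, "x0"]
    tot["angle"] <- tot["angle"] + a[r, "K2"] * dd^2 + a[r, "K3"] * dd^3 +
      a[r, "K4"] * dd^4
  }
  tot
}

# uniform test library: identical bonded term everywhere, x0 from the ideal
# geometry of the given sequence so energies stay moderate
uniformLib <- function(seq, K2 = 2, K3 = 0, K4 = 0.2, scheme = "eq5") {
  topo <- buildDuplexTopology(seq)
  xyz <- idealBDNABeads(topo)
  n <- topo@nbp
  measure <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  mid <- ceiling(n / 2)
  roles <- tetramerRoles(scheme)
  avg <- list()
  for (r in roles) {
    x0 <- if (startsWith(r, "stacking")) measure(mid, mid + 1)
          else if (startsWith(r, "pairing")) measure(mid, n + mid)
          else if (startsWith(r, "angle"))
            cgdna:::tripletAngle(xyz[mid - 1, ], xyz[mid, ], xyz[mid + 1, ])
          else {
            k <- as.integer(sub(".*\\.", "", r))
            measure(mid, n + min(max(mid + k, 1L), n))
          }
    avg[[cgdna:::genericRole(r)]] <- bondedTerm(K2, K3, K4, x0 = x0)
  }
  distant <- list()
  for (k in cgdna:::distantOffsets(scheme))
    distant[[as.character(k)]] <- bondedTerm(
      K2 / 4, 0, K4 / 4, x0 = measure(mid, n + min(max(mid + k, 1L), n)))
  parameterLibrary(classes = list(AVG = avg), distant = distant,
                   scheme = scheme)
}

# resolved model whose equilibrium values are reset to the exact geometry of
# `coords`, so that configuration is a strict energy minimum
relaxedModelAt <- function(model, coords) {
  b <- model$bonds
  for (r in seq_len(nrow(b)))
    b[r, "x0"] <- sqrt(sum((coords[b[r, "j"], ] - coords[b[r, "i"], ])^2))
  a <- model$angles
  for (r in seq_len(nrow(a)))
    a[r, "x0"] <- cgdna:::tripletAngle(coords[a[r, "i"], ],
                                       coords[a[r, "j"], ],
                                       coords[a[r, "k"], ])
  model$bonds <- b
  model$angles <- a
  model
}

randomRigid <- function(xyz) {
  r <- cgdna:::randomRotation()
  t <- stats::rnorm(3, 0, 20)
  sweep(xyz %*% r, 2, t, `+`)
}
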