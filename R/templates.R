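# Synthetic heavy-atom nucleotide templates, built in code from idealized
# ring geometry (uniform 1.55 A bonds). These are rigid placement fixtures
# for back-map training and make no claim of force-field-grade covalent
# geometry; atom names, counts and chirality-free connectivity follow the
# standard deoxynucleotide naming. Residue-local frame: C1' at the origin,
# +x the glycosidic direction (toward the paired bead), z the base-pair
# plane normal.

BOND_L <- 1.55

# vertices of a regular polygon in the plane spanned by (u, v), given the
# center, circumradius, and vertex angles
.polyVerts <- function(center, u, v, R, angles) {
  t(vapply(angles, function(a) center + R * (cos(a) * u + sin(a) * v),
           numeric(3)))
}

.baseAtoms <- function(base) {
  ex <- function(p, center, len = BOND_L) p + len * unitVec(p - center)
  xhat <- c(1, 0, 0); yhat <- c(0, 1, 0)
  gly <- c(1.56, 0, 0)                       # N1/N9 attachment point
  if (base %in% c("C", "T")) {
    cen <- gly + BOND_L * xhat               # hexagon: circumradius == bond
    ang <- pi - (0:5) * pi / 3               # N1 C2 N3 C4 C5 C6
    v <- .polyVerts(cen, xhat, yhat, BOND_L, ang)
    rownames(v) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    at <- rbind(v,
                O2 = ex(v["C2", ], cen),
                if (base == "C") rbind(N4 = ex(v["C4", ], cen))
                else rbind(O4 = ex(v["C4", ], cen), C7 = ex(v["C5", ], cen)))
    ord <- if (base == "C") c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
           else c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
    return(at[ord, , drop = FALSE])
  }
  # purine: imidazole pentagon N9 C4 C5 N7 C8, hexagon fused on C4-C5
  r5 <- BOND_L / (2 * sin(pi / 5))
  cen5 <- gly + r5 * xhat
  ang5 <- pi - (0:4) * 2 * pi / 5            # N9 C4 C5 N7 C8
  v5 <- .polyVerts(cen5, xhat, yhat, r5, ang5)
  rownames(v5) <- c("N9", "C4", "C5", "N7", "C8")
  mid <- (v5["C4", ] + v5["C5", ]) / 2
  dir <- unitVec(mid - cen5)
  cen6 <- mid + dir * BOND_L * sqrt(3) / 2   # hexagon apothem
  # hexagon vertices from C5, stepping away from C4
  a5 <- atan2(sum((v5["C5", ] - cen6) * yhat), sum((v5["C5", ] - cen6) * xhat))
  a4 <- atan2(sum((v5["C4", ] - cen6) * yhat), sum((v5["C4", ] - cen6) * xhat))
  stp <- if (sin(a4 - a5) > 0) -pi / 3 else pi / 3
  v6 <- .polyVerts(cen6, xhat, yhat, BOND_L, a5 + stp * (1:4))
  rownames(v6) <- c("C6", "N1", "C2", "N3")
  at <- rbind(v5, v6)
  if (base == "A") {
    at <- rbind(at, N6 = ex(v6["C6", ], cen6))
    ord <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "N6")
  } else {
    at <- rbind(at, O6 = ex(v6["C6", ], cen6), N2 = ex(v6["C2", ], cen6))
    ord <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "O6", "N2")
  }
  at[ord, , drop = FALSE]
}

.sugarAtoms <- function() {
  r5 <- BOND_L / (2 * sin(pi / 5))
  # ring plane: x-z, tilted; C1' at the origin
  u <- c(1, 0, 0); v <- c(0, 0, 1)
  d <- unitVec(c(-0.94, 0, 0.342))
  cen <- r5 * d
  a0 <- atan2(sum(-d * v), sum(-d * u))      # C1' direction from center
  ang <- a0 + (0:4) * 2 * pi / 5             # C1' C2' C3' C4' O4'
  ring <- .polyVerts(cen, u, v, r5, ang)
  rownames(ring) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  rad <- function(nm) unitVec(ring[nm, ] - cen)
  o3 <- ring["C3'", ] + BOND_L * unitVec(rad("C3'") + c(0, -0.8, -0.3))
  c5 <- ring["C4'", ] + BOND_L * unitVec(rad("C4'") + c(0, 0.8, 0.5))
  o5 <- c5 + BOND_L * unitVec(c(-0.4, 0.9, 0.6))
  p <- o5 + 1.60 * unitVec(c(-0.5, 0.9, 0.2))
  op1 <- p + BOND_L * unitVec(c(-0.2, 0.4, 1.0))
  op2 <- p + BOND_L * unitVec(c(-0.2, 0.4, -1.0))
  rbind(P = p, OP1 = op1, OP2 = op2, `O5'` = o5, `C5'` = c5,
        `C4'` = ring["C4'", ], `O4'` = ring["O4'", ], `C3'` = ring["C3'", ],
        `O3'` = o3, `C2'` = ring["C2'", ], `C1'` = ring["C1'", ])
}

#' Heavy-atom nucleotide template
#'
#' Synthetic idealized deoxynucleotide geometry in the residue-local frame
#' (C1' at the origin, +x toward the paired bead, z the base-plane normal).
#'
#' @param base "A", "C", "G" or "T".
#' @param fivePrime Drop the 5'-terminal phosphate group (P, OP1, OP2).
#' @return Matrix of atom coordinates with atom-name rownames; backbone atoms
#'   first (PDB order), then the base atoms.
#' @export
nucleotideTemplate <- function(base, fivePrime = FALSE) {
  stopifnot(base %in% DNA_BASES)
  at <- rbind(.sugarAtoms(), .baseAtoms(base))
  if (fivePrime) at <- at[setdiff(rownames(at), c("P", "OP1", "OP2")), ,
                          drop = FALSE]
  at
}

# Anchor atoms used as base-stage descriptors: always present regardless of
# terminal phosphate handling.
ANCHOR_ATOMS <- c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'")

# atom bookkeeping for a duplex: one row per atom
.atomTable <- function(seq) {
  if (is.character(seq)) seq <- duplexSequence(seq)
  topo <- buildDuplexTopology(seq)
  n <- topo@nbp
  rows <- list()
  resIdx <- 0L
  addStrand <- function(strand) {
    # residues in the strand's own 5'->3' order
    bps <- if (strand == 1L) seq_len(n) else rev(seq_len(n))
    for (k in seq_along(bps)) {
      p <- bps[k]
      base <- if (strand == 1L) topo@watson[p] else topo@crick[p]
      resIdx <<- resIdx + 1L
      tmpl <- nucleotideTemplate(base, fivePrime = (k == 1L && !seq@circular))
      rows[[resIdx]] <<- data.frame(
        res = resIdx, strand = strand, bp = p, base = base,
        atom = rownames(tmpl), stringsAsFactors = FALSE)
    }
  }
  addStrand(1L); addStrand(2L)
  at <- do.call(rbind, rows)
  rownames(at) <- NULL
  at
}

# Rigid per-residue placement: local frame from the bead positions and bp
# normal. beadXyz 2n x 3; normals n x 3 (bp frame z, Watson orientation).
.placeAtoms <- function(atoms, seq, beadXyz, normals) {
  topo <- buildDuplexTopology(seq)
  n <- topo@nbp
  xyz <- matrix(0, nrow(atoms), 3)
  tmplCache <- list()
  for (r in unique(atoms$res)) {
    idx <- which(atoms$res == r)
    strand <- atoms$strand[idx[1]]
    p <- atoms$bp[idx[1]]
    base <- atoms$base[idx[1]]
    key <- paste(base, length(idx))
    tmpl <- tmplCache[[key]]
    if (is.null(tmpl)) {
      tmpl <- nucleotideTemplate(base)
      if (nrow(tmpl) != length(idx))    # 5'-terminal residue: no phosphate
        tmpl <- nucleotideTemplate(base, fivePrime = TRUE)
      stopifnot(nrow(tmpl) == length(idx))
      tmplCache[[key]] <- tmpl
    }
    self <- if (strand == 1L) beadXyz[p, ] else beadXyz[n + p, ]
    partner <- if (strand == 1L) beadXyz[n + p, ] else beadXyz[p, ]
    zax <- if (strand == 1L) normals[p, ] else -normals[p, ]
    zax <- unitVec(zax)
    xax <- partner - self
    xax <- unitVec(xax - sum(xax * zax) * zax)
    yax <- pracmaCross(zax, xax)
    m <- cbind(xax, yax, zax)
    xyz[idx, ] <- sweep(tmpl %*% t(m), 2, self, `+`)
  }
  xyz
}

#' Ideal B-DNA all-atom build
#'
#' Heavy-atom coordinates built by rigid placement of the synthetic
#' nucleotide templates on the ideal helix frames; the C1' positions exactly
#' reproduce [idealBDNABeads()].
#'
#' @param seq [DuplexSequence-class] or string.
#' @param helix From [helixSpec()].
#' @return An [AtomisticStructure-class] with one frame.
#' @export
idealBDNAAtomistic <- function(seq, helix = helixSpec()) {
  if (is.character(seq)) seq <- duplexSequence(seq)
  atoms <- .atomTable(seq)
  beads <- idealBDNABeads(seq, helix)
  n <- nchar(seq@watson)
  normals <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  xyz <- .placeAtoms(atoms, seq, beads, normals)
  new("AtomisticStructure", atoms = atoms,
      xyz = array(xyz, c(nrow(xyz), 3, 1)), sequence = seq,
      provenance = list(generator = "idealBDNAAtomistic", helix = helix,
                        synthetic = TRUE))
}

#' Paired synthetic bead + all-atom ensembles
#'
#' Fluctuating training data for back-map fitting: bead frames from the
#' synthetic generator and matched heavy-atom frames built by rigid template
#' placement on the same fluctuating base-pair frames. The C1' subset of the
#' atom frames equals the bead frames exactly.
#'
#' @inheritParams synthEnsemble
#' @return List with `beads` (a [TrajectoryEnsemble-class]) and `atoms` (an
#'   [AtomisticStructure-class] with matching frames).
#' @export
synthAtomisticEnsemble <- function(seq, helix = helixSpec(),
                                   fluct = fluctuationSpec(),
                                   nFrames = 200, seed = 1L) {
  res <- .synthFrames(seq, helix, fluct, nFrames, seed, keepRots = TRUE)
  atoms <- .atomTable(res$sequence)
  n <- res$topology@nbp
  nf <- nFrames
  xyz <- array(0, c(nrow(atoms), 3, nf))
  for (f in seq_len(nf)) {
    normals <- t(res$rots[, 3, , f])   # bp frame z axes
    xyz[, , f] <- .placeAtoms(atoms, res$sequence, res$beads@frames[, , f],
                              normals)
  }
  atomsObj <- new("AtomisticStructure", atoms = atoms, xyz = xyz,
                  sequence = res$sequence,
                  provenance = list(generator = "synthAtomisticEnsemble",
                                    seed = seed, synthetic = TRUE))
  list(beads = res$beads, atoms = atomsObj)
}

#' Extract the C1' bead frames of an atomistic structure
#'
#' @param struct An [AtomisticStructure-class].
#' @return A [TrajectoryEnsemble-class] over the C1' atoms in bead order.
#' @export
extractBeads <- function(struct) {
  stopifnot(is(struct, "AtomisticStructure"))
  topo <- buildDuplexTopology(struct@sequence)
  n <- topo@nbp
  at <- struct@atoms
  idx <- integer(2L * n)
  for (r in seq_len(nrow(at))) {
    if (at$atom[r] == "C1'") {
      bead <- if (at$strand[r] == 1L) at$bp[r] else n + at$bp[r]
      idx[bead] <- r
    }
  }
  stopifnot(all(idx > 0L))
  new("TrajectoryEnsemble", frames = struct@xyz[idx, , , drop = FALSE],
      times = as.numeric(seq_len(dim(struct@xyz)[3]) - 1), topology = topo,
      provenance = list(generator = "extractBeads"))
}
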