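# Two-stage window-regression reconstruction of heavy-atom coordinates from
# beads: sequence-neutral backbone regression on sliding windows, then
# base-pair-class-dependent base placement, then soft-sphere clash
# relaxation. All regressions operate in locally superposed frames, which
# makes reconstruction rigid-motion equivariant by construction.

BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                    "O3'", "C2'", "C1'")

# rows of the atom table belonging to the backbone of residues covering
# base pairs `bps`
.backboneRows <- function(atoms, bps) {
  which(atoms$bp %in% bps & atoms$atom %in% BACKBONE_ATOMS)
}

# OLS (optionally PCA-rank-reduced) fit of Y (F x q) on X (F x p)
.linFit <- function(X, Y, rank = NULL) {
  ctrX <- colMeans(X)
  Xc <- sweep(X, 2, ctrX)
  pca <- NULL
  if (!is.null(rank) && rank < ncol(Xc)) {
    sv <- svd(Xc, nu = 0, nv = rank)
    pca <- sv$v
    Xc <- Xc %*% pca
  }
  if (nrow(Xc) <= ncol(Xc))
    stop(sprintf(
      "only %d frames for a rank-%d regression; supply more frames or a stronger rank reduction",
      nrow(Xc), ncol(Xc)))
  ctrY <- colMeans(Y)
  Yc <- sweep(Y, 2, ctrY)
  # minimum-norm least squares (the descriptors of near-rigid training data
  # can be rank deficient)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-8
  coef <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], Yc) / sv$d[keep])
  list(ctrX = ctrX, ctrY = ctrY, coef = coef, pca = pca)
}

.linPredict <- function(fit, x) {
  xc <- x - fit$ctrX
  if (!is.null(fit$pca)) xc <- as.numeric(xc %*% fit$pca)
  as.numeric(xc %*% fit$coef) + fit$ctrY
}

# purine-first bp classification: A.T/T.A -> "AT", G.C/C.G -> "GC"
.bpClass <- function(wBase) {
  list(cls = ifelse(wBase %in% c("A", "T"), "AT", "GC"),
       purineOnWatson = wBase %in% c("A", "G"))
}

.baseRows <- function(atoms, bp, strand) {
  which(atoms$bp == bp & atoms$strand == strand &
        !(atoms$atom %in% BACKBONE_ATOMS))
}

.anchorRows <- function(atoms, bp, strand) {
  idx <- which(atoms$bp == bp & atoms$strand == strand &
               atoms$atom %in% ANCHOR_ATOMS)
  idx[match(ANCHOR_ATOMS, atoms$atom[idx])]
}

#' Train a back-mapping model
#'
#' Fits the two-stage reconstruction on paired bead/atom ensembles: for every
#' sliding window of `window` base pairs, the window's `2 * window` beads are
#' superposed onto a canonical window frame and a least-squares linear map
#' (optionally PCA-rank-reduced) predicts the window's backbone heavy atoms;
#' a second, base-pair-class-dependent map (one per A.T/T.A and G.C/C.G,
#' purine-first orientation) predicts the base heavy atoms from the sugar
#' anchor atoms of the two residues.
#'
#' @param beads A [TrajectoryEnsemble-class]; must be the exact C1' subset of
#'   `atoms`.
#' @param atoms An [AtomisticStructure-class] with matching frames.
#' @param window Window size in bp (default 10).
#' @param rank Optional PCA rank reduction of the bead descriptors (needed
#'   when fewer frames than `6 * window` descriptors are available).
#' @param maxBaseSamples Cap on (frame, bp) samples for the base stage.
#' @return A [BackmapModel-class].
#' @export
trainBackmap <- function(beads, atoms, window = 10L, rank = NULL,
                         maxBaseSamples = 4000L) {
  stopifnot(is(beads, "TrajectoryEnsemble"), is(atoms, "AtomisticStructure"))
  topo <- beads@topology
  n <- topo@nbp
  nf <- dim(beads@frames)[3]
  if (n < window) stop("duplex shorter than the training window")
  if (dim(atoms@xyz)[3] != nf) stop("bead and atom frame counts differ")
  chk <- extractBeads(atoms)
  if (max(abs(chk@frames - beads@frames)) > 1e-6)
    stop("bead frames are not the C1' subset of the atom frames")
  at <- atoms@atoms

  nw <- n - window + 1L
  backbone <- vector("list", nw)
  for (w in seq_len(nw)) {
    bps <- w:(w + window - 1L)
    beadIdx <- c(bps, n + bps)
    rows <- .backboneRows(at, bps)
    sub <- beads@frames[beadIdx, , , drop = FALSE]
    refB <- superposeRMSD(sub, maxIter = 5L)$mean
    X <- matrix(0, nf, 3L * length(beadIdx))
    Y <- matrix(0, nf, 3L * length(rows))
    for (f in seq_len(nf)) {
      k <- kabsch(sub[, , f], refB)
      X[f, ] <- as.numeric(k$xyz)
      Y[f, ] <- as.numeric(sweep(atoms@xyz[rows, , f] %*% k$rotation, 2,
                                 k$translation, `+`))
    }
    fit <- .linFit(X, Y, rank)
    backbone[[w]] <- list(refB = refB, fit = fit,
                          atomNames = at$atom[rows],
                          strands = at$strand[rows],
                          bpOff = at$bp[rows] - w + 1L)
  }

  # base stage samples per class
  clsInfo <- .bpClass(topo@watson)
  samples <- list(AT = list(X = list(), Y = list()),
                  GC = list(X = list(), Y = list()))
  combos <- expand.grid(f = seq_len(nf), p = seq_len(n))
  if (nrow(combos) > maxBaseSamples)
    combos <- combos[seq(1L, nrow(combos),
                         length.out = maxBaseSamples), , drop = FALSE]
  for (r in seq_len(nrow(combos))) {
    f <- combos$f[r]; p <- combos$p[r]
    cls <- clsInfo$cls[p]
    purStrand <- if (clsInfo$purineOnWatson[p]) 1L else 2L
    pyrStrand <- 3L - purStrand
    anc <- c(.anchorRows(at, p, purStrand), .anchorRows(at, p, pyrStrand))
    bas <- c(.baseRows(at, p, purStrand), .baseRows(at, p, pyrStrand))
    samples[[cls]]$X[[length(samples[[cls]]$X) + 1L]] <- atoms@xyz[anc, , f]
    samples[[cls]]$Y[[length(samples[[cls]]$Y) + 1L]] <- atoms@xyz[bas, , f]
    if (is.null(samples[[cls]]$names)) {
      samples[[cls]]$names <- at$atom[bas]
      samples[[cls]]$nPur <- length(.baseRows(at, p, purStrand))
    }
  }
  bases <- list()
  for (cls in names(samples)) {
    sx <- samples[[cls]]$X
    if (length(sx) == 0) next
    refA <- sx[[1]]
    # one alignment pass to a mean anchor configuration
    aligned <- lapply(sx, function(m) kabsch(m, refA)$xyz)
    refA <- Reduce(`+`, aligned) / length(aligned)
    S <- length(sx)
    X <- matrix(0, S, 3L * nrow(refA))
    Y <- matrix(0, S, 3L * length(samples[[cls]]$names))
    for (s in seq_len(S)) {
      k <- kabsch(sx[[s]], refA)
      X[s, ] <- as.numeric(k$xyz)
      Y[s, ] <- as.numeric(sweep(samples[[cls]]$Y[[s]] %*% k$rotation, 2,
                                 k$translation, `+`))
    }
    baseRank <- if (is.null(rank)) NULL else min(rank, ncol(X) - 1L)
    bases[[cls]] <- list(refA = refA, fit = .linFit(X, Y, rank = baseRank),
                         atomNames = samples[[cls]]$names,
                         nPur = samples[[cls]]$nPur)
  }
  new("BackmapModel", window = as.integer(window), backbone = backbone,
      bases = bases,
      meta = list(sequence = paste(topo@watson, collapse = ""),
                  nFrames = nf, rank = rank,
                  frameConvention = "Kabsch onto stored window reference",
                  package = as.character(utils::packageVersion("cgdna"))))
}

# trained window index used for target window w of a duplex with nw windows
.windowMap <- function(w, nw, nTrain, circular) {
  if (nTrain == 1L) return(1L)
  if (!circular) {
    if (w == 1L) return(1L)
    if (w == nw) return(nTrain)
  }
  if (nTrain == 2L) return(if (w <= nw %/% 2L) 1L else 2L)
  2L + ((w - 2L) %% (nTrain - 2L))
}

#' Reconstruct an atomistic trajectory from beads
#'
#' Two-step back-projection: the backbone stage predicts backbone heavy atoms
#' per sliding window (overlapping window predictions are blended by
#' averaging in the global frame after back-superposition); the base stage
#' then places the base atoms per base pair from the established sugar
#' positions. Works on circular topologies through wraparound windows.
#'
#' @param cgTraj A [TrajectoryEnsemble-class] (any duplex at least as long as
#'   the model window).
#' @param model A [BackmapModel-class].
#' @return An [AtomisticStructure-class]; provenance records the per-frame
#'   mean seam discontinuity (inter-window disagreement before blending) and
#'   the maximum C1' deviation from the input beads.
#' @export
reconstructAtomistic <- function(cgTraj, model) {
  stopifnot(is(cgTraj, "TrajectoryEnsemble"), is(model, "BackmapModel"))
  topo <- cgTraj@topology
  n <- topo@nbp
  win <- model@window
  if (n < win) stop("duplex shorter than the model window")
  if (!all(topo@watson %in% DNA_BASES))
    stop("sequence alphabet does not match the model classes")
  seq <- duplexSequence(paste(topo@watson, collapse = ""),
                        circular = topo@circular)
  at <- .atomTable(seq)
  nf <- dim(cgTraj@frames)[3]
  nw <- if (topo@circular) n else n - win + 1L
  nTrain <- length(model@backbone)
  wrap <- function(p) ((p - 1L) %% n) + 1L
  xyz <- array(0, c(nrow(at), 3, nf))
  seam <- numeric(nf)
  c1Max <- 0
  rowKey <- stats::setNames(seq_len(nrow(at)),
                            paste(at$bp, at$strand, at$atom))
  # precompute per-window bead indices, trained fit and target atom rows
  winPre <- lapply(seq_len(nw), function(w) {
    bps <- wrap(w:(w + win - 1L))
    tw <- .windowMap(w, nw, nTrain, topo@circular)
    mdl <- model@backbone[[tw]]
    rows <- unname(rowKey[paste(bps[mdl$bpOff], mdl$strands, mdl$atomNames)])
    list(beadIdx = c(bps, n + bps), mdl = mdl, rows = rows)
  })
  clsInfo <- .bpClass(topo@watson)
  bpPre <- lapply(seq_len(n), function(p) {
    cls <- clsInfo$cls[p]
    if (is.null(model@bases[[cls]]))
      stop(sprintf("model lacks base class %s", cls))
    purStrand <- if (clsInfo$purineOnWatson[p]) 1L else 2L
    pyrStrand <- 3L - purStrand
    list(mdl = model@bases[[cls]],
         anc = c(.anchorRows(at, p, purStrand), .anchorRows(at, p, pyrStrand)),
         bas = c(.baseRows(at, p, purStrand), .baseRows(at, p, pyrStrand)))
  })
  c1Rows <- unname(rowKey[paste(topo@bpPos, topo@strand, "C1'")])
  for (f in seq_len(nf)) {
    acc <- matrix(0, nrow(at), 3)
    cnt <- numeric(nrow(at))
    m2 <- matrix(0, nrow(at), 3)     # for seam statistics
    for (w in seq_len(nw)) {
      pre <- winPre[[w]]
      ok <- !is.na(pre$rows)
      B <- cgTraj@frames[pre$beadIdx, , f]
      k <- kabsch(B, pre$mdl$refB)
      pred <- matrix(.linPredict(pre$mdl$fit, as.numeric(k$xyz)), ncol = 3)
      # back to the global frame
      pred <- sweep(pred, 2, k$translation) %*% t(k$rotation)
      rows <- pre$rows[ok]
      acc[rows, ] <- acc[rows, ] + pred[ok, , drop = FALSE]
      m2[rows, ] <- m2[rows, ] + pred[ok, , drop = FALSE]^2
      cnt[rows] <- cnt[rows] + 1
    }
    bb <- cnt > 0
    xyz[bb, , f] <- acc[bb, ] / cnt[bb]
    mult <- cnt > 1
    if (any(mult)) {
      vr <- m2[mult, ] / cnt[mult] - (acc[mult, ] / cnt[mult])^2
      seam[f] <- mean(sqrt(pmax(rowSums(vr), 0)))
    }
    # base stage
    for (p in seq_len(n)) {
      pre <- bpPre[[p]]
      k <- kabsch(xyz[pre$anc, , f], pre$mdl$refA)
      pred <- matrix(.linPredict(pre$mdl$fit, as.numeric(k$xyz)), ncol = 3)
      xyz[pre$bas, , f] <- sweep(pred, 2, k$translation) %*% t(k$rotation)
    }
    c1Max <- max(c1Max,
                 sqrt(max(rowSums((xyz[c1Rows, , f] -
                                   cgTraj@frames[, , f])^2))))
  }
  if (c1Max > 0.5)
    warning(sprintf("reconstructed C1' positions deviate up to %.2f A from the input beads",
                    c1Max))
  new("AtomisticStructure", atoms = at, xyz = xyz, sequence = seq,
      provenance = list(generator = "reconstructAtomistic",
                        nWindows = nw, seamMean = seam, c1MaxDev = c1Max,
                        synthetic = TRUE))
}

#' Relax steric clashes with a soft-sphere potential
#'
#' Steepest descent on a purely repulsive soft-sphere potential
#' `E = sum k (r0 - r)^2` over clashing atom pairs (pairs from the same
#' residue or sequence-adjacent residues on the same strand are exempt),
#' until the minimum interatomic distance reaches the threshold or the
#' iteration cap. Per-atom displacement from the input structure is capped.
#' This is a geometric clash removal step, not a molecular-mechanics
#' minimization; typical displacements are tenths of an Angstrom.
#'
#' @param struct An [AtomisticStructure-class].
#' @param threshold Clash threshold `r0`, A (default 1.7).
#' @param k Repulsion constant, kcal/mol/A^2.
#' @param maxIter Iteration cap per frame.
#' @param stepSize Steepest-descent step scale.
#' @param maxDisp Per-atom total displacement cap, A.
#' @return The relaxed structure; provenance gains a `relaxation` record. An
#'   unresolvable clash leaves a warning with the clash list and the
#'   structure is still returned.
#' @export
relaxClashes <- function(struct, threshold = 1.7, k = 10, maxIter = 200L,
                         stepSize = 0.05, maxDisp = 1.0) {
  stopifnot(is(struct, "AtomisticStructure"))
  at <- struct@atoms
  nA <- nrow(at)
  excl <- function(i, j) {
    at$res[i] == at$res[j] ||
      (at$strand[i] == at$strand[j] & abs(at$res[i] - at$res[j]) == 1L)
  }
  xyz <- struct@xyz
  nf <- dim(xyz)[3]
  moved <- 0; unresolved <- list()
  for (f in seq_len(nf)) {
    x0 <- xyz[, , f]
    x <- x0
    for (it in seq_len(maxIter)) {
      d <- as.matrix(stats::dist(x))
      diag(d) <- Inf
      clash <- which(d < threshold, arr.ind = TRUE)
      clash <- clash[clash[, 1] < clash[, 2], , drop = FALSE]
      if (nrow(clash))
        clash <- clash[!mapply(excl, clash[, 1], clash[, 2]), ,
                       drop = FALSE]
      if (nrow(clash) == 0) break
      g <- matrix(0, nA, 3)
      for (r in seq_len(nrow(clash))) {
        i <- clash[r, 1]; j <- clash[r, 2]
        rij <- x[j, ] - x[i, ]
        rr <- max(vecNorm(rij), 1e-6)
        # dE/dr = -2 k (r0 - r); push apart
        gmag <- 2 * k * (threshold - rr)
        dir <- rij / rr
        g[i, ] <- g[i, ] - gmag * dir
        g[j, ] <- g[j, ] + gmag * dir
      }
      x <- x + stepSize * g
      # cap total displacement
      disp <- x - x0
      dl <- sqrt(rowSums(disp^2))
      over <- dl > maxDisp
      if (any(over))
        x[over, ] <- x0[over, ] + disp[over, , drop = FALSE] *
          (maxDisp / dl[over])
    }
    d <- as.matrix(stats::dist(x)); diag(d) <- Inf
    clash <- which(d < threshold, arr.ind = TRUE)
    clash <- clash[clash[, 1] < clash[, 2], , drop = FALSE]
    if (nrow(clash))
      clash <- clash[!mapply(excl, clash[, 1], clash[, 2]), , drop = FALSE]
    if (nrow(clash) > 0)
      unresolved[[length(unresolved) + 1L]] <-
        cbind(frame = f, clash, dist = d[clash])
    moved <- max(moved, max(sqrt(rowSums((x - x0)^2))))
    xyz[, , f] <- x
  }
  if (length(unresolved)) {
    warning(sprintf("%d clash(es) remain below %.2f A after relaxation",
                    sum(vapply(unresolved, nrow, integer(1))), threshold))
  }
  prov <- struct@provenance
  prov$relaxation <- list(potential = "soft-sphere (not a force field)",
                          threshold = threshold, maxDisplacement = moved,
                          unresolved = unresolved)
  new("AtomisticStructure", atoms = at, xyz = xyz,
      sequence = struct@sequence, provenance = prov)
}

#' Serialize a BackmapModel to JSON
#'
#' Lossless at full double precision: a written-and-reread model produces
#' bit-identical reconstructions.
#'
#' @param model A [BackmapModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBackmapModel <- function(model, path) {
  packMat <- function(m) list(dim = dim(m), data = as.numeric(m))
  packFit <- function(fit) list(ctrX = fit$ctrX, ctrY = fit$ctrY,
                                coef = packMat(fit$coef),
                                pca = if (is.null(fit$pca)) NULL
                                      else packMat(fit$pca))
  obj <- list(
    format = "cgdna-backmap", version = 1L, window = model@window,
    meta = model@meta,
    backbone = lapply(model@backbone, function(b)
      list(refB = packMat(b$refB), fit = packFit(b$fit),
           atomNames = b$atomNames, strands = b$strands, bpOff = b$bpOff)),
    bases = lapply(model@bases, function(b)
      list(refA = packMat(b$refA), fit = packFit(b$fit),
           atomNames = b$atomNames, nPur = b$nPur)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a BackmapModel from JSON
#'
#' @param path Path written by [writeBackmapModel()].
#' @return A [BackmapModel-class].
#' @export
readBackmapModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "cgdna-backmap"))
    stop(sprintf("%s is not a cgdna backmap model file", path))
  num <- function(x) as.numeric(unlist(x))
  unpackMat <- function(m) matrix(num(m$data), num(m$dim)[1], num(m$dim)[2])
  unpackFit <- function(f) list(ctrX = num(f$ctrX), ctrY = num(f$ctrY),
                                coef = unpackMat(f$coef),
                                pca = if (is.null(f$pca) || length(f$pca) == 0)
                                  NULL else unpackMat(f$pca))
  backbone <- lapply(obj$backbone, function(b)
    list(refB = unpackMat(b$refB), fit = unpackFit(b$fit),
         atomNames = unlist(b$atomNames), strands = as.integer(num(b$strands)),
         bpOff = as.integer(num(b$bpOff))))
  bases <- lapply(obj$bases, function(b)
    list(refA = unpackMat(b$refA), fit = unpackFit(b$fit),
         atomNames = unlist(b$atomNames), nPur = as.integer(num(b$nPur))))
  new("BackmapModel", window = as.integer(num(obj$window)),
      backbone = backbone, bases = bases,
      meta = lapply(obj$meta, function(x) if (is.list(x)) unlist(x) else x))
}
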