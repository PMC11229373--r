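# DNA-mechanics analysis suite: superposition/RMSD, essential dynamics,
# end-to-end, persistence length, gyration shape, bending profiles, writhe,
# cross-RMSD matrices. All estimators are invariant to rigid motion of the
# input frames.

# normalize input to an (nPoints, 3, nFrames) array of curve points:
# TrajectoryEnsemble -> bp midpoints; array/matrix passed through
.pointCurves <- function(x) {
  if (is(x, "TrajectoryEnsemble")) return(bpMidpoints(x))
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[2] == 3L)
  x
}

#' Base-pair midpoint curves
#'
#' The C1'-C1' midpoint of every base pair, per frame; the centerline curve
#' most mechanics estimators operate on.
#'
#' @param ensemble A [TrajectoryEnsemble-class].
#' @return Array `c(nbp, 3, nFrames)`.
#' @export
bpMidpoints <- function(ensemble) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  n <- ensemble@topology@nbp
  (ensemble@frames[seq_len(n), , , drop = FALSE] +
     ensemble@frames[n + seq_len(n), , , drop = FALSE]) / 2
}

#' Superpose an ensemble and compute RMSD
#'
#' Optimal rigid-body (Kabsch, proper rotations only) superposition of every
#' frame onto a reference. With `reference = NULL` the reference is the
#' iterated average structure: frames are aligned to the first frame, the
#' mean is computed, frames are re-aligned to the mean, and so on until the
#' mean is self-consistent.
#'
#' @param x A [TrajectoryEnsemble-class] or `(n, 3, F)` array.
#' @param reference Optional n x 3 reference coordinates.
#' @param maxIter,tol Iteration control for the self-consistent mean.
#' @return List: `rmsd` (per frame, A), `mean` (average structure after
#'   superposition), `aligned` (superposed frame array).
#' @export
superposeRMSD <- function(x, reference = NULL, maxIter = 20L, tol = 1e-8) {
  fr <- if (is(x, "TrajectoryEnsemble")) x@frames else .pointCurves(x)
  nf <- dim(fr)[3]
  alignAll <- function(ref) {
    out <- fr
    r <- numeric(nf)
    for (f in seq_len(nf)) {
      k <- kabsch(fr[, , f], ref)
      out[, , f] <- k$xyz
      r[f] <- k$rmsd
    }
    list(aligned = out, rmsd = r)
  }
  if (!is.null(reference)) {
    al <- alignAll(reference)
    return(list(rmsd = al$rmsd, mean = apply(al$aligned, c(1, 2), mean),
                aligned = al$aligned))
  }
  ref <- fr[, , 1]
  for (it in seq_len(maxIter)) {
    al <- alignAll(ref)
    newRef <- apply(al$aligned, c(1, 2), mean)
    if (sqrt(mean((newRef - ref)^2)) < tol) { ref <- newRef; break }
    ref <- newRef
  }
  al <- alignAll(ref)
  list(rmsd = al$rmsd, mean = ref, aligned = al$aligned)
}

#' Essential deformation modes
#'
#' Eigendecomposition of the coordinate covariance matrix after superposition
#' onto the self-consistent mean: principal components of the ensemble's
#' fluctuations, ordered by decreasing variance.
#'
#' @param x A [TrajectoryEnsemble-class] or coordinate array.
#' @param nModes Number of modes to keep (default all available).
#' @return List: `modes` (3n x nModes orthonormal matrix), `eigenvalues`
#'   (A^2, non-increasing), `mean` (superposition reference).
#' @export
essentialModes <- function(x, nModes = NULL) {
  sup <- superposeRMSD(x)
  d <- dim(sup$aligned)
  nf <- d[3]
  if (is.null(nModes)) nModes <- min(3 * d[1], nf - 1)
  stopifnot(nf >= nModes)
  xm <- t(apply(sup$aligned, 3, identity))       # F x 3n
  xc <- sweep(xm, 2, colMeans(xm))
  sv <- svd(xc / sqrt(nf - 1), nu = 0, nv = nModes)
  list(modes = sv$v, eigenvalues = sv$d[seq_len(nModes)]^2, mean = sup$mean)
}

#' Root mean square inner product of two mode sets
#'
#' `RMSIP = sqrt( (1/n) sum_i sum_j (v_i . w_j)^2 )` over the first `n` modes
#' of each set; 1 for identical subspaces, ~sqrt(n/d) for random
#' n-dimensional subspaces of dimension d.
#'
#' @param a,b Mode matrices (columns orthonormal) or results of
#'   [essentialModes()].
#' @param n Number of modes compared (default 10).
#' @return Value in `[0, 1]`.
#' @export
rmsip <- function(a, b, n = 10L) {
  va <- if (is.list(a)) a$modes else a
  vb <- if (is.list(b)) b$modes else b
  n <- min(n, ncol(va), ncol(vb))
  ip <- crossprod(va[, seq_len(n), drop = FALSE],
                  vb[, seq_len(n), drop = FALSE])
  min(sqrt(sum(ip^2) / n), 1)
}

#' End-to-end distance
#'
#' Distance between the first and last base-pair C1'-midpoints per frame
#' (this definition is recorded in the result so alternatives, e.g. terminal
#' beads, can be distinguished downstream).
#'
#' @param x A linear-duplex [TrajectoryEnsemble-class] or point-curve array.
#' @return List: `mean` (A), `sd` (A), `series` (per frame), `definition`.
#' @export
endToEnd <- function(x) {
  if (is(x, "TrajectoryEnsemble") && x@topology@circular)
    stop("end-to-end distance is defined for linear duplexes")
  pc <- .pointCurves(x)
  n <- dim(pc)[1]
  series <- vapply(seq_len(dim(pc)[3]), function(f)
    sqrt(sum((pc[n, , f] - pc[1, , f])^2)), numeric(1))
  list(mean = mean(series), sd = if (length(series) > 1) stats::sd(series) else 0,
       series = series, definition = "terminal bp C1'-midpoints")
}

#' Persistence length from tangent correlations
#'
#' Tangents are taken along the (optionally smoothed) bp-midpoint curve; the
#' estimator fits `<cos theta(s)> = exp(-s / PL)` by log-linear regression
#' over the initial decay (down to `<cos theta> = 0.5` by default, so the fit
#' stays in the exponential regime). A chain whose correlations never decay
#' measurably is reported as `Inf`.
#'
#' @param x Ensemble or point-curve array; the chain should be much longer
#'   than the smoothing window.
#' @param window Running-mean smoothing window for the midpoint curve (odd,
#'   1 = no smoothing).
#' @param cosCut Fit range: separations with `<cos theta>` above this value.
#' @return List: `pl` (nm), `plAngstrom`, `step` (mean contour step, A),
#'   `cosTheta` (correlation curve), `sep` (separations, steps).
#' @export
persistenceLength <- function(x, window = 3L, cosCut = 0.5) {
  pc <- .pointCurves(x)
  n <- dim(pc)[1]; nf <- dim(pc)[3]
  if (window > 1L) {
    sm <- array(0, c(n - window + 1L, 3, nf))
    for (o in seq_len(window)) sm <- sm + pc[o:(n - window + o), , , drop = FALSE]
    pc <- sm / window
    n <- dim(pc)[1]
  }
  tg <- pc[-1, , , drop = FALSE] - pc[-n, , , drop = FALSE]
  segLen <- sqrt(tg[, 1, , drop = FALSE]^2 + tg[, 2, , drop = FALSE]^2 +
                 tg[, 3, , drop = FALSE]^2)
  step <- mean(segLen)
  for (d in 1:3) tg[, d, ] <- tg[, d, ] / segLen[, 1, ]
  nt <- n - 1L
  smax <- nt - 1L
  ct <- numeric(smax)
  for (s in seq_len(smax)) {
    dot <- tg[seq_len(nt - s), 1, ] * tg[s + seq_len(nt - s), 1, ] +
           tg[seq_len(nt - s), 2, ] * tg[s + seq_len(nt - s), 2, ] +
           tg[seq_len(nt - s), 3, ] * tg[s + seq_len(nt - s), 3, ]
    ct[s] <- mean(dot)
  }
  use <- which(ct > cosCut & ct > 0)
  use <- use[use == seq_along(use)]     # initial contiguous decay only
  if (length(use) < 2 || all(ct[use] > 0.9999))
    return(list(pl = Inf, plAngstrom = Inf, step = step, cosTheta = ct,
                sep = seq_len(smax)))
  s <- use * step
  fit <- stats::lm.fit(cbind(1, s), log(ct[use]))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    return(list(pl = Inf, plAngstrom = Inf, step = step, cosTheta = ct,
                sep = seq_len(smax)))
  plA <- -1 / slope
  list(pl = plA / 10, plAngstrom = plA, step = step, cosTheta = ct,
       sep = seq_len(smax))
}

#' Gyration-tensor shape descriptors
#'
#' Per frame: radius of gyration from the gyration-tensor trace and the
#' aspect ratio `sqrt(lambda_max / lambda_min)` of its eigenvalues.
#'
#' @param x A [TrajectoryEnsemble-class] (all beads are used) or point array.
#' @return List: `rg` (A, per frame), `aspect` (per frame).
#' @export
shapeDescriptors <- function(x) {
  fr <- if (is(x, "TrajectoryEnsemble")) x@frames else .pointCurves(x)
  nf <- dim(fr)[3]
  rg <- aspect <- numeric(nf)
  for (f in seq_len(nf)) {
    xc <- sweep(fr[, , f], 2, colMeans(fr[, , f]))
    gt <- crossprod(xc) / nrow(xc)
    ev <- eigen(gt, symmetric = TRUE, only.values = TRUE)$values
    rg[f] <- sqrt(sum(ev))
    aspect[f] <- sqrt(max(ev) / max(min(ev), 1e-12))
  }
  list(rg = rg, aspect = aspect)
}

#' Bending-angle profile
#'
#' At each position, the bending angle between the two chords joining the
#' position's bp midpoint to the midpoints `window / 2` away on either side
#' (the deviation from straight, in degrees). Linear profiles cover positions
#' `window/2 + 1 .. n - window/2` (length `n - window`); circular topologies
#' wrap and cover every position.
#'
#' @param x Ensemble or point-curve array.
#' @param window Even window size in bp (a typical choice for gene
#'   -length chains is 196; choose `< nbp`).
#' @param circular Closed-curve profile (default from the ensemble topology).
#' @return List: `position`, `mean` (deg), `sd` (deg), `window`.
#' @export
bendingProfile <- function(x, window = 10L, circular = NULL) {
  if (is.null(circular))
    circular <- if (is(x, "TrajectoryEnsemble")) x@topology@circular else FALSE
  stopifnot(window %% 2L == 0L)
  pc <- .pointCurves(x)
  n <- dim(pc)[1]; nf <- dim(pc)[3]
  if (window >= n) stop("window must be smaller than the chain")
  h <- window %/% 2L
  pos <- if (circular) seq_len(n) else seq.int(h + 1L, n - h)
  ang <- matrix(0, length(pos), nf)
  wrap <- function(p) ((p - 1L) %% n) + 1L
  for (f in seq_len(nf)) {
    m <- pc[, , f]
    a <- m[wrap(pos - h), , drop = FALSE]
    b <- m[wrap(pos), , drop = FALSE]
    cc <- m[wrap(pos + h), , drop = FALSE]
    u <- b - a; v <- cc - b
    ct <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    ang[, f] <- acos(pmax(-1, pmin(1, ct))) * 180 / pi
  }
  list(position = pos, mean = rowMeans(ang),
       sd = if (nf > 1) apply(ang, 1, stats::sd) else rep(0, length(pos)),
       window = window)
}

#' Writhe of a closed curve
#'
#' Discretized Gauss double integral over all segment pairs of the closed
#' bp-midpoint polygon (exact solid-angle formula per segment pair).
#'
#' @param x A closed curve: n x 3 matrix of vertices (the segment from the
#'   last to the first vertex closes the polygon), or a circular-topology
#'   [TrajectoryEnsemble-class] (first frame's midpoints), or a point array
#'   (first frame).
#' @return Writhe (dimensionless, signed).
#' @export
writhe <- function(x) {
  if (is(x, "TrajectoryEnsemble")) x <- bpMidpoints(x)[, , 1]
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1]
  n <- nrow(x)
  nxt <- c(2:n, 1L)
  wr <- 0
  for (i in seq_len(n)) {
    p1 <- x[i, ]; p2 <- x[nxt[i], ]
    for (j in seq_len(n)) {
      if (j == i || j == nxt[i] || nxt[j] == i) next
      if (j < i) next
      p3 <- x[j, ]; p4 <- x[nxt[j], ]
      r13 <- p3 - p1; r14 <- p4 - p1; r23 <- p3 - p2; r24 <- p4 - p2
      n1 <- pracmaCross(r13, r14); n2 <- pracmaCross(r14, r24)
      n3 <- pracmaCross(r24, r23); n4 <- pracmaCross(r23, r13)
      nn <- function(v) { l <- vecNorm(v); if (l < 1e-12) v else v / l }
      n1 <- nn(n1); n2 <- nn(n2); n3 <- nn(n3); n4 <- nn(n4)
      om <- asin(pmax(-1, pmin(1, sum(n1 * n2)))) +
            asin(pmax(-1, pmin(1, sum(n2 * n3)))) +
            asin(pmax(-1, pmin(1, sum(n3 * n4)))) +
            asin(pmax(-1, pmin(1, sum(n4 * n1))))
      sgn <- sign(sum(pracmaCross(p4 - p3, p2 - p1) * r13))
      wr <- wr + 2 * om * sgn
    }
  }
  wr / (4 * pi)
}

#' Cross-RMSD matrix between ensembles
#'
#' Pairwise superposed RMSD between all frames across one or more ensembles;
#' block boundaries (frame counts per ensemble) are reported so within- and
#' between-ensemble blocks can be read off.
#'
#' @param ... TrajectoryEnsembles or coordinate arrays with equal bead
#'   counts.
#' @return List: `rmsd` (symmetric matrix with zero diagonal), `blocks`
#'   (frame count per input).
#' @export
crossRMSDMatrix <- function(...) {
  ins <- lapply(list(...), function(x)
    if (is(x, "TrajectoryEnsemble")) x@frames else .pointCurves(x))
  nb <- vapply(ins, function(a) dim(a)[1], integer(1))
  if (length(unique(nb)) != 1L) stop("ensembles must have equal bead counts")
  blocks <- vapply(ins, function(a) dim(a)[3], integer(1))
  all <- array(unlist(ins), c(nb[1], 3, sum(blocks)))
  nf <- sum(blocks)
  m <- matrix(0, nf, nf)
  for (a in seq_len(nf - 1L))
    for (b in seq.int(a + 1L, nf)) {
      m[a, b] <- m[b, a] <- kabsch(all[, , b], all[, , a])$rmsd
    }
  list(rmsd = m, blocks = blocks)
}
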