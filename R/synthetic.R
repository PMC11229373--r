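#' Ideal B-DNA helix specification
#'
#' Geometry of the ideal helical build used for starting structures and
#' synthetic reference ensembles.
#'
#' @param rise Helical rise, Angstrom per bp (default 3.38).
#' @param twist Helical twist, degrees per bp (default 34.3).
#' @param radius Radius of the C1' bead circle, Angstrom (default 9.0).
#' @param phase Inter-strand phase, degrees. The default 180 places the two
#'   C1' beads of a base pair antipodally so every bp C1'-C1' midpoint lies
#'   exactly on the helix axis.
#' @return Named list of helix parameters.
#' @export
helixSpec <- function(rise = 3.38, twist = 34.3, radius = 9.0, phase = 180) {
  stopifnot(rise > 0, twist > 0, twist < 360, radius > 0)
  list(rise = rise, twist = twist, radius = radius, phase = phase)
}

#' Gaussian fluctuation specification for synthetic reference ensembles
#'
#' Controls the internal Gaussian fluctuations of [synthEnsemble()]: target
#' standard deviations of the stacking distance, pairing distance and
#' backbone-angle observables, optional per-tetramer-class amplitude
#' multipliers, and the smooth bending amplitude expressed as a target
#' persistence length.
#'
#' The default persistence length is deliberately stiffer than real B-DNA
#' (150 nm rather than ~50 nm) so that bending contributes only a minor share
#' of the local-distance variance and the SD knobs remain the controlling
#' parameters; bending-induced variance is measured on a seeded pilot
#' ensemble and subtracted before the per-bead jitter amplitudes are solved
#' for, which is what makes the sample SDs converge to the targets.
#'
#' @param sdStacking SD of intra-strand C1'-C1' stacking distances, A.
#' @param sdPairing SD of Watson-Crick C1'-C1' distances, A.
#' @param sdAngle SD of the intra-strand bead angle, rad.
#' @param classSd Named numeric: canonical tetramer class -> multiplier on the
#'   local jitter amplitudes of the base pairs in windows of that class.
#' @param persistenceLength Target persistence length of the bending modes,
#'   nm; `Inf` disables bending.
#' @return Named list.
#' @export
fluctuationSpec <- function(sdStacking = 0.30, sdPairing = 0.30,
                            sdAngle = 0.08, classSd = numeric(0),
                            persistenceLength = 150) {
  stopifnot(sdStacking >= 0, sdPairing >= 0, sdAngle >= 0,
            persistenceLength > 0)
  list(sdStacking = sdStacking, sdPairing = sdPairing, sdAngle = sdAngle,
       classSd = classSd, persistenceLength = persistenceLength)
}

#' Ideal B-DNA bead build
#'
#' Deterministic helical C1' coordinates; base-pair midpoints are colinear on
#' the z-axis and consecutive midpoints are separated by exactly the rise.
#'
#' @param x A [DuplexSequence-class], [BeadTopology-class] or string.
#' @param helix From [helixSpec()].
#' @return `2 nbp` x 3 coordinate matrix (bead order of the topology).
#' @export
#' @examples
#' xyz <- idealBDNABeads("ACGTACGTACGTACGTAC")
#' sqrt(sum((colMeans(xyz[c(1, 19), ]) - colMeans(xyz[c(18, 36), ]))^2)) # 17 x rise
idealBDNABeads <- function(x, helix = helixSpec()) {
  topo <- if (is(x, "BeadTopology")) x else buildDuplexTopology(x)
  n <- topo@nbp
  th <- (seq_len(n) - 1) * helix$twist * pi / 180
  z <- (seq_len(n) - 1) * helix$rise
  ph <- helix$phase * pi / 180
  rbind(cbind(helix$radius * cos(th), helix$radius * sin(th), z),
        cbind(helix$radius * cos(th + ph), helix$radius * sin(th + ph), z))
}

# Local (bp-frame) bead offsets and the per-bead jitter axes, from the ideal
# geometry. Axes: t = stacking bond direction, p = pairing direction
# orthogonalized against t, n = t x p.
.localGeometry <- function(helix) {
  tw <- helix$twist * pi / 180
  ph <- helix$phase * pi / 180
  R <- helix$radius
  w0 <- c(R, 0, 0)
  c0 <- c(R * cos(ph), R * sin(ph), 0)
  rot <- rotationMatrix(c(0, 0, 1), tw)      # acts on row vectors
  w1 <- as.numeric(w0 %*% rot) + c(0, 0, helix$rise)
  c1 <- as.numeric(c0 %*% rot) + c(0, 0, helix$rise)
  axesFor <- function(self, nxt, partner) {
    t <- unitVec(nxt - self)
    p <- partner - self
    p <- unitVec(p - sum(p * t) * t)
    cbind(t = t, p = p, n = pracmaCross(t, p))
  }
  list(w0 = w0, c0 = c0, w1 = w1, c1 = c1,
       axesW = axesFor(w0, w1, c0), axesC = axesFor(c0, c1, w0))
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Coefficients of Var(observable) as a linear form in (sd_t^2, sd_p^2,
# sd_n^2): squared projections of the jitter axes on the observable gradient,
# summed over the beads involved (first-order propagation, exact for the
# linearized observable). Each bead's jitter axes live in its own bp frame,
# so the axes of neighboring beads are rotated by the helical twist before
# projecting.
.jitterCoefficients <- function(helix) {
  g <- .localGeometry(helix)
  tw <- helix$twist * pi / 180
  rotF <- t(rotationMatrix(c(0, 0, 1), tw))     # column-vector convention
  rotB <- t(rotF)
  projBond <- function(a, b, axesA, axesB) {
    u <- unitVec(b - a)
    as.numeric(crossprod(axesA, u))^2 + as.numeric(crossprod(axesB, u))^2
  }
  # stacking: bead p (own frame) and bead p+1 (frame rotated by the twist)
  cs <- (projBond(g$w0, g$w1, g$axesW, rotF %*% g$axesW) +
         projBond(g$c0, g$c1, g$axesC, rotF %*% g$axesC)) / 2
  # pairing: both beads share the bp frame
  cp <- projBond(g$w0, g$c0, g$axesW, g$axesC)
  # angle at an interior Watson bead: numeric gradient over the 3 beads
  wm1 <- as.numeric(rotB %*% (g$w0 - c(0, 0, helix$rise)))
  pts <- list(wm1, g$w0, g$w1)
  axes <- list(rotB %*% g$axesW, g$axesW, rotF %*% g$axesW)
  grad <- matrix(0, 3, 3)
  h <- 1e-6
  for (b in 1:3) for (d in 1:3) {
    pp <- pts; pp[[b]][d] <- pp[[b]][d] + h
    pm <- pts; pm[[b]][d] <- pm[[b]][d] - h
    grad[b, d] <- (tripletAngle(pp[[1]], pp[[2]], pp[[3]]) -
                   tripletAngle(pm[[1]], pm[[2]], pm[[3]])) / (2 * h)
  }
  ca <- numeric(3)
  for (b in 1:3) ca <- ca + as.numeric((grad[b, ] %*% axes[[b]])^2)
  co <- rbind(stacking = cs, pairing = cp, angle = ca)
  colnames(co) <- c("t", "p", "n")
  co
}

# Backbone bp frames for one fluctuating frame: accumulated twist + random
# per-step bend (two transverse Gaussian angles). Returns list(origins n x 3,
# rots 3 x 3 x n). bendSd = 0 gives the ideal helix.
.backboneFrames <- function(n, helix, bendSd) {
  tw <- helix$twist * pi / 180
  rise <- helix$rise
  origins <- matrix(0, n, 3)
  rots <- array(0, c(3, 3, n))
  m <- diag(3)
  rots[, , 1] <- m
  rtw <- t(rotationMatrix(c(0, 0, 1), tw))  # column-vector convention
  for (p in seq_len(n - 1)) {
    m2 <- m %*% rtw
    if (bendSd > 0) {
      a <- stats::rnorm(2, 0, bendSd)
      m2 <- m2 %*% t(rotationMatrix(c(1, 0, 0), a[1])) %*%
            t(rotationMatrix(c(0, 1, 0), a[2]))
    }
    origins[p + 1, ] <- origins[p, ] + as.numeric(m2 %*% c(0, 0, rise))
    rots[, , p + 1] <- m2
    m <- m2
  }
  list(origins = origins, rots = rots)
}

# bead coordinates from backbone frames + per-bead local jitter (2n x 3)
.framesToBeads <- function(bb, helix, jitterW = NULL, jitterC = NULL) {
  n <- nrow(bb$origins)
  ph <- helix$phase * pi / 180
  wloc <- c(helix$radius, 0, 0)
  cloc <- c(helix$radius * cos(ph), helix$radius * sin(ph), 0)
  out <- matrix(0, 2L * n, 3)
  for (p in seq_len(n)) {
    m <- bb$rots[, , p]
    w <- wloc; cc <- cloc
    if (!is.null(jitterW)) { w <- w + jitterW[p, ]; cc <- cc + jitterC[p, ] }
    out[p, ] <- bb$origins[p, ] + as.numeric(m %*% w)
    out[n + p, ] <- bb$origins[p, ] + as.numeric(m %*% cc)
  }
  out
}

# per-bp jitter multipliers from tetramer-class overrides
.bpMultipliers <- function(topo, classSd) {
  n <- topo@nbp
  mult <- rep(1, n)
  if (length(classSd) == 0) return(mult)
  wins <- if (topo@circular) seq_len(n) else seq_len(max(0L, n - 3L))
  acc <- vector("list", n)
  wrap <- function(p) ((p - 1L) %% n) + 1L
  for (t in wins) {
    tet <- paste(topo@watson[wrap(t:(t + 3L))], collapse = "")
    cls <- canonicalTetramer(tet)$class
    m <- if (cls %in% names(classSd)) classSd[[cls]] else 1
    for (p in wrap(t:(t + 3L))) acc[[p]] <- c(acc[[p]], m)
  }
  vapply(seq_len(n), function(p)
    if (is.null(acc[[p]])) 1 else mean(acc[[p]]), numeric(1))
}

#' Synthetic fluctuating reference ensemble
#'
#' Generates a bead ensemble emulating an atomistic-MD reference: ideal
#' B-DNA plus seeded Gaussian internal fluctuations plus smooth bending
#' modes. Bending is applied as accumulated small random rotations of the
#' base-pair frames (a discrete worm-like chain); per-bead anisotropic
#' Gaussian jitter is calibrated (see [fluctuationSpec()]) so the sample SDs
#' of the stacking and pairing distances converge to the requested targets as
#' the frame count grows. Two runs with the same seed give identical
#' ensembles.
#'
#' @param seq [DuplexSequence-class] or string (linear duplexes).
#' @param helix From [helixSpec()].
#' @param fluct From [fluctuationSpec()].
#' @param nFrames Number of frames (>= 2).
#' @param seed RNG seed.
#' @return A [TrajectoryEnsemble-class].
#' @export
synthEnsemble <- function(seq, helix = helixSpec(), fluct = fluctuationSpec(),
                          nFrames = 1000, seed = 1L) {
  res <- .synthFrames(seq, helix, fluct, nFrames, seed, keepRots = FALSE)
  res$beads
}

# Shared generator; keepRots additionally returns per-frame bp frames for
# rigid atom placement.
.synthFrames <- function(seq, helix, fluct, nFrames, seed, keepRots = FALSE) {
  if (is.character(seq)) seq <- duplexSequence(seq)
  topo <- buildDuplexTopology(seq)
  if (topo@circular) stop("synthetic ensembles support linear duplexes only")
  if (nFrames < 2) stop("need at least 2 frames")
  n <- topo@nbp
  set.seed(seed)
  bendSd <- if (is.finite(fluct$persistenceLength))
    sqrt(helix$rise / (10 * fluct$persistenceLength)) else 0

  # pilot: bending-only variance of the target observables
  pilotVar <- c(stacking = 0, pairing = 0, angle = 0)
  if (bendSd > 0) {
    nPilot <- 400L
    sv <- av <- pv <- numeric(0)
    for (f in seq_len(nPilot)) {
      bb <- .backboneFrames(n, helix, bendSd)
      xyz <- .framesToBeads(bb, helix)
      w <- xyz[seq_len(n), ]
      sv <- c(sv, sqrt(rowSums((w[-1, , drop = FALSE] -
                                w[-n, , drop = FALSE])^2)))
      pv <- c(pv, sqrt(rowSums((xyz[n + seq_len(n), ] - w)^2)))
      if (n >= 3) {
        mid <- 2:(n - 1)
        av <- c(av, vapply(mid, function(p)
          tripletAngle(w[p - 1, ], w[p, ], w[p + 1, ]), numeric(1)))
      }
    }
    dim(sv) <- c(n - 1, nPilot); dim(pv) <- c(n, nPilot)
    if (n >= 3) dim(av) <- c(n - 2, nPilot)
    pilotVar["stacking"] <- mean(apply(sv, 1, stats::var))
    pilotVar["pairing"] <- mean(apply(pv, 1, stats::var))
    if (n >= 3) pilotVar["angle"] <- mean(apply(av, 1, stats::var))
  }

  targets <- c(stacking = fluct$sdStacking^2, pairing = fluct$sdPairing^2,
               angle = fluct$sdAngle^2)
  resid <- targets - pilotVar
  if (any(targets > 0 & resid < 0)) {
    warning("bending modes alone exceed a requested SD target; ",
            "jitter for that observable is disabled")
    resid <- pmax(resid, 0)
  }
  co <- .jitterCoefficients(helix)
  s2 <- if (all(resid == 0)) c(0, 0, 0) else {
    sol <- tryCatch(solve(co, resid), error = function(e) NULL)
    if (is.null(sol) || any(sol < -1e-8)) {
      # fall back to non-negative least squares via projected coordinates
      sol <- pmax(qr.solve(co, resid), 0)
    }
    pmax(sol, 0)
  }
  sdAxes <- sqrt(s2)

  g <- .localGeometry(helix)
  mult <- .bpMultipliers(topo, fluct$classSd)
  frames <- array(0, c(2L * n, 3, nFrames))
  rots <- if (keepRots) array(0, c(3, 3, n, nFrames)) else NULL
  origins <- if (keepRots) array(0, c(n, 3, nFrames)) else NULL
  for (f in seq_len(nFrames)) {
    bb <- .backboneFrames(n, helix, bendSd)
    if (any(sdAxes > 0)) {
      jW <- matrix(stats::rnorm(3 * n), n, 3) %*%
        t(g$axesW * rep(sdAxes, each = 3)) * mult
      jC <- matrix(stats::rnorm(3 * n), n, 3) %*%
        t(g$axesC * rep(sdAxes, each = 3)) * mult
    } else {
      jW <- jC <- matrix(0, n, 3)
    }
    frames[, , f] <- .framesToBeads(bb, helix, jW, jC)
    if (keepRots) { rots[, , , f] <- bb$rots; origins[, , f] <- bb$origins }
  }
  beads <- new("TrajectoryEnsemble", frames = frames,
               times = as.numeric(seq_len(nFrames) - 1), topology = topo,
               provenance = list(generator = "synthEnsemble", seed = seed,
                                 helix = helix, fluct = fluct,
                                 jitterSdAxes = sdAxes, bendSd = bendSd))
  list(beads = beads, rots = rots, origins = origins, topology = topo,
       sequence = seq)
}

#' Sample discrete worm-like chains
#'
#' Independent WLC realizations used as the persistence-length estimator
#' oracle: at every step the tangent is bent by two independent Gaussian
#' angles so that `PL = stepLen / sd^2` with `sd = sqrt(stepLen / PL)`.
#'
#' @param nSteps Segments per chain.
#' @param nFrames Number of chains.
#' @param stepLen Segment length, A (default the B-DNA rise).
#' @param persistenceLength Target persistence length, nm.
#' @param seed RNG seed.
#' @return Array `c(nSteps + 1, 3, nFrames)` of vertex coordinates.
#' @export
sampleWLC <- function(nSteps = 200, nFrames = 1000, stepLen = 3.38,
                      persistenceLength = 50, seed = 1L) {
  set.seed(seed)
  bendSd <- sqrt(stepLen / (10 * persistenceLength))
  cpp_wlc_curves(nSteps, nFrames, stepLen, bendSd)
}

#' Build a supercoiled minicircle starting structure
#'
#' Beads are laid on a planar ring of circumference `nbp * rise`; the
#' base-pair cross-section rotates around the ring centerline by
#' `(Lk0 + deltaLk) * 360 / nbp` degrees per step, so strand closure is exact
#' and the imposed linking number is `Lk0 + deltaLk`, with the intrinsic
#' `Lk0 = round(nbp / 10.5)`.
#'
#' @param seq Circular [DuplexSequence-class] (or string, coerced circular).
#' @param deltaLk Integer linking-number difference from the relaxed value.
#' @param helix From [helixSpec()].
#' @param lk0 Override for the intrinsic linking number.
#' @return List with `coords` (2 nbp x 3), `topology`, `lk0`, `deltaLk`, and
#'   `twistPerStep` (degrees).
#' @export
buildMinicircle <- function(seq, deltaLk = 0, helix = helixSpec(),
                            lk0 = NULL) {
  if (is.character(seq)) seq <- duplexSequence(seq, circular = TRUE)
  if (!seq@circular) stop("minicircle build needs a circular sequence")
  topo <- buildDuplexTopology(seq)
  n <- topo@nbp
  lk0 <- if (is.null(lk0)) round(n / 10.5) else as.integer(lk0)
  lk <- lk0 + deltaLk
  Rring <- n * helix$rise / (2 * pi)
  phi <- (seq_len(n) - 1) * 2 * pi / n
  psi <- (seq_len(n) - 1) * lk * 2 * pi / n
  ph <- helix$phase * pi / 180
  er <- cbind(cos(phi), sin(phi), 0)
  ez <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  ctr <- Rring * er
  w <- ctr + helix$radius * (cos(psi) * er + sin(psi) * ez)
  cc <- ctr + helix$radius * (cos(psi + ph) * er + sin(psi + ph) * ez)
  list(coords = rbind(w, cc), topology = topo, lk0 = lk0, deltaLk = deltaLk,
       twistPerStep = lk * 360 / n)
}
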