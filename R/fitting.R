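# Bottom-up parameterization: observable extraction from reference bead
# ensembles, sequence-independent baseline inversion, iterative per-tetramer
# refinement, and distant-term annealing against end-to-end statistics.

# per-frame instance values: list(bonds = nB x F matrix, angles = nA x F)
.instanceValues <- function(table, frames) {
  nf <- dim(frames)[3]
  b <- table@bonds
  a <- table@angles
  bv <- matrix(0, nrow(b), nf)
  av <- matrix(0, nrow(a), nf)
  for (f in seq_len(nf)) {
    x <- frames[, , f]
    d <- x[b$j, , drop = FALSE] - x[b$i, , drop = FALSE]
    bv[, f] <- sqrt(rowSums(d^2))
    if (nrow(a)) {
      u <- x[a$i, , drop = FALSE] - x[a$j, , drop = FALSE]
      v <- x[a$k, , drop = FALSE] - x[a$j, , drop = FALSE]
      ct <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
      av[, f] <- acos(pmax(-1, pmin(1, ct)))
    }
  }
  list(bonds = bv, angles = av)
}

#' Extract reference observables from an ensemble
#'
#' Computes per-interaction-instance sample means and variances over the
#' frames of a reference ensemble (equilibrium distances and angles), pools
#' them by tetramer class and role with multiplicity weighting, and records
#' selected covariances between instances sharing a bead.
#'
#' @param ensemble A [TrajectoryEnsemble-class] with >= 2 frames.
#' @param scheme Accounting scheme for the interaction enumeration.
#' @param maxCov Maximum number of shared-bead covariance pairs recorded.
#' @return A [ReferenceObservables-class].
#' @export
extractObservables <- function(ensemble, scheme = "eq5", maxCov = 200L) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  if (dim(ensemble@frames)[3] < 2L) stop("need at least 2 frames")
  topo <- ensemble@topology
  table <- enumerateInteractions(topo, scheme)
  vals <- .instanceValues(table, ensemble@frames)
  rowVar <- function(m) apply(m, 1, stats::var)
  b <- table@bonds
  inst <- data.frame(
    kind = c(b$kind, rep("angle", nrow(table@angles))),
    i = c(b$i, table@angles$i),
    j = c(b$j, table@angles$j),
    k = c(rep(NA_integer_, nrow(b)), table@angles$k),
    mean = c(rowMeans(vals$bonds), rowMeans(vals$angles)),
    var = c(rowVar(vals$bonds), rowVar(vals$angles)),
    stringsAsFactors = FALSE)
  inst$contexts <- c(b$contexts, table@angles$contexts)

  # multiplicity-weighted pooling per (class, role): every instance context
  # contributes once
  keys <- unlist(lapply(inst$contexts, unique))
  reps <- vapply(inst$contexts, function(x) length(unique(x)), integer(1))
  idx <- rep(seq_len(nrow(inst)), reps)
  sp <- split(idx, keys)
  byClass <- data.frame(
    class = vapply(strsplit(names(sp), "/", fixed = TRUE), `[`, character(1), 1),
    role = vapply(strsplit(names(sp), "/", fixed = TRUE), `[`, character(1), 2),
    mean = vapply(sp, function(ii) mean(inst$mean[ii]), numeric(1)),
    var = vapply(sp, function(ii) mean(inst$var[ii]), numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  # selected covariances: bonded instances sharing a bead (stacking pairs and
  # stacking-pairing pairs)
  covs <- data.frame(a = integer(0), b = integer(0), cov = numeric(0))
  bb <- which(b$kind %in% c("stacking", "pairing"))
  if (length(bb) > 1) {
    pairs <- list()
    for (u in seq_along(bb)) {
      for (v in seq_len(u - 1L)) {
        iu <- bb[u]; iv <- bb[v]
        if (length(intersect(c(b$i[iu], b$j[iu]), c(b$i[iv], b$j[iv])))) {
          pairs[[length(pairs) + 1L]] <- c(iv, iu)
          if (length(pairs) >= maxCov) break
        }
      }
      if (length(pairs) >= maxCov) break
    }
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      covs <- data.frame(
        a = pm[, 1], b = pm[, 2],
        cov = vapply(seq_len(nrow(pm)), function(r)
          stats::cov(vals$bonds[pm[r, 1], ], vals$bonds[pm[r, 2], ]),
          numeric(1)))
    }
  }
  new("ReferenceObservables", instances = inst, byClass = byClass,
      covariances = covs, nFrames = dim(ensemble@frames)[3],
      scheme = scheme)
}

# pooled stats per generic role across all tetramer classes (excluding the
# distant set), and per distant offset
.genericPools <- function(obs) {
  inst <- obs@instances
  keys <- character(0); idx <- integer(0)
  for (r in seq_len(nrow(inst))) {
    ctx <- unique(inst$contexts[[r]])
    parts <- strsplit(ctx, "/", fixed = TRUE)
    g <- unique(vapply(parts, function(p)
      if (p[1] == "DIST") paste0("distant.", p[2]) else genericRole(p[2]),
      character(1)))
    keys <- c(keys, g); idx <- c(idx, rep(r, length(g)))
  }
  sp <- split(idx, keys)
  data.frame(role = names(sp),
             mean = vapply(sp, function(ii) mean(inst$mean[ii]), numeric(1)),
             var = vapply(sp, function(ii) mean(inst$var[ii]), numeric(1)),
             n = vapply(sp, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sequence-independent baseline fit
#'
#' Equilibrium values are set to the pooled reference means; force constants
#' come from the harmonic inversion `K2 = kB T / (2 Var)`; the cubic term
#' starts at zero and the quartic confinement at `k4Frac * K2` (kept small so
#' the harmonic inversion stays accurate while large distortions remain
#' penalized). Produces a library holding only the sequence-averaged `"AVG"`
#' class plus the distant-offset terms.
#'
#' @param obs A [ReferenceObservables-class] with nonzero variances.
#' @param temperature Reference temperature, K.
#' @param k4Frac Initial `K4 / K2` ratio.
#' @param remote Remote settings for the resulting library.
#' @param bounds List with `K2min`, `K2max` box constraints (kcal/mol/x^2).
#' @return A [ParameterLibrary-class].
#' @export
fitBaseline <- function(obs, temperature = 300, k4Frac = 0.1,
                        remote = remoteSettings(),
                        bounds = list(K2min = 1e-3, K2max = 100)) {
  stopifnot(is(obs, "ReferenceObservables"))
  pools <- .genericPools(obs)
  if (any(pools$var <= 0))
    stop("zero reference variance for role(s): ",
         paste(pools$role[pools$var <= 0], collapse = ", "))
  kbt <- kBoltzmann * temperature
  mkTerm <- function(m, v) {
    k2 <- min(max(kbt / (2 * v), bounds$K2min), bounds$K2max)
    bondedTerm(K2 = k2, K3 = 0, K4 = k4Frac * k2, x0 = m)
  }
  isDist <- grepl("^distant\\.", pools$role)
  avg <- list()
  for (r in which(!isDist))
    avg[[pools$role[r]]] <- mkTerm(pools$mean[r], pools$var[r])
  distant <- list()
  for (r in which(isDist))
    distant[[sub("^distant\\.", "", pools$role[r])]] <-
      mkTerm(pools$mean[r], pools$var[r])
  parameterLibrary(classes = list(AVG = avg), distant = distant,
                   remote = remote, scheme = obs@scheme,
                   meta = list(fit = "baseline", temperature = temperature))
}

# effective (K2, x0) of an instance given a candidate parameter set for one
# class and the current library for the others
.effTerm <- function(ctxs, cls, theta, lib) {
  k2 <- 0; x0 <- 0
  for (ctx in ctxs) {
    parts <- strsplit(ctx, "/", fixed = TRUE)[[1]]
    key <- if (parts[1] == "AVG") genericRole(parts[2]) else parts[2]
    if (parts[1] == cls && !is.null(theta[[key]])) {
      k2 <- k2 + theta[[key]][1]
      x0 <- x0 + theta[[key]][2]
    } else {
      trm <- lookupTerm(lib, ctx)
      k2 <- k2 + trm[1]
      x0 <- x0 + trm[4]
    }
  }
  c(k2 / length(ctxs), x0 / length(ctxs))
}

#' Iterative per-tetramer refinement
#'
#' Sweeps over the tetramer classes present in the reference; for each class
#' a box-constrained derivative-free-style optimizer (L-BFGS-B on the class's
#' force constants and equilibrium values) minimizes the squared relative
#' discrepancy between model-implied and reference means/variances of every
#' instance the class participates in, holding the other classes at their
#' current values. Sweeps repeat until the maximum relative parameter change
#' drops below `tol` (typically 3-4 sweeps).
#'
#' Model-implied observables default to the harmonic closed form
#' (`Var = kB T / (2 K2_eff)`, mean = `x0_eff`): fast and deterministic. The
#' `"simulation"` mode additionally runs a seeded Langevin simulation each
#' sweep and folds the measured variance ratios and mean shifts into the same
#' objective, so the refinement targets what the coupled spring network
#' actually realizes in simulation rather than the isolated-term value.
#'
#' @param lib Baseline [ParameterLibrary-class] (must contain `"AVG"`).
#' @param obs A [ReferenceObservables-class].
#' @param temperature Reference temperature, K.
#' @param mode `"harmonic"` (default) or `"simulation"`.
#' @param tol Convergence tolerance on the max relative parameter change.
#' @param maxSweeps Maximum number of sweeps.
#' @param bounds Box constraints: `K2min`, `K2max`, and `x0Rel` (allowed
#'   relative deviation of equilibrium values from the reference mean).
#' @param topology Required for `"simulation"` mode: the [BeadTopology-class]
#'   the observables came from.
#' @param simSettings [dynamicsSettings()] for `"simulation"` mode (a short
#'   seeded run per sweep).
#' @param seed Seed controlling the simulation-backed mode.
#' @return List with `lib` (refined [ParameterLibrary-class]) and `report`
#'   (a [FitReport-class]).
#' @export
refineTetramers <- function(lib, obs, temperature = 300,
                            mode = c("harmonic", "simulation"),
                            tol = 1e-2, maxSweeps = 5L,
                            bounds = list(K2min = 1e-3, K2max = 100,
                                          x0Rel = 0.5),
                            topology = NULL, simSettings = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(lib, "ParameterLibrary"), is(obs, "ReferenceObservables"))
  kbt <- kBoltzmann * temperature
  inst <- obs@instances
  allCls <- unique(vapply(strsplit(unlist(inst$contexts), "/", fixed = TRUE),
                          `[`, character(1), 1))
  classes <- sort(setdiff(allCls, c("AVG", "DIST")))
  if (length(classes) == 0) stop("no tetramer classes in the observables")
  # the sequence-averaged fallback (terminal instances) is refined too
  if ("AVG" %in% allCls) classes <- c(classes, "AVG")

  # initialize every class from the sequence-averaged parameters
  cur <- lib
  for (cls in classes) {
    if (is.null(cur@classes[[cls]])) {
      roles <- tetramerRoles(lib@scheme)
      trm <- lapply(roles, function(r) lookupTerm(lib, paste0("AVG/", r)))
      names(trm) <- roles
      cur@classes[[cls]] <- trm
    }
  }

  # per-class instance indices
  clsInst <- lapply(classes, function(cls)
    which(vapply(inst$contexts, function(ctx)
      any(startsWith(ctx, paste0(cls, "/"))), logical(1))))
  names(clsInst) <- classes

  # Simulation mode models each instance's marginal variance as
  # kB T / (2 (Knet + K2_eff)): the rest of the spring network contributes an
  # implicit stiffness Knet, estimated from a seeded simulation each sweep
  # (Knet = 0 recovers the harmonic closed form exactly).
  knet <- rep(0, nrow(inst))
  shift <- rep(0, nrow(inst))   # simulation-mode mean correction
  snapshots <- list()
  merits <- numeric(0)
  msgs <- character(0)
  converged <- FALSE
  sweep <- 0L

  paramVec <- function(l) unlist(lapply(classes, function(cls)
    vapply(l@classes[[cls]], function(t) t[c(1, 4)], numeric(2))))
  applyParamVec <- function(l, vec) {
    i <- 0L
    for (cls in classes) for (r in names(l@classes[[cls]])) {
      old <- l@classes[[cls]][[r]]
      k2 <- min(max(vec[i + 1L], bounds$K2min), bounds$K2max)
      l@classes[[cls]][[r]] <- bondedTerm(K2 = k2, K3 = old[2],
                                          K4 = min(old[3], k2),
                                          x0 = max(vec[i + 2L], 1e-3))
      i <- i + 2L
    }
    l
  }
  prevDelta <- NULL

  while (sweep < maxSweeps) {
    sweep <- sweep + 1L
    before <- paramVec(cur)

    if (mode == "simulation") {
      if (is.null(topology)) stop("simulation mode needs the topology")
      ss <- simSettings %||% dynamicsSettings(temperature = temperature,
                                              nSteps = 100000L,
                                              saveStride = 25L,
                                              logInterval = 0L)
      ss$seed <- as.integer(seed + sweep)
      ss$temperature <- temperature
      sim <- runSimulation(topology, cur, ss, remote = FALSE)
      keep <- seq.int(ceiling(dim(sim@frames)[3] * 0.25), dim(sim@frames)[3])
      simObs <- extractObservables(
        trajectoryEnsemble(sim@frames[, , keep, drop = FALSE], topology),
        scheme = obs@scheme)
      for (r in seq_len(nrow(inst))) {
        eff <- .effTerm(inst$contexts[[r]], "__none__", list(), cur)
        kn <- kbt / (2 * simObs@instances$var[r]) - eff[1]
        # mild smoothing: the implicit stiffness drifts systematically as the
        # whole network softens, so favor the fresh estimate
        knet[r] <- if (sweep == 1L) kn else 0.25 * knet[r] + 0.75 * kn
        shift[r] <- simObs@instances$mean[r] - eff[2]
      }
    }

    sweepMerit <- 0
    for (cls in classes) {
      ii <- clsInst[[cls]]
      roles <- names(cur@classes[[cls]])
      # only roles actually used by this class's instances (the AVG fallback
      # stores generic role keys)
      instKeys <- lapply(inst$contexts[ii], function(ctx) {
        parts <- strsplit(ctx, "/", fixed = TRUE)
        r <- vapply(parts[vapply(parts, `[`, character(1), 1) == cls],
                    `[`, character(1), 2)
        if (cls == "AVG") genericRole(r) else r
      })
      roles <- intersect(roles, unique(unlist(instKeys)))
      if (length(roles) == 0) next
      th0 <- unlist(lapply(roles, function(r)
        cur@classes[[cls]][[r]][c(1, 4)]))
      m0 <- vapply(roles, function(r) {
        jj <- ii[vapply(instKeys, function(k) r %in% k, logical(1))]
        mean(inst$mean[jj])
      }, numeric(1))
      lower <- as.numeric(rbind(bounds$K2min, pmax(m0 * (1 - bounds$x0Rel), 1e-3)))
      upper <- as.numeric(rbind(bounds$K2max,
                                ifelse(grepl("^angle", roles), pi,
                                       m0 * (1 + bounds$x0Rel))))
      # vectorized objective: per instance, effective terms are the mean of
      # this class's candidate values (ownMat counts role participations)
      # and the fixed partner contributions
      nI <- length(ii)
      ownMat <- matrix(0, nI, length(roles), dimnames = list(NULL, roles))
      partnerK2 <- partnerX0 <- numeric(nI)
      nctx <- numeric(nI)
      for (q in seq_len(nI)) {
        ctxs <- inst$contexts[[ii[q]]]
        nctx[q] <- length(ctxs)
        for (ctx in ctxs) {
          parts <- strsplit(ctx, "/", fixed = TRUE)[[1]]
          key <- if (parts[1] == "AVG") genericRole(parts[2]) else parts[2]
          if (parts[1] == cls && key %in% roles) {
            ownMat[q, key] <- ownMat[q, key] + 1
          } else {
            trm <- lookupTerm(lib = cur, ctx)
            partnerK2[q] <- partnerK2[q] + trm[1]
            partnerX0[q] <- partnerX0[q] + trm[4]
          }
        }
      }
      refMean <- inst$mean[ii]; refVar <- inst$var[ii]
      knI <- knet[ii]; shI <- shift[ii]
      mainObj <- function(par) {
        k2 <- par[c(TRUE, FALSE)]
        x0 <- par[c(FALSE, TRUE)]
        effK2 <- (as.numeric(ownMat %*% k2) + partnerK2) / nctx
        effX0 <- (as.numeric(ownMat %*% x0) + partnerX0) / nctx
        vm <- kbt / (2 * pmax(knI + effK2, 1e-4))
        mm <- effX0 + shI
        mean(((mm - refMean) / refMean)^2 + ((vm - refVar) / refVar)^2)
      }
      # small proximal term (scaled to the current misfit): the role split
      # within an averaged pair is only weakly identified, and without an
      # anchor the parameters slide along the degenerate direction between
      # sweeps; the relative scaling keeps it from blocking genuine moves
      proxW <- max(1e-3 * mainObj(th0), 1e-2) / length(th0)
      objective <- function(par) {
        mainObj(par) + proxW * sum(((par - th0) / pmax(abs(th0), 1e-6))^2)
      }
      fit <- tryCatch(
        stats::optim(th0, objective, method = "L-BFGS-B",
                     lower = pmin(lower, th0), upper = pmax(upper, th0),
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(fit)) {
        msgs <- c(msgs, sprintf("sweep %d: optimizer failed for class %s; previous values kept",
                                sweep, cls))
        next
      }
      theta <- split(fit$par, rep(seq_along(roles), each = 2))
      names(theta) <- roles
      for (r in roles) {
        old <- cur@classes[[cls]][[r]]
        k2 <- theta[[r]][1]
        cur@classes[[cls]][[r]] <- bondedTerm(
          K2 = k2, K3 = old[2],
          K4 = min(old[3], k2),     # keep K4 within [0, K2]
          x0 = theta[[r]][2])
      }
      sweepMerit <- sweepMerit + fit$value
    }
    after <- paramVec(cur)
    delta <- max(abs(after - before) / pmax(abs(before), 1e-8))
    snapshots[[sweep]] <- after
    merits <- c(merits, sweepMerit / length(classes))
    if (delta < tol) { converged <- TRUE; break }
    # the Gauss-Seidel coupling through shared instances contracts
    # geometrically; in the deterministic mode, extrapolate the dominant mode
    # to its fixed point once the contraction ratio is established (the next
    # sweep then verifies convergence)
    dk <- after - before
    if (mode == "harmonic" && !is.null(prevDelta)) {
      rho <- sqrt(sum(dk^2) / max(sum(prevDelta^2), 1e-300))
      if (rho > 0.05 && rho < 0.95) {
        cur <- applyParamVec(cur, after + dk * rho / (1 - rho))
        dk <- NULL                       # ratio no longer meaningful
      }
    }
    prevDelta <- dk
  }
  cur@meta$fit <- c(cur@meta$fit, sprintf("refineTetramers(%s)", mode))
  list(lib = cur,
       report = new("FitReport", snapshots = snapshots, merit = merits,
                    converged = converged, iterations = sweep,
                    messages = msgs))
}

#' Distant-term refinement against end-to-end statistics
#'
#' Re-adjusts the sequence-averaged distant fan terms by Metropolis annealing
#' (an effective-temperature ladder ramped up and back down, repeated over
#' several seeds) followed by a conjugate-gradient polish of the best
#' candidate. The merit function is the summed squared relative error of the
#' simulated duplex end-to-end mean and variance versus the targets; merit
#' evaluations use a fixed simulation seed (common random numbers) so the
#' polish sees a deterministic surface.
#'
#' @param lib [ParameterLibrary-class] with the seq-4mer terms already fixed.
#' @param target List with `mean` (A) and `var` (A^2) of the reference
#'   end-to-end distance (a 40-mer duplex in the standard protocol).
#' @param topology The [BeadTopology-class] of the duplex simulated in the
#'   merit.
#' @param anneal List: `nSeeds`, `ladder` (effective temperatures, up then
#'   down), `stepsPerTemp`, `proposalSd` (relative), `polishIter`.
#' @param simSettings [dynamicsSettings()] for the merit simulations.
#' @param seed Base seed (fixes the common-random-numbers simulation stream).
#' @param chainSeed Seed offset for the Metropolis proposal chains (defaults
#'   to `seed`; varying it reruns the annealing on the same merit surface).
#' @return List with `lib` and `report` (merit holds the best-so-far trace).
#' @export
refineDistant <- function(lib, target, topology,
                          anneal = list(nSeeds = 2L,
                                        ladder = c(1, 2, 4, 2, 1) * 1e-3,
                                        stepsPerTemp = 10L,
                                        proposalSd = 0.05,
                                        polishIter = 5L),
                          simSettings = dynamicsSettings(nSteps = 20000L,
                                                         saveStride = 20L,
                                                         logInterval = 0L),
                          seed = 1L, chainSeed = seed) {
  stopifnot(is(lib, "ParameterLibrary"), is(topology, "BeadTopology"))
  offs <- names(lib@distant)
  pack <- function(l) unlist(lapply(l@distant, function(t) t[c(1, 4)]))
  unpack <- function(l, par) {
    th <- split(par, rep(seq_along(offs), each = 2))
    for (k in seq_along(offs))
      l@distant[[offs[k]]] <- bondedTerm(K2 = max(th[[k]][1], 1e-4),
                                         K3 = l@distant[[offs[k]]][2],
                                         K4 = l@distant[[offs[k]]][3],
                                         x0 = max(th[[k]][2], 1e-2))
    l
  }
  merit <- function(par) {
    # common random numbers inside; the annealing proposal stream must not
    # be reset by the simulation seed, so the outer RNG state is preserved
    rng <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(rng))
      assign(".Random.seed", rng, envir = globalenv()))
    l <- unpack(lib, par)
    ss <- simSettings
    ss$seed <- as.integer(seed)           # common random numbers
    sim <- runSimulation(topology, l, ss, remote = FALSE)
    nf <- dim(sim@frames)[3]
    keep <- seq.int(ceiling(nf / 2), nf)
    ee <- endToEnd(trajectoryEnsemble(sim@frames[, , keep, drop = FALSE],
                                      topology))
    ((ee$mean - target$mean) / target$mean)^2 +
      ((ee$sd^2 - target$var) / target$var)^2
  }
  p0 <- pack(lib)
  m0 <- merit(p0)
  best <- p0; bestM <- m0
  trace <- bestM
  for (s in seq_len(anneal$nSeeds)) {
    set.seed(chainSeed + s)
    cur <- best; curM <- bestM
    for (effT in anneal$ladder) {
      for (it in seq_len(anneal$stepsPerTemp)) {
        prop <- cur * (1 + stats::rnorm(length(cur), 0, anneal$proposalSd))
        pm <- merit(prop)
        if (pm < curM || stats::runif(1) < exp((curM - pm) / effT)) {
          cur <- prop; curM <- pm
        }
        if (curM < bestM) { best <- cur; bestM <- curM }
        trace <- c(trace, bestM)
      }
    }
  }
  polished <- tryCatch(
    stats::optim(best, merit, method = "CG",
                 control = list(maxit = anneal$polishIter)),
    error = function(e) list(par = best, value = bestM))
  if (polished$value < bestM) { best <- polished$par; bestM <- polished$value }
  trace <- c(trace, bestM)
  msgs <- character(0)
  if (bestM >= m0 - 1e-12 && m0 > 1e-10) {
    msgs <- "merit did not improve over the annealing ladder; returning best-so-far"
    warning(msgs)
  }
  out <- unpack(lib, best)
  out@meta$fit <- c(out@meta$fit, "refineDistant")
  list(lib = out,
       report = new("FitReport", snapshots = list(best), merit = trace,
                    converged = bestM <= m0, iterations = length(trace),
                    messages = msgs))
}
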