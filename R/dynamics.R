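#' Langevin dynamics settings
#'
#' @param dt Integration step, ps (default 0.1).
#' @param temperature Bath temperature, K.
#' @param friction Langevin friction, 1/ps (default 1.0; the results are
#'   robust to small perturbations of this coupling).
#' @param seed Integer RNG seed; every stochastic element of a run derives
#'   from it.
#' @param nSteps Number of integration steps.
#' @param saveStride Save a frame every this many steps.
#' @param logInterval Record the energy channels every this many steps
#'   (0 disables logging).
#' @return Named settings list.
#' @export
dynamicsSettings <- function(dt = 0.1, temperature = 300, friction = 1.0,
                             seed = 1L, nSteps = 10000L, saveStride = 10L,
                             logInterval = 1000L) {
  stopifnot(dt > 0, temperature >= 0, friction >= 0, nSteps >= 0,
            saveStride >= 1)
  list(dt = dt, temperature = temperature, friction = friction,
       seed = as.integer(seed), nSteps = as.integer(nSteps),
       saveStride = as.integer(saveStride),
       logInterval = as.integer(logInterval))
}

#' Maxwell-Boltzmann velocities
#'
#' Draws per-component Gaussian velocities with variance `kB T / m` (in
#' A/ps, using the package unit conversion) and removes the center-of-mass
#' velocity.
#'
#' @param masses Per-bead masses, Da.
#' @param temperature Kelvin.
#' @param seed Optional seed (`set.seed` is called when given).
#' @return N x 3 velocity matrix, A/ps.
#' @export
initializeVelocities <- function(masses, temperature, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(masses)
  if (temperature <= 0) return(matrix(0, n, 3))
  sd <- sqrt(accUnit * kBoltzmann * temperature / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  vcom <- colSums(v * masses) / sum(masses)
  sweep(v, 2, vcom)
}

#' Instantaneous kinetic temperature
#'
#' @param velocities N x 3 matrix, A/ps.
#' @param masses Per-bead masses, Da.
#' @param dof Degrees of freedom (default `3N`; use `3N - 3` when the
#'   center-of-mass motion has been removed and is conserved).
#' @return Temperature, K.
#' @export
kineticTemperature <- function(velocities, masses, dof = 3 * length(masses)) {
  ke <- 0.5 * sum(masses * rowSums(velocities^2)) / accUnit
  2 * ke / (kBoltzmann * dof)
}

#' One Langevin step
#'
#' A single BAOAB Langevin velocity-Verlet update: deterministic drift from
#' the analytic forces, friction `-gamma v`, and Gaussian noise satisfying the
#' fluctuation-dissipation relation, with deviates produced by Box-Muller from
#' the seeded uniform stream. Exposed for inspection and testing; whole runs
#' go through [runSimulation()], which advances the same kernel without
#' per-step overhead.
#'
#' @param state List with `coords`, `velocities` (N x 3) and optionally
#'   `step`.
#' @param model Resolved model from [resolveParameters()] /[buildModel()].
#' @param settings From [dynamicsSettings()] (dt, temperature, friction).
#' @param remote Evaluate remote terms.
#' @return Updated state list.
#' @export
langevinStep <- function(state, model, settings, remote = TRUE) {
  topo <- model$topology
  coords <- checkCoords(state$coords, topo)
  res <- cpp_run_langevin(coords, state$velocities, topo@masses,
                          model$bonds, model$angles,
                          isTRUE(remote) && length(model$remote) > 0,
                          model$remote, topo@bpPos, topo@nbp, topo@circular,
                          settings$dt, settings$friction,
                          settings$temperature, 1L, 1L, 0L)
  list(coords = res$coords, velocities = res$velocities,
       step = (state$step %||% 0L) + 1L)
}

#' Run a Langevin dynamics simulation
#'
#' Velocity-Verlet integration with a Langevin bath (BAOAB splitting) at
#' `dt = 0.1` ps by default, which keeps trajectories stable for temperatures
#' up to 500 K. Identical seed and inputs give a bit-identical trajectory.
#'
#' @param topology A [BeadTopology-class].
#' @param lib A [ParameterLibrary-class].
#' @param settings From [dynamicsSettings()].
#' @param coords Starting N x 3 coordinates; default is the ideal B-DNA build
#'   ([idealBDNABeads()] for linear, [buildMinicircle()] geometry must be
#'   passed explicitly for circles).
#' @param velocities Starting velocities; default Maxwell-Boltzmann at the
#'   bath temperature.
#' @param remote Include remote (LJ + electrostatic) terms.
#' @return A [TrajectoryEnsemble-class] of `nSteps / saveStride + 1` frames
#'   (the initial frame included), with the energy-channel log and full run
#'   provenance attached.
#' @export
runSimulation <- function(topology, lib, settings = dynamicsSettings(),
                          coords = NULL, velocities = NULL, remote = TRUE) {
  stopifnot(is(topology, "BeadTopology"), is(lib, "ParameterLibrary"))
  tab <- enumerateInteractions(topology, lib@scheme)
  model <- resolveParameters(tab, lib)
  set.seed(settings$seed)
  if (is.null(coords)) {
    if (topology@circular)
      stop("supply starting coordinates for circular topologies (buildMinicircle)")
    coords <- idealBDNABeads(topology)
  }
  coords <- checkCoords(coords, topology)
  if (is.null(velocities))
    velocities <- initializeVelocities(topology@masses, settings$temperature)
  res <- cpp_run_langevin(coords, velocities, topology@masses,
                          model$bonds, model$angles,
                          isTRUE(remote) && length(model$remote) > 0,
                          model$remote, topology@bpPos, topology@nbp,
                          topology@circular,
                          settings$dt, settings$friction,
                          settings$temperature, settings$nSteps,
                          settings$saveStride, settings$logInterval)
  new("TrajectoryEnsemble",
      frames = res$frames, times = res$times, topology = topology,
      provenance = list(generator = "runSimulation",
                        settings = settings,
                        seed = settings$seed,
                        remote = isTRUE(remote),
                        energyLog = res$energyLog,
                        finalVelocities = res$velocities,
                        package = as.character(utils::packageVersion("cgdna"))))
}

#' Construct a TrajectoryEnsemble
#'
#' @param frames Array `c(nBeads, 3, nFrames)` or a single N x 3 matrix.
#' @param topology The matching [BeadTopology-class].
#' @param times Frame times (ps); defaults to 0-based unit spacing.
#' @param provenance Optional provenance list.
#' @return A [TrajectoryEnsemble-class].
#' @export
trajectoryEnsemble <- function(frames, topology, times = NULL,
                               provenance = list()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (is.null(times)) times <- seq_len(dim(frames)[3]) - 1
  new("TrajectoryEnsemble", frames = frames, times = as.numeric(times),
      topology = topology, provenance = provenance)
}
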