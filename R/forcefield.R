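#' Bonded term energy
#'
#' The truncated polynomial potential `E(x) = sum_{a=2..4} K_a (x - x0)^a`
#' used for stacking, pairing, fan and angle interactions. The quadratic term
#' sets the basal harmonicity, the cubic modulates it and the quartic confines
#' large distortions.
#'
#' @param x Observed distance (A) or angle (rad); vectorized.
#' @param term A term from [bondedTerm()] (`c(K2, K3, K4, x0)`).
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' bondedEnergy(7, bondedTerm(K2 = 1, x0 = 5))  # pure harmonic: 4
bondedEnergy <- function(x, term) {
  d <- x - term[[4]]
  d^2 * (term[[1]] + d * (term[[2]] + d * term[[3]]))
}

# Coordinates as an N x 3 matrix, validated against a topology.
checkCoords <- function(coords, topology) {
  if (!is.matrix(coords) || ncol(coords) != 3L)
    stop("coordinates must be an N x 3 matrix")
  if (nrow(coords) != 2L * topology@nbp)
    stop(sprintf("coordinate count %d does not match topology (%d beads)",
                 nrow(coords), 2L * topology@nbp))
  storage.mode(coords) <- "double"
  coords
}

#' Full energy breakdown
#'
#' Evaluates every channel of the Hamiltonian: the sequential tetramer terms
#' (stacking, pairing, angle, fan), the sequence-averaged distant terms, and
#' (optionally) the remote Lennard-Jones and screened-electrostatic terms with
#' the 5-bp exclusion.
#'
#' @param coords N x 3 bead coordinates (A).
#' @param model Resolved model from [resolveParameters()].
#' @param remote Evaluate the remote channels (default TRUE).
#' @param remoteMethod "direct" (O(N^2) loop) or "list" (Verlet neighbor
#'   list); both give identical cutoffed energies.
#' @return List with `channels` (named vector: stacking, pairing, fan,
#'   distant, angle, LJ, electrostatic, kcal/mol) and `total` (their sum).
#' @export
energyBreakdown <- function(coords, model, remote = TRUE,
                            remoteMethod = "direct") {
  topo <- model$topology
  coords <- checkCoords(coords, topo)
  res <- cpp_energy_forces(coords, model$bonds, model$angles,
                           isTRUE(remote) && length(model$remote) > 0,
                           model$remote, topo@bpPos, topo@nbp,
                           topo@circular, remoteMethod)
  list(channels = res$energies, total = res$total)
}

#' Sequential (bonded) energy channels
#'
#' The sequential contribution only: per-channel totals equal the sum of
#' [bondedEnergy()] over the instance lists; the distant channel covers the
#' sequence-averaged fan offsets.
#'
#' @inheritParams energyBreakdown
#' @return As [energyBreakdown()], with remote channels zero.
#' @export
sequentialEnergy <- function(coords, model) {
  energyBreakdown(coords, model, remote = FALSE)
}

#' Remote (non-bonded) energy
#'
#' 12-6 Lennard-Jones plus Debye-Hueckel screened Coulomb over all
#' non-excluded bead pairs within the cutoff:
#' `E_LJ = sum 4 epsLJ ((sigma/r)^12 - (sigma/r)^6)` and
#' `E_ele = sum C q^2 exp(-kappa r) / (eps_r r)` with C the Coulomb constant
#' in kcal*A/(mol*e^2).
#'
#' @param coords N x 3 coordinates (A).
#' @param settings Remote settings from [remoteSettings()].
#' @param topology Optional [BeadTopology-class] supplying the 5-bp exclusion;
#'   with `NULL`, no pair is excluded.
#' @param method "direct" or "list" (neighbor-list accelerated).
#' @return List with `channels` (LJ, electrostatic) and `total`.
#' @export
remoteEnergy <- function(coords, settings, topology = NULL,
                         method = "direct") {
  if (!is.matrix(coords) || ncol(coords) != 3L)
    stop("coordinates must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (is.null(topology)) {
    bpPos <- as.integer(seq_len(n) * 1000L)
    nbp <- n; circ <- FALSE
  } else {
    coords <- checkCoords(coords, topology)
    bpPos <- topology@bpPos; nbp <- topology@nbp; circ <- topology@circular
  }
  noBonds <- matrix(numeric(0), 0, 7)
  noAng <- matrix(numeric(0), 0, 7)
  res <- cpp_energy_forces(coords, noBonds, noAng, TRUE, settings,
                           bpPos, nbp, circ, method)
  list(channels = res$energies[c("LJ", "electrostatic")], total = res$total)
}

#' Total forces
#'
#' Analytic gradient of the full Hamiltonian: returns `-dE/dx` for every bead,
#' all channels summed. Deterministic for fixed input.
#'
#' @inheritParams energyBreakdown
#' @return N x 3 force matrix (kcal/mol/A) with the energy breakdown attached
#'   as attributes `channels` and `total`.
#' @export
totalForces <- function(coords, model, remote = TRUE) {
  topo <- model$topology
  coords <- checkCoords(coords, topo)
  res <- cpp_energy_forces(coords, model$bonds, model$angles,
                           isTRUE(remote) && length(model$remote) > 0,
                           model$remote, topo@bpPos, topo@nbp,
                           topo@circular, "direct")
  fr <- res$forces
  attr(fr, "channels") <- res$energies
  attr(fr, "total") <- res$total
  fr
}

#' Resolve a sequence + library into an evaluable model
#'
#' Convenience wrapper: topology, interaction enumeration and parameter
#' resolution in one call.
#'
#' @param seq A [DuplexSequence-class] (or string).
#' @param lib A [ParameterLibrary-class].
#' @param fallback Passed to [resolveParameters()].
#' @return A resolved model list (see [resolveParameters()]).
#' @export
buildModel <- function(seq, lib, fallback = TRUE) {
  topo <- buildDuplexTopology(seq)
  tab <- enumerateInteractions(topo, lib@scheme)
  resolveParameters(tab, lib, fallback = fallback)
}
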