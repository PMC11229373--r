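#' @import methods
NULL

#' DuplexSequence: a double-stranded DNA sequence
#'
#' Holds the Watson strand (5'->3') of a B-DNA duplex; the Crick strand is
#' always derived as the reverse complement and never stored independently.
#'
#' @slot watson Character scalar over A/C/G/T, the Watson strand 5'->3'.
#' @slot circular Logical; closed (minicircle) duplexes wrap their ends.
#' @export
setClass("DuplexSequence",
         representation(watson = "character", circular = "logical"))

setValidity("DuplexSequence", function(object) {
  s <- object@watson
  if (length(s) != 1L) return("watson must be a single string")
  bad <- which(!strsplit(s, "")[[1]] %in% DNA_BASES)
  if (length(bad) > 0L)
    return(sprintf("invalid character at position %d (allowed: A, C, G, T)",
                   bad[1]))
  n <- nchar(s)
  if (isTRUE(object@circular) && n < 12L)
    return(sprintf("circular duplex needs >= 12 bp, got %d", n))
  if (!isTRUE(object@circular) && n < 4L)
    return(sprintf("linear duplex needs >= 4 bp, got %d", n))
  TRUE
})

#' BeadTopology: one bead per nucleotide
#'
#' The bead representation of a duplex: 2 beads per base pair, one per strand,
#' anchored at the C1' sugar positions. Beads `1..n` are the Watson strand at
#' base-pair positions `1..n` (5'->3'); beads `n+1..2n` are the Crick strand
#' stored by the base-pair position they pair with, so bead `n + p` is the
#' Watson-Crick partner of bead `p`. Crick strand position `q` (5'->3' along
#' Crick) corresponds to base-pair position `n + 1 - q`.
#'
#' @slot nbp Number of base pairs.
#' @slot circular Logical topology flag.
#' @slot watson,crick Character vectors of bases, base-pair indexed (crick[p]
#'   is the base paired with watson[p]).
#' @slot masses Numeric vector, Da, one per bead (length 2*nbp).
#' @slot strand Integer per bead: 1 Watson, 2 Crick.
#' @slot bpPos Integer per bead: base-pair position.
#' @slot pairedBead Integer per bead: the Watson-Crick partner bead id.
#' @export
setClass("BeadTopology",
         representation(nbp = "integer", circular = "logical",
                        watson = "character", crick = "character",
                        masses = "numeric", strand = "integer",
                        bpPos = "integer", pairedBead = "integer"))

setValidity("BeadTopology", function(object) {
  n <- object@nbp
  nb <- 2L * n
  if (length(object@masses) != nb) return("need one mass per bead")
  if (length(object@pairedBead) != nb) return("pairing map length mismatch")
  if (!identical(object@pairedBead[object@pairedBead], seq_len(nb)))
    return("pairing map must be an involution")
  if (any(object@masses <= 0)) return("masses must be positive")
  TRUE
})

#' InteractionTable: every interaction instance of the Hamiltonian
#'
#' Typed lists of interaction instances enumerated from a topology under an
#' accounting scheme. Distance-type instances (stacking, pairing, fan,
#' distant) live in `bonds`; angle triplets in `angles`. Each instance carries
#' the tetramer-context labels ("CLASS/role") used for parameter lookup;
#' instances shared by two tetramer windows carry both labels.
#'
#' @slot bonds data.frame: kind, i, j, offset, contexts (list column).
#' @slot angles data.frame: i, j, k (vertex j), contexts (list column).
#' @slot scheme Accounting scheme id ("eq5" or "fig1").
#' @slot topology The BeadTopology the table was enumerated from.
#' @export
setClass("InteractionTable",
         representation(bonds = "data.frame", angles = "data.frame",
                        scheme = "character", topology = "BeadTopology"))

#' ParameterLibrary: tetramer-class and sequence-averaged parameters
#'
#' Bonded parameters are stored per canonical tetramer class (four consecutive
#' Watson bases 5'->3', reduced by reverse-complement symmetry to the
#' lexicographically smaller representative) and per role within the tetramer
#' window: 2 stacking, 2 pairing, 4 angle and 8 fan terms. The reserved class
#' `"AVG"` holds the sequence-averaged set used as terminal fallback and as the
#' sequence-independent baseline. Each term is a numeric vector
#' `c(K2, K3, K4, x0)` (kcal/mol/A^a and A for distances; kcal/mol/rad^a and
#' rad for angles). `distant` holds sequence-averaged fan terms keyed by signed
#' offset; `remote` the Lennard-Jones / screened-electrostatics settings.
#'
#' @slot classes Named list: class -> named list of role -> c(K2, K3, K4, x0).
#' @slot distant Named list: signed offset (character) -> c(K2, K3, K4, x0).
#' @slot remote List: q, sigma, epsLJ, epsR, kappa, cutoff (see
#'   [remoteSettings()]).
#' @slot scheme Accounting scheme the library was built for.
#' @slot meta Provenance list (units, how the set was obtained).
#' @export
setClass("ParameterLibrary",
         representation(classes = "list", distant = "list", remote = "list",
                        scheme = "character", meta = "list"))

setValidity("ParameterLibrary", function(object) {
  for (cl in names(object@classes)) {
    trm <- object@classes[[cl]]
    for (r in names(trm)) {
      v <- trm[[r]]
      if (length(v) != 4L) return(sprintf("term %s/%s must be c(K2,K3,K4,x0)", cl, r))
      if (!is.finite(v[1]) || v[1] <= 0) return(sprintf("K2 must be > 0 in %s/%s", cl, r))
      if (!is.finite(v[3]) || v[3] < 0) return(sprintf("K4 must be >= 0 in %s/%s", cl, r))
    }
  }
  rs <- object@remote
  if (length(rs) > 0) {
    if (rs$sigma <= 0) return("remote sigma must be > 0")
    if (rs$epsLJ < 0) return("remote epsLJ must be >= 0")
    if (rs$kappa < 0) return("remote kappa must be >= 0")
    if (rs$cutoff <= rs$sigma) return("remote cutoff must exceed sigma")
  }
  TRUE
})

#' TrajectoryEnsemble: ordered frames of bead coordinates
#'
#' @slot frames Numeric array `c(nBeads, 3, nFrames)`, Angstrom.
#' @slot times Numeric vector of frame times (ps).
#' @slot topology The BeadTopology the frames belong to.
#' @slot provenance List: generator, settings, seed, package version, and for
#'   dynamics runs the energy-channel log.
#' @export
setClass("TrajectoryEnsemble",
         representation(frames = "array", times = "numeric",
                        topology = "BeadTopology", provenance = "list"))

setValidity("TrajectoryEnsemble", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[2] != 3L) return("frames must be nBeads x 3 x nFrames")
  if (d[1] != 2L * object@topology@nbp) return("frame shape does not match topology")
  if (length(object@times) != d[3]) return("one time per frame required")
  if (!all(is.finite(object@frames))) return("non-finite coordinates")
  TRUE
})

#' ReferenceObservables: per-interaction statistics of a reference ensemble
#'
#' @slot instances data.frame with per-instance kind, bead ids, mean, var and
#'   the context labels.
#' @slot byClass data.frame of multiplicity-weighted pooled mean/var per
#'   (class, role).
#' @slot covariances data.frame of selected covariances between instances that
#'   share a bead.
#' @slot nFrames Number of frames the statistics were computed from.
#' @slot scheme Accounting scheme used for the enumeration.
#' @export
setClass("ReferenceObservables",
         representation(instances = "data.frame", byClass = "data.frame",
                        covariances = "data.frame", nFrames = "integer",
                        scheme = "character"))

#' FitReport: record of an iterative parameter refinement
#'
#' @slot snapshots List of per-sweep parameter snapshots.
#' @slot merit Numeric vector of merit values (best-so-far for annealing).
#' @slot converged Logical convergence flag.
#' @slot iterations Number of sweeps / accepted steps performed.
#' @slot messages Character vector of per-class warnings.
#' @export
setClass("FitReport",
         representation(snapshots = "list", merit = "numeric",
                        converged = "logical", iterations = "integer",
                        messages = "character"))

#' BackmapModel: trained bead-to-atom regression model
#'
#' Two-stage window regression: a sequence-neutral backbone stage (one linear
#' map per sliding window from locally superposed bead coordinates to backbone
#' heavy atoms) and a base-pair-class stage (A.T/T.A and G.C/C.G) from sugar
#' anchor atoms to base heavy atoms. Local-frame conventions are stored with
#' the model so reconstruction is rigid-motion equivariant.
#'
#' @slot window Window size in base pairs (default training uses 10).
#' @slot backbone List of per-window fits (reference bead frame + coefficient
#'   matrix).
#' @slot bases List of per-class fits keyed "AT" and "GC".
#' @slot meta Training metadata (sequence, frame convention, sizes).
#' @export
setClass("BackmapModel",
         representation(window = "integer", backbone = "list",
                        bases = "list", meta = "list"))

#' AtomisticStructure: heavy-atom structure(s) of a duplex
#'
#' @slot atoms data.frame: residue index, strand (1 Watson / 2 Crick), base,
#'   base-pair position, atom name.
#' @slot xyz Numeric array `c(nAtoms, 3, nFrames)`, Angstrom.
#' @slot sequence The DuplexSequence the structure realizes.
#' @slot provenance List (generator, any clash-relaxation record).
#' @export
setClass("AtomisticStructure",
         representation(atoms = "data.frame", xyz = "array",
                        sequence = "DuplexSequence", provenance = "list"))

setValidity("AtomisticStructure", function(object) {
  d <- dim(object@xyz)
  if (length(d) != 3L || d[2] != 3L) return("xyz must be nAtoms x 3 x nFrames")
  if (d[1] != nrow(object@atoms)) return("atom table does not match coordinates")
  TRUE
})
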