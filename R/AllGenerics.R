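# Accessor generics shared across container classes.

#' Number of base pairs
#' @param x A DuplexSequence, BeadTopology or TrajectoryEnsemble.
#' @return Integer base-pair count.
#' @export
setGeneric("nbp", function(x) standardGeneric("nbp"))

#' Circular-topology flag
#' @param x A DuplexSequence, BeadTopology or TrajectoryEnsemble.
#' @return Logical.
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' Frame array of an ensemble
#' @param x A TrajectoryEnsemble or AtomisticStructure.
#' @return Numeric array `c(n, 3, nFrames)`.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Number of frames
#' @param x A TrajectoryEnsemble or AtomisticStructure.
#' @return Integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
#' @describeIn nbp base-pair count of a sequence
setMethod("nbp", "DuplexSequence", function(x) nchar(x@watson))
#' @export
#' @describeIn nbp base-pair count of a topology
setMethod("nbp", "BeadTopology", function(x) x@nbp)
#' @export
#' @describeIn nbp base-pair count of an ensemble's topology
setMethod("nbp", "TrajectoryEnsemble", function(x) x@topology@nbp)

#' @export
#' @describeIn isCircular flag of a sequence
setMethod("isCircular", "DuplexSequence", function(x) x@circular)
#' @export
#' @describeIn isCircular flag of a topology
setMethod("isCircular", "BeadTopology", function(x) x@circular)
#' @export
#' @describeIn isCircular flag of an ensemble's topology
setMethod("isCircular", "TrajectoryEnsemble", function(x) x@topology@circular)

#' @export
#' @describeIn frames frames of a bead ensemble
setMethod("frames", "TrajectoryEnsemble", function(x) x@frames)
#' @export
#' @describeIn frames frames of an atomistic structure
setMethod("frames", "AtomisticStructure", function(x) x@xyz)

#' @export
#' @describeIn nFrames frame count of a bead ensemble
setMethod("nFrames", "TrajectoryEnsemble", function(x) dim(x@frames)[3])
#' @export
#' @describeIn nFrames frame count of an atomistic structure
setMethod("nFrames", "AtomisticStructure", function(x) dim(x@xyz)[3])

setMethod("show", "DuplexSequence", function(object) {
  n <- nchar(object@watson)
  s <- if (n > 40) paste0(substr(object@watson, 1, 37), "...") else object@watson
  cat(sprintf("DuplexSequence: %d bp, %s\n  5'-%s-3'\n",
              n, if (object@circular) "circular" else "linear", s))
})

setMethod("show", "BeadTopology", function(object) {
  cat(sprintf("BeadTopology: %d bp (%d beads), %s\n", object@nbp,
              2L * object@nbp, if (object@circular) "circular" else "linear"))
})

setMethod("show", "InteractionTable", function(object) {
  kinds <- table(object@bonds$kind)
  cat(sprintf("InteractionTable (scheme '%s'): %s; %d angle triplets\n",
              object@scheme,
              paste(sprintf("%d %s", as.integer(kinds), names(kinds)),
                    collapse = ", "),
              nrow(object@angles)))
})

setMethod("show", "ParameterLibrary", function(object) {
  ncl <- sum(names(object@classes) != "AVG")
  cat(sprintf(
    "ParameterLibrary (scheme '%s'): %d tetramer classes%s, %d distant offsets\n",
    object@scheme, ncl,
    if ("AVG" %in% names(object@classes)) " + AVG fallback" else "",
    length(object@distant)))
  if (length(object@remote))
    cat(sprintf("  remote: sigma %.3g A, epsLJ %.3g kcal/mol, kappa %.3g 1/A, cutoff %.3g A\n",
                object@remote$sigma, object@remote$epsLJ, object@remote$kappa,
                object@remote$cutoff))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  d <- dim(object@frames)
  cat(sprintf("TrajectoryEnsemble: %d frames of %d beads (%d bp, %s)\n",
              d[3], d[1], object@topology@nbp,
              if (object@topology@circular) "circular" else "linear"))
  if (!is.null(object@provenance$generator))
    cat(sprintf("  generator: %s\n", object@provenance$generator))
})

setMethod("show", "ReferenceObservables", function(object) {
  cat(sprintf("ReferenceObservables: %d instances from %d frames (%d class/role groups)\n",
              nrow(object@instances), object@nFrames, nrow(object@byClass)))
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport: %d iterations, %s (final merit %.4g)\n",
              object@iterations,
              if (isTRUE(object@converged)) "converged" else "not converged",
              if (length(object@merit)) object@merit[length(object@merit)] else NA))
})

setMethod("show", "BackmapModel", function(object) {
  cat(sprintf("BackmapModel: window %d bp, %d backbone window fits, base classes: %s\n",
              object@window, length(object@backbone),
              paste(names(object@bases), collapse = ", ")))
})

setMethod("show", "AtomisticStructure", function(object) {
  d <- dim(object@xyz)
  cat(sprintf("AtomisticStructure: %d heavy atoms, %d frames (%d bp)\n",
              d[1], d[3], nchar(object@sequence@watson)))
})
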