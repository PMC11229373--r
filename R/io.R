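# Format readers/writers shared by all modules. Bead PDB dialect: one
# pseudo-atom (C1') per nucleotide, chain A = Watson 5'->3', chain B =
# Crick 5'->3', residue names DA/DC/DG/DT, MODEL/ENDMDL per frame,
# coordinates at the standard 3-decimal PDB precision. XYZ keeps full double
# precision. Every artifact carries a provenance REMARK/comment.

#' Read a duplex sequence
#'
#' @param x A single-record FASTA file path or a literal sequence string;
#'   lowercase is normalized to uppercase.
#' @param circular Circularity flag (never inferred from the input).
#' @return A [DuplexSequence-class].
#' @export
readSequence <- function(x, circular = FALSE) {
  if (length(x) == 1L && file.exists(x) && !grepl("^[ACGTacgt]+$", x)) {
    set <- Biostrings::readDNAStringSet(x)
    if (length(set) != 1L)
      stop(sprintf("FASTA file has %d records; exactly 1 is required",
                   length(set)))
    return(duplexSequence(as.character(set[[1]]), circular = circular))
  }
  duplexSequence(x, circular = circular)
}

#' Write a duplex sequence as FASTA
#'
#' @param seq A [DuplexSequence-class].
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
writeSequence <- function(seq, path, name = "duplex") {
  s <- Biostrings::DNAStringSet(seq@watson)
  names(s) <- name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

.provenanceLines <- function(provenance) {
  seed <- provenance$seed %||% NA
  sprintf("generated by cgdna %s; seed %s",
          as.character(utils::packageVersion("cgdna")), seed)
}

#' Write a bead trajectory as multi-model PDB
#'
#' @param ensemble A [TrajectoryEnsemble-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(ensemble, path) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  topo <- ensemble@topology
  n <- topo@nbp
  # file order: chain A beads 1..n; chain B in Crick 5'->3' order
  beadOrder <- c(seq_len(n), n + rev(seq_len(n)))
  resid <- paste0("D", c(topo@watson, rev(topo@crick)))
  chain <- rep(c("A", "B"), each = n)
  resno <- c(seq_len(n), n + seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 %s", .provenanceLines(ensemble@provenance)),
             con)
  nf <- dim(ensemble@frames)[3]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- ensemble@frames[beadOrder, , f]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(2L * n), "C1'", resid, chain, resno,
      x[, 1], x[, 2], x[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a bead trajectory from multi-model PDB
#'
#' Accepts only the package's bead dialect (one C1' pseudo-atom per
#' nucleotide, chains A/B, DA/DC/DG/DT residues); a foreign PDB is rejected
#' with the first offending atom record.
#'
#' @param path PDB file path.
#' @param circular Circularity flag for the resulting topology.
#' @return A [TrajectoryEnsemble-class].
#' @export
readTrajectoryPDB <- function(path, circular = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  bad <- which(at$elety != "C1'" | !(at$resid %in% c("DA", "DC", "DG", "DT")) |
               !(at$chain %in% c("A", "B")))
  if (length(bad) > 0L)
    stop(sprintf(
      "unexpected atom record %d (name '%s', residue '%s', chain '%s'); expected C1' beads of DA/DC/DG/DT on chains A/B",
      bad[1], at$elety[bad[1]], at$resid[bad[1]], at$chain[bad[1]]))
  n <- sum(at$chain == "A")
  if (sum(at$chain == "B") != n)
    stop("chains A and B have different lengths")
  watson <- sub("^D", "", at$resid[at$chain == "A"][order(at$resno[at$chain == "A"])])
  seq <- duplexSequence(paste(watson, collapse = ""), circular = circular)
  topo <- buildDuplexTopology(seq)
  nf <- nrow(pdb$xyz)
  frames <- array(0, c(2L * n, 3, nf))
  beadOrder <- c(seq_len(n), n + rev(seq_len(n)))  # file order -> bead id
  for (f in seq_len(nf)) {
    x <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    frames[beadOrder, , f] <- x
  }
  new("TrajectoryEnsemble", frames = frames,
      times = as.numeric(seq_len(nf) - 1), topology = topo,
      provenance = list(generator = "readTrajectoryPDB", path = path))
}

#' Write an atomistic structure as multi-model PDB
#'
#' @param struct An [AtomisticStructure-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAtomisticPDB <- function(struct, path) {
  stopifnot(is(struct, "AtomisticStructure"))
  at <- struct@atoms
  chain <- ifelse(at$strand == 1L, "A", "B")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 %s", .provenanceLines(struct@provenance)),
             con)
  if (!is.null(struct@provenance$relaxation))
    writeLines("REMARK   6 clash relaxation: soft-sphere repulsion (not a force-field minimization)",
               con)
  nf <- dim(struct@xyz)[3]
  fmtName <- ifelse(nchar(at$atom) < 4L, paste0(" ", at$atom), at$atom)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- struct@xyz[, , f]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(at)) %% 100000L, fmtName, paste0("D", at$base), chain,
      at$res, x[, 1], x[, 2], x[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a bead trajectory as XYZ
#'
#' Plain XYZ dialect at full double precision: per frame an atom-count line,
#' a comment line with time and provenance, then `label x y z` rows (labels
#' are the base letters, Watson beads 1..n then Crick beads by bp position).
#'
#' @param ensemble A [TrajectoryEnsemble-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryXYZ <- function(ensemble, path) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  topo <- ensemble@topology
  labels <- c(topo@watson, topo@crick)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(ensemble@frames)[3]
  for (f in seq_len(nf)) {
    writeLines(as.character(2L * topo@nbp), con)
    writeLines(sprintf("t= %.17g circular= %d %s", ensemble@times[f],
                       as.integer(topo@circular),
                       .provenanceLines(ensemble@provenance)), con)
    x <- ensemble@frames[, , f]
    writeLines(sprintf("%s %.17g %.17g %.17g", labels, x[, 1], x[, 2], x[, 3]),
               con)
  }
  invisible(path)
}

#' Read a bead trajectory from XYZ
#'
#' @param path XYZ file written by [writeTrajectoryXYZ()].
#' @return A [TrajectoryEnsemble-class].
#' @export
readTrajectoryXYZ <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); times <- numeric(0)
  watson <- NULL; circular <- FALSE
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    nAt <- as.integer(trimws(lines[pos]))
    cm <- lines[pos + 1L]
    tm <- as.numeric(sub("^t= ([^ ]+).*", "\\1", cm))
    circular <- grepl("circular= 1", cm)
    block <- lines[pos + 1L + seq_len(nAt)]
    parts <- strsplit(trimws(block), "\\s+")
    lab <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(watson)) watson <- lab[seq_len(nAt / 2L)]
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, tm)
    pos <- pos + 2L + nAt
  }
  seq <- duplexSequence(paste(watson, collapse = ""), circular = circular)
  topo <- buildDuplexTopology(seq)
  arr <- array(unlist(frames), c(2L * topo@nbp, 3, length(frames)))
  new("TrajectoryEnsemble", frames = arr, times = times, topology = topo,
      provenance = list(generator = "readTrajectoryXYZ", path = path))
}

#' Write a restart file
#'
#' JSON restart with coordinates, velocities, step counter and the full R
#' RNG state, so a run is bit-reproducibly continuable.
#'
#' @param state List with `coords`, `velocities`, `step` (as returned in a
#'   run's provenance or from [langevinStep()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRestart <- function(state, path) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(format = "cgdna-restart", version = 1L,
              step = state$step %||% 0L,
              coords = as.numeric(state$coords),
              dim = dim(state$coords),
              velocities = as.numeric(state$velocities),
              rngState = rng)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a restart file
#'
#' Restores the RNG state as a side effect.
#'
#' @param path Path written by [writeRestart()].
#' @return State list with `coords`, `velocities`, `step`.
#' @export
readRestart <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cgdna-restart"))
    stop(sprintf("%s is not a cgdna restart file", path))
  if (!is.null(obj$rngState))
    assign(".Random.seed", as.integer(obj$rngState), envir = globalenv())
  list(coords = matrix(obj$coords, obj$dim[1], obj$dim[2]),
       velocities = matrix(obj$velocities, obj$dim[1], obj$dim[2]),
       step = obj$step)
}
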