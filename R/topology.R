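#' Create a DuplexSequence
#'
#' @param watson Watson strand 5'->3' (string over A/C/G/T; lowercase
#'   accepted).
#' @param circular Logical; TRUE for closed (minicircle) duplexes. Circularity
#'   is always an explicit flag, never inferred from the sequence.
#' @return A [DuplexSequence-class] object.
#' @export
#' @examples
#' duplexSequence("ACGTACGT")
duplexSequence <- function(watson, circular = FALSE) {
  new("DuplexSequence", watson = toupper(watson), circular = isTRUE(circular))
}

#' Crick strand of a duplex
#'
#' @param x A DuplexSequence.
#' @return The Crick strand 5'->3' (reverse complement of the Watson strand).
#' @export
crickStrand <- function(x) {
  stopifnot(is(x, "DuplexSequence"))
  revcompChars(x@watson)
}

#' Build the bead topology of a duplex
#'
#' One bead per nucleotide, anchored at the C1' position, 2 beads per base
#' pair. Watson position p pairs with Crick strand position `n + 1 - p`
#' (reverse-complement pairing). Bead masses default to the nucleotide masses.
#'
#' @param seq A [DuplexSequence-class] (or a string, converted with default
#'   linear topology).
#' @param masses Named numeric table of per-base masses in Da (names A, C, G,
#'   T); defaults to [defaultMasses()].
#' @return A [BeadTopology-class] with `2 * nbp` beads.
#' @export
#' @examples
#' topo <- buildDuplexTopology(duplexSequence("ACGT"))
#' nbp(topo)
buildDuplexTopology <- function(seq, masses = defaultMasses()) {
  if (is.character(seq)) seq <- duplexSequence(seq)
  stopifnot(is(seq, "DuplexSequence"))
  if (!all(DNA_BASES %in% names(masses)))
    stop("mass table must name all of A, C, G, T")
  w <- strsplit(seq@watson, "")[[1]]
  n <- length(w)
  cr <- DNA_COMPLEMENT[w]                 # base paired with watson[p], bp-indexed
  beads <- 2L * n
  new("BeadTopology",
      nbp = n, circular = seq@circular,
      watson = unname(w), crick = unname(cr),
      masses = unname(c(masses[w], masses[cr])),
      strand = rep(1:2, each = n),
      bpPos = rep(seq_len(n), 2L),
      pairedBead = c(seq_len(n) + n, seq_len(n)))
}

#' Bead index lookup
#'
#' Maps (strand, position) to a bead id. For the Crick strand, `position` is
#' the strand's own 5'->3' position, which corresponds to base-pair position
#' `n + 1 - position`.
#'
#' @param topology A BeadTopology.
#' @param strand 1 for Watson, 2 for Crick.
#' @param position Position along the given strand, 5'->3'.
#' @return Integer bead id(s).
#' @export
beadIndex <- function(topology, strand, position) {
  n <- topology@nbp
  stopifnot(all(position >= 1L), all(position <= n))
  ifelse(strand == 1L, position, n + (n + 1L - position))
}

# ---- tetramer bookkeeping ----------------------------------------------

#' Canonical tetramer class
#'
#' A tetramer is labelled by its four consecutive Watson bases 5'->3';
#' reverse-complement symmetry is reduced by taking the lexicographically
#' smaller of the tetramer and its reverse complement.
#'
#' @param tet Character vector of 4-letter tetramer strings.
#' @return data.frame with `class` (canonical label) and `flipped` (TRUE when
#'   the canonical representative is the reverse complement, in which case
#'   Watson/Crick roles within the window are exchanged).
#' @export
#' @examples
#' canonicalTetramer(c("AAAA", "TTTT", "AATT"))
canonicalTetramer <- function(tet) {
  rc <- vapply(tet, revcompChars, character(1))
  flipped <- rc < tet
  data.frame(class = ifelse(flipped, rc, tet), flipped = flipped,
             row.names = NULL)
}

# Role flip under reverse-complement canonicalization: the window is read
# from the other strand, exchanging Watson/Crick and the w2/w3 centers, and
# negating fan offsets.
flipRole <- function(role) {
  map <- c(stacking.W = "stacking.C", stacking.C = "stacking.W",
           pairing.w2 = "pairing.w3", pairing.w3 = "pairing.w2",
           angle.w1 = "angle.c2", angle.w2 = "angle.c1",
           angle.c1 = "angle.w2", angle.c2 = "angle.w1")
  out <- unname(map[role])
  isfan <- grepl("^fan\\.", role)
  if (any(isfan)) {
    parts <- strsplit(role[isfan], ".", fixed = TRUE)
    out[isfan] <- vapply(parts, function(p) {
      center <- if (p[2] == "w2") "w3" else "w2"
      k <- as.integer(p[3])
      sprintf("fan.%s.%d", center, -k)
    }, character(1))
  }
  out
}

#' Role keys of a tetramer class
#'
#' @param scheme Accounting scheme: "eq5" (fan offsets +-1, +-2 at tetramer
#'   level) or "fig1" (+-1..+-3).
#' @return Character vector of the role keys each tetramer class carries.
#' @export
tetramerRoles <- function(scheme = "eq5") {
  kmax <- switch(scheme, eq5 = 2L, fig1 = 3L,
                 stop(sprintf("unknown scheme '%s'; available: eq5, fig1", scheme)))
  ks <- setdiff(seq(-kmax, kmax), 0L)
  c("stacking.W", "stacking.C", "pairing.w2", "pairing.w3",
    "angle.w1", "angle.w2", "angle.c1", "angle.c2",
    as.vector(outer(c("w2", "w3"), ks, function(a, b) sprintf("fan.%s.%d", a, b))))
}

# Signed distant offsets of a scheme.
distantOffsets <- function(scheme = "eq5") {
  switch(scheme,
         eq5 = c(-5L, -4L, -3L, 3L, 4L, 5L),
         fig1 = c(-5L, -4L, 4L, 5L),
         stop(sprintf("unknown scheme '%s'; available: eq5, fig1", scheme)))
}

# Map a role key to the generic role used by the sequence-averaged AVG class.
genericRole <- function(role) {
  out <- role
  out[grepl("^stacking", role)] <- "stacking"
  out[grepl("^pairing", role)] <- "pairing"
  out[grepl("^angle", role)] <- "angle"
  isfan <- grepl("^fan\\.", role)
  if (any(isfan)) {
    k <- vapply(strsplit(role[isfan], ".", fixed = TRUE), `[`, character(1), 3)
    out[isfan] <- paste0("fan.", k)
  }
  out
}

#' Enumerate the interactions of the Hamiltonian
#'
#' Walks every tetramer window of the duplex and instantiates, per window, 2
#' stacking, 2 pairing, 4 angle and 8 fan interactions (default `"eq5"`
#' scheme; fan offsets +-1, +-2 carried at tetramer level). An interaction
#' lying in two windows is a single instance carrying both context labels.
#' Remaining cross-strand offsets (+-3, +-4, +-5 under `"eq5"`; +-4, +-5
#' under `"fig1"`, which instead keeps +-3 at tetramer level) are enumerated
#' as sequence-averaged distant instances. Terminal instances whose tetramer
#' context is truncated fall back to the sequence-averaged `"AVG"` context.
#' Offsets reaching beyond a linear duplex are silently dropped; circular
#' topologies wrap.
#'
#' @param topology A [BeadTopology-class].
#' @param scheme Accounting scheme id, `"eq5"` (default) or `"fig1"`.
#' @return An [InteractionTable-class].
#' @export
#' @examples
#' tab <- enumerateInteractions(buildDuplexTopology("ACGTACGTAC"))
#' tab
enumerateInteractions <- function(topology, scheme = "eq5") {
  stopifnot(is(topology, "BeadTopology"))
  kmaxTet <- switch(scheme, eq5 = 2L, fig1 = 3L,
                    stop(sprintf("unknown scheme '%s'; available: eq5, fig1",
                                 scheme)))
  n <- topology@nbp
  circ <- topology@circular
  wrap <- function(p) ((p - 1L) %% n) + 1L
  inRange <- function(p) circ | (p >= 1L & p <= n)

  # registries keyed by instance identity
  bondKey <- new.env(parent = emptyenv())
  bonds <- list(); bctx <- list()
  addBond <- function(kind, i, j, offset, ctx) {
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(kind, i, j, sep = "_")
    idx <- bondKey[[key]]
    if (is.null(idx)) {
      idx <- length(bonds) + 1L
      bonds[[idx]] <<- list(kind = kind, i = i, j = j, offset = offset)
      bctx[[idx]] <<- character(0)
      bondKey[[key]] <- idx
    }
    bctx[[idx]] <<- c(bctx[[idx]], ctx)
  }
  angKey <- new.env(parent = emptyenv())
  angs <- list(); actx <- list()
  addAngle <- function(i, j, k, ctx) {
    if (i > k) { tmp <- i; i <- k; k <- tmp }
    key <- paste(i, j, k, sep = "_")
    idx <- angKey[[key]]
    if (is.null(idx)) {
      idx <- length(angs) + 1L
      angs[[idx]] <<- list(i = i, j = j, k = k)
      actx[[idx]] <<- character(0)
      angKey[[key]] <- idx
    }
    actx[[idx]] <<- c(actx[[idx]], ctx)
  }

  wBead <- function(p) wrap(p)
  cBead <- function(p) n + wrap(p)

  windows <- if (circ) seq_len(n) else seq_len(max(0L, n - 3L))
  for (t in windows) {
    tet <- paste(topology@watson[wrap(t:(t + 3L))], collapse = "")
    can <- canonicalTetramer(tet)
    lab <- function(role) {
      r <- if (can$flipped) flipRole(role) else role
      paste0(can$class, "/", r)
    }
    b <- t + 1L; c2 <- t + 2L         # w2, w3 bp positions
    addBond("stacking", wBead(b), wBead(c2), 1L, lab("stacking.W"))
    addBond("stacking", cBead(b), cBead(c2), 1L, lab("stacking.C"))
    addBond("pairing", wBead(b), cBead(b), 0L, lab("pairing.w2"))
    addBond("pairing", wBead(c2), cBead(c2), 0L, lab("pairing.w3"))
    addAngle(wBead(t), wBead(b), wBead(c2), lab("angle.w1"))
    addAngle(wBead(b), wBead(c2), wBead(t + 3L), lab("angle.w2"))
    addAngle(cBead(t), cBead(b), cBead(c2), lab("angle.c1"))
    addAngle(cBead(b), cBead(c2), cBead(t + 3L), lab("angle.c2"))
    for (k in setdiff(seq(-kmaxTet, kmaxTet), 0L)) {
      for (ctr in c("w2", "w3")) {
        p <- if (ctr == "w2") b else c2
        if (inRange(p + k))
          addBond("fan", wBead(p), cBead(p + k), k,
                  lab(sprintf("fan.%s.%d", ctr, k)))
      }
    }
  }

  if (!circ) {
    # terminal fallback instances with truncated tetramer context
    for (p in c(1L, n - 1L)) {        # steps never in the middle of a window
      addBond("stacking", wBead(p), wBead(p + 1L), 1L, "AVG/stacking.W")
      addBond("stacking", cBead(p), cBead(p + 1L), 1L, "AVG/stacking.C")
    }
    for (p in c(1L, n)) {
      addBond("pairing", wBead(p), cBead(p), 0L, "AVG/pairing.w2")
      for (k in setdiff(seq(-kmaxTet, kmaxTet), 0L))
        if (inRange(p + k))
          addBond("fan", wBead(p), cBead(p + k), k,
                  sprintf("AVG/fan.w2.%d", k))
    }
  }

  # sequence-averaged distant fan instances
  for (k in distantOffsets(scheme))
    for (p in seq_len(n))
      if (inRange(p + k))
        addBond("distant", wBead(p), cBead(p + k), k,
                sprintf("DIST/%d", k))

  bondsDf <- data.frame(
    kind = vapply(bonds, `[[`, character(1), "kind"),
    i = vapply(bonds, `[[`, integer(1), "i"),
    j = vapply(bonds, `[[`, integer(1), "j"),
    offset = vapply(bonds, `[[`, integer(1), "offset"),
    stringsAsFactors = FALSE)
  bondsDf$contexts <- lapply(bctx, unique)
  angDf <- data.frame(
    i = vapply(angs, `[[`, integer(1), "i"),
    j = vapply(angs, `[[`, integer(1), "j"),
    k = vapply(angs, `[[`, integer(1), "k"))
  angDf$contexts <- lapply(actx, unique)
  if (any(vapply(bondsDf$contexts, length, integer(1)) == 0L) ||
      (nrow(angDf) && any(vapply(angDf$contexts, length, integer(1)) == 0L)))
    stop("internal error: interaction instance without context")
  new("InteractionTable", bonds = bondsDf, angles = angDf,
      scheme = scheme, topology = topology)
}

#' Remote-term exclusion mask
#'
#' The remote (Lennard-Jones + electrostatic) contribution is switched off for
#' bead pairs whose base-pair positions are within 5 bp of each other, on
#' either strand or across strands, and for self pairs. On circular
#' topologies the separation is computed on the circle.
#'
#' @param topology A [BeadTopology-class].
#' @return A symmetric logical matrix (`2 nbp` square); TRUE marks excluded
#'   pairs. For energy evaluation the compiled kernel recomputes the same
#'   criterion from base-pair positions; this explicit form is the reference.
#' @export
remoteExclusionMask <- function(topology) {
  stopifnot(is(topology, "BeadTopology"))
  n <- topology@nbp
  pos <- topology@bpPos
  d <- abs(outer(pos, pos, `-`))
  if (topology@circular) d <- pmin(d, n - d)
  m <- d <= 5L
  diag(m) <- TRUE
  m
}
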