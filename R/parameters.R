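#' Remote (non-bonded) settings
#'
#' Beads carry the nucleotide charge `q = -1 e` and interact, beyond the
#' 5-bp sequential exclusion, through a 12-6 Lennard-Jones term and
#' Debye-Hueckel screened electrostatics
#' `E_ele = C q^2 exp(-kappa r) / (eps_r r)`. Defaults correspond to 100 mM
#' 1:1 salt in water at room temperature: `kappa = 0.104 1/A` from the
#' standard Debye-length formula and `eps_r = 78.5`; `sigma = 10 A` and
#' `epsLJ = 0.59 kcal/mol`.
#'
#' @param q Bead charge in elementary charges.
#' @param sigma Lennard-Jones diameter, Angstrom.
#' @param epsLJ Lennard-Jones well depth, kcal/mol.
#' @param epsR Relative dielectric constant.
#' @param kappa Inverse Debye length, 1/Angstrom.
#' @param cutoff Pair cutoff, Angstrom (default 2.5 sigma, no switching
#'   function).
#' @return Named list of remote settings.
#' @export
remoteSettings <- function(q = -1, sigma = 10, epsLJ = 0.59, epsR = 78.5,
                           kappa = 0.104, cutoff = 2.5 * sigma) {
  stopifnot(sigma > 0, epsLJ >= 0, kappa >= 0, cutoff > sigma)
  list(q = q, sigma = sigma, epsLJ = epsLJ, epsR = epsR, kappa = kappa,
       cutoff = cutoff)
}

#' Construct a ParameterLibrary
#'
#' @param classes Named list of tetramer classes (see
#'   [ParameterLibrary-class]); must include the `"AVG"` fallback unless every
#'   sequence to be simulated is covered explicitly.
#' @param distant Named list of distant fan terms keyed by signed offset.
#' @param remote Remote settings from [remoteSettings()].
#' @param scheme Accounting scheme id.
#' @param meta Optional provenance list.
#' @return A [ParameterLibrary-class].
#' @export
parameterLibrary <- function(classes, distant, remote = remoteSettings(),
                             scheme = "eq5", meta = list()) {
  meta$units <- list(distance = "A", angle = "rad", energy = "kcal/mol")
  new("ParameterLibrary", classes = classes, distant = distant,
      remote = remote, scheme = scheme, meta = meta)
}

#' A bonded term
#'
#' The truncated polynomial potential `sum_{a=2..4} K_a (x - x0)^a`.
#'
#' @param K2,K3,K4 Force constants (kcal/mol/A^a for distances,
#'   kcal/mol/rad^a for angles); `K2 > 0`, `K4 >= 0`.
#' @param x0 Equilibrium distance (A) or angle (rad).
#' @return Numeric vector `c(K2, K3, K4, x0)`.
#' @export
bondedTerm <- function(K2, K3 = 0, K4 = 0, x0) {
  stopifnot(K2 > 0, K4 >= 0)
  c(K2 = unname(K2)[1], K3 = unname(K3)[1], K4 = unname(K4)[1],
    x0 = unname(x0)[1])
}

# Term lookup for a context label "CLASS/role". DIST contexts index the
# distant table by signed offset.
lookupTerm <- function(lib, ctx, fallback = TRUE) {
  parts <- strsplit(ctx, "/", fixed = TRUE)[[1]]
  cls <- parts[1]; role <- parts[2]
  if (cls == "DIST") {
    trm <- lib@distant[[role]]
    if (is.null(trm)) stop(sprintf("no distant term for offset %s", role))
    return(trm)
  }
  if (cls == "AVG") {
    trm <- lib@classes[["AVG"]][[genericRole(role)]]
    if (is.null(trm)) stop(sprintf("no AVG fallback term for role %s", role))
    return(trm)
  }
  clTerms <- lib@classes[[cls]]
  if (is.null(clTerms)) {
    if (!fallback)
      stop(sprintf("parameter library has no tetramer class %s and fallback is disabled",
                   cls))
    return(lookupTerm(lib, paste0("AVG/", role)))
  }
  trm <- clTerms[[role]]
  if (is.null(trm)) {
    if (!fallback)
      stop(sprintf("class %s lacks role %s and fallback is disabled", cls, role))
    return(lookupTerm(lib, paste0("AVG/", role)))
  }
  trm
}

#' Resolve per-instance parameters
#'
#' Each interaction instance receives the arithmetic mean of the bonded
#' parameters `(K2, K3, K4, x0)` over its tetramer-context labels; instances
#' present in two tetramer windows are therefore averaged between them.
#' Terminal instances with truncated context use the sequence-averaged
#' fallback class.
#'
#' @param table An [InteractionTable-class].
#' @param lib A [ParameterLibrary-class] covering every tetramer class present
#'   (or supplying the `"AVG"` fallback).
#' @param fallback Allow falling back to the `"AVG"` class for missing
#'   tetramer classes; if `FALSE` a missing class is an error naming it.
#' @return List with `bonds` (matrix: i, j, K2, K3, K4, x0, channel with
#'   1 = stacking, 2 = pairing, 3 = fan, 4 = distant), `angles` (matrix: i, j,
#'   k, K2, K3, K4, x0), the `remote` settings and the source `topology`.
#' @export
resolveParameters <- function(table, lib, fallback = TRUE) {
  stopifnot(is(table, "InteractionTable"), is(lib, "ParameterLibrary"))
  if (!identical(table@scheme, lib@scheme))
    warning(sprintf("table scheme '%s' differs from library scheme '%s'",
                    table@scheme, lib@scheme))
  chan <- c(stacking = 1, pairing = 2, fan = 3, distant = 4)
  bonds <- table@bonds
  bterms <- t(vapply(bonds$contexts, function(ctxs) {
    rowMeans(vapply(ctxs, function(ctx) lookupTerm(lib, ctx, fallback),
                    numeric(4)))
  }, numeric(4)))
  bmat <- cbind(i = bonds$i, j = bonds$j, bterms,
                channel = unname(chan[bonds$kind]))
  colnames(bmat) <- c("i", "j", "K2", "K3", "K4", "x0", "channel")
  angles <- table@angles
  if (nrow(angles)) {
    aterms <- t(vapply(angles$contexts, function(ctxs) {
      rowMeans(vapply(ctxs, function(ctx) lookupTerm(lib, ctx, fallback),
                      numeric(4)))
    }, numeric(4)))
    amat <- cbind(i = angles$i, j = angles$j, k = angles$k, aterms)
  } else {
    amat <- matrix(numeric(0), 0, 7)
  }
  colnames(amat) <- c("i", "j", "k", "K2", "K3", "K4", "x0")
  list(bonds = bmat, angles = amat, remote = lib@remote,
       topology = table@topology)
}

# ---- JSON serialization -------------------------------------------------

#' Write a ParameterLibrary to JSON
#'
#' The JSON format declares units explicitly and stores tetramer-class keys,
#' distant-offset keys and remote settings; the round trip through
#' [readParameterLibrary()] is lossless at full double precision.
#'
#' @param lib A [ParameterLibrary-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeParameterLibrary <- function(lib, path) {
  obj <- list(
    format = "cgdna-parameters",
    version = 1L,
    scheme = lib@scheme,
    units = list(distance = "A", angle = "rad", energy = "kcal/mol"),
    term_layout = c("K2", "K3", "K4", "x0"),
    classes = lapply(lib@classes, function(cl) lapply(cl, unname)),
    distant = lapply(lib@distant, unname),
    remote = lib@remote,
    meta = lib@meta[setdiff(names(lib@meta), "units")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a ParameterLibrary from JSON
#'
#' @param path Path to a file written by [writeParameterLibrary()].
#' @return A [ParameterLibrary-class].
#' @export
readParameterLibrary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "cgdna-parameters"))
    stop(sprintf("%s is not a cgdna parameter file", path))
  fixTerm <- function(v) {
    v <- as.numeric(unlist(v))
    names(v) <- c("K2", "K3", "K4", "x0")
    v
  }
  classes <- lapply(obj$classes, function(cl) lapply(cl, fixTerm))
  distant <- lapply(obj$distant, fixTerm)
  remote <- lapply(obj$remote, function(x) if (is.numeric(x)) x else as.numeric(x))
  parameterLibrary(classes = classes, distant = distant, remote = remote,
                   scheme = obj$scheme,
                   meta = lapply(obj$meta, identity) %||% list())
}
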