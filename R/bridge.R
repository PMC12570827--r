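# Interface to the RDKit worker process.
#
# All cheminformatics primitives (SMILES/SMARTS parsing, canonicalization,
# RDKFingerprint, distance-geometry embedding + UFF optimization, molecular
# graph edits with valence sanitization) are delegated to RDKit through a
# small batched JSON protocol: one python process per call, a list of ops in,
# a list of results out.  Results for pure queries are memoised per session,
# so repeated parsing of the same molecule costs one subprocess round trip.

.polytag <- new.env(parent = emptyenv())
.polytag$cache <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for RDKit calls
#'
#' The interpreter is taken from `options(polytag.python=)` if set, else from
#' the `POLYTAG_PYTHON` environment variable, else `python` on the `PATH`.
#'
#' @return Path to the interpreter (character scalar).
#' @export
polytag_python <- function() {
  p <- getOption("polytag.python", "")
  if (!nzchar(p)) p <- Sys.getenv("POLYTAG_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) {
    stop("No python interpreter found; install RDKit-enabled Python and/or ",
         "set options(polytag.python=...)", call. = FALSE)
  }
  unname(p)
}

bridge_script <- function() {
  path <- system.file("python", "rdkit_bridge.py", package = "polytag")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is on the source path
    path <- file.path("inst", "python", "rdkit_bridge.py")
  }
  if (!file.exists(path)) stop("rdkit_bridge.py not found", call. = FALSE)
  path
}

#' Run a batch of operations through the RDKit worker
#'
#' Low-level entry point; the typed wrappers below are preferred.
#'
#' @param ops List of op lists, each with an `op` element naming the
#'   operation (`mol_info`, `fingerprint`, `embed`, `edit`, `canonicalize`).
#' @return List of result lists, one per op, each with an `ok` flag.
#' @keywords internal
bridge_call <- function(ops) {
  req <- jsonlite::toJSON(list(ops = ops), auto_unbox = TRUE, null = "null")
  out <- suppressWarnings(system2(
    polytag_python(), shQuote(bridge_script()),
    input = req, stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RDKit bridge process failed (exit ", status, ")", call. = FALSE)
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

cache_key <- function(...) paste(..., sep = "\r")

#' Clear the session cache of molecule queries and reactivity profiles
#'
#' Cached results are deterministic, so clearing is only needed to measure
#' raw recomputation (e.g. determinism checks) or to free memory.
#'
#' @return Invisibly, the number of entries dropped.
#' @export
polytag_clear_cache <- function() {
  n <- length(ls(.polytag$cache))
  rm(list = ls(.polytag$cache), envir = .polytag$cache)
  invisible(n)
}

bridge_cached <- function(key, op) {
  hit <- .polytag$cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- bridge_call(list(op))[[1]]
  assign(key, res, envir = .polytag$cache)
  res
}

#' Parse a molecule and report its graph, matches and identity
#'
#' Canonicalizes `smiles` with RDKit and reports atoms, bonds, ring
#' membership, substructure matches for a set of SMARTS patterns, and
#' electron bookkeeping.  All atom indices are 0-based and refer to the atom
#' order of the returned canonical SMILES, which every downstream step
#' (reactivity profile, graph edits) shares.
#'
#' @param smiles Single-component SMILES string.
#' @param patterns Named character vector of SMARTS patterns to match
#'   (may be empty).
#' @return List with elements `canonical_smiles`, `atoms` (list of per-atom
#'   records), `bonds`, `matches` (named list of integer-vector lists,
#'   0-based), `n_heavy`, `n_electrons`, `net_charge`,
#'   `n_radical_electrons`.
#' @export
mol_info <- function(smiles, patterns = character()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- cache_key("mol_info", smiles, paste(names(patterns), patterns,
                                             collapse = ";"))
  res <- bridge_cached(key, list(
    op = "mol_info", smiles = smiles,
    patterns = as.list(patterns)
  ))
  if (!isTRUE(res$ok)) stop("mol_info: ", res$error, call. = FALSE)
  res$matches <- lapply(res$matches, function(hits) {
    lapply(hits, function(h) as.integer(unlist(h)))
  })
  res
}

#' Canonicalize SMILES strings with RDKit
#'
#' @param smiles Character vector; entries may contain wildcard atoms (`*`)
#'   and atom maps.
#' @return Character vector of canonical SMILES; `NA` where parsing or
#'   valence sanitization fails.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character())
  res <- bridge_cached(cache_key("canon", paste(smiles, collapse = "\n")),
                       list(op = "canonicalize", smiles = as.list(smiles)))
  vapply(res$canonical, function(x) if (is.null(x)) NA_character_ else x,
         character(1))
}
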