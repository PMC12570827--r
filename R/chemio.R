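# Input/output and monomer selection.
#
# Input is a CSV naming each polymer and giving either a monomer SMILES or a
# reaction SMILES (reactants>>products, optionally reactants>agents>products).
# For reaction records the monomer is the reactant whose RDKFingerprint is
# most Tanimoto-similar to the (largest) product.

#' Accepted column-header aliases for the input CSV
#'
#' @return List with `name` and `smiles` alias vectors (matched
#'   case-insensitively).
#' @export
default_header_aliases <- function() {
  list(
    name   = c("polymer_name", "name", "polymer"),
    smiles = c("smiles", "reaction", "reaction_smiles", "monomer_smiles")
  )
}

#' Read the pipeline input CSV
#'
#' @param path CSV file with a polymer-name column and a SMILES column
#'   (header aliases per `aliases`).
#' @param aliases Header aliases, see [default_header_aliases()].
#' @return Data frame with columns `polymer_name`, `raw_smiles`,
#'   `record_kind` ("monomer"/"reaction") and `valid` (FALSE for rows whose
#'   SMILES does not parse; such rows are flagged, never dropped).  Row order
#'   follows the file.
#' @export
read_input_csv <- function(path, aliases = default_header_aliases()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(which) {
    idx <- match(tolower(aliases[[which]]), tolower(names(df)))
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) {
      stop("input CSV lacks a ", which, " column; accepted headers: ",
           paste(aliases[[which]], collapse = ", "), call. = FALSE)
    }
    idx[1L]
  }
  name_col <- pick("name")
  smiles_col <- pick("smiles")
  raw <- trimws(as.character(df[[smiles_col]]))
  kind <- ifelse(grepl(">", raw, fixed = TRUE), "reaction", "monomer")
  valid <- vapply(seq_along(raw), function(i) {
    if (!nzchar(raw[i])) return(FALSE)
    if (kind[i] == "reaction") {
      ok <- tryCatch({ parse_reaction_smiles(raw[i]); TRUE },
                     error = function(e) FALSE)
      return(ok)
    }
    comps <- split_components(raw[i])
    !anyNA(canonical_smiles(comps))
  }, logical(1))
  data.frame(
    polymer_name = as.character(df[[name_col]]),
    raw_smiles = raw,
    record_kind = kind,
    valid = valid,
    stringsAsFactors = FALSE
  )
}

#' Split a multi-component SMILES on "."
#' @param smiles SMILES string, possibly "."-separated.
#' @return Character vector of component SMILES.
#' @export
split_components <- function(smiles) {
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

#' Parse a reaction SMILES into reactants, agents and products
#'
#' Accepts the two-field `reactants>>products` and three-field
#' `reactants>agents>products` forms; components split on ".".  Atom-map
#' numbers are preserved in the returned strings (fingerprinting ignores
#' them via canonicalization).
#'
#' @param s Reaction SMILES.
#' @return List with character vectors `reactants`, `agents`, `products`.
#' @export
parse_reaction_smiles <- function(s) {
  n_sep <- lengths(regmatches(s, gregexpr(">", s, fixed = TRUE)))
  if (n_sep != 2L) {
    stop("malformed reaction SMILES (expected 2 or 3 '>'-separated fields): ",
         s, call. = FALSE)
  }
  # "a>>b" splits to c("a", "", "b"); "a>x>b" to c("a", "x", "b");
  # trailing empty fields are dropped by strsplit, pad them back
  fields <- strsplit(s, ">", fixed = TRUE)[[1]]
  fields <- c(fields, rep("", 3L - length(fields)))
  part <- function(x, what, required) {
    comps <- if (nzchar(x)) split_components(x) else character()
    comps <- comps[nzchar(comps)]
    if (required && length(comps) == 0L) {
      stop("reaction SMILES has an empty ", what, " field: ", s,
           call. = FALSE)
    }
    comps
  }
  list(
    reactants = part(fields[1], "reactant", TRUE),
    agents    = part(fields[2], "agent", FALSE),
    products  = part(fields[3], "product", TRUE)
  )
}

#' Topological (path-based) fingerprint of a molecule
#'
#' RDKit's `RDKFingerprint` (2048-bit Daylight-style path fingerprint).
#'
#' @param smiles Single SMILES string.
#' @return Object of class `polytag_fp`: list with `on_bits` (0-based sorted
#'   integer vector) and `n_bits`.
#' @export
topological_fingerprint <- function(smiles) {
  res <- bridge_cached(cache_key("fp", smiles),
                       list(op = "fingerprint", smiles = list(smiles)))
  fp <- res$fingerprints[[1]]
  if (is.null(fp)) stop("invalid SMILES for fingerprint: ", smiles,
                        call. = FALSE)
  structure(list(on_bits = sort(as.integer(unlist(fp$on_bits))),
                 n_bits = as.integer(fp$n_bits)),
            class = "polytag_fp")
}

#' Tanimoto similarity between two bit fingerprints
#'
#' |a AND b| / |a OR b|; two all-zero fingerprints compare as 0.
#'
#' @param a,b `polytag_fp` objects of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "polytag_fp"), inherits(b, "polytag_fp"))
  if (a$n_bits != b$n_bits) stop("fingerprint lengths differ", call. = FALSE)
  union_n <- length(union(a$on_bits, b$on_bits))
  if (union_n == 0L) return(0)
  length(intersect(a$on_bits, b$on_bits)) / union_n
}

#' Select the monomer among the reactants of a reaction
#'
#' Each reactant is compared by Tanimoto similarity of RDKFingerprints
#' against the largest product (by heavy-atom count); the arg-max wins, ties
#' broken by first occurrence.
#'
#' @param parts Result of [parse_reaction_smiles()].
#' @return List with `monomer_smiles` and named numeric
#'   `similarity_by_reactant`.
#' @export
select_monomer <- function(parts) {
  stopifnot(length(parts$reactants) >= 1L, length(parts$products) >= 1L)
  heavy <- vapply(parts$products, function(p) {
    tryCatch(mol_info(p)$n_heavy, error = function(e) NA_integer_)
  }, integer(1))
  if (all(is.na(heavy))) stop("no parseable product", call. = FALSE)
  target <- parts$products[which.max(heavy)]
  fp_target <- topological_fingerprint(target)
  sims <- vapply(parts$reactants, function(r) {
    tryCatch(tanimoto(topological_fingerprint(r), fp_target),
             error = function(e) NA_real_)
  }, numeric(1))
  names(sims) <- parts$reactants
  if (all(is.na(sims))) stop("no parseable reactant", call. = FALSE)
  best <- which.max(replace(sims, is.na(sims), -Inf))
  list(monomer_smiles = parts$reactants[best], similarity_by_reactant = sims)
}

result_columns <- function() {
  c("polymer_name", "input_smiles", "reaction_mapped", "reaction_unmapped",
    "monomer_smiles", "polymer_class", "mechanism", "vinyl_subcategory",
    "tagged_smiles", "head_atom_index", "tail_atom_index", "status",
    "message")
}

#' Write pipeline result rows to CSV
#'
#' Fixed column order; an empty row list yields a header-only file.
#' Re-reading with [read_results_csv()] round-trips all fields.
#'
#' @param rows Data frame of results (as from [run_pipeline()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(rows, path) {
  cols <- result_columns()
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- as.data.frame(setNames(rep(list(character()), length(cols)),
                                   cols), stringsAsFactors = FALSE)
  }
  missing <- setdiff(cols, names(rows))
  for (m in missing) rows[[m]] <- NA
  utils::write.csv(rows[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline results CSV
#' @param path CSV written by [write_results_csv()].
#' @return Data frame with the standard result columns.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("head_atom_index", "tail_atom_index")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  df
}
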