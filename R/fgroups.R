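# Functional-group SMARTS library and polymer-class candidate rules.
#
# Eleven built-in patterns cover the groups that license the five polymer
# classes.  Each pattern carries a role (nucleophile / electrophile /
# structural) and the index, within its SMARTS atom order, of the "key"
# nucleophilic atom used for head selection when no reactivity profile is
# needed (NA when ambiguous, e.g. both alkene carbons are candidates).

POLYMER_CLASSES <- c("polyvinyl", "polyamide", "polyester", "polyether",
                     "polyurethane")

default_patterns <- function() {
  p <- function(name, smarts, role, key = NA_integer_) {
    list(name = name, smarts = smarts, role = role, key_atom = key)
  }
  list(
    p("alkene",            "[CX3]=[CX3]",        "nucleophile"),
    p("alkyne",            "[CX2]#[CX2]",        "nucleophile"),
    p("primary_amine",     "[NX3;H2][#6]",       "nucleophile", 0L),
    p("carboxylic_acid",   "[CX3](=O)[OX2H1]",   "electrophile", 0L),
    p("acyl_halide",       "[CX3](=O)[F,Cl,Br,I]", "electrophile", 0L),
    p("secondary_amide",   "[NX3;H1][CX3]=O",    "nucleophile", 0L),
    p("heterocycle",       "[O,N;R]",            "structural", 0L),
    p("aliphatic_alcohol", "[CX4][OX2H]",        "nucleophile", 1L),
    p("ether",             "[OX2]([#6])[#6]",    "nucleophile", 0L),
    p("hydroxyl",          "[OX2H]",             "nucleophile", 0L),
    p("isocyanate",        "[NX2]=[CX2]=[OX1]",  "electrophile", 1L)
  )
}

# opt-in corrected rule: a lactone (ester oxygen in a ring) licenses
# polyester directly, fixing the documented cyclic-ester misclassification
LACTONE_SMARTS <- "[CX3](=O)[OX2;R]"
# the default cyclic polyester route fires only for small-ring (strained)
# lactones: ester oxygen in a 3- or 4-membered ring
SMALL_LACTONE_SMARTS <- "[CX3](=O)[OX2;r3,r4]"

#' Load the functional-group pattern library
#'
#' @param config Optional path to a YAML or JSON file with a list of
#'   `{name, smarts, role}` records overriding or extending the defaults.
#' @return List of patterns, each with `name`, `smarts`, `role`, `key_atom`.
#'   Every SMARTS is checked to compile.
#' @export
load_pattern_library <- function(config = NULL) {
  lib <- default_patterns()
  if (!is.null(config)) {
    ext <- tolower(tools::file_ext(config))
    entries <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = FALSE)
    }
    for (e in entries) {
      if (is.null(e$name) || is.null(e$smarts)) {
        stop("pattern override entries need 'name' and 'smarts'",
             call. = FALSE)
      }
      idx <- which(vapply(lib, `[[`, "", "name") == e$name)
      rec <- list(name = e$name, smarts = e$smarts,
                  role = if (is.null(e$role)) "nucleophile" else e$role,
                  key_atom = if (is.null(e$key_atom)) NA_integer_
                             else as.integer(e$key_atom))
      if (length(idx)) lib[[idx]] <- rec else lib <- c(lib, list(rec))
    }
  }
  # validate that every SMARTS compiles (cheap probe molecule)
  smarts <- vapply(lib, `[[`, "", "smarts")
  names(smarts) <- vapply(lib, `[[`, "", "name")
  ok <- tryCatch({ mol_info("C", patterns = smarts); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) stop("pattern library failed to compile: ", ok,
                        call. = FALSE)
  lib
}

pattern_smarts <- function(lib) {
  s <- vapply(lib, `[[`, "", "smarts")
  names(s) <- vapply(lib, `[[`, "", "name")
  s
}

#' Match the functional-group library against one component
#'
#' @param component_smiles Single-component SMILES.
#' @param library Pattern library from [load_pattern_library()].
#' @return List with `info` (the [mol_info()] record, canonical atom order)
#'   and `matches`: a list of records `pattern_name`, `atom_indices`
#'   (0-based), `role`, `key_atom` (0-based absolute index or NA), one per
#'   deduplicated substructure hit.
#' @export
match_groups <- function(component_smiles,
                         library = load_pattern_library()) {
  smarts <- c(pattern_smarts(library),
              .lactone = LACTONE_SMARTS, .small_lactone = SMALL_LACTONE_SMARTS)
  info <- mol_info(component_smiles, patterns = smarts)
  out <- list()
  for (pat in library) {
    for (hit in info$matches[[pat$name]]) {
      key_abs <- if (is.na(pat$key_atom)) NA_integer_ else hit[pat$key_atom + 1L]
      out[[length(out) + 1L]] <- list(
        pattern_name = pat$name,
        atom_indices = hit,
        role = pat$role,
        key_atom = key_abs
      )
    }
  }
  list(info = info, matches = out)
}

match_names <- function(matches) {
  vapply(matches, `[[`, "", "pattern_name")
}

atom_field <- function(info, field) {
  vapply(info$atoms, function(a) a[[field]], vector(mode = "numeric", 1L))
}

# does the reacting core of this match sit on ring atoms?  For amide/ester
# patterns the exocyclic carbonyl O is excluded: a lactam's N-C(=O) is in
# the ring while its =O never is.
match_in_ring <- function(info, m) {
  in_ring <- vapply(info$atoms, function(a) isTRUE(a$in_ring), logical(1))
  core <- m$atom_indices
  if (m$pattern_name %in% c("secondary_amide", "carboxylic_acid")) {
    sym <- vapply(info$atoms[core + 1L], `[[`, "", "symbol")
    keep <- !(sym == "O" & !in_ring[core + 1L])
    core <- core[keep]
  }
  all(in_ring[core + 1L])
}

#' Derive polymer-class candidates from per-component matches
#'
#' Rule table (matches may come from different components of a copolymer
#' record; polyurethane requires its two groups on different components):
#' \itemize{
#'   \item polyvinyl: alkene or alkyne
#'   \item polyamide: (primary amine and carboxylic acid) or (primary amine
#'     and acyl halide) or (secondary amide whose atoms lie in a ring)
#'   \item polyester: (aliphatic alcohol and carboxylic acid) or (ring-member
#'     carboxylic acid) or (small-ring lactone); with `fix_lactones`, any
#'     lactone
#'   \item polyether: an ether whose oxygen is in a ring
#'   \item polyurethane: hydroxyl on one component, isocyanate on another
#' }
#' A monomer satisfying several rules yields several candidates; resolution
#' is the assigner's job.
#'
#' @param per_component List of [match_groups()] results, one per
#'   "."-component.
#' @param fix_lactones Opt-in corrected rule: any lactone licenses polyester.
#' @return List of candidates, each `polymer_class`, `supporting_matches`
#'   (with a `component` index added to every match), `requires_two_components`.
#' @export
candidate_classes <- function(per_component, fix_lactones = FALSE) {
  all_matches <- list()
  for (ci in seq_along(per_component)) {
    comp <- per_component[[ci]]
    for (m in comp$matches) {
      m$component <- ci
      m$in_ring <- match_in_ring(comp$info, m)
      all_matches[[length(all_matches) + 1L]] <- m
    }
  }
  nm <- match_names(all_matches)
  of <- function(p) all_matches[nm == p]
  has <- function(p) any(nm == p)
  cands <- list()
  add <- function(class, supports, two = FALSE) {
    cands[[length(cands) + 1L]] <<- list(
      polymer_class = class,
      supporting_matches = supports,
      requires_two_components = two
    )
  }

  if (has("alkene") || has("alkyne")) {
    add("polyvinyl", c(of("alkene"), of("alkyne")))
  }

  amide_ring <- Filter(function(m) m$in_ring, of("secondary_amide"))
  if (has("primary_amine") && (has("carboxylic_acid") || has("acyl_halide"))) {
    add("polyamide", c(of("primary_amine"), of("carboxylic_acid"),
                       of("acyl_halide")))
  } else if (length(amide_ring)) {
    add("polyamide", amide_ring)
  }

  lactone <- function(which) {
    lapply(per_component[[1]]$info$matches[[which]], identity)
  }
  small_lactones <- unlist(lapply(seq_along(per_component), function(ci) {
    hits <- per_component[[ci]]$info$matches[[".small_lactone"]]
    lapply(hits, function(h) list(pattern_name = "lactone",
                                  atom_indices = h, role = "electrophile",
                                  key_atom = h[3L], component = ci,
                                  in_ring = TRUE))
  }), recursive = FALSE)
  any_lactones <- unlist(lapply(seq_along(per_component), function(ci) {
    hits <- per_component[[ci]]$info$matches[[".lactone"]]
    lapply(hits, function(h) list(pattern_name = "lactone",
                                  atom_indices = h, role = "electrophile",
                                  key_atom = h[3L], component = ci,
                                  in_ring = TRUE))
  }), recursive = FALSE)
  acid_ring <- Filter(function(m) m$in_ring, of("carboxylic_acid"))
  if (has("aliphatic_alcohol") && has("carboxylic_acid")) {
    add("polyester", c(of("aliphatic_alcohol"), of("carboxylic_acid")))
  } else if (length(acid_ring)) {
    add("polyester", acid_ring)
  } else if (fix_lactones && length(any_lactones)) {
    add("polyester", any_lactones)
  } else if (!fix_lactones && length(small_lactones)) {
    add("polyester", small_lactones)
  }

  ring_ethers <- Filter(function(m) {
    # the ether oxygen itself (first SMARTS atom) must be a ring member
    comp <- per_component[[m$component]]
    isTRUE(comp$info$atoms[[m$atom_indices[1L] + 1L]]$in_ring)
  }, of("ether"))
  if (length(ring_ethers)) add("polyether", ring_ethers)

  oh <- of("hydroxyl"); nco <- of("isocyanate")
  oh_comps <- unique(vapply(oh, `[[`, 0L, "component"))
  nco_comps <- unique(vapply(nco, `[[`, 0L, "component"))
  if (length(oh) && length(nco) &&
      length(setdiff(oh_comps, nco_comps)) > 0L) {
    add("polyurethane", c(oh, nco), two = TRUE)
  }

  cands
}
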