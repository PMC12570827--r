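# Pipeline orchestration, validation against ground truth, fixtures.

#' Pipeline configuration
#'
#' @param seed Conformer seed for every quantum-backed step.
#' @param basis,method Passed to [run_rhf()].
#' @param fix_lactones Opt-in corrected lactone rule (any cyclic ester
#'   licenses polyester, not only strained small-ring lactones).
#' @param quantum "auto" computes a reactivity profile only when class
#'   resolution or head selection needs one; "always" profiles every
#'   monomer; "never" disables the quantum step (structural conventions
#'   only).
#' @param patterns,initiators Optional override file paths (YAML/JSON).
#' @param max_uff_steps Force-field step cap for embedding.
#' @return Config list for [run_pipeline()].
#' @export
polytag_config <- function(seed = 42L, basis = "STO-3G", method = "RHF",
                           fix_lactones = FALSE, quantum = "auto",
                           patterns = NULL, initiators = NULL,
                           max_uff_steps = 5000L) {
  stopifnot(quantum %in% c("auto", "always", "never"))
  list(seed = as.integer(seed), basis = basis, method = method,
       fix_lactones = isTRUE(fix_lactones), quantum = quantum,
       patterns = patterns, initiators = initiators,
       max_uff_steps = as.integer(max_uff_steps))
}

#' Collapse head/tail tokens and canonicalize
#'
#' Both `[*:1]` and `[*:2]` (any map number) are rewritten to the plain
#' wildcard `*`, then the SMILES is canonicalized, so head/tail numbering
#' does not influence comparison.
#'
#' @param tagged Tagged SMILES (may contain `[*:n]`, `[*]` or `*`).
#' @return Canonical SMILES with plain `*` tokens, or `NA` if the string
#'   does not parse (e.g. valence violations) -- callers count `NA` as
#'   incomparable, hence incorrect.
#' @export
collapse_tokens <- function(tagged) {
  if (is.na(tagged) || !nzchar(tagged)) return(NA_character_)
  plain <- gsub("\\[\\*(:[0-9]+)?\\]", "*", tagged)
  canonical_smiles(plain)
}

#' Compare a predicted tagged monomer with a ground-truth string
#'
#' True iff both collapse (tokens replaced by `*`, canonicalized) to the
#' same string; an invalid prediction or truth is FALSE.
#'
#' @param predicted Tagged SMILES (or the list returned by
#'   [tag_monomer()]).
#' @param truth Ground-truth tagged SMILES.
#' @return Logical flag.
#' @export
compare_assignment <- function(predicted, truth) {
  if (is.list(predicted)) predicted <- predicted$tagged_smiles
  a <- collapse_tokens(predicted)
  b <- collapse_tokens(truth)
  !is.na(a) && !is.na(b) && a == b
}

#' Score a prediction set against ground truth
#'
#' Entries are aligned by polymer name (the row order of either set is
#' irrelevant); duplicate or unmatched names are reported.
#'
#' @param predictions Data frame with `polymer_name`, `tagged_smiles` and
#'   optionally `polymer_class`.
#' @param truths Data frame with `polymer_name`, `tagged_smiles` and
#'   optionally `polymer_class`.
#' @return List: `per_entry` data frame (`polymer_name`, `class_correct`,
#'   `headtail_correct`), `class_accuracy`, `headtail_accuracy`,
#'   `per_class` breakdown, `unmatched_names`.
#' @export
score_dataset <- function(predictions, truths) {
  dup_p <- unique(predictions$polymer_name[duplicated(predictions$polymer_name)])
  dup_t <- unique(truths$polymer_name[duplicated(truths$polymer_name)])
  if (length(dup_p) || length(dup_t)) {
    stop("duplicate polymer names: ",
         paste(unique(c(dup_p, dup_t)), collapse = ", "), call. = FALSE)
  }
  common <- intersect(predictions$polymer_name, truths$polymer_name)
  if (length(common) == 0L) stop("no polymer names in common", call. = FALSE)
  unmatched <- c(setdiff(predictions$polymer_name, common),
                 setdiff(truths$polymer_name, common))
  p <- predictions[match(common, predictions$polymer_name), ]
  t <- truths[match(common, truths$polymer_name), ]
  has_class <- !is.null(p$polymer_class) && !is.null(t$polymer_class)
  class_ok <- if (has_class) {
    !is.na(p$polymer_class) & p$polymer_class == t$polymer_class
  } else {
    rep(NA, length(common))
  }
  ht_ok <- vapply(seq_along(common), function(i) {
    compare_assignment(p$tagged_smiles[i], t$tagged_smiles[i])
  }, logical(1))
  per_entry <- data.frame(polymer_name = common, class_correct = class_ok,
                          headtail_correct = ht_ok,
                          stringsAsFactors = FALSE)
  by_class <- if (has_class) {
    split(per_entry, t$polymer_class)
  } else {
    list()
  }
  per_class <- lapply(by_class, function(df) {
    c(n = nrow(df), class_correct = sum(df$class_correct),
      headtail_correct = sum(df$headtail_correct))
  })
  list(per_entry = per_entry,
       class_accuracy = if (has_class) mean(class_ok) else NA_real_,
       headtail_accuracy = mean(ht_ok),
       per_class = per_class,
       unmatched_names = unmatched)
}

strip_atom_maps <- function(s) gsub(":[0-9]+\\]", "]", s)

# ---- per-record processing -------------------------------------------------

empty_row <- function(name, raw, status, message = "") {
  data.frame(polymer_name = name, input_smiles = raw,
             reaction_mapped = NA_character_,
             reaction_unmapped = NA_character_,
             monomer_smiles = NA_character_, polymer_class = NA_character_,
             mechanism = NA_character_, vinyl_subcategory = "unspecified",
             tagged_smiles = NA_character_, head_atom_index = NA_integer_,
             tail_atom_index = NA_integer_, status = status,
             message = message, stringsAsFactors = FALSE)
}

# decide whether the quantum profile is needed for this resolution
needs_profile <- function(candidates) {
  classes <- unique(vapply(candidates, `[[`, "", "polymer_class"))
  if (length(classes) > 1L) return(TRUE)
  m <- nucleophilic_supports(candidates[[1L]])[[1L]]
  is.na(m$key_atom) && length(m$atom_indices) > 1L
}

process_record <- function(name, raw, kind, cfg, lib, initiators) {
  row <- empty_row(name, raw, "ok")
  monomer <- raw
  subcat <- "unspecified"
  if (kind == "reaction") {
    parts <- parse_reaction_smiles(raw)
    sel <- select_monomer(parts)
    monomer <- sel$monomer_smiles
    row$reaction_mapped <- raw
    row$reaction_unmapped <- strip_atom_maps(raw)
    subcat <- vinyl_subcategory(parts$reactants, initiators)
  }
  row$monomer_smiles <- monomer

  comps <- split_components(monomer)
  per_comp <- lapply(comps, function(cs) match_groups(cs, lib))
  cands <- candidate_classes(per_comp, fix_lactones = cfg$fix_lactones)
  if (length(cands) == 0L) {
    row$status <- "unclassified"
    row$message <- "no functional-group rule licenses a polymer class"
    return(row)
  }

  profiles <- vector("list", length(comps))
  want_q <- switch(cfg$quantum, never = FALSE, always = TRUE,
                   auto = needs_profile(cands))
  if (want_q) {
    involved <- unique(unlist(lapply(cands, function(cand) {
      vapply(cand$supporting_matches, `[[`, 0L, "component")
    })))
    for (ci in involved) {
      profiles[[ci]] <- reactivity_profile(comps[ci], seed = cfg$seed,
                                           basis = cfg$basis,
                                           method = cfg$method,
                                           max_iters = cfg$max_uff_steps)
    }
  }

  assignment <- resolve_class(cands, if (want_q) profiles else NULL)
  if (!identical(assignment$status, "ok")) {
    row$status <- "unclassified"
    return(row)
  }
  row$polymer_class <- assignment$polymer_class
  mech <- assign_mechanism(assignment)
  row$mechanism <- mech$mechanism
  if (assignment$polymer_class == "polyvinyl" && kind == "reaction") {
    row$vinyl_subcategory <- subcat
  }

  # ---- tagging
  supports <- assignment$candidates[[
    which(vapply(assignment$candidates, `[[`, "", "polymer_class") ==
            assignment$polymer_class)[1L]]]$supporting_matches
  involved_comps <- sort(unique(vapply(supports, `[[`, 0L, "component")))

  tag_results <- list()
  if (assignment$polymer_class == "polyurethane") {
    for (ci in involved_comps) {
      tag_results[[as.character(ci)]] <-
        tag_urethane_component(per_comp[[ci]]$info, per_comp[[ci]]$matches)
    }
  } else if (length(involved_comps) > 1L) {
    # condensation copolymer pair: each component tagged as a bifunctional
    for (ci in involved_comps) {
      tag_results[[as.character(ci)]] <-
        tag_bifunctional_component(per_comp[[ci]]$info,
                                   per_comp[[ci]]$matches)
    }
  } else {
    ci <- involved_comps[1L]
    tag_results[[as.character(ci)]] <-
      tag_component(per_comp[[ci]]$info, assignment,
                    per_comp[[ci]]$matches, profiles[[ci]])
  }

  bad <- Filter(function(tr) !identical(tr$status, "ok"), tag_results)
  if (length(bad)) {
    first <- bad[[1L]]
    row$status <- first$status
    row$message <- if (!is.null(first$message)) first$message else ""
    return(row)
  }
  row$tagged_smiles <- paste(vapply(tag_results,
                                    function(tr) tr$tagged$tagged_smiles, ""),
                             collapse = ".")
  first <- tag_results[[1L]]
  row$head_atom_index <- first$head
  row$tail_atom_index <- first$tail
  if (length(tag_results) > 1L) {
    row$message <- paste0("copolymer: head/tail indices refer to component ",
                          names(tag_results)[1L])
  }
  row
}

#' Run the full assignment pipeline
#'
#' For each record: (reaction: select the monomer) -> match functional
#' groups -> derive class candidates -> (when needed) compute the
#' nucleophilicity profile -> resolve class -> assign mechanism (and, for
#' reactions, the vinyl subcategory) -> select head/tail -> apply
#' ring-opening or condensation edits -> emit the tagged repeat unit.
#' Failures are isolated per record: one bad row never aborts the run.
#'
#' @param input Path to an input CSV (see [read_input_csv()]) or a data
#'   frame with columns `polymer_name`, `raw_smiles`/`smiles` and
#'   optionally `record_kind`.
#' @param config See [polytag_config()].
#' @param verbose Print per-record progress.
#' @return Data frame of result rows (columns as in [write_results_csv()]).
#' @export
run_pipeline <- function(input, config = polytag_config(), verbose = FALSE) {
  records <- if (is.character(input)) read_input_csv(input) else input
  if (is.null(records$raw_smiles) && !is.null(records$smiles)) {
    records$raw_smiles <- records$smiles
  }
  if (is.null(records$record_kind)) {
    records$record_kind <- ifelse(grepl(">", records$raw_smiles, fixed = TRUE),
                                  "reaction", "monomer")
  }
  if (is.null(records$valid)) records$valid <- TRUE
  lib <- load_pattern_library(config$patterns)
  initiators <- load_initiators(config$initiators)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    name <- records$polymer_name[i]
    raw <- records$raw_smiles[i]
    if (verbose) message("[", i, "/", nrow(records), "] ", name)
    if (!isTRUE(records$valid[i])) {
      rows[[i]] <- empty_row(name, raw, "error", "unparseable SMILES")
      next
    }
    rows[[i]] <- tryCatch(
      process_record(name, raw, records$record_kind[i], config, lib,
                     initiators),
      error = function(e) {
        msg <- conditionMessage(e)
        status <- if (grepl("unsupported species|open shell", msg)) {
          "unsupported-species"
        } else {
          "error"
        }
        empty_row(name, raw, status, msg)
      })
  }
  do.call(rbind, rows)
}

#' Built-in fixture cases
#'
#' Reference monomers covering all five polymer classes, the ring-opening
#' worked examples, and the two documented cyclic-ester misclassification
#' cases (assigned polyether under default rules, polyester under
#' `fix_lactones`).  Expected tagged SMILES use plain `*` tokens (head/tail
#' numbering collapses in validation).
#'
#' @return Data frame: `polymer_name`, `smiles`, `expected_class`,
#'   `expected_class_fixed` (under `fix_lactones`), `expected_mechanism`,
#'   `expected_tagged`.
#' @export
builtin_fixtures <- function() {
  f <- function(name, smiles, cls, mech, tagged, cls_fixed = cls) {
    data.frame(polymer_name = name, smiles = smiles, expected_class = cls,
               expected_class_fixed = cls_fixed, expected_mechanism = mech,
               expected_tagged = tagged, stringsAsFactors = FALSE)
  }
  rbind(
    f("polyacrylamide", "C=CC(N)=O", "polyvinyl", "polyaddition",
      "*CC(*)C(N)=O"),
    f("polystyrene", "C=Cc1ccccc1", "polyvinyl", "polyaddition",
      "*CC(*)c1ccccc1"),
    f("nylon-10", "NCCCCCCCCCC(=O)O", "polyamide", "polycondensation",
      "*NCCCCCCCCCC(=O)*"),
    f("nylon-3", "O=C1CCN1", "polyamide", "polycondensation",
      "O=C(*)CCN*"),
    f("nylon-6", "O=C1CCCCCN1", "polyamide", "polycondensation",
      "O=C(*)CCCCCN*"),
    f("poly(ethylene glycol)", "C1CO1", "polyether", "ring_opening",
      "*CCO*"),
    f("poly(hexamethylene oxide)", "C1CCCCCO1", "polyether", "ring_opening",
      "*CCCCCCO*"),
    f("poly(propylene glycol)", "CC1CO1", "polyether", "ring_opening",
      "CC(C*)O*"),
    f("poly(3-hydroxybutyrate)", "CC1CC(=O)O1", "polyester", "ring_opening",
      "CC(CC(=O)*)O*"),
    f("polylactic acid", "CC(O)C(=O)O", "polyester", "polycondensation",
      "*OC(C)C(=O)*"),
    f("poly(caprolactone)", "O=C1CCCCCO1", "polyether", "ring_opening",
      "*C(=O)CCCCCO*", cls_fixed = "polyester"),
    f("poly(4-hydroxybutyrate)", "O=C1CCCO1", "polyether", "ring_opening",
      "*C(=O)CCCO*", cls_fixed = "polyester"),
    f("polyurethane-deg-hdi", "OCCOCCO.O=C=NCCCCCCN=C=O", "polyurethane",
      "polycondensation", "*OCCOCCO*.O=C(*)NCCCCCCNC(=O)*"),
    f("PET", "OCCO.O=C(O)c1ccc(C(=O)O)cc1", "polyester", "polycondensation",
      "*OCCO*.O=C(*)c1ccc(C(=O)*)cc1")
  )
}
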