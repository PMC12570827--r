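# Class resolution, mechanism table and vinyl subcategory.
#
# A monomer with one candidate class is assigned directly; competing
# candidates are resolved by the nucleophilicity profile: each candidate is
# scored by the highest R_X over the heavy atoms of its nucleophilic
# supporting matches, and the best-scoring class wins.  Exact score ties
# fall back to a fixed priority order (vinyl first, matching the alkene
# resolution of amide-containing vinyl monomers).

CLASS_PRIORITY <- c(polyvinyl = 1, polyamide = 2, polyester = 3,
                    polyurethane = 4, polyether = 5)

#' Default polymerization-initiator table
#'
#' Canonical textbook initiators per polyaddition subcategory; matching is
#' by exact fingerprint identity, so the table is data, not chemistry rules.
#'
#' @return Named list of SMILES vectors for subcategories `radical`,
#'   `anionic`, `cationic`.
#' @export
default_initiators <- function() {
  list(
    radical = c(
      benzoyl_peroxide = "O=C(OOC(=O)c1ccccc1)c1ccccc1",
      aibn = "CC(C)(C#N)/N=N/C(C)(C)C#N",
      potassium_persulfate = "[K+].[K+].[O-]S(=O)(=O)OOS(=O)(=O)[O-]"
    ),
    anionic = c(
      n_butyllithium = "[Li]CCCC",
      sodium_amide = "[Na+].[NH2-]"
    ),
    cationic = c(
      boron_trifluoride = "FB(F)F",
      sulfuric_acid = "OS(=O)(=O)O",
      aluminum_trichloride = "Cl[Al](Cl)Cl"
    )
  )
}

#' Load an initiator table, optionally from a YAML/JSON override
#' @param config Optional path to a YAML or JSON map
#'   `{radical|anionic|cationic: [SMILES, ...]}`.
#' @return Named list of SMILES vectors.
#' @export
load_initiators <- function(config = NULL) {
  tab <- default_initiators()
  if (is.null(config)) return(tab)
  ext <- tolower(tools::file_ext(config))
  over <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
          else jsonlite::fromJSON(config, simplifyVector = TRUE)
  for (nm in names(over)) tab[[nm]] <- unlist(over[[nm]])
  tab
}

# nucleophilic matches supporting a candidate (falls back to all supports
# for candidates whose rule is keyed on an electrophilic group, e.g. the
# cyclic ester route, where the reacting heteroatom lies inside that match)
nucleophilic_supports <- function(candidate) {
  sup <- candidate$supporting_matches
  nuc <- Filter(function(m) identical(m$role, "nucleophile"), sup)
  if (length(nuc)) nuc else sup
}

#' Resolve the polymer class among candidates
#'
#' With a single candidate the quantum profile is never consulted (and may
#' be NULL).  With several, each candidate scores the maximum R_X over the
#' heavy atoms of its nucleophilic supporting matches; the highest score
#' wins, exact ties broken by the fixed priority polyvinyl > polyamide >
#' polyester > polyurethane > polyether.
#'
#' @param candidates List from [candidate_classes()].
#' @param profiles List of `polytag_profile` (or NULL) per component;
#'   required only when competing candidates must be scored.
#' @return List with `polymer_class`, `winning_match` (the supporting match
#'   containing the selected nucleophilic site), `score` (max R_X or NA),
#'   `candidates`; or `status = "unclassified"` when no candidate exists.
#' @export
resolve_class <- function(candidates, profiles = NULL) {
  if (length(candidates) == 0L) {
    return(list(status = "unclassified", polymer_class = NA_character_))
  }
  pick_match <- function(cand) {
    # representative nucleophilic match: if profiles available use max R_X,
    # else first nucleophilic support
    sups <- nucleophilic_supports(cand)
    if (!is.null(profiles)) {
      best <- NULL; best_rx <- -Inf
      for (m in sups) {
        prof <- profiles[[m$component]]
        if (is.null(prof)) next
        rx <- suppressWarnings(max(profile_rx(prof, m$atom_indices),
                                   na.rm = TRUE))
        if (is.finite(rx) && rx > best_rx) { best_rx <- rx; best <- m }
      }
      if (!is.null(best)) return(list(match = best, score = best_rx))
    }
    list(match = sups[[1L]], score = NA_real_)
  }
  if (length(candidates) == 1L) {
    sel <- pick_match(candidates[[1L]])
    return(list(status = "ok",
                polymer_class = candidates[[1L]]$polymer_class,
                winning_match = sel$match, score = sel$score,
                candidates = candidates))
  }
  if (is.null(profiles) || all(vapply(profiles, is.null, logical(1)))) {
    stop("competing class candidates require reactivity profiles",
         call. = FALSE)
  }
  scored <- lapply(candidates, pick_match)
  scores <- vapply(scored, `[[`, 0, "score")
  prio <- CLASS_PRIORITY[vapply(candidates, `[[`, "", "polymer_class")]
  # highest score wins; ties (within 1e-9) by class priority
  best_score <- max(scores, na.rm = TRUE)
  tied <- which(abs(scores - best_score) < 1e-9)
  winner <- tied[which.min(prio[tied])]
  list(status = "ok",
       polymer_class = candidates[[winner]]$polymer_class,
       winning_match = scored[[winner]]$match,
       score = scores[winner],
       candidates = candidates)
}

#' Assign the polymerization mechanism for a resolved class
#'
#' Fixed table: polyamide and polyurethane condense; polyester condenses
#' unless the winning match sits in a ring (ring-opening); polyether opens
#' a ring; polyvinyl adds across the multiple bond.
#'
#' @param assignment Result of [resolve_class()].
#' @return List with `mechanism` and `vinyl_subcategory` ("unspecified"
#'   unless set later from a reaction record by [vinyl_subcategory()]).
#' @export
assign_mechanism <- function(assignment) {
  cls <- assignment$polymer_class
  mech <- switch(cls,
    polyamide = "polycondensation",
    polyurethane = "polycondensation",
    polyvinyl = "polyaddition",
    polyether = "ring_opening",
    polyester = {
      m <- assignment$winning_match
      if (!is.null(m) && isTRUE(m$in_ring)) "ring_opening"
      else "polycondensation"
    },
    stop("unknown polymer class: ", cls, call. = FALSE)
  )
  list(mechanism = mech, vinyl_subcategory = "unspecified")
}

#' Identify the polyaddition subcategory from reaction reactants
#'
#' Each reactant is fingerprint-compared against the initiator table; only
#' an exact match (Tanimoto similarity of 1.0) assigns a subcategory, first
#' match in table order wins.
#'
#' @param reactants Character vector of reactant SMILES.
#' @param initiators Table from [load_initiators()].
#' @return One of "radical", "anionic", "cationic", "unspecified".
#' @export
vinyl_subcategory <- function(reactants, initiators = load_initiators()) {
  if (length(reactants) == 0L) return("unspecified")
  fps <- lapply(reactants, function(r) {
    tryCatch(topological_fingerprint(r), error = function(e) NULL)
  })
  for (sub in names(initiators)) {
    for (ini in initiators[[sub]]) {
      fp_ini <- tryCatch(topological_fingerprint(ini),
                         error = function(e) NULL)
      if (is.null(fp_ini)) next
      for (fp in fps) {
        if (!is.null(fp) && tanimoto(fp, fp_ini) == 1.0) return(sub)
      }
    }
  }
  "unspecified"
}
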