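# Head/tail selection, ring opening, condensation edits and tagging.
#
# All edits are molecular-graph operations (delete a bond, change a bond
# order, delete a leaving group, attach a wildcard atom); the edited graph
# is re-sanitized, so a valence-violating output can never be emitted as a
# success.  Tag numbering convention: head [*:1] / tail [*:2] for
# condensation and vinyl routes; for ring-opened units the carbon end
# carries [*:1] and the heteroatom end [*:2] (validation collapses the two
# tokens, so the numbering is cosmetic).

# ---- small graph helpers on a mol_info record -----------------------------

atom_rec <- function(info, idx0) info$atoms[[idx0 + 1L]]

neighbors0 <- function(info, idx0) {
  nb <- integer()
  for (b in info$bonds) {
    if (b$begin == idx0) nb <- c(nb, b$end)
    if (b$end == idx0) nb <- c(nb, b$begin)
  }
  nb
}

bond_between <- function(info, i0, j0) {
  for (b in info$bonds) {
    if ((b$begin == i0 && b$end == j0) || (b$begin == j0 && b$end == i0)) {
      return(b)
    }
  }
  NULL
}

# carbon with a double-bonded exocyclic O (acyl / carbonyl carbon)?
is_acyl_carbon <- function(info, idx0) {
  a <- atom_rec(info, idx0)
  if (a$symbol != "C") return(FALSE)
  for (nb in neighbors0(info, idx0)) {
    b <- bond_between(info, idx0, nb)
    if (atom_rec(info, nb)$symbol == "O" && b$order == 2) return(TRUE)
  }
  FALSE
}

heavy_atoms_of <- function(info, idx0s) {
  idx0s[vapply(idx0s, function(i) atom_rec(info, i)$atomic_num > 1,
               logical(1))]
}

# ---- head and tail selection ----------------------------------------------

#' Select the head atom of a polymerizing component
#'
#' The head is the most nucleophilic heavy atom of the winning match: the
#' arg-max of R_X over the match's heavy atoms when a reactivity profile is
#' available (ties by lower canonical index), otherwise the pattern's
#' designated nucleophilic key atom (amine N, hydroxyl/alcohol O, ring
#' heteroatom), which is where the HOMO concentrates for these groups.
#'
#' @param assignment Result of [resolve_class()] (provides `winning_match`).
#' @param profile `polytag_profile` for the component, or NULL.
#' @param info [mol_info()] record of the component.
#' @return 0-based canonical atom index.
#' @export
select_head_atom <- function(assignment, profile = NULL, info) {
  m <- assignment$winning_match
  heavy <- heavy_atoms_of(info, m$atom_indices)
  if (length(heavy) == 0L) {
    stop("winning match contains no heavy atom", call. = FALSE)
  }
  # eligible head sites: the pattern's designated nucleophilic atom when it
  # has one (amine N, hydroxyl O, ring heteroatom), else every heavy atom of
  # the match (alkene/alkyne, where either carbon can start the chain)
  eligible <- if (!is.na(m$key_atom)) m$key_atom else heavy
  if (length(eligible) > 1L && !is.null(profile)) {
    rx <- profile_rx(profile, eligible)
    if (anyNA(rx)) stop("reactivity profile lacks atoms of the winning match",
                        call. = FALSE)
    return(eligible[order(-rx, eligible)][1L])
  }
  sort(eligible)[1L]
}

#' Select the tail atom given the head
#'
#' polyvinyl: the other atom of the reacting multiple bond; condensation
#' routes: the acyl carbon of the carboxylic acid / acyl halide; ring
#' routes: the ring atom across the bond chosen by [open_ring()].
#'
#' @param assignment Result of [resolve_class()].
#' @param matches All matches of the component (from [match_groups()]).
#' @param head 0-based head index.
#' @param info [mol_info()] record.
#' @return List with `tail` (0-based index or NA), `route`
#'   ("vinyl"/"condensation"/"ring"), `leaving` (atom indices to delete) and
#'   `ring_bond` (c(i, j) to delete, ring route only); `status` is
#'   "tail-unassigned" when no electrophilic site exists.
#' @export
select_tail_atom <- function(assignment, matches, head, info) {
  cls <- assignment$polymer_class
  m <- assignment$winning_match
  if (cls == "polyvinyl") {
    paira <- heavy_atoms_of(info, m$atom_indices)
    tail <- setdiff(paira, head)[1L]
    return(list(tail = tail, route = "vinyl", leaving = integer(),
                status = "ok"))
  }
  head_in_ring <- isTRUE(atom_rec(info, head)$in_ring)
  if (head_in_ring && cls %in% c("polyether", "polyamide", "polyester")) {
    ob <- open_ring(info, head, cls)
    if (!is.null(ob$status) && ob$status != "ok") {
      return(list(tail = NA_integer_, route = "ring", leaving = integer(),
                  status = ob$status))
    }
    tail <- setdiff(ob$bond, head)
    return(list(tail = tail, route = "ring", leaving = integer(),
                ring_bond = ob$bond, status = "ok"))
  }
  # condensation: acyl carbon of an acid or acyl halide, plus its leaving group
  elec <- Filter(function(x) x$pattern_name %in%
                   c("carboxylic_acid", "acyl_halide"), matches)
  if (length(elec) == 0L) {
    return(list(tail = NA_integer_, route = "condensation",
                leaving = integer(), status = "tail-unassigned"))
  }
  e <- elec[[1L]]
  tail <- e$atom_indices[1L]           # SMARTS atom order: C, =O, OH/X
  leaving <- e$atom_indices[3L]
  list(tail = tail, route = "condensation", leaving = leaving, status = "ok")
}

#' Choose the ring bond to delete when opening a cyclic monomer
#'
#' Exactly one ring bond incident to the ring heteroatom is deleted: the
#' heteroatom-acyl bond for lactones/lactams (the bond broken by acyl
#' substitution), otherwise the heteroatom-carbon bond on the
#' less-substituted side (fewer heavy neighbors; ties by lower canonical
#' index), so e.g. a methyl-substituted epoxide opens away from the
#' substituent.
#'
#' @param info [mol_info()] record.
#' @param head 0-based ring-heteroatom index.
#' @param class Polymer class (unused in the choice itself; kept for
#'   interface clarity).
#' @return List with `bond` = c(head, neighbor) or `status` in
#'   "not-in-ring"/"unsupported-topology".
#' @export
open_ring <- function(info, head, class = NULL) {
  a <- atom_rec(info, head)
  if (!isTRUE(a$in_ring)) {
    warning("head atom is not in a ring; no ring opening performed")
    return(list(status = "not-in-ring"))
  }
  if (a$n_rings > 1L) return(list(status = "unsupported-topology"))
  ring_nb <- Filter(function(nb) {
    b <- bond_between(info, head, nb)
    isTRUE(b$in_ring) && atom_rec(info, nb)$n_rings <= 1L
  }, neighbors0(info, head))
  ring_nb <- unlist(ring_nb)
  if (length(ring_nb) == 0L) return(list(status = "unsupported-topology"))
  acyl <- ring_nb[vapply(ring_nb, function(nb) is_acyl_carbon(info, nb),
                         logical(1))]
  pick <- if (length(acyl)) {
    acyl[1L]
  } else {
    deg <- vapply(ring_nb, function(nb) atom_rec(info, nb)$heavy_degree, 0)
    ring_nb[order(deg, ring_nb)][1L]
  }
  list(bond = c(head, pick), status = "ok")
}

#' Derive the condensation edits for an acyclic monomer
#'
#' The leaving hydroxyl (or halide) is deleted at the tail acyl carbon; the
#' head heteroatom loses one hydrogen implicitly when the tag bond is
#' attached.  Net heavy-atom loss equals the leaving group only.
#'
#' @param info [mol_info()] record.
#' @param head,tail 0-based indices.
#' @param leaving Atom indices to delete (from [select_tail_atom()]).
#' @return List of edit ops (`remove_atoms`) or `status = "edit-failed"`
#'   when the tail lacks a leaving group.
#' @export
apply_condensation_edits <- function(info, head, tail, leaving) {
  if (length(leaving) == 0L) {
    tl <- atom_rec(info, tail)
    nb_ok <- any(vapply(neighbors0(info, tail), function(nb) {
      a <- atom_rec(info, nb)
      b <- bond_between(info, tail, nb)
      (a$symbol == "O" && a$n_h >= 1L && b$order == 1) ||
        a$symbol %in% c("F", "Cl", "Br", "I")
    }, logical(1)))
    if (!nb_ok || tl$symbol != "C") return(list(status = "edit-failed"))
  }
  list(remove_atoms = as.list(leaving), status = "ok")
}

#' Execute graph edits and emit the tagged repeat-unit SMILES
#'
#' Applies bond-order changes, bond/atom deletions and the two wildcard
#' tags, re-sanitizes, and canonicalizes.  Outputs that fail valence
#' sanitization come back with `is_valid = FALSE` and a diagnostic; they are
#' never silently returned as success.
#'
#' @param smiles Canonical component SMILES the edit indices refer to.
#' @param head,tail 0-based atom indices receiving `[*:1]` and `[*:2]`.
#' @param set_bonds List of `c(i, j, order)` bond-order changes.
#' @param remove_bonds List of `c(i, j)` bond deletions.
#' @param remove_atoms Atom indices to delete.
#' @param head_tag,tail_tag Map numbers for head and tail (default 1, 2).
#' @return List: `tagged_smiles`, `canonical_form` (tags collapsed to `*`),
#'   `is_valid`, `n_heavy`, `error`.
#' @export
tag_monomer <- function(smiles, head, tail, set_bonds = list(),
                        remove_bonds = list(), remove_atoms = list(),
                        head_tag = 1L, tail_tag = 2L) {
  op <- list(op = "edit", smiles = smiles,
             set_bonds = lapply(set_bonds, as.integer),
             remove_bonds = lapply(remove_bonds, as.integer),
             remove_atoms = lapply(remove_atoms, as.integer),
             add_tags = list(c(as.integer(head), as.integer(head_tag)),
                             c(as.integer(tail), as.integer(tail_tag))))
  res <- bridge_call(list(op))[[1L]]
  if (!isTRUE(res$ok)) {
    return(list(tagged_smiles = NA_character_, canonical_form = NA_character_,
                is_valid = FALSE, error = res$error))
  }
  if (!isTRUE(res$valid)) {
    return(list(tagged_smiles = NA_character_, canonical_form = NA_character_,
                is_valid = FALSE, error = res$error))
  }
  list(tagged_smiles = res$tagged_smiles,
       canonical_form = collapse_tokens(res$tagged_smiles),
       is_valid = TRUE, n_heavy = res$n_heavy, error = NA_character_)
}

# ---- per-component tagging driver -----------------------------------------

# Tag one polymerizing component for a resolved class.  Returns
# list(tagged, head, tail, status, message).
tag_component <- function(info, assignment, matches, profile = NULL) {
  cls <- assignment$polymer_class
  head <- tryCatch(select_head_atom(assignment, profile, info),
                   error = function(e) NA_integer_)
  if (is.na(head)) {
    return(list(status = "error", message = "head selection failed"))
  }
  sel <- select_tail_atom(assignment, matches, head, info)
  if (sel$status != "ok") {
    return(list(status = sel$status, head = head,
                message = paste("tail selection:", sel$status)))
  }
  tail <- sel$tail
  if (identical(sel$route, "vinyl")) {
    b <- bond_between(info, head, tail)
    new_order <- b$order - 1L
    tm <- tag_monomer(info$canonical_smiles, head, tail,
                      set_bonds = list(c(head, tail, new_order)))
  } else if (identical(sel$route, "ring")) {
    # carbon end gets [*:1], heteroatom end [*:2]
    tm <- tag_monomer(info$canonical_smiles, head = tail, tail = head,
                      remove_bonds = list(sel$ring_bond))
  } else {
    ed <- apply_condensation_edits(info, head, tail, sel$leaving)
    if (!identical(ed$status, "ok")) {
      return(list(status = "edit-failed", head = head, tail = tail,
                  message = "tail carbon lacks a leaving hydroxyl/halide"))
    }
    tm <- tag_monomer(info$canonical_smiles, head, tail,
                      remove_atoms = ed$remove_atoms)
  }
  if (!isTRUE(tm$is_valid)) {
    return(list(status = "error", head = head, tail = tail,
                message = paste("sanitization failed:", tm$error)))
  }
  list(status = "ok", head = head, tail = tail, tagged = tm)
}

# Polyurethane route: tag each component as a polymerized entity.
# Diols: both hydroxyl hydrogens replaced by tags.  Diisocyanates: each
# N=C=O carbon gains a tag bond and its nitrogen a hydrogen (the
# urethane-forming addition).
tag_urethane_component <- function(info, matches) {
  oh <- Filter(function(m) m$pattern_name == "hydroxyl", matches)
  nco <- Filter(function(m) m$pattern_name == "isocyanate", matches)
  if (length(oh) >= 2L) {
    sites <- vapply(oh, `[[`, 0L, "key_atom")[1:2]
    tm <- tag_monomer(info$canonical_smiles, sites[1L], sites[2L])
    return(list(status = if (tm$is_valid) "ok" else "error",
                head = sites[1L], tail = sites[2L], tagged = tm,
                message = tm$error))
  }
  if (length(nco) >= 2L) {
    carbons <- vapply(nco, function(m) m$atom_indices[2L], 0L)[1:2]
    set_bonds <- lapply(nco[1:2], function(m) {
      c(m$atom_indices[1L], m$atom_indices[2L], 1L)  # N=C -> N-C
    })
    tm <- tag_monomer(info$canonical_smiles, carbons[1L], carbons[2L],
                      set_bonds = set_bonds)
    return(list(status = if (tm$is_valid) "ok" else "error",
                head = carbons[1L], tail = carbons[2L], tagged = tm,
                message = tm$error))
  }
  list(status = "tail-unassigned",
       message = "polyurethane component lacks two hydroxyl/isocyanate sites")
}

# Condensation copolymer component with two like groups (diamine, diacid,
# diol): tag the two nucleophilic heteroatoms, or the two acyl carbons with
# both leaving hydroxyls/halides removed.
tag_bifunctional_component <- function(info, matches) {
  nuc <- Filter(function(m) m$pattern_name %in%
                  c("primary_amine", "aliphatic_alcohol"), matches)
  elec <- Filter(function(m) m$pattern_name %in%
                   c("carboxylic_acid", "acyl_halide"), matches)
  if (length(nuc) >= 2L) {
    sites <- vapply(nuc, `[[`, 0L, "key_atom")[1:2]
    tm <- tag_monomer(info$canonical_smiles, sites[1L], sites[2L])
    return(list(status = if (tm$is_valid) "ok" else "error",
                head = sites[1L], tail = sites[2L], tagged = tm,
                message = tm$error))
  }
  if (length(elec) >= 2L) {
    carbons <- vapply(elec, function(m) m$atom_indices[1L], 0L)[1:2]
    leaving <- vapply(elec, function(m) m$atom_indices[3L], 0L)[1:2]
    tm <- tag_monomer(info$canonical_smiles, carbons[1L], carbons[2L],
                      remove_atoms = as.list(leaving))
    return(list(status = if (tm$is_valid) "ok" else "error",
                head = carbons[1L], tail = carbons[2L], tagged = tm,
                message = tm$error))
  }
  list(status = "tail-unassigned",
       message = "component lacks a tag-able functional-group pair")
}
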