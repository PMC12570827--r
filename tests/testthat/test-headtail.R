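# Ring opening, condensation edits, tagging contracts.

with_groups <- function(smiles) match_groups(smiles, load_pattern_library())

test_that("ring opening breaks the heteroatom bond on the right side", {
  # propylene oxide: break away from the methyl-substituted carbon
  mg <- with_groups("CC1CO1")
  o_idx <- which(vapply(mg$info$atoms, `[[`, "", "symbol") == "O") - 1L
  ob <- open_ring(mg$info, o_idx)
  expect_equal(ob$status, "ok")
  other <- setdiff(ob$bond, o_idx)
  expect_equal(mg$info$atoms[[other + 1]]$heavy_degree, 2L)  # CH2, not CH(CH3)

  # beta-butyrolactone: acyl-O cleavage wins over the alkyl side
  mg2 <- with_groups("CC1CC(=O)O1")
  ring_o <- which(vapply(seq_along(mg2$info$atoms), function(i) {
    a <- mg2$info$atoms[[i]]
    a$symbol == "O" && isTRUE(a$in_ring)
  }, logical(1))) - 1L
  ob2 <- open_ring(mg2$info, ring_o)
  other2 <- setdiff(ob2$bond, ring_o)
  expect_true(polytag:::is_acyl_carbon(mg2$info, other2))

  # head not in a ring: warning and no-op status
  mg3 <- with_groups("CCO")
  expect_warning(res <- open_ring(mg3$info, 2L), "not in a ring")
  expect_equal(res$status, "not-in-ring")

  # fused/bridged heteroatom is refused, not guessed
  mg4 <- with_groups("C1CC2CCC1O2")   # bridged bicyclic ether
  o4 <- which(vapply(mg4$info$atoms, `[[`, "", "symbol") == "O") - 1L
  expect_equal(open_ring(mg4$info, o4)$status, "unsupported-topology")
})

test_that("condensation edits remove exactly the leaving group", {
  rows <- run_pipeline(fixture_records("polylactic acid"))
  expect_equal(rows$status, "ok")
  # lactic acid C3O3 loses one O: repeat unit has 5 heavy atoms
  info <- mol_info(gsub("\\[\\*:[0-9]+\\]", "", "CC(O)C(=O)O"))
  collapsed <- collapse_tokens(rows$tagged_smiles)
  unit <- mol_info(collapsed)
  # wildcards are not heavy atoms; the unit lost exactly the leaving O
  expect_equal(unit$n_heavy, info$n_heavy - 1L)

  # a tail carbon without OH/halide fails the precondition
  mg <- with_groups("NCCC=O")  # aldehyde, no acid
  ed <- apply_condensation_edits(mg$info, head = 0L, tail = 3L,
                                 leaving = integer())
  expect_equal(ed$status, "edit-failed")
})

test_that("tagging emits exactly one head and one tail tag per unit and
           never an invalid SMILES", {
  fx <- builtin_fixtures()
  rows <- run_pipeline(fixture_records(
    c("poly(propylene glycol)", "nylon-3", "polyacrylamide")))
  for (i in seq_len(nrow(rows))) {
    expect_equal(rows$status[i], "ok")
    tagged <- rows$tagged_smiles[i]
    expect_equal(lengths(regmatches(tagged, gregexpr("\\[\\*:1\\]", tagged))),
                 1L)
    expect_equal(lengths(regmatches(tagged, gregexpr("\\[\\*:2\\]", tagged))),
                 1L)
    # parses and re-canonicalizes to itself
    expect_identical(canonical_smiles(tagged), tagged)
  }
})

test_that("heavy atoms are conserved through ring opening", {
  for (smiles in c("C1CO1", "CC1CO1", "C1CCCCCO1", "O=C1CCN1")) {
    rows <- run_pipeline(data.frame(polymer_name = smiles,
                                    raw_smiles = smiles,
                                    stringsAsFactors = FALSE))
    expect_equal(rows$status, "ok")
    pre <- mol_info(smiles)$n_heavy
    post <- mol_info(collapse_tokens(rows$tagged_smiles))$n_heavy
    expect_equal(post, pre)   # wildcards are not heavy; nothing lost
  }
})

test_that("polyvinyl tags sit on the formerly unsaturated adjacent carbons", {
  rows <- run_pipeline(fixture_records("polyacrylamide"))
  info <- mol_info(rows$tagged_smiles)
  stars <- which(vapply(info$atoms, `[[`, 0, "atomic_num") == 0) - 1L
  carriers <- vapply(stars, function(s) {
    polytag:::neighbors0(info, s)[1]
  }, 0L)
  b <- polytag:::bond_between(info, carriers[1], carriers[2])
  expect_false(is.null(b))        # tagged atoms are adjacent
  expect_equal(b$order, 1L)       # double bond was reduced
  # an alkyne reduces to a double bond instead
  rows2 <- run_pipeline(data.frame(polymer_name = "polyacetylene",
                                   raw_smiles = "C#C",
                                   stringsAsFactors = FALSE))
  expect_equal(rows2$polymer_class, "polyvinyl")
  info2 <- mol_info(rows2$tagged_smiles)
  cc <- Filter(function(bd) {
    info2$atoms[[bd$begin + 1]]$atomic_num == 6 &&
      info2$atoms[[bd$end + 1]]$atomic_num == 6
  }, info2$bonds)
  expect_equal(cc[[1]]$order, 2L)
})

test_that("urethane components are tagged as polymerized entities", {
  rows <- run_pipeline(fixture_records("polyurethane-deg-hdi"))
  expect_equal(rows$status, "ok")
  comps <- split_components(rows$tagged_smiles)
  expect_length(comps, 2L)
  for (comp in comps) {
    expect_equal(lengths(regmatches(comp, gregexpr("\\[\\*:", comp))), 2L)
  }
  # the diisocyanate component gained N-H (urethane addition): no N=C=O left
  di <- comps[grepl("N", comps)][1]
  expect_false(grepl("N=C=O", di))
})
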