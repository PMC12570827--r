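# Functional-group library and polymer-class candidate rules.

test_that("default pattern library loads, overrides apply, bad SMARTS error", {
  lib <- load_pattern_library()
  expect_length(lib, 11L)
  expect_setequal(vapply(lib, `[[`, "", "name"),
                  c("alkene", "alkyne", "primary_amine", "carboxylic_acid",
                    "acyl_halide", "secondary_amide", "heterocycle",
                    "aliphatic_alcohol", "ether", "hydroxyl", "isocyanate"))

  over <- tempfile(fileext = ".yaml")
  writeLines(c("- name: alkene", "  smarts: '[CX3]=[CX3][!O]'",
               "  role: nucleophile"), over)
  lib2 <- load_pattern_library(over)
  alkene <- lib2[[which(vapply(lib2, `[[`, "", "name") == "alkene")]]
  expect_equal(alkene$smarts, "[CX3]=[CX3][!O]")

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("- name: alkene", "  smarts: 'C('"), bad)
  expect_error(load_pattern_library(bad), "compile")
})

test_that("group matching finds the documented groups with atom indices", {
  lib <- load_pattern_library()

  nylon <- match_groups("NCCCCCCCCCC(=O)O", lib)
  nms <- unique(vapply(nylon$matches, `[[`, "", "pattern_name"))
  expect_true(all(c("primary_amine", "carboxylic_acid") %in% nms))
  amine <- Filter(function(m) m$pattern_name == "primary_amine",
                  nylon$matches)[[1]]
  expect_equal(nylon$info$atoms[[amine$key_atom + 1]]$symbol, "N")

  acryl <- match_groups("C=CC(N)=O", lib)
  nms2 <- vapply(acryl$matches, `[[`, "", "pattern_name")
  expect_true("alkene" %in% nms2)
  expect_true("primary_amine" %in% nms2)  # the amide NH2 matches the N pattern

  expect_length(match_groups("CCCC", lib)$matches, 0L)

  # all reported indices are in bounds and hits are deduplicated
  eth <- match_groups("CCOCC", lib)
  for (m in eth$matches) {
    expect_true(all(m$atom_indices >= 0 &
                      m$atom_indices < length(eth$info$atoms)))
  }
  keysets <- vapply(eth$matches, function(m) {
    paste(m$pattern_name, paste(sort(m$atom_indices), collapse = ","))
  }, "")
  expect_equal(anyDuplicated(keysets), 0L)
})

candidates_for <- function(smiles, fix_lactones = FALSE) {
  lib <- load_pattern_library()
  per <- lapply(split_components(smiles), match_groups, library = lib)
  cands <- candidate_classes(per, fix_lactones = fix_lactones)
  vapply(cands, `[[`, "", "polymer_class")
}

test_that("class rules reproduce the documented assignments", {
  expect_equal(candidates_for("C1CO1"), "polyether")
  expect_true("polyamide" %in% candidates_for("NCCCCCCCCCC(=O)O"))
  expect_equal(candidates_for("C=CC(N)=O"), "polyvinyl")
  # caprolactone: cyclic ester looks like a ring ether, no free acid
  expect_equal(candidates_for("O=C1CCCCCO1"), "polyether")
  expect_equal(candidates_for("O=C1CCCO1"), "polyether")
  # strained 4-ring lactone also licenses polyester
  expect_setequal(candidates_for("CC1CC(=O)O1"), c("polyester", "polyether"))
  # lactam via in-ring secondary amide
  expect_equal(candidates_for("O=C1CCCCCN1"), "polyamide")
  # two-component polyurethane
  expect_equal(candidates_for("OCCOCCO.O=C=NCCCCCCN=C=O"), "polyurethane")
  # hydroxyl alone licenses nothing
  expect_length(candidates_for("OCCOCCO"), 0L)
  # fix_lactones extends polyester to every lactone
  expect_true("polyester" %in% candidates_for("O=C1CCCCCO1",
                                              fix_lactones = TRUE))
})

test_that("candidate sets are invariant to SMILES rewriting and inert
           substituents", {
  # same molecule, different atom orders
  expect_equal(candidates_for("C1OC1"), candidates_for("C1CO1"))
  expect_equal(candidates_for("OC(=O)CCCCCCCCCN"),
               candidates_for("NCCCCCCCCCC(=O)O"))
  # adding a methyl does not change the licensed classes
  expect_equal(candidates_for("CC1CO1"), candidates_for("C1CO1"))
  expect_equal(candidates_for("CC(O)C(=O)O"), candidates_for("OCC(=O)O"))
})

test_that("every candidate's supporting matches satisfy its rule on
           re-check", {
  lib <- load_pattern_library()
  for (smiles in c("NCCCCCCCCCC(=O)O", "C1CO1", "CC1CC(=O)O1",
                   "OCCOCCO.O=C=NCCCCCCN=C=O")) {
    per <- lapply(split_components(smiles), match_groups, library = lib)
    for (cand in candidate_classes(per)) {
      sup_names <- vapply(cand$supporting_matches, `[[`, "", "pattern_name")
      ok <- switch(cand$polymer_class,
        polyvinyl = any(sup_names %in% c("alkene", "alkyne")),
        polyamide = (("primary_amine" %in% sup_names) &&
                       any(c("carboxylic_acid", "acyl_halide") %in%
                             sup_names)) ||
                    "secondary_amide" %in% sup_names,
        polyester = ("carboxylic_acid" %in% sup_names &&
                       "aliphatic_alcohol" %in% sup_names) ||
                    "lactone" %in% sup_names ||
                    "carboxylic_acid" %in% sup_names,
        polyether = all(sup_names == "ether"),
        polyurethane = all(c("hydroxyl", "isocyanate") %in% sup_names))
      expect_true(ok, info = paste(smiles, cand$polymer_class))
      if (cand$polymer_class == "polyurethane") {
        comps <- vapply(cand$supporting_matches, `[[`, 0L, "component")
        expect_gt(length(unique(comps)), 1L)
      }
    }
  }
})
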