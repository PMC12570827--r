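# Token collapse, comparison, dataset scoring, pipeline behavior.

test_that("token collapse makes head/tail numbering irrelevant", {
  a <- collapse_tokens("CC(C[*:1])O[*:2]")
  b <- collapse_tokens("CC(C[*:2])O[*:1]")
  expect_identical(a, b)
  # the documented propylene glycol mismatch stays a mismatch
  wrong <- collapse_tokens("CC(C([*:2])O([*:1]))")
  expect_false(identical(wrong, a))
  # a valence-violating string is incomparable
  expect_true(is.na(collapse_tokens("CCCC(=O)([*:2])O([*:1])")))
  # plain * tokens are accepted on input
  expect_identical(collapse_tokens("CC(C*)O*"), a)
})

test_that("assignment comparison is reflexive, symmetric, and strict", {
  p <- "CC(C[*:1])O[*:2]"
  expect_true(compare_assignment(p, p))
  expect_true(compare_assignment(p, "CC(C[*:2])O[*:1]"))
  expect_equal(compare_assignment(p, "CC(C*)O*"),
               compare_assignment("CC(C*)O*", p))
  expect_false(compare_assignment(p, "CC(CC[*:1])O[*:2]"))  # extra methyl
  expect_false(compare_assignment("CCCC(=O)([*:2])O([*:1])", p))
})

test_that("dataset scoring aligns by name and reports accuracies", {
  pred <- data.frame(
    polymer_name = c("a", "b", "c", "d"),
    tagged_smiles = c("*CCO*", "CC(C*)O*", "*CC(*)C(N)=O", "*CCCCO*"),
    polymer_class = c("polyether", "polyether", "polyvinyl", "polyether"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    polymer_name = c("d", "c", "b", "a"),   # shuffled on purpose
    tagged_smiles = c("*CCCCO*", "[*:1]CC([*:2])C(N)=O", "CC(C[*:2])O[*:1]",
                      "*CCO*"),
    polymer_class = c("polyether", "polyvinyl", "polyether", "polyether"),
    stringsAsFactors = FALSE)
  rep <- score_dataset(pred, truth)
  expect_equal(rep$headtail_accuracy, 1.0)
  expect_equal(rep$class_accuracy, 1.0)
  expect_equal(sum(vapply(rep$per_class, `[[`, 0, "n")), 4)

  truth$tagged_smiles[1] <- "*CCCO*"
  rep2 <- score_dataset(pred, truth)
  expect_equal(rep2$headtail_accuracy, 0.75)

  expect_error(score_dataset(rbind(pred, pred[1, ]), truth), "duplicate")
  truth2 <- truth; truth2$polymer_name <- c("x", "y", "z", "w")
  expect_error(score_dataset(pred, truth2), "in common")
})

test_that("one bad record changes exactly its own row", {
  base <- fixture_records(c("poly(ethylene glycol)", "polylactic acid"))
  poisoned <- rbind(base,
                    data.frame(polymer_name = "broken", raw_smiles = "C1CC",
                               stringsAsFactors = FALSE))
  poisoned$valid <- c(TRUE, TRUE, FALSE)
  rows <- run_pipeline(poisoned)
  expect_equal(rows$status, c("ok", "ok", "error"))
  clean <- run_pipeline(base)
  expect_equal(rows$tagged_smiles[1:2], clean$tagged_smiles)
})

test_that("radical monomers surface as unsupported species rows", {
  rows <- run_pipeline(data.frame(polymer_name = "methyl radical",
                                  raw_smiles = "C=C[CH2]",
                                  stringsAsFactors = FALSE))
  expect_equal(rows$status, "unsupported-species")
})

test_that("reaction records select the monomer and spot the initiator", {
  rx <- paste0("C=Cc1ccccc1.O=C(OOC(=O)c1ccccc1)c1ccccc1",
               ">>CC(c1ccccc1)CC(C)c1ccccc1")
  rows <- run_pipeline(data.frame(polymer_name = "polystyrene-rxn",
                                  raw_smiles = rx, stringsAsFactors = FALSE))
  expect_equal(rows$status, "ok")
  expect_equal(rows$monomer_smiles, "C=Cc1ccccc1")
  expect_equal(rows$polymer_class, "polyvinyl")
  expect_equal(rows$vinyl_subcategory, "radical")
  expect_equal(rows$reaction_mapped, rx)
  # atom-map stripping only affects mapped strings
  rx2 <- "[CH2:1]=[CH2:2]>>[CH2:1][CH2:2]"
  rows2 <- run_pipeline(data.frame(polymer_name = "pe",
                                   raw_smiles = rx2,
                                   stringsAsFactors = FALSE))
  expect_false(grepl(":", rows2$reaction_unmapped))
})

test_that("pipeline reruns with one seed are byte-identical", {
  recs <- fixture_records(c("poly(propylene glycol)", "polylactic acid",
                            "nylon-3"))
  cfg <- polytag_config(seed = 7L)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  polytag_clear_cache()
  write_results_csv(run_pipeline(recs, cfg), f1)
  polytag_clear_cache()
  write_results_csv(run_pipeline(recs, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fixtures are self-consistent", {
  fx <- builtin_fixtures()
  expect_gte(nrow(fx), 10L)
  expect_setequal(unique(fx$expected_class),
                  c("polyvinyl", "polyamide", "polyester", "polyether",
                    "polyurethane"))
  # every expected tagged SMILES parses after token collapse
  for (tagged in fx$expected_tagged) {
    expect_false(is.na(collapse_tokens(tagged)))
  }
  # the worked ring-opening example is present token-equivalently
  expect_true(any(vapply(fx$expected_tagged, function(t) {
    compare_assignment("[*:1]CCCCCCO[*:2]", t)
  }, logical(1))))
  # both documented misclassification monomers are present
  expect_true(all(c("poly(caprolactone)", "poly(4-hydroxybutyrate)") %in%
                    fx$polymer_name))
})
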