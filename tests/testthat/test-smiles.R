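# Strict SMILES parsing, the valence model, and canonicalization.

test_that("tokenizer splits atoms, bonds, rings and branches correctly", {
  toks <- smi_tokenize("CC(=O)[O-]")
  expect_equal(toks$text, c("C", "C", "(", "=", "O", ")", "[O-]"))
  expect_equal(toks$kind, c("atom", "atom", "open", "bond", "atom", "close", "atom"))
  expect_equal(smi_tokenize("Clc1ccccc1")$text[1], "Cl")
  expect_equal(smi_tokenize("C%12CCCCCCCCCC%12")$text[2], "%12")
})

test_that("malformed strings are rejected with the offending string named", {
  for (bad in c("C(", "(((", "C1CC", "CC)", "C==C", "C[XyzQ]1", "[#$]", "C%1")) {
    err <- tryCatch({ smi_parse(bad); NULL }, error = function(e) e)
    expect_s3_class(err, "ocsr_smiles_error")
    expect_match(conditionMessage(err), bad, fixed = TRUE)
  }
})

test_that("parser builds the expected molecular graph", {
  mol <- smi_parse("CC(=O)O")
  expect_equal(nrow(mol$atoms), 4L)
  expect_equal(nrow(mol$bonds), 3L)
  expect_equal(mol$bonds$order[mol$bonds$symbol == "="], 2)
  ring <- smi_parse("c1ccccc1")
  expect_equal(sum(ring$bonds$ring), 1L)
  expect_true(all(ring$atoms$aromatic))
  expect_equal(nrow(ring$bonds), 6L)
})

test_that("bracket atoms carry isotope, charge and hydrogen count", {
  mol <- smi_parse("[13CH3+][2H]")
  expect_equal(mol$atoms$isotope, c(13L, 2L))
  expect_equal(mol$atoms$charge, c(1L, 0L))
  expect_equal(mol$atoms$hcount, c(3L, 0L))
  expect_equal(smi_parse("[O-]")$atoms$charge, -1L)
  expect_equal(smi_parse("[Fe+2]")$atoms$charge, 2L)
})

test_that("implicit hydrogen counts follow the organic-subset convention", {
  expect_equal(smi_implicit_h(smi_parse("C")), 4L)
  expect_equal(smi_implicit_h(smi_parse("CCO")), c(3L, 2L, 1L))
  expect_equal(smi_implicit_h(smi_parse("c1ccccc1")), rep(1L, 6L))
  expect_equal(smi_implicit_h(smi_parse("C1C=CC=CC=1")), rep(1L, 6L))
  expect_equal(smi_implicit_h(smi_parse("[CH3]C")), c(3L, 3L))
  expect_equal(smi_implicit_h(smi_parse("N#N")), c(0L, 0L))
  # fused aromatic carbons carry no hydrogen
  naph <- smi_implicit_h(smi_parse("c1ccc2ccccc2c1"))
  expect_equal(sum(naph == 0L), 2L)
})

test_that("canonicalize maps equivalent spellings to one string and is idempotent", {
  expect_equal(canonicalize("OCC"), canonicalize("CCO"))
  expect_equal(canonicalize("C1=CC=CC=C1"), canonicalize("c1ccccc1"))
  for (s in c("CCO", "c1ccccc1", "CC(=O)OC1=CC=CC=C1C(=O)O",
              "C1=CC=C(C=C1)CC2=CC=CC=C2")) {
    for (form in c("aromatic", "kekule")) {
      can <- canonicalize(s, form)
      expect_identical(canonicalize(can, form), can)
    }
  }
  expect_error(canonicalize("C("), class = "ocsr_smiles_error")
})

test_that("ring-form rewriting preserves molecule identity", {
  kek <- to_ring_form("c1ccccc1", "kekule")
  expect_false(grepl("[cnops]", gsub("\\[[^]]*\\]", "", kek)))
  expect_match(kek, "=", fixed = TRUE)
  expect_equal(canonicalize(kek), "c1ccccc1")
  expect_equal(to_ring_form("C1=CC=CC=C1", "aromatic"), "c1ccccc1")
  expect_equal(to_ring_form("CCO", "kekule"), "CCO")
  # pyridine round-trips through both forms
  py <- canonicalize("c1ccncc1")
  expect_equal(canonicalize(to_ring_form(py, "kekule")), py)
})

test_that("canonical forms agree with an independent toolkit on aromatics", {
  skip_if_not(have_rdkit(), "python rdkit not available")
  ours <- canonicalize(c("C1=CC=CC=C1", "OCC", "C1C=CC=CC=1"))
  theirs <- rdkit_canonical(c("c1ccccc1", "CCO", "c1ccccc1"))
  # cross-toolkit: equivalent inputs must be equivalent under the oracle
  expect_equal(rdkit_canonical(ours), theirs)
})
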