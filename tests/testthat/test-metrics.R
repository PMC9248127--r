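# Evaluation metrics: exact match, Tanimoto, BLEU, ROUGE-L, stratification.

test_that("exact match counts byte-identical pairs only", {
  expect_equal(exact_match_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(exact_match_accuracy(c("a", "b", "c", "d"),
                                    c("a", "b", "c", "x")), 0.75)
  # a trailing extra token breaks the match
  expect_equal(exact_match_accuracy("CCO)", "CCO"), 0)
})

test_that("path fingerprints are graph invariants of the molecule", {
  expect_identical(path_fingerprint("OCC"), path_fingerprint("CCO"))
  expect_identical(path_fingerprint("c1ccccc1"), path_fingerprint("c1ccccc1"))
  expect_false(identical(path_fingerprint("CCO"), path_fingerprint("CCN")))
  # canonical and non-canonical spellings of one molecule agree
  s <- "CC(=O)OC1=CC=CC=C1C(=O)O"
  expect_identical(path_fingerprint(s), path_fingerprint(canonicalize(s)))
})

test_that("tanimoto equals the brute-force bit-set computation", {
  fa <- path_fingerprint("CCO")
  fb <- path_fingerprint("CCN")
  brute <- length(intersect(fa, fb)) / length(union(fa, fb))
  expect_equal(tanimoto(fa, fb), brute)
  expect_equal(as.numeric(tanimoto_similarity("CCO", "CCN")), brute)
  # identity and validity rules
  expect_equal(as.numeric(tanimoto_similarity("cccccc6", "cccccc6")), 1)
  inv <- tanimoto_similarity("(((", "CCO")
  expect_equal(as.numeric(inv), 0)
  expect_false(attr(inv, "valid"))
})

test_that("corpus BLEU behaves at the boundaries and on short sequences", {
  expect_equal(bleu_score(list("CCCCO"), list("CCCCO")), 1)
  expect_equal(bleu_score(list("CCO"), list("CCO")), 1)   # shorter than 4-grams
  expect_equal(bleu_score(list("NNNNN"), list("CCCCC")), 0)
  expect_equal(bleu_score(list(""), list("CCO")), 0)
  # brevity penalty: a strict prefix scores below 1
  expect_lt(bleu_score(list("CCCC"), list("CCCCCCCC")), 1)
  # corpus-level pooling over several pairs
  sc <- bleu_score(list("CCOC", "CCN"), list("CCOC", "CCN"))
  expect_equal(sc, 1)
})

test_that("ROUGE-L matches a hand-computed LCS on a 3-token pair", {
  # LCS(ABC, ADC) = 2 -> P = R = 2/3 -> F1 = 2/3
  expect_equal(rouge_l_score(list(c("A", "B", "C")), list(c("A", "D", "C"))),
               2 / 3)
  expect_equal(rouge_l_score(list("CCO"), list("CCO")), 1)
  expect_equal(rouge_l_score(list("NN"), list("CC")), 0)
})

test_that("exact match implies all similarity metrics equal one", {
  refs <- tiny_corpus()$deepsmiles[1:6]
  rep_ <- stratified_report(refs, refs, tiny_corpus()[1:6, ])
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$tanimoto, 1)
  expect_equal(rep_$bleu, 1)
  expect_equal(rep_$rouge, 1)
  expect_equal(rep_$valid_deepsmiles_rate, 1)
  expect_equal(rep_$valid_smiles_rate, 1)
  expect_true(all(stats::na.omit(rep_$per_category_accuracy) == 1))
  expect_true(all(stats::na.omit(rep_$per_bin_accuracy) == 1))
})

test_that("stratified report bins, counts and validity rates are consistent", {
  recs <- new_corpus_records(
    smiles = c("CCO", "CCN", "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC", "CCC"),
    deepsmiles = c("CCO", "CCN", strrep("C", 80L), "CCC"),
    category = c(1L, 2L, 3L, 4L))
  preds <- c("CCO", "CCX", strrep("C", 80L), "(((")
  rep_ <- suppressWarnings(
    stratified_report(preds, recs$deepsmiles, recs))
  expect_equal(rep_$n, 4L)
  expect_equal(rep_$accuracy, 0.5)
  expect_equal(sum(rep_$per_bin_n), 4L)
  expect_equal(unname(rep_$per_bin_n[c("[1,25]", "[76,100]")]), c(3L, 1L))
  expect_equal(unname(rep_$per_bin_accuracy[["[76,100]"]]), 1)
  expect_equal(sum(rep_$per_category_n), rep_$n)
  # "CCX": X is no atom token -> invalid; "(((": not DeepSMILES grammar
  expect_equal(rep_$valid_deepsmiles_rate, 0.5)
  expect_equal(rep_$valid_smiles_rate, 0.5)
  expect_equal(unname(rep_$per_category_accuracy), c(1, 0, 1, 0))
})

test_that("report metrics are invariant to sample order", {
  corp <- tiny_corpus()[1:8, ]
  preds <- corp$deepsmiles
  preds[2] <- "CCO"
  r1 <- stratified_report(preds, corp$deepsmiles, corp)
  perm <- c(5L, 2L, 8L, 1L, 7L, 3L, 6L, 4L)
  r2 <- stratified_report(preds[perm], corp$deepsmiles[perm], corp[perm, ])
  for (field in c("accuracy", "tanimoto", "rouge", "valid_deepsmiles_rate",
                  "per_category_accuracy", "per_bin_accuracy"))
    expect_equal(r1[[field]], r2[[field]], info = field)
})
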