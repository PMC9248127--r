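# Corpus construction: pools, substituent attachment, category building,
# splits, determinism.

test_that("bundled pools contain the full bracket-atom inventory and attachable entries", {
  pools <- substituent_pools()
  required <- c("[Pb]", "[NH]", "[Ru]", "[Li]", "[K]", "[Si]", "[S+]", "[O]",
                "[O-]", "[N+]", "[N]", "[P]", "[C]", "[H]", "[2H]", "[3H]", "[B]")
  expect_true(all(required %in% pools$bracket_atoms))
  expect_gte(length(pools$substituents), 20L)
  # every pool entry attached to a test scaffold yields a parseable SMILES
  for (frag in c(pools$substituents, pools$bracket_atoms)) {
    expect_true(is_valid_smiles(paste0("CC(", frag, ")C")), info = frag)
  }
})

test_that("attachment with a single-entry pool bonds that entry at a carbon", {
  pools <- structure(list(substituents = character(0), bracket_atoms = "[Li]"),
                     class = "ocsr_pools")
  out <- attach_substituents("CC", pools, n_attach = 1L, seed = 4L)
  expect_match(out, "[Li]", fixed = TRUE)
  expect_true(is_valid_smiles(out))
  mol <- smi_parse(out)
  li <- which(mol$atoms$element == "Li")
  nb <- c(mol$bonds$a2[mol$bonds$a1 == li], mol$bonds$a1[mol$bonds$a2 == li])
  expect_equal(mol$atoms$element[nb], "C")
})

test_that("attachment is deterministic under a fixed seed and respects sites", {
  pools <- substituent_pools()
  a <- attach_substituents("C1=CC=CC=C1", pools, n_attach = 2L, seed = 9L)
  b <- attach_substituents("C1=CC=CC=C1", pools, n_attach = 2L, seed = 9L)
  expect_identical(a, b)
  expect_true(is_valid_smiles(a))
  # no substitutable heavy atom: every site enumerated has no implicit H
  expect_equal(smi_implicit_h(smi_parse("[H][H]")), c(0L, 0L))
  expect_error(attach_substituents("[H][H]", pools, n_attach = 1L, seed = 1L),
               "no substitutable site")
})

test_that("build_corpus fills exact per-category counts with unique canonical records", {
  src <- read_lines_clean(ocsr_extdata("source_smiles.txt"))[1:10]
  pools <- substituent_pools()
  recs <- build_corpus(src, c(2L, 2L, 2L, 2L), pools, seed = 2L)
  expect_equal(nrow(recs), 8L)
  expect_equal(as.vector(table(recs$category)), rep(2L, 4L))
  for (k in 1:4) expect_false(anyDuplicated(recs$smiles[recs$category == k]) > 0)
  # determinism: byte-identical manifest
  expect_identical(recs, build_corpus(src, c(2L, 2L, 2L, 2L), pools, seed = 2L))
  # kekule categories carry no aromatic atoms; aromatic categories do for ring systems
  kek <- recs$smiles[recs$category %in% c(1L, 3L)]
  expect_false(any(grepl("[cnops]", gsub("\\[[^]]*\\]", "", kek))))
})

test_that("insufficient unique molecules raise an error naming the shortfall", {
  pools <- substituent_pools()
  expect_error(build_corpus(c("CCO", "OCC"), c(3L, 0L, 0L, 0L), pools, seed = 1L),
               "short by 2 in category 1")
})

test_that("category 3/4 records grow their parent molecule by attachment", {
  src <- read_lines_clean(ocsr_extdata("source_smiles.txt"))[1:12]
  recs <- build_corpus(src, c(0L, 0L, 3L, 3L), substituent_pools(), seed = 6L,
                       track_parents = TRUE)
  expect_true(all(!is.na(recs$parent)))
  for (i in seq_len(nrow(recs))) {
    n_child <- nrow(smi_parse(recs$smiles[i])$atoms)
    n_parent <- nrow(smi_parse(recs$parent[i])$atoms)
    expect_gt(n_child, n_parent)
  }
})

test_that("split ratios follow 18:1:1 with remainders to train", {
  recs <- new_corpus_records(sprintf("C%d", 1:20), sprintf("C%d", 1:20),
                             rep(1L, 20L))
  sp <- split_corpus(recs, seed = 3L)
  expect_equal(sum(sp$split == "train"), 18L)
  expect_equal(sum(sp$split == "validation"), 1L)
  expect_equal(sum(sp$split == "test"), 1L)
  # the published full-scale sizes: 1.25M per category -> 1,125,000 / 62,500 / 62,500
  n <- 1250000L
  big <- new_corpus_records(as.character(seq_len(n)), as.character(seq_len(n)),
                            rep(1L, n))
  bs <- split_corpus(big, seed = 1L)
  expect_equal(sum(bs$split == "train"), 1125000L)
  expect_equal(sum(bs$split == "validation"), 62500L)
  expect_equal(sum(bs$split == "test"), 62500L)
  # 4 x 1.25M -> 4.5M / 250k / 250k overall follows by per-category symmetry
  expect_warning(split_corpus(recs[1:10, ], seed = 1L), "proportional rounding")
})

test_that("splits are disjoint, exhaustive and deterministic", {
  corp <- tiny_corpus()
  expect_true(all(corp$split %in% c("train", "validation", "test")))
  expect_equal(nrow(corp), sum(table(corp$split)))
  again <- generate_tiny_corpus(4L, seed = 11L)
  expect_identical(corp, again)
  different <- generate_tiny_corpus(4L, seed = 12L)
  expect_false(identical(corp, different))
})

test_that("tiny corpus exercises all categories, ring sizes >= 5 and bracket atoms", {
  corp <- generate_tiny_corpus(8L, seed = 5L)
  expect_equal(nrow(corp), 32L)
  expect_equal(sort(unique(corp$category)), 1:4)
  expect_true(any(grepl("\\[", corp$smiles)))
  # label lengths span at least two of the evaluation bins
  bins <- unique(findInterval(nchar(corp$deepsmiles), c(1, 26, 51, 76)))
  expect_gte(length(bins), 2L)
})

test_that("corpus manifests round-trip through the tab-separated format", {
  corp <- tiny_corpus()
  dir <- withr::local_tempdir()
  manifest <- write_corpus(corp, dir)
  expect_true(file.exists(manifest))
  expect_true(all(file.exists(file.path(dir, c("train.txt", "validation.txt",
                                               "test.txt")))))
  back <- read_corpus(manifest)
  expect_equal(back$smiles, corp$smiles)
  expect_equal(back$deepsmiles, corp$deepsmiles)
  expect_equal(back$category, corp$category)
  expect_equal(nrow(back), sum(lengths(lapply(
    file.path(dir, c("train.txt", "validation.txt", "test.txt")), readLines))))
})
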