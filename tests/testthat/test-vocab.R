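# Vocabulary, label encoding, token statistics.

test_that("the fixed inventory has 76 character tokens and 79 ids with specials", {
  v <- build_vocab()
  expect_length(v$tokens, 76L)
  expect_equal(v$size, 79L)
  expect_setequal(names(v$specials), c("start", "end", "pad"))
  expect_false(any(v$specials %in% v$tokens))
  # maps are mutually inverse bijections
  expect_equal(unname(v$token_to_id[v$id_to_token]), seq_len(v$size))
  expect_equal(v$id_to_token[v$token_to_id], names(v$token_to_id))
})

test_that("corpus-built vocabularies are deterministic subsets of the inventory", {
  expect_setequal(build_vocab(c("CC", "CO"))$tokens, c("C", "O"))
  corp <- tiny_corpus()
  v1 <- build_vocab(corp$deepsmiles)
  v2 <- build_vocab(sample(corp$deepsmiles))
  expect_identical(v1$token_to_id, v2$token_to_id)
  expect_true(all(v1$tokens %in% build_vocab()$tokens))
})

test_that("encode/decode invert exactly with start, end and pad handling", {
  v <- build_vocab()
  e <- encode_ids("C=O", v, 10L)
  expect_length(e, 10L)
  expect_equal(e[1], v$start_id)
  expect_equal(e[5], v$end_id)
  expect_equal(sum(e != v$pad_id), 5L)
  expect_equal(decode_ids(e, v), "C=O")
  # empty label
  e0 <- encode_ids("", v, 4L)
  expect_equal(e0[1:2], c(v$start_id, v$end_id))
  expect_equal(decode_ids(e0, v), "")
  # the long fixture round-trips unchanged
  ds <- long_deepsmiles_fixture()
  expect_identical(decode_ids(encode_ids(ds, v, 150L), v), ds)
  # every generated label round-trips
  for (d in tiny_corpus()$deepsmiles)
    expect_identical(decode_ids(encode_ids(d, v, 150L), v), d)
})

test_that("encoding rejects out-of-vocabulary characters and overlong labels", {
  v <- build_vocab(c("CC"))
  expect_error(encode_ids("CN", v, 10L), "'N'")
  expect_error(encode_ids(strrep("C", 20L), build_vocab(), 10L), "max_len")
})

test_that("token frequencies count exactly and sum to the total", {
  tf <- token_frequencies("CC")
  expect_equal(tf$count[tf$token == "C"], 2L)
  expect_equal(attr(tf, "total"), 2L)
  corp <- tiny_corpus()
  tf2 <- token_frequencies(corp$deepsmiles, build_vocab())
  expect_equal(attr(tf2, "total"), sum(nchar(corp$deepsmiles)))
  expect_equal(sum(tf2$count), attr(tf2, "total"))
  # a constructed long-tailed corpus reproduces its decreasing histogram
  zipf <- c(rep("C", 32L), rep(")", 16L), rep("=", 8L), rep("O", 4L),
            rep("N", 2L), "S")
  tfz <- token_frequencies(paste(zipf, collapse = ""))
  expect_equal(tfz$count, c(32L, 16L, 8L, 4L, 2L, 1L))
  expect_true(all(diff(tfz$count) < 0))
})

test_that("alpha weight schemes behave as specified", {
  v <- build_vocab()
  u <- alpha_weights(v)
  expect_true(all(u == 0.25))
  tf <- token_frequencies(tiny_corpus()$deepsmiles, v)
  w <- alpha_weights(v, "inverse_frequency", freq = tf)
  expect_length(w, v$size)
  expect_true(all(w >= 0))
  expect_equal(mean(w[seq_len(76L)]), 1)
  # rarer tokens weigh at least as much as commoner ones
  cnt <- tf$count[match(v$tokens, tf$token)]
  ord <- order(cnt)
  expect_true(all(diff(w[ord]) <= 1e-9))
})

test_that("vocabulary files round-trip with specials last", {
  v <- build_vocab()
  f <- withr::local_tempfile()
  write_vocab(v, f)
  lines <- readLines(f)
  expect_equal(tail(lines, 3L), c("<start>", "<end>", "<pad>"))
  v2 <- read_vocab(f)
  expect_identical(v2$token_to_id, v$token_to_id)
  expect_error(read_vocab(withr::local_tempfile(lines = c("a", "b"))),
               "special markers")
})
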