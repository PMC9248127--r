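# Depiction pipeline: rendering, binarization, model-input shaping.

test_that("renders are non-empty, deterministic and sized to the molecule", {
  img <- fixture_render("CCO")
  expect_true(is.matrix(img))
  expect_true(all(img >= 0 & img <= 1))
  expect_gt(sum(img < 0.5), 0)                    # some ink
  expect_identical(img, fixture_render("CCO"))    # pure function of inputs
  big <- fixture_render("CN1CCN(CC1)C1=CC=C(C=C1)OCC1=CC=CC=C1")
  expect_gt(prod(dim(big)), prod(dim(img)))       # larger molecule, larger canvas
})

test_that("rotation seeds change the drawing but keep it reproducible", {
  st <- depiction_style(bond_px = 30L, rotate = TRUE)
  a <- render_molecule("c1ccncc1", st, seed = 1L)
  b <- render_molecule("c1ccncc1", st, seed = 2L)
  a2 <- render_molecule("c1ccncc1", st, seed = 1L)
  expect_identical(a, a2)
  expect_false(identical(dim(a), dim(b)) && identical(a, b))
})

test_that("substituted molecules carry more ink than their parents", {
  st <- depiction_style(rotate = FALSE, bond_px = 30L, margin_px = 12L)
  pools <- substituent_pools()
  parent <- "C1C=CC=CC=1"
  child <- attach_substituents(parent, pools, n_attach = 1L, seed = 3L)
  ink_parent <- sum(binarize(render_molecule(parent, st, 1L)))
  ink_child <- sum(binarize(render_molecule(child, st, 1L)))
  expect_gt(ink_child, ink_parent)
})

test_that("binarization is exact on separated intensities and monotone in the threshold", {
  m <- matrix(c(0, 1, 1, 0), 2L)
  b <- binarize(m, 0.5)
  expect_identical(as.vector(b), c(1L, 0L, 0L, 1L))
  blank <- binarize(matrix(1, 4L, 4L), 0.5)
  expect_true(isTRUE(attr(blank, "blank")))
  expect_true(all(blank == 0L))
  img <- fixture_render("CC(=O)NC1=CC=C(O)C=C1")
  counts <- vapply(seq(0.3, 0.7, by = 0.1), function(t) sum(binarize(img, t)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("model inputs are 224x224x3 binary arrays with identical channels", {
  bin <- binarize(fixture_render("CCO"))
  x <- to_model_input(bin)
  expect_equal(dim(x), c(224L, 224L, 3L))
  expect_true(all(x %in% c(0, 1)))
  expect_identical(x[, , 1], x[, , 2])
  expect_identical(x[, , 2], x[, , 3])
})

test_that("pad-then-resize preserves the ink bounding-box aspect ratio", {
  m <- matrix(0L, 120L, 240L)
  m[40:80, 60:180] <- 1L                          # 41 x 121 box, ratio ~1/3
  x <- to_model_input(m, side = 224L)
  ink <- which(x[, , 1] == 1, arr.ind = TRUE)
  h <- diff(range(ink[, 1])) + 1L
  w <- diff(range(ink[, 2])) + 1L
  expect_equal(h / w, 41 / 121, tolerance = 0.05)
})

test_that("rendered samples satisfy the emitted-sample invariants", {
  v <- build_vocab()
  corp <- tiny_corpus()[1:6, ]
  samples <- render_samples(corp, v, depiction_style(bond_px = 24L), seed = 7L,
                            max_len = 150L, side = 64L)
  expect_length(samples, 6L)
  for (s in samples) {
    expect_equal(dim(s$image), c(64L, 64L, 3L))
    expect_true(all(s$image %in% c(0, 1)))
    expect_identical(s$image[, , 1], s$image[, , 3])
    expect_identical(decode_ids(s$label_ids, v), corp$deepsmiles[s$record])
  }
  expect_identical(
    lapply(samples, `[[`, "image"),
    lapply(render_samples(corp, v, depiction_style(bond_px = 24L), seed = 7L,
                          max_len = 150L, side = 64L), `[[`, "image"))
})

test_that("render_corpus writes PNGs and a manifest pairing images with labels", {
  corp <- tiny_corpus()[1:3, ]
  dir <- withr::local_tempdir()
  manifest <- render_corpus(corp, dir, depiction_style(bond_px = 24L),
                            seed = 1L, side = 64L)
  tab <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_true(all(file.exists(file.path(dir, tab$image))))
  expect_equal(tab$deepsmiles, corp$deepsmiles)
  px <- png::readPNG(file.path(dir, tab$image[1]))
  expect_equal(dim(px)[1:2], c(64L, 64L))
})
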