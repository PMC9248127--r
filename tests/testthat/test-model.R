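# Architecture contracts: shapes, causality, determinism, decoding,
# checkpointing.

shared_tiny_model <- function() {
  cached("tiny_model", {
    v <- build_vocab()
    list(vocab = v, model = init_ocsr_model(tiny_model_config(v$size), seed = 2L))
  })
}

random_image <- function(side, seed = 1L, density = 0.2) {
  with_seed(seed, array(as.numeric(stats::runif(side * side * 3) < density),
                        dim = c(side, side, 3L)))
}

test_that("config invariants are enforced at construction", {
  expect_error(model_config(79, image_size = 100L), "divisible")
  expect_error(model_config(79, d_model = 250L, n_heads = 8L), "divisible")
  expect_error(model_config(79, depths = c(2L, 2L)), "length 4")
  cfg <- model_config(79)
  expect_equal(backbone_out_len(cfg), 49L)
  expect_equal(backbone_out_dim(cfg), 1536L)
  expect_equal(stage_dim(cfg, 4L), 1536L)
})

test_that("backbone flattens a 224 input to 49 positions with 8x channel growth", {
  v <- build_vocab()
  cfg <- tiny_model_config(v$size, image_size = 224L, window = 7L)
  m <- init_ocsr_model(cfg, seed = 1L)
  s_b <- ag_val(ag_no_grad(backbone_forward(m, random_image(224L))))
  expect_equal(dim(s_b), c(49L, 8L * cfg$embed_dim))
})

test_that("backbone is deterministic in eval mode and non-constant in the image", {
  tm <- shared_tiny_model()
  img <- random_image(64L, seed = 5L)
  s1 <- ag_val(ag_no_grad(backbone_forward(tm$model, img)))
  s2 <- ag_val(ag_no_grad(backbone_forward(tm$model, img)))
  expect_identical(s1, s2)
  s0 <- ag_val(ag_no_grad(backbone_forward(tm$model, array(0, c(64, 64, 3)))))
  sA <- ag_val(ag_no_grad(backbone_forward(tm$model, array(1, c(64, 64, 3)))))
  expect_gt(max(abs(s0 - sA)), 1e-3)
})

test_that("encoder output has the backbone sequence length and d_model width", {
  tm <- shared_tiny_model()
  s_b <- ag_no_grad(backbone_forward(tm$model, random_image(64L)))
  s_e <- ag_val(ag_no_grad(project_and_encode(tm$model, s_b)))
  expect_equal(nrow(s_e), nrow(ag_val(s_b)))
  expect_equal(ncol(s_e), tm$model$config$d_model)
})

test_that("self-attention is equivariant to permuting positions", {
  tm <- shared_tiny_model()
  attn <- tm$model$params$encoder$layers[[1]]$attn
  x <- matrix(rnorm(6 * 64), 6L, 64L)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  out <- ag_val(ag_no_grad(mha_fwd(attn, ag_const(x), ag_const(x))))
  out_p <- ag_val(ag_no_grad(mha_fwd(attn, ag_const(x[perm, ]),
                                     ag_const(x[perm, ]))))
  expect_equal(out_p, out[perm, ], tolerance = 1e-12)
})

test_that("decoder logits are causal: future tokens cannot change earlier rows", {
  tm <- shared_tiny_model()
  v <- tm$vocab
  s_e <- matrix(rnorm(4 * 64), 4L, 64L)
  base <- c(v$start_id, 4L, 6L, 7L)
  alt <- c(v$start_id, 4L, 6L, 9L)
  l1 <- ag_val(ag_no_grad(decode_logits(tm$model, base, s_e, v)))
  l2 <- ag_val(ag_no_grad(decode_logits(tm$model, alt, s_e, v)))
  expect_identical(l1[1:3, ], l2[1:3, ])
  expect_gt(max(abs(l1[4, ] - l2[4, ])), 0)
})

test_that("softmax over decoder logits is a probability distribution", {
  tm <- shared_tiny_model()
  v <- tm$vocab
  l <- ag_val(ag_no_grad(decode_logits(tm$model, c(v$start_id, 4L),
                                       matrix(0, 4L, 64L), v)))
  p <- exp(l) / rowSums(exp(l))
  expect_equal(rowSums(p), rep(1, nrow(l)), tolerance = 1e-12)
})

test_that("cross-attention couples the decoder to the encoder sequence", {
  tm <- shared_tiny_model()
  v <- tm$vocab
  s_e <- matrix(rnorm(4 * 64), 4L, 64L)
  l1 <- ag_val(ag_no_grad(decode_logits(tm$model, c(v$start_id, 4L), s_e, v)))
  l0 <- ag_val(ag_no_grad(decode_logits(tm$model, c(v$start_id, 4L), s_e * 0, v)))
  expect_gt(max(abs(l1 - l0)), 1e-6)
})

test_that("prefix contract is enforced", {
  tm <- shared_tiny_model()
  v <- tm$vocab
  s_e <- matrix(0, 4L, 64L)
  expect_error(decode_logits(tm$model, c(4L, 5L), s_e, v), "start token")
  expect_error(decode_logits(tm$model, c(v$start_id, v$pad_id, 4L), s_e, v),
               "pad token")
})

test_that("greedy decoding stops at the end marker and respects the cap", {
  tm <- shared_tiny_model()
  v <- tm$vocab
  img <- random_image(64L, seed = 3L)
  ids <- greedy_decode(tm$model, img, v, max_len = 12L)
  expect_equal(ids[1], v$start_id)
  expect_lte(length(ids), 12L)
  if (v$end_id %in% ids) {
    expect_equal(which(ids == v$end_id), length(ids))
  } else {
    expect_equal(length(ids), 12L)
  }
  expect_identical(ids, greedy_decode(tm$model, img, v, max_len = 12L))
})

test_that("parameter count is a stable function of the configuration", {
  v <- build_vocab()
  m1 <- init_ocsr_model(tiny_model_config(v$size), seed = 1L)
  m2 <- init_ocsr_model(tiny_model_config(v$size), seed = 99L)
  expect_identical(n_parameters(m1), n_parameters(m2))
  # regression snapshot for the default tiny configuration
  expect_identical(n_parameters(m1), 3739967)
})

test_that("checkpoints restore weights and forward behaviour exactly", {
  tm <- shared_tiny_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(tm$model, f)
  m2 <- load_checkpoint(f)
  img <- random_image(64L, seed = 8L)
  expect_identical(ag_val(ag_no_grad(backbone_forward(tm$model, img))),
                   ag_val(ag_no_grad(backbone_forward(m2, img))))
  expect_identical(m2$config, tm$model$config)
})
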