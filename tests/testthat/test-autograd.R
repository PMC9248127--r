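# Reverse-mode autodiff: every op's backward rule against central finite
# differences, plus the dense/windowed attention equivalence.

fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b) + 1e-10)

test_that("elementary op gradients match finite differences", {
  set.seed(42)
  x <- matrix(rnorm(12), 3L, 4L)
  checks <- list(
    sigmoid = ag_sigmoid,
    gelu = ag_gelu,
    softmax = ag_softmax_rows
  )
  for (nm in names(checks)) {
    f_ag <- function(xv) {
      ag_reset_tape()
      p <- ag_param(xv)
      out <- ag_mean_all(ag_mul(checks[[nm]](p), ag_const(x + 2)))
      ag_backward(out)
      list(val = out$v[1], grad = p$g)
    }
    got <- f_ag(x)
    num <- fd_grad(function(xv) f_ag(xv)$val, x)
    expect_lt(rel_err(got$grad, num), 1e-6, label = nm)
  }
  # transpose (weights the transposed matrix elementwise)
  f_t <- function(xv) {
    ag_reset_tape()
    p <- ag_param(xv)
    out <- ag_mean_all(ag_mul(ag_t(p), ag_const(t(x) + 2)))
    ag_backward(out)
    list(val = out$v[1], grad = p$g)
  }
  expect_lt(rel_err(f_t(x)$grad, fd_grad(function(xv) f_t(xv)$val, x)), 1e-6)
})

test_that("matmul, linear, layernorm, attention-score gradients match finite differences", {
  set.seed(7)
  x <- matrix(rnorm(15), 5L, 3L)
  W <- matrix(rnorm(12) * 0.5, 3L, 4L)
  b <- matrix(rnorm(4) * 0.1, 1L, 4L)
  run <- function(Wv, bv) {
    ag_reset_tape()
    pw <- ag_param(Wv); pb <- ag_param(bv)
    g1 <- ag_param(matrix(1, 1L, 4L)); b1 <- ag_param(matrix(0, 1L, 4L))
    h <- ag_layernorm(ag_linear_op(ag_const(x), pw, pb), g1, b1)
    sc <- ag_attn_scores(h, h, 0.5, mask = NULL)
    # weight the attention rows so the objective is not constant
    out <- ag_mean_all(ag_mul(ag_softmax_rows(sc), ag_const(x %*% t(x))))
    ag_backward(out)
    list(val = out$v[1], gW = pw$g, gb = pb$g)
  }
  got <- run(W, b)
  numW <- fd_grad(function(Wv) run(Wv, b)$val, W)
  numb <- fd_grad(function(bv) run(W, bv)$val, b)
  expect_lt(rel_err(got$gW, numW), 1e-5)
  expect_lt(rel_err(got$gb, numb), 1e-5)
})

test_that("row gather accumulates gradients over duplicated indices", {
  set.seed(3)
  E <- matrix(rnorm(10), 5L, 2L)
  idx <- c(2L, 2L, 4L, 2L)
  run <- function(Ev) {
    ag_reset_tape()
    p <- ag_param(Ev)
    out <- ag_mean_all(ag_mul(ag_rows(p, idx), ag_const(matrix(1:8, 4L, 2L))))
    ag_backward(out)
    list(val = out$v[1], g = p$g)
  }
  got <- run(E)
  num <- fd_grad(function(Ev) run(Ev)$val, E)
  expect_lt(rel_err(got$g, num), 1e-6)
  expect_equal(got$g[c(1, 3, 5), ], matrix(0, 3L, 2L))
})

test_that("fused loss gradients match finite differences", {
  set.seed(9)
  o <- matrix(rnorm(3 * 7), 3L, 7L)
  y <- c(2L, 5L, 1L)
  keep <- c(TRUE, FALSE, TRUE)
  alpha <- runif(7)
  for (fused in list(
    function(p) ag_mfl_loss(p, y, alpha, 2, keep),
    function(p) ag_ce_loss(p, y, keep))) {
    run <- function(ov) {
      ag_reset_tape()
      p <- ag_param(ov)
      out <- fused(p)
      ag_backward(out)
      list(val = out$v[1], g = p$g)
    }
    got <- run(o)
    num <- fd_grad(function(ov) run(ov)$val, o)
    expect_lt(rel_err(got$g, num), 1e-4)
  }
})

test_that("no-grad mode records nothing and backward is a no-op there", {
  ag_reset_tape()
  before <- .ag$k
  res <- ag_no_grad({
    p <- ag_param(matrix(1, 2L, 2L))
    ag_mean_all(ag_sigmoid(p))
  })
  expect_equal(.ag$k, before)
  expect_equal(res$v[1], stats::plogis(1))
})

test_that("dense masked attention equals the per-window computation exactly", {
  v <- build_vocab()
  m <- init_ocsr_model(tiny_model_config(v$size), seed = 2L)
  img <- array(as.numeric(stats::runif(64 * 64 * 3) > 0.7), dim = c(64, 64, 3))
  m_win <- m
  m_win$layouts <- lapply(m$layouts, function(st)
    lapply(st, function(wr) { wr$dense <- NULL; wr }))
  s_dense <- ag_val(ag_no_grad(backbone_forward(m, img)))
  s_window <- ag_val(ag_no_grad(backbone_forward(m_win, img)))
  expect_identical(s_dense, s_window)
})

test_that("shifted-window masks block exactly the wrapped-together pairs", {
  lay <- win_layout(8L, 8L, 4L, 2L)
  expect_length(lay, 4L)
  expect_setequal(unlist(lapply(lay, `[[`, "idx")), 1:64)
  # windows away from the wrap boundary need no mask; boundary windows do
  masked <- vapply(lay, function(w) !is.null(w$mask), logical(1))
  expect_true(any(masked))
  for (w in lay[masked]) {
    expect_true(all(w$mask %in% c(0, -1e9)))
    expect_true(all(diag(w$mask) == 0))  # every position attends to itself
    expect_true(isSymmetric(w$mask))
  }
})
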