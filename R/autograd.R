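# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices.  This is the substrate for the window-attention backbone and
# the Transformer encoder-decoder: every layer is composed from the ops
# below, and gradients are obtained by replaying the tape in reverse.
#
# Conventions: every value is a numeric matrix (a sequence is L x C, a
# scalar is 1 x 1).  Nodes are environments; parameters are nodes created
# outside the tape whose gradients persist until an optimizer consumes
# them.  Correctness of each op's backward rule is covered by finite-
# difference tests.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$k <- 0L
.ag$recording <- TRUE

ag_reset_tape <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$k <- 0L
  invisible(NULL)
}

# Evaluate `expr` without recording to the tape (inference mode).
ag_no_grad <- function(expr) {
  old <- .ag$recording
  .ag$recording <- FALSE
  on.exit(.ag$recording <- old)
  expr
}

ag_node <- function(v, parents = NULL, bk = NULL, req = FALSE) {
  n <- new.env(parent = emptyenv())
  n$v <- v; n$g <- NULL; n$parents <- parents; n$bk <- bk; n$req <- req
  class(n) <- "ag_node"
  if (.ag$recording && !is.null(bk) && req) {
    .ag$k <- .ag$k + 1L
    if (.ag$k > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[.ag$k]] <- n
  }
  n
}

ag_const <- function(v) ag_node(as.matrix(v))

ag_param <- function(v) {
  n <- ag_node(as.matrix(v), req = TRUE)
  n$param <- TRUE
  n
}

ag_is_node <- function(x) inherits(x, "ag_node")
ag_val <- function(x) if (ag_is_node(x)) x$v else x
ag_req <- function(x) ag_is_node(x) && isTRUE(x$req)

ag_accum <- function(node, g) {
  if (!ag_req(node)) return(invisible(NULL))
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

# Run backpropagation from a scalar loss node through the current tape.
ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss), length(loss$v) == 1L)
  loss$g <- matrix(1, 1L, 1L)
  if (.ag$k < 1L) return(invisible(NULL))
  for (k in .ag$k:1L) {
    node <- .ag$tape[[k]]
    if (!is.null(node$g) && !is.null(node$bk)) node$bk(node)
  }
  invisible(NULL)
}

op <- function(v, parents, bk) {
  req <- FALSE
  for (p in parents) if (ag_req(p)) { req <- TRUE; break }
  ag_node(v, parents = parents, bk = bk, req = req)
}

ag_matmul <- function(a, b) {
  op(ag_val(a) %*% ag_val(b), list(a, b), function(n) {
    ag_accum(n$parents[[1]], tcrossprod(n$g, ag_val(n$parents[[2]])))
    ag_accum(n$parents[[2]], crossprod(ag_val(n$parents[[1]]), n$g))
  })
}

ag_add <- function(a, b) {
  op(ag_val(a) + ag_val(b), list(a, b), function(n) {
    ag_accum(n$parents[[1]], n$g)
    ag_accum(n$parents[[2]], n$g)
  })
}

# Add a 1 x C bias row to every row of an L x C matrix.
ag_add_bias <- function(a, bias) {
  av <- ag_val(a)
  op(sweep(av, 2L, as.numeric(ag_val(bias)), "+"), list(a, bias), function(n) {
    ag_accum(n$parents[[1]], n$g)
    ag_accum(n$parents[[2]], matrix(colSums(n$g), 1L))
  })
}

ag_mul <- function(a, b) {
  op(ag_val(a) * ag_val(b), list(a, b), function(n) {
    ag_accum(n$parents[[1]], n$g * ag_val(n$parents[[2]]))
    ag_accum(n$parents[[2]], n$g * ag_val(n$parents[[1]]))
  })
}

ag_scale <- function(a, s) {
  op(ag_val(a) * s, list(a), function(n) ag_accum(n$parents[[1]], n$g * s))
}

# Add a constant matrix (e.g. an attention mask); gradient passes through.
ag_addc <- function(a, cmat) {
  op(ag_val(a) + cmat, list(a), function(n) ag_accum(n$parents[[1]], n$g))
}

ag_t <- function(a) {
  op(t(ag_val(a)), list(a), function(n) ag_accum(n$parents[[1]], t(n$g)))
}

# Gather rows; duplicated indices accumulate their gradients.
ag_rows <- function(a, idx) {
  op(ag_val(a)[idx, , drop = FALSE], list(a), function(n) {
    p <- n$parents[[1]]
    if (!ag_req(p)) return(invisible(NULL))
    g <- matrix(0, nrow(ag_val(p)), ncol(ag_val(p)))
    if (anyDuplicated(idx)) {
      rs <- rowsum(n$g, group = idx, reorder = TRUE)
      g[as.integer(rownames(rs)), ] <- rs
    } else {
      g[idx, ] <- n$g
    }
    ag_accum(p, g)
  })
}

ag_rbind <- function(parts) {
  vs <- lapply(parts, ag_val)
  rows <- vapply(vs, nrow, integer(1))
  ends <- cumsum(rows)
  op(do.call(rbind, vs), parts, function(n) {
    for (i in seq_along(n$parents)) {
      sel <- (ends[i] - rows[i] + 1L):ends[i]
      ag_accum(n$parents[[i]], n$g[sel, , drop = FALSE])
    }
  })
}

ag_cbind <- function(parts) {
  vs <- lapply(parts, ag_val)
  cols <- vapply(vs, ncol, integer(1))
  ends <- cumsum(cols)
  op(do.call(cbind, vs), parts, function(n) {
    for (i in seq_along(n$parents)) {
      sel <- (ends[i] - cols[i] + 1L):ends[i]
      ag_accum(n$parents[[i]], n$g[, sel, drop = FALSE])
    }
  })
}

# Fused affine map: x %*% W + bias row (one tape node per linear layer).
ag_linear_op <- function(x, W, b) {
  xv <- ag_val(x); Wv <- ag_val(W)
  v <- xv %*% Wv
  v <- v + rep(as.numeric(ag_val(b)), each = nrow(v))
  op(v, list(x, W, b), function(n) {
    ag_accum(n$parents[[1]], tcrossprod(n$g, Wv))
    ag_accum(n$parents[[2]], crossprod(xv, n$g))
    ag_accum(n$parents[[3]], matrix(colSums(n$g), 1L))
  })
}

# Fused attention scores: (q %*% t(k)) * scale + mask.
ag_attn_scores <- function(q, k, scale, mask = NULL) {
  qv <- ag_val(q); kv <- ag_val(k)
  v <- tcrossprod(qv, kv) * scale
  if (!is.null(mask)) v <- v + mask
  op(v, list(q, k), function(n) {
    gs <- n$g * scale
    ag_accum(n$parents[[1]], gs %*% kv)
    ag_accum(n$parents[[2]], crossprod(gs, qv))
  })
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ag_val(a)))
  n <- op(s, list(a), function(n) {
    sv <- n$v
    ag_accum(n$parents[[1]], n$g * sv * (1 - sv))
  })
  n
}

# GELU, tanh approximation.
ag_gelu <- function(a) {
  x <- ag_val(a)
  k <- sqrt(2 / pi)
  inner <- k * (x + 0.044715 * x^3)
  th <- tanh(inner)
  v <- 0.5 * x * (1 + th)
  op(v, list(a), function(n) {
    sech2 <- 1 - th^2
    dinner <- k * (1 + 3 * 0.044715 * x^2)
    dv <- 0.5 * (1 + th) + 0.5 * x * sech2 * dinner
    ag_accum(n$parents[[1]], n$g * dv)
  })
}

ag_softmax_rows <- function(a) {
  x <- ag_val(a)
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  s <- e / rowSums(e)
  op(s, list(a), function(n) {
    sv <- n$v
    dot <- rowSums(n$g * sv)
    ag_accum(n$parents[[1]], (n$g - dot) * sv)
  })
}

# Row-wise layer normalization with learned 1 x C scale and shift.
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- ag_val(a)
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(ag_val(gamma)); bv <- as.numeric(ag_val(beta))
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  op(v, list(a, gamma, beta), function(n) {
    g <- n$g
    ag_accum(n$parents[[3]], matrix(colSums(g), 1L))
    ag_accum(n$parents[[2]], matrix(colSums(g * xhat), 1L))
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    ag_accum(n$parents[[1]], dx)
  })
}

# Inverted dropout; identity when training = FALSE or p = 0.
ag_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(ag_val(a)), 1L, 1 - p) / (1 - p),
                 nrow(ag_val(a)), ncol(ag_val(a)))
  op(ag_val(a) * mask, list(a), function(n)
    ag_accum(n$parents[[1]], n$g * mask))
}

ag_mean_all <- function(a) {
  x <- ag_val(a)
  op(matrix(mean(x), 1L, 1L), list(a), function(n)
    ag_accum(n$parents[[1]], matrix(n$g[1] / length(x), nrow(x), ncol(x))))
}

# Collect all parameter nodes from a nested list structure.
ag_collect_params <- function(x) {
  out <- list()
  walk <- function(y) {
    if (ag_is_node(y)) {
      if (isTRUE(y$param)) out[[length(out) + 1L]] <<- y
    } else if (is.list(y)) {
      for (el in y) walk(el)
    }
  }
  walk(x)
  out
}

ag_zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}
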