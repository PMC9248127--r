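# Neural layers composed from autograd ops: linear, layer norm, multi-head
# attention, MLP, sinusoidal positional encoding, and the window/shifted-
# window partition geometry of the hierarchical backbone.

# Glorot-scaled Gaussian init: sd = sqrt(2 / (fan_in + fan_out)) unless an
# explicit sd is given.
init_mat <- function(nr, nc, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# Bias init is uniform +-1/sqrt(fan_in), not zero: an all-background patch
# otherwise embeds to an exactly constant row, whose layer-norm backward is
# amplified by 1/sqrt(eps) and explodes through stacked blocks.
linear_new <- function(d_in, d_out, sd = NULL) {
  bound <- 1 / sqrt(d_in)
  list(W = ag_param(init_mat(d_in, d_out, sd)),
       b = ag_param(matrix(stats::runif(d_out, -bound, bound), 1L, d_out)))
}

linear_fwd <- function(l, x) ag_linear_op(x, l$W, l$b)

layernorm_new <- function(C) {
  list(gamma = ag_param(matrix(1, 1L, C)), beta = ag_param(matrix(0, 1L, C)))
}

ln_fwd <- function(l, x) ag_layernorm(x, l$gamma, l$beta)

#' @keywords internal
mha_new <- function(d_q, d_kv, n_heads, sd = NULL) {
  stopifnot(d_q %% n_heads == 0L)
  dh <- d_q %/% n_heads
  heads <- lapply(seq_len(n_heads), function(h) list(
    Wq = ag_param(init_mat(d_q, dh, sd)),
    Wk = ag_param(init_mat(d_kv, dh, sd)),
    Wv = ag_param(init_mat(d_kv, dh, sd))))
  list(heads = heads, proj = linear_new(d_q, d_q, sd), dh = dh)
}

# Multi-head attention; xq is Lq x d_q, xkv is Lk x d_kv, mask an optional
# additive Lq x Lk constant matrix (0 allowed / -1e9 blocked).
mha_fwd <- function(m, xq, xkv, mask = NULL, dropout = 0, training = FALSE) {
  outs <- lapply(m$heads, function(h) {
    q <- ag_matmul(xq, h$Wq)
    k <- ag_matmul(xkv, h$Wk)
    v <- ag_matmul(xkv, h$Wv)
    attn <- ag_softmax_rows(ag_attn_scores(q, k, 1 / sqrt(m$dh), mask))
    attn <- ag_dropout(attn, dropout, training)
    ag_matmul(attn, v)
  })
  linear_fwd(m$proj, ag_cbind(outs))
}

mlp_new <- function(C, hidden, sd = NULL) {
  list(fc1 = linear_new(C, hidden, sd), fc2 = linear_new(hidden, C, sd))
}

mlp_fwd <- function(m, x, dropout = 0, training = FALSE) {
  h <- ag_gelu(linear_fwd(m$fc1, x))
  h <- ag_dropout(h, dropout, training)
  linear_fwd(m$fc2, h)
}

# Fixed sinusoidal positional encoding, L x C.
sinusoidal_pe <- function(L, C) {
  pos <- seq_len(L) - 1L
  i <- seq_len(C) - 1L
  angle <- outer(pos, 10000^(-(i %/% 2L) * 2 / C))
  pe <- matrix(0, L, C)
  even <- which(i %% 2L == 0L)
  odd <- which(i %% 2L == 1L)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

# Causal additive mask (L x L): position i may attend to j <= i.
causal_mask <- function(L) {
  m <- matrix(-1e9, L, L)
  m[lower.tri(m, diag = TRUE)] <- 0
  m
}

# Window partition of an H x W grid (row-major positions 1..H*W), with an
# optional cyclic shift.  Returns one entry per window: the original
# position indices in within-window row-major order and, for shifted
# windows, the additive attention mask that blocks pairs wrapped together
# from different image regions.
win_layout <- function(H, W, win, shift = 0L) {
  stopifnot(H %% win == 0L, W %% win == 0L, shift >= 0L, shift < win)
  nwr <- H %/% win; nwc <- W %/% win
  rr <- rep(seq_len(H) - 1L, each = W)      # rolled row, 0-based
  cc <- rep(seq_len(W) - 1L, times = H)
  if (shift > 0L) {
    or_ <- (rr + shift) %% H                # original coordinates
    oc_ <- (cc + shift) %% W
    grp <- function(z, n) ifelse(z < n - win, 0L, ifelse(z < n - shift, 1L, 2L))
    lab <- grp(rr, H) * 3L + grp(cc, W)
  } else {
    or_ <- rr; oc_ <- cc
    lab <- rep(0L, H * W)
  }
  orig_idx <- or_ * W + oc_ + 1L
  wid <- (rr %/% win) * nwc + (cc %/% win)
  out <- vector("list", nwr * nwc)
  for (w in seq_len(nwr * nwc)) {
    sel <- which(wid == w - 1L)
    # already in row-major rolled order
    idx <- orig_idx[sel]
    mask <- NULL
    if (shift > 0L) {
      lw <- lab[sel]
      mask <- matrix(0, length(sel), length(sel))
      mask[outer(lw, lw, "!=")] <- -1e9
      if (all(mask == 0)) mask <- NULL
    }
    out[[w]] <- list(idx = idx, mask = mask)
  }
  out
}

# Dense equivalent of the window partition: an L x L additive mask that
# blocks attention between positions in different windows (and, for
# shifted layouts, between wrapped-together regions inside a window).
# Window attention under this mask equals the per-window computation.
dense_window_mask <- function(layout, L) {
  M <- matrix(-1e9, L, L)
  for (w in layout) {
    M[w$idx, w$idx] <- if (is.null(w$mask)) 0 else w$mask
  }
  M
}

# Apply a window-partitioned operation: gather each window's rows, run
# `fn(x_window, mask)`, and scatter results back to original position order.
apply_windowed <- function(x, layout, fn) {
  L <- nrow(ag_val(x))
  outs <- vector("list", length(layout))
  all_idx <- integer(0)
  for (w in seq_along(layout)) {
    lw <- layout[[w]]
    outs[[w]] <- fn(ag_rows(x, lw$idx), lw$mask)
    all_idx <- c(all_idx, lw$idx)
  }
  inv <- integer(L)
  inv[all_idx] <- seq_len(L)
  ag_rows(ag_rbind(outs), inv)
}

# One hierarchical-backbone block: pre-norm windowed (or shifted-window)
# multi-head self-attention, then pre-norm MLP, each with residual.
swin_block_new <- function(C, n_heads, mlp_ratio, sd = NULL) {
  list(ln1 = layernorm_new(C), attn = mha_new(C, C, n_heads, sd),
       ln2 = layernorm_new(C), mlp = mlp_new(C, as.integer(C * mlp_ratio), sd))
}

swin_block_fwd <- function(blk, x, layout, dropout = 0, training = FALSE) {
  h <- ln_fwd(blk$ln1, x)
  att <- if (!is.null(layout$dense)) {
    # small grids: one masked attention over the whole grid (identical
    # result, far fewer intermediate tensors)
    mha_fwd(blk$attn, h, h, mask = layout$dense, dropout = dropout,
            training = training)
  } else {
    apply_windowed(h, layout$windows, function(xw, mask)
      mha_fwd(blk$attn, xw, xw, mask = mask, dropout = dropout,
              training = training))
  }
  x <- ag_add(x, ag_dropout(att, dropout, training))
  h2 <- ln_fwd(blk$ln2, x)
  ag_add(x, ag_dropout(mlp_fwd(blk$mlp, h2, dropout, training), dropout, training))
}

# Patch merging: concatenate each 2x2 patch neighbourhood (4C), layer-norm,
# project to 2C; halves both grid sides.
patch_merge_new <- function(C, sd = NULL) {
  list(ln = layernorm_new(4L * C), red = linear_new(4L * C, 2L * C, sd))
}

patch_merge_fwd <- function(pm, x, H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  r <- rep(seq_len(H) - 1L, each = W)
  c_ <- rep(seq_len(W) - 1L, times = H)
  pos <- function(rpar, cpar)
    which(r %% 2L == rpar & c_ %% 2L == cpar)  # row-major order preserved
  groups <- list(pos(0L, 0L), pos(1L, 0L), pos(0L, 1L), pos(1L, 1L))
  cat4 <- ag_cbind(lapply(groups, function(idx) ag_rows(x, idx)))
  linear_fwd(pm$red, ln_fwd(pm$ln, cat4))
}

# Split an H x W x 3 image array into non-overlapping p x p patches,
# row-major over the patch grid; each row is the flattened raw pixel patch.
patchify <- function(image, p) {
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3] == 3L, d[1] %% p == 0L, d[2] %% p == 0L)
  nr <- d[1] %/% p; nc <- d[2] %/% p
  out <- matrix(0, nr * nc, p * p * 3L)
  k <- 0L
  for (pr in seq_len(nr)) {
    rows <- ((pr - 1L) * p + 1L):(pr * p)
    for (pc in seq_len(nc)) {
      k <- k + 1L
      cols <- ((pc - 1L) * p + 1L):(pc * p)
      out[k, ] <- as.numeric(image[rows, cols, ])
    }
  }
  out
}
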