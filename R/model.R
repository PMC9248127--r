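# The image-to-sequence OCSR network: a hierarchical window-attention
# backbone that turns a 224 x 224 x 3 depiction into a flattened feature
# sequence S_b, a Transformer encoder producing S_e, and a masked
# autoregressive Transformer decoder emitting per-position token logits.

#' Model configuration
#'
#' Architecture hyperparameters for the full-scale model.  The backbone
#' partitions the image into `patch_size` x `patch_size` patches, embeds
#' them to `embed_dim` channels, and runs four stages of window-attention
#' blocks with patch merging between stages (channels double, spatial sides
#' halve), so a 224 input with patch size 4 ends as a 49-position sequence
#' of `8 * embed_dim` channels.  The encoder/decoder operate at `d_model`
#' with fixed sinusoidal positional encodings.
#'
#' @param vocab_size number of token classes (vocabulary ids).
#' @param image_size input spatial side; must be divisible by
#'   `patch_size * 8`.
#' @param patch_size patch side in pixels.
#' @param embed_dim stage-1 channel width.
#' @param depths blocks per stage (length 4).
#' @param heads attention heads per stage (length 4).
#' @param window window side for (shifted-)window attention; stages whose
#'   grid side is smaller use the grid side itself.
#' @param d_model encoder/decoder width (token embedding dimension).
#' @param n_encoder_layers,n_decoder_layers Transformer depth.
#' @param n_heads encoder/decoder attention heads; must divide `d_model`.
#' @param mlp_ratio MLP hidden width as a multiple of the layer width.
#' @param dropout dropout rate used during training.
#' @param max_len maximum label sequence length (with start/end markers).
#' @param prenorm place layer normalization before each encoder/decoder
#'   sublayer (with a final normalization after the stack) instead of after
#'   the residual.  The post-norm arrangement is the classic Transformer
#'   one; pre-norm optimizes more reliably at small scale.
#' @return A validated `ocsr_config` list.
#' @export
model_config <- function(vocab_size, image_size = 224L, patch_size = 4L,
                         embed_dim = 192L, depths = c(2L, 2L, 18L, 2L),
                         heads = c(6L, 12L, 24L, 48L), window = 7L,
                         d_model = 256L, n_encoder_layers = 6L,
                         n_decoder_layers = 6L, n_heads = 8L,
                         mlp_ratio = 4, dropout = 0.1, max_len = 150L,
                         prenorm = FALSE) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              image_size = as.integer(image_size),
              patch_size = as.integer(patch_size),
              embed_dim = as.integer(embed_dim),
              depths = as.integer(depths), heads = as.integer(heads),
              window = as.integer(window), d_model = as.integer(d_model),
              n_encoder_layers = as.integer(n_encoder_layers),
              n_decoder_layers = as.integer(n_decoder_layers),
              n_heads = as.integer(n_heads), mlp_ratio = mlp_ratio,
              dropout = dropout, max_len = as.integer(max_len),
              prenorm = isTRUE(prenorm))
  if (length(cfg$depths) != 4L || length(cfg$heads) != 4L)
    stop("depths and heads must have length 4")
  if (cfg$image_size %% (cfg$patch_size * 8L) != 0L)
    stop("image_size must be divisible by patch_size * 8")
  if (cfg$d_model %% cfg$n_heads != 0L)
    stop("d_model must be divisible by n_heads")
  for (k in 1:4) {
    side <- stage_side(cfg, k)
    w <- min(cfg$window, side)
    if (side %% w != 0L)
      stop(sprintf("stage %d grid side %d is not divisible by its window %d",
                   k, side, w))
    if (stage_dim(cfg, k) %% cfg$heads[k] != 0L)
      stop(sprintf("stage %d width not divisible by its head count", k))
  }
  structure(cfg, class = "ocsr_config")
}

stage_side <- function(cfg, k) cfg$image_size %/% cfg$patch_size %/% (2L^(k - 1L))
stage_dim <- function(cfg, k) cfg$embed_dim * 2L^(k - 1L)
backbone_out_dim <- function(cfg) stage_dim(cfg, 4L)   # 8 * embed_dim
backbone_out_len <- function(cfg) stage_side(cfg, 4L)^2

#' @rdname model_config
#' @param ... overrides passed through to [model_config()].
#' @details `tiny_model_config()` is the desk-scale variant (64 px inputs,
#'   embed width 48, depths 2/2/2/2, two encoder and decoder layers) used
#'   for tests and CPU experiments; it defaults to the pre-norm sublayer
#'   arrangement, which trains far more reliably in the small-step regime.
#' @export
tiny_model_config <- function(vocab_size, ...) {
  defaults <- list(vocab_size = vocab_size, image_size = 64L, patch_size = 4L,
                   embed_dim = 48L, depths = c(2L, 2L, 2L, 2L),
                   heads = c(2L, 4L, 8L, 16L), window = 4L, d_model = 64L,
                   n_encoder_layers = 2L, n_decoder_layers = 2L, n_heads = 4L,
                   mlp_ratio = 2, dropout = 0, max_len = 64L, prenorm = TRUE)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(model_config, defaults)
}

#' Initialize an OCSR model
#'
#' Builds all parameter tensors (Glorot-scaled Gaussian weights; biases
#' and layer-norm shifts zero) for the backbone, encoder and decoder described
#' by `config`.  Deterministic for a fixed seed.
#'
#' @param config an [model_config()] object.
#' @param seed integer seed for the parameter draw.
#' @return An object of class `ocsr_model`.
#' @export
init_ocsr_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ocsr_config"))
  with_seed(seed, {
    cfg <- config
    backbone <- list(
      embed = linear_new(cfg$patch_size^2 * 3L, cfg$embed_dim),
      embed_ln = layernorm_new(cfg$embed_dim),
      stages = lapply(1:4, function(k) {
        C <- stage_dim(cfg, k)
        list(blocks = lapply(seq_len(cfg$depths[k]), function(b)
               swin_block_new(C, cfg$heads[k], cfg$mlp_ratio)),
             merge = if (k < 4L) patch_merge_new(C) else NULL)
      }),
      final_ln = layernorm_new(backbone_out_dim(cfg)))
    encoder <- list(
      proj = linear_new(backbone_out_dim(cfg), cfg$d_model),
      final_ln = layernorm_new(cfg$d_model),
      layers = lapply(seq_len(cfg$n_encoder_layers), function(l) list(
        attn = mha_new(cfg$d_model, cfg$d_model, cfg$n_heads),
        ln1 = layernorm_new(cfg$d_model),
        mlp = mlp_new(cfg$d_model, as.integer(cfg$d_model * cfg$mlp_ratio)),
        ln2 = layernorm_new(cfg$d_model))))
    decoder <- list(
      tok_embed = ag_param(init_mat(cfg$vocab_size, cfg$d_model)),
      head = linear_new(cfg$d_model, cfg$vocab_size),
      final_ln = layernorm_new(cfg$d_model),
      layers = lapply(seq_len(cfg$n_decoder_layers), function(l) list(
        self_attn = mha_new(cfg$d_model, cfg$d_model, cfg$n_heads),
        ln1 = layernorm_new(cfg$d_model),
        cross_attn = mha_new(cfg$d_model, cfg$d_model, cfg$n_heads),
        ln2 = layernorm_new(cfg$d_model),
        mlp = mlp_new(cfg$d_model, as.integer(cfg$d_model * cfg$mlp_ratio)),
        ln3 = layernorm_new(cfg$d_model))))
    structure(list(config = cfg,
                   params = list(backbone = backbone, encoder = encoder,
                                 decoder = decoder),
                   layouts = precompute_layouts(cfg)),
              class = "ocsr_model")
  })
}

# Window layouts per stage and shift parity, computed once.  Grids of up
# to 1024 positions also carry the dense block mask used by the fast
# whole-grid attention path.
precompute_layouts <- function(cfg) {
  lapply(1:4, function(k) {
    side <- stage_side(cfg, k)
    L <- side^2
    w <- min(cfg$window, side)
    shift <- if (w < side) w %/% 2L else 0L
    plain <- win_layout(side, side, w)
    shifted <- if (shift > 0L) win_layout(side, side, w, shift) else plain
    wrap <- function(lay) list(
      windows = lay,
      dense = if (L <= 1024L) dense_window_mask(lay, L) else NULL)
    list(plain = wrap(plain), shifted = wrap(shifted))
  })
}

#' @export
print.ocsr_model <- function(x, ...) {
  cat(sprintf(
    "<ocsr_model> image %d, patch %d, embed %d, depths %s | d_model %d, enc %d, dec %d | vocab %d\n  parameters: %s\n",
    x$config$image_size, x$config$patch_size, x$config$embed_dim,
    paste(x$config$depths, collapse = "/"), x$config$d_model,
    x$config$n_encoder_layers, x$config$n_decoder_layers,
    x$config$vocab_size, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model an `ocsr_model`.
#' @return Integer scalar: total element count across parameter tensors.
#' @export
n_parameters <- function(model) {
  sum(vapply(ag_collect_params(model$params), function(p) length(p$v), numeric(1)))
}

#' Backbone forward pass
#'
#' Partitions the image into patches, embeds them, and runs the four-stage
#' window-attention hierarchy (blocks alternate plain and shifted windows;
#' patch merging halves the grid and doubles the channels between stages).
#' The final feature map is already a flattened row-major sequence: for a
#' 224 input the result `S_b` has 49 positions of `8 * embed_dim` channels.
#'
#' @param model an `ocsr_model`.
#' @param image `image_size` x `image_size` x 3 numeric array, or a
#'   pre-computed patch matrix from an internal call.
#' @param training enable dropout.
#' @return An autograd node; its value is the `S_b` matrix.
#' @export
backbone_forward <- function(model, image, training = FALSE) {
  cfg <- model$config
  pm <- if (is.matrix(image)) image else patchify(image, cfg$patch_size)
  if (nrow(pm) != (cfg$image_size %/% cfg$patch_size)^2)
    stop("image size does not match the model configuration")
  bb <- model$params$backbone
  x <- ln_fwd(bb$embed_ln, linear_fwd(bb$embed, ag_const(pm)))
  for (k in 1:4) {
    side <- stage_side(cfg, k)
    st <- bb$stages[[k]]
    for (b in seq_along(st$blocks)) {
      layout <- if (b %% 2L == 1L) model$layouts[[k]]$plain
                else model$layouts[[k]]$shifted
      x <- swin_block_fwd(st$blocks[[b]], x, layout, cfg$dropout, training)
    }
    if (!is.null(st$merge)) x <- patch_merge_fwd(st$merge, x, side, side)
  }
  ln_fwd(bb$final_ln, x)
}

#' Project S_b and run the Transformer encoder
#'
#' A learned linear map takes the backbone channels to `d_model`, a fixed
#' sinusoidal positional encoding is added, and the standard encoder layers
#' (self-attention then MLP, each followed by a residual connection and
#' layer normalization) produce `S_e` with the same sequence length.
#'
#' @param model an `ocsr_model`.
#' @param s_b autograd node or matrix from [backbone_forward()].
#' @param training enable dropout.
#' @return An autograd node for `S_e`.
#' @export
project_and_encode <- function(model, s_b, training = FALSE) {
  cfg <- model$config
  enc <- model$params$encoder
  if (!ag_is_node(s_b)) s_b <- ag_const(s_b)
  x <- linear_fwd(enc$proj, s_b)
  L <- nrow(ag_val(x))
  x <- ag_addc(x, sinusoidal_pe(L, cfg$d_model))
  x <- ag_dropout(x, cfg$dropout, training)
  for (ly in enc$layers) {
    if (cfg$prenorm) {
      a <- mha_fwd(ly$attn, ln_fwd(ly$ln1, x), ln_fwd(ly$ln1, x),
                   dropout = cfg$dropout, training = training)
      x <- ag_add(x, ag_dropout(a, cfg$dropout, training))
      m <- mlp_fwd(ly$mlp, ln_fwd(ly$ln2, x), cfg$dropout, training)
      x <- ag_add(x, ag_dropout(m, cfg$dropout, training))
    } else {
      a <- mha_fwd(ly$attn, x, x, dropout = cfg$dropout, training = training)
      x <- ln_fwd(ly$ln1, ag_add(x, ag_dropout(a, cfg$dropout, training)))
      m <- mlp_fwd(ly$mlp, x, cfg$dropout, training)
      x <- ln_fwd(ly$ln2, ag_add(x, ag_dropout(m, cfg$dropout, training)))
    }
  }
  if (cfg$prenorm) x <- ln_fwd(enc$final_ln, x)
  x
}

#' Decoder forward pass: logits for every prefix position
#'
#' Embeds the prefix tokens, adds the positional encoding, and runs the
#' decoder layers (causally masked self-attention, cross-attention over
#' `S_e`, MLP; residual + layer normalization after each sublayer) followed
#' by the linear vocabulary head.  The causal mask guarantees the logits at
#' position i depend only on tokens at positions <= i.
#'
#' @param model an `ocsr_model`.
#' @param prefix_ids integer token ids; must begin with the start id and
#'   contain no pad before an end marker.
#' @param s_e autograd node or matrix from [project_and_encode()].
#' @param vocab the vocabulary (for the start/pad id contract checks).
#' @param training enable dropout.
#' @return An autograd node; value is a `length(prefix_ids)` x `vocab_size`
#'   logit matrix.
#' @export
decode_logits <- function(model, prefix_ids, s_e, vocab, training = FALSE) {
  cfg <- model$config
  if (length(prefix_ids) < 1L || prefix_ids[1] != vocab$start_id)
    stop("prefix must begin with the start token")
  if (length(prefix_ids) > cfg$max_len)
    stop("prefix exceeds max_len")
  endpos <- match(vocab$end_id, prefix_ids)
  pads <- which(prefix_ids == vocab$pad_id)
  if (length(pads) > 0L && (is.na(endpos) || any(pads < endpos)))
    stop("prefix contains a pad token before the end marker")
  dec <- model$params$decoder
  if (!ag_is_node(s_e)) s_e <- ag_const(s_e)
  L <- length(prefix_ids)
  x <- ag_rows(dec$tok_embed, prefix_ids)
  x <- ag_addc(x, sinusoidal_pe(L, cfg$d_model))
  x <- ag_dropout(x, cfg$dropout, training)
  cmask <- causal_mask(L)
  for (ly in dec$layers) {
    if (cfg$prenorm) {
      h <- ln_fwd(ly$ln1, x)
      a <- mha_fwd(ly$self_attn, h, h, mask = cmask, dropout = cfg$dropout,
                   training = training)
      x <- ag_add(x, ag_dropout(a, cfg$dropout, training))
      cr <- mha_fwd(ly$cross_attn, ln_fwd(ly$ln2, x), s_e,
                    dropout = cfg$dropout, training = training)
      x <- ag_add(x, ag_dropout(cr, cfg$dropout, training))
      m <- mlp_fwd(ly$mlp, ln_fwd(ly$ln3, x), cfg$dropout, training)
      x <- ag_add(x, ag_dropout(m, cfg$dropout, training))
    } else {
      a <- mha_fwd(ly$self_attn, x, x, mask = cmask, dropout = cfg$dropout,
                   training = training)
      x <- ln_fwd(ly$ln1, ag_add(x, ag_dropout(a, cfg$dropout, training)))
      cr <- mha_fwd(ly$cross_attn, x, s_e, dropout = cfg$dropout,
                    training = training)
      x <- ln_fwd(ly$ln2, ag_add(x, ag_dropout(cr, cfg$dropout, training)))
      m <- mlp_fwd(ly$mlp, x, cfg$dropout, training)
      x <- ln_fwd(ly$ln3, ag_add(x, ag_dropout(m, cfg$dropout, training)))
    }
  }
  if (cfg$prenorm) x <- ln_fwd(dec$final_ln, x)
  linear_fwd(dec$head, x)   # per-position vocabulary logits
}

#' Greedy autoregressive decoding
#'
#' Runs the backbone and encoder once, then repeatedly appends the
#' highest-logit token (ties broken by the lowest token id) until the end
#' marker or `max_len` is reached.  Deterministic in inference mode.
#'
#' @param model an `ocsr_model`.
#' @param image input image array (or patch matrix).
#' @param vocab the vocabulary.
#' @param max_len cap on the emitted sequence length (including markers).
#' @return Integer id sequence starting with the start id; ends with the
#'   end id unless the cap was hit.
#' @export
greedy_decode <- function(model, image, vocab, max_len = model$config$max_len) {
  ag_no_grad({
    s_b <- backbone_forward(model, image, training = FALSE)
    s_e <- project_and_encode(model, s_b, training = FALSE)
    ids <- vocab$start_id
    while (length(ids) < max_len) {
      logits <- ag_val(decode_logits(model, ids, s_e, vocab, training = FALSE))
      nxt <- which.max(logits[nrow(logits), ])   # first max = lowest id
      if (nxt == vocab$pad_id) break             # pad terminates the sequence
      ids <- c(ids, nxt)
      if (nxt == vocab$end_id) break
    }
    as.integer(ids)
  })
}

# --- checkpointing ---------------------------------------------------------

params_to_values <- function(x) {
  if (ag_is_node(x)) return(x$v)
  if (is.list(x)) return(lapply(x, params_to_values))
  x
}

values_into_params <- function(params, values) {
  if (ag_is_node(params)) {
    stopifnot(is.matrix(values), all(dim(values) == dim(params$v)))
    params$v <- values
    return(invisible(NULL))
  }
  if (is.list(params)) {
    stopifnot(length(params) == length(values))
    for (i in seq_along(params)) values_into_params(params[[i]], values[[i]])
  }
  invisible(NULL)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the full configuration and every parameter tensor;
#' loading rebuilds the model and restores the weights exactly.
#'
#' @param model an `ocsr_model`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               values = params_to_values(model$params)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), character(0))])
  model <- init_ocsr_model(cfg, seed = 0L)
  values_into_params(model$params, ck$values)
  model
}
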