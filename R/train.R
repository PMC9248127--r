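# Teacher-forced training with Adam and the two-group learning-rate
# schedule: the backbone group follows cosine decay, the Transformer
# (encoder/decoder) group step decay.

#' Training configuration
#'
#' @param epochs number of passes over the training samples.
#' @param batch_size samples per optimizer step.
#' @param lr initial learning rate for both parameter groups.
#' @param loss `"mfl"` (multi-label focal loss) or `"ce"` (softmax
#'   cross-entropy).
#' @param gamma focal focusing parameter (MFL only).
#' @param alpha per-class focal weights: a scalar, a vector of length
#'   `vocab_size`, or `"uniform"` for the 0.25 convention.
#' @param step_size,step_factor step-decay schedule of the Transformer
#'   group: multiply the rate by `step_factor` every `step_size` epochs.
#' @param seed integer seed (shuffling, dropout).
#' @param clip_norm clip the global gradient norm of each batch to this
#'   value (`Inf` disables clipping).
#' @param log_every log the running loss every this many epochs.
#' @return An `ocsr_train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, lr = 5e-4,
                         loss = c("mfl", "ce"), gamma = 2, alpha = "uniform",
                         step_size = 10L, step_factor = 0.5, seed = 1L,
                         clip_norm = 5, log_every = 10L) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, gamma >= 0, clip_norm > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, loss = loss, gamma = gamma, alpha = alpha,
                 step_size = as.integer(step_size), step_factor = step_factor,
                 seed = as.integer(seed), clip_norm = clip_norm,
                 log_every = as.integer(log_every)),
            class = "ocsr_train_config")
}

adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$m)) { p$m <- p$v * 0; p$s <- p$v * 0; p$t <- 0L }
    p$t <- p$t + 1L
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$s <- beta2 * p$s + (1 - beta2) * p$g^2
    mhat <- p$m / (1 - beta1^p$t)
    shat <- p$s / (1 - beta2^p$t)
    p$v <- p$v - lr * mhat / (sqrt(shat) + eps)
  }
  invisible(NULL)
}

# Per-epoch learning rates for the two parameter groups.
schedule_lrs <- function(cfg, epoch) {
  cosine <- cfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(1L, cfg$epochs - 1L)))
  step <- cfg$lr * cfg$step_factor^((epoch - 1L) %/% cfg$step_size)
  list(backbone = cosine, transformer = step)
}

# Teacher-forced loss for one sample: input = ids[1:(T-1)], target =
# ids[2:T]; pads are trimmed beforehand so every position counts.
sample_loss_node <- function(model, patches, ids, vocab, loss, alpha_vec, gamma,
                             training = TRUE) {
  s_b <- backbone_forward(model, patches, training = training)
  s_e <- project_and_encode(model, s_b, training = training)
  Tn <- length(ids)
  logits <- decode_logits(model, ids[1:(Tn - 1L)], s_e, vocab,
                          training = training)
  targets <- ids[2:Tn]
  if (loss == "mfl") ag_mfl_loss(logits, targets, alpha_vec, gamma)
  else ag_ce_loss(logits, targets)
}

trim_pads <- function(ids, vocab) {
  endpos <- match(vocab$end_id, ids)
  if (is.na(endpos)) stop("label sequence has no end marker")
  ids[1:endpos]
}

#' Train the model on rendered samples
#'
#' Teacher-forced next-token training.  Backbone parameters follow a
#' cosine-decayed learning rate, encoder/decoder parameters a step-decayed
#' one; both start at `config$lr` and are updated with Adam.  Gradients are
#' averaged over each batch.  A per-epoch loss log is recorded, and when
#' validation samples are supplied the checkpoint with the best validation
#' exact-match accuracy is kept and restored at the end.
#'
#' @param model an `ocsr_model` (modified in place and returned).
#' @param samples list of samples from [render_samples()].
#' @param vocab the vocabulary used to encode the labels.
#' @param config an [train_config()].
#' @param val_samples optional validation samples for checkpoint selection.
#' @param val_every validate every this many epochs.
#' @param stop_at_accuracy stop training early once the validation
#'   exact-match accuracy reaches this value (default `NULL`: never).
#' @param verbose print progress lines.
#' @return The trained model, with attribute `history` (data frame of
#'   epoch, mean loss, learning rates, validation accuracy if computed).
#' @export
train_model <- function(model, samples, vocab, config = train_config(),
                        val_samples = NULL, val_every = 10L,
                        stop_at_accuracy = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ocsr_model"), length(samples) >= 1L)
  params_bb <- ag_collect_params(model$params$backbone)
  params_tr <- ag_collect_params(list(model$params$encoder, model$params$decoder))
  all_params <- c(params_bb, params_tr)
  alpha_vec <- if (identical(config$alpha, "uniform")) rep(0.25, model$config$vocab_size)
               else rep(config$alpha, length.out = model$config$vocab_size)
  prep <- lapply(samples, function(s) list(
    patches = patchify(s$image, model$config$patch_size),
    ids = trim_pads(s$label_ids, vocab)))
  history <- list()
  best_acc <- -Inf
  best_values <- NULL
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lrs <- schedule_lrs(config, epoch)
      ord <- sample(length(prep))
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        ag_zero_grads(all_params)
        for (b in batch) {
          ag_reset_tape()
          ln <- sample_loss_node(model, prep[[b]]$patches, prep[[b]]$ids,
                                 vocab, config$loss, alpha_vec, config$gamma)
          losses <- c(losses, ag_val(ln)[1])
          ag_backward(ln)
        }
        for (p in all_params) if (!is.null(p$g)) p$g <- p$g / length(batch)
        if (is.finite(config$clip_norm)) {
          gnorm <- sqrt(sum(vapply(all_params, function(p)
            if (is.null(p$g)) 0 else sum(p$g^2), numeric(1))))
          if (gnorm > config$clip_norm) {
            sc <- config$clip_norm / gnorm
            for (p in all_params) if (!is.null(p$g)) p$g <- p$g * sc
          }
        }
        adam_step(params_bb, lrs$backbone)
        adam_step(params_tr, lrs$transformer)
      }
      val_acc <- NA_real_
      if (!is.null(val_samples) &&
          (epoch %% val_every == 0L || epoch == config$epochs)) {
        val_acc <- evaluate_exact_match(model, val_samples, vocab)
        if (val_acc >= best_acc) {
          best_acc <- val_acc
          best_values <- params_to_values(model$params)
        }
      }
      history[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                     lr_backbone = lrs$backbone,
                                     lr_transformer = lrs$transformer,
                                     val_accuracy = val_acc)
      if (verbose && (epoch %% config$log_every == 0L || epoch == 1L))
        message(sprintf("epoch %3d  loss %.5f  lr_bb %.2e lr_tr %.2e%s",
                        epoch, mean(losses), lrs$backbone, lrs$transformer,
                        if (!is.na(val_acc)) sprintf("  val_acc %.3f", val_acc) else ""))
      if (!is.null(stop_at_accuracy) && !is.na(val_acc) &&
          val_acc >= stop_at_accuracy) break
    }
  })
  if (!is.null(best_values)) values_into_params(model$params, best_values)
  attr(model, "history") <- do.call(rbind, history)
  model
}

# Greedy-decode every sample and score exact sequence match.
evaluate_exact_match <- function(model, samples, vocab) {
  ok <- vapply(samples, function(s) {
    pred <- greedy_decode(model, s$image, vocab)
    identical(decode_ids(pred, vocab), decode_ids(s$label_ids, vocab))
  }, logical(1))
  mean(ok)
}

#' Predict the DeepSMILES (and SMILES) for one depiction
#'
#' Greedy-decodes the model on a rendered image and reports the token
#' string plus, when the prediction is valid DeepSMILES, its reconstructed
#' SMILES.
#'
#' @param model a trained `ocsr_model`.
#' @param image image array sized for the model (see [to_model_input()]).
#' @param vocab the vocabulary.
#' @return List with `deepsmiles`, `smiles` (NA when undecodable) and
#'   `valid` flags.
#' @export
predict_structure <- function(model, image, vocab) {
  ids <- greedy_decode(model, image, vocab)
  ds <- decode_ids(ids, vocab)
  valid_ds <- is_valid_deepsmiles(ds)
  sm <- NA_character_
  valid_sm <- FALSE
  if (valid_ds) {
    sm_try <- from_deepsmiles(ds)
    if (is_valid_smiles(sm_try)) { sm <- sm_try; valid_sm <- TRUE }
  }
  list(deepsmiles = ds, smiles = sm, valid_deepsmiles = valid_ds,
       valid_smiles = valid_sm)
}


#' Desk-scale learnability benchmark: overfit a tiny model on its own corpus
#'
#' Renders a small generated corpus (a few molecules per category), trains
#' the tiny model configuration on it, and reports the exact-match accuracy
#' of greedy decoding on the same samples.  Recovering the training labels
#' verbatim is the desk-scale surrogate for full-scale learnability: it
#' exercises the whole pipeline (corpus, depiction, tokenizer, backbone,
#' encoder-decoder, loss, decoding) end to end.
#'
#' @param seed integer seed controlling corpus, rendering, initialization
#'   and training.
#' @param n_per_category molecules kept per category (total 4x this); the
#'   benchmark generates a larger corpus and keeps the records with the
#'   shortest labels in each category, so the task sits in the first
#'   label-length bin — the problem size chosen for a single-CPU run.
#' @param epochs epoch budget of the main training phase; training stops
#'   early once the training-set exact match reaches 1.
#' @param loss `"mfl"` or `"ce"`.
#' @param lr learning rate of the main phase.
#' @param refine_rounds after the main phase, up to this many continuation
#'   rounds (100 epochs each, learning rate halved per round) are run while
#'   the exact match is still below 1.
#' @param verbose print per-epoch progress.
#' @return List: `accuracy` (exact match on the training samples), `report`
#'   (the full [stratified_report()]), `model`, `samples`, `records`,
#'   `vocab`, `history` (main-phase log).
#' @export
overfit_benchmark <- function(seed = 1L, n_per_category = 2L, epochs = 300L,
                              loss = "ce", lr = 1e-3, refine_rounds = 2L,
                              verbose = FALSE) {
  vocab <- build_vocab()
  pool_recs <- generate_tiny_corpus(3L * n_per_category, seed = seed)
  # keep the shortest-labelled records per category (first length bin)
  keep <- unlist(lapply(split(seq_len(nrow(pool_recs)), pool_recs$category),
                        function(idx) {
    idx[order(nchar(pool_recs$deepsmiles[idx]))][seq_len(n_per_category)]
  }), use.names = FALSE)
  records <- pool_recs[sort(keep), ]
  rownames(records) <- NULL
  style <- depiction_style(bond_px = 30L, margin_px = 12L)
  samples <- render_samples(records, vocab, style, seed = seed + 1L,
                            max_len = 64L, side = 64L)
  model <- init_ocsr_model(tiny_model_config(vocab$size), seed = seed + 2L)
  # full-batch steps: the image-conditional signal is a small difference of
  # per-sample gradients, and averaging the whole corpus keeps it unbiased
  cfg <- train_config(epochs = epochs, batch_size = length(samples),
                      lr = lr, loss = loss, seed = seed + 3L, step_size = 150L,
                      log_every = 25L)
  model <- train_model(model, samples, vocab, cfg, val_samples = samples,
                       val_every = 10L, stop_at_accuracy = 1, verbose = verbose)
  history <- attr(model, "history")
  # continuation: restart the schedules at a lower rate to clean up the
  # last unmatched samples (the best-validation checkpoint is kept, so
  # rounds never reduce the final accuracy)
  for (round in seq_len(refine_rounds)) {
    acc_in <- evaluate_exact_match(model, samples, vocab)
    if (acc_in >= 1) break
    before <- params_to_values(model$params)
    cfg_r <- train_config(epochs = 100L, batch_size = length(samples),
                          lr = lr / 2^round, loss = loss,
                          seed = seed + 3L + round, step_size = 150L,
                          log_every = 25L)
    model <- train_model(model, samples, vocab, cfg_r, val_samples = samples,
                         val_every = 10L, stop_at_accuracy = 1,
                         verbose = verbose)
    if (evaluate_exact_match(model, samples, vocab) < acc_in)
      values_into_params(model$params, before)   # round hurt; roll back
  }
  report <- evaluate_model(model, samples, records, vocab)
  list(accuracy = report$accuracy, report = report, model = model,
       samples = samples, records = records, vocab = vocab,
       history = history)
}
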