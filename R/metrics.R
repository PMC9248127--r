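# Evaluation protocol: exact-match accuracy, Tanimoto over binary
# fingerprints, corpus BLEU, ROUGE-L, validity rates, and the stratified
# report (per category, per label-length bin).

#' Exact-match accuracy
#'
#' Fraction of prediction/reference pairs that are byte-identical strings;
#' a length mismatch (e.g. a trailing extra token) is a mismatch.
#'
#' @param predictions,references equal-length character vectors.
#' @return Fraction in `[0, 1]`.
#' @export
exact_match_accuracy <- function(predictions, references) {
  stopifnot(length(predictions) == length(references))
  mean(predictions == references)
}

#' Path-based binary molecular fingerprint
#'
#' The molecule is first brought to its canonical aromatic form, so any two
#' spellings of one structure (including Kekulé vs aromatic ring forms)
#' give identical bit sets.  All simple linear atom paths of up to
#' `max_len` bonds are enumerated, each path (and its reverse) is written
#' as a canonical element/bond-order string, and hashed onto `nbits` bits.
#'
#' @param smiles a valid SMILES string.
#' @param max_len maximum path length in bonds.
#' @param nbits fingerprint width.
#' @return Sorted integer vector of set bit positions (1-based).
#' @export
path_fingerprint <- function(smiles, max_len = 6L, nbits = 1024L) {
  mol <- smi_parse(canonicalize(smiles))
  adj <- mol_adjacency(mol)
  na <- nrow(mol$atoms)
  atom_sym <- ifelse(mol$atoms$aromatic, tolower(mol$atoms$element),
                     mol$atoms$element)
  atom_sym <- paste0(atom_sym,
                     ifelse(mol$atoms$charge != 0L,
                            sprintf("%+d", mol$atoms$charge), ""))
  keys <- new.env(parent = emptyenv())
  add_path <- function(atoms, orders) {
    fw <- paste(atom_sym[atoms],
                c(sprintf("%g", orders), ""), sep = "", collapse = "")
    rv <- paste(atom_sym[rev(atoms)],
                c(sprintf("%g", rev(orders)), ""), sep = "", collapse = "")
    assign(min(fw, rv), TRUE, envir = keys)
  }
  dfs <- function(path, orders) {
    add_path(path, orders)
    if (length(orders) >= max_len) return(invisible(NULL))
    cur <- path[length(path)]
    a <- adj[[cur]]
    for (j in seq_along(a$nb)) {
      nb <- a$nb[j]
      if (nb %in% path) next
      ord <- if (a$aromatic[j]) 1.5 else a$order[j]
      dfs(c(path, nb), c(orders, ord))
    }
  }
  for (a0 in seq_len(na)) dfs(a0, numeric(0))
  bits <- vapply(ls(keys), function(k) str_hash(k, nbits), integer(1),
                 USE.NAMES = FALSE)
  sort(unique(bits))
}

# Deterministic polynomial string hash onto 1..nbits.
str_hash <- function(s, nbits) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  as.integer(h %% nbits) + 1L
}

#' Tanimoto similarity of two binary bit sets
#'
#' @param a,b integer vectors of set bit positions.
#' @return `|a intersect b| / |a union b|` (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Tanimoto similarity between a predicted and a reference DeepSMILES
#'
#' Both strings are decoded back to SMILES and fingerprinted
#' ([path_fingerprint()] by default); the similarity is the Tanimoto
#' coefficient of the bit sets.  An undecodable or chemically invalid
#' prediction scores 0 and is flagged.
#'
#' @param pred_deepsmiles,ref_deepsmiles DeepSMILES strings; the reference
#'   must decode to a valid molecule.
#' @param fingerprint function mapping a SMILES string to a bit set.
#' @return Similarity in `[0, 1]` with attribute `valid` (logical: did the
#'   prediction decode to a valid molecule).
#' @export
tanimoto_similarity <- function(pred_deepsmiles, ref_deepsmiles,
                                fingerprint = path_fingerprint) {
  ref_sm <- from_deepsmiles(ref_deepsmiles)
  if (!is_valid_smiles(ref_sm)) stop("reference does not decode to a valid molecule")
  pred_sm <- tryCatch(from_deepsmiles(pred_deepsmiles), error = function(e) NA_character_)
  if (is.na(pred_sm) || !is_valid_smiles(pred_sm))
    return(structure(0, valid = FALSE))
  structure(tanimoto(fingerprint(pred_sm), fingerprint(ref_sm)), valid = TRUE)
}

ngrams <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(character(0))
  vapply(seq_len(L - n + 1L), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = "\x1f"), character(1))
}

count_clip <- function(pred_ng, ref_ng) {
  if (length(pred_ng) == 0L) return(0L)
  pt <- table(pred_ng); rt <- table(ref_ng)
  sum(pmin(pt, as.integer(rt[names(pt)])), na.rm = TRUE) +
    0L  # names absent from rt give NA -> dropped by na.rm
}

#' Corpus BLEU over token sequences
#'
#' Standard corpus-level BLEU with up to 4-gram precisions (geometric mean)
#' and the brevity penalty; sequences are character-token vectors or
#' strings (split into characters).
#'
#' @param predictions,references equal-length lists of token vectors or
#'   character vectors of strings.
#' @param max_n largest n-gram order.
#' @return BLEU score in `[0, 1]`.
#' @export
bleu_score <- function(predictions, references, max_n = 4L) {
  tok <- function(x) if (is.character(x) && length(x) == 1L)
    strsplit(x, "", fixed = TRUE)[[1]] else as.character(x)
  preds <- lapply(predictions, tok)
  refs <- lapply(references, tok)
  stopifnot(length(preds) == length(refs))
  pred_len <- sum(lengths(preds)); ref_len <- sum(lengths(refs))
  if (pred_len == 0L) return(0)
  log_p <- numeric(0)
  for (n in seq_len(max_n)) {
    clipped <- 0L; total <- 0L
    for (i in seq_along(preds)) {
      png_ <- ngrams(preds[[i]], n)
      clipped <- clipped + count_clip(png_, ngrams(refs[[i]], n))
      total <- total + length(png_)
    }
    # orders longer than every sequence carry no evidence and are skipped
    if (total == 0L) next
    if (clipped == 0L) return(0)
    log_p <- c(log_p, log(clipped / total))
  }
  if (length(log_p) == 0L) return(0)
  bp <- if (pred_len > ref_len) 1 else exp(1 - ref_len / pred_len)
  bp * exp(mean(log_p))
}

lcs_length <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(0L)
  prev <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    match_i <- a[i] == b
    for (j in seq_len(lb)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[lb + 1L]
}

#' ROUGE-L F-measure over token sequences
#'
#' Longest-common-subsequence recall/precision combined as F1, averaged
#' over pairs.
#'
#' @inheritParams bleu_score
#' @return Mean ROUGE-L F1 in `[0, 1]`.
#' @export
rouge_l_score <- function(predictions, references) {
  tok <- function(x) if (is.character(x) && length(x) == 1L)
    strsplit(x, "", fixed = TRUE)[[1]] else as.character(x)
  preds <- lapply(predictions, tok)
  refs <- lapply(references, tok)
  stopifnot(length(preds) == length(refs))
  f1 <- vapply(seq_along(preds), function(i) {
    l <- lcs_length(preds[[i]], refs[[i]])
    if (l == 0L) return(0)
    p <- l / length(preds[[i]]); r <- l / length(refs[[i]])
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

LENGTH_BINS <- list(c(1L, 25L), c(26L, 50L), c(51L, 75L), c(76L, 100L))

#' Stratified evaluation report
#'
#' Computes the four headline metrics (exact-match accuracy, mean Tanimoto,
#' BLEU, ROUGE-L), the two validity rates (parseable DeepSMILES; decodes to
#' parseable SMILES), accuracy per molecule category 1-4, and accuracy per
#' reference label-length bin ([1,25], [26,50], [51,75], [76,100],
#' inclusive bounds on the DeepSMILES character length).
#'
#' @param predictions character vector of predicted DeepSMILES.
#' @param references character vector of reference DeepSMILES.
#' @param records corpus records data frame aligned with the pairs (for the
#'   `category` column).
#' @param fingerprint fingerprint function for the Tanimoto metric.
#' @return An `ocsr_eval_report` list.
#' @export
stratified_report <- function(predictions, references, records,
                              fingerprint = path_fingerprint) {
  stopifnot(length(predictions) == length(references),
            length(predictions) == nrow(records))
  if (any(is.na(records$category)) || !all(records$category %in% 1:4))
    stop("every record needs a category in 1..4")
  n <- length(predictions)
  tan <- numeric(n); valid_ds <- logical(n); valid_sm <- logical(n)
  for (i in seq_len(n)) {
    valid_ds[i] <- is_valid_deepsmiles(predictions[i])
    if (valid_ds[i])
      valid_sm[i] <- is_valid_smiles(tryCatch(from_deepsmiles(predictions[i]),
                                              error = function(e) "("))
    ts <- tanimoto_similarity(predictions[i], references[i], fingerprint)
    tan[i] <- as.numeric(ts)
  }
  match_ <- predictions == references
  per_cat <- vapply(1:4, function(k) {
    sel <- records$category == k
    if (!any(sel)) NA_real_ else mean(match_[sel])
  }, numeric(1))
  reflen <- nchar(references)
  per_bin <- vapply(LENGTH_BINS, function(b) {
    sel <- reflen >= b[1] & reflen <= b[2]
    if (!any(sel)) NA_real_ else mean(match_[sel])
  }, numeric(1))
  bin_counts <- vapply(LENGTH_BINS, function(b)
    sum(reflen >= b[1] & reflen <= b[2]), integer(1))
  structure(list(
    n = n,
    accuracy = mean(match_),
    tanimoto = mean(tan),
    bleu = bleu_score(predictions, references),
    rouge = rouge_l_score(predictions, references),
    valid_deepsmiles_rate = mean(valid_ds),
    valid_smiles_rate = mean(valid_sm),
    per_category_accuracy = stats::setNames(per_cat, paste0("category", 1:4)),
    per_category_n = stats::setNames(
      vapply(1:4, function(k) sum(records$category == k), integer(1)),
      paste0("category", 1:4)),
    per_bin_accuracy = stats::setNames(
      per_bin, vapply(LENGTH_BINS, function(b) sprintf("[%d,%d]", b[1], b[2]),
                      character(1))),
    per_bin_n = stats::setNames(
      bin_counts, vapply(LENGTH_BINS, function(b) sprintf("[%d,%d]", b[1], b[2]),
                         character(1))),
    fingerprint = deparse(substitute(fingerprint))
  ), class = "ocsr_eval_report")
}

#' @export
print.ocsr_eval_report <- function(x, ...) {
  cat(sprintf("<ocsr_eval_report> n = %d\n", x$n))
  cat(sprintf("  accuracy  %.4f   tanimoto %.4f   bleu %.4f   rouge-L %.4f\n",
              x$accuracy, x$tanimoto, x$bleu, x$rouge))
  cat(sprintf("  valid DeepSMILES %.4f   valid SMILES %.4f\n",
              x$valid_deepsmiles_rate, x$valid_smiles_rate))
  cat("  per-category accuracy:",
      paste(sprintf("%s=%.3f", names(x$per_category_accuracy),
                    x$per_category_accuracy), collapse = "  "), "\n")
  cat("  per-length-bin accuracy:",
      paste(sprintf("%s=%.3f", names(x$per_bin_accuracy), x$per_bin_accuracy),
            collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate a trained model on rendered samples
#'
#' Greedy-decodes every sample and assembles the [stratified_report()].
#'
#' @param model a trained `ocsr_model`.
#' @param samples samples from [render_samples()].
#' @param records the corpus records the samples reference.
#' @param vocab the vocabulary.
#' @return An `ocsr_eval_report` with attribute `predictions`.
#' @export
evaluate_model <- function(model, samples, records, vocab) {
  preds <- vapply(samples, function(s)
    decode_ids(greedy_decode(model, s$image, vocab), vocab), character(1))
  refs <- vapply(samples, function(s) decode_ids(s$label_ids, vocab), character(1))
  rep_ <- stratified_report(preds, refs,
                            records[vapply(samples, `[[`, 0L, "record"), ,
                                    drop = FALSE])
  attr(rep_, "predictions") <- preds
  rep_
}
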