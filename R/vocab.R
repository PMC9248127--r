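# Character-level DeepSMILES vocabulary, label encoding, and
# token-frequency statistics.

# The 76-character token inventory observed over the full-scale DeepSMILES
# corpus, in its published order.  Each character is one token.
DEEPSMILES_TOKENS_76 <- c(
  "c", "6", ")", "C", "=", "O", "N", "S", "l", "s", "5", "B", "r", "n",
  "[", "H", "+", "]", "%", "1", "0", "/", "\\", "R", "F", "#", "4", "(",
  "9", "-", "@", "L", "3", "8", "2", "'", "G", "a", "7", "Z", ".", "P",
  "t", "Y", "o", "A", "X", "i", "J", "q", "x", "Q", "m", "b", "d", "E",
  "w", "I", "V", "z", "e", "M", ",", "D", "K", "p", "v", "h", "y", "u",
  "g", "k", "T", "W", "U", "f")

VOCAB_SPECIALS <- c(start = "<start>", end = "<end>", pad = "<pad>")

new_vocabulary <- function(tokens) {
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary")
  if (any(tokens %in% VOCAB_SPECIALS)) stop("special markers clash with tokens")
  all_tokens <- c(tokens, unname(VOCAB_SPECIALS))
  ids <- seq_along(all_tokens)
  names(ids) <- all_tokens
  structure(list(
    tokens = tokens,
    specials = VOCAB_SPECIALS,
    token_to_id = ids,
    id_to_token = all_tokens,
    start_id = ids[[VOCAB_SPECIALS[["start"]]]],
    end_id = ids[[VOCAB_SPECIALS[["end"]]]],
    pad_id = ids[[VOCAB_SPECIALS[["pad"]]]],
    size = length(all_tokens)
  ), class = "ocsr_vocab")
}

#' Build a character-level vocabulary
#'
#' With no argument, returns the fixed 76-character inventory (79 ids with
#' the three special markers `<start>`, `<end>`, `<pad>`, which always take
#' the last three ids).  Given a corpus of label strings, returns the
#' sorted set of characters that occur in them plus the specials — a
#' deterministic assignment for any input order.
#'
#' @param corpus optional character vector of DeepSMILES label strings.
#' @return An `ocsr_vocab`: token list, special markers, and mutually
#'   inverse token/id maps.
#' @examples
#' v <- build_vocab()            # the fixed 76-token inventory
#' v$size                        # 79
#' build_vocab(c("CC", "CO"))$tokens
#' @export
build_vocab <- function(corpus = NULL) {
  if (is.null(corpus)) return(new_vocabulary(DEEPSMILES_TOKENS_76))
  stopifnot(is.character(corpus), length(corpus) > 0L)
  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE)),
                method = "radix")
  new_vocabulary(chars)
}

#' @export
print.ocsr_vocab <- function(x, ...) {
  cat(sprintf("<ocsr_vocab> %d character tokens + %d specials (%d ids)\n",
              length(x$tokens), length(x$specials), x$size))
  invisible(x)
}

#' Encode a label string to a padded id sequence
#'
#' Produces `[start] + character ids + [end]`, padded with the pad id to
#' `max_len`.  [decode_ids()] inverts exactly: it strips the start marker,
#' stops at the first end marker (ignoring pads), and concatenates the
#' character tokens, so `decode_ids(encode_ids(s)) == s`.
#'
#' @param deepsmiles character scalar label.
#' @param vocab an `ocsr_vocab`.
#' @param max_len total sequence length including the two markers.
#' @return Integer vector of length `max_len`.
#' @export
encode_ids <- function(deepsmiles, vocab, max_len = 150L) {
  stopifnot(inherits(vocab, "ocsr_vocab"), is.character(deepsmiles),
            length(deepsmiles) == 1L)
  chars <- if (nzchar(deepsmiles)) strsplit(deepsmiles, "", fixed = TRUE)[[1]]
           else character(0)
  if (length(chars) + 2L > max_len)
    stop(sprintf("label of length %d exceeds max_len %d", length(chars), max_len))
  ids <- vocab$token_to_id[chars]
  if (anyNA(ids)) {
    bad <- unique(chars[is.na(ids)])
    stop(sprintf("out-of-vocabulary character(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  }
  out <- c(vocab$start_id, unname(ids), vocab$end_id)
  c(out, rep(vocab$pad_id, max_len - length(out)))
}

#' @rdname encode_ids
#' @param ids integer id vector (possibly shorter than `max_len`, e.g. a
#'   greedy-decoded prefix).
#' @export
decode_ids <- function(ids, vocab) {
  stopifnot(inherits(vocab, "ocsr_vocab"))
  keep <- character(0)
  for (id in ids) {
    if (id == vocab$end_id) break
    if (id == vocab$start_id || id == vocab$pad_id) next
    if (id < 1L || id > length(vocab$id_to_token)) stop("id out of range")
    keep <- c(keep, vocab$id_to_token[[id]])
  }
  paste(keep, collapse = "")
}

#' Token frequencies over a corpus of labels
#'
#' Counts every character occurrence in the label strings (special markers
#' are not part of labels and never counted).  The long-tailed shape of
#' this distribution is what motivates the focal loss over plain
#' cross-entropy.
#'
#' @param corpus character vector of DeepSMILES labels.
#' @param vocab optional vocabulary; tokens absent from the corpus get an
#'   explicit zero count.
#' @return An object of class `ocsr_token_freq`: data frame (`token`,
#'   `count`) sorted by decreasing count, with attribute `total`.
#' @export
token_frequencies <- function(corpus, vocab = NULL) {
  stopifnot(is.character(corpus), length(corpus) > 0L)
  chars <- unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE)
  tab <- table(chars)
  tokens <- if (is.null(vocab)) names(tab) else vocab$tokens
  counts <- as.integer(tab[tokens])
  counts[is.na(counts)] <- 0L
  ord <- order(-counts, tokens, method = "radix")
  out <- data.frame(token = tokens[ord], count = counts[ord],
                    stringsAsFactors = FALSE)
  structure(out, total = sum(counts), class = c("ocsr_token_freq", "data.frame"))
}

#' Per-class weighting factors for the focal loss
#'
#' `scheme = "uniform"` gives every class the same weight `alpha0` (the
#' focal-loss convention, default 0.25).  `scheme = "inverse_frequency"`
#' sets weights proportional to `1 / (count + smoothing)` from a
#' [token_frequencies()] table, normalized to mean 1, so rare tokens weigh
#' more; classes absent from the table (the special markers) get the mean
#' weight 1.
#'
#' @param vocab an `ocsr_vocab`.
#' @param scheme `"uniform"` or `"inverse_frequency"`.
#' @param freq an `ocsr_token_freq` (required for inverse frequency).
#' @param alpha0 the uniform weight value.
#' @param smoothing additive count smoothing for inverse frequency.
#' @return Numeric vector of length `vocab$size`, one weight per class id.
#' @export
alpha_weights <- function(vocab, scheme = c("uniform", "inverse_frequency"),
                          freq = NULL, alpha0 = 0.25, smoothing = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(vocab, "ocsr_vocab"))
  if (scheme == "uniform") return(rep(alpha0, vocab$size))
  stopifnot(inherits(freq, "ocsr_token_freq"))
  counts <- freq$count[match(vocab$tokens, freq$token)]
  counts[is.na(counts)] <- 0L
  w <- 1 / (counts + smoothing)
  w <- w / mean(w)
  c(w, rep(1, length(vocab$specials)))
}

#' Write / read a vocabulary as plain text
#'
#' One token per line, character tokens first, the three special markers
#' (`<start>`, `<end>`, `<pad>`) last; line number = token id.
#'
#' @param vocab an `ocsr_vocab`.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$id_to_token, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ns <- length(VOCAB_SPECIALS)
  if (length(lines) <= ns ||
      !identical(lines[(length(lines) - ns + 1L):length(lines)],
                 unname(VOCAB_SPECIALS)))
    stop("not a vocabulary file (special markers must be the last lines)")
  new_vocabulary(lines[seq_len(length(lines) - ns)])
}
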