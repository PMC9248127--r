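# DeepSMILES <-> SMILES conversion.
#
# DeepSMILES rewrites two SMILES constructs that are error-prone for
# sequence generators because they require paired symbols:
#   * Branches: the '(' is dropped and each ')' pops exactly one atom from
#     the current chain, so a SMILES branch of n atoms ends in a run of n
#     ')' characters.
#   * Ring closures: the paired ring-bond digits are replaced by a single
#     number at the closing atom giving the distance, along the current
#     chain (the branch stack), to the ring partner -- for a simple ring
#     this is the ring size (benzene: "cccccc6").  Distances above 9 use
#     the "%nn" notation.
# Both directions are purely syntactic and share the tokenizer in smiles.R.

deepsmiles_error <- function(msg, s) {
  stop(structure(
    class = c("ocsr_deepsmiles_error", "error", "condition"),
    list(message = sprintf("%s [in: %s]", msg, s), call = sys.call(-1))
  ))
}

#' Convert SMILES to DeepSMILES
#'
#' Both branches and ring closures are rewritten (closing-parenthesis runs
#' and ring-distance digits).  The conversion is syntactic: atom tokens and
#' bond symbols are preserved verbatim.
#'
#' @param smiles character vector of valid SMILES strings.
#' @return Character vector of DeepSMILES strings.
#' @examples
#' to_deepsmiles("c1ccccc1")   # "cccccc6"
#' to_deepsmiles("CC(C)O")     # "CCC)O"
#' to_deepsmiles("CCO")        # "CCO" (acyclic unbranched: unchanged)
#' @export
to_deepsmiles <- function(smiles) {
  vapply(smiles, to_deepsmiles1, character(1), USE.NAMES = FALSE)
}

to_deepsmiles1 <- function(s) {
  toks <- smi_tokenize(s)
  out <- character(0)
  stack <- integer(0)        # atom ids along the current chain
  branch <- list()           # stack snapshots at each '('
  ring_open <- list()        # label -> list(atom, symbol)
  n_atoms <- 0L
  atom_pos <- integer(0)     # atom id -> position in `stack` bookkeeping via match

  for (k in seq_len(nrow(toks))) {
    kind <- toks$kind[k]; text <- toks$text[k]
    if (kind == "atom") {
      n_atoms <- n_atoms + 1L
      stack <- c(stack, n_atoms)
      out <- c(out, text)
    } else if (kind == "bond") {
      # bond symbols before ring digits are handled at the ring token; all
      # others pass through in place
      nxt <- if (k < nrow(toks)) toks$kind[k + 1L] else ""
      if (nxt != "ring") out <- c(out, text)
    } else if (kind == "open") {
      branch[[length(branch) + 1L]] <- length(stack)
    } else if (kind == "close") {
      if (length(branch) == 0L) smiles_error("unmatched ')'", s)
      depth <- branch[[length(branch)]]
      branch[[length(branch)]] <- NULL
      n_pop <- length(stack) - depth
      if (n_pop < 1L) smiles_error("empty branch", s)
      out <- c(out, rep(")", n_pop))
      stack <- stack[seq_len(depth)]
    } else if (kind == "ring") {
      label <- if (startsWith(text, "%")) substring(text, 2L) else text
      cur <- stack[length(stack)]
      sym <- if (k > 1L && toks$kind[k - 1L] == "bond") toks$text[k - 1L] else NA_character_
      if (!is.null(ring_open[[label]])) {
        op <- ring_open[[label]]
        pos <- match(op$atom, stack)
        if (is.na(pos))
          deepsmiles_error(sprintf(
            "ring partner for closure %s is not on the current chain; not representable",
            label), s)
        dist <- length(stack) - pos + 1L
        use_sym <- if (!is.na(sym)) sym else op$symbol
        out <- c(out, if (!is.na(use_sym)) use_sym,
                 if (dist <= 9L) as.character(dist) else sprintf("%%%02d", dist))
        ring_open[[label]] <- NULL
      } else {
        ring_open[[label]] <- list(atom = cur, symbol = sym)
      }
    } else if (kind == "dot") {
      if (length(branch) > 0L) smiles_error("'.' inside a branch", s)
      stack <- integer(0)
      out <- c(out, ".")
    }
  }
  if (length(ring_open) > 0L) smiles_error("unmatched ring closure", s)
  paste(out, collapse = "")
}

#' Convert DeepSMILES back to SMILES
#'
#' Reconstructs the branch tree by popping one atom per `)` and resolving
#' each ring-distance number against the current chain, then writes a
#' SMILES string by depth-first traversal.  Malformed input (a ring
#' distance reaching past the chain start, an unmatched `(`, a `)` with no
#' atom to pop, an impossible bracket atom) raises an
#' `ocsr_deepsmiles_error`; callers computing validity rates should catch
#' it, e.g. with [is_valid_deepsmiles()].
#'
#' @param deepsmiles character vector of DeepSMILES strings.
#' @return Character vector of SMILES strings.
#' @examples
#' from_deepsmiles("cccccc6")  # "c1ccccc1"
#' from_deepsmiles("CCC)O")    # "CC(C)O"
#' @export
from_deepsmiles <- function(deepsmiles) {
  vapply(deepsmiles, from_deepsmiles1, character(1), USE.NAMES = FALSE)
}

from_deepsmiles1 <- function(s) {
  toks <- tryCatch(smi_tokenize(s), error = function(e)
    deepsmiles_error(conditionMessage(e), s))
  n <- 0L
  tokens <- character(0)     # atom id -> atom token text
  parent <- integer(0)       # atom id -> parent atom id (0 = root)
  pbond <- character(0)      # atom id -> bond symbol to parent ("" = default)
  children <- list()         # atom id -> ordered child ids
  rings <- list()            # list of list(a1, a2, symbol)
  stack <- integer(0)
  pending <- NA_character_
  roots <- integer(0)

  for (k in seq_len(nrow(toks))) {
    kind <- toks$kind[k]; text <- toks$text[k]
    if (kind == "atom") {
      if (grepl("^\\[", text)) parse_bracket_atom(text, s)  # validate
      n <- n + 1L
      tokens[n] <- text
      children[[n]] <- integer(0)
      if (length(stack) > 0L) {
        par <- stack[length(stack)]
        parent[n] <- par
        pbond[n] <- if (is.na(pending)) "" else pending
        children[[par]] <- c(children[[par]], n)
      } else {
        parent[n] <- 0L
        pbond[n] <- ""
        roots <- c(roots, n)
      }
      pending <- NA_character_
      stack <- c(stack, n)
    } else if (kind == "bond") {
      if (!is.na(pending)) deepsmiles_error("two consecutive bond symbols", s)
      pending <- text
    } else if (kind == "close") {
      if (!is.na(pending)) deepsmiles_error("bond symbol before ')'", s)
      if (length(stack) <= 1L)
        deepsmiles_error("')' pops past the start of the chain", s)
      stack <- stack[-length(stack)]
    } else if (kind == "open") {
      deepsmiles_error("'(' is not part of the DeepSMILES grammar", s)
    } else if (kind == "ring") {
      dist <- as.integer(if (startsWith(text, "%")) substring(text, 2L) else text)
      if (dist < 3L) deepsmiles_error(sprintf("impossible ring size %d", dist), s)
      if (length(stack) < dist)
        deepsmiles_error(sprintf("ring distance %d reaches past the chain start", dist), s)
      cur <- stack[length(stack)]
      partner <- stack[length(stack) - dist + 1L]
      for (r in rings)
        if ((r$a1 == partner && r$a2 == cur))
          deepsmiles_error("duplicate ring bond", s)
      rings[[length(rings) + 1L]] <- list(a1 = partner, a2 = cur,
                                          symbol = if (is.na(pending)) "" else pending)
      pending <- NA_character_
    } else if (kind == "dot") {
      if (!is.na(pending)) deepsmiles_error("bond symbol before '.'", s)
      stack <- integer(0)
    }
  }
  if (!is.na(pending)) deepsmiles_error("dangling bond symbol at end", s)
  if (n == 0L) deepsmiles_error("no atoms", s)

  # assign SMILES ring-closure labels: smallest label whose lifetime
  # [opening atom, closing atom] does not overlap any ring already holding
  # that label (labels may be reused once their ring has closed)
  ring_at <- vector("list", n)  # atom id -> list of list(label, symbol, closing)
  if (length(rings) > 0L) {
    events <- rings
    opens_at <- vapply(events, function(r) r$a1, integer(1))
    closes_at <- vapply(events, function(r) r$a2, integer(1))
    label_of <- integer(length(events))
    for (e in order(opens_at, closes_at)) {
      lab <- 1L
      repeat {
        clash <- any(label_of == lab &
                     !(closes_at < opens_at[e] | opens_at > closes_at[e]))
        if (!clash) break
        lab <- lab + 1L
      }
      label_of[e] <- lab
    }
    for (j in seq_along(events)) {
      r <- events[[j]]
      ring_at[[r$a1]] <- c(ring_at[[r$a1]],
                           list(list(label = label_of[j], symbol = "", closing = FALSE)))
      ring_at[[r$a2]] <- c(ring_at[[r$a2]],
                           list(list(label = label_of[j], symbol = r$symbol, closing = TRUE)))
    }
  }

  write_atom <- function(a) {
    parts <- tokens[a]
    for (rc in ring_at[[a]]) {
      lab <- if (rc$label <= 9L) as.character(rc$label) else sprintf("%%%02d", rc$label)
      parts <- paste0(parts, if (rc$closing && nzchar(rc$symbol)) rc$symbol, lab)
    }
    kids <- children[[a]]
    if (length(kids) > 0L) {
      for (kid in kids[-length(kids)])
        parts <- paste0(parts, "(", pbond[kid], write_atom(kid), ")")
      last <- kids[length(kids)]
      parts <- paste0(parts, pbond[last], write_atom(last))
    }
    parts
  }
  paste(vapply(roots, write_atom, character(1)), collapse = ".")
}

#' Test whether strings are syntactically valid DeepSMILES
#'
#' A string is valid when [from_deepsmiles()] reconstructs a SMILES string
#' from it without error.  Use [is_valid_smiles()] on the reconstruction to
#' additionally test chemical parseability.
#'
#' @param deepsmiles character vector.
#' @return Logical vector.
#' @export
is_valid_deepsmiles <- function(deepsmiles) {
  vapply(deepsmiles, function(d)
    tryCatch({ from_deepsmiles1(d); TRUE }, error = function(e) FALSE),
    logical(1), USE.NAMES = FALSE)
}
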