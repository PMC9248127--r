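# SMILES tokenizer, strict syntactic parser and a light valence model.
#
# The parser is deliberately independent of any external toolkit: it is the
# basis for DeepSMILES conversion (which is purely syntactic), for locating
# substitutable sites during corpus construction, and for the path-based
# fingerprints used by the Tanimoto metric.  Canonicalization itself is
# delegated to OpenBabel (see babel.R); this parser enforces the strictness
# (balanced branches, matched ring bonds, known atom symbols) that permissive
# toolkits silently repair.

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                    "b", "c", "n", "o", "p", "s")
BOND_CHARS <- c("-", "=", "#", "$", ":", "/", "\\")
BOND_ORDER <- c("-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1, "/" = 1, "\\" = 1)

smiles_error <- function(msg, smiles) {
  stop(structure(
    class = c("ocsr_smiles_error", "error", "condition"),
    list(message = sprintf("%s [in: %s]", msg, smiles), call = sys.call(-1))
  ))
}

#' Tokenize a SMILES (or DeepSMILES) string
#'
#' Splits a string into atom, bond, branch, ring-closure and dot tokens.
#' DeepSMILES shares the same token inventory (its `)` runs and ring-size
#' digits reuse the branch-close and ring-closure token kinds), so a single
#' tokenizer serves both grammars.
#'
#' @param s character scalar to tokenize.
#' @return A data frame with columns `kind` (one of `atom`, `bond`, `open`,
#'   `close`, `ring`, `dot`), `text` (the token), and `pos` (1-based
#'   character offset of the token start).
#' @examples
#' smi_tokenize("c1ccccc1")
#' smi_tokenize("CC(=O)[O-]")
#' @export
smi_tokenize <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) smiles_error("empty string", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kinds <- character(0); texts <- character(0); poss <- integer(0)
  i <- 1L
  push <- function(kind, text, pos) {
    kinds[[length(kinds) + 1L]] <<- kind
    texts[[length(texts) + 1L]] <<- text
    poss[[length(poss) + 1L]] <<- pos
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) smiles_error(sprintf("unclosed bracket atom at position %d", i), s)
      push("atom", paste(chars[i:j], collapse = ""), i)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push("atom", paste0(ch, chars[i + 1L]), i)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      push("atom", ch, i)
      i <- i + 1L
    } else if (ch %in% BOND_CHARS) {
      push("bond", ch, i)
      i <- i + 1L
    } else if (ch == "(") {
      push("open", ch, i); i <- i + 1L
    } else if (ch == ")") {
      push("close", ch, i); i <- i + 1L
    } else if (ch == ".") {
      push("dot", ch, i); i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      push("ring", ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        smiles_error(sprintf("malformed %%nn ring closure at position %d", i), s)
      push("ring", paste(chars[i:(i + 2L)], collapse = ""), i)
      i <- i + 3L
    } else {
      smiles_error(sprintf("unexpected character '%s' at position %d", ch, i), s)
    }
  }
  data.frame(kind = kinds, text = texts, pos = poss, stringsAsFactors = FALSE)
}

# Parse the inside of a bracket atom token "[...]" into its fields.
parse_bracket_atom <- function(tok, s) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  if (!nzchar(body)) smiles_error("empty bracket atom", s)
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Z][a-z]?|[a-z]|\\*)((?:@{1,2}|@TH[12])?)(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L || !nzchar(m[1]))
    smiles_error(sprintf("malformed bracket atom '%s'", tok), s)
  iso <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
  elem <- m[3]
  hstr <- m[5]
  hcount <- if (is.na(hstr) || !nzchar(hstr)) 0L
            else if (hstr == "H") 1L else as.integer(substring(hstr, 2L))
  cstr <- m[6]
  charge <- 0L
  if (!is.na(cstr) && nzchar(cstr)) {
    if (grepl("^[+-][0-9]+$", cstr)) {
      charge <- as.integer(cstr)
    } else {
      charge <- (nchar(cstr)) * if (substr(cstr, 1L, 1L) == "+") 1L else -1L
    }
  }
  list(element = elem, aromatic = grepl("^[a-z]", elem) && elem != "*",
       isotope = iso, hcount = hcount, charge = charge)
}

#' Parse a SMILES string into a molecular graph
#'
#' Strict syntactic parse: unbalanced branches, unmatched ring-closure
#' digits, bonds in illegal positions, and unknown atom symbols are all
#' rejected with an error naming the offending string.  No aromaticity
#' perception or valence normalization is performed beyond what the string
#' states.
#'
#' @param s character scalar, a SMILES string.
#' @return An object of class `ocsr_mol`: a list with `atoms` (data frame:
#'   `token`, `element`, `aromatic`, `bracket`, `hcount`, `charge`,
#'   `isotope`, `tok_row` index into the token table), `bonds` (data frame:
#'   `a1`, `a2`, `order`, `symbol`, `ring` flag), `tokens` (the token table)
#'   and `smiles` (the input).
#' @examples
#' mol <- smi_parse("CC(=O)O")
#' mol$atoms$element
#' @export
smi_parse <- function(s) {
  toks <- smi_tokenize(s)
  n_tok <- nrow(toks)
  atoms <- list(); bonds <- list()
  stack <- integer(0)                # current chain of atom ids
  branch <- list()                   # saved stack tops at each '('
  ring_open <- list()                # label -> list(atom, symbol)
  pending_bond <- NA_character_
  last_was_atom_or_ring <- FALSE

  add_bond <- function(a1, a2, symbol, ring = FALSE) {
    arom <- atoms[[a1]]$aromatic && atoms[[a2]]$aromatic && is.na(symbol)
    ord <- if (is.na(symbol)) 1 else unname(BOND_ORDER[[symbol]])
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = ord,
                                         symbol = symbol, aromatic = arom,
                                         ring = ring)
  }

  for (k in seq_len(n_tok)) {
    kind <- toks$kind[k]; text <- toks$text[k]
    if (kind == "atom") {
      if (text %in% ORGANIC_SUBSET) {
        at <- list(token = text, element = toupper(text),
                   aromatic = text %in% c("b", "c", "n", "o", "p", "s"),
                   bracket = FALSE, hcount = NA_integer_, charge = 0L,
                   isotope = NA_integer_, tok_row = k)
        at$element <- if (at$aromatic) toupper(text) else text
      } else {
        ba <- parse_bracket_atom(text, s)
        at <- list(token = text,
                   element = if (ba$aromatic) {
                     paste0(toupper(substr(ba$element, 1L, 1L)),
                            substring(ba$element, 2L))
                   } else ba$element,
                   aromatic = ba$aromatic, bracket = TRUE,
                   hcount = ba$hcount, charge = ba$charge,
                   isotope = ba$isotope, tok_row = k)
      }
      atoms[[length(atoms) + 1L]] <- at
      id <- length(atoms)
      if (length(stack) > 0L) add_bond(stack[length(stack)], id, pending_bond)
      pending_bond <- NA_character_
      stack <- c(stack, id)
      last_was_atom_or_ring <- TRUE
    } else if (kind == "bond") {
      if (!is.na(pending_bond))
        smiles_error(sprintf("two consecutive bond symbols at position %d", toks$pos[k]), s)
      pending_bond <- text
      last_was_atom_or_ring <- FALSE
    } else if (kind == "open") {
      if (length(stack) == 0L)
        smiles_error(sprintf("branch opened before any atom at position %d", toks$pos[k]), s)
      if (!is.na(pending_bond))
        smiles_error(sprintf("bond symbol before '(' at position %d", toks$pos[k]), s)
      branch[[length(branch) + 1L]] <- stack
      last_was_atom_or_ring <- FALSE
    } else if (kind == "close") {
      if (length(branch) == 0L)
        smiles_error(sprintf("unmatched ')' at position %d", toks$pos[k]), s)
      if (!last_was_atom_or_ring)
        smiles_error(sprintf("empty or ill-formed branch closing at position %d", toks$pos[k]), s)
      stack <- branch[[length(branch)]]
      branch[[length(branch)]] <- NULL
      last_was_atom_or_ring <- TRUE
    } else if (kind == "ring") {
      if (length(stack) == 0L)
        smiles_error(sprintf("ring closure before any atom at position %d", toks$pos[k]), s)
      label <- if (startsWith(text, "%")) substring(text, 2L) else text
      cur <- stack[length(stack)]
      if (!is.null(ring_open[[label]])) {
        op <- ring_open[[label]]
        if (op$atom == cur)
          smiles_error(sprintf("ring bond %s closes on its opening atom", label), s)
        symbol <- if (!is.na(pending_bond)) pending_bond else op$symbol
        add_bond(op$atom, cur, symbol, ring = TRUE)
        ring_open[[label]] <- NULL
      } else {
        ring_open[[label]] <- list(atom = cur, symbol = pending_bond)
      }
      pending_bond <- NA_character_
      last_was_atom_or_ring <- TRUE
    } else if (kind == "dot") {
      if (!is.na(pending_bond))
        smiles_error(sprintf("bond symbol before '.' at position %d", toks$pos[k]), s)
      if (length(branch) > 0L)
        smiles_error(sprintf("'.' inside a branch at position %d", toks$pos[k]), s)
      stack <- integer(0)
      last_was_atom_or_ring <- FALSE
    }
  }
  if (length(branch) > 0L) smiles_error("unbalanced '(' left open", s)
  if (length(ring_open) > 0L)
    smiles_error(sprintf("unmatched ring closure(s): %s",
                         paste(names(ring_open), collapse = ", ")), s)
  if (!is.na(pending_bond)) smiles_error("dangling bond symbol at end", s)
  if (length(atoms) == 0L) smiles_error("no atoms", s)

  atoms_df <- do.call(rbind, lapply(atoms, function(a)
    data.frame(token = a$token, element = a$element, aromatic = a$aromatic,
               bracket = a$bracket, hcount = a$hcount, charge = a$charge,
               isotope = a$isotope, tok_row = a$tok_row,
               stringsAsFactors = FALSE)))
  bonds_df <- if (length(bonds) > 0L) {
    do.call(rbind, lapply(bonds, function(b)
      data.frame(a1 = b$a1, a2 = b$a2, order = b$order,
                 symbol = ifelse(is.na(b$symbol), "", b$symbol),
                 aromatic = b$aromatic, ring = b$ring,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0),
               symbol = character(0), aromatic = logical(0), ring = logical(0),
               stringsAsFactors = FALSE)
  }
  structure(list(atoms = atoms_df, bonds = bonds_df, tokens = toks, smiles = s),
            class = "ocsr_mol")
}

# Typical valences used for the implicit-hydrogen estimate.  For elements
# with several typical valences the smallest one at or above the explicit
# bond-order sum is used, as in the SMILES organic-subset convention.
TYPICAL_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

#' Implicit hydrogen counts for a parsed molecule
#'
#' Organic-subset atoms receive the standard implicit-hydrogen count: the
#' smallest typical valence at or above the explicit bond-order sum minus
#' that sum.  Aromatic atoms count each ring bond as one and reserve one
#' additional unit of valence for the delocalized system (so an unfused
#' aromatic carbon with two ring neighbours carries one hydrogen).  Bracket
#' atoms state their hydrogens explicitly and always report the stated
#' count.
#'
#' @param mol an `ocsr_mol` from [smi_parse()].
#' @return Integer vector, one entry per atom.
#' @export
smi_implicit_h <- function(mol) {
  stopifnot(inherits(mol, "ocsr_mol"))
  na <- nrow(mol$atoms)
  bsum <- numeric(na)
  if (nrow(mol$bonds) > 0L) {
    for (i in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[i, ]
      ord <- if (b$aromatic) 1 else b$order
      bsum[b$a1] <- bsum[b$a1] + ord
      bsum[b$a2] <- bsum[b$a2] + ord
    }
  }
  out <- integer(na)
  for (i in seq_len(na)) {
    a <- mol$atoms[i, ]
    if (a$bracket) { out[i] <- a$hcount; next }
    need <- bsum[i] + if (a$aromatic) 1 else 0
    vals <- TYPICAL_VALENCE[[a$element]]
    if (is.null(vals)) { out[i] <- 0L; next }
    v <- vals[vals >= need]
    out[i] <- if (length(v) == 0L) 0L else as.integer(v[1] - need)
  }
  out
}

# Adjacency list (atom id -> data.frame of neighbour id, order, aromatic).
mol_adjacency <- function(mol) {
  adj <- vector("list", nrow(mol$atoms))
  for (i in seq_along(adj)) adj[[i]] <- list(nb = integer(0), order = numeric(0),
                                             aromatic = logical(0))
  if (nrow(mol$bonds) > 0L) {
    for (i in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[i, ]
      adj[[b$a1]]$nb <- c(adj[[b$a1]]$nb, b$a2)
      adj[[b$a1]]$order <- c(adj[[b$a1]]$order, b$order)
      adj[[b$a1]]$aromatic <- c(adj[[b$a1]]$aromatic, b$aromatic)
      adj[[b$a2]]$nb <- c(adj[[b$a2]]$nb, b$a1)
      adj[[b$a2]]$order <- c(adj[[b$a2]]$order, b$order)
      adj[[b$a2]]$aromatic <- c(adj[[b$a2]]$aromatic, b$aromatic)
    }
  }
  adj
}

#' @export
print.ocsr_mol <- function(x, ...) {
  cat(sprintf("<ocsr_mol> %s: %d atoms, %d bonds\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}
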