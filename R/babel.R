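# Canonicalization and 2D coordinate generation via OpenBabel.
#
# Strings are validated by the package's own strict parser before being
# handed to OpenBabel, because OpenBabel silently repairs syntax errors
# (e.g. it parses "C(" as methane) that must be rejected here.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("the 'obabel' executable was not found on the PATH")
  unname(p)
}

# Conversion through obabel, one molecule per process: OpenBabel's Kekulé
# writer carries perception state across molecules within a run, so batching
# would make each output depend on the rest of the batch.  Results are
# memoized per session.
.ob_cache <- new.env(parent = emptyenv())

ob_convert_smiles <- function(smiles, kekule = FALSE) {
  if (length(smiles) == 0L) return(character(0))
  vapply(smiles, function(s) {
    key <- paste0(if (kekule) "k|" else "a|", s)
    hit <- get0(key, envir = .ob_cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    args <- c("-ismi", "-ocan", if (kekule) "-xk")
    out <- suppressWarnings(system2(obabel_path(), args, stdout = TRUE,
                                    stderr = FALSE, input = s))
    res <- if (length(out) >= 1L && nzchar(trimws(out[1])))
      strsplit(trimws(out[1]), "\t", fixed = TRUE)[[1]][1]
    else NA_character_
    assign(key, res, envir = .ob_cache)
    res
  }, character(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Validates each string with the strict parser, then converts it to the
#' canonical form.  `form = "aromatic"` (default) writes aromatic rings
#' with lowercase atoms; `form = "kekule"` writes alternating explicit
#' bonds.  Canonicalization is idempotent: applying it to its own output
#' returns the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @param form `"aromatic"` or `"kekule"` ring form of the output.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize("OCC")                      # "CCO"
#' canonicalize("C1=CC=CC=C1")              # "c1ccccc1"
#' canonicalize("c1ccccc1", form = "kekule")
#' @export
canonicalize <- function(smiles, form = c("aromatic", "kekule")) {
  form <- match.arg(form)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  for (s in smiles) smi_parse(s)            # strict syntax gate
  kek <- identical(form, "kekule")
  # The canonical atom order is stable after one pass, but the Kekulé
  # writer's double-bond placement depends on the input's explicit bond
  # pattern and can cycle between equivalent assignments.  Iterate the
  # writer until its orbit repeats and return the lexicographically
  # smallest string on the cycle: a deterministic canonical representative
  # that is a fixed point of this whole procedure.
  vapply(smiles, function(s0) {
    cur <- ob_convert_smiles(s0, kekule = kek)
    if (is.na(cur) || !nzchar(cur))
      smiles_error("canonicalization failed", s0)
    seen <- character(0)
    for (pass in 1:10) {
      hit <- match(cur, seen)
      if (!is.na(hit)) return(min(seen[hit:length(seen)]))
      seen <- c(seen, cur)
      cur <- ob_convert_smiles(cur, kekule = kek)
      if (is.na(cur)) smiles_error("canonicalization failed", s0)
    }
    smiles_error("canonical form did not stabilize", s0)
  }, character(1), USE.NAMES = FALSE)
}

#' Rewrite a molecule in aromatic or Kekulé ring form
#'
#' Both forms are canonical strings for the same molecule: the aromatic
#' form uses lowercase aromatic atom symbols, the Kekulé form spells
#' aromatic rings with alternating explicit single/double bonds.  Molecule
#' identity is preserved (the aromatic canonical forms of input and output
#' agree); acyclic molecules are returned unchanged up to canonical
#' ordering.
#'
#' @param smiles character vector of valid SMILES strings.
#' @param form `"aromatic"` or `"kekule"`.
#' @return Character vector of rewritten canonical SMILES.
#' @examples
#' to_ring_form("c1ccccc1", "kekule")
#' to_ring_form("C1=CC=CC=C1", "aromatic")  # "c1ccccc1"
#' @export
to_ring_form <- function(smiles, form = c("aromatic", "kekule")) {
  form <- match.arg(form)
  out <- canonicalize(smiles, form = form)
  if (identical(form, "kekule")) {
    arom <- grepl("[cnops]", gsub("\\[[^]]*\\]", "", out))
    if (any(arom))
      smiles_error(sprintf("kekulization failed for: %s",
                           paste(smiles[arom], collapse = ", ")), smiles[arom][1])
  }
  out
}

#' Test whether strings are valid SMILES
#'
#' A string is valid when it passes the strict syntactic parser and
#' OpenBabel parses it to at least one atom.
#'
#' @param smiles character vector.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    ok <- tryCatch({ smi_parse(s); TRUE }, error = function(e) FALSE)
    if (!ok) return(FALSE)
    out <- tryCatch(ob_convert_smiles(s), error = function(e) NA_character_)
    !is.na(out) && nzchar(out)
  }, logical(1), USE.NAMES = FALSE)
}

# 2D coordinates: returns list(coords = n x 2 matrix, elements, charges,
# isotopes, bonds = data.frame(a1, a2, order)) from an OpenBabel --gen2d
# molfile.  Atom order follows the input SMILES atom order.
ob_gen2d <- function(smiles) {
  input <- paste0(smiles, " mol", "\n")
  out <- suppressWarnings(system2(obabel_path(), c("-ismi", "-omol", "--gen2d"),
                                  stdout = TRUE, stderr = FALSE, input = input))
  if (length(out) < 4L) smiles_error("2D coordinate generation failed", smiles)
  counts <- out[4]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L) smiles_error("2D coordinate generation failed", smiles)
  atom_lines <- out[5:(4L + na)]
  coords <- t(vapply(atom_lines, function(l)
    c(as.numeric(substr(l, 1L, 10L)), as.numeric(substr(l, 11L, 20L))),
    numeric(2), USE.NAMES = FALSE))
  elements <- trimws(substr(atom_lines, 32L, 34L))
  bonds <- if (nb > 0L) {
    bl <- out[(5L + na):(4L + na + nb)]
    data.frame(a1 = as.integer(substr(bl, 1L, 3L)),
               a2 = as.integer(substr(bl, 4L, 6L)),
               order = as.integer(substr(bl, 7L, 9L)))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  charges <- integer(na); isotopes <- integer(na)
  for (l in grep("^M  (CHG|ISO)", out, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(substring(l, 7L)), "\\s+")[[1]])
    nset <- fields[1]
    for (k in seq_len(nset)) {
      at <- fields[2L * k]; val <- fields[2L * k + 1L]
      if (startsWith(l, "M  CHG")) charges[at] <- val else isotopes[at] <- val
    }
  }
  list(coords = coords, elements = elements, charges = charges,
       isotopes = isotopes, bonds = bonds)
}
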