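# Four-category synthetic molecule corpus with DeepSMILES labels.
#
# Categories follow the two-way design of the training corpus:
#   1  Kekule ring form,   no injected substituent
#   2  aromatic ring form, no injected substituent
#   3  Kekule ring form,   with injected substituents / bracket atoms
#   4  aromatic ring form, with injected substituents / bracket atoms
# Category 3 derives from category-1-style molecules and category 4 from
# category-2-style molecules by graph-aware substituent attachment.

#' Substituent and bracket-atom pools
#'
#' Loads the attachable-group inventories used when building categories 3
#' and 4.  The bundled defaults hold 34 common patent-style substituent
#' fragments and the 17-entry bracket-atom inventory; both files are plain
#' text (one entry per line, `#` comments) and can be swapped for larger
#' lists.
#'
#' @param substituents_file,bracket_atoms_file optional paths overriding the
#'   bundled pools.
#' @return An object of class `ocsr_pools`: list with character vectors
#'   `substituents` and `bracket_atoms`.
#' @export
substituent_pools <- function(substituents_file = NULL, bracket_atoms_file = NULL) {
  subs <- read_lines_clean(substituents_file %||% ocsr_extdata("substituents.txt"))
  bracks <- read_lines_clean(bracket_atoms_file %||% ocsr_extdata("bracket_atoms.txt"))
  if (length(subs) == 0L || length(bracks) == 0L)
    stop("substituent pools must be non-empty")
  structure(list(substituents = subs, bracket_atoms = bracks),
            class = "ocsr_pools")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ocsr_pools <- function(x, ...) {
  cat(sprintf("<ocsr_pools> %d substituents, %d bracket atoms\n",
              length(x$substituents), length(x$bracket_atoms)))
  invisible(x)
}

# Character offset just after an atom token and its trailing ring-closure
# digits (and their bond prefixes), i.e. the legal insertion point for a
# new branch on that atom.
branch_insertion_offset <- function(mol, atom_id) {
  toks <- mol$tokens
  k <- mol$atoms$tok_row[atom_id]
  end_tok <- k
  j <- k + 1L
  while (j <= nrow(toks)) {
    if (toks$kind[j] == "ring") { end_tok <- j; j <- j + 1L }
    else if (toks$kind[j] == "bond" && j < nrow(toks) && toks$kind[j + 1L] == "ring") {
      end_tok <- j + 1L; j <- j + 2L
    } else break
  }
  toks$pos[end_tok] + nchar(toks$text[end_tok]) - 1L
}

#' Attach substituents to a molecule
#'
#' Inserts `n_attach` entries drawn from the pools as branches at uniformly
#' chosen substitutable sites (non-bracket atoms carrying at least one
#' implicit hydrogen).  Attachment operates on the molecular graph via the
#' string: the fragment is inserted as a parenthesised branch immediately
#' after the chosen atom token (after its ring-closure digits), which
#' always yields a syntactically valid string, and the result is verified
#' to parse.  Deterministic for a fixed `seed`.
#'
#' @param smiles character scalar, a valid SMILES string.
#' @param pools an `ocsr_pools` object.
#' @param n_attach number of attachments (>= 1).
#' @param seed integer seed for site and fragment choice.
#' @param max_tries retry budget for sites whose attachment fails to parse.
#' @return A valid SMILES string with the attachments in place (not
#'   canonicalized, so the inserted fragments are still textually visible).
#' @export
attach_substituents <- function(smiles, pools, n_attach = 1L, seed = 1L,
                                max_tries = 20L) {
  stopifnot(inherits(pools, "ocsr_pools"), n_attach >= 1L)
  with_seed(seed, {
    cur <- smiles
    entries <- c(pools$substituents, pools$bracket_atoms)
    for (a in seq_len(n_attach)) {
      mol <- smi_parse(cur)
      hs <- smi_implicit_h(mol)
      sites <- which(hs >= 1L & !mol$atoms$bracket)
      if (length(sites) == 0L)
        smiles_error("no substitutable site (no atom with an implicit hydrogen)", cur)
      done <- FALSE
      for (try in seq_len(max_tries)) {
        site <- sample_from(sites)
        frag <- sample_from(entries)
        off <- branch_insertion_offset(mol, site)
        cand <- paste0(substr(cur, 1L, off), "(", frag, ")",
                       substring(cur, off + 1L))
        ok <- tryCatch({ smi_parse(cand); TRUE }, error = function(e) FALSE)
        if (ok && is_valid_smiles(cand)) { cur <- cand; done <- TRUE; break }
      }
      if (!done)
        smiles_error(sprintf("attachment failed after %d attempts", max_tries), cur)
    }
    cur
  })
}

new_corpus_records <- function(smiles, deepsmiles, category, split = NA_character_) {
  n <- length(smiles)
  data.frame(smiles = smiles, deepsmiles = deepsmiles,
             category = rep(as.integer(category), length.out = n),
             split = rep(split, length.out = n),
             stringsAsFactors = FALSE)
}

#' Build the four-category corpus
#'
#' From a pool of source molecules, builds `sizes_per_category[k]` records
#' for each category k with unique canonical SMILES within each category:
#' category 1 is the canonical Kekulé form, category 2 the canonical
#' aromatic form, and categories 3 and 4 add substituents to category-1 and
#' category-2 style molecules respectively before re-canonicalizing in the
#' matching ring form.  Every record carries its DeepSMILES label.
#' Deterministic for a fixed `seed`.
#'
#' @param source_smiles character vector of source molecules.
#' @param sizes_per_category integer vector of length 4.
#' @param pools an `ocsr_pools` object (see [substituent_pools()]).
#' @param seed integer seed.
#' @param n_attach_range inclusive range the per-molecule attachment count
#'   is drawn from for categories 3 and 4.
#' @param track_parents also return a `parent` column holding, for
#'   categories 3 and 4, the unsubstituted base molecule each record was
#'   derived from (`NA` for categories 1 and 2).  The column is dropped by
#'   [write_corpus()], which emits the fixed four-column manifest.
#' @return A data frame of corpus records (`smiles`, `deepsmiles`,
#'   `category`, `split`); `split` is `NA` until [split_corpus()] is
#'   applied.
#' @export
build_corpus <- function(source_smiles, sizes_per_category, pools, seed = 1L,
                         n_attach_range = c(1L, 3L), track_parents = FALSE) {
  stopifnot(length(sizes_per_category) == 4L, all(sizes_per_category >= 0L),
            inherits(pools, "ocsr_pools"))
  canon <- unique(canonicalize(source_smiles, form = "aromatic"))
  with_seed(seed, {
    shuffled <- sample(canon)
    recs <- list()
    shortfall <- integer(0)
    # one cursor across all categories: each category draws fresh source
    # molecules, mirroring the full-scale corpus where categories are built
    # from distinct structures rather than re-dressings of the same ones
    src_i <- 0L
    for (cat in 1:4) {
      need <- sizes_per_category[cat]
      if (need == 0L) next
      form <- if (cat %in% c(1L, 3L)) "kekule" else "aromatic"
      seen <- character(0)
      got_s <- character(0)
      got_parent <- character(0)
      while (length(got_s) < need) {
        src_i <- src_i + 1L
        if (src_i > length(shuffled)) break
        base <- tryCatch(to_ring_form(shuffled[src_i], form = form),
                         error = function(e) NA_character_)
        if (is.na(base)) next
        s <- if (cat >= 3L) {
          att_seed <- sample.int(.Machine$integer.max, 1L)
          n_att <- sample(seq(n_attach_range[1], n_attach_range[2]), 1L)
          tryCatch(
            to_ring_form(attach_substituents(base, pools, n_attach = n_att,
                                             seed = att_seed), form = form),
            error = function(e) NA_character_)
        } else base
        if (is.na(s) || s %in% seen) next
        seen <- c(seen, s)
        got_s <- c(got_s, s)
        got_parent <- c(got_parent, if (cat >= 3L) base else NA_character_)
      }
      if (length(got_s) < need) {
        shortfall[as.character(cat)] <- need - length(got_s)
        next
      }
      recs[[cat]] <- new_corpus_records(got_s, to_deepsmiles(got_s), cat)
      if (track_parents) recs[[cat]]$parent <- got_parent
    }
    if (length(shortfall) > 0L)
      stop(sprintf(
        "not enough unique molecules: short by %s",
        paste(sprintf("%d in category %s", shortfall, names(shortfall)),
              collapse = ", ")))
    do.call(rbind, recs)
  })
}

#' Assign train/validation/test splits
#'
#' Splits records within each category independently at the given ratio
#' (default 18:1:1).  Validation and test sizes are `floor(n * part /
#' sum(ratio))`; integer remainders go to the training split.  Assignment
#' is a seeded random permutation, so the partition is disjoint, exhaustive
#' and reproducible.
#'
#' @param records corpus records data frame.
#' @param ratio positive numeric vector of length 3 (train, validation,
#'   test parts).
#' @param seed integer seed.
#' @return The records with the `split` column filled with `"train"`,
#'   `"validation"` or `"test"`.
#' @export
split_corpus <- function(records, ratio = c(18, 1, 1), seed = 1L) {
  stopifnot(length(ratio) == 3L, all(ratio > 0))
  unit <- sum(ratio)
  with_seed(seed, {
    for (cat in sort(unique(records$category))) {
      idx <- which(records$category == cat)
      n <- length(idx)
      if (n < unit)
        warning(sprintf(
          "category %d has only %d records (< %d); split by proportional rounding",
          cat, n, unit))
      n_val <- floor(n * ratio[2] / unit)
      n_test <- floor(n * ratio[3] / unit)
      perm <- sample(idx)
      records$split[perm] <- c(rep("validation", n_val), rep("test", n_test),
                               rep("train", n - n_val - n_test))
    }
    records
  })
}

#' Generate a small fully-formed corpus from the bundled molecule list
#'
#' Desk-scale fixture generator: builds `n_per_category` records per
#' category from the bundled source list and pools, assigns 18:1:1 splits,
#' and is byte-reproducible for a fixed seed.  The bundled list guarantees
#' rings of size >= 5, bracket atoms, and DeepSMILES label lengths spanning
#' several evaluation length bins.
#'
#' @param n_per_category records per category (>= 1).
#' @param seed integer seed.
#' @return A corpus records data frame with splits assigned.
#' @export
generate_tiny_corpus <- function(n_per_category = 8L, seed = 1L) {
  stopifnot(n_per_category >= 1L)
  src <- read_lines_clean(ocsr_extdata("source_smiles.txt"))
  pools <- substituent_pools()
  recs <- build_corpus(src, rep(n_per_category, 4L), pools, seed = seed)
  suppressWarnings(split_corpus(recs, seed = seed + 1L))
}

#' Write / read a corpus manifest
#'
#' The manifest is a tab-separated text file with columns `smiles`,
#' `deepsmiles`, `category`, `split`.  `write_corpus()` additionally emits
#' one DeepSMILES line-list per split (`train.txt`, `validation.txt`,
#' `test.txt`) next to the manifest.
#'
#' @param records corpus records data frame.
#' @param dir output directory (created if missing).
#' @return `write_corpus()` returns the manifest path invisibly;
#'   `read_corpus()` returns the records data frame.
#' @export
write_corpus <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(dir, "corpus.tsv")
  utils::write.table(records[, c("smiles", "deepsmiles", "category", "split")],
                     manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in c("train", "validation", "test")) {
    writeLines(records$deepsmiles[records$split == sp],
               file.path(dir, paste0(sp, ".txt")))
  }
  invisible(manifest)
}

#' @rdname write_corpus
#' @param path manifest file path.
#' @export
read_corpus <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}
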