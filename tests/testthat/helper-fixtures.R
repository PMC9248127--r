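# Shared fixtures, computed lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- get0(key, envir = .fixture_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .fixture_cache)
  val
}

tiny_corpus <- function() cached("tiny_corpus", generate_tiny_corpus(4L, seed = 11L))

# A long multi-branch DeepSMILES example (benzyl-protected aromatic ester)
# used as a worst-case conversion fixture.
long_deepsmiles_fixture <- function() {
  paste0("CCC)NCCC=CC=CC=C6)OCC=CC=CC=C6)))))))))OCC=CC=CC=C6))))))))))",
         "[N+]=O)[O-]))))OC=O)OCC)C)C)))))))C=O)OCC)C)C")
}

# Deterministic flat-style renders for a couple of small molecules.
fixture_render <- function(smiles, seed = 1L) {
  cached(paste0("render_", smiles, "_", seed),
         render_molecule(smiles, depiction_style(rotate = FALSE, bond_px = 30L,
                                                 margin_px = 12L), seed = seed))
}

have_rdkit <- function() {
  cached("have_rdkit", {
    out <- tryCatch(suppressWarnings(system2(
      "python", c("-c", shQuote("import rdkit; print('ok')")),
      stdout = TRUE, stderr = FALSE)), error = function(e) "")
    identical(out[1], "ok")
  })
}

# Independent canonicalizer (RDKit via python) used as a cross-toolkit
# oracle; returns NA when unavailable.
rdkit_canonical <- function(smiles) {
  if (!have_rdkit()) return(rep(NA_character_, length(smiles)))
  script <- paste0(
    "import sys\nfrom rdkit import Chem\n",
    "for line in sys.stdin.read().splitlines():\n",
    "    m = Chem.MolFromSmiles(line)\n",
    "    print(Chem.MolToSmiles(m) if m is not None else '')")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE,
                                  input = smiles))
  if (length(out) != length(smiles)) return(rep(NA_character_, length(smiles)))
  ifelse(nzchar(out), out, NA_character_)
}
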