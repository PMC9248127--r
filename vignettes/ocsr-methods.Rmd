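---
title: "Methods: synthetic corpora, the window-attention recognizer, and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic corpora, the window-attention recognizer, and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`ocsr`: what the synthetic data emulate, how the model is put together,
which parameters matter, and what the desk-scale tests do and do not show.

## The recognition problem

Optical chemical structure recognition maps a raster depiction of a
molecule to a structure string. We cast it as image-to-sequence
translation: the image is encoded into a feature sequence and a
token-level decoder emits the structure left to right. The output grammar
is DeepSMILES rather than SMILES: a branch of *n* atoms closes with a run
of *n* `)` characters (no opening symbol to balance), and a ring bond is a
single digit giving the distance along the current chain to the ring
partner (6 for benzene). Both rewrites remove the paired-symbol
bookkeeping that autoregressive generators most often violate, so more of
the raw output parses.

`to_deepsmiles()`/`from_deepsmiles()` implement the conversion purely
syntactically over a shared tokenizer, with a branch stack and ring-
partner resolution against that stack. Decoding rebuilds the molecular
tree (one atom popped per `)`) and writes SMILES by depth-first traversal,
re-assigning ring-closure labels so that label lifetimes never overlap.
Correctness is asserted two ways: frozen hand-derived encodings (benzene
`cccccc6`, naphthalene `ccccccccc6c%10`, branch runs like `CCCC)))O`), and
the round-trip property `canonicalize(from_deepsmiles(to_deepsmiles(s)))
== canonicalize(s)` on every generated corpus record, cross-checked
against an independent cheminformatics toolkit in the test suite.

## The synthetic corpus

Training data are generated, not collected. Source molecules (a bundled
list of 77 drug-like structures spanning label lengths from a few to ~80
characters) are expanded into four categories that mimic the two axes of
variation in printed depictions:

| category | ring form | substituents injected |
|---|---|---|
| 1 | Kekulé | no |
| 2 | aromatic | no |
| 3 | Kekulé | yes |
| 4 | aromatic | yes |

Substituent injection models patent-style decorated scaffolds: 1–3
fragments (uniform, seeded) drawn from a pool of 34 common substituents
plus a 17-entry bracket-atom inventory are attached as branches at
uniformly chosen atoms carrying at least one implicit hydrogen. Attachment
is done by inserting a parenthesised branch directly after the chosen atom
token (after its ring-closure digits), which is always syntactically
valid, and the result is re-parsed and re-canonicalized; this graph-aware
insertion guarantees validity where raw string splicing would not. The
pools are plain-text files and can be swapped for larger inventories.

Records are deduplicated by canonical SMILES within each category and
split 18:1:1 (train/validation/test) independently per category, floors
for the two small splits and remainders to train — at the published
full-scale sizes (1.25 M per category) this yields exactly
1,125,000/62,500/62,500. Every generator in the package is a pure function
of its seed; byte-identical reruns are asserted in the tests.

### Canonicalization

Canonical forms come from OpenBabel. Two of its behaviours required
handling: perception state leaks between molecules converted in one
process, so conversions run one molecule per invocation (memoized); and
the Kekulé writer's double-bond placement depends on the input's explicit
bonds and can alternate between two equivalent assignments on re-reading.
`canonicalize()` therefore iterates the writer until its orbit repeats and
returns the lexicographically smallest string on the cycle — a
deterministic representative that is a fixed point of the whole procedure,
which the record invariant (re-canonicalization is the identity) requires.

## Depictions

Rendering uses OpenBabel's 2D layout and draws on an off-screen cairo
canvas: single/double/triple bonds as parallel strokes, aromatic rings
(category 2/4) as a single-stroke ring with an inner circle, heteroatoms
and bracket atoms as text labels with condensed hydrogens ("NH2", "OH").
The canvas is sized to the molecule at a fixed 50 px per bond (margin
30 px), so image resolution grows with the molecule as it does in real
depiction pipelines; a seeded random rotation varies orientation.
Binarization thresholds at 0.5 of the intensity range (ink = 1,
background = 0; the threshold is configurable since real pipelines differ),
then the image is padded to a square with background, resized
nearest-neighbour (preserving the binary value set), and replicated to
three identical channels. What these images do *not* emulate: scan noise,
font diversity, wavy bonds, superatom abbreviations — the degradations
that make literature images hard. Tests passing on these clean renders
demonstrate pipeline correctness and learnability, not literature-level
recognition.

## Model

The backbone follows the hierarchical window-attention design: 4×4 patch
partition, linear embedding (width 192 at full scale), four stages of
blocks alternating window attention and shifted-window attention
(window 7), patch merging between stages (2×2 neighbourhood concatenation,
layer norm, linear halving to 2C), and a final layer norm; the last
feature map is already a row-major sequence `S_b` (49 × 1536 for a 224
input). Blocks are pre-norm with GELU MLPs, as is conventional for this
backbone family. Shifted windows are realized by cyclic index rolling with
an additive mask that blocks pairs wrapped together from different image
regions; for grids of ≤1024 positions the same computation is executed as
one dense attention under a block mask (bitwise-identical output, far
fewer intermediate tensors — asserted by a test), with the per-window loop
used above that size.

A learned linear map takes `S_b` to the decoder width `d_model = 256`
(the two widths are otherwise unrelated), fixed sinusoidal positional
encodings are added, and six standard encoder layers (self-attention +
MLP, residual + layer norm) produce `S_e`. The decoder stacks six layers
of causally masked self-attention, cross-attention over `S_e`, and MLP,
then a linear vocabulary head and softmax. Causality is tested exactly:
changing any future token leaves earlier logit rows bit-identical.
Greedy decoding appends the argmax token (ties to the lowest id) until the
end marker or the length cap; an emitted pad also terminates.

Unspecified details we fixed: 8 encoder/decoder heads; MLP ratio 4;
sinusoidal (not learned) positional encodings; no relative-position bias
inside windows; no weight tying between the token embedding and the output
head.

### The desk-scale ("tiny") configuration

All tests and the acceptance benchmark use a reduced configuration: 64 px
inputs, embedding width 48, depths 2/2/2/2, heads 2/4/8/16 (uniform head
dimension 24), window 4, `d_model` 64 with 2 encoder and 2 decoder layers,
MLP ratio 2, no dropout (~3.7 M parameters). Two deviations from the
full-scale description were forced by small-step optimization behaviour,
both established experimentally during development:

* **Pre-norm encoder/decoder.** With post-norm sublayers the joint model
  reliably converged to the *image-blind* optimum — the loss value
  attainable while ignoring the encoder entirely (computable by hand from
  the label set) — even though gradient flow was verified correct by
  finite differences. Pre-norm escapes this plateau; the tiny
  configuration therefore defaults to `prenorm = TRUE`, while
  `model_config()` keeps the classic post-norm arrangement.
* **Non-zero bias initialization.** Weights are Glorot-scaled Gaussians;
  linear biases are uniform ±1/√fan-in rather than zero. With zero
  biases, an all-background patch embeds to an exactly constant feature
  row, and layer normalization's backward pass on a constant row is
  amplified by 1/√ε — stacked over eight blocks this produced gradient
  norms of 10^16. The uniform bias (the convention of the major deep
  learning frameworks) removes the degeneracy; a global gradient-norm
  clip (default 5) remains as standard insurance.

## Objectives

Cross-entropy is the softmax baseline. The multi-label focal loss treats
the single-token target at each position as a multi-label problem over all
classes: `p_i = σ(o_i)` for the positive class and `1 − σ(o_i)` otherwise,
and averages `−α_i (1−p_i)^γ log p_i` over classes, then over unmasked
positions (pad positions are excluded; in practice labels are trimmed at
the end marker so every kept position is real). Defaults follow the focal
loss convention, γ = 2 and uniform α = 0.25; an inverse-frequency α
derived from corpus token counts (normalized to mean 1) is available,
motivated by the long-tailed token distribution. Probabilities are clamped
at 10⁻¹² before the log. Closed-form gradients avoid the `(1−p)^(γ−1)`
singularity and are finite-difference tested, as is the exact identity
MFL(γ=0, α=1) = mean binary cross-entropy.

## Training and the learnability benchmark

Training is teacher-forced next-token prediction with Adam at initial
learning rate 10⁻³ for desk-scale runs (5×10⁻⁴ at full-scale defaults),
cosine decay for the backbone group and step decay (×0.5 every
`step_size` epochs) for the encoder/decoder group, gradients averaged per
batch.

`overfit_benchmark()` is the desk-scale surrogate for full-scale
learnability: a generated corpus is reduced to the 8 records (2 per
category) with the shortest labels — the problem size we chose for a
single-CPU run sits in the first label-length bin — rendered at 64 px, and
the tiny model is trained to reproduce its own training labels, stopping
early at 100 % training exact match (main phase capped at 300 epochs with
up to two lower-rate continuation rounds; about 5 minutes on one CPU).
Two empirical properties of this regime shaped the recipe. First,
full-batch steps matter: the image-conditional signal is a small
*difference* between per-sample gradients, and sub-batch noise drowns it
at this scale. Second, the corpus draws *distinct* source molecules for
every category (one cursor through the shuffled source list): when a
category-3 record is built from the same parent as a category-1 record,
their 64 px renders differ by only a few label pixels, which misrepresents
the full-scale corpus (millions of distinct structures) and stalls
desk-scale training on near-duplicate images. The benchmark trains with
cross-entropy. The MFL at this scale drives its loss very low while its
greedy exact match lags far behind CE (sigmoid scores are not normalized
across classes, so a near-zero class average tolerates a miscalibrated
argmax at the few image-conditional positions); CE reaches exact-match
saturation in the same budget. Both losses are exercised by the unit
tests; the MFL's token-imbalance benefit is a full-scale phenomenon that
an eight-sample overfit cannot and does not try to demonstrate.

What the benchmark shows: the whole pipeline — corpus, rendering,
tokenization, backbone, encoder/decoder, loss, decoding, metrics — is
wired correctly and can fit image-conditional structure. What it does not
show: generalization to unseen molecules or literature images.

## Evaluation protocol

Four headline metrics per prediction/reference pair, plus stratification:

* **Exact match** — byte-identical DeepSMILES (length mismatch fails).
* **Tanimoto** — both strings are decoded to SMILES and fingerprinted
  with a deterministic path fingerprint: the molecule is first
  re-canonicalized (so Kekulé and aromatic spellings coincide), all simple
  atom paths up to 6 bonds are written as element/bond-order strings
  (reverse-canonicalized) and hashed onto 1024 bits; similarity is
  |A∩B|/|A∪B|. Undecodable or invalid predictions score 0 and are flagged.
  The scheme is configurable; it is not a reimplementation of any
  particular toolkit's fingerprint, and absolute values are not comparable
  across schemes.
* **BLEU** — corpus-level, up to 4-grams with brevity penalty; n-gram
  orders longer than every sequence are skipped (so identical short
  corpora score 1), and any order with zero clipped matches scores 0.
* **ROUGE-L** — LCS-based F1 averaged over pairs.

Validity rates report the fraction of predictions that parse as
DeepSMILES and that decode to parseable SMILES. Accuracy is additionally
stratified by category (1–4) and by reference label length in the
inclusive bins [1,25], [26,50], [51,75], [76,100]. Exact match = 1 implies
all similarity metrics equal 1; this implication and permutation
invariance of the report are tested.

## Known limitations

* OpenBabel is the single canonicalization authority; molecules it cannot
  kekulize or lay out are rejected or dropped (with a warning) rather
  than repaired.
* The valence model behind substitution sites and fingerprints covers the
  SMILES organic subset with standard valences; exotic valences fall back
  conservatively (no implicit hydrogens).
* Rendered depictions are clean vector-style drawings; no degradation
  model is included, by design.
* Training at full scale (millions of images, GPU batches) is out of
  scope for this implementation; all configured defaults at that scale
  are untested beyond shape contracts.
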