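# 2D molecule depiction, binarization and model-input shaping.
#
# Layout coordinates come from OpenBabel's 2D generator; drawing is done on
# an off-screen cairo PNG canvas: bond line segments (with parallel strokes
# for double/triple bonds or an inner circle for aromatic rings), text
# labels for heteroatoms and bracket atoms, then read back as a grayscale
# matrix.  A depiction is a pure function of (molecule, style, seed).

#' Depiction style parameters
#'
#' The canvas is sized to the molecule at a fixed pixel-per-bond scale (as
#' chemistry depiction toolkits do), so larger molecules produce larger
#' images; [to_model_input()] later pads and resizes to the square model
#' input.
#'
#' @param bond_px drawn length of a single bond in pixels.
#' @param margin_px blank margin around the drawing in pixels.
#' @param max_px cap on either canvas side in pixels.
#' @param lwd bond line width (device units).
#' @param cex atom-label character expansion (font size scale).
#' @param bond_sep separation of the parallel strokes of multiple bonds, as
#'   a fraction of the bond length.
#' @param shorten fraction of a bond trimmed at a labelled atom so the bond
#'   does not strike through the label glyphs.
#' @param aromatic_circles draw aromatic rings found in the SMILES as a
#'   single-stroke ring with an inner circle (the usual depiction of the
#'   aromatic form); Kekulé-form strings are unaffected since they carry no
#'   aromatic atoms.
#' @param rotate randomly rotate the whole depiction (seeded); set `FALSE`
#'   for a fixed upright layout.
#' @param show_hydrogens append implicit-hydrogen counts to heteroatom
#'   labels (condensed-formula style, e.g. "NH2", "OH").
#' @return An object of class `ocsr_style`.
#' @export
depiction_style <- function(bond_px = 50L, margin_px = 30L, max_px = 1200L,
                            lwd = 2, cex = 1.3, bond_sep = 0.15,
                            shorten = 0.22, aromatic_circles = TRUE,
                            rotate = TRUE, show_hydrogens = TRUE) {
  stopifnot(bond_px >= 10L, margin_px >= 0L, max_px >= 4L * bond_px)
  structure(list(bond_px = as.integer(bond_px),
                 margin_px = as.integer(margin_px),
                 max_px = as.integer(max_px), lwd = lwd, cex = cex,
                 bond_sep = bond_sep, shorten = shorten,
                 aromatic_circles = aromatic_circles, rotate = rotate,
                 show_hydrogens = show_hydrogens),
            class = "ocsr_style")
}

# Smallest ring through each aromatic ring-closure bond (BFS avoiding the
# bond itself); returns a list of unique atom-id vectors.
aromatic_rings <- function(mol) {
  arom_bonds <- which(mol$bonds$aromatic & mol$bonds$ring)
  if (length(arom_bonds) == 0L) return(list())
  adj <- mol_adjacency(mol)
  rings <- list()
  for (bi in arom_bonds) {
    a <- mol$bonds$a1[bi]; b <- mol$bonds$a2[bi]
    # BFS from a to b not using edge (a,b)
    prev <- rep(NA_integer_, nrow(mol$atoms))
    prev[a] <- 0L
    queue <- a
    while (length(queue) > 0L && is.na(prev[b])) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]$nb) {
        if ((cur == a && nb == b) || (cur == b && nb == a)) next
        if (is.na(prev[nb])) { prev[nb] <- cur; queue <- c(queue, nb) }
      }
    }
    if (is.na(prev[b])) next
    path <- b
    while (path[1] != a) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = ",")
    if (!key %in% names(rings)) rings[[key]] <- path
  }
  unname(rings)
}

atom_label_text <- function(element, charge, isotope, hcount, show_h) {
  lab <- element
  if (!is.na(isotope) && isotope > 0L) lab <- paste0(isotope, lab)
  if (show_h && !is.na(hcount) && hcount > 0L)
    lab <- paste0(lab, "H", if (hcount > 1L) hcount else "")
  if (!is.na(charge) && charge != 0L) {
    sign <- if (charge > 0L) "+" else "-"
    lab <- paste0(lab, if (abs(charge) > 1L) abs(charge) else "", sign)
  }
  lab
}

#' Render a molecule as a grayscale depiction
#'
#' @param smiles a valid SMILES string (Kekulé or aromatic form).
#' @param style an [depiction_style()] object.
#' @param seed integer seed controlling the random rotation.
#' @return A numeric matrix in `[0, 1]` (1 = white background, 0 = black
#'   ink), sized to the molecule at `style$bond_px` pixels per bond, with
#'   attribute `smiles`.
#' @examples
#' \dontrun{
#' img <- render_molecule("CCO", depiction_style(rotate = FALSE), seed = 1)
#' }
#' @export
render_molecule <- function(smiles, style = depiction_style(), seed = 1L) {
  stopifnot(inherits(style, "ocsr_style"))
  mol <- smi_parse(smiles)
  lay <- ob_gen2d(smiles)
  if (nrow(mol$atoms) != length(lay$elements))
    smiles_error("2D layout atom count mismatch", smiles)
  hs <- smi_implicit_h(mol)
  with_seed(seed, {
    xy <- lay$coords
    if (style$rotate) {
      th <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      xy <- xy %*% rot
    }
    bonds <- lay$bonds
    # layout units per bond (OpenBabel's generator uses ~1.0)
    ubond <- if (nrow(bonds) > 0L)
      stats::median(sqrt((xy[bonds$a1, 1] - xy[bonds$a2, 1])^2 +
                         (xy[bonds$a1, 2] - xy[bonds$a2, 2])^2))
    else 1
    if (!is.finite(ubond) || ubond < 1e-9) ubond <- 1
    # canvas sized to the molecule at a fixed pixels-per-bond scale
    rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
    px_per_unit <- style$bond_px / ubond
    w_px <- min(style$max_px, max(
      2L * style$bond_px,
      as.integer(ceiling((rng_x[2] - rng_x[1]) * px_per_unit)) + 2L * style$margin_px))
    h_px <- min(style$max_px, max(
      2L * style$bond_px,
      as.integer(ceiling((rng_y[2] - rng_y[1]) * px_per_unit)) + 2L * style$margin_px))
    # map layout units to the plot's [0,1] coordinates; keep the scale
    # isotropic by normalizing against the larger canvas side
    big <- max(w_px, h_px)
    sc <- min(px_per_unit,  # never exceed the fixed scale
              (w_px - 2L * style$margin_px) / max(rng_x[2] - rng_x[1], 1e-9),
              (h_px - 2L * style$margin_px) / max(rng_y[2] - rng_y[1], 1e-9))
    xs <- (w_px / big); ys <- (h_px / big)
    xy[, 1] <- 0.5 * xs + (xy[, 1] - mean(rng_x)) * sc / big
    xy[, 2] <- 0.5 * ys + (xy[, 2] - mean(rng_y)) * sc / big
    blen <- style$bond_px / big * (sc / px_per_unit)

    labelled <- mol$atoms$element != "C" | mol$atoms$bracket |
      mol$atoms$charge != 0L | !is.na(mol$atoms$isotope)
    rings <- if (style$aromatic_circles) aromatic_rings(mol) else list()
    ring_bond <- rep(FALSE, nrow(bonds))
    if (length(rings) > 0L && nrow(bonds) > 0L) {
      for (rg in rings) {
        inr <- bonds$a1 %in% rg & bonds$a2 %in% rg
        ring_bond <- ring_bond | inr
      }
    }

    f <- tempfile(fileext = ".png")
    grDevices::png(f, width = w_px, height = h_px, type = "cairo")
    on.exit(unlink(f), add = TRUE)
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, xs), ylim = c(0, ys))
    if (nrow(bonds) > 0L) {
      for (i in seq_len(nrow(bonds))) {
        a <- bonds$a1[i]; b <- bonds$a2[i]
        p <- xy[a, ]; q <- xy[b, ]
        d <- q - p; len <- sqrt(sum(d^2)); if (len < 1e-9) next
        u <- d / len
        if (labelled[a]) p <- p + u * style$shorten * blen
        if (labelled[b]) q <- q - u * style$shorten * blen
        nvec <- c(-u[2], u[1]) * style$bond_sep * blen
        order_i <- if (ring_bond[i]) 1L else bonds$order[i]
        offs <- switch(as.character(max(1L, min(3L, order_i))),
                       "1" = list(c(0, 0)),
                       "2" = list(nvec / 2, -nvec / 2),
                       "3" = list(c(0, 0), nvec, -nvec))
        for (o in offs)
          graphics::segments(p[1] + o[1], p[2] + o[2], q[1] + o[1], q[2] + o[2],
                             lwd = style$lwd, lend = 1)
      }
    }
    for (rg in rings) {
      cx <- mean(xy[rg, 1]); cy <- mean(xy[rg, 2])
      r <- 0.55 * mean(sqrt((xy[rg, 1] - cx)^2 + (xy[rg, 2] - cy)^2))
      tt <- seq(0, 2 * pi, length.out = 64L)
      graphics::lines(cx + r * cos(tt), cy + r * sin(tt), lwd = style$lwd)
    }
    for (i in which(labelled)) {
      lab <- atom_label_text(mol$atoms$element[i], mol$atoms$charge[i],
                             mol$atoms$isotope[i], hs[i], style$show_hydrogens)
      w <- graphics::strwidth(lab, cex = style$cex)
      h <- graphics::strheight(lab, cex = style$cex)
      graphics::rect(xy[i, 1] - 0.6 * w, xy[i, 2] - 0.6 * h,
                     xy[i, 1] + 0.6 * w, xy[i, 2] + 0.6 * h,
                     col = "white", border = NA)
      graphics::text(xy[i, 1], xy[i, 2], lab, cex = style$cex)
    }
    grDevices::dev.off()
    px <- png::readPNG(f)
    gray <- if (length(dim(px)) == 3L) (px[, , 1] + px[, , 2] + px[, , 3]) / 3
            else px
    structure(gray, smiles = smiles)
  })
}

#' Binarize a grayscale depiction
#'
#' Ink is dark-on-light: pixels strictly below `threshold` of the intensity
#' range become ink (value 1), the rest background (value 0).  Raising the
#' threshold therefore never shrinks the ink set.  An image with no ink at
#' all is flagged with attribute `blank = TRUE`.
#'
#' @param image numeric matrix (or array with identical channels) in `[0, 1]`.
#' @param threshold intensity threshold in `(0, 1)`.
#' @return Integer 0/1 matrix of the same spatial size.
#' @export
binarize <- function(image, threshold = 0.5) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  if (length(dim(image)) == 3L) image <- image[, , 1]
  ink <- matrix(as.integer(image < threshold), nrow(image), ncol(image))
  if (sum(ink) == 0L) attr(ink, "blank") <- TRUE
  ink
}

# Nearest-neighbour resize of a matrix to side x side (preserves the value
# set, so binary images stay binary).
resize_nearest <- function(m, side) {
  ri <- pmin(nrow(m), pmax(1L, as.integer(ceiling(seq_len(side) * nrow(m) / side))))
  ci <- pmin(ncol(m), pmax(1L, as.integer(ceiling(seq_len(side) * ncol(m) / side))))
  m[ri, ci, drop = FALSE]
}

#' Shape a binary depiction into a model input
#'
#' Pads the image to a square with background pixels (centred), resizes to
#' `side` x `side` with nearest-neighbour interpolation (so values stay in
#' {0, 1}), and replicates the single channel three times.
#'
#' @param bin integer 0/1 matrix from [binarize()].
#' @param side output spatial size (default 224).
#' @return A `side` x `side` x 3 array with identical binary channels.
#' @export
to_model_input <- function(bin, side = 224L) {
  stopifnot(is.matrix(bin), all(bin %in% c(0L, 1L)))
  n <- max(nrow(bin), ncol(bin))
  sq <- matrix(0L, n, n)
  r0 <- (n - nrow(bin)) %/% 2L
  c0 <- (n - ncol(bin)) %/% 2L
  sq[r0 + seq_len(nrow(bin)), c0 + seq_len(ncol(bin))] <- bin
  out <- resize_nearest(sq, as.integer(side))
  array(rep(out, 3L), dim = c(side, side, 3L))
}

#' Render corpus records into model-ready samples
#'
#' Runs the full depiction pipeline (render, binarize, shape) for each
#' record and pairs the image with its encoded label.  Records whose
#' depiction fails or comes out blank are dropped with a warning naming
#' them.  Per-record rotation seeds are drawn from `seed`, so the sample
#' set is reproducible.
#'
#' @param records corpus records data frame.
#' @param vocab an `ocsr_vocab` covering the labels.
#' @param style an [depiction_style()].
#' @param seed integer seed.
#' @param max_len label sequence length passed to [encode_ids()].
#' @param side model input spatial size.
#' @param threshold binarization threshold.
#' @return List of samples: each `list(image, label_ids, record)` where
#'   `record` is the row index into `records`.
#' @export
render_samples <- function(records, vocab, style = depiction_style(),
                           seed = 1L, max_len = 150L, side = 224L,
                           threshold = 0.5) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(records)))
  out <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(records))) {
    img <- tryCatch(render_molecule(records$smiles[i], style, seed = seeds[i]),
                    error = function(e) NULL)
    bin <- if (!is.null(img)) binarize(img, threshold) else NULL
    if (is.null(bin) || isTRUE(attr(bin, "blank"))) {
      dropped <- c(dropped, records$smiles[i])
      next
    }
    out[[length(out) + 1L]] <- list(
      image = to_model_input(bin, side),
      label_ids = encode_ids(records$deepsmiles[i], vocab, max_len),
      record = i)
  }
  if (length(dropped) > 0L)
    warning(sprintf("dropped %d record(s) with failed/blank depictions: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  out
}

#' Render a corpus to PNG files with a manifest
#'
#' Writes one black-on-white PNG per record plus a tab-separated manifest
#' (`image`, `deepsmiles`, `category`, `split`) linking images to labels.
#'
#' @inheritParams render_samples
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
render_corpus <- function(records, dir, style = depiction_style(), seed = 1L,
                          side = 224L, threshold = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(records)))
  paths <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    img <- render_molecule(records$smiles[i], style, seed = seeds[i])
    bin <- binarize(img, threshold)
    arr <- to_model_input(bin, side)
    paths[i] <- file.path(dir, sprintf("mol_%05d.png", i))
    png::writePNG(1 - arr[, , 1], paths[i])
  }
  manifest <- file.path(dir, "images.tsv")
  utils::write.table(
    data.frame(image = basename(paths), deepsmiles = records$deepsmiles,
               category = records$category, split = records$split),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
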