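# Synthetic fixture generator: multi-panel figures with known panel tiles,
# label glyphs rendered from a built-in 5x7 bitmap font (so tests need no
# OCR engine -- clean tokens come straight from ground truth), captions in
# the field's label styles, seeded OCR corruption, and whole-document
# operator streams with logos and fragmented figures. Every fixture carries
# the ground truth needed to check each pipeline stage exactly.

# 5x7 bitmap font, one integer per row, 5 bits, MSB leftmost.
.font5x7 <- list(
  A = c(0x0E, 0x11, 0x11, 0x1F, 0x11, 0x11, 0x11),
  B = c(0x1E, 0x11, 0x11, 0x1E, 0x11, 0x11, 0x1E),
  C = c(0x0E, 0x11, 0x10, 0x10, 0x10, 0x11, 0x0E),
  D = c(0x1E, 0x11, 0x11, 0x11, 0x11, 0x11, 0x1E),
  E = c(0x1F, 0x10, 0x10, 0x1E, 0x10, 0x10, 0x1F),
  F = c(0x1F, 0x10, 0x10, 0x1E, 0x10, 0x10, 0x10),
  G = c(0x0E, 0x11, 0x10, 0x17, 0x11, 0x11, 0x0F),
  H = c(0x11, 0x11, 0x11, 0x1F, 0x11, 0x11, 0x11),
  I = c(0x0E, 0x04, 0x04, 0x04, 0x04, 0x04, 0x0E),
  J = c(0x07, 0x02, 0x02, 0x02, 0x02, 0x12, 0x0C),
  K = c(0x11, 0x12, 0x14, 0x18, 0x14, 0x12, 0x11),
  L = c(0x10, 0x10, 0x10, 0x10, 0x10, 0x10, 0x1F),
  M = c(0x11, 0x1B, 0x15, 0x15, 0x11, 0x11, 0x11),
  N = c(0x11, 0x19, 0x15, 0x13, 0x11, 0x11, 0x11),
  O = c(0x0E, 0x11, 0x11, 0x11, 0x11, 0x11, 0x0E),
  P = c(0x1E, 0x11, 0x11, 0x1E, 0x10, 0x10, 0x10),
  V = c(0x11, 0x11, 0x11, 0x11, 0x11, 0x0A, 0x04),
  X = c(0x11, 0x11, 0x0A, 0x04, 0x0A, 0x11, 0x11),
  `0` = c(0x0E, 0x11, 0x13, 0x15, 0x19, 0x11, 0x0E),
  `1` = c(0x04, 0x0C, 0x04, 0x04, 0x04, 0x04, 0x0E),
  `2` = c(0x0E, 0x11, 0x01, 0x06, 0x08, 0x10, 0x1F),
  `3` = c(0x1F, 0x02, 0x04, 0x02, 0x01, 0x11, 0x0E),
  `4` = c(0x02, 0x06, 0x0A, 0x12, 0x1F, 0x02, 0x02),
  `5` = c(0x1F, 0x10, 0x1E, 0x01, 0x01, 0x11, 0x0E),
  `6` = c(0x06, 0x08, 0x10, 0x1E, 0x11, 0x11, 0x0E),
  `7` = c(0x1F, 0x01, 0x02, 0x04, 0x08, 0x08, 0x08),
  `8` = c(0x0E, 0x11, 0x11, 0x0E, 0x11, 0x11, 0x0E),
  `9` = c(0x0E, 0x11, 0x11, 0x0F, 0x01, 0x02, 0x0C)
)

.glyph_scale <- 2L
.glyph_w <- 5L * .glyph_scale   # 10 px
.glyph_h <- 7L * .glyph_scale   # 14 px
.glyph_gap <- 2L

# Draw label `chars` into img (integer matrix) at top-left (x0, y0), 0-based.
# Returns the tight bbox of the drawn text.
draw_label <- function(img, chars, x0, y0, value = 0L) {
  x <- x0
  for (ch in strsplit(chars, "")[[1]]) {
    rows <- .font5x7[[ch]]
    if (is.null(rows)) stop("no glyph for character: ", ch)
    for (r in seq_len(7L)) {
      bits <- rows[[r]]
      for (cbit in seq_len(5L)) {
        if (bitwAnd(bits, bitwShiftL(1L, 5L - cbit)) != 0L) {
          yr <- y0 + (r - 1L) * .glyph_scale
          xc <- x + (cbit - 1L) * .glyph_scale
          img[(yr + 1L):(yr + .glyph_scale),
              (xc + 1L):(xc + .glyph_scale)] <- value
        }
      }
    }
    x <- x + .glyph_w + .glyph_gap
  }
  w <- x - .glyph_gap - x0
  list(img = img, box = bbox(x0, y0, x0 + w, y0 + .glyph_h))
}

label_chars_for <- function(n, alphabet) {
  vapply(seq_len(n), label_from_position, "", alphabet = alphabet)
}

#' Specification of one synthetic figure fixture
#'
#' Defaults state a typical clean multi-panel figure: square-ish panels of
#' about 110 x 96 px separated by 14 px whitespace gutters (well above the
#' 8 px floor), one dark content blob per panel on a white background, Latin
#' labels drawn at each panel's top-left, and noise off.
#'
#' @param rows,cols grid shape (1-4 each, `rows*cols <= 16`).
#' @param ragged optional integer vector of panels per row (overrides
#'   `cols`; e.g. `c(1, 2)` is one full-width top panel over two bottom
#'   panels).
#' @param label_alphabet `latin`, `roman` (needs `<= 12` panels) or
#'   `arabic`.
#' @param label_category OCR token style: `simple` ("A"), `right_closed`
#'   ("A)"), `closed` ("(A)").
#' @param caption_style `per_label`, `range`, or `none`.
#' @param content_kind `blob` (one rectangle component per panel), `bars`,
#'   or `texture`.
#' @param ocr_drop_rate,ocr_confusion_rate OCR noise rates in `[0,1]`.
#' @param caption_label_corruption insert a decoy duplicate label token
#'   (e.g. an abbreviation "(C)") into the caption text.
#' @param figure_number number used in the caption head.
#' @param seed integer seed; fixtures are bit-identical given a seed.
#' @return a `figseg_fixture_spec` list.
#' @export
fixture_spec <- function(rows = 2L, cols = 2L, ragged = NULL,
                         label_alphabet = "latin",
                         label_category = "closed",
                         caption_style = "per_label",
                         content_kind = "blob",
                         ocr_drop_rate = 0, ocr_confusion_rate = 0,
                         caption_label_corruption = FALSE,
                         figure_number = 1L, seed = 1L) {
  label_alphabet <- match.arg(label_alphabet, .alphabets)
  label_category <- match.arg(label_category,
                              c("simple", "right_closed", "closed"))
  caption_style <- match.arg(caption_style, c("per_label", "range", "none"))
  content_kind <- match.arg(content_kind, c("blob", "bars", "texture"))
  if (is.null(ragged)) {
    stopifnot(rows >= 1L, rows <= 4L, cols >= 1L, cols <= 4L,
              rows * cols <= 16L)
    ragged <- rep(as.integer(cols), rows)
  } else {
    ragged <- as.integer(ragged)
    rows <- length(ragged)
    stopifnot(all(ragged >= 1L), sum(ragged) <= 16L)
  }
  n <- sum(ragged)
  if (label_alphabet == "roman") stopifnot(n <= 12L)
  stopifnot(ocr_drop_rate >= 0, ocr_drop_rate <= 1,
            ocr_confusion_rate >= 0, ocr_confusion_rate <= 1)
  structure(list(rows = rows, cols = max(ragged), ragged = ragged,
                 n_panels = n, label_alphabet = label_alphabet,
                 label_category = label_category,
                 caption_style = caption_style, content_kind = content_kind,
                 ocr_drop_rate = ocr_drop_rate,
                 ocr_confusion_rate = ocr_confusion_rate,
                 caption_label_corruption = caption_label_corruption,
                 figure_number = as.integer(figure_number),
                 seed = as.integer(seed)),
            class = "figseg_fixture_spec")
}

.tile_w <- 110L
.tile_h <- 96L
.gutter <- 14L
.label_off <- 6L
.bg_val <- 255L
.content_val <- 40L

token_text_for <- function(char, category) {
  switch(category, simple = char,
         right_closed = paste0(char, ")"),
         closed = paste0("(", char, ")"))
}

#' Generate a synthetic multi-panel figure with ground truth
#'
#' Panels sit on a grid (or ragged rows), separated by whitespace gutters;
#' each panel holds one or more dark components well above the default
#' 50 px area threshold plus a label glyph at its top-left whose box is
#' recorded as a clean OCR token. Deterministic given the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `image` (integer matrix) and `truth`: `n_panels`,
#'   `labels`, `panel_boxes` (the tile regions an exact partition should
#'   recover; NULL for ragged layouts), `content_boxes`, `label_boxes`,
#'   `tokens` (clean OCR token data.frame), `cuts_x`, `cuts_y`, `caption`,
#'   `subcaptions`, `spec`.
#' @export
generate_figure <- function(spec) {
  stopifnot(inherits(spec, "figseg_fixture_spec"))
  rng <- fs_rng(spec$seed * 7919L + 13L)
  rows <- spec$rows
  ragged <- spec$ragged
  regular <- length(unique(ragged)) == 1L
  cols <- max(ragged)
  W <- cols * .tile_w + (cols - 1L) * .gutter
  H <- rows * .tile_h + (rows - 1L) * .gutter
  img <- matrix(.bg_val, H, W)
  labels <- label_chars_for(spec$n_panels, spec$label_alphabet)
  content_boxes <- list(); label_boxes <- list(); tokens <- list()
  tiles <- list()
  p <- 0L
  for (r in seq_len(rows)) {
    k <- ragged[[r]]
    pw <- (W - (k - 1L) * .gutter) %/% k
    y0 <- (r - 1L) * (.tile_h + .gutter)
    for (cc in seq_len(k)) {
      p <- p + 1L
      x0 <- (cc - 1L) * (pw + .gutter)
      x1 <- if (cc == k) W else x0 + pw
      tiles[[p]] <- bbox(x0, y0, x1, y0 + .tile_h)
      dl <- draw_label(img, labels[[p]], x0 + .label_off, y0 + .label_off)
      img <- dl$img
      label_boxes[[p]] <- dl$box
      # content: jittered box inside the tile, clear of label and gutters.
      # Rows spanning more than one column (ragged layouts) get nearly
      # full-width content, as wide panels do in practice; this is what
      # makes a cut through them costly.
      j <- rng$int(4L, 0L, 5L)
      spanning <- k < cols
      cx0 <- if (spanning) x0 + 4L + j[[1]] %% 3L else x0 + 20L + j[[1]]
      cy0 <- y0 + 30L + j[[2]]
      cx1 <- if (spanning) x1 - 4L - j[[3]] %% 3L else x1 - 14L - j[[3]]
      cy1 <- y0 + .tile_h - 10L - j[[4]]
      content_boxes[[p]] <- bbox(cx0, cy0, cx1, cy1)
      if (spec$content_kind == "blob") {
        img[(cy0 + 1L):cy1, (cx0 + 1L):cx1] <- .content_val
      } else if (spec$content_kind == "bars") {
        nb <- 3L
        bw <- (cx1 - cx0) %/% (2L * nb)
        base <- cy1
        for (b in seq_len(nb)) {
          bh <- rng$int(1L, 20L, cy1 - cy0 - 2L)
          bx0 <- cx0 + (b - 1L) * 2L * bw
          img[(base - bh + 1L):base, (bx0 + 1L):(bx0 + bw)] <- .content_val
        }
        # baseline joins the bars into one component
        img[(cy1 - 1L):cy1, (cx0 + 1L):cx1] <- .content_val
      } else { # texture: dense random stipple on a filled band
        img[(cy0 + 1L):cy1, (cx0 + 1L):cx1] <- .content_val
        nn <- as.integer(0.3 * (cy1 - cy0) * (cx1 - cx0))
        ys <- rng$int(nn, cy0 + 1L, cy1)
        xs <- rng$int(nn, cx0 + 1L, cx1)
        img[cbind(ys, xs)] <- 120L
      }
      tokens[[p]] <- data.frame(
        text = token_text_for(labels[[p]], spec$label_category),
        x_min = dl$box[[1]], y_min = dl$box[[2]],
        x_max = dl$box[[3]], y_max = dl$box[[4]], conf = 1
      )
    }
  }
  tokens <- do.call(rbind, tokens)
  # analytic expected cut coordinates (regular grids only): the min-cost
  # zero window starts after the rightmost/bottom content edge, and the
  # corridor midpoint between the left-anchored labels always falls left
  # of/above it, so the first zero-cost coordinate is selected
  cuts_x <- cuts_y <- NULL
  panel_boxes <- NULL
  if (regular) {
    cb <- boxes_to_df(content_boxes)
    col_of <- rep(sequence(ragged), 1L)
    col_idx <- unlist(lapply(ragged, seq_len))
    row_idx <- rep(seq_len(rows), ragged)
    cuts_x <- if (cols > 1L)
      vapply(seq_len(cols - 1L), function(cc)
        max(cb$x_max[col_idx == cc]), 1) else numeric(0)
    cuts_y <- if (rows > 1L)
      vapply(seq_len(rows - 1L), function(r)
        max(cb$y_max[row_idx == r]), 1) else numeric(0)
    xb <- c(0, cuts_x, W); yb <- c(0, cuts_y, H)
    panel_boxes <- list()
    p <- 0L
    for (r in seq_len(rows)) for (cc in seq_len(cols)) {
      p <- p + 1L
      panel_boxes[[p]] <- bbox(xb[[cc]], yb[[r]], xb[[cc + 1L]], yb[[r + 1L]])
    }
  }
  truth <- list(n_panels = spec$n_panels, labels = labels,
                panel_boxes = panel_boxes, tiles = tiles,
                content_boxes = content_boxes, label_boxes = label_boxes,
                tokens = tokens, cuts_x = cuts_x, cuts_y = cuts_y,
                spec = spec)
  cap <- generate_caption(spec, truth)
  truth$caption <- cap$caption
  truth$subcaptions <- cap$subcaptions
  truth$decoy_span <- cap$decoy_span
  truth$n_labeled <- cap$n_labeled
  list(image = img, truth = truth)
}

.filler_words <- c("binding", "assay", "staining", "control", "lysate",
                   "overlay", "construct", "interaction", "fraction",
                   "extract", "profile", "signal")

#' Generate a caption and subcaption ground truth for a fixture
#'
#' `per_label` emits one parenthesized token per panel; `range` emits one
#' range token covering all but the last panel plus a single token (or a
#' two-label "(A and B)" list); `none` emits plain text with no panel
#' markers. Corruption appends a decoy duplicate token such as "(C)" inside
#' the final subcaption.
#'
#' @param spec a [fixture_spec()].
#' @param truth partial truth from [generate_figure()] (needs `labels`).
#' @return list `caption`, `subcaptions` (data.frame label/text/shared),
#'   `n_labeled`, `decoy_span` (character offsets of the decoy or NULL).
#' @export
generate_caption <- function(spec, truth) {
  rng <- fs_rng(spec$seed * 104729L + 7L)
  labels <- truth$labels
  n <- length(labels)
  head_txt <- sprintf("Figure %d.", spec$figure_number)
  filler <- function(k) {
    paste(.filler_words[rng$int(k, 1L, length(.filler_words))],
          collapse = " ")
  }
  if (spec$caption_style == "none" || n == 0L) {
    caption <- paste0(head_txt, " Representative ", filler(3L), " results.")
    # with no accepted labels the single ∅ subcaption covers the whole
    # caption, head included
    return(list(caption = caption,
                subcaptions = data.frame(label = "∅", text = caption,
                                         shared = FALSE),
                n_labeled = 0L, decoy_span = NULL))
  }
  style <- spec$caption_style
  if (style == "range" && n < 2L) style <- "per_label"
  parts <- character(0)
  rows <- list()
  if (style == "per_label") {
    for (i in seq_len(n)) {
      w <- filler(3L)
      txt <- paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)), ".")
      parts <- c(parts, sprintf("(%s) %s", labels[[i]], txt))
      rows[[i]] <- data.frame(label = labels[[i]], text = txt,
                              shared = FALSE)
    }
  } else { # range
    k <- n - 1L
    shared_txt <- paste0("Shared ", filler(2L), ".")
    if (k >= 2L) {
      parts <- c(parts, sprintf("(%s-%s) %s", labels[[1]], labels[[k]],
                                shared_txt))
    } else {
      # n == 2: two-label list token, both panels share the text
      k <- 2L
      parts <- c(parts, sprintf("(%s and %s) %s", labels[[1]], labels[[2]],
                                shared_txt))
    }
    for (i in seq_len(k)) {
      rows[[i]] <- data.frame(label = labels[[i]], text = shared_txt,
                              shared = TRUE)
    }
    if (k < n) {
      last_txt <- paste0("Final ", filler(2L), ".")
      parts <- c(parts, sprintf("(%s) %s", labels[[n]], last_txt))
      rows[[n]] <- data.frame(label = labels[[n]], text = last_txt,
                              shared = FALSE)
    }
  }
  caption <- paste(c(head_txt, parts), collapse = " ")
  subcaps <- do.call(rbind, rows)
  decoy_span <- NULL
  if (spec$caption_label_corruption && n >= 2L) {
    decoy_lab <- labels[[min(3L, n)]]
    decoy <- sprintf(" Compare with (%s) control.", decoy_lab)
    at <- nchar(caption)
    caption <- paste0(caption, decoy)
    open <- at + regexpr("(", decoy, fixed = TRUE)
    decoy_span <- c(open, open + nchar(decoy_lab) + 1L)
    # the decoy extends the text of the last subcaption
    subcaps$text[nrow(subcaps)] <- paste0(subcaps$text[nrow(subcaps)],
                                          sub("\\.$", "", decoy), ".")
    if (isTRUE(subcaps$shared[nrow(subcaps)])) {
      subcaps$text[subcaps$shared] <- subcaps$text[nrow(subcaps)]
    }
  }
  list(caption = caption, subcaptions = subcaps,
       n_labeled = n, decoy_span = decoy_span)
}

# OCR confusion table: visually similar substitutions; characters with no
# entry degrade to "#" (unrecognized), which downstream treats as text.
.confusion_table <- c(D = "I", B = "8", O = "0", I = "L", C = "G",
                      E = "F", G = "C", S = "5", Z = "2", `1` = "I",
                      `0` = "O", `5` = "S", `8` = "B")

#' Corrupt clean OCR tokens with drops and character confusions
#'
#' Each token is independently dropped with `drop_rate`; surviving tokens
#' have their label character replaced via a visual-confusion table (e.g.
#' D read as I) with `confusion_rate`. Deterministic given `seed`.
#'
#' @param tokens clean token data.frame (from fixture truth).
#' @param drop_rate,confusion_rate rates in `[0,1]`.
#' @param seed integer seed.
#' @return list: `tokens` (noisy data.frame), `dropped` (indices into the
#'   input), `confused` (indices), `original` (the input).
#' @export
corrupt_ocr <- function(tokens, drop_rate, confusion_rate, seed) {
  stopifnot(drop_rate >= 0, drop_rate <= 1,
            confusion_rate >= 0, confusion_rate <= 1)
  rng <- fs_rng(seed * 31L + 17L)
  n <- nrow(tokens)
  keep <- logical(n); confused <- integer(0)
  out <- tokens
  u1 <- rng$unif(n); u2 <- rng$unif(n)
  for (i in seq_len(n)) {
    keep[i] <- u1[i] >= drop_rate
    if (!keep[i]) next
    if (u2[i] < confusion_rate) {
      core <- gsub("[^[:alnum:]]", "", tokens$text[i])
      sub_ch <- .confusion_table[core]
      if (is.na(sub_ch)) sub_ch <- "#"
      out$text[i] <- sub(core, sub_ch, tokens$text[i], fixed = TRUE)
      confused <- c(confused, i)
    }
  }
  list(tokens = out[keep, , drop = FALSE], dropped = which(!keep),
       confused = intersect(confused, which(keep)), original = tokens)
}

# Small seeded blob image used as a standalone document figure.
.doc_figure_image <- function(rng, h = 80L, w = 100L) {
  img <- matrix(255L, h, w)
  x0 <- rng$int(1L, 5L, 20L); y0 <- rng$int(1L, 5L, 20L)
  img[y0:(y0 + 39L), x0:(x0 + 59L)] <- 30L
  img
}

#' Generate a synthetic document operator stream with ground truth
#'
#' Each page carries body text (defining the page text rectangle), figures
#' with captions directly below them in the same column, optionally a
#' journal logo outside the text rectangle, optionally a figure stored as
#' three stacked fragments, and (multi-figure documents only) an in-text
#' citation paragraph "(Fig. 1) ..." that the caption filter must discard.
#'
#' @param n_pages number of pages, one figure-caption pair per page.
#' @param logos place a logo on every page.
#' @param fragmented_page 1-based page whose figure is emitted as three
#'   fragments (0 = none).
#' @param two_column place figure and caption in the left column of a
#'   two-column page.
#' @param citations insert citation paragraphs (ignored for 1-page docs).
#' @param seed integer seed.
#' @return list `stream`, `text_rects`, and `truth`: `pairs` (data.frame of
#'   figure/caption operator indices), `logo_ops`, `fragment_ops`,
#'   `reconstructed_dim` (`c(h, w)` or NULL), `caption_texts`.
#' @export
generate_operator_stream <- function(n_pages = 2L, logos = TRUE,
                                     fragmented_page = 0L,
                                     two_column = FALSE,
                                     citations = TRUE, seed = 1L) {
  rng <- fs_rng(seed * 52711L + 3L)
  stream <- list()
  text_rects <- list()
  pairs <- list(); logo_ops <- integer(0); fragment_ops <- integer(0)
  caption_texts <- character(n_pages)
  reconstructed_dim <- NULL
  line_h <- 12
  push <- function(op) {
    stream[[length(stream) + 1L]] <<- op
    length(stream)
  }
  for (pg in seq_len(n_pages) - 1L) {
    rect <- bbox(40, 60, 560, 780)
    text_rects[[as.character(pg)]] <- rect
    col_w <- (rect[[3]] - rect[[1]] - 20) / 2
    body_x1 <- if (two_column) rect[[1]] + col_w else rect[[3]]
    # body paragraph
    y <- 60
    for (l in 1:3) {
      push(operator_text(pg, bbox(rect[[1]], y, body_x1, y + line_h),
                         paste("Body text line", l, "page", pg + 1L)))
      y <- y + line_h + 2
    }
    if (citations && n_pages > 1L) {
      y <- y + 3 * line_h # paragraph break
      push(operator_text(pg, bbox(rect[[1]], y, body_x1, y + line_h),
                         "(Fig. 1) as discussed in the first experiment."))
      y <- y + line_h + 2
    }
    if (logos) {
      logo_img <- matrix(0L, 16L, 16L)
      logo_ops <- c(logo_ops, push(operator_image(
        pg, bbox(570, 10, 600, 40), logo_img)))
    }
    fig_x0 <- rect[[1]] + 20
    fig_x1 <- if (two_column) fig_x0 + 180 else fig_x0 + 200
    fig_y0 <- 300
    if (fragmented_page == pg + 1L) {
      full <- .doc_figure_image(rng, h = 90L, w = 200L)
      reconstructed_dim <- dim(full)
      s <- 0.5 # placed at half native size; canvas restores native pixels
      frag_idx <- integer(0)
      for (f in 1:3) {
        strip <- full[((f - 1L) * 30L + 1L):(f * 30L), , drop = FALSE]
        frag_idx <- c(frag_idx, push(operator_image(
          pg, bbox(fig_x0, fig_y0 + (f - 1L) * 30L * s,
                   fig_x0 + 200L * s, fig_y0 + f * 30L * s), strip)))
      }
      fragment_ops <- c(fragment_ops, frag_idx)
      fig_op <- frag_idx[[1]]
      fig_y1 <- fig_y0 + 90L * s
    } else {
      img <- .doc_figure_image(rng)
      fig_op <- push(operator_image(pg, bbox(fig_x0, fig_y0, fig_x1,
                                             fig_y0 + 80), img))
      fig_y1 <- fig_y0 + 80
    }
    cap_lines <- c(sprintf("Figure %d. Interaction of protein", pg + 1L),
                   "complexes resolved by", "cosedimentation analysis.")
    cap_y <- fig_y1 + 4
    cap_op <- NA_integer_
    for (cl in cap_lines) {
      idx <- push(operator_text(pg, bbox(fig_x0, cap_y, fig_x1,
                                         cap_y + line_h), cl))
      if (is.na(cap_op)) cap_op <- idx
      cap_y <- cap_y + line_h + 2
    }
    caption_texts[pg + 1L] <- paste(cap_lines, collapse = " ")
    pairs[[length(pairs) + 1L]] <- data.frame(figure_op = fig_op,
                                              caption_op = cap_op,
                                              page = pg)
  }
  list(stream = stream, text_rects = text_rects,
       truth = list(pairs = do.call(rbind, pairs), logo_ops = logo_ops,
                    fragment_ops = fragment_ops,
                    reconstructed_dim = reconstructed_dim,
                    caption_texts = caption_texts))
}
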