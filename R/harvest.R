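# Figure/caption harvesting from a typed document operator stream: an
# event-driven FSM walks the operators, captions fragmented across one-line
# text operators are merged, journal logos outside the page text rectangle
# are dropped, fragmented figures are reassembled at the highest native
# resolution, figure citations are separated from true captions by
# descriptor clustering, and figures are matched to captions by a greedy
# minimum-cost association.

.fig_cue_re <- "^\\s*\\(?fig(ure)?\\.?(\\s|$)"

is_caption_start <- function(text) {
  grepl(.fig_cue_re, text, ignore.case = TRUE)
}

#' Build a text operator
#' @param page 0-based page index.
#' @param box a [bbox()] in page coordinates.
#' @param text one line of text.
#' @return operator list.
#' @export
operator_text <- function(page, box, text) {
  validate_bbox(box)
  list(kind = "text", page = as.integer(page), bbox = box, text = text)
}

#' Build an image operator
#' @param page 0-based page index.
#' @param box placement [bbox()] on the page.
#' @param image pixel matrix (native resolution).
#' @param orientation placement rotation, one of 0, 90, 180, 270 (clockwise).
#' @return operator list.
#' @export
operator_image <- function(page, box, image, orientation = 0L) {
  validate_bbox(box)
  stopifnot(is.matrix(image), orientation %in% c(0L, 90L, 180L, 270L))
  list(kind = "image", page = as.integer(page), bbox = box, image = image,
       orientation = as.integer(orientation))
}

.valid_operator <- function(op) {
  is.list(op) && !is.null(op$kind) && op$kind %in% c("text", "image") &&
    !is.null(op$page) && op$page >= 0 && !is.null(op$bbox) &&
    !inherits(try(validate_bbox(op$bbox), silent = TRUE), "try-error") &&
    ((op$kind == "text" && is.character(op$text)) ||
       (op$kind == "image" && is.matrix(op$image)))
}

#' Recover captions and figures from an operator stream
#'
#' Four-state FSM: reading operators, reading a caption (consecutive text
#' operators of one paragraph are merged into a single caption), reading an
#' image, finish. End-of-stream finishes cleanly from any reading state.
#'
#' @param stream list of operators ([operator_text()], [operator_image()]) in
#'   emission order.
#' @return list with `captions` (each: `text`, `page`, `bbox`,
#'   `figure_number`, `op_index`) and `figures` (each: `image`, `page`,
#'   `bbox`, `orientation`, `op_index`, `is_reconstructed = FALSE`).
#' @export
extract_objects <- function(stream) {
  captions <- list()
  figures <- list()
  i <- 1L
  n <- length(stream)
  while (i <= n) {
    op <- stream[[i]]
    if (!.valid_operator(op)) {
      warning("skipping malformed operator at position ", i)
      i <- i + 1L
      next
    }
    if (op$kind == "image") { # "Reading Image" state
      figures[[length(figures) + 1L]] <- list(
        image = op$image, page = op$page, bbox = op$bbox,
        orientation = op$orientation %||% 0L, op_index = i,
        is_reconstructed = FALSE
      )
      i <- i + 1L
    } else if (is_caption_start(op$text)) { # "Reading Caption" state
      parts <- op$text
      box <- op$bbox
      last <- op
      start_i <- i
      i <- i + 1L
      while (i <= n) {
        nx <- stream[[i]]
        if (!.valid_operator(nx) || nx$kind != "text" ||
            nx$page != last$page || is_caption_start(nx$text)) break
        line_h <- last$bbox[[4]] - last$bbox[[2]]
        gap <- nx$bbox[[2]] - last$bbox[[4]]
        if (gap > line_h) break # paragraph ended
        parts <- c(parts, nx$text)
        box <- bbox_union(box, nx$bbox)
        last <- nx
        i <- i + 1L
      }
      text <- paste(parts, collapse = " ")
      num <- sub("^\\s*\\(?fig(?:ure)?\\.?[ :]*([0-9]+).*$", "\\1", text,
                 ignore.case = TRUE, perl = TRUE)
      captions[[length(captions) + 1L]] <- list(
        text = text, page = op$page, bbox = box,
        figure_number = if (grepl("^[0-9]+$", num)) as.integer(num) else NA_integer_,
        op_index = start_i
      )
    } else {
      i <- i + 1L # plain text: stay in "Reading Operator"
    }
  }
  list(captions = captions, figures = figures)
}

#' Remove figures lying outside the page text rectangle
#'
#' Journal/conference logos sit in page margins; a figure whose box is
#' entirely outside the rectangle bounding the article text on its page is
#' dropped. Figures straddling the rectangle edge are kept.
#'
#' @param figures list of figure objects (from [extract_objects()]).
#' @param text_rects named list of [bbox()] keyed by page index as character
#'   (`"0"`, `"1"`, ...).
#' @return list with `kept` and `removed` figure lists.
#' @export
filter_logos <- function(figures, text_rects) {
  kept <- list(); removed <- list()
  for (f in figures) {
    rect <- text_rects[[as.character(f$page)]]
    if (is.null(rect)) {
      warning("no text rectangle for page ", f$page, "; keeping figure")
      kept[[length(kept) + 1L]] <- f
    } else if (bbox_overlaps(f$bbox, rect)) {
      kept[[length(kept) + 1L]] <- f
    } else {
      removed[[length(removed) + 1L]] <- f
    }
  }
  list(kept = kept, removed = removed)
}

rotate_image <- function(img, orientation) {
  switch(as.character(orientation),
         "0" = img,
         "90" = t(img[nrow(img):1, , drop = FALSE]),
         "180" = img[nrow(img):1, ncol(img):1, drop = FALSE],
         "270" = t(img)[ncol(img):1, , drop = FALSE],
         stop("orientation must be 0/90/180/270"))
}

resample_nearest <- function(img, th, tw) {
  oh <- nrow(img); ow <- ncol(img)
  if (oh == th && ow == tw) return(img)
  ry <- pmin(oh, pmax(1L, floor((seq_len(th) - 0.5) * oh / th) + 1L))
  rx <- pmin(ow, pmax(1L, floor((seq_len(tw) - 0.5) * ow / tw) + 1L))
  img[ry, rx, drop = FALSE]
}

#' Merge a fragmented figure into one high-resolution image
#'
#' PDFs frequently store one logical figure as several image operators. Each
#' fragment's scaling factor is its placed size over its native size; the
#' merged canvas is the page-space bounding box of all placements rendered
#' at the resolution implied by the smallest scaling factor, so the sharpest
#' fragment keeps its native resolution and nothing is undersampled.
#'
#' @param subfigs list of figure objects with `image`, `bbox` (placement) and
#'   `orientation`.
#' @return one figure object; `is_reconstructed` is TRUE when more than one
#'   fragment was merged. A single fragment is returned untouched.
#' @export
merge_subfigures <- function(subfigs) {
  stopifnot(length(subfigs) >= 1L)
  if (length(subfigs) == 1L) return(subfigs[[1]])
  oriented <- lapply(subfigs, function(f)
    rotate_image(f$image, f$orientation %||% 0L))
  s <- vapply(seq_along(subfigs), function(k) {
    b <- subfigs[[k]]$bbox
    (b[[3]] - b[[1]]) / ncol(oriented[[k]])
  }, 1)
  smin <- min(s)
  U <- bbox_union_all(lapply(subfigs, `[[`, "bbox"))
  W <- as.integer(round((U[[3]] - U[[1]]) / smin))
  H <- as.integer(round((U[[4]] - U[[2]]) / smin))
  canvas <- matrix(255L, H, W)
  written <- matrix(FALSE, H, W)
  overlap <- FALSE
  for (k in seq_along(subfigs)) {
    b <- subfigs[[k]]$bbox
    tx0 <- as.integer(round((b[[1]] - U[[1]]) / smin))
    ty0 <- as.integer(round((b[[2]] - U[[2]]) / smin))
    tw <- as.integer(round((b[[3]] - b[[1]]) / smin))
    th <- as.integer(round((b[[4]] - b[[2]]) / smin))
    tw <- min(tw, W - tx0); th <- min(th, H - ty0)
    piece <- resample_nearest(oriented[[k]], th, tw)
    rows <- (ty0 + 1L):(ty0 + th)
    cols <- (tx0 + 1L):(tx0 + tw)
    if (any(written[rows, cols])) overlap <- TRUE
    canvas[rows, cols] <- piece # later fragment wins on overlap
    written[rows, cols] <- TRUE
  }
  if (overlap) warning("overlapping subfigure placements; later fragment wins")
  list(image = canvas, page = subfigs[[1]]$page, bbox = U,
       orientation = 0L, op_index = subfigs[[1]]$op_index,
       is_reconstructed = TRUE)
}

#' Caption descriptor for citation filtering
#'
#' Built from the first two whitespace-delimited words of the text;
#' alphabetic, special and punctuation characters are preserved and each
#' maximal digit run collapses to one `#`. True captions ("Figure 2.") and
#' in-text citations ("(Fig. 2)") then cluster apart.
#'
#' @param text caption or paragraph string.
#' @return descriptor string; idempotent.
#' @export
#' @examples
#' caption_descriptor("Figure 2. Binding assay")  # "Figure #."
#' caption_descriptor("Fig. 10, lanes 1-4")       # "Fig. #,"
caption_descriptor <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  words <- strsplit(trimws(text), "\\s+")[[1]]
  stopifnot(length(words) >= 1L)
  desc <- paste(head(words, 2L), collapse = " ")
  gsub("[0-9]+", "#", desc)
}

#' Select the caption cluster with the most unique figure links
#'
#' Captions are clustered by identical descriptor; the cluster linking the
#' most unique figure numbers is the true caption set, the rest (typically
#' figure citations) are discarded. Ties go to the cluster whose first
#' member appears earliest in the document.
#'
#' @param captions list of caption objects carrying `text` and
#'   `figure_number`.
#' @return list with `selected` (captions, original order) and `discarded`.
#' @export
select_caption_group <- function(captions) {
  if (length(captions) == 0L) return(list(selected = list(), discarded = list()))
  desc <- vapply(captions, function(cp) caption_descriptor(cp$text), "")
  uniq <- unique(desc)
  score <- vapply(uniq, function(d) {
    nums <- vapply(captions[desc == d], function(cp)
      cp$figure_number %||% NA_integer_, 1L)
    length(unique(nums[!is.na(nums)]))
  }, 1L)
  first_at <- vapply(uniq, function(d) which(desc == d)[[1]], 1L)
  win <- uniq[order(-score, first_at)][[1]]
  list(selected = captions[desc == win], discarded = captions[desc != win])
}

#' Assign column tags from the page text rectangle
#'
#' An object is `left`/`right` when its box lies entirely within the
#' left/right half of the page text rectangle (5% width tolerance),
#' otherwise `double`.
#'
#' @param objs list of objects with `page` and `bbox`.
#' @param text_rects named list of page text rectangles.
#' @param tol half-assignment tolerance as a fraction of rect width.
#' @return `objs` with a `column_tag` field added.
#' @export
assign_column_tags <- function(objs, text_rects, tol = 0.05) {
  lapply(objs, function(o) {
    rect <- text_rects[[as.character(o$page)]]
    if (is.null(rect)) {
      o$column_tag <- "double"
      return(o)
    }
    mid <- (rect[[1]] + rect[[3]]) / 2
    slack <- tol * (rect[[3]] - rect[[1]])
    o$column_tag <- if (o$bbox[[3]] <= mid + slack) "left"
    else if (o$bbox[[1]] >= mid - slack) "right"
    else "double"
    o
  })
}

# Cost of associating one figure-caption pair.
pair_cost <- function(fig_bbox, cap_bbox, same_column,
                      penalty_factor = 10, disparity = 1) {
  d <- bbox_min_distance(fig_bbox, cap_bbox)
  p <- if (same_column) 1 else penalty_factor
  d * p * disparity
}

.greedy_match <- function(cost) {
  matches <- list()
  fleft <- seq_len(nrow(cost)); cleft <- seq_len(ncol(cost))
  while (length(fleft) > 0L && length(cleft) > 0L) {
    sub <- cost[fleft, cleft, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ] # deterministic tie
    fi <- fleft[[k[[1]]]]; ci <- cleft[[k[[2]]]]
    matches[[length(matches) + 1L]] <- c(fi, ci, cost[fi, ci])
    fleft <- setdiff(fleft, fi); cleft <- setdiff(cleft, ci)
  }
  matches
}

#' Match figures to captions across a document
#'
#' Per page: a single figure and single caption match directly; otherwise a
#' cost matrix `C = d * p` (boundary distance times a cross-column penalty)
#' is greedily consumed, always associating the current global-minimum
#' entry. Leftovers from all pages are pooled into one matrix with
#' `C = d * p * (1 + |page difference|)` and matched the same way. Every
#' object is matched at most once.
#'
#' @param figures,captions lists of objects with `page`, `bbox`,
#'   `column_tag` (see [assign_column_tags()]).
#' @param penalty_factor cross-column penalty (default 10).
#' @return list: `matches` data.frame (`figure`, `caption` -- indices into
#'   the input lists -- `cost`, `stage`), `unmatched_figures`,
#'   `unmatched_captions` (index vectors).
#' @export
match_document <- function(figures, captions, penalty_factor = 10) {
  empty <- data.frame(figure = integer(0), caption = integer(0),
                      cost = numeric(0), stage = character(0))
  if (length(figures) == 0L || length(captions) == 0L) {
    return(list(matches = empty,
                unmatched_figures = seq_along(figures),
                unmatched_captions = seq_along(captions)))
  }
  ord_key <- function(o) c(o$page, o$bbox[[2]], o$bbox[[1]])
  fkey <- t(vapply(figures, ord_key, numeric(3)))
  ckey <- t(vapply(captions, ord_key, numeric(3)))
  ford <- order(fkey[, 1], fkey[, 2], fkey[, 3])
  cord <- order(ckey[, 1], ckey[, 2], ckey[, 3])
  rows <- list()
  fmatched <- logical(length(figures)); cmatched <- logical(length(captions))
  for (pg in sort(unique(c(fkey[, 1], ckey[, 1])))) {
    fi <- ford[fkey[ford, 1] == pg]
    ci <- cord[ckey[cord, 1] == pg]
    if (length(fi) == 0L || length(ci) == 0L) next
    if (length(fi) == 1L && length(ci) == 1L) {
      f <- figures[[fi]]; cp <- captions[[ci]]
      rows[[length(rows) + 1L]] <- data.frame(
        figure = fi, caption = ci,
        cost = pair_cost(f$bbox, cp$bbox,
                         identical(f$column_tag, cp$column_tag),
                         penalty_factor),
        stage = "one_to_one")
      fmatched[fi] <- TRUE; cmatched[ci] <- TRUE
      next
    }
    cost <- matrix(0, length(fi), length(ci))
    for (a in seq_along(fi)) for (b in seq_along(ci)) {
      cost[a, b] <- pair_cost(
        figures[[fi[a]]]$bbox, captions[[ci[b]]]$bbox,
        identical(figures[[fi[a]]]$column_tag, captions[[ci[b]]]$column_tag),
        penalty_factor)
    }
    for (m in .greedy_match(cost)) {
      rows[[length(rows) + 1L]] <- data.frame(
        figure = fi[m[[1]]], caption = ci[m[[2]]], cost = m[[3]],
        stage = "greedy_page")
      fmatched[fi[m[[1]]]] <- TRUE; cmatched[ci[m[[2]]]] <- TRUE
    }
  }
  fi <- ford[!fmatched[ford]]
  ci <- cord[!cmatched[cord]]
  if (length(fi) > 0L && length(ci) > 0L) {
    cost <- matrix(0, length(fi), length(ci))
    for (a in seq_along(fi)) for (b in seq_along(ci)) {
      f <- figures[[fi[a]]]; cp <- captions[[ci[b]]]
      cost[a, b] <- pair_cost(f$bbox, cp$bbox,
                              identical(f$column_tag, cp$column_tag),
                              penalty_factor,
                              disparity = 1 + abs(f$page - cp$page))
    }
    for (m in .greedy_match(cost)) {
      rows[[length(rows) + 1L]] <- data.frame(
        figure = fi[m[[1]]], caption = ci[m[[2]]], cost = m[[3]],
        stage = "cross_page")
      fmatched[fi[m[[1]]]] <- TRUE; cmatched[ci[m[[2]]]] <- TRUE
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else empty
  list(matches = matches,
       unmatched_figures = which(!fmatched),
       unmatched_captions = which(!cmatched))
}

#' Harvest a whole document operator stream
#'
#' Orchestrates [extract_objects()], logo filtering, fragmented-figure
#' merging (maximal runs of adjacent image operators on a page followed by a
#' caption), citation filtering via [select_caption_group()], column
#' tagging, and [match_document()].
#'
#' @param stream operator list.
#' @param text_rects optional named list of page text rectangles; when NULL
#'   they are computed as the union of non-caption text operator boxes per
#'   page.
#' @param penalty_factor cross-column matching penalty.
#' @return list with `figures`, `captions`, `matches` (data.frame of paired
#'   figure/caption list indices), `logos_removed`, `unmatched_figures`,
#'   `unmatched_captions`.
#' @export
harvest_document <- function(stream, text_rects = NULL, penalty_factor = 10) {
  eo <- extract_objects(stream)
  if (is.null(text_rects)) {
    text_rects <- list()
    for (i in seq_along(stream)) {
      op <- stream[[i]]
      if (!.valid_operator(op) || op$kind != "text") next
      if (is_caption_start(op$text)) next
      key <- as.character(op$page)
      text_rects[[key]] <- if (is.null(text_rects[[key]])) op$bbox
      else bbox_union(text_rects[[key]], op$bbox)
    }
  }
  lg <- filter_logos(eo$figures, text_rects)
  figures <- lg$kept
  # Merge maximal runs of stream-adjacent image operators on one page that
  # precede a caption (N-to-1 subfigure correspondence).
  if (length(figures) > 1L) {
    idx <- vapply(figures, `[[`, 1L, "op_index")
    page <- vapply(figures, `[[`, 1L, "page")
    runs <- list(); cur <- 1L
    for (k in seq_along(figures)[-1]) {
      if (idx[k] == idx[k - 1L] + 1L && page[k] == page[k - 1L]) {
        cur <- c(cur, k)
      } else {
        runs[[length(runs) + 1L]] <- cur; cur <- k
      }
    }
    runs[[length(runs) + 1L]] <- cur
    cap_on_page_after <- function(pg, after_op) {
      any(vapply(eo$captions, function(cp)
        cp$page == pg && cp$op_index > after_op, TRUE))
    }
    figures <- lapply(runs, function(r) {
      if (length(r) >= 2L &&
          cap_on_page_after(page[r[[1]]], max(idx[r]))) {
        merge_subfigures(figures[r])
      } else if (length(r) == 1L) figures[[r]] else {
        # adjacent but no caption follows: leave unmerged
        figures[r]
      }
    })
    figures <- do.call(c, lapply(figures, function(f)
      if (!is.null(f$image)) list(f) else f))
  }
  cg <- select_caption_group(eo$captions)
  captions <- cg$selected
  figures <- assign_column_tags(figures, text_rects)
  captions <- assign_column_tags(captions, text_rects)
  mm <- match_document(figures, captions, penalty_factor)
  list(figures = figures, captions = captions, matches = mm$matches,
       logos_removed = lg$removed,
       unmatched_figures = mm$unmatched_figures,
       unmatched_captions = mm$unmatched_captions)
}
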