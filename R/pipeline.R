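# End-to-end orchestration: caption analysis, OCR label recovery, pixel
# preprocessing, panel-count estimation, layout-graph partitioning and
# subcaption pairing for one figure; corpus-level evaluation against
# fixture ground truth; construction of the noisy evidence corpus that
# trains the fallback count model.

#' Default pipeline configuration
#' @param penalty_factor cross-column matching penalty (harvest stage).
#' @param min_cc_area connected-component area threshold in pixels.
#' @param text_box_padding padding around OCR boxes before text removal.
#' @return named list.
#' @export
figseg_config <- function(penalty_factor = 10, min_cc_area = 50L,
                          text_box_padding = 0L) {
  list(penalty_factor = penalty_factor, min_cc_area = as.integer(min_cc_area),
       text_box_padding = as.integer(text_box_padding))
}

#' Segment one figure into labeled panels with subcaptions
#'
#' Runs the full per-figure pipeline: the caption is lexed and split into
#' subcaptions; panel labels are recovered from the OCR tokens; the image is
#' thresholded and reduced to merged connected components (text regions
#' removed); the three counts are reconciled into a panel-count estimate;
#' the label sequence is completed, the layout graph built and the figure
#' partitioned along minimum-cost cuts; finally panels are paired with
#' subcaptions by label.
#'
#' @param image grayscale matrix (or RGB array).
#' @param caption caption text.
#' @param tokens OCR token data.frame (`text`, bbox columns, optional
#'   `conf`); may have zero rows.
#' @param config list from [figseg_config()].
#' @param model optional `figseg_count_model` for the fallback path.
#' @return list: `panels` (data.frame with `label`, bbox columns,
#'   `subcaption`, `shared`), `n_panels`, `decision`, `degraded`,
#'   `unplaced` (subcaption labels without a panel), `evidence`, and
#'   `intermediates` (caption analysis, selected label group, components,
#'   cuts, region map).
#' @export
run_figure <- function(image, caption, tokens,
                       config = figseg_config(), model = NULL) {
  gray <- as_gray(image)
  H <- nrow(gray); W <- ncol(gray)
  cap <- segment_caption(caption)
  ns <- cap$n_labeled
  group <- recover_labels(tokens)
  nl <- if (is.null(group)) 0L else nrow(group$members)
  gaps <- if (is.null(group)) 0L else group$Gaps
  text_boxes <- if (!is.null(tokens) && nrow(tokens) > 0L)
    df_to_boxes(tokens) else list()
  prep <- preprocess_figure(gray, text_boxes,
                            min_area = config$min_cc_area,
                            pad = config$text_box_padding)
  ncc <- nrow(prep$components)
  ev <- list(n_subcaptions = ns, n_labels = nl, n_cc = ncc, gaps = gaps)
  est <- estimate_panel_count(ev, model)
  n <- est$n
  degraded <- FALSE
  full_box <- bbox(0, 0, W, H)
  single_panel <- function(label) {
    data.frame(label = label, position = 1L, x_min = 0, y_min = 0,
               x_max = W, y_max = H, n_pixels = W * H, region_id = 1L)
  }
  part <- NULL
  if (n == 1L || is.null(group)) {
    if (n > 1L) degraded <- TRUE # multi-panel figure but no label anchors
    lab <- if (!is.null(group)) group$members$char[[1]]
    else if (nrow(cap$accepted) > 0L) cap$accepted$label[[1]]
    else "∅"
    panels <- single_panel(lab)
  } else {
    nodes <- fill_label_gaps(group, c(W, H), n_target = n)
    if (length(attr(nodes, "unfillable")) > 0L) degraded <- TRUE
    if (nrow(nodes) == 0L) {
      panels <- single_panel("∅")
      degraded <- TRUE
    } else {
      graph <- build_layout_graph(nodes)
      part <- partition_figure(c(W, H), graph, prep$components)
      degraded <- degraded || part$degraded
      panels <- part$panels
    }
  }
  assoc <- associate_panels(panels, cap$subcaptions)
  list(panels = assoc$records, n_panels = n, decision = est$decision,
       degraded = degraded, unplaced = assoc$unplaced,
       evidence = ev,
       intermediates = list(caption = cap, group = group,
                            components = prep$components,
                            threshold = prep$threshold,
                            cuts = part$cuts, region_map = part$region_map))
}

# Default fixture shape cycle: all grids from 1x1 to 4x4.
.shape_cycle <- function(i) {
  shapes <- expand.grid(rows = 1:4, cols = 1:4)
  shapes[(i - 1L) %% nrow(shapes) + 1L, ]
}

#' Generate a corpus of fixture cases
#'
#' Cycles through all grid shapes 1x1..4x4 and the three label alphabets,
#' applying the requested OCR/caption noise. Each case carries everything
#' [run_figure()] needs plus ground truth.
#'
#' @param n number of cases.
#' @param seed base seed; case i uses `seed + i`.
#' @param ocr_drop_rate,ocr_confusion_rate,caption_label_corruption noise
#'   settings passed to the generator.
#' @param alphabets alphabets to cycle over.
#' @param min_panels skip shapes with fewer panels than this.
#' @return list of cases: `image`, `caption`, `tokens` (noisy), `truth`,
#'   `noise` (corruption record).
#' @export
make_fixture_corpus <- function(n, seed = 0L, ocr_drop_rate = 0,
                                ocr_confusion_rate = 0,
                                caption_label_corruption = FALSE,
                                alphabets = c("latin", "roman", "arabic"),
                                min_panels = 1L) {
  out <- vector("list", n)
  i <- 0L; tries <- 0L
  while (i < n) {
    tries <- tries + 1L
    sh <- .shape_cycle(tries)
    npan <- sh$rows * sh$cols
    if (npan < min_panels) next
    alpha <- alphabets[(tries - 1L) %% length(alphabets) + 1L]
    if (alpha == "roman" && npan > 12L) alpha <- "latin"
    cat_cycle <- c("closed", "right_closed", "simple")
    style_cycle <- c("per_label", "range")
    i <- i + 1L
    spec <- fixture_spec(
      rows = sh$rows, cols = sh$cols, label_alphabet = alpha,
      label_category = cat_cycle[(tries - 1L) %% 3L + 1L],
      caption_style = if (npan >= 2L)
        style_cycle[(tries - 1L) %% 2L + 1L] else "per_label",
      ocr_drop_rate = ocr_drop_rate,
      ocr_confusion_rate = ocr_confusion_rate,
      caption_label_corruption = caption_label_corruption,
      figure_number = (tries %% 9L) + 1L,
      seed = seed + i
    )
    fx <- generate_figure(spec)
    noise <- corrupt_ocr(fx$truth$tokens, ocr_drop_rate, ocr_confusion_rate,
                         seed = seed + 100000L + i)
    out[[i]] <- list(image = fx$image, caption = fx$truth$caption,
                     tokens = noise$tokens, truth = fx$truth, noise = noise)
  }
  out
}

#' Collect count evidence from fixture cases
#'
#' Runs the caption, OCR-label and component stages (not the partition) on
#' each case and returns the evidence table used to train or test the count
#' model.
#'
#' @param cases list from [make_fixture_corpus()].
#' @param config pipeline configuration.
#' @return data.frame `n_subcaptions`, `n_labels`, `n_cc`, `gaps`,
#'   `true_count`.
#' @export
collect_count_evidence <- function(cases, config = figseg_config()) {
  rows <- lapply(cases, function(cs) {
    cap <- segment_caption(cs$caption)
    group <- recover_labels(cs$tokens)
    text_boxes <- if (nrow(cs$tokens) > 0L) df_to_boxes(cs$tokens) else list()
    prep <- preprocess_figure(cs$image, text_boxes,
                              min_area = config$min_cc_area,
                              pad = config$text_box_padding)
    data.frame(
      n_subcaptions = cap$n_labeled,
      n_labels = if (is.null(group)) 0L else nrow(group$members),
      n_cc = nrow(prep$components),
      gaps = if (is.null(group)) 0L else group$Gaps,
      true_count = cs$truth$n_panels
    )
  })
  do.call(rbind, rows)
}

#' Evaluate the pipeline over a fixture corpus
#'
#' Success definitions: a caption is successfully segmented when it yields
#' as many subcaptions as the gold panel count; labels are successful when
#' the selected group's characters equal the gold label set; a figure's
#' panels are successful when the estimated count is right and every gold
#' content box falls inside the region of its own label.
#'
#' @param cases list from [make_fixture_corpus()].
#' @param model optional count model.
#' @param config pipeline configuration.
#' @return list with `rates` (caption/label/count/panel success rates in
#'   \[0,1\]), `per_figure` data.frame, `decisions` table.
#' @export
evaluate_corpus <- function(cases, model = NULL, config = figseg_config()) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    res <- run_figure(cs$image, cs$caption, cs$tokens, config, model)
    truth <- cs$truth
    caption_ok <- nrow(res$intermediates$caption$subcaptions) ==
      truth$n_panels &&
      all(res$intermediates$caption$subcaptions$label != "∅")
    group <- res$intermediates$group
    labels_ok <- !is.null(group) &&
      identical(sort(group$members$char), sort(truth$labels))
    count_ok <- res$n_panels == truth$n_panels
    panels_ok <- count_ok && !res$degraded
    if (panels_ok) {
      for (p in seq_len(truth$n_panels)) {
        reg <- res$panels[res$panels$label == truth$labels[[p]], ]
        if (nrow(reg) != 1L ||
            !bbox_contains(bbox(reg$x_min, reg$y_min, reg$x_max, reg$y_max),
                           truth$content_boxes[[p]])) {
          panels_ok <- FALSE
          break
        }
      }
    }
    data.frame(case = i, n_true = truth$n_panels, n_est = res$n_panels,
               decision = res$decision, caption_ok = caption_ok,
               labels_ok = labels_ok, count_ok = count_ok,
               panels_ok = panels_ok, degraded = res$degraded)
  })
  per_figure <- do.call(rbind, rows)
  list(
    rates = c(caption = mean(per_figure$caption_ok),
              labels = mean(per_figure$labels_ok),
              count = mean(per_figure$count_ok),
              panels = mean(per_figure$panels_ok)),
    per_figure = per_figure,
    decisions = table(per_figure$decision)
  )
}
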