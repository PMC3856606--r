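img1 <- matrix(0L, 10, 10)

test_that("FSM merges caption lines and collects figures", {
  stream <- list(
    operator_text(0, bbox(50, 100, 300, 112), "Fig. 1 Interaction of"),
    operator_text(0, bbox(50, 114, 300, 126), "A and B."),
    operator_image(0, bbox(50, 140, 150, 240), img1)
  )
  eo <- extract_objects(stream)
  expect_length(eo$captions, 1L)
  expect_equal(eo$captions[[1]]$text, "Fig. 1 Interaction of A and B.")
  expect_equal(eo$captions[[1]]$figure_number, 1L)
  expect_length(eo$figures, 1L)

  eo <- extract_objects(list(operator_image(0, bbox(0, 0, 10, 10), img1)))
  expect_length(eo$captions, 0L)
  expect_length(eo$figures, 1L)

  expect_length(extract_objects(list())$figures, 0L)
})

test_that("a paragraph gap ends the caption; malformed operators are skipped", {
  stream <- list(
    operator_text(0, bbox(50, 100, 300, 112), "Figure 2. Short caption."),
    operator_text(0, bbox(50, 160, 300, 172), "Distant body text."),
    list(kind = "text", page = 0) # malformed
  )
  expect_warning(eo <- extract_objects(stream), "malformed")
  expect_equal(eo$captions[[1]]$text, "Figure 2. Short caption.")
})

test_that("extract_objects reproduces generator captions exactly", {
  doc <- generate_operator_stream(n_pages = 3, seed = 7)
  eo <- extract_objects(doc$stream)
  true_caps <- vapply(Filter(
    function(cp) is_caption_start(cp$text) &&
      !startsWith(cp$text, "("), eo$captions), `[[`, "", "text")
  expect_true(all(doc$truth$caption_texts %in% true_caps))
  expect_equal(length(eo$figures),
               sum(vapply(doc$stream, function(o) o$kind == "image", TRUE)))
})

test_that("logo filtering removes only fully-outside figures", {
  rects <- list(`0` = bbox(50, 80, 550, 750))
  figs <- list(
    list(image = img1, page = 0L, bbox = bbox(600, 0, 700, 40)),    # logo
    list(image = img1, page = 0L, bbox = bbox(60, 100, 500, 400)),  # inside
    list(image = img1, page = 0L, bbox = bbox(500, 100, 600, 200))  # straddles
  )
  lg <- filter_logos(figs, rects)
  expect_length(lg$removed, 1L)
  expect_equal(lg$removed[[1]]$bbox, bbox(600, 0, 700, 40))
  expect_length(lg$kept, 2L)
  expect_warning(filter_logos(list(list(image = img1, page = 3L,
                                        bbox = bbox(0, 0, 5, 5))), rects),
                 "no text rectangle")
})

test_that("merge_subfigures: identity, stacking, and smallest-scaling canvas", {
  f <- list(image = matrix(1:20, 4, 5), page = 0L, bbox = bbox(0, 0, 5, 4),
            orientation = 0L)
  expect_identical(merge_subfigures(list(f))$image, f$image)

  # three stacked strips at equal scaling reassemble pixel-exactly
  full <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  frags <- lapply(1:3, function(k) {
    list(image = full[((k - 1) * 10 + 1):(k * 10), , drop = FALSE],
         page = 0L, bbox = bbox(10, 50 + (k - 1) * 5, 20, 50 + k * 5),
         orientation = 0L)
  })
  m <- merge_subfigures(frags)
  expect_true(m$is_reconstructed)
  expect_identical(dim(m$image), dim(full))
  expect_identical(m$image, full)

  # scalings 0.5 and 0.25: canvas sized by the smaller factor
  a <- list(image = matrix(0L, 20, 20), page = 0L,
            bbox = bbox(0, 0, 10, 10), orientation = 0L)   # s = 0.5
  b <- list(image = matrix(0L, 40, 40), page = 0L,
            bbox = bbox(10, 0, 20, 10), orientation = 0L)  # s = 0.25
  m <- merge_subfigures(list(a, b))
  expect_equal(dim(m$image), c(40L, 80L)) # union 20x10 page units / 0.25
})

test_that("caption descriptors collapse digit runs and are idempotent", {
  expect_equal(caption_descriptor("Figure 2. Binding assay of X"),
               "Figure #.")
  expect_equal(caption_descriptor("Fig. 10, lanes 1-4"), "Fig. #,")
  expect_equal(caption_descriptor("(Fig. 3) citation text"), "(Fig. #)")
  expect_equal(caption_descriptor("Figure"), "Figure")
  d <- caption_descriptor("Figure 17. Something")
  expect_equal(caption_descriptor(d), d)
})

test_that("caption group selection keeps the cluster with most unique links", {
  mk <- function(txt, num, i) list(text = txt, figure_number = num,
                                   page = 0L, bbox = bbox(0, i * 10, 10, i * 10 + 5))
  caps <- list(mk("Figure 1. one", 1L, 1), mk("Figure 2. two", 2L, 2),
               mk("Figure 3. three", 3L, 3), mk("Figure 4. four", 4L, 4),
               mk("(Fig. 1) cited", 1L, 5), mk("(Fig. 1) again", 1L, 6),
               mk("(Fig. 2) more", 2L, 7))
  sel <- select_caption_group(caps)
  expect_length(sel$selected, 4L)
  expect_true(all(startsWith(vapply(sel$selected, `[[`, "", "text"),
                             "Figure")))
  # single cluster returned unchanged, duplicates retained
  caps2 <- list(mk("Figure 1. a", 1L, 1), mk("Figure 1. b", 1L, 2))
  expect_length(select_caption_group(caps2)$selected, 2L)
})

test_that("matching: direct, same-column greedy, and cross-page disparity", {
  # 1 figure + 1 caption on a page
  f <- list(page = 0L, bbox = bbox(0, 0, 100, 100), column_tag = "left")
  cp <- list(page = 0L, bbox = bbox(0, 110, 100, 130), column_tag = "left")
  mm <- match_document(list(f), list(cp))
  expect_equal(mm$matches$stage, "one_to_one")
  expect_equal(mm$matches$cost, 10)

  # 2x2 same-column below-figure: identity matching
  figs <- list(list(page = 0L, bbox = bbox(0, 0, 100, 100), column_tag = "left"),
               list(page = 0L, bbox = bbox(200, 0, 300, 100), column_tag = "right"))
  caps <- list(list(page = 0L, bbox = bbox(0, 110, 100, 130), column_tag = "left"),
               list(page = 0L, bbox = bbox(200, 110, 300, 130), column_tag = "right"))
  mm <- match_document(figs, caps)
  expect_equal(mm$matches$figure, mm$matches$caption)

  # leftover figure on page 2, caption on page 3: disparity 1 + |dp| = 2
  f2 <- list(page = 2L, bbox = bbox(0, 0, 100, 100), column_tag = "left")
  c3 <- list(page = 3L, bbox = bbox(0, 110, 100, 130), column_tag = "left")
  mm <- match_document(list(f2), list(c3))
  expect_equal(mm$matches$stage, "cross_page")
  expect_equal(mm$matches$cost, 10 * 1 * 2)

  # partial injection with leftovers reported
  mm <- match_document(figs, caps[1])
  expect_equal(nrow(mm$matches), 1L)
  expect_length(mm$unmatched_figures, 1L)
})

test_that("column tags follow the page text rectangle halves", {
  rects <- list(`0` = bbox(0, 0, 400, 700))
  objs <- list(list(page = 0L, bbox = bbox(10, 10, 150, 100)),
               list(page = 0L, bbox = bbox(250, 10, 390, 100)),
               list(page = 0L, bbox = bbox(50, 10, 350, 100)))
  tags <- vapply(assign_column_tags(objs, rects), `[[`, "", "column_tag")
  expect_equal(tags, c("left", "right", "double"))
})

test_that("harvest_document is a partial injection on generated documents", {
  doc <- generate_operator_stream(n_pages = 3, logos = TRUE,
                                  fragmented_page = 2, seed = 11)
  h <- harvest_document(doc$stream, doc$text_rects)
  expect_equal(length(h$logos_removed), length(doc$truth$logo_ops))
  expect_false(anyDuplicated(h$matches$figure) > 0)
  expect_false(anyDuplicated(h$matches$caption) > 0)
  expect_equal(nrow(h$matches), 3L)
})
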