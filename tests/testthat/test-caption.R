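test_that("lexer recognizes single, range and bare label tokens", {
  t1 <- lex_caption_labels("Figure 1. (A) Gel. (B) Blot.")
  expect_equal(t1$style, c("paren_single", "paren_single"))
  expect_equal(unlist(t1$labels), c("A", "B"))

  t2 <- lex_caption_labels("(A-C) Staining. (D) Merge.")
  expect_equal(t2$style, c("paren_range", "paren_single"))
  expect_equal(t2$labels[[1]], c("A", "B", "C"))
  expect_equal(t2$labels[[2]], "D")

  t3 <- lex_caption_labels("Results (I, II, and III) are shown.")
  expect_equal(t3$style, "paren_range")
  expect_equal(t3$alphabet, "roman")
  expect_equal(t3$labels[[1]], c("I", "II", "III"))

  t4 <- lex_caption_labels("a) first lane. b) second lane.")
  expect_equal(t4$style, c("bare", "bare"))
  expect_equal(unlist(t4$labels), c("A", "B")) # canonical uppercase

  t5 <- lex_caption_labels("(a to c) merged panels.")
  expect_equal(t5$labels[[1]], c("A", "B", "C"))
})

test_that("the caption-head figure number is not a label", {
  toks <- lex_caption_labels("Figure 12. (1) Input. (2) Output.")
  expect_equal(vapply(toks$labels, `[[`, "", 1), c("1", "2"))
  expect_true(all(toks$start > nchar("Figure 12.")))
})

test_that("spans do not overlap and tokens come in order", {
  txt <- "Fig. 3. (A-B) Double staining. C. last panel, (D) merge."
  toks <- lex_caption_labels(txt)
  expect_true(all(diff(toks$start) > 0))
  for (i in seq_len(nrow(toks) - 1)) {
    expect_lt(toks$end[i], toks$start[i + 1])
  }
})

test_that("filtering drops duplicates, strays and lower-priority alphabets", {
  # duplicate "(C)" later in the caption (abbreviation) is removed
  acc <- filter_label_candidates(
    lex_caption_labels("(A) gel. (B) blot. (C) stain. Note (C) is carbon."))
  expect_equal(acc$label, c("A", "B", "C"))

  # letters beat numbers when both form sequences
  acc <- filter_label_candidates(
    lex_caption_labels("(A) one (B) two (C) three with (1) and (2) inside."))
  expect_equal(acc$label, c("A", "B", "C"))

  # decreasing pair: longest increasing subsequence, earliest offset -> B
  acc <- filter_label_candidates(lex_caption_labels("(B) first. (A) second."))
  expect_equal(acc$label, "B")
})

test_that("sequence filtering equals the exhaustive LIS oracle", {
  set.seed(5)
  for (k in 1:60) {
    pos <- sample(1:9, sample(2:8, 1), replace = TRUE)
    labs <- LETTERS[pos]
    txt <- paste0("Figure 1. ", paste0("(", labs, ") t", seq_along(labs), ".",
                                       collapse = " "))
    toks <- lex_caption_labels(txt)
    acc <- filter_label_candidates(toks)
    # apply first-occurrence dedupe to the raw positions, as the filter does
    keep <- !duplicated(pos)
    expect_equal(acc$label, unique(labs)[oracle_lis(pos[keep])],
                 info = paste(pos, collapse = ","))
  }
})

test_that("splitting assigns text between tokens and expands ranges", {
  sp <- split_subcaptions("Fig 1. (A) Gel. (B) Blot.",
                          filter_label_candidates(
                            lex_caption_labels("Fig 1. (A) Gel. (B) Blot.")))
  expect_equal(sp$subcaptions$text, c("Gel.", "Blot."))
  expect_false(any(sp$subcaptions$shared))

  txt <- "(A-C) Staining. (D) Merge."
  sp <- split_subcaptions(txt, filter_label_candidates(lex_caption_labels(txt)))
  expect_equal(nrow(sp$subcaptions), 4L)
  expect_equal(sp$subcaptions$label, c("A", "B", "C", "D"))
  expect_equal(sp$subcaptions$text, c(rep("Staining.", 3), "Merge."))
  expect_equal(sp$subcaptions$shared, c(TRUE, TRUE, TRUE, FALSE))

  sp <- split_subcaptions("No labels at all here.",
                          filter_label_candidates(
                            lex_caption_labels("No labels at all here.")))
  expect_equal(sp$subcaptions$label, "∅")
})

test_that("token surfaces plus segments reconstruct the caption exactly", {
  caps <- c("Figure 2. (A) First panel. (B-D) Shared text. (E) Last.",
            "Fig. 9. a) one b) two c) three",
            "(I) alpha (II) beta (III) gamma")
  for (txt in caps) {
    acc <- filter_label_candidates(lex_caption_labels(txt))
    sp <- split_subcaptions(txt, acc)
    seg <- attr(sp, "segments")
    rebuilt <- paste0(seg$preamble,
                      paste0(seg$surfaces, seg$raw, collapse = ""))
    expect_identical(rebuilt, txt)
  }
})

test_that("200 generated captions across styles/alphabets split exactly", {
  for (i in 0:199) {
    n <- (i %% 9L) + 1L
    alpha <- c("latin", "roman", "arabic")[(i %% 3L) + 1L]
    style <- if (n >= 2L) c("per_label", "range")[(i %% 2L) + 1L]
    else "per_label"
    spec <- fixture_spec(rows = 1, cols = 1, label_alphabet = alpha,
                         caption_style = style, seed = i)
    # caption generation needs only the label sequence
    truth <- list(labels = vapply(seq_len(n), label_from_position, "",
                                  alphabet = alpha))
    cap <- generate_caption(spec, truth)
    s <- segment_caption(cap$caption)
    expect_equal(s$accepted$label, truth$labels, info = paste("case", i))
    got <- s$subcaptions$text[match(truth$labels, s$subcaptions$label)]
    expect_equal(got,
                 cap$subcaptions$text[match(truth$labels,
                                            cap$subcaptions$label)],
                 info = paste("case", i))
  }
})

test_that("subcaption count equals accepted labels after range expansion", {
  for (txt in c("(A-D) all shared.", "(A) x (B) y", "plain text")) {
    s <- segment_caption(txt)
    expected <- max(1L, nrow(s$accepted))
    expect_equal(nrow(s$subcaptions), expected)
  }
})
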