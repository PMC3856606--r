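test_that("panel count estimation follows consensus / CC / model order", {
  ev <- list(n_subcaptions = 4, n_labels = 4, n_cc = 9, gaps = 0)
  est <- estimate_panel_count(ev)
  expect_equal(est$n, 4L); expect_equal(est$decision, "consensus")

  ev <- list(n_subcaptions = 4, n_labels = 3, n_cc = 4, gaps = 1)
  est <- estimate_panel_count(ev)
  expect_equal(est$n, 4L); expect_equal(est$decision, "cc_arbitrated")

  est <- estimate_panel_count(list(n_subcaptions = 0, n_labels = 0,
                                   n_cc = 0, gaps = 0))
  expect_equal(est$n, 1L); expect_equal(est$decision, "default_single")

  # disagreement everywhere routes to the model
  corpus <- data.frame(n_subcaptions = rep(2:5, each = 20),
                       n_labels = rep(2:5, each = 20) - 1L,
                       n_cc = rep(2:5, each = 20) + 2L,
                       gaps = 1L, true_count = rep(2:5, each = 20))
  m <- train_count_model(corpus)
  est <- estimate_panel_count(list(n_subcaptions = 3, n_labels = 2,
                                   n_cc = 5, gaps = 1), m)
  expect_equal(est$decision, "model")
  expect_equal(est$n, 3L)
})

mk_group <- function(chars, cx, cy, alphabet = "latin", w = 10, h = 14) {
  members <- data.frame(
    char = chars, alphabet = alphabet, category = "closed",
    position = vapply(chars, label_position, 1L, alphabet = alphabet),
    x_min = cx - w / 2, y_min = cy - h / 2, x_max = cx + w / 2,
    y_max = cy + h / 2)
  panels <- max(members$position)
  list(alphabet = alphabet, category = "closed", members = members,
       Panels = panels, Gaps = panels - nrow(members),
       confidence = 1 / (1 + (panels - nrow(members)) * panels))
}

test_that("gap filling: midpoint in a row, grid alignment, identity", {
  # row with A at x=50, C at x=350, B missing -> B at x=200
  g <- mk_group(c("A", "C"), cx = c(50, 350), cy = c(20, 20))
  nodes <- fill_label_gaps(g, c(500, 120))
  b <- nodes[nodes$char == "B", ]
  expect_equal(b$cx, 200)
  expect_equal(b$cy, 20)
  expect_true(b$filled)

  # grid rows (A,B,C) at y=40 and (.,E,F) at y=420, D missing
  g <- mk_group(c("A", "B", "C", "E", "F"),
                cx = c(50, 250, 450, 250, 450),
                cy = c(40, 40, 40, 420, 420))
  nodes <- fill_label_gaps(g, c(520, 500))
  d <- nodes[nodes$char == "D", ]
  expect_equal(d$cx, 50)   # x of A (its column)
  expect_equal(d$cy, 420)  # y of E (its row)

  # complete group is returned unchanged
  g <- mk_group(c("A", "B"), cx = c(50, 250), cy = c(20, 20))
  nodes <- fill_label_gaps(g, c(400, 100))
  expect_false(any(nodes$filled))
  expect_equal(attr(nodes, "unfillable"), integer(0))
})

test_that("gap at a sequence end extrapolates by neighbor spacing", {
  g <- mk_group(c("A", "B"), cx = c(50, 150), cy = c(20, 20))
  nodes <- fill_label_gaps(g, c(400, 80), n_target = 3)
  c3 <- nodes[nodes$char == "C", ]
  expect_equal(c3$cx, 250)
})

test_that("layout graph links nearest band-sharing neighbors per side", {
  nodes <- data.frame(char = c("A", "B", "C", "D"), position = 1:4,
                      cx = c(10, 210, 10, 210), cy = c(10, 10, 210, 210),
                      x_min = c(5, 205, 5, 205), y_min = c(5, 5, 205, 205),
                      x_max = c(15, 215, 15, 215),
                      y_max = c(15, 15, 215, 215), filled = FALSE)
  gr <- build_layout_graph(nodes)
  expect_equal(nrow(gr$edges), 4L)
  expect_equal(sum(gr$edges$orientation == "horizontal"), 2L)
  expect_equal(sum(gr$edges$orientation == "vertical"), 2L)

  single <- nodes[1, ]
  expect_equal(nrow(build_layout_graph(single)$edges), 0L)

  row3 <- data.frame(char = c("A", "B", "C"), position = 1:3,
                     cx = c(10, 110, 210), cy = 10,
                     x_min = c(5, 105, 205), y_min = 5,
                     x_max = c(15, 115, 215), y_max = 15, filled = FALSE)
  gr <- build_layout_graph(row3)
  expect_equal(nrow(gr$edges), 2L)
  expect_true(all(gr$edges$orientation == "horizontal"))
})

test_that("cut selection: whitespace corridor, uniform tie, empty figure", {
  ni <- list(cx = 45, cy = 50); nj <- list(cx = 155, cy = 50)
  comps <- data.frame(x_min = c(0, 110), y_min = 0, x_max = c(90, 200),
                      y_max = 100)
  comps$area <- (comps$x_max - comps$x_min) * 100
  cut <- compute_cut(ni, nj, "horizontal", comps, c(200, 100))
  expect_equal(cut$orientation, "vertical")
  expect_equal(cut$cost, 0)
  expect_gte(cut$coordinate, 90); expect_lte(cut$coordinate, 110)

  # one component spans the corridor: flat cost, tie -> mid-corridor
  comps2 <- data.frame(x_min = 0, y_min = 0, x_max = 200, y_max = 100,
                       area = 20000)
  cut2 <- compute_cut(ni, nj, "horizontal", comps2, c(200, 100))
  expect_equal(cut2$cost, 200)
  expect_equal(cut2$coordinate, 100)

  # no components: zero cost everywhere, cut at the corridor midpoint
  none <- data.frame(x_min = numeric(0), y_min = numeric(0),
                     x_max = numeric(0), y_max = numeric(0),
                     area = numeric(0))
  cut3 <- compute_cut(ni, nj, "horizontal", none, c(200, 100))
  expect_equal(cut3$cost, 0)
  expect_equal(cut3$coordinate, 100)

  expect_error(compute_cut(list(cx = 50, cy = 10), list(cx = 51, cy = 10),
                           "horizontal", none, c(200, 100)), "closer")
})

test_that("partitioning a clean 2x2 fixture matches ground truth exactly", {
  fx <- clean_fixture(21) # seed 21 in the shape cycle -> multi-panel grid
  res <- run_figure(fx$image, fx$truth$caption, fx$truth$tokens)
  expect_false(res$degraded)
  got <- as.matrix(res$panels[match(fx$truth$labels, res$panels$label),
                              c("x_min", "y_min", "x_max", "y_max")])
  gt <- do.call(rbind, fx$truth$panel_boxes)
  dimnames(got) <- NULL; dimnames(gt) <- NULL
  expect_equal(got, gt)
  # regions partition the figure pixels
  expect_equal(sum(res$panels$n_pixels), length(fx$image))
})

test_that("a single label yields one full-figure panel", {
  nodes <- data.frame(char = "A", position = 1L, cx = 20, cy = 20,
                      x_min = 15, y_min = 15, x_max = 25, y_max = 25,
                      filled = FALSE)
  gr <- build_layout_graph(nodes)
  none <- data.frame(x_min = numeric(0), y_min = numeric(0),
                     x_max = numeric(0), y_max = numeric(0),
                     area = numeric(0))
  part <- partition_figure(c(300, 200), gr, none)
  expect_equal(nrow(part$panels), 1L)
  expect_equal(part$panels$n_pixels, 300 * 200)
  expect_equal(unname(unlist(
    part$panels[, c("x_min", "y_min", "x_max", "y_max")])),
    c(0, 0, 300, 200))
})

test_that("the costlier cut stops at the crossing in ragged layouts", {
  fx <- generate_figure(fixture_spec(ragged = c(1, 2), seed = 21))
  res <- run_figure(fx$image, fx$truth$caption, fx$truth$tokens)
  expect_false(res$degraded)
  expect_equal(res$n_panels, 3L)
  # the top panel must span the full figure width
  top <- res$panels[res$panels$label == "A", ]
  expect_equal(top$x_min, 0)
  expect_equal(top$x_max, ncol(fx$image))
  # each panel region contains its own content
  for (p in 1:3) {
    reg <- res$panels[res$panels$label == fx$truth$labels[[p]], ]
    expect_true(figseg:::bbox_contains(
      bbox(reg$x_min, reg$y_min, reg$x_max, reg$y_max),
      fx$truth$content_boxes[[p]]))
  }
  # pixel partition is exact
  expect_equal(sum(res$panels$n_pixels), length(fx$image))
})

test_that("zero-cost cuts never slice a component box", {
  for (i in c(17, 21, 33)) {
    fx <- clean_fixture(i)
    res <- run_figure(fx$image, fx$truth$caption, fx$truth$tokens)
    comps <- res$intermediates$components
    for (cut in res$intermediates$cuts) {
      if (cut$cost > 0) next
      if (cut$orientation == "vertical") {
        expect_false(any(comps$x_min < cut$coordinate &
                           cut$coordinate < comps$x_max))
      } else {
        expect_false(any(comps$y_min < cut$coordinate &
                           cut$coordinate < comps$y_max))
      }
    }
  }
})

test_that("association joins panels and subcaptions by label", {
  panels <- data.frame(label = c("A", "B"), position = 1:2,
                       x_min = c(0, 50), y_min = 0, x_max = c(50, 100),
                       y_max = 50, n_pixels = 2500, region_id = 1:2)
  subs <- data.frame(label = c("A", "B"), text = c("one", "two"),
                     shared = FALSE)
  a <- associate_panels(panels, subs)
  expect_equal(a$records$subcaption, c("one", "two"))
  expect_length(a$unplaced, 0L)

  a <- associate_panels(panels, subs[1, ])
  expect_true(is.na(a$records$subcaption[2]))
  expect_length(a$unplaced, 0L)

  subs3 <- rbind(subs, data.frame(label = "C", text = "three",
                                  shared = FALSE))
  a <- associate_panels(panels, subs3)
  expect_equal(a$unplaced, "C")

  expect_error(associate_panels(rbind(panels, panels), subs))
})
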