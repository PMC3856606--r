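test_that("triangle threshold: bimodal, collinear tie, mirror symmetry", {
  counts <- integer(256)
  counts[19:23] <- 900  # bins 18-22 (0-based)
  counts[21] <- 1000    # peak at intensity 20
  counts[201] <- 50     # tail at intensity 200
  t <- triangle_threshold(counts)
  expect_gt(t, 22); expect_lt(t, 200)
  expect_equal(t, oracle_triangle(counts))

  # linear ramp from peak to tail: all collinear, tie -> bin nearest tail
  ramp <- integer(256)
  ramp[1:100] <- seq(1000, 10, length.out = 100)
  t <- triangle_threshold(ramp)
  expect_equal(t, oracle_triangle(ramp))
  expect_equal(t, 98) # last interior bin, nearest the tail

  # mirrored histogram gives the mirrored threshold
  counts2 <- rev(counts)
  expect_equal(triangle_threshold(counts2), 255 - triangle_threshold(counts))

  single <- integer(256); single[42] <- 10
  expect_warning(t <- triangle_threshold(single), "degenerate")
  expect_equal(t, 41)
})

test_that("triangle threshold equals the brute-force oracle incl. ties", {
  set.seed(77)
  for (k in 1:300) {
    h <- random_histogram()
    expect_equal(triangle_threshold(h), oracle_triangle(h),
                 info = paste("histogram", k))
  }
})

test_that("binarize keeps the minority side as foreground", {
  img <- matrix(245L, 50, 50); img[10:20, 10:40] <- 10L
  m <- binarize(img, 128)
  expect_true(all(m[10:20, 10:40]))
  expect_equal(sum(m), 11 * 31)

  inv <- 255L - img
  m2 <- binarize(inv, 128)
  expect_identical(m2, m)

  expect_equal(sum(binarize(matrix(7L, 5, 5), 7)), 0)
})

test_that("component extraction: connectivity, area filter, box merging", {
  # two squares touching only diagonally stay separate under 4-connectivity
  m <- matrix(FALSE, 40, 40)
  m[1:10, 1:10] <- TRUE
  m[11:20, 11:20] <- TRUE
  cc <- extract_components(m, min_area = 50)
  expect_equal(nrow(cc), 2L)

  # a 7x7 blob (area 49) is dropped at the default threshold of 50
  m <- matrix(FALSE, 20, 20); m[2:8, 2:8] <- TRUE
  expect_equal(nrow(extract_components(m)), 0L)
  expect_equal(nrow(extract_components(m, min_area = 49)), 1L)

  # disjoint pixels with overlapping boxes merge into one record
  m <- matrix(FALSE, 40, 40)
  m[1:20, 1:8] <- TRUE    # tall bar, box [0,0,8,20]
  m[9:12, 5:30] <- TRUE   # crossing bar; pixels touch -> one cc anyway
  m2 <- matrix(FALSE, 40, 40)
  m2[1:20, 1:8] <- TRUE
  m2[22:30, 3:6] <- TRUE  # below, disjoint, box overlaps in x only
  cc2 <- extract_components(m2, min_area = 10)
  expect_equal(nrow(cc2), 2L) # boxes do not overlap -> stay separate
  m3 <- matrix(FALSE, 40, 40)
  m3[1:20, 1:20] <- TRUE
  m3[1:20, 1:20][cbind(rep(10, 5), 1:5)] <- TRUE
  m3[5:8, 25:30] <- TRUE
  m3[1:30, 22:24] <- TRUE # tall bar whose box overlaps the small blob's rows
  cc3 <- extract_components(m3, min_area = 10)
  boxes <- lapply(seq_len(nrow(cc3)), function(i)
    bbox(cc3$x_min[i], cc3$y_min[i], cc3$x_max[i], cc3$y_max[i]))
  if (length(boxes) > 1) {
    for (i in seq_along(boxes)) for (j in seq_along(boxes)) {
      if (i < j) expect_false(bbox_overlaps(boxes[[i]], boxes[[j]]))
    }
  }

  # text boxes are cleared before labeling
  m4 <- matrix(FALSE, 30, 30); m4[5:25, 5:25] <- TRUE
  cc4 <- extract_components(m4, text_boxes = list(bbox(0, 0, 30, 30)))
  expect_equal(nrow(cc4), 0L)
  expect_equal(nrow(extract_components(matrix(FALSE, 5, 5))), 0L)
})

test_that("4-connected labeling equals the flood-fill oracle", {
  set.seed(99)
  for (k in 1:60) {
    m <- matrix(runif(32 * 32) < 0.45, 32, 32)
    lab <- figseg:::.cc_label_4(m)
    oracle <- oracle_flood_label(m)
    expect_equal(max(lab), max(oracle))
    expect_identical(partition_representatives(lab),
                     partition_representatives(oracle))
    # pre-merge area bookkeeping: labeled pixels = foreground pixels
    expect_equal(sum(lab > 0), sum(m))
  }
})

test_that("component areas sum to surviving foreground pixels", {
  set.seed(3)
  m <- matrix(runif(64 * 64) < 0.35, 64, 64)
  lab <- figseg:::.cc_label_4(m)
  areas <- tabulate(lab[lab > 0])
  keep <- areas[areas >= 20]
  cc <- extract_components(m, min_area = 20)
  expect_equal(sum(cc$area), sum(keep))
})

test_that("gray conversion accepts RGB arrays and 0-1 matrices", {
  arr <- array(0, dim = c(4, 4, 3))
  arr[, , 1] <- 255
  g <- as_gray(arr)
  expect_equal(g[1, 1], as.integer(round(0.299 * 255)))
  gm <- as_gray(matrix(0.5, 3, 3))
  expect_equal(gm[1, 1], 128L)
})
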