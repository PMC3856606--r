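# Pixel-level preprocessing: grayscale conversion, intensity histogram,
# triangle-method thresholding, binarization, and extraction of merged
# 4-connected component bounding boxes with OCR text regions removed.

#' Convert an image to 8-bit grayscale
#'
#' Accepts an integer/numeric matrix (already gray, values 0-255) or a
#' `H x W x 3` array (RGB in 0-255 or 0-1), converted with ITU-R BT.601
#' luminance weights.
#'
#' @param img matrix or 3-band array.
#' @return integer matrix with values in `[0, 255]` (rows = y, cols = x).
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) {
    m <- img
    if (max(m) <= 1 && min(m) >= 0 && !all(m == floor(m)))
      m <- m * 255
    return(matrix(as.integer(pmin(255, pmax(0, round(m)))), nrow(m), ncol(m)))
  }
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    m <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    if (max(img) <= 1) m <- m * 255
    return(matrix(as.integer(pmin(255, pmax(0, round(m)))), dim(img)[1],
                  dim(img)[2]))
  }
  stop("unsupported image shape")
}

#' 256-bin intensity histogram
#' @param img grayscale integer matrix (values 0-255).
#' @return integer vector of 256 counts (bin i holds intensity i-1).
#' @export
intensity_histogram <- function(img) {
  stopifnot(is.matrix(img))
  v <- as.integer(img)
  stopifnot(all(v >= 0L & v <= 255L))
  tabulate(v + 1L, nbins = 256L)
}

#' Triangle-method threshold of an intensity histogram
#'
#' A line is drawn from the histogram peak (bin of maximum count) to the
#' farthest non-zero tail bin; the threshold is the bin between them whose
#' count lies at maximum perpendicular distance below that line. Ties go to
#' the bin nearest the tail. Classic shape-based thresholding for images
#' whose histogram has one dominant background mode.
#'
#' @param counts integer vector of 256 bin counts.
#' @return integer threshold intensity in `[0, 255]`.
#' @export
triangle_threshold <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  nz <- which(counts > 0L)
  if (length(nz) == 0L) stop("empty histogram")
  if (length(nz) == 1L) {
    warning("degenerate histogram: single non-zero bin")
    return(nz[[1]] - 1L)
  }
  peak <- which.max(counts)
  lo <- min(nz); hi <- max(nz)
  # tail = non-zero extreme farther from the peak; tie to the high side
  tail_bin <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (tail_bin == peak) tail_bin <- if (peak == hi) lo else hi
  bins <- if (tail_bin > peak) seq(peak + 1L, tail_bin - 1L)
          else seq(tail_bin + 1L, peak - 1L)
  if (length(bins) == 0L) return(tail_bin - 1L)
  x1 <- peak; y1 <- counts[peak]
  x2 <- tail_bin; y2 <- counts[tail_bin]
  # perpendicular distance of (b, counts[b]) to the peak-tail line
  num <- abs((y2 - y1) * (bins - x1) - (x2 - x1) * (counts[bins] - y1))
  d <- num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  best <- max(d)
  cand <- bins[d >= best - 1e-12]
  pick <- cand[which.min(abs(cand - tail_bin))]
  as.integer(pick - 1L)
}

#' Binarize a grayscale image at a threshold
#'
#' Pixels are split at `t` (`<= t` vs `> t`); the foreground is the minority
#' side, which makes objects foreground for both dark-ink-on-light and
#' inverted panels. An exact tie takes the dark side as foreground.
#'
#' @param img grayscale integer matrix.
#' @param t threshold in `[0, 255]`.
#' @return logical matrix, TRUE = foreground.
#' @export
binarize <- function(img, t) {
  stopifnot(is.matrix(img), t >= 0, t <= 255)
  le <- img <= t
  n_le <- sum(le)
  n_gt <- length(img) - n_le
  if (n_le <= n_gt) le else !le
}

#' Extract merged connected components from a binary mask
#'
#' Pixels inside `text_boxes` (OCR-detected text, optionally padded) are
#' cleared first; remaining foreground is labeled with 4-connectivity;
#' components smaller than `min_area` pixels are dropped; finally, bounding
#' boxes that overlap are merged transitively (union box, summed area) until
#' no two boxes overlap.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param text_boxes list of [bbox()] in the same pixel frame (may be empty).
#' @param min_area minimum component area in pixels (default 50).
#' @param pad padding in pixels applied around each text box before clearing.
#' @return data.frame: `id`, `area`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
extract_components <- function(mask, text_boxes = list(), min_area = 50L,
                               pad = 0L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  H <- nrow(mask); W <- ncol(mask)
  for (tb in text_boxes) {
    validate_bbox(tb)
    x0 <- max(0L, floor(tb[[1]] - pad)); y0 <- max(0L, floor(tb[[2]] - pad))
    x1 <- min(W, ceiling(tb[[3]] + pad)); y1 <- min(H, ceiling(tb[[4]] + pad))
    if (x1 > x0 && y1 > y0)
      mask[(y0 + 1L):y1, (x0 + 1L):x1] <- FALSE
  }
  empty <- data.frame(id = integer(0), area = numeric(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0))
  if (!any(mask)) return(empty)
  lab <- .cc_label_4(mask)
  k <- max(lab)
  fg <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  areas <- tabulate(ids, nbins = k)
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(empty)
  f <- factor(ids, levels = keep)
  ok <- !is.na(f)
  ymin <- tapply(fg[ok, 1], f[ok], min); ymax <- tapply(fg[ok, 1], f[ok], max)
  xmin <- tapply(fg[ok, 2], f[ok], min); xmax <- tapply(fg[ok, 2], f[ok], max)
  comps <- lapply(seq_along(keep), function(i) {
    list(area = areas[[keep[[i]]]],
         box = bbox(xmin[[i]] - 1L, ymin[[i]] - 1L, xmax[[i]], ymax[[i]]))
  })
  comps <- merge_overlapping_boxes(comps)
  out <- data.frame(
    id = seq_along(comps),
    area = vapply(comps, `[[`, 1, "area"),
    x_min = vapply(comps, function(c) c$box[[1]], 1),
    y_min = vapply(comps, function(c) c$box[[2]], 1),
    x_max = vapply(comps, function(c) c$box[[3]], 1),
    y_max = vapply(comps, function(c) c$box[[4]], 1)
  )
  out
}

# Merge overlapping component boxes to a fixed point (transitive closure).
merge_overlapping_boxes <- function(comps) {
  repeat {
    n <- length(comps)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (j <= i) next
        if (bbox_overlaps(comps[[i]]$box, comps[[j]]$box)) {
          comps[[i]] <- list(area = comps[[i]]$area + comps[[j]]$area,
                             box = bbox_union(comps[[i]]$box, comps[[j]]$box))
          comps[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) return(comps)
  }
}

#' Preprocess a figure image end to end
#'
#' Gray conversion, histogram, triangle threshold, binarization, text
#' removal, component extraction.
#'
#' @param img image (matrix or RGB array).
#' @param text_boxes OCR token boxes to clear.
#' @param min_area component area threshold (default 50).
#' @param pad text box padding (default 0).
#' @return list with `gray`, `threshold`, `mask`, `components`.
#' @export
preprocess_figure <- function(img, text_boxes = list(), min_area = 50L,
                              pad = 0L) {
  gray <- as_gray(img)
  h <- intensity_histogram(gray)
  t <- if (sum(h > 0L) < 2L) {
    suppressWarnings(triangle_threshold(h))
  } else triangle_threshold(h)
  mask <- binarize(gray, t)
  comps <- extract_components(mask, text_boxes, min_area = min_area,
                              pad = pad)
  list(gray = gray, threshold = t, mask = mask, components = comps)
}
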