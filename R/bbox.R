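# Axis-aligned pixel rectangles: the geometry carrier for figures, captions,
# OCR tokens, connected components and panels.
#
# Convention (used everywhere in the package): origin at the top-left of the
# image/page, x grows rightward, y grows downward, and intervals are
# half-open: a box covers pixel columns [x_min, x_max) and rows
# [y_min, y_max). Serialized as [x_min, y_min, x_max, y_max].

#' Construct an axis-aligned bounding box
#'
#' @param x_min,y_min,x_max,y_max box edges in pixels; half-open
#'   `[x_min, x_max) x [y_min, y_max)`, origin top-left, y downward.
#' @return numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @export
#' @examples
#' bbox(0, 0, 10, 10)
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  if (!is.numeric(b) || length(b) != 4L || anyNA(b))
    stop("bbox must be a numeric vector [x_min, y_min, x_max, y_max]")
  if (b[[1]] >= b[[3]] || b[[2]] >= b[[4]])
    stop("invalid bbox: need x_min < x_max and y_min < y_max, got [",
         paste(b, collapse = ", "), "]")
  invisible(b)
}

#' Box area in pixels
#' @param b a [bbox()].
#' @return numeric area, `> 0` for a valid box.
#' @export
bbox_area <- function(b) {
  validate_bbox(b)
  (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])
}

#' Box center
#' @param b a [bbox()].
#' @return numeric `c(x, y)` of the box center.
#' @export
bbox_center <- function(b) {
  validate_bbox(b)
  c(x = (b[[1]] + b[[3]]) / 2, y = (b[[2]] + b[[4]]) / 2)
}

#' Minimum Euclidean distance between two boxes
#'
#' Distance between the closed rectangles: 0 when they overlap or touch,
#' otherwise the length of the shortest segment joining their boundaries.
#'
#' @param a,b boxes from [bbox()].
#' @return non-negative distance in pixels.
#' @export
#' @examples
#' bbox_min_distance(bbox(0, 0, 10, 10), bbox(20, 0, 30, 10)) # 10
#' bbox_min_distance(bbox(0, 0, 10, 10), bbox(13, 14, 20, 20)) # 5 (3-4-5)
bbox_min_distance <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  dx <- max(a[[1]] - b[[3]], b[[1]] - a[[3]], 0)
  dy <- max(a[[2]] - b[[4]], b[[2]] - a[[4]], 0)
  sqrt(dx * dx + dy * dy)
}

#' Do two boxes overlap?
#'
#' Intersection of the half-open pixel sets; boxes that merely share an edge
#' (e.g. `x_max` of one equals `x_min` of the other) do not overlap.
#'
#' @param a,b boxes from [bbox()].
#' @return logical.
#' @export
bbox_overlaps <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  a[[1]] < b[[3]] && b[[1]] < a[[3]] && a[[2]] < b[[4]] && b[[2]] < a[[4]]
}

#' Smallest box containing two boxes
#' @param a,b boxes from [bbox()].
#' @return a [bbox()]; the operation is associative, commutative and
#'   idempotent.
#' @export
bbox_union <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  bbox(min(a[[1]], b[[1]]), min(a[[2]], b[[2]]),
       max(a[[3]], b[[3]]), max(a[[4]], b[[4]]))
}

# Union over a list of boxes.
bbox_union_all <- function(boxes) {
  Reduce(bbox_union, boxes)
}

# TRUE when box `inner` lies entirely inside `outer` (half-open containment).
bbox_contains <- function(outer, inner) {
  validate_bbox(outer); validate_bbox(inner)
  inner[[1]] >= outer[[1]] && inner[[2]] >= outer[[2]] &&
    inner[[3]] <= outer[[3]] && inner[[4]] <= outer[[4]]
}

# Does box contain the point (x, y)? Half-open.
bbox_contains_point <- function(b, x, y) {
  x >= b[[1]] && x < b[[3]] && y >= b[[2]] && y < b[[4]]
}

# data.frame <-> list-of-bbox plumbing used by several modules.
boxes_to_df <- function(boxes) {
  if (length(boxes) == 0L)
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0)))
  m <- do.call(rbind, boxes)
  data.frame(x_min = m[, 1], y_min = m[, 2], x_max = m[, 3], y_max = m[, 4])
}

df_to_boxes <- function(df) {
  lapply(seq_len(nrow(df)),
         function(i) bbox(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i]))
}
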