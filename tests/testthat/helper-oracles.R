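# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the code paths they check.

# Brute-force min distance between two boxes: minimize pairwise distance
# over boundary points sampled on a fine grid. With integer box corners the
# true closest points lie on the grid, so agreement is exact.
oracle_bbox_min_distance <- function(a, b, step = 0.25) {
  pts <- function(bb) {
    xs <- seq(bb[[1]], bb[[3]], by = step)
    ys <- seq(bb[[2]], bb[[4]], by = step)
    rbind(cbind(xs, bb[[2]]), cbind(xs, bb[[4]]),
          cbind(bb[[1]], ys), cbind(bb[[3]], ys))
  }
  pa <- pts(a); pb <- pts(b)
  # overlap: distance zero by definition of closed rectangles
  if (a[[1]] <= b[[3]] && b[[1]] <= a[[3]] &&
      a[[2]] <= b[[4]] && b[[2]] <= a[[4]]) return(0)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(min(d2))
}

# Recursive/stack flood-fill 4-connected labeling in pure R.
oracle_flood_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  stack <- integer(H * W)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nxt
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      y <- (p - 1L) %% H + 1L
      x <- (p - 1L) %/% H + 1L
      for (q in c(if (y > 1L) p - 1L, if (y < H) p + 1L,
                  if (x > 1L) p - H, if (x < W) p + H)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  lab
}

# Canonical representative per component: the smallest linear pixel index of
# the component each foreground pixel belongs to. Two labelings induce the
# same partition iff their representatives agree pixelwise.
partition_representatives <- function(lab) {
  idx <- which(lab > 0L)
  ave(idx, lab[idx], FUN = min)
}

# Triangle-threshold oracle: per-bin perpendicular distance computed by
# rotating into the line frame (independent arithmetic from the
# cross-product form), same peak/tail and tie conventions.
oracle_triangle <- function(counts) {
  nz <- which(counts > 0L)
  if (length(nz) == 1L) return(nz[[1]] - 1L)
  peak <- which.max(counts)
  lo <- min(nz); hi <- max(nz)
  tail_bin <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (tail_bin == peak) tail_bin <- if (peak == hi) lo else hi
  bins <- if (tail_bin > peak) seq(peak + 1L, tail_bin - 1L)
          else seq(tail_bin + 1L, peak - 1L)
  if (length(bins) == 0L) return(tail_bin - 1L)
  theta <- atan2(counts[tail_bin] - counts[peak], tail_bin - peak)
  d <- abs(-sin(theta) * (bins - peak) +
             cos(theta) * (counts[bins] - counts[peak]))
  best <- max(d)
  cand <- bins[d >= best - 1e-12]
  cand[which.min(abs(cand - tail_bin))] - 1L
}

random_histogram <- function() {
  counts <- integer(256)
  k <- sample(2:40, 1)
  bins <- sample(1:256, k)
  counts[bins] <- sample(1:1000, k, replace = TRUE)
  counts
}

# Exhaustive longest-strictly-increasing-subsequence oracle (n <= 10),
# earliest index set among maximal-length ones.
oracle_lis <- function(pos) {
  n <- length(pos)
  best <- integer(0)
  for (m in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(idx) >= 2L && any(diff(pos[idx]) <= 0)) next
    if (length(idx) > length(best)) {
      best <- idx
    } else if (length(idx) == length(best) && length(idx) > 0L) {
      cmp <- idx - best
      f <- which(cmp != 0)[1]
      if (!is.na(f) && cmp[f] < 0) best <- idx # earliest index set wins
    }
  }
  best
}

# Standard grid of fixture shapes used by corpus-style tests.
shape_for <- function(i) {
  shapes <- expand.grid(rows = 1:4, cols = 1:4)
  shapes[(i %% 16L) + 1L, ]
}

clean_fixture <- function(i) {
  sh <- shape_for(i)
  alpha <- c("latin", "roman", "arabic")[(i %% 3L) + 1L]
  if (alpha == "roman" && sh$rows * sh$cols > 12L) alpha <- "latin"
  spec <- fixture_spec(
    rows = sh$rows, cols = sh$cols, label_alphabet = alpha,
    label_category = c("closed", "right_closed", "simple")[(i %% 3L) + 1L],
    caption_style = if (sh$rows * sh$cols >= 2L)
      c("per_label", "range")[(i %% 2L) + 1L] else "per_label",
    seed = i
  )
  generate_figure(spec)
}
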