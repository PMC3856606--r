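# Panel segmentation: reconcile the three panel-count estimates, complete
# gapped label sequences geometrically, build the layout graph over label
# positions, cut the figure along minimum-cost lines perpendicular to graph
# edges, and pair the resulting regions with subcaptions.

#' Estimate the number of panels in a figure
#'
#' The subcaption count is the most trusted source: when it agrees with the
#' in-image label count the consensus value is used. Otherwise, when the
#' connected-component count matches exactly one of the two, that one wins
#' (`cc_arbitrated`). Failing both, the trained decision tree predicts the
#' count (`model`), floored at 1. All counts zero means a single-panel
#' figure.
#'
#' @param ev list or one-row data.frame with `n_subcaptions`, `n_labels`,
#'   `n_cc`, `gaps`.
#' @param model a `figseg_count_model` (required only on the model path).
#' @return list with `n` (integer `>= 1`) and `decision` (one of
#'   `consensus`, `cc_arbitrated`, `model`, `default_single`).
#' @export
estimate_panel_count <- function(ev, model = NULL) {
  ns <- as.integer(ev$n_subcaptions); nl <- as.integer(ev$n_labels)
  ncc <- as.integer(ev$n_cc); gaps <- as.integer(ev$gaps)
  stopifnot(ns >= 0L, nl >= 0L, ncc >= 0L, gaps >= 0L)
  if (ns == 0L && nl == 0L && ncc == 0L)
    return(list(n = 1L, decision = "default_single"))
  if (ns == nl && ns > 0L)
    return(list(n = ns, decision = "consensus"))
  cc_hits <- unique(c(ns, nl)[c(ns, nl) == ncc & c(ns, nl) > 0L])
  if (length(cc_hits) == 1L)
    return(list(n = cc_hits, decision = "cc_arbitrated"))
  if (is.null(model))
    return(list(n = max(1L, ns, nl), decision = "no_model_fallback"))
  n <- predict(model, data.frame(n_subcaptions = ns, n_labels = nl,
                                 n_cc = ncc, gaps = gaps))
  list(n = max(1L, n), decision = "model")
}

# Cluster 1-D coordinates into bands; returns integer cluster index per
# value, clusters ordered by coordinate.
.cluster_1d <- function(v, tol) {
  ord <- order(v)
  cl <- integer(length(v))
  cur <- 1L
  cl[ord[1]] <- 1L
  for (k in seq_along(ord)[-1]) {
    if (v[ord[k]] - v[ord[k - 1L]] > tol) cur <- cur + 1L
    cl[ord[k]] <- cur
  }
  cl
}

#' Fill gaps in a panel-label sequence geometrically
#'
#' The figure is discretized into blocks from the detected label positions.
#' In a single row or column, a missing label is placed at the midpoint of
#' its sequence-adjacent neighbors (extrapolated by the neighbor spacing at
#' sequence ends). In a 2-D grid the missing label's row comes from its own
#' row band and its column from the aligned labels of the other rows,
#' provided the estimated block is empty.
#'
#' @param group selected label group from [score_and_select()].
#' @param figure_size `c(width, height)` in pixels.
#' @param n_target total panel count to complete to (default the group's
#'   `Panels`).
#' @return data.frame of nodes: `char`, `position`, `cx`, `cy`, bbox
#'   columns, `filled`; attribute `"unfillable"` lists positions that could
#'   not be placed.
#' @export
fill_label_gaps <- function(group, figure_size, n_target = NULL) {
  stopifnot(!is.null(group))
  m <- group$members
  n_target <- as.integer(n_target %||% group$Panels)
  W <- figure_size[[1]]; H <- figure_size[[2]]
  nodes <- data.frame(
    char = m$char, position = m$position,
    cx = (m$x_min + m$x_max) / 2, cy = (m$y_min + m$y_max) / 2,
    x_min = m$x_min, y_min = m$y_min, x_max = m$x_max, y_max = m$y_max,
    filled = FALSE
  )
  nodes <- nodes[nodes$position <= n_target, , drop = FALSE]
  missing <- setdiff(seq_len(n_target), nodes$position)
  if (length(missing) == 0L) {
    rownames(nodes) <- NULL
    attr(nodes, "unfillable") <- integer(0)
    return(nodes)
  }
  if (nrow(nodes) == 0L) {
    attr(nodes, "unfillable") <- missing
    return(nodes)
  }
  bw <- median(nodes$x_max - nodes$x_min)
  bh <- median(nodes$y_max - nodes$y_min)
  row_cl <- .cluster_1d(nodes$cy, max(6, 1.5 * bh))
  col_cl <- .cluster_1d(nodes$cx, max(6, 1.5 * bw))
  n_rows <- max(row_cl); n_cols <- max(col_cl)
  unfillable <- integer(0)
  add_node <- function(pos, cx, cy) {
    alpha <- group$alphabet
    data.frame(char = label_from_position(pos, alpha), position = pos,
               cx = cx, cy = cy, x_min = cx - bw / 2, y_min = cy - bh / 2,
               x_max = cx + bw / 2, y_max = cy + bh / 2, filled = TRUE)
  }
  # grid-consistency check against row-major / column-major reading order
  grid_mode <- NULL
  if (n_rows > 1L && n_cols > 1L) {
    rm_ok <- all((nodes$position - 1L) %/% n_cols + 1L == row_cl &
                   (nodes$position - 1L) %% n_cols + 1L == col_cl)
    cm_ok <- all((nodes$position - 1L) %% n_rows + 1L == row_cl &
                   (nodes$position - 1L) %/% n_rows + 1L == col_cl)
    if (rm_ok) grid_mode <- "row_major" else if (cm_ok) grid_mode <- "col_major"
  }
  axis_centers <- function(cl, v) {
    vapply(seq_len(max(cl)), function(k) mean(v[cl == k]), 1)
  }
  if (!is.null(grid_mode)) {
    rc <- axis_centers(row_cl, nodes$cy)
    cc <- axis_centers(col_cl, nodes$cx)
    for (p in missing) {
      r <- if (grid_mode == "row_major") (p - 1L) %/% n_cols + 1L
      else (p - 1L) %% n_rows + 1L
      cidx <- if (grid_mode == "row_major") (p - 1L) %% n_cols + 1L
      else (p - 1L) %/% n_rows + 1L
      if (r > n_rows || cidx > n_cols) {
        unfillable <- c(unfillable, p)
        next
      }
      occupied <- any(row_cl == r & col_cl == cidx &
                        nodes$position != p & !nodes$filled)
      if (occupied) {
        unfillable <- c(unfillable, p)
        next
      }
      nodes <- rbind(nodes, add_node(p, cc[[cidx]], rc[[r]]))
    }
  } else {
    # single row / single column (or degenerate): 1-D fill along the axis
    # with more spread; with one detected label, the longer figure side.
    horiz <- if (nrow(nodes) >= 2L) {
      diff(range(nodes$cx)) >= diff(range(nodes$cy))
    } else W >= H
    coord <- if (horiz) nodes$cx else nodes$cy
    cross <- if (horiz) median(nodes$cy) else median(nodes$cx)
    extent <- if (horiz) W else H
    det <- nodes[order(nodes$position), , drop = FALSE]
    dpos <- det$position
    dcoord <- if (horiz) det$cx else det$cy
    spacing <- if (length(dpos) >= 2L) {
      median(diff(dcoord) / diff(dpos))
    } else extent / n_target
    for (p in missing) {
      prev <- which(dpos < p)
      nxt <- which(dpos > p)
      c_est <- if (length(prev) && length(nxt)) {
        i <- max(prev); j <- min(nxt)
        dcoord[i] + (dcoord[j] - dcoord[i]) * (p - dpos[i]) / (dpos[j] - dpos[i])
      } else if (length(prev)) {
        dcoord[max(prev)] + spacing * (p - dpos[max(prev)])
      } else if (length(nxt)) {
        dcoord[min(nxt)] - spacing * (dpos[min(nxt)] - p)
      } else NA_real_
      if (is.na(c_est) || c_est < 0 || c_est > extent) {
        unfillable <- c(unfillable, p)
        next
      }
      if (horiz) nodes <- rbind(nodes, add_node(p, c_est, cross))
      else nodes <- rbind(nodes, add_node(p, cross, c_est))
    }
  }
  nodes <- nodes[order(nodes$position), , drop = FALSE]
  rownames(nodes) <- NULL
  attr(nodes, "unfillable") <- unfillable
  nodes
}

#' Build the layout graph over panel-label nodes
#'
#' Each node is linked to its nearest neighbor among nodes sharing its row
#' band (horizontal edge) and among nodes sharing its column band (vertical
#' edge); duplicate edges collapse. A single node yields no edges.
#'
#' @param nodes data.frame from [fill_label_gaps()] (or with the same
#'   columns).
#' @return list `nodes`, `edges` (data.frame `i`, `j`, `orientation`).
#' @export
build_layout_graph <- function(nodes) {
  stopifnot(nrow(nodes) >= 1L)
  edges <- data.frame(i = integer(0), j = integer(0),
                      orientation = character(0))
  n <- nrow(nodes)
  if (n > 1L) {
    seen <- character(0)
    band_overlap <- function(a0, a1, b0, b1) a0 < b1 && b0 < a1
    for (i in seq_len(n)) {
      # closest band-sharing neighbor on each side of the node
      best <- list(h_neg = NA_integer_, h_pos = NA_integer_,
                   v_neg = NA_integer_, v_pos = NA_integer_)
      dist <- list(h_neg = Inf, h_pos = Inf, v_neg = Inf, v_pos = Inf)
      for (j in seq_len(n)) {
        if (i == j) next
        if (band_overlap(nodes$y_min[i], nodes$y_max[i],
                         nodes$y_min[j], nodes$y_max[j])) {
          dx <- nodes$cx[j] - nodes$cx[i]
          slot <- if (dx < 0) "h_neg" else "h_pos"
          if (abs(dx) < dist[[slot]] - 1e-9) {
            dist[[slot]] <- abs(dx); best[[slot]] <- j
          }
        }
        if (band_overlap(nodes$x_min[i], nodes$x_max[i],
                         nodes$x_min[j], nodes$x_max[j])) {
          dy <- nodes$cy[j] - nodes$cy[i]
          slot <- if (dy < 0) "v_neg" else "v_pos"
          if (abs(dy) < dist[[slot]] - 1e-9) {
            dist[[slot]] <- abs(dy); best[[slot]] <- j
          }
        }
      }
      for (slot in names(best)) {
        j <- best[[slot]]
        if (is.na(j)) next
        o <- if (startsWith(slot, "h")) "horizontal" else "vertical"
        key <- paste(min(i, j), max(i, j), o)
        if (key %in% seen) next
        seen <- c(seen, key)
        edges <- rbind(edges, data.frame(i = min(i, j), j = max(i, j),
                                         orientation = o))
      }
    }
  }
  list(nodes = nodes, edges = edges)
}

#' Minimum-cost cut line for one layout-graph edge
#'
#' A horizontal edge induces a vertical cut and vice versa. For every
#' integer coordinate strictly between the two node anchors along the edge
#' axis, the cut cost is the summed extent (along the edge axis) of the
#' connected components the full-span perpendicular line would slice. The
#' minimum-cost coordinate wins; ties go to the candidate closest to the
#' corridor midpoint, then the smaller coordinate.
#'
#' @param node_i,node_j rows of the node data.frame (edge endpoints).
#' @param orientation edge orientation, `"horizontal"` or `"vertical"`.
#' @param components component data.frame from [extract_components()].
#' @param figure_size `c(width, height)`.
#' @return list: `orientation` (of the cut line), `coordinate`, `cost`,
#'   `lo`, `hi` (span along the cut axis), `anchor` (edge midpoint along the
#'   cut axis, used by the crossing rule).
#' @export
compute_cut <- function(node_i, node_j, orientation, components, figure_size) {
  W <- figure_size[[1]]; H <- figure_size[[2]]
  if (orientation == "horizontal") {
    a1 <- min(node_i$cx, node_j$cx); a2 <- max(node_i$cx, node_j$cx)
    lohi <- c(0L, H)
    anchor <- (node_i$cy + node_j$cy) / 2
    c0 <- components$x_min; c1 <- components$x_max
    ext <- components$x_max - components$x_min
    cut_orient <- "vertical"
  } else {
    a1 <- min(node_i$cy, node_j$cy); a2 <- max(node_i$cy, node_j$cy)
    lohi <- c(0L, W)
    anchor <- (node_i$cx + node_j$cx) / 2
    c0 <- components$y_min; c1 <- components$y_max
    ext <- components$y_max - components$y_min
    cut_orient <- "horizontal"
  }
  if (a2 - a1 < 2) stop("label anchors closer than 2 px; cannot cut")
  cand <- seq.int(floor(a1) + 1L, ceiling(a2) - 1L)
  cand <- cand[cand > a1 & cand < a2]
  if (length(cand) == 0L) stop("no cut candidates between anchors")
  cost <- vapply(cand, function(x) sum(ext[c0 < x & x < c1]), 1)
  mid <- (a1 + a2) / 2
  best <- min(cost)
  tied <- cand[cost <= best + 1e-9]
  pick <- tied[order(abs(tied - mid), tied)][[1]]
  list(orientation = cut_orient, coordinate = as.integer(pick), cost = best,
       lo = lohi[[1]], hi = lohi[[2]], anchor = anchor)
}

# Apply the crossing rule: where a horizontal and a vertical cut cross, the
# higher-cost cut stops at the crossing, keeping the side that contains its
# originating edge (its anchor). Equal-cost crossings coexist (clean grids).
.resolve_crossings <- function(cuts) {
  if (length(cuts) < 2L) return(cuts)
  vidx <- which(vapply(cuts, function(c) c$orientation == "vertical", TRUE))
  hidx <- which(vapply(cuts, function(c) c$orientation == "horizontal", TRUE))
  processed <- character(0)
  repeat {
    changed <- FALSE
    for (vi in vidx) for (hi in hidx) {
      key <- paste(vi, hi)
      if (key %in% processed) next
      v <- cuts[[vi]]; h <- cuts[[hi]]
      crossing <- v$coordinate >= h$lo && v$coordinate < h$hi &&
        h$coordinate >= v$lo && h$coordinate < v$hi
      if (!crossing) next
      if (abs(v$cost - h$cost) <= 1e-9) next
      processed <- c(processed, key)
      if (v$cost > h$cost) {
        if (v$anchor >= h$coordinate) v$lo <- h$coordinate
        else v$hi <- h$coordinate
        cuts[[vi]] <- v
      } else {
        if (h$anchor >= v$coordinate) h$lo <- v$coordinate
        else h$hi <- v$coordinate
        cuts[[hi]] <- h
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  cuts
}

#' Partition the figure into panel regions
#'
#' Computes one cut per layout-graph edge, resolves crossings (the
#' higher-cost cut stops at the intersection), rasterizes the surviving cut
#' segments as walls and labels the enclosed faces so that every pixel
#' belongs to exactly one region. Each face must contain exactly one label
#' node; otherwise the partition degrades to nearest-anchor blocks.
#'
#' @param figure_size `c(width, height)`.
#' @param graph from [build_layout_graph()].
#' @param components component data.frame.
#' @return list: `panels` data.frame (`label`, `position`, bbox columns,
#'   `n_pixels`, `region_id`), `region_map` (integer matrix H x W),
#'   `cuts`, `degraded` (logical).
#' @export
partition_figure <- function(figure_size, graph, components) {
  W <- as.integer(figure_size[[1]]); H <- as.integer(figure_size[[2]])
  nodes <- graph$nodes
  stopifnot(nrow(nodes) >= 1L)
  cuts <- list()
  if (nrow(graph$edges) > 0L) {
    for (e in seq_len(nrow(graph$edges))) {
      cut <- compute_cut(nodes[graph$edges$i[e], ], nodes[graph$edges$j[e], ],
                         graph$edges$orientation[e], components,
                         c(W, H))
      cuts[[length(cuts) + 1L]] <- cut
    }
    # collapse duplicate cuts (same orientation and coordinate)
    key <- vapply(cuts, function(c) paste(c$orientation, c$coordinate), "")
    cuts <- cuts[!duplicated(key)]
    cuts <- .resolve_crossings(cuts)
  }
  vw <- do.call(rbind, lapply(cuts, function(c)
    if (c$orientation == "vertical") c(c$coordinate, c$lo, c$hi) else NULL))
  hw <- do.call(rbind, lapply(cuts, function(c)
    if (c$orientation == "horizontal") c(c$coordinate, c$lo, c$hi) else NULL))
  if (is.null(vw)) vw <- matrix(0L, 0, 3)
  if (is.null(hw)) hw <- matrix(0L, 0, 3)
  region_map <- .region_label_walls(H, W, vw, hw)
  nfaces <- max(region_map)
  node_region <- vapply(seq_len(nrow(nodes)), function(k) {
    x <- min(W - 1L, max(0L, as.integer(floor(nodes$cx[k]))))
    y <- min(H - 1L, max(0L, as.integer(floor(nodes$cy[k]))))
    region_map[y + 1L, x + 1L]
  }, 1L)
  degraded <- nfaces != nrow(nodes) || anyDuplicated(node_region) > 0L
  if (degraded) {
    # nearest-anchor fallback blocks
    d2 <- array(Inf, dim = c(H, W))
    assign <- matrix(0L, H, W)
    xs <- matrix(rep(0:(W - 1L), each = H), H, W)
    ys <- matrix(rep(0:(H - 1L), W), H, W)
    for (k in seq_len(nrow(nodes))) {
      dk <- (xs - nodes$cx[k])^2 + (ys - nodes$cy[k])^2
      upd <- dk < d2
      assign[upd] <- k
      d2[upd] <- dk[upd]
    }
    region_map <- assign
    node_region <- seq_len(nrow(nodes))
  }
  panels <- lapply(seq_len(nrow(nodes)), function(k) {
    rid <- node_region[[k]]
    idx <- which(region_map == rid, arr.ind = TRUE)
    data.frame(label = nodes$char[k], position = nodes$position[k],
               x_min = min(idx[, 2]) - 1L, y_min = min(idx[, 1]) - 1L,
               x_max = max(idx[, 2]), y_max = max(idx[, 1]),
               n_pixels = nrow(idx), region_id = rid)
  })
  panels <- do.call(rbind, panels)
  rownames(panels) <- NULL
  list(panels = panels, region_map = region_map, cuts = cuts,
       degraded = degraded)
}

#' Pair panels with subcaptions by label
#'
#' @param panels panel data.frame from [partition_figure()].
#' @param subcaptions data.frame `label`/`text`/`shared` from
#'   [split_subcaptions()].
#' @return list: `records` (panels with `subcaption` and `shared` columns;
#'   NA when a panel has no subcaption) and `unplaced` (subcaption labels
#'   with no panel).
#' @export
associate_panels <- function(panels, subcaptions) {
  stopifnot(anyDuplicated(panels$label) == 0L,
            anyDuplicated(subcaptions$label) == 0L)
  idx <- match(panels$label, subcaptions$label)
  panels$subcaption <- ifelse(is.na(idx), NA_character_,
                              subcaptions$text[idx])
  panels$shared <- ifelse(is.na(idx), NA, subcaptions$shared[idx])
  unplaced <- setdiff(subcaptions$label[subcaptions$label != "∅"],
                      panels$label)
  list(records = panels, unplaced = unplaced)
}
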