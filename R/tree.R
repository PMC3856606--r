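# Minimal deterministic CART classifier. Used as the fallback panel-count
# model (C4.5-style decision tree in the original method; the environment
# carries no tree package, and four small integer features need nothing
# heavier). Splits minimize weighted Gini impurity; ties break on the
# earlier feature then the smaller threshold, so training is reproducible.

gini_impurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

.majority <- function(y) {
  tb <- table(y)
  as.integer(names(tb)[which.max(tb)])
}

.grow_tree <- function(X, y, depth, max_depth, min_split) {
  n <- length(y)
  if (n < min_split || depth >= max_depth || length(unique(y)) == 1L) {
    return(list(leaf = TRUE, class = .majority(y), n = n))
  }
  best <- NULL
  base <- gini_impurity(y)
  for (f in seq_along(X)) {
    v <- X[[f]]
    cuts <- sort(unique(v))
    if (length(cuts) < 2L) next
    thr <- (head(cuts, -1) + tail(cuts, -1)) / 2
    for (t in thr) {
      left <- v <= t
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      imp <- (nl * gini_impurity(y[left]) +
                (n - nl) * gini_impurity(y[!left])) / n
      if (is.null(best) || imp < best$imp - 1e-12) {
        best <- list(f = f, t = t, imp = imp, left = left)
      }
    }
  }
  if (is.null(best) || best$imp >= base - 1e-12) {
    return(list(leaf = TRUE, class = .majority(y), n = n))
  }
  list(
    leaf = FALSE, feature = names(X)[[best$f]], threshold = best$t, n = n,
    left = .grow_tree(lapply(X, `[`, best$left), y[best$left],
                      depth + 1L, max_depth, min_split),
    right = .grow_tree(lapply(X, `[`, !best$left), y[!best$left],
                       depth + 1L, max_depth, min_split)
  )
}

.predict_node <- function(node, row) {
  while (!node$leaf) {
    node <- if (row[[node$feature]] <= node$threshold) node$left else node$right
  }
  node$class
}

#' Train the panel-count decision tree
#'
#' Features are the cardinalities of the three independent panel-count
#' estimates -- subcaptions (`n_subcaptions`), in-image labels (`n_labels`),
#' connected components (`n_cc`) -- plus the number of gaps in the label
#' sequence (`gaps`). The class is the true panel count.
#'
#' @param corpus data.frame with columns `n_subcaptions`, `n_labels`, `n_cc`,
#'   `gaps`, `true_count`.
#' @param max_depth,min_split tree-growing controls.
#' @return object of class `figseg_count_model`.
#' @export
train_count_model <- function(corpus, max_depth = 10L, min_split = 4L) {
  feats <- c("n_subcaptions", "n_labels", "n_cc", "gaps")
  stopifnot(is.data.frame(corpus),
            all(c(feats, "true_count") %in% names(corpus)))
  if (nrow(corpus) == 0L) stop("empty training corpus")
  y <- as.integer(corpus$true_count)
  X <- lapply(corpus[feats], as.numeric)
  if (length(unique(y)) == 1L)
    warning("degenerate corpus: single class; constant model")
  tree <- .grow_tree(X, y, 0L, max_depth, min_split)
  structure(list(tree = tree, features = feats, n_train = nrow(corpus),
                 classes = sort(unique(y))),
            class = "figseg_count_model")
}

#' Predict panel counts from count evidence
#' @param object a `figseg_count_model`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... unused.
#' @return integer vector of predicted counts (each `>= 1`).
#' @export
predict.figseg_count_model <- function(object, newdata, ...) {
  stopifnot(all(object$features %in% names(newdata)))
  out <- integer(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    row <- lapply(newdata[object$features], function(col) as.numeric(col[[i]]))
    names(row) <- object$features
    out[[i]] <- .predict_node(object$tree, row)
  }
  pmax(1L, out)
}

#' @export
print.figseg_count_model <- function(x, ...) {
  cat("figseg panel-count model (CART),", x$n_train, "training figures,",
      "classes", paste(x$classes, collapse = ","), "\n")
  invisible(x)
}

#' Serialize / restore a count model as JSON
#' @param model a `figseg_count_model`.
#' @param path file path.
#' @return `read_count_model` returns the model; `write_count_model` the path,
#'   invisibly.
#' @export
write_count_model <- function(model, path) {
  stopifnot(inherits(model, "figseg_count_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_count_model
#' @export
read_count_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fix <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    if (!node$leaf) {
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    } else {
      node$class <- as.integer(node$class)
    }
    node
  }
  obj$tree <- fix(obj$tree)
  obj$classes <- as.integer(obj$classes)
  structure(obj, class = "figseg_count_model")
}
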