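# Panel-label recovery from OCR tokens found inside the figure. OCR output
# over biomedical figures is noisy (random letters inside charts, characters
# lost in textured regions), so candidates are grouped into typed sequences
# and the group whose label sequence has the fewest gaps wins:
# confidence = 1 / (1 + Gaps * Panels).

.right_delims <- c(")", "]", ".", ",", ";", ":")
.closed_pairs <- list(c("(", ")"), c("[", "]"), c("{", "}"))

#' Classify OCR tokens into panel-label candidates
#'
#' A token yields candidates iff its text is: a lone label character
#' (`simple`), a label character followed by a right delimiter such as `")"`,
#' `"]"`, `"."`, `","`, `";"` (`right_closed`), or a label character wrapped
#' in matching delimiters, `"(A)"`, `"[B]"` (`closed`). Longer words never
#' yield candidates. A single "I", "V" or "X" is readable as both a Latin
#' letter and a Roman numeral; it is read as Roman exactly when an
#' unambiguous Roman token (e.g. "II") occurs among the tokens, else as
#' Latin -- otherwise a stray "I" would form a spurious complete Roman
#' "sequence" and outscore a genuinely gapped Latin one.
#'
#' @param tokens data.frame with columns `text`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, and optionally `conf` (in `[0,1]`; logged, not used for
#'   selection).
#' @return data.frame of candidates: `char` (canonical label), `alphabet`,
#'   `category`, `position`, and the token bbox columns.
#' @export
#' @examples
#' toks <- data.frame(text = c("(A)", "B)", "C", "Merge"),
#'                    x_min = c(0, 100, 200, 300), y_min = 0,
#'                    x_max = c(20, 120, 220, 360), y_max = 20)
#' classify_tokens(toks)
classify_tokens <- function(tokens) {
  empty <- data.frame(char = character(0), alphabet = character(0),
                      category = character(0), position = integer(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0))
  if (is.null(tokens) || nrow(tokens) == 0L) return(empty)
  stopifnot(all(c("text", "x_min", "y_min", "x_max", "y_max") %in%
                  names(tokens)))
  cores <- vapply(tokens$text, function(s)
    gsub("[][(){}.,;: ]", "", trimws(s)), "")
  roman_ctx <- any(vapply(cores, function(s)
    identical(label_alphabets(s), "roman"), TRUE))
  rows <- list()
  for (i in seq_len(nrow(tokens))) {
    txt <- trimws(tokens$text[i])
    if (!nzchar(txt)) next
    core <- NULL
    category <- NULL
    first <- substr(txt, 1L, 1L)
    last <- substr(txt, nchar(txt), nchar(txt))
    for (pair in .closed_pairs) {
      if (first == pair[[1]] && last == pair[[2]] && nchar(txt) >= 3L) {
        core <- substr(txt, 2L, nchar(txt) - 1L)
        category <- "closed"
        break
      }
    }
    if (is.null(core) && nchar(txt) >= 2L && last %in% .right_delims) {
      core <- substr(txt, 1L, nchar(txt) - 1L)
      category <- "right_closed"
    }
    if (is.null(core)) {
      core <- txt
      category <- "simple"
    }
    core <- trimws(core)
    alphas <- label_alphabets(core)
    if (length(alphas) == 0L) next
    if (setequal(alphas, c("latin", "roman")))
      alphas <- if (roman_ctx) "roman" else "latin"
    for (alpha in alphas) {
      rows[[length(rows) + 1L]] <- data.frame(
        char = canonical_label(core), alphabet = alpha, category = category,
        position = label_position(core, alpha),
        x_min = tokens$x_min[i], y_min = tokens$y_min[i],
        x_max = tokens$x_max[i], y_max = tokens$y_max[i]
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster label candidates into typed groups
#'
#' One group per (alphabet, category) pair with at least one member. Members
#' are sorted by alphabetical/numeric position; duplicates at the same
#' position keep the top-left-most bbox. `Panels` is the largest position in
#' the group (sequences are assumed to start at 1), `Gaps` the number of
#' missing positions, and `confidence = 1 / (1 + Gaps * Panels)`.
#'
#' @param cands data.frame from [classify_tokens()].
#' @return list of groups; each a list with `alphabet`, `category`,
#'   `members` (data.frame), `Panels`, `Gaps`, `confidence`.
#' @export
build_groups <- function(cands) {
  if (nrow(cands) == 0L) return(list())
  key <- paste(cands$alphabet, cands$category, sep = "/")
  groups <- list()
  for (k in unique(key)) {
    g <- cands[key == k, , drop = FALSE]
    g <- g[order(g$position, g$y_min, g$x_min), , drop = FALSE]
    g <- g[!duplicated(g$position), , drop = FALSE]
    panels <- max(g$position)
    gaps <- panels - nrow(g)
    groups[[length(groups) + 1L]] <- list(
      alphabet = g$alphabet[[1]], category = g$category[[1]],
      members = g, Panels = as.integer(panels), Gaps = as.integer(gaps),
      confidence = 1 / (1 + gaps * panels)
    )
  }
  groups
}

#' Select the most coherent label group
#'
#' Returns the group maximizing `confidence`; ties broken by larger `Panels`,
#' then alphabet priority (Latin, Roman, Arabic), then category
#' (simple, right_closed, closed).
#'
#' @param groups list from [build_groups()].
#' @return a single group, or `NULL` when `groups` is empty.
#' @export
score_and_select <- function(groups) {
  if (length(groups) == 0L) return(NULL)
  conf <- vapply(groups, `[[`, 1, "confidence")
  panels <- vapply(groups, `[[`, 1L, "Panels")
  arank <- vapply(groups, function(g) alphabet_rank(g$alphabet), 1L)
  crank <- vapply(groups, function(g)
    match(g$category, c("simple", "right_closed", "closed")), 1L)
  ord <- order(-conf, -panels, arank, crank)
  groups[[ord[[1]]]]
}

#' Recover the panel-label group from raw OCR tokens
#'
#' Convenience wrapper: [classify_tokens()] then [build_groups()] then
#' [score_and_select()].
#'
#' @param tokens OCR token data.frame (see [classify_tokens()]).
#' @return selected group or `NULL`.
#' @export
recover_labels <- function(tokens) {
  score_and_select(build_groups(classify_tokens(tokens)))
}
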