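# Caption segmentation: find panel-label tokens in a figure caption, remove
# false positives (abbreviations, citations, out-of-sequence strays), and cut
# the caption into per-panel subcaptions. Range tokens such as "(A-C)" are
# expanded, duplicating the following text for each label in the range.

# Regex fragment matching one label atom: Latin letter, Roman numeral <= XII,
# or integer 1-20. Multi-character alternatives first so the longest wins.
.lab_re <- "(?:XII|XI|IX|VIII|VII|VI|IV|III|II|20|1[0-9]|[A-Za-z]|[1-9])"

.caption_patterns <- function() {
  lab <- .lab_re
  list(
    # "(A - C)", "(a to c)", "(II-IV)"
    range_dash = sprintf("(?i)\\( *%s(?: *[-–—] *| +to +)%s *\\)", lab, lab),
    # "(A, B, and C)", "(a and b)", "(1, 2, 3)"
    range_list = sprintf("(?i)\\( *%s(?:(?: *, *(?:and +)?| +and +)%s)+ *\\)", lab, lab),
    # "(A)", "[b]" is an OCR-side form; captions use parentheses
    paren_single = sprintf("(?i)\\( *%s *\\)", lab),
    # "X.", "x)", "X,", "x;" preceded by start-of-text or whitespace
    bare = sprintf("(?i)(?<=^|\\s)%s[).,;](?![[:alnum:]])", lab)
  )
}

# Span of the caption head ("Figure 12.", "Fig. 3:", "(Fig. 10)") which is
# exempt from label lexing -- the figure number is not a panel label.
.caption_head_end <- function(text) {
  m <- regexpr("^\\s*\\(?fig(?:ure)?\\.?[ :]*(?:[0-9]{1,3}|[ivxlc]{1,6}\\b)?\\)?[.:,]?",
               text, perl = TRUE, ignore.case = TRUE)
  if (m == 1L) attr(m, "match.length") else 0L
}

# Parse the inside of a matched token surface into labels + alphabet.
# Returns NULL when the elements do not form a coherent label set.
.parse_label_surface <- function(surface, style) {
  inner <- gsub("^\\(|\\)$", "", trimws(surface))
  if (style == "bare") inner <- sub("[).,;]$", "", inner)
  if (style == "range_dash") {
    parts <- strsplit(inner, " *[-–—] *| +[Tt][Oo] +")[[1]]
  } else if (style == "range_list") {
    parts <- strsplit(inner, " *, *(?:[Aa][Nn][Dd] +)? *| +[Aa][Nn][Dd] +",
                      perl = TRUE)[[1]]
  } else {
    parts <- inner
  }
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return(NULL)
  alpha_sets <- lapply(parts, label_alphabets)
  if (any(vapply(alpha_sets, length, 1L) == 0L)) return(NULL)
  shared <- Reduce(intersect, alpha_sets)
  if (length(shared) == 0L) return(NULL)
  # Prefer the reading all elements support: arabic for digits, roman when a
  # roman-only element forces it, latin otherwise.
  alphabet <- if ("arabic" %in% shared) "arabic"
  else if (any(vapply(alpha_sets, function(a) identical(a, "roman"), TRUE)) &&
           "roman" %in% shared) "roman"
  else if ("latin" %in% shared) "latin"
  else shared[[1]]
  # every element readable as both Latin and Roman (I, V, X): keep both
  # readings; the filter resolves them from caption context
  ambiguous <- alphabet == "latin" && "roman" %in% shared
  expand <- function(parts, alphabet) {
    labels <- canonical_label(parts)
    if (style == "range_dash") {
      p1 <- label_position(labels[[1]], alphabet)
      p2 <- label_position(labels[[2]], alphabet)
      if (p2 <= p1 || p2 - p1 > 25L) return(NULL)
      labels <- vapply(p1:p2, label_from_position, "", alphabet = alphabet)
    }
    if (anyDuplicated(labels)) return(NULL)
    labels
  }
  labels <- expand(parts, alphabet)
  if (is.null(labels)) return(NULL)
  alt_labels <- if (ambiguous) expand(parts, "roman") else NULL
  list(labels = labels, alphabet = alphabet, ambiguous = ambiguous,
       alt_labels = alt_labels)
}

#' Lex panel-label tokens out of a caption
#'
#' Recognizes, case-insensitively and over Latin letters, Roman numerals and
#' Arabic numbers: parenthesized single labels `"(A)"`, parenthesized ranges
#' `"(A-C)"`, `"(a to c)"`, `"(A, B, and C)"`, `"(x and y)"`, and bare
#' delimited labels `"X."`, `"x)"`, `"X,"`, `"x;"`. The figure-number word in
#' the caption head (`"Figure 12."`) is never a label. Longest match wins and
#' token spans do not overlap.
#'
#' @param text caption string (UTF-8).
#' @return data.frame with one row per token: `surface`, `start`, `end`
#'   (1-based inclusive character offsets), `style` (`paren_single`,
#'   `paren_range`, `bare`), `alphabet`, `ambiguous` (single I/V/X, readable
#'   as Latin or Roman), and list-column `labels` (canonical labels the token
#'   denotes; more than one only for ranges/lists).
#' @export
#' @examples
#' lex_caption_labels("Figure 1. (A) Gel. (B) Blot.")
#' lex_caption_labels("(A-C) Staining. (D) Merge.")
lex_caption_labels <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  pats <- .caption_patterns()
  from <- .caption_head_end(text)
  cand <- list()
  for (pi in seq_along(pats)) {
    name <- names(pats)[[pi]]
    m <- gregexpr(pats[[pi]], text, perl = TRUE)[[1]]
    if (m[[1]] == -1L) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      if (m[[k]] <= from) next
      cand[[length(cand) + 1L]] <- list(
        start = as.integer(m[[k]]),
        end = as.integer(m[[k]] + len[[k]] - 1L),
        style = name, priority = pi,
        surface = substr(text, m[[k]], m[[k]] + len[[k]] - 1L)
      )
    }
  }
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), style = character(0),
                      alphabet = character(0), ambiguous = logical(0))
  empty$labels <- list()
  if (length(cand) == 0L) return(empty)
  ord <- order(vapply(cand, `[[`, 1L, "start"),
               -vapply(cand, function(x) x$end - x$start, 1L),
               vapply(cand, `[[`, 1L, "priority"))
  cand <- cand[ord]
  rows <- list()
  last_end <- 0L
  for (tk in cand) {
    if (tk$start <= last_end) next
    parsed <- .parse_label_surface(tk$surface, tk$style)
    if (is.null(parsed)) next
    style <- switch(tk$style, range_dash = , range_list = "paren_range",
                    paren_single = "paren_single", bare = "bare")
    rows[[length(rows) + 1L]] <- list(
      surface = tk$surface, start = tk$start, end = tk$end, style = style,
      alphabet = parsed$alphabet,
      ambiguous = parsed$ambiguous && !is.null(parsed$alt_labels),
      labels = parsed$labels,
      alt_labels = parsed$alt_labels
    )
    last_end <- tk$end
  }
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    surface = vapply(rows, `[[`, "", "surface"),
    start = vapply(rows, `[[`, 1L, "start"),
    end = vapply(rows, `[[`, 1L, "end"),
    style = vapply(rows, `[[`, "", "style"),
    alphabet = vapply(rows, `[[`, "", "alphabet"),
    ambiguous = vapply(rows, `[[`, TRUE, "ambiguous")
  )
  out$labels <- lapply(rows, `[[`, "labels")
  out$alt_labels <- lapply(rows, `[[`, "alt_labels")
  out
}

# Longest strictly-increasing subsequence of `pos`, preferring the earliest
# (lexicographically smallest) index set among maximal-length ones.
# Exhaustive enough at caption scale; O(n^2).
lis_earliest <- function(pos) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  g <- integer(n) # length of longest increasing run starting at i
  for (i in n:1) {
    g[i] <- 1L
    for (j in seq_len(n)) {
      if (j > i && pos[j] > pos[i] && g[j] + 1L > g[i]) g[i] <- g[j] + 1L
    }
  }
  L <- max(g)
  out <- integer(0)
  prev_pos <- -Inf
  prev_idx <- 0L
  for (need in L:1) {
    i <- which(g == need & pos > prev_pos & seq_len(n) > prev_idx)[1]
    out <- c(out, i)
    prev_pos <- pos[i]
    prev_idx <- i
  }
  out
}

#' Filter lexed label tokens down to one coherent panel-label sequence
#'
#' Labels are clustered by alphabet; repeated labels keep their first
#' occurrence; within an alphabet the longest strictly-increasing subsequence
#' of label positions survives (ties to the earliest caption offset); among
#' surviving alphabets priority is Latin, then Roman, then Arabic. A bare "I"
#' is accepted only when another Roman-only token co-occurs (guards against
#' the English pronoun), and ambiguous I/V/X tokens are read as Roman exactly
#' when a Roman-only token co-occurs.
#'
#' @param tokens data.frame from [lex_caption_labels()].
#' @return data.frame of accepted labels in caption order: `label`,
#'   `alphabet`, `position`, `token_id`, `start`, `end`, `style`, `shared`
#'   (TRUE when the label comes from a range token).
#' @export
filter_label_candidates <- function(tokens) {
  empty <- data.frame(label = character(0), alphabet = character(0),
                      position = integer(0), token_id = integer(0),
                      start = integer(0), end = integer(0),
                      style = character(0), shared = logical(0))
  if (nrow(tokens) == 0L) return(empty)
  roman_ctx <- any(tokens$alphabet == "roman" & !tokens$ambiguous)
  alphabet <- tokens$alphabet
  use_alt <- tokens$ambiguous & roman_ctx &
    !vapply(tokens$alt_labels, is.null, TRUE)
  alphabet[use_alt] <- "roman"
  drop <- tokens$style == "bare" & !roman_ctx &
    vapply(tokens$labels, function(l) identical(toupper(l), "I"), TRUE)
  rows <- list()
  for (i in seq_len(nrow(tokens))) {
    if (drop[i]) next
    labs <- if (use_alt[i]) tokens$alt_labels[[i]] else tokens$labels[[i]]
    for (lab in labs) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = canonical_label(lab), alphabet = alphabet[i],
        position = label_position(lab, alphabet[i]), token_id = i,
        start = tokens$start[i], end = tokens$end[i],
        style = tokens$style[i], shared = length(labs) > 1L
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  flat <- do.call(rbind, rows)
  flat <- flat[!duplicated(flat[, c("alphabet", "label")]), , drop = FALSE]
  best <- empty
  for (alpha in .alphabets) { # priority order latin > roman > arabic
    cl <- flat[flat$alphabet == alpha, , drop = FALSE]
    if (nrow(cl) == 0L) next
    keep <- lis_earliest(cl$position)
    best <- cl[keep, , drop = FALSE]
    break
  }
  rownames(best) <- NULL
  best
}

#' Split a caption into per-panel subcaptions
#'
#' Each subcaption runs from the end of its label token to the start of the
#' next (or the end of the caption). The text following a range token is
#' duplicated once per label in the range, flagged `shared`. Text before the
#' first token is returned separately as figure-level preamble.
#'
#' @param text the caption string.
#' @param accepted accepted labels from [filter_label_candidates()].
#' @return list with `preamble` (string, possibly empty), and `subcaptions`,
#'   a data.frame `label`/`text`/`shared`; when no labels were accepted the
#'   single subcaption has label `"∅"` and covers the whole caption.
#'   Attribute `"segments"` holds the raw (untrimmed) text segments for
#'   round-trip checks.
#' @export
#' @examples
#' toks <- lex_caption_labels("(A-C) Staining. (D) Merge.")
#' split_subcaptions("(A-C) Staining. (D) Merge.",
#'                   filter_label_candidates(toks))
split_subcaptions <- function(text, accepted) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nrow(accepted) == 0L) {
    out <- list(preamble = "",
                subcaptions = data.frame(label = "∅", text = trimws(text),
                                         shared = FALSE))
    attr(out, "segments") <- list(preamble = "", raw = character(0))
    return(out)
  }
  tok <- unique(accepted[, c("token_id", "start", "end")])
  tok <- tok[order(tok$start), , drop = FALSE]
  preamble_raw <- substr(text, 1L, tok$start[1] - 1L)
  nseg <- nrow(tok)
  seg_raw <- character(nseg)
  for (i in seq_len(nseg)) {
    seg_end <- if (i < nseg) tok$start[i + 1L] - 1L else nchar(text)
    seg_raw[i] <- substr(text, tok$end[i] + 1L, seg_end)
  }
  rows <- list()
  for (i in seq_len(nseg)) {
    labs <- accepted[accepted$token_id == tok$token_id[i], , drop = FALSE]
    for (k in seq_len(nrow(labs))) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = labs$label[k], text = trimws(seg_raw[i]),
        shared = labs$shared[k]
      )
    }
  }
  out <- list(preamble = trimws(preamble_raw),
              subcaptions = do.call(rbind, rows))
  rownames(out$subcaptions) <- NULL
  attr(out, "segments") <- list(preamble = preamble_raw, raw = seg_raw,
                                surfaces = vapply(seq_len(nseg), function(i) {
                                  substr(text, tok$start[i], tok$end[i])
                                }, ""))
  out
}

#' Full caption analysis: lex, filter, split
#'
#' @param text caption string.
#' @return list with `tokens`, `accepted`, `preamble`, `subcaptions`, and
#'   `n_labeled` (number of accepted labels after range expansion; 0 when the
#'   caption gives no panel hint).
#' @export
segment_caption <- function(text) {
  tokens <- lex_caption_labels(text)
  accepted <- filter_label_candidates(tokens)
  sp <- split_subcaptions(text, accepted)
  list(tokens = tokens, accepted = accepted, preamble = sp$preamble,
       subcaptions = sp$subcaptions, n_labeled = nrow(accepted),
       segments = attr(sp, "segments"))
}
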