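# Shared label-alphabet helpers and small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Roman numerals recognized as panel labels. Bounded at XII: corpus figures
# average ~3 panels, and larger numerals collide with ordinary words.
.roman_values <- c(
  I = 1L, II = 2L, III = 3L, IV = 4L, V = 5L, VI = 6L,
  VII = 7L, VIII = 8L, IX = 9L, X = 10L, XI = 11L, XII = 12L
)

.max_arabic_label <- 20L

.alphabets <- c("latin", "roman", "arabic")

#' Ordinal position of a panel label within its alphabet
#'
#' `position('b') = 2`, `position('D') = 4`, `position('III') = 3`,
#' `position('7') = 7`. Latin labels are case-insensitive.
#'
#' @param label a label string ("A", "iv", "12").
#' @param alphabet one of `"latin"`, `"roman"`, `"arabic"`.
#' @return integer position, `>= 1`.
#' @export
#' @examples
#' label_position("D", "latin")   # 4
#' label_position("iii", "roman") # 3
label_position <- function(label, alphabet) {
  alphabet <- match.arg(alphabet, .alphabets)
  up <- toupper(label)
  pos <- switch(alphabet,
    latin = match(up, LETTERS),
    roman = unname(.roman_values[up]),
    arabic = suppressWarnings(as.integer(label))
  )
  if (is.na(pos) || pos < 1L)
    stop("not a valid ", alphabet, " label: ", label)
  as.integer(pos)
}

#' Label string at a given position of an alphabet
#' @param pos integer position (1-based).
#' @param alphabet one of `"latin"`, `"roman"`, `"arabic"`.
#' @return canonical (uppercase) label string.
#' @export
label_from_position <- function(pos, alphabet) {
  alphabet <- match.arg(alphabet, .alphabets)
  pos <- as.integer(pos)
  stopifnot(pos >= 1L)
  switch(alphabet,
    latin = {
      stopifnot(pos <= 26L)
      LETTERS[pos]
    },
    roman = {
      stopifnot(pos <= length(.roman_values))
      names(.roman_values)[pos]
    },
    arabic = as.character(pos)
  )
}

# Possible alphabet readings of a single token string. "I", "V", "X" are both
# Latin letters and Roman numerals; multi-letter numerals are roman-only.
label_alphabets <- function(s) {
  up <- toupper(s)
  out <- character(0)
  if (nchar(up) == 1L && up %in% LETTERS) out <- c(out, "latin")
  if (up %in% names(.roman_values)) out <- c(out, "roman")
  n <- suppressWarnings(as.integer(s))
  if (!is.na(n) && n >= 1L && n <= .max_arabic_label && grepl("^[0-9]+$", s))
    out <- c(out, "arabic")
  out
}

# Canonical form of a label: uppercase; arabic left as digits.
canonical_label <- function(s) toupper(trimws(s))

alphabet_rank <- function(alphabet) match(alphabet, .alphabets)

# Deterministic little generator independent of R's global RNG, so fixture
# generation never perturbs user seeds. Parkland-Miller minimal standard.
fs_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  list(
    unif = function(n = 1L) {
      out <- numeric(n)
      for (i in seq_len(n)) {
        state <<- (state * 16807) %% 2147483647
        out[i] <- state / 2147483647
      }
      out
    },
    int = function(n = 1L, lo, hi) {
      u <- numeric(n)
      for (i in seq_len(n)) {
        state <<- (state * 16807) %% 2147483647
        u[i] <- state / 2147483647
      }
      as.integer(lo + floor(u * (hi - lo + 1L)))
    }
  )
}
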