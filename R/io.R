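# Plain-text I/O: PGM (P2) images, JSONL operator streams, OCR-token JSON.
# PGM keeps every fixture and intermediate inspectable and diff-able; PNG
# reading/writing is available through the optional `png` package.

#' Write a grayscale image as ASCII PGM (P2)
#' @param img integer matrix, values 0-255.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply_rows <- apply(img, 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#' @param path file path.
#' @return integer matrix.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  stopifnot(txt[[1]] == "P2")
  vals <- as.integer(unlist(strsplit(paste(txt[-1], collapse = " "), "\\s+")))
  vals <- vals[!is.na(vals)]
  w <- vals[[1]]; h <- vals[[2]]
  stopifnot(length(vals) >= 3 + w * h)
  matrix(vals[4:(3 + w * h)], nrow = h, ncol = w, byrow = TRUE)
}

#' Read an image file (PGM always; PNG when the `png` package is installed)
#' @param path file path ending in `.pgm` or `.png`.
#' @return integer grayscale matrix.
#' @export
read_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package")
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) return(as_gray(arr * 255))
    return(as_gray(arr * 255))
  }
  stop("unsupported image format: ", path)
}

#' Serialize an operator stream as JSON lines plus PGM images
#'
#' One operator per line: `{"kind","page","bbox","text"}` or
#' `{"kind","page","bbox","image_ref","orientation"}`; images land as PGM
#' files next to the stream.
#'
#' @param stream operator list.
#' @param path path of the `.jsonl` file; images are stored beside it.
#' @return the path, invisibly.
#' @export
write_operator_stream <- function(stream, path) {
  dir <- dirname(path)
  lines <- character(length(stream))
  img_n <- 0L
  for (i in seq_along(stream)) {
    op <- stream[[i]]
    rec <- list(kind = op$kind, page = op$page, bbox = as.numeric(op$bbox))
    if (op$kind == "text") {
      rec$text <- op$text
    } else {
      img_n <- img_n + 1L
      ref <- sprintf("%s_img%03d.pgm",
                     sub("\\.jsonl$", "", basename(path)), img_n)
      write_pgm(op$image, file.path(dir, ref))
      rec$image_ref <- ref
      rec$orientation <- op$orientation %||% 0L
    }
    lines[[i]] <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                                digits = NA))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an operator stream written by [write_operator_stream()]
#' @param path path of the `.jsonl` file.
#' @return operator list.
#' @export
read_operator_stream <- function(path) {
  dir <- dirname(path)
  lines <- readLines(path)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    b <- bbox(rec$bbox[[1]], rec$bbox[[2]], rec$bbox[[3]], rec$bbox[[4]])
    if (rec$kind == "text") {
      operator_text(rec$page, b, rec$text)
    } else {
      operator_image(rec$page, b, read_pgm(file.path(dir, rec$image_ref)),
                     rec$orientation %||% 0L)
    }
  })
}

#' Write / read OCR tokens as JSON
#' @param tokens data.frame `text`, `x_min`, `y_min`, `x_max`, `y_max`,
#'   optional `conf`.
#' @param path file path.
#' @return `read_ocr_tokens` returns the data.frame.
#' @export
write_ocr_tokens <- function(tokens, path) {
  recs <- lapply(seq_len(nrow(tokens)), function(i) {
    list(text = tokens$text[i],
         bbox = c(tokens$x_min[i], tokens$y_min[i],
                  tokens$x_max[i], tokens$y_max[i]),
         conf = if ("conf" %in% names(tokens)) tokens$conf[i] else NULL)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ocr_tokens
#' @export
read_ocr_tokens <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(recs) == 0L)
    return(data.frame(text = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), conf = numeric(0)))
  do.call(rbind, lapply(recs, function(r) {
    data.frame(text = r$text, x_min = r$bbox[[1]], y_min = r$bbox[[2]],
               x_max = r$bbox[[3]], y_max = r$bbox[[4]],
               conf = r$conf %||% NA_real_)
  }))
}
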