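#' Read and write CoNLL-style column files
#'
#' Sequence-labeling corpora are stored one character per line with
#' whitespace-separated columns and a blank line between sentences. Two
#' columns hold `(char, tag)`; when dictionary and part-of-speech features
#' are attached the file has four columns `(char, dict_tag, pos_tag, tag)`.
#'
#' @param path File path.
#' @param x A tibble with list-columns `chars` and `tags` (and optionally
#'   `dict_tags`, `pos_tags`), one row per sentence — the shape returned by
#'   `read_column_file()`.
#' @param alphabet Optional tag alphabet; unknown tags on read are an error.
#' @return A tibble with columns `sentence_id`, `chars`, `tags` and, for
#'   4-column files, `dict_tags` and `pos_tags`.
#' @export
read_column_file <- function(path, alphabet = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blocks <- split_blocks(lines)
  rows <- lapply(seq_along(blocks), function(i) {
    parts <- strsplit(trimws(blocks[[i]]), "[ \t]+")
    w <- unique(lengths(parts))
    if (length(w) != 1 || !w %in% c(2L, 4L))
      abort(sprintf("Sentence %d: lines must have uniformly 2 or 4 columns.", i))
    cs <- vapply(parts, `[`, "", 1)
    tg <- vapply(parts, `[`, "", w)
    if (!is.null(alphabet) && !all(tg %in% alphabet))
      abort(sprintf("Sentence %d: unknown tag(s) %s.", i,
                    paste(unique(setdiff(tg, alphabet)), collapse = ", ")))
    row <- tibble(sentence_id = sprintf("s%d", i), chars = list(cs), tags = list(tg))
    if (w == 4L) {
      row$dict_tags <- list(vapply(parts, `[`, "", 2))
      row$pos_tags <- list(vapply(parts, `[`, "", 3))
    }
    row
  })
  if (length(rows) == 0)
    return(tibble(sentence_id = character(0), chars = list(), tags = list()))
  dplyr::bind_rows(rows)
}

#' @rdname read_column_file
#' @export
write_column_file <- function(x, path) {
  has_feats <- all(c("dict_tags", "pos_tags") %in% names(x))
  blocks <- vapply(seq_len(nrow(x)), function(i) {
    cs <- x$chars[[i]]; tg <- x$tags[[i]]
    if (length(cs) != length(tg))
      abort(sprintf("Sentence %d: %d chars but %d tags.", i, length(cs), length(tg)))
    if (has_feats)
      paste(sprintf("%s\t%s\t%s\t%s", cs, x$dict_tags[[i]], x$pos_tags[[i]], tg),
            collapse = "\n")
    else
      paste(sprintf("%s\t%s", cs, tg), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}
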