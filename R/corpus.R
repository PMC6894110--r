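#' Build an annotated record from text and entity tuples
#'
#' An annotated clinical record is a raw text plus a set of entity mentions,
#' each given as `{surface, start, end, type}`. Offsets are **0-based with an
#' inclusive end**: in the record
#' `"患者1个月前无明显诱因出现上腹部不适"` the anatomy mention
#' `"上腹部"` spans `(13, 15)` and the symptom `"不适"` spans `(16, 17)`.
#' Parsing verifies that slicing the text at `[start, end]` reproduces each
#' surface, that offsets are in range, and that mentions do not overlap.
#'
#' @param text A single UTF-8 string.
#' @param mentions A data frame with columns `surface`, `start`, `end`,
#'   `type` (surface may be omitted, in which case it is filled from the
#'   text).
#' @param record_id Identifier for the record.
#' @param types Optional character vector restricting the allowed entity
#'   types.
#' @return A one-row corpus tibble (columns `record_id`, `text`, `mentions`)
#'   of class `cner_corpus`; bind rows of these to form a corpus.
#' @examples
#' parse_annotations(
#'   "患者1个月前无明显诱因出现上腹部不适",
#'   tibble::tibble(surface = c("上腹部", "不适"),
#'                  start = c(13, 16), end = c(15, 17),
#'                  type = c("AP", "SD")))
#' @export
parse_annotations <- function(text, mentions = NULL, record_id = "r1", types = NULL) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  text <- enc2utf8(text)
  m <- as_mentions(mentions)
  cs <- chars(text)
  check_mention_bounds(m, length(cs))
  if (nrow(m) > 0) {
    slice <- vapply(seq_len(nrow(m)), function(i)
      paste(cs[(m$start[i] + 1L):(m$end[i] + 1L)], collapse = ""), character(1))
    known <- !is.na(m$surface)
    if (any(known & m$surface != slice)) {
      i <- which(known & m$surface != slice)[1]
      abort(sprintf(
        "Surface/offset mismatch for mention %d: text[%d..%d] is \"%s\", not \"%s\".",
        i, m$start[i], m$end[i], slice[i], m$surface[i]))
    }
    m$surface <- slice
    if (!is.null(types) && !all(m$type %in% types))
      abort(sprintf("Unknown entity type(s): %s.",
                    paste(setdiff(m$type, types), collapse = ", ")))
  }
  new_corpus(tibble(record_id = as.character(record_id), text = text,
                    mentions = list(m)))
}

new_corpus <- function(df) {
  class(df) <- c("cner_corpus", class(tibble()))
  df
}

#' @export
print.cner_corpus <- function(x, ...) {
  n_m <- sum(vapply(x$mentions, nrow, integer(1)))
  cat(sprintf("<cner_corpus: %d record(s), %d mention(s)>\n", nrow(x), n_m))
  NextMethod()
}

#' Read and write annotated-record files
#'
#' The on-disk annotation format is UTF-8 plain text with one record per
#' block: the first line is the raw record text, each following line is a
#' tab-separated mention `surface<TAB>start<TAB>end<TAB>type` (0-based
#' inclusive offsets), and a blank line separates records.
#'
#' @param path File path.
#' @param corpus A corpus tibble as returned by [parse_annotations()] or
#'   [gen_corpus()].
#' @param types Optional allowed type set, checked on read.
#' @return `read_annotations()` returns a corpus tibble;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path, types = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blocks <- split_blocks(lines)
  recs <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    m <- NULL
    if (length(b) > 1) {
      parts <- strsplit(b[-1], "\t", fixed = TRUE)
      if (any(lengths(parts) != 4))
        abort(sprintf("Record %d: mention lines must have 4 tab-separated fields.", i))
      m <- tibble(surface = vapply(parts, `[`, "", 1),
                  start = as.integer(vapply(parts, `[`, "", 2)),
                  end = as.integer(vapply(parts, `[`, "", 3)),
                  type = vapply(parts, `[`, "", 4))
    }
    parse_annotations(b[1], m, record_id = sprintf("r%d", i), types = types)
  })
  new_corpus(dplyr::bind_rows(recs))
}

#' @rdname read_annotations
#' @export
write_annotations <- function(corpus, path) {
  blocks <- vapply(seq_len(nrow(corpus)), function(i) {
    m <- corpus$mentions[[i]]
    lines <- corpus$text[i]
    if (nrow(m) > 0)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", m$surface, m$start, m$end, m$type))
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

split_blocks <- function(lines) {
  lines <- enc2utf8(lines)
  keep <- cumsum(!nzchar(lines) & c(TRUE, nzchar(head(lines, -1))))
  grp <- split(lines, keep)
  grp <- lapply(grp, function(b) b[nzchar(b)])
  grp[lengths(grp) > 0]
}

# Delimiters that end a clause. Full-width and ASCII comma/period both count;
# other punctuation never splits.
clause_delims <- function(mode) {
  if (mode == "short") c("，", ",", "。", ".") else c("。", ".")
}

#' Split annotated records into clauses
#'
#' Clinical records are split into model-ready sentences at punctuation:
#' `"short"` mode splits on commas and periods (the unit over which
#' attention is computed), `"long"` mode on periods only. Both full-width
#' (，。) and ASCII (`,.`) delimiters are recognized; delimiters are dropped
#' from the sentence text but recorded so the record can be reconstructed
#' exactly. Mention offsets are remapped to be sentence-relative (still
#' 0-based inclusive).
#'
#' Sentences longer than `max_len` characters are hard-truncated with a
#' warning, and mentions that fall past the cut are dropped with a warning.
#' A mention spanning a split boundary is an error; with
#' `cross_mention = "fallback_long"` the offending record is re-split in
#' long mode instead (an error if the mention crosses a period too).
#'
#' @param corpus A corpus tibble.
#' @param mode `"short"` (comma + period) or `"long"` (period only).
#' @param max_len Maximum sentence length in characters (default 150, the
#'   model's time-step budget).
#' @param cross_mention `"error"` or `"fallback_long"`.
#' @return A tibble of class `cner_sentences` with columns `record_id`,
#'   `sentence_id`, `origin_offset` (0-based offset of the sentence's first
#'   character in the record), `text`, `lead` (delimiters preceding the
#'   first sentence of a record), `delim` (delimiters following the
#'   sentence), `mode`, and a `mentions` list-column.
#' @examples
#' co <- parse_annotations("腹部不适，头痛。")
#' split_sentences(co, mode = "short")$text
#' @export
split_sentences <- function(corpus, mode = c("short", "long"), max_len = 150L,
                            cross_mention = c("error", "fallback_long")) {
  mode <- match.arg(mode)
  cross_mention <- match.arg(cross_mention)
  out <- lapply(seq_len(nrow(corpus)), function(i)
    split_record(corpus$record_id[i], corpus$text[i], corpus$mentions[[i]],
                 mode, max_len, cross_mention))
  res <- dplyr::bind_rows(out)
  class(res) <- c("cner_sentences", class(tibble()))
  res
}

split_record <- function(record_id, text, mentions, mode, max_len, cross_mention) {
  cs <- chars(text)
  delims <- clause_delims(mode)
  is_delim <- cs %in% delims
  # segment boundaries between delimiters
  seg_start <- integer(0); seg_end <- integer(0)  # 1-based char indices
  cur <- NULL
  for (p in seq_along(cs)) {
    if (is_delim[p]) {
      if (!is.null(cur)) { seg_start <- c(seg_start, cur); seg_end <- c(seg_end, p - 1L) }
      cur <- NULL
    } else if (is.null(cur)) cur <- p
  }
  if (!is.null(cur)) { seg_start <- c(seg_start, cur); seg_end <- c(seg_end, length(cs)) }

  if (length(seg_start) == 0) {
    # record is all delimiters (or empty): no sentences
    return(tibble(record_id = character(0), sentence_id = character(0),
                  origin_offset = integer(0), text = character(0),
                  lead = character(0), delim = character(0), mode = character(0),
                  mentions = list()))
  }

  lead <- if (seg_start[1] > 1) paste(cs[seq_len(seg_start[1] - 1L)], collapse = "") else ""
  delim_after <- vapply(seq_along(seg_start), function(k) {
    from <- seg_end[k] + 1L
    to <- if (k < length(seg_start)) seg_start[k + 1L] - 1L else length(cs)
    if (from > to) "" else paste(cs[from:to], collapse = "")
  }, character(1))

  m <- as_mentions(mentions)
  # assign each mention to its segment; crossing a boundary is an error
  if (nrow(m) > 0) {
    seg_of <- function(pos0) {
      k <- which(seg_start - 1L <= pos0 & pos0 <= seg_end - 1L)
      if (length(k) == 0) NA_integer_ else k[1]
    }
    ks <- vapply(m$start, seg_of, integer(1))
    ke <- vapply(m$end, seg_of, integer(1))
    crossing <- is.na(ks) | is.na(ke) | ks != ke
    if (any(crossing)) {
      if (cross_mention == "fallback_long" && mode == "short")
        return(split_record(record_id, text, mentions, "long", max_len, "error"))
      abort(sprintf(
        "Record %s: mention \"%s\" (%d,%d) crosses a sentence boundary.",
        record_id, m$surface[which(crossing)[1]], m$start[which(crossing)[1]],
        m$end[which(crossing)[1]]))
    }
  } else ks <- integer(0)

  rows <- lapply(seq_along(seg_start), function(k) {
    off0 <- seg_start[k] - 1L
    stext <- paste(cs[seg_start[k]:seg_end[k]], collapse = "")
    mm <- m[which(ks == k), , drop = FALSE]
    mm$start <- mm$start - off0
    mm$end <- mm$end - off0
    slen <- seg_end[k] - seg_start[k] + 1L
    if (slen > max_len) {
      warn(sprintf("Record %s sentence %d truncated from %d to %d characters.",
                   record_id, k, slen, max_len))
      stext <- paste(cs[seg_start[k]:(seg_start[k] + max_len - 1L)], collapse = "")
      keep <- mm$end <= max_len - 1L
      if (any(!keep))
        warn(sprintf("Record %s sentence %d: %d mention(s) dropped past the cut.",
                     record_id, k, sum(!keep)))
      mm <- mm[keep, , drop = FALSE]
    }
    tibble(record_id = record_id, sentence_id = sprintf("%s.%d", record_id, k),
           origin_offset = off0, text = stext,
           lead = if (k == 1) lead else "", delim = delim_after[k],
           mode = mode, mentions = list(mm))
  })
  dplyr::bind_rows(rows)
}

#' Reassemble the original record texts from split sentences
#'
#' Inverse of [split_sentences()] (exact when no truncation occurred):
#' concatenates each record's sentences with their recorded delimiters.
#'
#' @param sentences A `cner_sentences` tibble.
#' @return A tibble with columns `record_id`, `text`.
#' @export
unsplit_sentences <- function(sentences) {
  sentences |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(
      text = paste0(.data$lead[1], paste0(.data$text, .data$delim, collapse = "")),
      .groups = "drop")
}
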