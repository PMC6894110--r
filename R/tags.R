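#' Entity type sets and the BIESO tag alphabet
#'
#' Clinical NER over character-segmented text labels every character with a
#' positional tag: `B-t` (begin), `I-t` (interior), `E-t` (end) and `S-t`
#' (single) for each entity type `t`, plus `O` for characters outside any
#' entity. `tag_alphabet()` builds the full label set for a vector of entity
#' types; `ccks2018_types()` and `ccks2017_types()` give the two standard
#' clinical type sets (anatomical part, symptom description, independent
#' symptom, drug, operation; and body part, symptom, diagnosis, test,
#' treatment respectively).
#'
#' @param types Character vector of entity type labels.
#' @return `tag_alphabet()`: a character vector of tags, ordered
#'   `B-t, I-t, E-t, S-t` per type in the given order, with `"O"` last.
#' @examples
#' tag_alphabet(c("AP", "Drug"))
#' ccks2018_types()
#' @export
tag_alphabet <- function(types) {
  stopifnot(is.character(types), length(types) >= 1, !anyDuplicated(types))
  c(as.vector(vapply(types, function(t) paste0(c("B-", "I-", "E-", "S-"), t),
                     character(4))), "O")
}

#' @rdname tag_alphabet
#' @export
ccks2018_types <- function() c("AP", "SD", "IS", "Drug", "Operation")

#' @rdname tag_alphabet
#' @export
ccks2017_types <- function() c("BodyPart", "Symptom", "Diagnosis", "Test", "Treatment")

# Split a UTF-8 string into its code points.
chars <- function(x) {
  if (length(x) != 1 || is.na(x)) abort("`x` must be a single string.")
  if (!nzchar(x)) return(character(0))
  strsplit(enc2utf8(x), "", fixed = FALSE)[[1]]
}

n_chars <- function(x) nchar(enc2utf8(x), type = "chars")

#' Encode entity mentions as a BIESO tag sequence
#'
#' Converts offset-based entity mentions into per-character BIESO labels.
#' A length-1 mention becomes `S-t`; length 2 becomes `B-t, E-t`; longer
#' mentions become `B-t, I-t, ..., E-t`. All remaining characters are `O`.
#' Offsets are 0-based with an inclusive end, the convention used throughout
#' the package (see [parse_annotations()]).
#'
#' @param mentions A data frame with columns `start`, `end` (0-based,
#'   inclusive) and `type`; typically a `mentions` list-column element of a
#'   corpus tibble.
#' @param n Sentence length in characters, or a string whose character count
#'   is used.
#' @return A character vector of `n` tags.
#' @examples
#' encode_bieso(tibble::tibble(start = 0, end = 2, type = "AP"), n = 4)
#' @export
encode_bieso <- function(mentions, n) {
  if (is.character(n)) n <- n_chars(n)
  n <- as.integer(n)
  m <- as_mentions(mentions)
  check_mention_bounds(m, n)
  tags <- rep("O", n)
  if (nrow(m) == 0) return(tags)
  for (i in seq_len(nrow(m))) {
    s <- m$start[i] + 1L
    e <- m$end[i] + 1L
    t <- m$type[i]
    len <- e - s + 1L
    if (len == 1L) {
      tags[s] <- paste0("S-", t)
    } else {
      tags[s] <- paste0("B-", t)
      tags[e] <- paste0("E-", t)
      if (len > 2L) tags[(s + 1L):(e - 1L)] <- paste0("I-", t)
    }
  }
  tags
}

#' Decode a BIESO tag sequence into entity mentions
#'
#' The inverse of [encode_bieso()]. In `"strict"` mode any malformed
#' sequence (an `I` or `E` without a matching `B`, an unclosed `B`, a type
#' switch mid-span) raises an error. In `"conservative"` mode only maximal
#' well-formed spans (`S-t`, or `B-t (I-t)* E-t` with a uniform type) are
#' extracted and every malformed stretch is ignored — the repair used on raw
#' model output when transition constraints are off.
#'
#' @param tags Character vector of BIESO tags.
#' @param repair `"strict"` or `"conservative"`.
#' @param text Optional sentence string used to fill the `surface` column.
#' @return A tibble with columns `surface` (NA unless `text` given),
#'   `start`, `end` (0-based inclusive) and `type`, sorted by `start`.
#' @examples
#' decode_bieso(c("B-AP", "I-AP", "E-AP", "O"))
#' decode_bieso(c("I-AP", "O"), repair = "conservative")
#' @export
decode_bieso <- function(tags, repair = c("strict", "conservative"), text = NULL) {
  repair <- match.arg(repair)
  stopifnot(is.character(tags))
  n <- length(tags)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  bad <- function(i, why) {
    if (repair == "strict")
      abort(sprintf("Malformed BIESO sequence at position %d (0-based %d): %s.",
                    i, i - 1L, why))
  }
  i <- 1L
  while (i <= n) {
    tg <- tags[i]
    if (tg == "O") { i <- i + 1L; next }
    pos <- substr(tg, 1, 1)
    ty <- substring(tg, 3)
    if (pos == "S") {
      starts <- c(starts, i - 1L); ends <- c(ends, i - 1L); types <- c(types, ty)
      i <- i + 1L
    } else if (pos == "B") {
      j <- i + 1L
      while (j <= n && tags[j] == paste0("I-", ty)) j <- j + 1L
      if (j <= n && tags[j] == paste0("E-", ty)) {
        starts <- c(starts, i - 1L); ends <- c(ends, j - 1L); types <- c(types, ty)
        i <- j + 1L
      } else {
        bad(i, sprintf("'B-%s' span is never closed by 'E-%s'", ty, ty))
        i <- j  # conservative: skip the scanned B/I run, re-examine tags[j]
      }
    } else {
      bad(i, sprintf("'%s' does not start a well-formed span", tg))
      i <- i + 1L
    }
  }
  surface <- rep(NA_character_, length(starts))
  if (!is.null(text) && length(starts) > 0) {
    cs <- chars(text)
    surface <- vapply(seq_along(starts), function(k)
      paste(cs[(starts[k] + 1L):(ends[k] + 1L)], collapse = ""), character(1))
  }
  out <- tibble(surface = surface, start = starts, end = ends, type = types)
  out[order(out$start), , drop = FALSE]
}

# --- mention helpers ------------------------------------------------------

as_mentions <- function(x) {
  if (is.null(x)) x <- tibble(surface = character(), start = integer(),
                              end = integer(), type = character())
  x <- as_tibble(x)
  if (!all(c("start", "end", "type") %in% names(x)))
    abort("Mentions need columns `start`, `end`, `type`.")
  if (!"surface" %in% names(x)) x$surface <- NA_character_
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$type <- as.character(x$type)
  x <- x[, c("surface", "start", "end", "type")]
  x[order(x$start), , drop = FALSE]
}

check_mention_bounds <- function(m, n) {
  if (nrow(m) == 0) return(invisible(m))
  if (any(m$start < 0L) || any(m$end >= n) || any(m$start > m$end))
    abort(sprintf(
      "Mention offsets out of range: need 0 <= start <= end <= %d (0-based inclusive).",
      n - 1L))
  if (nrow(m) > 1 && any(m$start[-1] <= m$end[-nrow(m)]))
    abort("Overlapping mentions are not supported.")
  invisible(m)
}
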