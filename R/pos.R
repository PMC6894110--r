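#' Per-character part-of-speech tags from a pluggable word tagger
#'
#' Clinical taggers operate on words; the model consumes characters. Given a
#' word-level tagger — any function `function(text)` returning a data frame
#' with columns `word` and `tag` whose words concatenate exactly to the
#' input — every character receives its containing word's tag. With no
#' tagger configured every character gets the `"NONE"` tag, which disables
#' the feature gracefully.
#'
#' @param text A string or character vector of single characters.
#' @param tagger A tagger function, or `NULL`.
#' @return A character vector of POS tags, one per character.
#' @examples
#' tg <- function(text) tibble::tibble(word = c("腹部", "痛"), tag = c("n", "v"))
#' pos_tags_per_char("腹部痛", tg)
#' @export
pos_tags_per_char <- function(text, tagger = NULL) {
  cs <- if (length(text) > 1) text else chars(text)
  if (is.null(tagger)) return(rep("NONE", length(cs)))
  seg <- as_tibble(tagger(paste(cs, collapse = "")))
  if (!all(c("word", "tag") %in% names(seg)))
    abort("Tagger must return columns `word` and `tag`.")
  lens <- vapply(seg$word, n_chars, integer(1), USE.NAMES = FALSE)
  if (sum(lens) != length(cs) ||
      paste(seg$word, collapse = "") != paste(cs, collapse = ""))
    abort("Tagger segmentation does not cover the text.")
  rep(as.character(seg$tag), lens)
}

#' A deterministic toy word tagger
#'
#' A stand-in segmenter/tagger for tests and synthetic corpora: it chunks
#' the text into 1-3 character "words" and assigns one of the tags
#' `n, v, a, m, x`, both decided by arithmetic on the characters' code
#' points. It carries no linguistic meaning but is deterministic, covers any
#' input exactly, and exercises the POS feature pathway end to end.
#'
#' @return A tagger function suitable for [pos_tags_per_char()].
#' @export
toy_pos_tagger <- function() {
  tagset <- c("n", "v", "a", "m", "x")
  function(text) {
    cp <- utf8ToInt(enc2utf8(text))
    n <- length(cp)
    words <- character(0); tags <- character(0)
    i <- 1L
    while (i <= n) {
      w <- min((cp[i] %% 3L) + 1L, n - i + 1L)
      span <- i:(i + w - 1L)
      words <- c(words, intToUtf8(cp[span]))
      tags <- c(tags, tagset[(sum(cp[span]) %% 5L) + 1L])
      i <- i + w
    }
    tibble(word = words, tag = tags)
  }
}
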