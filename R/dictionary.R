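#' Term dictionaries for dictionary features
#'
#' A term dictionary is a named set of clinical terms (e.g. anatomy, drug or
#' operation vocabularies) used to derive per-character dictionary-match
#' features. `term_dictionary()` builds one from a character vector;
#' `load_dictionary()` reads a UTF-8 file with one term per line.
#' Duplicates are removed and empty lines skipped; an empty dictionary is an
#' error.
#'
#' @param terms Character vector of terms.
#' @param name Dictionary name, used in the feature tag (e.g.
#'   `"Dic_anatomy"` giving tags like `B-Dic_anatomy`).
#' @param path Path to a one-term-per-line UTF-8 file.
#' @return A `term_dictionary`: list with `name`, `terms` (unique, non-empty)
#'   and `max_len` (length of the longest term in characters).
#' @examples
#' d <- term_dictionary(c("上腹部", "腹部"), "Dic_anatomy")
#' d$max_len
#' @export
term_dictionary <- function(terms, name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  terms <- unique(enc2utf8(terms[!is.na(terms) & nzchar(terms)]))
  if (length(terms) == 0) abort(sprintf("Dictionary '%s' is empty.", name))
  lens <- vapply(terms, n_chars, integer(1), USE.NAMES = FALSE)
  hash <- new.env(hash = TRUE, parent = emptyenv(), size = length(terms))
  for (tm in terms) assign(tm, TRUE, envir = hash)
  structure(list(name = name, terms = terms, max_len = max(lens), hash = hash),
            class = "term_dictionary")
}

#' @rdname term_dictionary
#' @export
load_dictionary <- function(path, name) {
  term_dictionary(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)), name)
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("<term_dictionary '%s': %d terms, max length %d>\n",
              x$name, length(x$terms), x$max_len))
  invisible(x)
}

dict_has <- function(dict, term) exists(term, envir = dict$hash, inherits = FALSE)

#' Greedy maximum matching against a term dictionary
#'
#' Scans the text once, from the left (`forward`) or the right (`backward`),
#' taking at each position the longest dictionary term starting (forward) or
#' ending (backward) there. Matched spans never overlap; characters without
#' a match are skipped one at a time.
#'
#' @param text A string or character vector of single characters.
#' @param dict A [term_dictionary()].
#' @param direction `"forward"` or `"backward"`.
#' @return A tibble with columns `start`, `end` (0-based inclusive) and
#'   `name`, sorted by `start`.
#' @examples
#' d <- term_dictionary(c("上腹部", "腹部"), "Dic_anatomy")
#' max_match("上腹部痛", d)
#' @export
max_match <- function(text, dict, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  cs <- if (length(text) > 1) text else chars(text)
  n <- length(cs)
  if (n == 0) abort("`text` must be non-empty.")
  starts <- integer(0); ends <- integer(0)
  if (direction == "forward") {
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (L in seq(min(dict$max_len, n - i + 1L), 1L)) {
        if (dict_has(dict, paste(cs[i:(i + L - 1L)], collapse = ""))) { hit <- L; break }
      }
      if (hit > 0L) {
        starts <- c(starts, i - 1L); ends <- c(ends, i + hit - 2L); i <- i + hit
      } else i <- i + 1L
    }
  } else {
    j <- n
    while (j >= 1L) {
      hit <- 0L
      for (L in seq(min(dict$max_len, j), 1L)) {
        if (dict_has(dict, paste(cs[(j - L + 1L):j], collapse = ""))) { hit <- L; break }
      }
      if (hit > 0L) {
        starts <- c(starts, j - hit); ends <- c(ends, j - 1L); j <- j - hit
      } else j <- j - 1L
    }
  }
  out <- tibble(start = starts, end = ends, name = rep(dict$name, length(starts)))
  out[order(out$start), , drop = FALSE]
}

#' Per-character dictionary tags by bi-directional maximum matching
#'
#' Runs [max_match()] in both directions for every dictionary, merges the
#' candidate matches, and resolves conflicts deterministically: a longer
#' match beats a shorter one; among equal lengths the forward-scan and then
#' leftmost match wins; a remaining cross-dictionary tie is broken by the
#' order of `dictionaries` (the precedence order). Surviving matches are
#' encoded per character as `B/I/E/S-<dictionary name>` (single-character
#' matches get `S`); all other characters are `O`.
#'
#' @param text A string or character vector of single characters.
#' @param dictionaries A list of [term_dictionary()] objects with distinct
#'   names, in precedence order.
#' @return A character vector of dictionary tags, one per character.
#' @examples
#' d <- term_dictionary(c("上腹部"), "Dic_anatomy")
#' bidirectional_dict_tags("上腹部痛", list(d))
#' @export
bidirectional_dict_tags <- function(text, dictionaries) {
  cs <- if (length(text) > 1) text else chars(text)
  n <- length(cs)
  tags <- rep("O", n)
  if (n == 0) return(tags)
  nms <- vapply(dictionaries, function(d) d$name, character(1))
  if (anyDuplicated(nms)) abort("Dictionaries must have distinct names.")
  cand <- dplyr::bind_rows(lapply(seq_along(dictionaries), function(k) {
    fwd <- max_match(cs, dictionaries[[k]], "forward")
    bwd <- max_match(cs, dictionaries[[k]], "backward")
    fwd$dir <- 0L; bwd$dir <- 1L
    out <- dplyr::bind_rows(fwd, bwd)
    out$rank <- k
    out
  }))
  if (nrow(cand) == 0) return(tags)
  # same span found by both scans of one dictionary: keep the forward copy
  cand <- cand[!duplicated(cand[, c("start", "end", "name")]), , drop = FALSE]
  len <- cand$end - cand$start + 1L
  ord <- order(-len, cand$dir, cand$start, cand$rank)
  cand <- cand[ord, , drop = FALSE]
  taken <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):(cand$end[i] + 1L)
    if (any(taken[span])) next
    taken[span] <- TRUE
    nm <- cand$name[i]
    if (length(span) == 1L) {
      tags[span] <- paste0("S-", nm)
    } else {
      tags[span[1]] <- paste0("B-", nm)
      tags[span[length(span)]] <- paste0("E-", nm)
      if (length(span) > 2L) tags[span[-c(1, length(span))]] <- paste0("I-", nm)
    }
  }
  tags
}

#' The dictionary-feature tag alphabet for a set of dictionaries
#'
#' @param dictionaries A list of [term_dictionary()] objects (or their
#'   names).
#' @return Character vector `{B,I,E,S}-name` for each dictionary plus `"O"`.
#' @export
dict_tag_alphabet <- function(dictionaries) {
  nms <- vapply(dictionaries, function(d) if (is.character(d)) d else d$name,
                character(1))
  c(as.vector(vapply(nms, function(nm) paste0(c("B-", "I-", "E-", "S-"), nm),
                     character(4))), "O")
}
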