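#' Build a character vocabulary
#'
#' Maps characters to integer ids for the embedding layer. Ids 1 and 2 are
#' reserved for the padding token `<PAD>` and the unknown token `<UNK>`;
#' characters seen fewer than `min_count` times are excluded and map to
#' `<UNK>` at lookup time.
#'
#' @param x A character vector of texts, a sentences tibble (its `text`
#'   column is used), or a list of per-sentence character vectors.
#' @param min_count Minimum corpus frequency for a character to get its own
#'   id.
#' @return A `cner_vocab`: list with `tokens` (id-ordered, starting
#'   `<PAD>, <UNK>`) and `size`.
#' @examples
#' v <- build_vocab(c("腹部痛", "腹部"))
#' v$size
#' @export
build_vocab <- function(x, min_count = 1L) {
  if (is.data.frame(x)) x <- x$text
  if (is.list(x)) x <- vapply(x, paste, character(1), collapse = "")
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) == 0) abort("Empty corpus.")
  all_chars <- unlist(lapply(x, chars))
  uniq <- unique(all_chars)  # first-seen order: locale-independent
  counts <- tabulate(match(all_chars, uniq), nbins = length(uniq))
  new_vocab(uniq[counts >= min_count])
}

new_vocab <- function(tokens) {
  tokens <- c("<PAD>", "<UNK>", setdiff(tokens, c("<PAD>", "<UNK>")))
  idx <- new.env(hash = TRUE, parent = emptyenv(), size = length(tokens))
  for (i in seq_along(tokens)) assign(tokens[i], i, envir = idx)
  structure(list(tokens = tokens, size = length(tokens), index = idx),
            class = "cner_vocab")
}

#' @export
print.cner_vocab <- function(x, ...) {
  cat(sprintf("<cner_vocab: %d tokens (incl. <PAD>, <UNK>)>\n", x$size))
  invisible(x)
}

#' Look up vocabulary ids for tokens
#'
#' @param vocab A `cner_vocab`.
#' @param tokens Character vector of tokens.
#' @return Integer ids; unknown tokens map to the `<UNK>` id (2).
#' @export
lookup_ids <- function(vocab, tokens) {
  vapply(tokens, function(tk) {
    v <- get0(tk, envir = vocab$index, inherits = FALSE)
    if (is.null(v)) 2L else as.integer(v)
  }, integer(1), USE.NAMES = FALSE)
}

#' Load pre-trained character embeddings into a vocabulary-aligned matrix
#'
#' Reads a text embedding table (`token v1 ... v_d` per line; an optional
#' leading `count dim` header is tolerated) and returns one row per
#' vocabulary token. Tokens present in the file take their stored vector;
#' missing tokens are initialized with small uniform random values drawn
#' from `seed`, so two runs with the same seed agree everywhere and runs
#' with different seeds differ exactly on the missing rows. The `<PAD>` row
#' is all zeros.
#'
#' @param path Path to the embedding text file.
#' @param vocab A `cner_vocab`.
#' @param dim Expected embedding dimension; inferred from the file when
#'   `NULL`. A line with a different dimension is an error.
#' @param seed Integer seed for the random rows.
#' @return A numeric matrix of shape `vocab$size` x `dim`.
#' @export
load_pretrained_embeddings <- function(path, vocab, dim = NULL, seed = 1L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (length(parts) > 0 && length(parts[[1]]) == 2 &&
      !is.na(suppressWarnings(as.numeric(parts[[1]][2]))) &&
      !is.na(suppressWarnings(as.numeric(parts[[1]][1]))))
    parts <- parts[-1]
  if (length(parts) == 0) abort("Embedding file has no vectors.")
  dims <- lengths(parts) - 1L
  if (is.null(dim)) dim <- dims[1]
  if (any(dims != dim))
    abort(sprintf("Inconsistent embedding dimensions: expected %d, found %s.",
                  dim, paste(unique(dims[dims != dim]), collapse = ", ")))
  toks <- vapply(parts, `[`, "", 1)
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  E <- random_embedding(vocab$size, dim, seed)
  hit <- match(vocab$tokens, toks)
  for (i in which(!is.na(hit))) E[i, ] <- vecs[[hit[i]]]
  E[1, ] <- 0  # <PAD>
  E
}

# Small uniform init in [-sqrt(3/d), sqrt(3/d)]; <PAD> row zero.
random_embedding <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lim <- sqrt(3 / d)
  E <- matrix(runif(n * d, -lim, lim), nrow = n)
  E[1, ] <- 0
  E
}

#' Bundle embedding tables for characters and additional features
#'
#' @param char_vocab Character vocabulary ([build_vocab()]).
#' @param d_char Character embedding dimension (default 200).
#' @param feature_vocabs Named list of feature vocabularies (e.g. `dict`,
#'   `pos`), each a `cner_vocab` over the feature's tag alphabet.
#' @param d_feature Embedding dimension per additional feature (default
#'   100).
#' @param pretrained Optional pre-loaded `char` matrix (e.g. from
#'   [load_pretrained_embeddings()]).
#' @param seed Integer seed for random initialization.
#' @return An `embedding_bank`: list with `char` matrix and one matrix per
#'   feature vocabulary.
#' @export
embedding_bank <- function(char_vocab, d_char = 200L, feature_vocabs = list(),
                           d_feature = 100L, pretrained = NULL, seed = 1L) {
  set.seed(seed)
  char <- if (!is.null(pretrained)) {
    stopifnot(nrow(pretrained) == char_vocab$size)
    pretrained
  } else random_embedding(char_vocab$size, d_char)
  feats <- lapply(feature_vocabs, function(v) random_embedding(v$size, d_feature))
  structure(c(list(char = char), feats), class = "embedding_bank")
}

vocab_from_alphabet <- function(alphabet) new_vocab(alphabet)
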