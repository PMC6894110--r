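# Independent brute-force oracles used to check the fast implementations.
# These deliberately share no code with the package internals: dictionary
# matching enumerates every substring with a plain %in%, and the CRF oracles
# enumerate every tag path explicitly.

chars_of <- function(x) strsplit(enc2utf8(x), "")[[1]]

# All (start, end, 0-based inclusive) substrings of cs present in `terms`.
oracle_substring_matches <- function(cs, terms) {
  n <- length(cs)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (paste(cs[i:j], collapse = "") %in% terms)
      out[[length(out) + 1L]] <- c(i - 1L, j - 1L)
  }
  out
}

# Greedy longest-at-position from the exhaustive table.
oracle_max_match <- function(cs, terms, direction = "forward") {
  tab <- oracle_substring_matches(cs, terms)
  n <- length(cs)
  res <- list()
  if (direction == "forward") {
    i <- 0L
    while (i < n) {
      ends <- vapply(tab, function(m) if (m[1] == i) m[2] else -1L, integer(1))
      if (length(ends) && max(ends) >= 0L) {
        res[[length(res) + 1L]] <- c(i, max(ends))
        i <- max(ends) + 1L
      } else i <- i + 1L
    }
  } else {
    j <- n - 1L
    while (j >= 0L) {
      starts <- vapply(tab, function(m) if (m[2] == j) m[1] else .Machine$integer.max,
                       integer(1))
      if (length(starts) && min(starts) < .Machine$integer.max) {
        res[[length(res) + 1L]] <- c(min(starts), j)
        j <- min(starts) - 1L
      } else j <- j - 1L
    }
  }
  res
}

# Bi-directional merge with the same precedence cascade, from the oracles.
oracle_bidi_tags <- function(cs, dict_list) {
  n <- length(cs)
  cand <- data.frame(start = integer(0), end = integer(0), name = character(0),
                     dir = integer(0), rank = integer(0))
  for (k in seq_along(dict_list)) {
    d <- dict_list[[k]]
    for (m in oracle_max_match(cs, d$terms, "forward"))
      cand <- rbind(cand, data.frame(start = m[1], end = m[2], name = d$name,
                                     dir = 0L, rank = k))
    for (m in oracle_max_match(cs, d$terms, "backward"))
      cand <- rbind(cand, data.frame(start = m[1], end = m[2], name = d$name,
                                     dir = 1L, rank = k))
  }
  tags <- rep("O", n)
  if (nrow(cand) == 0) return(tags)
  cand <- cand[!duplicated(cand[, c("start", "end", "name")]), , drop = FALSE]
  len <- cand$end - cand$start + 1L
  cand <- cand[order(-len, cand$dir, cand$start, cand$rank), , drop = FALSE]
  taken <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):(cand$end[i] + 1L)
    if (any(taken[span])) next
    taken[span] <- TRUE
    nm <- cand$name[i]
    if (length(span) == 1L) tags[span] <- paste0("S-", nm)
    else {
      tags[span[1]] <- paste0("B-", nm)
      tags[span[length(span)]] <- paste0("E-", nm)
      if (length(span) > 2L) tags[span[-c(1, length(span))]] <- paste0("I-", nm)
    }
  }
  tags
}

# ---- CRF enumeration oracles --------------------------------------------

enum_paths <- function(n, k) as.matrix(expand.grid(rep(list(seq_len(k)), n)))

oracle_path_score <- function(S, Trans, y) {
  n <- nrow(S); K <- ncol(S)
  sc <- Trans[K + 1L, y[1]]
  for (i in seq_len(n)) sc <- sc + S[i, y[i]]
  if (n > 1) for (i in seq_len(n - 1L)) sc <- sc + Trans[y[i], y[i + 1L]]
  sc + Trans[y[n], K + 2L]
}

oracle_all_scores <- function(S, Trans) {
  P <- enum_paths(nrow(S), ncol(S))
  apply(P, 1, function(y) oracle_path_score(S, Trans, y))
}

oracle_log_partition <- function(S, Trans) {
  sc <- oracle_all_scores(S, Trans)
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

random_crf_instance <- function(n, k) {
  list(S = matrix(runif(n * k, -2, 2), n, k),
       Trans = matrix(runif((k + 2)^2, -1, 1), k + 2, k + 2))
}

# ---- shared fixtures -----------------------------------------------------

# Random CJK-ish text + mentions for round-trip tests (independent of the
# package generator).
random_tagged_sentence <- function(types = c("AP", "Drug")) {
  n <- sample(3:20, 1)
  pos <- 0L
  starts <- integer(0); ends <- integer(0); tys <- character(0)
  while (pos < n) {
    if (runif(1) < 0.4 && n - pos >= 1) {
      len <- sample(1:min(4, n - pos), 1)
      starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
      tys <- c(tys, sample(types, 1))
      pos <- pos + len + sample(0:2, 1)
    } else pos <- pos + 1L
  }
  keep <- ends <= n - 1L
  list(n = n, mentions = tibble::tibble(start = starts[keep], end = ends[keep],
                                        type = tys[keep]))
}

# A tiny fast model configuration for training-path tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(d_char = 16, d_feature = 8, lstm_hidden = 12, d_attn = 12,
                   dropout = 0.2)
  do.call(model_config, utils::modifyList(defaults, args))
}

# One-clause-per-record corpus from split sentences.
sentences_as_records <- function(sent) {
  cner:::new_corpus(tibble::tibble(record_id = sent$sentence_id,
                                   text = sent$text, mentions = sent$mentions))
}
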