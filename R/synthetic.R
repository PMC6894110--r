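#' Specification for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the tagger assumes in
#' clinical records, without any licensed data: five entity types with the
#' standard clinical distribution (anatomical part 52%, symptom description
#' 14%, independent symptom 20%, drug 7%, operation 7%), short
#' comma-delimited clauses whose lengths follow a truncated log-normal
#' (mean about 15 characters, capped at 176), contextual keyword cues
#' around operation entities (a prefix character before and a suffix
#' character ending the mention, mirroring the fixed "undergo"/"surgery"
#' keywords of real operation mentions), nested-term ambiguity (anatomy
#' surfaces that are proper prefixes of operation surfaces), and feature
#' dictionaries that cover only part of the entity vocabulary. Records are
#' split into a train and a test portion, and test-split entities are drawn
#' from an out-of-vocabulary surface pool at rate `oov_entity_rate` to
#' emulate unseen mentions.
#'
#' Entity surfaces use real CJK code points but carry no linguistic
#' meaning; each entity type draws from its own code-point pool, disjoint
#' from the filler pool.
#'
#' @param n_records Number of records.
#' @param types Entity types.
#' @param type_proportions Named fractions summing to 1; the probability of
#'   each type per generated mention.
#' @param entity_length_ranges Named list of `c(min, max)` surface lengths.
#' @param entities_per_type Named sizes of the per-type surface
#'   vocabularies.
#' @param clause_len_meanlog,clause_len_sdlog,clause_len_max Log-normal
#'   parameters and cap for the clause length in characters.
#' @param clauses_per_record `c(min, max)` clauses per record.
#' @param entities_per_clause_lambda Poisson mean for mentions per clause
#'   (truncated at 3).
#' @param keyword_cue_prob Probability that an operation mention carries
#'   its keyword cues.
#' @param cue_prefix,cue_suffix The cue characters.
#' @param dictionary_coverage Fraction of each entity vocabulary included
#'   in the corresponding feature dictionary.
#' @param distractor_frac Distractor terms added to each dictionary, as a
#'   fraction of its size.
#' @param oov_entity_rate Probability that a test-split mention uses an
#'   out-of-vocabulary surface.
#' @param train_frac Fraction of records in the train split.
#' @param seed Integer seed; every generated artifact is a pure function of
#'   `(spec, seed)`.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(
    n_records = 100L,
    types = ccks2018_types(),
    type_proportions = c(AP = 0.52, SD = 0.14, IS = 0.20, Drug = 0.07,
                         Operation = 0.07),
    entity_length_ranges = list(AP = c(2, 4), SD = c(2, 3), IS = c(2, 4),
                                Drug = c(2, 5), Operation = c(4, 8)),
    entities_per_type = c(AP = 60, SD = 25, IS = 35, Drug = 35, Operation = 35),
    clause_len_meanlog = log(15) - 0.45^2 / 2, clause_len_sdlog = 0.45,
    clause_len_max = 176L,
    clauses_per_record = c(3L, 8L),
    entities_per_clause_lambda = 1.2,
    keyword_cue_prob = 0.9,
    cue_prefix = "行", cue_suffix = "术",
    dictionary_coverage = 0.7, distractor_frac = 0.2,
    oov_entity_rate = 0.2, train_frac = 0.6, seed = 1L) {
  stopifnot(setequal(names(type_proportions), types),
            abs(sum(type_proportions) - 1) <= 1e-9,
            all(type_proportions >= 0), all(type_proportions <= 1),
            dictionary_coverage >= 0, dictionary_coverage <= 1,
            oov_entity_rate >= 0, oov_entity_rate <= 1,
            train_frac >= 0, train_frac <= 1)
  structure(as.list(environment()), class = "generator_spec")
}

# Disjoint code-point pools: filler from one CJK block, each entity type
# from its own block, cue characters outside all pools.
filler_pool <- function() 0x4E00:0x4EFF

type_pool <- function(type_index) {
  start <- 0x5100L + (type_index - 1L) * 0x200L
  start:(start + 199L)
}

rand_string <- function(pool, len) intToUtf8(pool[sample.int(length(pool), len,
                                                             replace = TRUE)])

#' Generate the per-type entity surface vocabulary
#'
#' Draws each type's surfaces from its own CJK code-point pool with the
#' configured length range. Operation surfaces end with the cue suffix with
#' probability `keyword_cue_prob`, and a few operation surfaces are
#' constructed as `<anatomy surface><...><suffix>` so that an anatomy term
#' is a proper prefix of an operation term — the nested-term ambiguity the
#' attention layer is meant to resolve.
#'
#' @param spec A [generator_spec()].
#' @param oov Generate the held-out out-of-vocabulary pool instead (same
#'   structure, disjoint surfaces).
#' @return Named list: type to character vector of surfaces.
#' @export
gen_entity_vocab <- function(spec, oov = FALSE) {
  set.seed(spec$seed + if (oov) 1000003L else 0L)
  vocab <- setNames(vector("list", length(spec$types)), spec$types)
  for (i in seq_along(spec$types)) {
    ty <- spec$types[i]
    rng <- spec$entity_length_ranges[[ty]]
    n_i <- spec$entities_per_type[[ty]]
    pool <- type_pool(i)
    surf <- vapply(seq_len(n_i), function(k) {
      len <- sample(rng[1]:rng[2], 1)
      s <- rand_string(pool, len)
      if (ty == "Operation" && runif(1) < spec$keyword_cue_prob)
        s <- paste0(substr(s, 1, len - 1), spec$cue_suffix)
      s
    }, character(1))
    vocab[[ty]] <- unique(surf)
  }
  if (all(c("AP", "Operation") %in% spec$types)) {
    ap <- vocab$AP[seq_len(min(3, length(vocab$AP)))]
    nested <- paste0(ap, vapply(seq_along(ap), function(k)
      rand_string(type_pool(match("Operation", spec$types)), 2), character(1)),
      spec$cue_suffix)
    vocab$Operation <- unique(c(nested, vocab$Operation))
  }
  vocab
}

gen_clause <- function(spec, vocab, oov_vocab, is_test) {
  L <- min(max(5, round(exp(rnorm(1, spec$clause_len_meanlog,
                                  spec$clause_len_sdlog)))), spec$clause_len_max)
  k <- min(rpois(1, spec$entities_per_clause_lambda), 3L)
  tys <- if (k > 0)
    spec$types[sample.int(length(spec$types), k, replace = TRUE,
                          prob = spec$type_proportions[spec$types])]
  else character(0)
  pieces <- character(0)
  starts <- integer(0); ends <- integer(0); etypes <- character(0)
  pos <- 0L
  budget <- L
  fill <- function(len) if (len > 0) rand_string(filler_pool(), len) else ""
  n_gaps <- k + 1L
  for (j in seq_len(k)) {
    ty <- tys[j]
    pool_v <- if (is_test && runif(1) < spec$oov_entity_rate)
      oov_vocab[[ty]] else vocab[[ty]]
    surf <- pool_v[sample.int(length(pool_v), 1)]
    cue <- ty == "Operation" && runif(1) < spec$keyword_cue_prob
    gap <- max(1L, round(budget / n_gaps) - n_chars(surf) - as.integer(cue))
    f <- fill(gap)
    pieces <- c(pieces, f)
    pos <- pos + n_chars(f)
    if (cue) { pieces <- c(pieces, spec$cue_prefix); pos <- pos + 1L }
    pieces <- c(pieces, surf)
    starts <- c(starts, pos)
    ends <- c(ends, pos + n_chars(surf) - 1L)
    etypes <- c(etypes, ty)
    pos <- pos + n_chars(surf)
  }
  tail_len <- max(1L, L - pos)
  pieces <- c(pieces, fill(tail_len))
  text <- paste(pieces, collapse = "")
  list(text = text,
       mentions = tibble(surface = if (length(starts)) vapply(seq_along(starts),
         function(m) substr(text, starts[m] + 1L, ends[m] + 1L), character(1))
         else character(0),
         start = starts, end = ends, type = etypes))
}

#' Generate a synthetic annotated corpus with feature dictionaries
#'
#' Draws `n_records` records of comma-delimited clauses with embedded,
#' exactly-offset entity mentions under the structure described in
#' [generator_spec()], plus anatomy/drug/operation term dictionaries
#' covering `dictionary_coverage` of the corresponding entity vocabularies
#' (with added distractor terms).
#'
#' @param spec A [generator_spec()].
#' @return A list with `corpus` (a corpus tibble with an extra `split`
#'   column), `dictionaries` (list of [term_dictionary()]), `entity_vocab`
#'   and `oov_vocab`.
#' @examples
#' sim <- gen_corpus(generator_spec(n_records = 5, seed = 7))
#' corpus_stats(sim$corpus)
#' @export
gen_corpus <- function(spec) {
  vocab <- gen_entity_vocab(spec)
  oov_vocab <- gen_entity_vocab(spec, oov = TRUE)
  oov_vocab <- lapply(setNames(spec$types, spec$types), function(ty)
    setdiff(oov_vocab[[ty]], vocab[[ty]]))
  set.seed(spec$seed + 2L)
  n_train <- ceiling(spec$train_frac * spec$n_records)
  recs <- vector("list", spec$n_records)
  for (r in seq_len(spec$n_records)) {
    is_test <- r > n_train
    n_cl <- sample(spec$clauses_per_record[1]:spec$clauses_per_record[2], 1)
    texts <- character(n_cl)
    ms <- vector("list", n_cl)
    off <- 0L
    for (ci in seq_len(n_cl)) {
      cl <- gen_clause(spec, vocab, oov_vocab, is_test)
      texts[ci] <- cl$text
      m <- cl$mentions
      m$start <- m$start + off
      m$end <- m$end + off
      ms[[ci]] <- m
      off <- off + n_chars(cl$text) + 1L  # +1 for the delimiter
    }
    text <- paste0(paste(texts, collapse = "，"), "。")
    rec <- parse_annotations(text, dplyr::bind_rows(ms),
                             record_id = sprintf("r%04d", r), types = spec$types)
    rec$split <- if (is_test) "test" else "train"
    recs[[r]] <- rec
  }
  corpus <- new_corpus(dplyr::bind_rows(recs))

  dict_name <- c(AP = "Dic_anatomy", Drug = "Dic_drug", Operation = "Dic_operation")
  dicts <- list()
  for (ty in intersect(names(dict_name), spec$types)) {
    terms <- vocab[[ty]]
    n_keep <- max(1L, round(spec$dictionary_coverage * length(terms)))
    kept <- terms[sample.int(length(terms), n_keep)]
    n_dis <- ceiling(spec$distractor_frac * n_keep)
    distract <- vapply(seq_len(n_dis), function(k)
      rand_string(filler_pool(), sample(2:4, 1)), character(1))
    dicts[[dict_name[[ty]]]] <- term_dictionary(c(kept, distract), dict_name[[ty]])
  }
  list(corpus = corpus, dictionaries = unname(dicts), entity_vocab = vocab,
       oov_vocab = oov_vocab, spec = spec)
}

#' Entity distribution of a corpus
#'
#' Per-type mention counts and percentages, the summary used to check a
#' generated corpus against its target distribution.
#'
#' @param corpus A corpus tibble.
#' @param types Optional type ordering.
#' @return A tibble with columns `type`, `count`, `pct`.
#' @export
corpus_stats <- function(corpus, types = NULL) {
  all_m <- dplyr::bind_rows(corpus$mentions)
  types <- types %||% (if (nrow(all_m)) unique(all_m$type) else character(0))
  counts <- vapply(types, function(ty) sum(all_m$type == ty), integer(1))
  total <- sum(counts)
  tibble(type = types, count = unname(counts),
         pct = if (total > 0) unname(100 * counts / total) else rep(0, length(types)))
}
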