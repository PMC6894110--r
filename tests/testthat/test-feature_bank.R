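test_that("term dictionaries deduplicate, skip blanks, and reject empty input", {
  d <- term_dictionary(c("上腹部", "腹部", "腹部", ""), "Dic_anatomy")
  expect_equal(sort(d$terms), sort(c("上腹部", "腹部")))
  expect_equal(d$max_len, 3L)
  expect_error(term_dictionary(character(0), "Dic_x"), "empty")

  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("上腹部", "", "腹部", "腹部"), p)
  d2 <- load_dictionary(p, "Dic_anatomy")
  expect_equal(sort(d2$terms), sort(c("上腹部", "腹部")))
  writeLines(c("", "  "), p)
  expect_error(load_dictionary(p, "Dic_x"), "empty")
})

test_that("a large synthetic dictionary records the correct max term length", {
  set.seed(2)
  terms <- vapply(1:800, function(i)
    intToUtf8(sample(0x4E00:0x4FFF, sample(2:7, 1), replace = TRUE)), character(1))
  d <- term_dictionary(terms, "Dic_drug")
  expect_equal(d$max_len, max(nchar(unique(terms[nzchar(terms)]))))
})

test_that("maximum matching takes the longest term at each position", {
  d <- term_dictionary(c("上腹部", "腹部"), "Dic_anatomy")
  m <- max_match("上腹部痛", d, "forward")
  expect_equal(m$start, 0L); expect_equal(m$end, 2L)
  d2 <- term_dictionary("腹部", "Dic_anatomy")
  m2 <- max_match("上腹部痛", d2, "forward")
  expect_equal(m2$start, 1L); expect_equal(m2$end, 2L)
  expect_equal(nrow(max_match("xyz", d, "forward")), 0L)
  # backward scan prefers terms ending at the scan position
  d3 <- term_dictionary(c("ab", "bc"), "Dic_x")
  expect_equal(max_match("abc", d3, "forward")$start, 0L)
  expect_equal(max_match("abc", d3, "backward")$start, 1L)
})

test_that("max_match agrees with the exhaustive substring oracle", {
  set.seed(13)
  pool <- c("甲", "乙", "丙", "丁", "戊")
  for (rep in 1:120) {
    cs <- sample(pool, sample(3:12, 1), replace = TRUE)
    terms <- unique(vapply(1:sample(2:6, 1), function(i) {
      s <- sample(seq_along(cs), 1); l <- sample(1:3, 1)
      paste(cs[s:min(s + l, length(cs))], collapse = "")
    }, character(1)))
    d <- term_dictionary(terms, "Dic_x")
    for (dir in c("forward", "backward")) {
      got <- max_match(cs, d, dir)
      want <- oracle_max_match(cs, d$terms, dir)
      want <- if (length(want)) do.call(rbind, want)[, 1:2, drop = FALSE] else
        matrix(integer(0), 0, 2)
      want <- want[order(want[, 1]), , drop = FALSE]
      expect_equal(got$start, unname(want[, 1]))
      expect_equal(got$end, unname(want[, 2]))
    }
  }
})

test_that("bidirectional dictionary tags encode merged matches in B/I/E/S + name", {
  d <- term_dictionary("上腹部", "Dic_anatomy")
  expect_equal(bidirectional_dict_tags("上腹部", list(d)),
               c("B-Dic_anatomy", "I-Dic_anatomy", "E-Dic_anatomy"))
  expect_equal(bidirectional_dict_tags("某某某", list(d)), c("O", "O", "O"))
  # single-character match is S
  d1 <- term_dictionary("痛", "Dic_anatomy")
  expect_equal(bidirectional_dict_tags("头痛", list(d1)), c("O", "S-Dic_anatomy"))
  expect_error(bidirectional_dict_tags("x", list(d, d)), "distinct")
})

test_that("bidirectional tags match the all-substrings oracle with the same precedence", {
  set.seed(17)
  pool <- c("甲", "乙", "丙", "丁")
  for (rep in 1:100) {
    cs <- sample(pool, sample(4:12, 1), replace = TRUE)
    mk_terms <- function() unique(vapply(1:sample(2:5, 1), function(i) {
      s <- sample(seq_along(cs), 1); l <- sample(0:2, 1)
      paste(cs[s:min(s + l, length(cs))], collapse = "")
    }, character(1)))
    dicts <- list(term_dictionary(mk_terms(), "Dic_a"),
                  term_dictionary(mk_terms(), "Dic_b"))
    got <- bidirectional_dict_tags(cs, dicts)
    want <- oracle_bidi_tags(cs, lapply(dicts, function(d)
      list(name = d$name, terms = d$terms)))
    expect_equal(got, want)
  }
})

test_that("dictionary tag sequences are well-formed and length-preserving", {
  set.seed(23)
  pool <- c("甲", "乙", "丙")
  for (rep in 1:60) {
    cs <- sample(pool, sample(3:15, 1), replace = TRUE)
    terms <- unique(replicate(4, paste(sample(pool, sample(1:3, 1), replace = TRUE),
                                       collapse = "")))
    tags <- bidirectional_dict_tags(cs, list(term_dictionary(terms, "Dic_a")))
    expect_length(tags, length(cs))
    # every B is closed by an E of the same dictionary before any new span
    expect_silent(decode_bieso(tags, repair = "strict"))
  }
})

test_that("POS tags broadcast from words to characters", {
  tg <- function(text) tibble::tibble(word = c("腹部", "痛"), tag = c("n", "v"))
  expect_equal(pos_tags_per_char("腹部痛", tg), c("n", "n", "v"))
  expect_equal(pos_tags_per_char("腹部痛", NULL), rep("NONE", 3))
  bad <- function(text) tibble::tibble(word = "腹部", tag = "n")
  expect_error(pos_tags_per_char("腹部痛", bad), "cover")
})

test_that("the toy tagger is deterministic and always covers its input", {
  tg <- toy_pos_tagger()
  txt <- "患者上腹部不适CERBB-2(2+)"
  seg1 <- tg(txt); seg2 <- tg(txt)
  expect_equal(seg1, seg2)
  expect_equal(paste(seg1$word, collapse = ""), txt)
  expect_length(pos_tags_per_char(txt, tg), nchar(txt))
})

test_that("vocabulary reserves PAD and UNK and applies the frequency cutoff", {
  v <- build_vocab(c("aba", "c"), min_count = 1)
  expect_equal(v$size, 5L)  # a, b, c + 2 reserved
  expect_equal(v$tokens[1:2], c("<PAD>", "<UNK>"))
  v2 <- build_vocab(c("aba", "c"), min_count = 10)
  expect_equal(v2$size, 2L)
  expect_error(build_vocab(character(0)), "Empty")
  # rare characters map to <UNK> at lookup
  v3 <- build_vocab(c("aab"), min_count = 2)
  expect_equal(lookup_ids(v3, c("a", "b")), c(3L, 2L))
  # id -> token -> id round-trips for every in-vocab character
  v4 <- build_vocab(c("xyzzy", "abc"))
  ids <- lookup_ids(v4, v4$tokens[-(1:2)])
  expect_equal(v4$tokens[ids], v4$tokens[-(1:2)])
})

test_that("pretrained embeddings fill stored vectors and seed the missing rows", {
  p <- withr::local_tempfile(fileext = ".vec")
  v <- build_vocab(c("abc"))
  writeLines(c("3 4", "a 1 2 3 4", "b 0 0 0 1"), p)
  E1 <- load_pretrained_embeddings(p, v, seed = 1)
  expect_equal(dim(E1), c(5L, 4L))
  expect_equal(E1[lookup_ids(v, "a"), ], c(1, 2, 3, 4))
  expect_equal(E1[1, ], rep(0, 4))  # <PAD>
  E2 <- load_pretrained_embeddings(p, v, seed = 2)
  # stored rows identical across seeds; missing rows differ
  expect_equal(E1[lookup_ids(v, "b"), ], E2[lookup_ids(v, "b"), ])
  expect_false(isTRUE(all.equal(E1[lookup_ids(v, "c"), ],
                                E2[lookup_ids(v, "c"), ])))
  # same seed reproduces everything
  expect_identical(E1, load_pretrained_embeddings(p, v, seed = 1))
  writeLines(c("a 1 2", "b 1 2 3"), p)
  expect_error(load_pretrained_embeddings(p, v), "Inconsistent")
})

test_that("embedding bank shapes follow the vocabularies and dimensions", {
  v <- build_vocab("abcd")
  fv <- list(dict = cner:::vocab_from_alphabet(dict_tag_alphabet(list("Dic_a"))))
  bank <- embedding_bank(v, d_char = 20, feature_vocabs = fv, d_feature = 10)
  expect_equal(dim(bank$char), c(v$size, 20L))
  expect_equal(dim(bank$dict), c(fv$dict$size, 10L))
})
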