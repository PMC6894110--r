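test_that("parse_annotations validates offsets against the text slice", {
  txt <- "患者1个月前无明显诱因出现上腹部不适"
  co <- parse_annotations(txt, tibble::tibble(
    surface = c("上腹部", "不适"), start = c(13, 16), end = c(15, 17),
    type = c("AP", "SD")))
  m <- co$mentions[[1]]
  expect_equal(m$start, c(13L, 16L))
  expect_equal(m$end, c(15L, 17L))
  expect_equal(m$surface, c("上腹部", "不适"))

  # wrong surface for the slice
  expect_error(parse_annotations(txt, tibble::tibble(
    surface = "腹部", start = 13, end = 15, type = "AP")), "mismatch")
  # out of range
  expect_error(parse_annotations("abc", tibble::tibble(
    start = 1, end = 5, type = "AP")), "out of range")
  expect_error(parse_annotations("abc", tibble::tibble(
    start = -1, end = 1, type = "AP")), "out of range")
  # overlap
  expect_error(parse_annotations("abcdef", tibble::tibble(
    start = c(0, 2), end = c(3, 4), type = c("AP", "AP"))), "Overlap")
  # unknown type against a configured set
  expect_error(parse_annotations("abc", tibble::tibble(
    start = 0, end = 1, type = "Foo"), types = c("AP")), "Unknown entity type")
  # empty mention list is fine
  expect_equal(nrow(parse_annotations("abc")$mentions[[1]]), 0L)
})

test_that("short mode splits on commas and periods, long mode on periods only", {
  co <- parse_annotations("ABC，DE。FG",
                          tibble::tibble(start = c(0, 4), end = c(1, 5),
                                         type = c("AP", "Drug")))
  s <- split_sentences(co, mode = "short")
  expect_equal(s$text, c("ABC", "DE", "FG"))
  expect_equal(s$origin_offset, c(0L, 4L, 7L))
  # remapped mention offsets
  expect_equal(s$mentions[[2]]$start, 0L)
  expect_equal(s$mentions[[2]]$end, 1L)

  l <- split_sentences(co, mode = "long")
  expect_equal(l$text, c("ABC，DE", "FG"))

  # ASCII delimiters split too; semicolons do not
  s2 <- split_sentences(parse_annotations("ab,cd.e；f"))
  expect_equal(s2$text, c("ab", "cd", "e；f"))

  # no delimiters: one sentence equal to the record
  s3 <- split_sentences(parse_annotations("abcdef"))
  expect_equal(s3$text, "abcdef")
})

test_that("sentence concatenation with delimiters reconstructs every record", {
  set.seed(41)
  sim <- gen_corpus(generator_spec(n_records = 25, seed = 5))
  for (mode in c("short", "long")) {
    s <- split_sentences(sim$corpus, mode = mode, max_len = 1000)
    rec <- unsplit_sentences(s)
    expect_equal(rec$text[match(sim$corpus$record_id, rec$record_id)],
                 sim$corpus$text)
  }
  # consecutive and leading delimiters are preserved
  odd <- parse_annotations("，ab，，cd。")
  s <- split_sentences(odd)
  expect_equal(unsplit_sentences(s)$text, "，ab，，cd。")
})

test_that("a mention crossing a clause boundary errors, or falls back to long mode", {
  co <- parse_annotations("ab，cd", tibble::tibble(start = 1, end = 3, type = "AP"))
  expect_error(split_sentences(co, mode = "short"), "crosses")
  fb <- split_sentences(co, mode = "short", cross_mention = "fallback_long")
  expect_equal(fb$text, "ab，cd")
  expect_equal(nrow(fb$mentions[[1]]), 1L)
  # crossing a period fails even in fallback
  co2 <- parse_annotations("ab。cd", tibble::tibble(start = 1, end = 3, type = "AP"))
  expect_error(split_sentences(co2, cross_mention = "fallback_long"), "crosses")
})

test_that("over-long sentences are truncated with a warning and late mentions dropped", {
  txt <- paste(rep("a", 10), collapse = "")
  co <- parse_annotations(txt, tibble::tibble(start = 8, end = 9, type = "AP"))
  expect_warning(expect_warning(
    s <- split_sentences(co, max_len = 5), "truncated"), "dropped")
  expect_equal(nchar(s$text), 5L)
  expect_equal(nrow(s$mentions[[1]]), 0L)
})

test_that("BIESO encoding follows the scheme for each mention length", {
  expect_equal(encode_bieso(tibble::tibble(start = 0, end = 2, type = "AP"), 4),
               c("B-AP", "I-AP", "E-AP", "O"))
  expect_equal(encode_bieso(tibble::tibble(start = 1, end = 2, type = "Drug"), 3),
               c("O", "B-Drug", "E-Drug"))
  expect_equal(encode_bieso(tibble::tibble(start = 2, end = 2, type = "SD"), 3),
               c("O", "O", "S-SD"))
  expect_equal(encode_bieso(NULL, 3), c("O", "O", "O"))
  expect_error(encode_bieso(tibble::tibble(start = c(0, 1), end = c(1, 2),
                                           type = c("AP", "AP")), 4), "Overlap")
})

test_that("BIESO decoding inverts encoding and handles malformed input", {
  m <- decode_bieso(c("B-AP", "I-AP", "E-AP", "O"))
  expect_equal(m$start, 0L); expect_equal(m$end, 2L); expect_equal(m$type, "AP")
  expect_equal(nrow(decode_bieso(c("I-AP", "O"), repair = "conservative")), 0L)
  expect_error(decode_bieso(c("I-AP", "O"), repair = "strict"), "Malformed")
  expect_error(decode_bieso(c("B-AP", "O"), repair = "strict"), "Malformed")
  expect_error(decode_bieso(c("B-AP", "I-Drug", "E-AP"), repair = "strict"))
  s2 <- decode_bieso(c("S-Drug", "S-Drug"))
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$start, c(0L, 1L)); expect_equal(s2$end, c(0L, 1L))
  # conservative keeps the well-formed spans around junk
  m3 <- decode_bieso(c("E-AP", "S-AP", "B-AP", "I-AP", "O", "B-AP", "E-AP"),
                     repair = "conservative")
  expect_equal(m3$start, c(1L, 5L))
  expect_equal(m3$end, c(1L, 6L))
})

test_that("encode/decode round-trips random mention layouts exactly", {
  set.seed(7)
  for (rep in 1:200) {
    x <- random_tagged_sentence()
    tags <- encode_bieso(x$mentions, x$n)
    back <- decode_bieso(tags, repair = "strict")
    expect_equal(back[, c("start", "end", "type")],
                 x$mentions[order(x$mentions$start), c("start", "end", "type")],
                 ignore_attr = TRUE)
  }
})

test_that("column files round-trip and reject ragged or unknown-tag input", {
  p <- withr::local_tempfile(fileext = ".txt")
  x <- tibble::tibble(sentence_id = c("s1", "s2"),
                      chars = list(c("上", "腹", "部"), c("不", "适")),
                      tags = list(c("B-AP", "I-AP", "E-AP"), c("B-SD", "E-SD")))
  write_column_file(x, p)
  y <- read_column_file(p)
  expect_equal(y$chars, x$chars)
  expect_equal(y$tags, x$tags)
  # four-column variant with features
  x$dict_tags <- list(c("B-Dic_anatomy", "I-Dic_anatomy", "E-Dic_anatomy"),
                      c("O", "O"))
  x$pos_tags <- list(c("n", "n", "n"), c("v", "v"))
  write_column_file(x, p)
  y4 <- read_column_file(p)
  expect_equal(y4$dict_tags, x$dict_tags)
  expect_equal(y4$pos_tags, x$pos_tags)

  writeLines(c("a B-AP", "b"), p)
  expect_error(read_column_file(p), "columns")
  writeLines(c("a B-Foo"), p)
  expect_error(read_column_file(p, alphabet = tag_alphabet("AP")), "unknown tag")
  # empty file
  writeLines(character(0), p)
  expect_equal(nrow(read_column_file(p)), 0L)
})

test_that("annotation files round-trip through write and read", {
  sim <- gen_corpus(generator_spec(n_records = 10, seed = 9))
  p <- withr::local_tempfile(fileext = ".txt")
  write_annotations(sim$corpus, p)
  back <- read_annotations(p)
  expect_equal(back$text, sim$corpus$text)
  for (i in seq_len(nrow(back)))
    expect_equal(back$mentions[[i]], sim$corpus$mentions[[i]])
})
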