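test_that("input width follows the enabled feature embeddings", {
  expect_equal(cner:::cfg_d_in(model_config()), 200L)
  expect_equal(cner:::cfg_d_in(model_config(use_dict = TRUE, use_pos = TRUE)),
               400L)
  expect_equal(cner:::cfg_d_in(model_config(use_dict = TRUE)), 300L)
  # tag alphabet size: 4 positional tags per type plus O
  expect_length(tag_alphabet(ccks2018_types()), 21L)
})

test_that("attention scores are bounded by tanh and masked outside the window", {
  set.seed(71)
  R <- matrix(rnorm(8 * 3), 8, 3)
  w <- rnorm(6)
  e <- attention_scores(R, w, r = Inf)
  expect_true(all(is.finite(e)))
  expect_true(all(e >= -1 & e <= 1))
  # r = 0: only the diagonal is finite
  e0 <- attention_scores(R, w, r = 0)
  expect_true(all(is.finite(diag(e0))))
  expect_true(all(e0[row(e0) != col(e0)] == -Inf))
  # window |t-j| <= r
  e2 <- attention_scores(R, w, r = 2)
  idx <- abs(outer(1:8, 1:8, "-"))
  expect_true(all(is.infinite(e2[idx > 2])))
  expect_true(all(is.finite(e2[idx <= 2])))
  # masked columns are -Inf for every row
  em <- attention_scores(R, w, mask = c(rep(TRUE, 6), FALSE, FALSE))
  expect_true(all(em[, 7:8] == -Inf))
})

test_that("attention weights are a row softmax with exact zeros off-window", {
  expect_equal(attention_weights(matrix(0.3, 1, 1)), matrix(1))
  # constant scores over a k-wide window give uniform weights 1/k
  e <- matrix(-Inf, 5, 5)
  for (t in 1:5) for (j in max(1, t - 1):min(5, t + 1)) e[t, j] <- 0.42
  A <- attention_weights(e)
  expect_equal(A[2, 1:3], rep(1 / 3, 3))
  expect_equal(A[1, 1:2], rep(1 / 2, 2))
  expect_true(all(A[e == -Inf] == 0))
  # random scores match a direct exp/sum computation
  set.seed(73)
  er <- matrix(rnorm(36), 6, 6)
  Ar <- attention_weights(er)
  direct <- t(apply(er, 1, function(x) exp(x) / sum(exp(x))))
  expect_equal(Ar, direct, tolerance = 1e-9)
  expect_equal(unname(rowSums(Ar)), rep(1, 6), tolerance = 1e-9)
  expect_error(attention_weights(matrix(-Inf, 2, 2)), "masked")
})

test_that("attention fusion is the weighted context concatenated and squashed", {
  set.seed(79)
  n <- 5; dh <- 4; dz <- 3
  H <- matrix(rnorm(n * dh), n, dh)
  W_z <- matrix(rnorm(2 * dh * dz), 2 * dh, dz)
  # identity weights: context equals the hidden states
  out <- attention_fuse(diag(n), H, W_z)
  expect_equal(out$C, H)
  expect_equal(out$Z, tanh(cbind(H, H) %*% W_z))
  # uniform weights: context is the window mean
  A <- matrix(1 / n, n, n)
  expect_equal(attention_fuse(A, H, W_z)$C,
               matrix(colMeans(H), n, dh, byrow = TRUE))
  # random weights vs an explicit loop
  A2 <- attention_weights(matrix(rnorm(n * n), n, n))
  C2 <- attention_fuse(A2, H, W_z)$C
  for (t in 1:n) {
    ct <- rep(0, dh)
    for (j in 1:n) ct <- ct + A2[t, j] * H[j, ]
    expect_equal(unname(C2[t, ]), ct, tolerance = 1e-9)
  }
})

test_that("the scoring layer maps fused vectors to one score per tag", {
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(emissions(Z, matrix(0, 3, 5)), matrix(0, 4, 5))
  S <- emissions(Z, matrix(rnorm(15), 3, 5), activation = "tanh")
  expect_true(all(abs(S) < 1))
  W <- matrix(rnorm(15), 3, 5)
  expect_equal(emissions(Z, W, activation = "linear"), Z %*% W)
})

test_that("sentences score identically alone and inside a padded batch", {
  set.seed(83)
  cfg <- tiny_config(dropout = 0)
  v <- build_vocab(c("abcdefg"))
  m <- cner_model(v, cfg, seed = 3)
  feats <- list(
    list(n = 6L, char_ids = lookup_ids(v, chars_of("abcdef"))),
    list(n = 2L, char_ids = lookup_ids(v, chars_of("gb"))),
    list(n = 4L, char_ids = lookup_ids(v, chars_of("fedc"))))
  batch <- cner:::pack_batch(feats, cfg)
  fw <- cner:::forward_batch(m$par, cfg, batch, training = FALSE)
  for (b in seq_along(feats)) {
    solo <- cner:::forward_batch(m$par, cfg, cner:::pack_batch(feats[b], cfg),
                                 training = FALSE)
    expect_equal(fw$sent[[b]]$S, solo$sent[[1]]$S, tolerance = 1e-6)
    # every attention row over the real positions sums to 1
    expect_equal(unname(rowSums(fw$sent[[b]]$A)), rep(1, feats[[b]]$n),
                 tolerance = 1e-6)
  }
})

test_that("a wide-enough window reproduces the unwindowed model bit for bit", {
  set.seed(89)
  v <- build_vocab("abcdef")
  cfg_inf <- tiny_config(dropout = 0, attention_width = Inf)
  m <- cner_model(v, cfg_inf, seed = 5)
  feats <- list(list(n = 5L, char_ids = lookup_ids(v, chars_of("fbcae"))))
  cfg_wide <- tiny_config(dropout = 0, attention_width = 4)  # r >= n-1
  s_inf <- cner:::forward_batch(m$par, cfg_inf, cner:::pack_batch(feats, cfg_inf))
  s_wide <- cner:::forward_batch(m$par, cfg_wide, cner:::pack_batch(feats, cfg_wide))
  expect_identical(s_inf$sent[[1]]$S, s_wide$sent[[1]]$S)
  # a narrow window changes the result and zeroes far weights
  cfg_1 <- tiny_config(dropout = 0, attention_width = 1)
  s_1 <- cner:::forward_batch(m$par, cfg_1, cner:::pack_batch(feats, cfg_1))
  A <- s_1$sent[[1]]$A
  expect_true(all(A[abs(outer(1:5, 1:5, "-")) > 1] == 0))
})

test_that("disabling attention wires emissions directly from the encoder", {
  set.seed(97)
  v <- build_vocab("abcd")
  cfg <- tiny_config(dropout = 0, attention = FALSE)
  m <- cner_model(v, cfg, seed = 7)
  feats <- list(list(n = 3L, char_ids = lookup_ids(v, chars_of("dca"))))
  fw <- cner:::forward_batch(m$par, cfg, cner:::pack_batch(feats, cfg))
  expect_equal(fw$sent[[1]]$S, fw$sent[[1]]$Hs %*% m$par$W_p)
  expect_null(fw$sent[[1]]$A)
})

test_that("gradients stay finite over repeated optimization steps", {
  set.seed(101)
  sim <- gen_corpus(generator_spec(n_records = 4, seed = 31))
  sent <- split_sentences(sim$corpus)
  corp <- sentences_as_records(sent)
  cfg <- tiny_config()
  tc <- train_config(epochs = 10, batch_size = 4, seed = 2)
  fit <- cner_fit(corp, cfg, tc)
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(all(vapply(fit$par, function(p) all(is.finite(p)), logical(1))))
})

test_that("checkpoints reload to the same forward outputs", {
  set.seed(103)
  sim <- gen_corpus(generator_spec(n_records = 4, seed = 33))
  corp <- sentences_as_records(split_sentences(sim$corpus))
  cfg <- tiny_config(use_dict = TRUE, attention_width = 3)
  fit <- cner_fit(corp, cfg, train_config(epochs = 1, batch_size = 8, seed = 4),
                  dictionaries = sim$dictionaries)
  p <- withr::local_tempfile(fileext = ".json")
  save_cner(fit, p)
  back <- load_cner(p)
  feats <- cner:::featurize_sentences(fit, split_sentences(sim$corpus)[1:3, ],
                                      with_gold = FALSE)
  b <- cner:::pack_batch(feats, cfg)
  f1 <- cner:::forward_batch(fit$par, fit$config, b)
  f2 <- cner:::forward_batch(back$par, back$config, b)
  for (k in 1:3) expect_equal(f1$sent[[k]]$S, f2$sent[[k]]$S, tolerance = 1e-6)
  # featurization pipeline also survives the round trip
  feats2 <- cner:::featurize_sentences(back, split_sentences(sim$corpus)[1:3, ],
                                       with_gold = FALSE)
  expect_equal(feats2, feats)
  pred1 <- predict(fit, sim$corpus)
  pred2 <- predict(back, sim$corpus)
  expect_equal(pred2$mentions, pred1$mentions)
})
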