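#' Training configuration
#'
#' Defaults are the standard schedule for this tagger: 30 epochs, batch
#' size 32, learning rate 0.001 with the Adam optimizer (default moment
#' parameters), dropout handled by the model config. With a fixed `seed`
#' the batching order, dropout masks and weight initialization — and hence
#' the whole loss curve — are bitwise reproducible on a single CPU thread.
#'
#' @param epochs Maximum number of passes over the training set.
#' @param batch_size Sentences per optimization step.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment/stability parameters.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param eval_every Epochs between dev-set evaluations (when a dev set is
#'   given).
#' @param keep_best Keep the weights of the best dev-F1 epoch (the training
#'   schedule itself is unchanged); with no dev set the final weights are
#'   kept.
#' @param verbose Print per-epoch loss.
#' @return A list of class `cner_train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         seed = 1L, eval_every = 1L, keep_best = TRUE,
                         verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed),
                 eval_every = as.integer(eval_every), keep_best = isTRUE(keep_best),
                 verbose = isTRUE(verbose)), class = "cner_train_config")
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, grads, st, tc) {
  st$t <- st$t + 1L
  lr_t <- tc$learning_rate * sqrt(1 - tc$beta2^st$t) / (1 - tc$beta1^st$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- tc$beta1 * st$m[[nm]] + (1 - tc$beta1) * g
    st$v[[nm]] <- tc$beta2 * st$v[[nm]] + (1 - tc$beta2) * g^2
    par[[nm]] <- par[[nm]] - lr_t * st$m[[nm]] / (sqrt(st$v[[nm]]) + tc$epsilon)
  }
  list(par = par, st = st)
}

# Loss and full gradient for one packed batch (mean NLL per sentence).
batch_loss_grad <- function(par, cfg, feats, training = TRUE) {
  batch <- pack_batch(feats, cfg)
  fw <- forward_batch(par, cfg, batch, training = training)
  B <- batch$B
  dS_list <- vector("list", B)
  dT <- matrix(0, nrow(par$Trans), ncol(par$Trans))
  nll <- 0
  for (b in seq_len(B)) {
    y <- feats[[b]]$tag_ids
    gr <- crf_grad(fw$sent[[b]]$S, par$Trans, y)
    nll <- nll + gr$nll
    dS_list[[b]] <- gr$dS / B
    dT <- dT + gr$dT / B
  }
  grads <- backward_batch(par, cfg, fw, dS_list)
  grads$Trans <- dT
  list(loss = nll / B, grads = grads)
}

#' Fit the BiLSTM-attention-CRF tagger
#'
#' The main entry point: takes an annotated corpus (records, or already
#' split sentences), builds the vocabulary and feature pipeline, and trains
#' the tagger by maximum likelihood — minimizing the CRF negative
#' log-likelihood with Adam under the schedule in [train_config()]. Records
#' are split into clauses first (`split_mode`); each clause is one training
#' sequence and the unit over which attention operates.
#'
#' @param corpus A corpus tibble ([parse_annotations()], [read_annotations()]
#'   or [gen_corpus()]), or a `cner_sentences` tibble from
#'   [split_sentences()].
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param dictionaries Optional list of [term_dictionary()] objects; enables
#'   the dictionary feature when `config$use_dict`.
#' @param pos_tagger,pos_tagset Optional tagger for the POS feature.
#' @param dev Optional held-out corpus evaluated every `eval_every` epochs;
#'   with `keep_best` the best-dev-F1 weights are retained.
#' @param pretrained Optional pre-trained character embedding matrix.
#' @param vocab Optional pre-built [build_vocab()] vocabulary (built from
#'   the training sentences by default).
#' @param split_mode `"short"` (split on commas and periods) or `"long"`
#'   (periods only); stored in the model and reused at prediction time.
#' @param min_count Minimum character frequency for the vocabulary.
#' @return A trained `cner_model`; `$history` holds the per-epoch loss (and
#'   dev F1 when a dev set is given). Use [predict()][predict.cner_model],
#'   [tidy()], [glance()] and [autoplot()] on the result.
#' @examples
#' \donttest{
#' sim <- gen_corpus(generator_spec(n_records = 8, seed = 42))
#' cfg <- model_config(d_char = 16, lstm_hidden = 8, d_attn = 8)
#' fit <- cner_fit(sim$corpus, cfg, train_config(epochs = 2, verbose = FALSE))
#' glance(fit)
#' }
#' @export
cner_fit <- function(corpus, config = model_config(), train = train_config(),
                     dictionaries = NULL, pos_tagger = NULL,
                     pos_tagset = c("n", "v", "a", "m", "x"),
                     dev = NULL, pretrained = NULL, vocab = NULL,
                     split_mode = c("short", "long"), min_count = 1L) {
  split_mode <- match.arg(split_mode)
  sentences <- if (inherits(corpus, "cner_sentences")) corpus else
    split_sentences(corpus, mode = split_mode, max_len = config$max_len)
  if (nrow(sentences) == 0) abort("Empty training corpus.")
  if (is.null(vocab)) vocab <- build_vocab(sentences, min_count = min_count)

  model <- cner_model(vocab, config, dictionaries = dictionaries,
                      pos_tagger = pos_tagger, pos_tagset = pos_tagset,
                      pretrained = pretrained, seed = train$seed)
  model$split_mode <- if (inherits(corpus, "cner_sentences"))
    (corpus$mode[1] %||% split_mode) else split_mode

  feats <- featurize_sentences(model, sentences, with_gold = TRUE)
  if (any(vapply(feats, function(f) anyNA(f$tag_ids), logical(1))))
    abort("Gold tags outside the model's tag alphabet.")

  par <- model$par
  st <- adam_init(par)
  ns <- length(feats)
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_dev <- numeric(0)
  best_f1 <- -Inf; best_par <- NULL; best_epoch <- NA_integer_

  for (ep in seq_len(train$epochs)) {
    ord <- sample.int(ns)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, ns, by = train$batch_size)) {
      idx <- ord[start:min(start + train$batch_size - 1L, ns)]
      lg <- batch_loss_grad(par, config, feats[idx], training = TRUE)
      if (!is.finite(lg$loss))
        abort(sprintf("Non-finite loss at epoch %d, batch %d.", ep, nb + 1L))
      upd <- adam_step(par, lg$grads, st, train)
      par <- upd$par; st <- upd$st
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    dev_f1 <- NA_real_
    if (!is.null(dev) && (ep %% train$eval_every == 0L || ep == train$epochs)) {
      model$par <- par
      pred <- predict(model, dev)
      dev_f1 <- strict_eval(dev, pred)$micro$f1
      if (train$keep_best && dev_f1 >= best_f1) {
        best_f1 <- dev_f1; best_par <- par; best_epoch <- ep
      }
    }
    hist_epoch <- c(hist_epoch, ep); hist_loss <- c(hist_loss, ep_loss)
    hist_dev <- c(hist_dev, dev_f1)
    if (train$verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, ep_loss,
                      if (is.na(dev_f1)) "" else sprintf(", dev F1 %.3f", dev_f1)))
  }

  model$par <- if (!is.null(dev) && train$keep_best && !is.null(best_par))
    best_par else par
  model$best_epoch <- if (!is.null(dev)) best_epoch else train$epochs
  model$train_config <- train
  model$history <- tibble(epoch = hist_epoch, loss = hist_loss, dev_f1 = hist_dev)
  model
}

#' Predict entity mentions for new records
#'
#' Applies the full pipeline: clause splitting (with the mode used in
#' training), feature extraction, the network forward pass, Viterbi
#' decoding and BIESO span decoding (conservative repair, so raw tag output
#' that is not well-formed yields no spurious mentions), then maps clause
#' offsets back to record offsets.
#'
#' @param object A trained `cner_model`.
#' @param newdata A corpus tibble (mentions, if present, are ignored).
#' @param batch_size Sentences per forward batch.
#' @param ... Unused.
#' @return A corpus tibble with predicted `mentions`.
#' @export
predict.cner_model <- function(object, newdata, batch_size = 64L, ...) {
  cfg <- object$config
  sentences <- if (inherits(newdata, "cner_sentences")) newdata else
    split_sentences(newdata, mode = object$split_mode, max_len = cfg$max_len)
  record_ids <- if (inherits(newdata, "cner_sentences"))
    unique(newdata$record_id) else newdata$record_id
  texts <- if (inherits(newdata, "cner_sentences"))
    unsplit_sentences(newdata)$text[match(record_ids, unsplit_sentences(newdata)$record_id)]
  else newdata$text

  per_record <- setNames(vector("list", length(record_ids)), record_ids)
  if (nrow(sentences) > 0) {
    feats <- featurize_sentences(object, sentences, with_gold = FALSE)
    Trans <- object$par$Trans
    if (cfg$constrain_decoding)
      Trans <- Trans + constrained_transitions(cfg$types)
    for (start in seq(1L, nrow(sentences), by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, nrow(sentences))
      batch <- pack_batch(feats[idx], cfg)
      fw <- forward_batch(object$par, cfg, batch, training = FALSE)
      for (k in seq_along(idx)) {
        i <- idx[k]
        tags <- object$alphabet[crf_viterbi(fw$sent[[k]]$S, Trans)$path]
        m <- decode_bieso(tags, repair = "conservative", text = sentences$text[i])
        m$start <- m$start + sentences$origin_offset[i]
        m$end <- m$end + sentences$origin_offset[i]
        rid <- sentences$record_id[i]
        per_record[[rid]] <- dplyr::bind_rows(per_record[[rid]], m)
      }
    }
  }
  mentions <- lapply(record_ids, function(rid) {
    m <- per_record[[rid]]
    if (is.null(m)) as_mentions(NULL) else as_mentions(m)
  })
  new_corpus(tibble(record_id = record_ids, text = texts, mentions = mentions))
}
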