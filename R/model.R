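#' Model configuration
#'
#' Collects the architecture hyper-parameters of the character-level
#' BiLSTM-attention-CRF tagger. Defaults follow the standard clinical
#' configuration: 200-dimensional character embeddings, 100 dimensions per
#' additional feature (dictionary, POS), 300 LSTM hidden units per
#' direction, dropout 0.2, a 150-character sentence budget, and an
#' unwindowed attention layer.
#'
#' @param types Entity type labels (default the five clinical types of
#'   [ccks2018_types()]).
#' @param d_char Character embedding size.
#' @param d_feature Embedding size per additional feature.
#' @param lstm_hidden LSTM hidden units per direction.
#' @param d_attn Size of the fused attention output `z_t`.
#' @param dropout Dropout rate applied (training only) to the embedding
#'   concatenation and the encoder output.
#' @param attention Logical; `FALSE` gives the plain BiLSTM-CRF ablation
#'   (`z_t := h_t`).
#' @param attention_width Attention width `r`: each position attends to the
#'   `r` positions on either side of itself (window `2r+1`); `Inf` means
#'   unwindowed.
#' @param alignment_source `"inputs"` (alignment scores over the embedded
#'   inputs, the literal reading of the alignment function) or `"hidden"`
#'   (over the encoder states).
#' @param emission_activation `"linear"` (default: an unbounded dense
#'   scoring layer, the standard choice for CRF emissions) or `"tanh"`
#'   (emission scores bounded to (-1,1); see the methods vignette for why
#'   the bounded variant saturates on class-imbalanced corpora).
#' @param use_dict,use_pos Enable the dictionary / POS feature embeddings.
#' @param constrain_decoding Apply the BIESO structural transition mask
#'   ([constrained_transitions()]) at decode time.
#' @param max_len Maximum sentence length in characters.
#' @return A list of class `cner_config`.
#' @export
model_config <- function(types = ccks2018_types(), d_char = 200L, d_feature = 100L,
                         lstm_hidden = 300L, d_attn = 300L, dropout = 0.2,
                         attention = TRUE, attention_width = Inf,
                         alignment_source = c("inputs", "hidden"),
                         emission_activation = c("linear", "tanh"),
                         use_dict = FALSE, use_pos = FALSE,
                         constrain_decoding = FALSE, max_len = 150L) {
  alignment_source <- match.arg(alignment_source)
  emission_activation <- match.arg(emission_activation)
  stopifnot(d_char > 0, d_feature > 0, lstm_hidden > 0, d_attn > 0,
            dropout >= 0, dropout < 1, attention_width >= 0, max_len >= 1)
  structure(list(
    types = types, d_char = as.integer(d_char), d_feature = as.integer(d_feature),
    lstm_hidden = as.integer(lstm_hidden), d_attn = as.integer(d_attn),
    dropout = dropout, attention = isTRUE(attention),
    attention_width = attention_width, alignment_source = alignment_source,
    emission_activation = emission_activation,
    use_dict = isTRUE(use_dict), use_pos = isTRUE(use_pos),
    constrain_decoding = isTRUE(constrain_decoding),
    max_len = as.integer(max_len)), class = "cner_config")
}

cfg_d_in <- function(cfg) {
  cfg$d_char + cfg$use_dict * cfg$d_feature + cfg$use_pos * cfg$d_feature
}

cfg_d_align <- function(cfg) {
  if (cfg$alignment_source == "inputs") cfg_d_in(cfg) else 2L * cfg$lstm_hidden
}

# Initialize all parameters. Uses the current RNG state (callers seed).
init_params <- function(cfg, char_vocab, dict_vocab = NULL, pos_vocab = NULL,
                        pretrained = NULL) {
  d_in <- cfg_d_in(cfg)
  H <- cfg$lstm_hidden
  K <- length(tag_alphabet(cfg$types))
  par <- list()
  par$E_char <- if (!is.null(pretrained)) pretrained else
    random_embedding(char_vocab$size, cfg$d_char)
  if (cfg$use_dict) par$E_dict <- random_embedding(dict_vocab$size, cfg$d_feature)
  if (cfg$use_pos) par$E_pos <- random_embedding(pos_vocab$size, cfg$d_feature)
  for (dir in c("f", "b")) {
    par[[paste0("W", dir)]] <- glorot(d_in, 4L * H)
    par[[paste0("U", dir)]] <- glorot(H, 4L * H)
    b <- rep(0, 4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias: remember by default
    par[[paste0("b", dir)]] <- b
  }
  if (cfg$attention) {
    da <- cfg_d_align(cfg)
    par$w_a <- runif(2L * da, -sqrt(3 / da), sqrt(3 / da))
    par$W_z <- glorot(4L * H, cfg$d_attn)
  }
  d_emit <- if (cfg$attention) cfg$d_attn else 2L * H
  par$W_p <- glorot(d_emit, K)
  par$Trans <- matrix(runif((K + 2L)^2, -0.1, 0.1), K + 2L, K + 2L)
  par
}

#' Construct an untrained tagger
#'
#' Builds the model object — configuration, vocabularies, embedding tables
#' and randomly initialized weights — without training it. [cner_fit()] is
#' the usual entry point and calls this internally.
#'
#' @param char_vocab A [build_vocab()] vocabulary.
#' @param config A [model_config()].
#' @param dictionaries Optional list of [term_dictionary()] objects
#'   (required when `config$use_dict`).
#' @param pos_tagger Optional tagger function (see [pos_tags_per_char()]);
#'   required when `config$use_pos`.
#' @param pos_tagset Tag set of the tagger (defaults to the toy tagger's
#'   `n, v, a, m, x`); tags outside it map to `<UNK>`.
#' @param pretrained Optional pre-trained character embedding matrix
#'   aligned to `char_vocab` ([load_pretrained_embeddings()]).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cner_model`.
#' @export
cner_model <- function(char_vocab, config = model_config(), dictionaries = NULL,
                       pos_tagger = NULL, pos_tagset = c("n", "v", "a", "m", "x"),
                       pretrained = NULL, seed = 1L) {
  if (config$use_dict && length(dictionaries) == 0)
    abort("`use_dict = TRUE` requires `dictionaries`.")
  if (config$use_pos && is.null(pos_tagger))
    abort("`use_pos = TRUE` requires a `pos_tagger`.")
  dict_vocab <- if (config$use_dict)
    vocab_from_alphabet(dict_tag_alphabet(dictionaries)) else NULL
  pos_vocab <- if (config$use_pos)
    vocab_from_alphabet(unique(c(pos_tagset, "NONE"))) else NULL
  set.seed(seed)
  par <- init_params(config, char_vocab, dict_vocab, pos_vocab, pretrained)
  structure(list(
    par = par, config = config, char_vocab = char_vocab,
    dict_vocab = dict_vocab, pos_vocab = pos_vocab,
    dictionaries = dictionaries, pos_tagger = pos_tagger,
    alphabet = tag_alphabet(config$types), split_mode = "short",
    history = NULL), class = "cner_model")
}

#' @export
print.cner_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<cner_model: %s%s, %d tags, |V|=%d, hidden=%d, width r=%s%s%s>\n",
    if (cfg$attention) "BiLSTM-Att-CRF" else "BiLSTM-CRF",
    if (cfg$use_dict || cfg$use_pos) "+features" else "",
    length(x$alphabet), x$char_vocab$size, cfg$lstm_hidden,
    format(cfg$attention_width),
    if (!is.null(x$history)) sprintf(", trained %d epochs", max(x$history$epoch)) else "",
    ""))
  invisible(x)
}

# ---- featurization -------------------------------------------------------

# Turn a sentences tibble into per-sentence id vectors (+ gold tag ids when
# mentions are present). Dictionary tags are computed on the full sentence
# text; POS via the stored tagger.
featurize_sentences <- function(model, sentences, with_gold = TRUE) {
  cfg <- model$config
  lapply(seq_len(nrow(sentences)), function(i) {
    cs <- chars(sentences$text[i])
    out <- list(n = length(cs),
                char_ids = lookup_ids(model$char_vocab, cs))
    if (cfg$use_dict)
      out$dict_ids <- lookup_ids(model$dict_vocab,
                                 bidirectional_dict_tags(cs, model$dictionaries))
    if (cfg$use_pos)
      out$pos_ids <- lookup_ids(model$pos_vocab,
                                pos_tags_per_char(cs, model$pos_tagger))
    if (with_gold && "mentions" %in% names(sentences)) {
      tags <- encode_bieso(sentences$mentions[[i]], length(cs))
      out$tag_ids <- match(tags, model$alphabet)
    }
    out
  })
}

# Pack a list of featurized sentences into time-major big matrices.
pack_batch <- function(feats, cfg) {
  B <- length(feats)
  lens <- vapply(feats, `[[`, integer(1), "n")
  n <- max(lens)
  pad_ids <- function(field) {
    m <- matrix(1L, B, n)  # 1 = <PAD>
    for (b in seq_len(B)) m[b, seq_len(lens[b])] <- feats[[b]][[field]]
    m
  }
  ids <- list(char = pad_ids("char_ids"))
  if (cfg$use_dict) ids$dict <- pad_ids("dict_ids")
  if (cfg$use_pos) ids$pos <- pad_ids("pos_ids")
  mask <- matrix(0, B, n)
  for (b in seq_len(B)) mask[b, seq_len(lens[b])] <- 1
  list(B = B, n = n, lens = lens, ids = ids, mask = mask)
}
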