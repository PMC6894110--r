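#' Save and reload a fitted tagger
#'
#' The checkpoint is a single JSON file holding the configuration,
#' vocabularies, tag alphabet, dictionaries and all weights at full
#' numeric precision, so a reloaded model reproduces forward outputs to
#' within floating-point round-off (well under 1e-6). A POS tagger is a
#' function and cannot be serialized: pass it again on load when the model
#' uses the POS feature.
#'
#' @param model A `cner_model`.
#' @param path File path (conventionally `.json`).
#' @param pos_tagger Tagger function to reattach on load.
#' @return `load_cner()` returns the `cner_model`; `save_cner()` returns
#'   `path` invisibly.
#' @export
save_cner <- function(model, path) {
  num <- function(x) unclass(x)
  cfg <- model$config
  cfg$attention_width <- if (is.infinite(cfg$attention_width)) "inf" else
    cfg$attention_width
  obj <- list(
    format = "cner-checkpoint-1",
    config = unclass(cfg),
    alphabet = model$alphabet,
    split_mode = model$split_mode,
    char_tokens = model$char_vocab$tokens,
    dict_tokens = if (!is.null(model$dict_vocab)) model$dict_vocab$tokens,
    pos_tokens = if (!is.null(model$pos_vocab)) model$pos_vocab$tokens,
    dictionaries = lapply(model$dictionaries, function(d)
      list(name = d$name, terms = d$terms)),
    par = lapply(model$par, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = length(p), data = as.vector(p))))
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_cner
#' @export
load_cner <- function(path, pos_tagger = NULL) {
  obj <- jsonlite::fromJSON(paste(readLines(path, encoding = "UTF-8",
                                            warn = FALSE), collapse = ""),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "cner-checkpoint-1"))
    abort("Not a cner checkpoint file.")
  cfg <- obj$config
  cfg$attention_width <- if (identical(cfg$attention_width, "inf")) Inf else
    as.numeric(cfg$attention_width)
  cfg <- do.call(model_config, cfg[names(cfg) %in% names(formals(model_config))])
  par <- lapply(obj$par, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  })
  dicts <- if (length(obj$dictionaries))
    lapply(obj$dictionaries, function(d) term_dictionary(unlist(d$terms), d$name))
  if (cfg$use_pos && is.null(pos_tagger))
    warn("Model uses the POS feature; supply `pos_tagger` to predict.")
  model <- structure(list(
    par = par, config = cfg,
    char_vocab = new_vocab(setdiff(unlist(obj$char_tokens),
                                   c("<PAD>", "<UNK>"))),
    dict_vocab = if (!is.null(obj$dict_tokens))
      new_vocab(setdiff(unlist(obj$dict_tokens), c("<PAD>", "<UNK>"))),
    pos_vocab = if (!is.null(obj$pos_tokens))
      new_vocab(setdiff(unlist(obj$pos_tokens), c("<PAD>", "<UNK>"))),
    dictionaries = dicts, pos_tagger = pos_tagger,
    alphabet = unlist(obj$alphabet), split_mode = obj$split_mode,
    history = NULL), class = "cner_model")
  model
}
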