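#' Strict entity-level evaluation
#'
#' A predicted mention counts as a true positive only if its start, end and
#' entity type all equal a gold mention of the same record (the strict
#' match used in clinical NER shared tasks); each gold mention can be
#' consumed by at most one prediction, and duplicate exact matches become
#' false positives. Precision is `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, with division by zero giving 0. Micro counts are the
#' sums of the per-type counts.
#'
#' @param gold,pred Corpus tibbles aligned by `record_id` (same set of
#'   ids).
#' @param types Optional type set for the per-type table (defaults to the
#'   types present in gold or predictions).
#' @return A `cner_eval` object: list with `by_type` (tibble `type, tp, fp,
#'   fn, precision, recall, f1`) and `micro` (one-row tibble of the same
#'   shape).
#' @examples
#' g <- parse_annotations("abcdef", tibble::tibble(start = c(0, 4), end = c(2, 5),
#'                                                 type = c("AP", "Drug")))
#' p <- parse_annotations("abcdef", tibble::tibble(start = c(0, 4), end = c(2, 5),
#'                                                 type = c("AP", "AP")))
#' strict_eval(g, p)$micro
#' @export
strict_eval <- function(gold, pred, types = NULL) {
  if (!setequal(gold$record_id, pred$record_id))
    abort("Gold and predicted corpora must cover the same record ids.")
  pred <- pred[match(gold$record_id, pred$record_id), , drop = FALSE]
  all_types <- types %||% sort(unique(c(
    unlist(lapply(gold$mentions, function(m) m$type)),
    unlist(lapply(pred$mentions, function(m) m$type)))))
  tp <- fp <- fn <- setNames(rep(0L, length(all_types)), all_types)
  for (i in seq_len(nrow(gold))) {
    g <- as_mentions(gold$mentions[[i]])
    p <- as_mentions(pred$mentions[[i]])
    gk <- sprintf("%d|%d|%s", g$start, g$end, g$type)
    pk <- sprintf("%d|%d|%s", p$start, p$end, p$type)
    used <- rep(FALSE, length(gk))
    hit <- rep(FALSE, length(pk))
    for (j in seq_along(pk)) {
      m <- which(!used & gk == pk[j])
      if (length(m) > 0) { used[m[1]] <- TRUE; hit[j] <- TRUE }
    }
    for (ty in all_types) {
      tp[ty] <- tp[ty] + sum(hit & p$type == ty)
      fp[ty] <- fp[ty] + sum(!hit & p$type == ty)
      fn[ty] <- fn[ty] + sum(!used & g$type == ty)
    }
  }
  prf <- function(tp, fp, fn) {
    p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
    list(p = p, r = r, f = f)
  }
  bt <- prf(tp, fp, fn)
  by_type <- tibble(type = all_types, tp = as.integer(tp), fp = as.integer(fp),
                    fn = as.integer(fn), precision = unname(bt$p),
                    recall = unname(bt$r), f1 = unname(bt$f))
  mi <- prf(sum(tp), sum(fp), sum(fn))
  micro <- tibble(type = "micro", tp = sum(tp), fp = sum(fp), fn = sum(fn),
                  precision = mi$p, recall = mi$r, f1 = mi$f)
  structure(list(by_type = by_type, micro = micro), class = "cner_eval")
}

#' @export
print.cner_eval <- function(x, ...) {
  cat("Strict entity-level evaluation\n")
  print(dplyr::bind_rows(x$by_type, x$micro))
  invisible(x)
}

#' @rdname strict_eval
#' @param x A `cner_eval` object.
#' @param ... Unused.
#' @method tidy cner_eval
#' @export
tidy.cner_eval <- function(x, ...) dplyr::bind_rows(x$by_type, x$micro)

#' @method autoplot cner_eval
#' @export
autoplot.cner_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_type, c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Strict per-type performance") +
    ggplot2::theme_minimal()
}

#' Broom-style accessors for a fitted tagger
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary; `autoplot()` draws the loss (and dev-F1) curves.
#'
#' @param x,object A fitted `cner_model`.
#' @param ... Unused.
#' @return `tidy()`: tibble `epoch, loss, dev_f1`; `glance()`: one-row
#'   tibble with final loss, best epoch and model dimensions.
#' @method tidy cner_model
#' @export
tidy.cner_model <- function(x, ...) {
  x$history %||% tibble(epoch = integer(0), loss = numeric(0), dev_f1 = numeric(0))
}

#' @rdname tidy.cner_model
#' @method glance cner_model
#' @export
glance.cner_model <- function(x, ...) {
  h <- tidy(x)
  tibble(epochs = nrow(h),
         final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
         best_epoch = x$best_epoch %||% NA_integer_,
         best_dev_f1 = if (all(is.na(h$dev_f1))) NA_real_ else
           max(h$dev_f1, na.rm = TRUE),
         n_tags = length(x$alphabet),
         vocab_size = x$char_vocab$size,
         attention = x$config$attention,
         attention_width = x$config$attention_width)
}

#' @rdname tidy.cner_model
#' @method autoplot cner_model
#' @export
autoplot.cner_model <- function(object, ...) {
  h <- tidy(object)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Epoch", y = "Mean NLL per sentence",
                  title = "Training loss") +
    ggplot2::theme_minimal()
  p
}

#' Attention-width experiment
#'
#' Trains one model per combination of attention width `r` and split mode
#' (`short`: comma + period clauses; `long`: period-only sentences) under a
#' shared seed, and evaluates each with the strict metric. This is the
#' harness for studying how much context the attention layer needs: widths
#' grow from local windows to the unwindowed model (`Inf`).
#'
#' @param corpus Training corpus tibble.
#' @param widths Numeric vector of attention widths (positive integers or
#'   `Inf`).
#' @param modes Character vector of split modes.
#' @param config Base [model_config()]; its `attention_width` is overridden
#'   per run.
#' @param train A [train_config()]; the same seed is used for every run.
#' @param eval_corpus Corpus for evaluation (defaults to `corpus`, i.e.
#'   training-set performance).
#' @param ... Passed on to [cner_fit()].
#' @return A tibble with columns `width, mode, precision, recall, f1`.
#' @export
width_experiment <- function(corpus, widths, modes = c("short", "long"),
                             config = model_config(), train = train_config(),
                             eval_corpus = NULL, ...) {
  stopifnot(all(widths >= 0))
  eval_corpus <- eval_corpus %||% corpus
  grid <- expand.grid(width = widths, mode = modes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$attention_width <- grid$width[i]
    fit <- cner_fit(corpus, cfg, train, split_mode = grid$mode[i], ...)
    ev <- strict_eval(eval_corpus, predict(fit, eval_corpus))
    tibble(width = grid$width[i], mode = grid$mode[i],
           precision = ev$micro$precision, recall = ev$micro$recall,
           f1 = ev$micro$f1)
  })
  dplyr::bind_rows(rows)
}

#' Read and write the width-experiment results table
#'
#' Tab-separated with header `width  mode  precision  recall  f1`; `Inf`
#' serializes as the string `inf`.
#'
#' @param results Tibble from [width_experiment()].
#' @param path File path.
#' @return `read_width_results()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_width_results <- function(results, path) {
  out <- results
  out$width <- ifelse(is.infinite(out$width), "inf",
                      format(out$width, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_width_results
#' @export
read_width_results <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$width <- ifelse(df$width == "inf", Inf, as.numeric(df$width))
  as_tibble(df)
}
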