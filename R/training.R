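# Training loop (SGD, mini-batch of one sentence, best-validation-F
# checkpointing) and prediction back to mentions/BRAT/CoNLL.

# encode every sentence of a corpus to features + gold joint-label indices
prepare_corpus <- function(docs, model) {
  sents <- list(); golds <- list(); refs <- list()
  for (di in seq_along(docs)) {
    doc <- docs[[di]]
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      if (nrow(sent$tokens) == 0L) next
      joint <- bmewov_encode(sent)$joint
      gi <- match(joint, model$labels)
      if (anyNA(gi)) {
        stop("label(s) missing from the joint vocabulary: ",
             paste(unique(joint[is.na(gi)]), collapse = ", "))
      }
      sents[[length(sents) + 1L]] <- model_featurize(model, sent)
      golds[[length(golds) + 1L]] <- gi
      refs[[length(refs) + 1L]] <- c(doc = di, sent = si)
    }
  }
  list(sents = sents, golds = golds, refs = refs)
}

#' Train the recurrent CRF model
#'
#' Minimizes the mean CRF negative log-likelihood by stochastic gradient
#' descent (one sentence per update, order reshuffled every epoch from the
#' run seed), with dropout on the concatenated token features and the token
#' encoder output and gradient-norm clipping.  After each epoch the
#' entity-level F on `valid_docs` is computed and logged; the parameters
#' with the best validation F are kept.  Fully reproducible given
#' `config$seed`.
#'
#' @param train_docs,valid_docs lists of `ns_document`s sharing one label
#'   inventory
#' @param config an [crf_config()]
#' @param word_table,sense_table optional pretrained embeddings
#' @param labels joint label vocabulary; derived from the training corpus
#'   when `NULL`
#' @param quiet suppress per-epoch messages
#' @return an `ns_checkpoint`: list with `model` (best parameters), `log`
#'   (per-epoch data.frame: epoch, mean_loss, valid_f1), `best_epoch`
#' @export
train_model <- function(train_docs, valid_docs, config = crf_config(),
                        word_table = NULL, sense_table = NULL,
                        labels = NULL, quiet = FALSE) {
  if (length(train_docs) == 0L ||
      sum(vapply(train_docs, function(d) length(d$sentences), 1L)) == 0L) {
    stop("training set is empty")
  }
  if (is.null(labels)) {
    ent_labels <- unique(vapply(
      unlist(lapply(train_docs, doc_mentions), recursive = FALSE),
      `[[`, "", "label"))
    if (length(ent_labels) == 0L) stop("training corpus has no mentions")
    labels <- joint_vocabulary(ent_labels, train_docs)
  }
  vocab <- build_vocab(train_docs, lowercase = config$lowercase)
  model <- crf_model(labels, vocab, config, word_table, sense_table)

  tr <- prepare_corpus(train_docs, model)
  n_tr <- length(tr$sents)

  log <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                    valid_f1 = numeric(0))
  best_f <- -1; best_params <- model$params; best_epoch <- 0L
  stale <- 0L
  set.seed(config$seed)   # governs epoch shuffles and dropout draws
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    res <- cpp_train_epoch(model$params, tr$sents[ord], tr$golds[ord],
                           config$lr, config$dropout, config$clip)
    model$params <- res$params
    vf <- if (length(valid_docs) > 0L) {
      pred <- predict_mentions(model, valid_docs)
      rep_ <- entity_eval(valid_docs, pred)
      rep_$overall$f1
    } else NA_real_
    log <- rbind(log, data.frame(epoch = ep, mean_loss = res$mean_loss,
                                 valid_f1 = vf))
    if (!quiet) {
      message(sprintf("epoch %3d  loss %.4f  valid F %.4f",
                      ep, res$mean_loss, vf))
    }
    if (!is.na(vf) && vf > best_f) {
      best_f <- vf; best_params <- model$params; best_epoch <- ep
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (config$patience > 0L && stale >= config$patience) break
    }
  }
  if (length(valid_docs) == 0L) { best_params <- model$params }
  model$params <- best_params
  structure(list(model = model, log = log, best_epoch = best_epoch,
                 best_valid_f1 = if (best_f >= 0) best_f else NA_real_),
            class = "ns_checkpoint")
}

#' @export
print.ns_checkpoint <- function(x, ...) {
  cat(sprintf("<checkpoint> best epoch %d, valid F %.4f (%d epochs run)\n",
              x$best_epoch, x$best_valid_f1, nrow(x$log)))
  invisible(x)
}

#' Predict mentions for tokenized documents
#'
#' Per sentence: featurize, encode emissions, Viterbi-decode the joint
#' labels, repair, and decode tags back to mentions.  The returned
#' documents carry the predicted mentions and can be written as BRAT or
#' CoNLL.
#'
#' @param model an `ns_crf_model` or `ns_checkpoint`
#' @param docs list of `ns_document`s (mentions, if any, are ignored)
#' @return list of `ns_document`s with predicted mentions
#' @export
predict_mentions <- function(model, docs) {
  if (inherits(model, "ns_checkpoint")) model <- model$model
  lapply(docs, function(doc) {
    feats <- lapply(doc$sentences, function(sent) {
      if (nrow(sent$tokens) == 0L) NULL else model_featurize(model, sent)
    })
    keep <- !vapply(feats, is.null, TRUE)
    ems <- if (any(keep)) cpp_emissions_batch(model$params, feats[keep])
           else list()
    ki <- 0L
    doc$sentences <- lapply(seq_along(doc$sentences), function(si) {
      sent <- doc$sentences[[si]]
      sent$mentions <- list()
      if (!keep[si]) return(sent)
      ki <<- ki + 1L
      y <- cpp_viterbi(ems[[ki]], model$params$trans)
      joint <- bmewov_repair(model$labels[y])
      sent$tags <- split_joint(joint)
      sent$mentions <- bmewov_decode(sent$tags, sent$tokens, repair = FALSE)
      sent
    })
    doc
  })
}
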