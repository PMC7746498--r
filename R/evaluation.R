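# Four scoring levels: token, entity/cue (exact span+label match), scope
# (boundaries AND nested cues both exact), and sentence (does the sentence
# contain a cue).  Precision = tp/(tp+fp), recall = tp/(tp+fn), F1 their
# harmonic mean; degenerate denominators report 0 and are flagged.

prf <- function(tp, fp, fn) {
  degenerate <- (tp + fp == 0L) || (tp + fn == 0L)
  p <- if (tp + fp > 0L) tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f,
       degenerate = degenerate)
}

new_eval_report <- function(level, by_label, overall) {
  structure(list(level = level, by_label = by_label, overall = overall),
            class = "ns_eval")
}

#' @export
print.ns_eval <- function(x, ...) {
  cat(sprintf("== %s-level evaluation ==\n", x$level))
  if (nrow(x$by_label) > 0L) {
    df <- x$by_label
    df$precision <- sprintf("%.1f", 100 * df$precision)
    df$recall <- sprintf("%.1f", 100 * df$recall)
    df$f1 <- sprintf("%.1f", 100 * df$f1)
    print(df, row.names = FALSE)
  }
  o <- x$overall
  cat(sprintf("overall: P %.1f  R %.1f  F %.1f  (tp %d fp %d fn %d)%s\n",
              100 * o$precision, 100 * o$recall, 100 * o$f1,
              o$tp, o$fp, o$fn,
              if (o$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

eval_to_list <- function(x) {
  list(level = x$level, by_label = x$by_label, overall = x$overall)
}

check_parallel_docs <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must contain the same documents")
  }
  gid <- vapply(gold, `[[`, "", "id")
  pid <- vapply(pred, `[[`, "", "id")
  if (!identical(gid, pid)) stop("mismatched document ids: ",
                                 paste(gid[gid != pid], collapse = ", "))
}

# one row per mention: doc, label, key
mention_table <- function(docs, labels = NULL) {
  rows <- list()
  for (doc in docs) {
    for (m in doc_mentions(doc)) {
      if (!is.null(labels) && !(m$label %in% labels)) next
      rows[[length(rows) + 1L]] <-
        data.frame(doc = doc$id, label = m$label,
                   key = paste0(doc$id, "::", mention_key(m)),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(doc = character(0), label = character(0),
                      key = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

count_matches <- function(gold_keys, pred_keys) {
  gt <- table(gold_keys); pt <- table(pred_keys)
  common <- intersect(names(gt), names(pt))
  sum(pmin(gt[common], pt[common]))   # each gold matches at most one pred
}

#' Entity-level (cue-level) evaluation
#'
#' A predicted mention is a true positive iff a gold mention with the same
#' label and the exact same fragment set exists in the same document; each
#' gold mention matches at most one prediction.  Boundary-shifted or
#' partially overlapping predictions count as one false positive plus one
#' false negative.
#'
#' @param gold,pred lists of `ns_document`s over the same tokenized text
#' @param labels optional label filter (e.g. cue labels only)
#' @return an `ns_eval` report
#' @export
entity_eval <- function(gold, pred, labels = NULL) {
  check_parallel_docs(gold, pred)
  gt <- mention_table(gold, labels)
  pt <- mention_table(pred, labels)
  all_labels <- sort(unique(c(gt$label, pt$label)))
  by_label <- do.call(rbind, lapply(all_labels, function(l) {
    g <- gt$key[gt$label == l]; p <- pt$key[pt$label == l]
    tp <- count_matches(g, p)
    s <- prf(tp, length(p) - tp, length(g) - tp)
    data.frame(label = l, tp = s$tp, fp = s$fp, fn = s$fn,
               precision = s$precision, recall = s$recall, f1 = s$f1,
               degenerate = s$degenerate, stringsAsFactors = FALSE)
  }))
  if (is.null(by_label)) {
    by_label <- data.frame(label = character(0), tp = integer(0),
                           fp = integer(0), fn = integer(0),
                           precision = numeric(0), recall = numeric(0),
                           f1 = numeric(0), degenerate = logical(0))
  }
  tp <- count_matches(gt$key, pt$key)
  new_eval_report("entity", by_label,
                  prf(tp, nrow(pt) - tp, nrow(gt) - tp))
}

# scope descriptors: one per scope mention, bundling its span with the
# (label, span) set of cue mentions nested inside it
scope_keys <- function(docs, scope_labels, cue_labels) {
  keys <- character(0)
  for (doc in docs) {
    ms <- doc_mentions(doc)
    scopes <- Filter(function(m) m$label %in% scope_labels, ms)
    cues <- Filter(function(m) m$label %in% cue_labels, ms)
    for (sc in scopes) {
      sp <- mention_span(sc)
      inside <- vapply(cues, function(cu) {
        cs <- mention_span(cu)
        cs[1L] >= sp[1L] && cs[2L] <= sp[2L]
      }, TRUE)
      cue_sig <- paste(sort(vapply(cues[inside], mention_key, "")),
                       collapse = "+")
      keys <- c(keys, paste0(doc$id, "::", mention_key(sc), "::", cue_sig))
    }
  }
  keys
}

#' Scope-level evaluation
#'
#' A predicted scope is a true positive iff both its boundaries and the set
#' of cue mentions nested inside it exactly match a gold scope (correct
#' boundaries with a wrong or missing cue are not a true positive, and vice
#' versa).
#'
#' @param gold,pred lists of `ns_document`s
#' @param scope_labels labels identifying scope mentions
#' @param cue_labels labels identifying cue mentions
#' @return an `ns_eval` report
#' @export
scope_eval <- function(gold, pred, scope_labels, cue_labels) {
  check_parallel_docs(gold, pred)
  g <- scope_keys(gold, scope_labels, cue_labels)
  p <- scope_keys(pred, scope_labels, cue_labels)
  tp <- count_matches(g, p)
  new_eval_report("scope",
                  data.frame(label = character(0), tp = integer(0),
                             fp = integer(0), fn = integer(0),
                             precision = numeric(0), recall = numeric(0),
                             f1 = numeric(0), degenerate = logical(0)),
                  prf(tp, length(p) - tp, length(g) - tp))
}

#' Sentence-level evaluation
#'
#' A sentence is positive iff it contains at least one cue-labeled mention;
#' reports P/R/F of the positive class (the chief sentence-level metric for
#' speculation detection).
#'
#' @param gold,pred lists of `ns_document`s with identical sentence
#'   segmentation
#' @param cue_labels labels identifying cue mentions
#' @return an `ns_eval` report
#' @export
sentence_eval <- function(gold, pred, cue_labels) {
  check_parallel_docs(gold, pred)
  has_cue <- function(sent) {
    any(vapply(sent$mentions, function(m) m$label %in% cue_labels, TRUE))
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (di in seq_along(gold)) {
    gs <- gold[[di]]$sentences; ps <- pred[[di]]$sentences
    if (length(gs) != length(ps)) {
      stop("documents must have the same sentence segmentation")
    }
    for (si in seq_along(gs)) {
      g <- has_cue(gs[[si]]); p <- has_cue(ps[[si]])
      if (g && p) tp <- tp + 1L
      else if (!g && p) fp <- fp + 1L
      else if (g && !p) fn <- fn + 1L
    }
  }
  new_eval_report("sentence",
                  data.frame(label = character(0), tp = integer(0),
                             fp = integer(0), fn = integer(0),
                             precision = numeric(0), recall = numeric(0),
                             f1 = numeric(0), degenerate = logical(0)),
                  prf(tp, fp, fn))
}

#' Token-level evaluation
#'
#' Compares the joint BMEWO-V tag of every token; a token is a true
#' positive when gold and prediction agree on a non-`O` tag, a false
#' positive when the prediction is a non-`O` tag that disagrees with gold,
#' and a false negative when a gold non-`O` tag is missed.
#'
#' @param gold,pred lists of `ns_document`s with identical tokenization
#' @return an `ns_eval` report
#' @export
token_eval <- function(gold, pred) {
  check_parallel_docs(gold, pred)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (di in seq_along(gold)) {
    gs <- gold[[di]]$sentences; ps <- pred[[di]]$sentences
    if (length(gs) != length(ps)) {
      stop("documents must have the same sentence segmentation")
    }
    for (si in seq_along(gs)) {
      g <- bmewov_encode(gs[[si]])$joint
      p <- bmewov_encode(ps[[si]])$joint
      if (length(g) != length(p)) stop("documents must share tokenization")
      tp <- tp + sum(g == p & g != "O")
      fp <- fp + sum(p != "O" & p != g)
      fn <- fn + sum(g != "O" & g != p)
    }
  }
  new_eval_report("token",
                  data.frame(label = character(0), tp = integer(0),
                             fp = integer(0), fn = integer(0),
                             precision = numeric(0), recall = numeric(0),
                             f1 = numeric(0), degenerate = logical(0)),
                  prf(tp, fp, fn))
}

#' All four evaluation levels at once
#'
#' @inheritParams scope_eval
#' @return named list of `ns_eval` reports: `token`, `entity`, `cue`,
#'   `scope`, `sentence`
#' @export
evaluate_all <- function(gold, pred, scope_labels, cue_labels) {
  list(token = token_eval(gold, pred),
       entity = entity_eval(gold, pred),
       cue = entity_eval(gold, pred, labels = cue_labels),
       scope = scope_eval(gold, pred, scope_labels, cue_labels),
       sentence = sentence_eval(gold, pred, cue_labels))
}
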