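# Hand-checked precision/recall/F at the four scoring levels.

# build a one-sentence document from token strings and mention blueprints
mini_doc <- function(id, toks, mentions = list()) {
  text <- paste(toks, collapse = " ")
  s <- ns_tokenize(text)[[1]]
  s$mentions <- mentions
  structure(list(id = id, text = text, sentences = list(s)),
            class = "ns_document")
}

tok_span <- function(toks, from, to) {
  starts <- cumsum(c(0L, nchar(toks) + 1L))
  c(starts[from], starts[to] + nchar(toks[to]))
}

test_that("entity level: perfect, spurious, and boundary-shifted predictions", {
  toks <- c("no", "dolor", "toracico", "hoy")
  sp_cue <- tok_span(toks, 1, 1)
  sp_ent <- tok_span(toks, 2, 3)
  gold <- list(mini_doc("d1", toks,
                        list(mention("Cue", sp_cue[1], sp_cue[2]))))
  # pred == gold
  r <- entity_eval(gold, gold)
  expect_equal(r$overall$precision, 1)
  expect_equal(r$overall$recall, 1)
  expect_equal(r$overall$f1, 1)

  # 1 gold, 2 predictions (one exact, one spurious): P 0.5, R 1, F 2/3
  pred <- list(mini_doc("d1", toks,
                        list(mention("Cue", sp_cue[1], sp_cue[2]),
                             mention("Cue", sp_ent[1], sp_ent[2]))))
  r2 <- entity_eval(gold, pred)
  expect_equal(r2$overall$precision, 0.5)
  expect_equal(r2$overall$recall, 1)
  expect_equal(r2$overall$f1, 2 / 3)

  # boundary-shifted prediction counts as fp + fn, not a partial match
  shift <- tok_span(toks, 1, 2)
  pred3 <- list(mini_doc("d1", toks,
                         list(mention("Cue", sp_cue[1], shift[2]))))
  r3 <- entity_eval(gold, pred3)
  expect_equal(r3$overall$tp, 0L)
  expect_equal(r3$overall$fp, 1L)
  expect_equal(r3$overall$fn, 1L)

  # label filter restricts the tally to cue labels
  gold4 <- list(mini_doc("d1", toks,
                         list(mention("Cue", sp_cue[1], sp_cue[2]),
                              mention("DISO", sp_ent[1], sp_ent[2]))))
  pred4 <- list(mini_doc("d1", toks,
                         list(mention("Cue", sp_cue[1], sp_cue[2]))))
  r4 <- entity_eval(gold4, pred4, labels = "Cue")
  expect_equal(r4$overall$f1, 1)

  expect_error(entity_eval(gold, list(mini_doc("other", toks))), "ids")
})

test_that("scope level requires exact boundaries AND exact nested cue set", {
  toks <- c("no", "dolor", "toracico", ",", "estable")
  cue <- tok_span(toks, 1, 1)
  cue2 <- tok_span(toks, 2, 2)
  scope <- tok_span(toks, 1, 3)
  scope_short <- tok_span(toks, 1, 2)
  g <- list(mini_doc("d1", toks,
                     list(mention("Cue", cue[1], cue[2]),
                          mention("Scope", scope[1], scope[2]))))
  # identical prediction: F = 1
  expect_equal(scope_eval(g, g, "Scope", "Cue")$overall$f1, 1)

  # correct boundaries, wrong cue inside: not a TP
  p_wrongcue <- list(mini_doc("d1", toks,
                              list(mention("Cue", cue2[1], cue2[2]),
                                   mention("Scope", scope[1], scope[2]))))
  r <- scope_eval(g, p_wrongcue, "Scope", "Cue")
  expect_equal(r$overall$tp, 0L)
  expect_equal(r$overall$fp, 1L)
  expect_equal(r$overall$fn, 1L)

  # correct cue, scope one token short: fp + fn
  p_short <- list(mini_doc("d1", toks,
                           list(mention("Cue", cue[1], cue[2]),
                                mention("Scope", scope_short[1],
                                        scope_short[2]))))
  r2 <- scope_eval(g, p_short, "Scope", "Cue")
  expect_equal(c(r2$overall$tp, r2$overall$fp, r2$overall$fn),
               c(0L, 1L, 1L))
})

test_that("sentence level scores the positive (cue-bearing) class", {
  toks1 <- c("no", "dolor"); toks2 <- c("sin", "cambios")
  toks3 <- c("estado", "estable"); toks4 <- c("afebril", "hoy")
  cue1 <- tok_span(toks1, 1, 1); cue2 <- tok_span(toks2, 1, 1)
  make <- function(id, toks, with_cue) {
    mini_doc(id, toks, if (with_cue)
      list(mention("Cue", tok_span(toks, 1, 1)[1], tok_span(toks, 1, 1)[2]))
      else list())
  }
  # 3 gold-positive sentences; 2 predicted positive, both correct:
  # P = 1, R = 2/3, F = 0.8
  gold <- list(make("a", toks1, TRUE), make("b", toks2, TRUE),
               make("c", toks3, TRUE), make("d", toks4, FALSE))
  pred <- list(make("a", toks1, TRUE), make("b", toks2, TRUE),
               make("c", toks3, FALSE), make("d", toks4, FALSE))
  r <- sentence_eval(gold, pred, "Cue")
  expect_equal(r$overall$precision, 1)
  expect_equal(r$overall$recall, 2 / 3)
  expect_equal(r$overall$f1, 0.8)

  # all correct: F = 1
  expect_equal(sentence_eval(gold, gold, "Cue")$overall$f1, 1)

  # no positives anywhere: all metrics 0 and flagged degenerate
  neg <- list(make("a", toks3, FALSE))
  r0 <- sentence_eval(neg, neg, "Cue")
  expect_equal(c(r0$overall$precision, r0$overall$recall, r0$overall$f1),
               c(0, 0, 0))
  expect_true(r0$overall$degenerate)
})

test_that("token level counts per-token joint tag agreement", {
  toks <- c("no", "dolor", "hoy")
  cue <- tok_span(toks, 1, 1)
  ent <- tok_span(toks, 2, 2)
  gold <- list(mini_doc("d1", toks, list(mention("Cue", cue[1], cue[2]),
                                         mention("DISO", ent[1], ent[2]))))
  pred <- list(mini_doc("d1", toks, list(mention("Cue", cue[1], cue[2]))))
  r <- token_eval(gold, pred)
  expect_equal(r$overall$tp, 1L)   # "no" tagged W-Cue in both
  expect_equal(r$overall$fn, 1L)   # missed W-DISO on "dolor"
  expect_equal(r$overall$fp, 0L)
})

test_that("counts are consistent and adding a correct prediction helps", {
  docs <- generate_corpus(gen_config(seed = 41, n_sentences = 40))
  pred <- lapply(docs, function(d) {
    d$sentences <- lapply(d$sentences, function(s) {
      # drop every second mention
      s$mentions <- s$mentions[seq_along(s$mentions) %% 2L == 1L]
      s
    })
    d
  })
  r <- entity_eval(docs, pred)
  n_gold <- length(unlist(lapply(docs, negscope:::doc_mentions),
                          recursive = FALSE))
  n_pred <- length(unlist(lapply(pred, negscope:::doc_mentions),
                          recursive = FALSE))
  expect_equal(r$overall$tp + r$overall$fn, n_gold)
  expect_equal(r$overall$tp + r$overall$fp, n_pred)
  # permutation invariance over documents
  r_perm <- entity_eval(rev(docs), rev(pred))
  expect_equal(r_perm$overall, r$overall)
  # restoring a dropped mention never lowers recall
  pred2 <- pred
  pred2[[1]]$sentences[[1]]$mentions <- docs[[1]]$sentences[[1]]$mentions
  expect_gte(entity_eval(docs, pred2)$overall$recall, r$overall$recall)
})
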