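# Seeded synthetic negation corpora.
#
# Emulates the structural phenomena of clinical/review negation corpora:
# sentences with single- and multi-token cues, scopes that start at the cue
# (or after it) and end at the next punctuation, inner entity mentions
# nested inside scopes (forcing V tags), double negation (two cues in one
# scope) and discontinuous cues ("no ... ni").  The vocabulary is nonsense
# tokens plus the cue lexicon, so no external resource is ever needed;
# entity words carry label-specific suffixes, mirroring the lexical
# regularity of clinical findings.

#' Configuration for the synthetic corpus generator
#'
#' @param seed integer seed; the same seed reproduces the corpus exactly
#' @param n_sentences number of sentences to generate
#' @param vocab_size number of nonsense noise-word types
#' @param len_min,len_max sentence length range (tokens, uniform), before
#'   punctuation
#' @param p_cue probability a sentence carries a negation cue (and scope)
#' @param p_multiword_cue probability a cue is a multiword locution
#' @param p_double_negation probability a scope holds a second cue
#' @param p_discontinuous probability a cue is discontinuous ("no ... ni")
#' @param p_inner_entity probability a scope token is an inner entity
#' @param cue_lexicon single-token cue strings
#' @param multiword_lexicon multiword cue strings (space-separated tokens)
#' @param entity_labels inner entity types
#' @param cue_label,scope_label mention labels for cues and scopes
#' @param scope_starts_after_cue start scopes after the cue instead of at it
#'   (emulates corpora that exclude parts of the clause from the scope)
#' @param sentences_per_doc sentences grouped into one document
#' @return a `gen_config` list
#' @export
gen_config <- function(seed = 7L, n_sentences = 100L, vocab_size = 80L,
                       len_min = 5L, len_max = 12L, p_cue = 0.5,
                       p_multiword_cue = 0.15, p_double_negation = 0.1,
                       p_discontinuous = 0.05, p_inner_entity = 0.4,
                       cue_lexicon = c("no", "sin", "tampoco", "nunca"),
                       multiword_lexicon = c("ausencia de", "ni siquiera",
                                             "en ningun momento"),
                       entity_labels = c("DISO", "PROC"),
                       cue_label = "NegMarker", scope_label = "Scope",
                       scope_starts_after_cue = FALSE,
                       sentences_per_doc = 10L) {
  cfg <- list(seed = as.integer(seed), n_sentences = as.integer(n_sentences),
              vocab_size = as.integer(vocab_size),
              len_min = as.integer(len_min), len_max = as.integer(len_max),
              p_cue = p_cue, p_multiword_cue = p_multiword_cue,
              p_double_negation = p_double_negation,
              p_discontinuous = p_discontinuous,
              p_inner_entity = p_inner_entity,
              cue_lexicon = cue_lexicon,
              multiword_lexicon = multiword_lexicon,
              entity_labels = entity_labels, cue_label = cue_label,
              scope_label = scope_label,
              scope_starts_after_cue = isTRUE(scope_starts_after_cue),
              sentences_per_doc = as.integer(sentences_per_doc))
  probs <- unlist(cfg[c("p_cue", "p_multiword_cue", "p_double_negation",
                        "p_discontinuous", "p_inner_entity")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cue_lexicon) == 0L) stop("cue lexicon must be non-empty")
  max_cue <- max(vapply(strsplit(c(cue_lexicon, multiword_lexicon), " "),
                        length, 1L))
  if (max_cue + 3L > cfg$len_max) {
    stop("longest cue does not fit the maximum sentence length")
  }
  structure(cfg, class = "gen_config")
}

# syllable inventory excludes "ni"/"no"/"si" so no noise word can contain a
# cue form as a confusing substring
syllables <- c("ba", "ce", "di", "fo", "gu", "la", "me", "po", "ra",
               "se", "ti", "vo", "zu", "ka", "lo")

make_lexicons <- function(cfg) {
  mk <- function(n, nsyl, suffix = "") {
    out <- character(0)
    while (length(out) < n) {
      w <- paste0(paste(sample(syllables, nsyl, replace = TRUE),
                        collapse = ""), suffix)
      if (!(w %in% out) && !(w %in% cfg$cue_lexicon)) out <- c(out, w)
    }
    out
  }
  noise <- mk(cfg$vocab_size, 3L)
  ents <- lapply(seq_along(cfg$entity_labels), function(i) {
    mk(8L, 2L, suffix = c("itis", "grafia", "oma", "emia")[((i - 1L) %% 4L) + 1L])
  })
  names(ents) <- cfg$entity_labels
  list(noise = noise, entities = ents)
}

cap_first <- function(w) {
  paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)))
}

# build one sentence: returns list(tokens = character vector, mention
# blueprints in token indices)
gen_sentence_tokens <- function(cfg, lex) {
  L <- sample(cfg$len_min:cfg$len_max, 1L)
  has_cue <- runif(1) < cfg$p_cue
  toks <- character(0)
  mentions <- list()   # list(label, from, to, frag2 = c(from,to) or NULL)
  if (!has_cue) {
    toks <- sample(lex$noise, L, replace = TRUE)
  } else {
    disc <- runif(1) < cfg$p_discontinuous
    multi <- !disc && runif(1) < cfg$p_multiword_cue
    cue_toks <- if (disc) "no"
                else if (multi) strsplit(sample(cfg$multiword_lexicon, 1L),
                                         " ")[[1L]]
                else sample(cfg$cue_lexicon, 1L)
    tail_len <- sample(2:4, 1L)
    if (disc) tail_len <- max(tail_len, 3L)
    n_fixed <- length(cue_toks) + tail_len
    n_pre <- sample(0:max(0L, L - n_fixed), 1L)
    n_suf <- max(0L, L - n_fixed - n_pre)
    pre <- if (n_pre > 0L) sample(lex$noise, n_pre, replace = TRUE) else
      character(0)
    tail_toks <- sample(lex$noise, tail_len, replace = TRUE)
    is_entity <- runif(tail_len) < cfg$p_inner_entity
    ent_lab <- character(tail_len)
    for (i in which(is_entity)) {
      ent_lab[i] <- sample(cfg$entity_labels, 1L)
      tail_toks[i] <- sample(lex$entities[[ent_lab[i]]], 1L)
    }
    frag2_at <- NA_integer_
    if (disc) {
      # second fragment "ni" replaces a middle tail slot
      frag2_at <- sample(2:(tail_len - 1L), 1L)
      tail_toks[frag2_at] <- "ni"
      is_entity[frag2_at] <- FALSE; ent_lab[frag2_at] <- ""
    }
    dbl_at <- NA_integer_
    if (!disc && runif(1) < cfg$p_double_negation) {
      free <- setdiff(which(!is_entity), c(1L))
      if (length(free) > 0L) {
        dbl_at <- if (length(free) == 1L) free else sample(free, 1L)
        tail_toks[dbl_at] <- sample(cfg$cue_lexicon, 1L)
      }
    }
    cue_from <- n_pre + 1L
    cue_to <- n_pre + length(cue_toks)
    tail_from <- cue_to + 1L
    toks <- c(pre, cue_toks, tail_toks)
    scope_from <- if (cfg$scope_starts_after_cue) tail_from else cue_from
    scope_to <- tail_from + tail_len - 1L
    mentions[[length(mentions) + 1L]] <-
      list(label = cfg$cue_label, from = cue_from, to = cue_to,
           frag2 = if (disc) rep(tail_from + frag2_at - 1L, 2L) else NULL)
    mentions[[length(mentions) + 1L]] <-
      list(label = cfg$scope_label, from = scope_from, to = scope_to,
           frag2 = NULL)
    for (i in which(is_entity)) {
      mentions[[length(mentions) + 1L]] <-
        list(label = ent_lab[i], from = tail_from + i - 1L,
             to = tail_from + i - 1L, frag2 = NULL)
    }
    if (!is.na(dbl_at)) {
      mentions[[length(mentions) + 1L]] <-
        list(label = cfg$cue_label, from = tail_from + dbl_at - 1L,
             to = tail_from + dbl_at - 1L, frag2 = NULL)
    }
    if (n_suf > 0L) {
      # punctuation closes the scope; suffix noise follows it
      toks <- c(toks, ",", sample(lex$noise, n_suf, replace = TRUE))
    }
  }
  toks <- c(toks, ".")
  toks[1L] <- cap_first(toks[1L])
  list(tokens = toks, mentions = mentions)
}

#' Generate a synthetic annotated corpus
#'
#' Every cue-bearing sentence contains a cue mention and a scope mention
#' starting at the cue (or after it) and ending at the next punctuation;
#' inner entity mentions are placed inside scopes (forcing V tags); double
#' negation yields two cues in one scope; discontinuous cues carry two
#' fragments.  Every document passes [bmewov_encode()] without error, and
#' the same seed yields a byte-identical corpus.
#'
#' @param config a [gen_config()]
#' @return list of `ns_document`s with gold mentions
#' @export
generate_corpus <- function(config = gen_config()) {
  set.seed(config$seed)
  lex <- make_lexicons(config)
  n_docs <- ceiling(config$n_sentences / config$sentences_per_doc)
  docs <- list()
  left <- config$n_sentences
  for (d in seq_len(n_docs)) {
    n_s <- min(config$sentences_per_doc, left)
    left <- left - n_s
    text <- ""
    sents <- list()
    for (s in seq_len(n_s)) {
      g <- gen_sentence_tokens(config, lex)
      n <- length(g$tokens)
      offset <- nchar(text) + if (nzchar(text)) 1L else 0L
      starts <- integer(n); ends <- integer(n)
      pos <- offset
      for (i in seq_len(n)) {
        starts[i] <- pos
        ends[i] <- pos + nchar(g$tokens[i])
        pos <- ends[i] + 1L
      }
      sent_text <- paste(g$tokens, collapse = " ")
      text <- if (nzchar(text)) paste(text, sent_text) else sent_text
      tokens <- data.frame(text = g$tokens, start = starts, end = ends,
                           index = seq_len(n) - 1L, stringsAsFactors = FALSE)
      ms <- lapply(g$mentions, function(b) {
        frags <- cbind(starts[b$from], ends[b$to])
        if (!is.null(b$frag2)) {
          frags <- rbind(frags, cbind(starts[b$frag2[1L]], ends[b$frag2[2L]]))
        }
        mention(b$label, fragments = frags)
      })
      sents[[length(sents) + 1L]] <-
        new_sentence(tokens, mentions = ms, text = sent_text,
                     start = starts[1L], end = ends[n])
    }
    docs[[length(docs) + 1L]] <-
      new_document(sprintf("synth_%04d", d), text, sents)
  }
  docs
}
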