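# Vocabularies and per-token feature bundles: character index sequences,
# word vectors and sense vectors.  Pretrained tables are optional; absent
# tables fall back to trainable embeddings (words/chars) or zero vectors
# (senses) so the pipeline runs without any external resource.

#' Load word vectors in word2vec text format
#'
#' First line `"<count> <dim>"`, then one `"token v1 ... vdim"` line per
#' vector.  Duplicated tokens keep their first occurrence with a warning.
#'
#' @param file path to the vector file (UTF-8)
#' @param kind `"word"` or `"sense"`
#' @return an `ns_embeddings` object: list with `vectors` (matrix, one row
#'   per token, rownames = tokens), `dim`, `kind`
#' @export
load_word_vectors <- function(file, kind = c("word", "sense")) {
  kind <- match.arg(kind)
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty vector file: ", file)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("line 1: expected header '<count> <dim>'")
  }
  dim <- hdr[2L]
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  toks <- character(length(body))
  vecs <- matrix(NA_real_, length(body), dim)
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(parts) != dim + 1L) {
      stop(sprintf("line %d: expected %d values after token, got %d",
                   i + 1L, dim, length(parts) - 1L))
    }
    toks[i] <- parts[1L]
    v <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric vector component", i + 1L))
    vecs[i, ] <- v
  }
  if (anyDuplicated(toks)) {
    dup <- unique(toks[duplicated(toks)])
    warning("duplicated tokens kept at first occurrence: ",
            paste(dup, collapse = ", "))
    keep <- !duplicated(toks)
    toks <- toks[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  rownames(vecs) <- toks
  structure(list(vectors = vecs, dim = dim, kind = kind),
            class = "ns_embeddings")
}

#' @export
print.ns_embeddings <- function(x, ...) {
  cat(sprintf("<%s embeddings> %d vectors, dim %d\n", x$kind,
              nrow(x$vectors), x$dim))
  invisible(x)
}

UNK <- "<unk>"

#' Build word and character vocabularies from training documents
#'
#' Index 1 is reserved for the unknown word/character in both alphabets;
#' unseen items at test time map to it.  The character alphabet is built
#' from training data only.
#'
#' @param docs list of `ns_document`s
#' @param lowercase build the word vocabulary over lowercased forms
#' @return an `ns_vocab`: list with named integer vectors `words`, `chars`
#'   and the `lowercase` flag
#' @export
build_vocab <- function(docs, lowercase = FALSE) {
  words <- character(0)
  for (doc in docs) {
    for (sent in doc$sentences) words <- c(words, sent$tokens$text)
  }
  if (lowercase) words <- tolower(words)
  wtypes <- sort(unique(words))
  ctypes <- sort(unique(unlist(strsplit(words, ""))))
  structure(list(
    words = setNames(seq_along(wtypes) + 1L, wtypes),
    chars = setNames(seq_along(ctypes) + 1L, ctypes),
    lowercase = lowercase),
    class = "ns_vocab")
}

word_index <- function(vocab, w) {
  if (vocab$lowercase) w <- tolower(w)
  i <- unname(vocab$words[w])
  i[is.na(i)] <- 1L
  i
}

char_indices <- function(vocab, w) {
  cs <- strsplit(w, "")[[1L]]
  i <- unname(vocab$chars[cs])
  i[is.na(i)] <- 1L
  if (length(i) == 0L) i <- 1L   # empty surface: lone unknown char
  i
}

# deterministic, seeded unknown-word vector (trainable init)
unk_vector <- function(dim, seed = 1L) {
  r <- get_rng_substate(seed)
  on.exit(r())
  runif(dim, -0.25, 0.25)
}

get_rng_substate <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-token feature bundle
#'
#' Word lookup order: exact surface form, then (if `lowercase_fallback`)
#' the lowercased form, then the unknown vector.  The sense lookup key is
#' `"surface|POS"` when a `pos` is supplied, else the lowercased surface;
#' with no sense table configured the sense vector is all zeros.  Characters
#' unseen in training map to the unknown index.
#'
#' @param token one row of a token data.frame (or list with `$text`)
#' @param word_table,sense_table optional `ns_embeddings`
#' @param vocab an `ns_vocab`
#' @param lowercase_fallback try the lowercased form on word lookup miss
#' @param pos optional part-of-speech tag for the sense key
#' @param sense_dim sense vector width when no table is configured
#' @param unk_seed seed of the trainable unknown-word vector
#' @return list with `char_indices`, `word_vector`, `sense_vector`
#' @export
featurize <- function(token, word_table = NULL, sense_table = NULL,
                      vocab, lowercase_fallback = TRUE, pos = NULL,
                      sense_dim = 0L, unk_seed = 1L) {
  surf <- token$text
  wv <- NULL
  if (!is.null(word_table)) {
    vs <- word_table$vectors
    if (surf %in% rownames(vs)) {
      wv <- vs[surf, ]
    } else if (lowercase_fallback && tolower(surf) %in% rownames(vs)) {
      wv <- vs[tolower(surf), ]
    } else {
      wv <- unk_vector(word_table$dim, unk_seed)
    }
  }
  sv <- NULL
  if (!is.null(sense_table)) {
    key <- if (!is.null(pos)) paste0(surf, "|", pos) else tolower(surf)
    vs <- sense_table$vectors
    sv <- if (key %in% rownames(vs)) vs[key, ] else
      rep(0, sense_table$dim)
  } else if (sense_dim > 0L) {
    sv <- rep(0, sense_dim)
  }
  list(char_indices = char_indices(vocab, surf),
       word_vector = wv,
       sense_vector = sv)
}

# ---- model-facing featurization -------------------------------------------
# A featurized sentence for the compiled encoder: 1-based char index
# sequences, 1-based word indices into the trainable embedding matrix (or a
# dense matrix of pretrained vectors), and an n x d_s sense matrix.
featurize_sentence <- function(sent, vocab, word_table = NULL,
                               sense_table = NULL, sense_dim = 0L) {
  toks <- sent$tokens$text
  n <- length(toks)
  ci <- lapply(toks, function(w) char_indices(vocab, w))
  wi <- word_index(vocab, toks)
  if (!is.null(sense_table)) {
    sm <- matrix(0, n, sense_table$dim)
    vs <- sense_table$vectors
    keys <- tolower(toks)
    hit <- keys %in% rownames(vs)
    if (any(hit)) sm[hit, ] <- vs[keys[hit], , drop = FALSE]
  } else {
    sm <- matrix(0, n, sense_dim)
  }
  wvm <- NULL
  if (!is.null(word_table)) {
    vs <- word_table$vectors
    wvm <- matrix(0, n, word_table$dim)
    for (i in seq_len(n)) {
      f <- featurize(list(text = toks[i]), word_table = word_table,
                     vocab = vocab)
      wvm[i, ] <- f$word_vector
    }
  }
  list(char_idx = ci, word_idx = wi, sense = sm, word_vecs = wvm, n = n)
}
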