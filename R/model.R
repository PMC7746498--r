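# Model configuration, parameter initialization and the emission encoder
# surface over the compiled core.

#' Model and training configuration
#'
#' Defaults follow the reference training regime for this architecture: hidden size 100 per
#' recurrent direction, character embedding dimension 25 with a 25-unit
#' character encoder per direction (so the morphological feature is
#' 50-wide), stochastic gradient descent with learning rate 0.005, dropout
#' 0.5 and 100 epochs.  Word/sense dimensions are taken from pretrained
#' tables when supplied; the from-scratch trainable defaults are
#' `word_dim = 50`, `sense_dim = 0`.
#'
#' @param word_dim trainable word embedding dimension (overridden by a
#'   pretrained table's dimension)
#' @param sense_dim sense vector width when no sense table is configured
#' @param char_dim character embedding dimension
#' @param char_hidden character encoder hidden units per direction
#' @param hidden token encoder hidden units per direction
#' @param lr SGD learning rate
#' @param dropout dropout rate on token features and encoder output
#' @param epochs training epochs
#' @param clip gradient-norm clipping threshold (0 disables)
#' @param patience early-stopping patience in epochs (0 = off, train the
#'   full `epochs`)
#' @param constrain forbid shape-invalid transitions with `-Inf` scores
#' @param seed integer seed governing all randomness of a run
#' @param lowercase lowercase word forms for the trainable vocabulary
#' @return a list of class `ns_config`
#' @export
crf_config <- function(word_dim = 50L, sense_dim = 0L, char_dim = 25L,
                       char_hidden = 25L, hidden = 100L, lr = 0.005,
                       dropout = 0.5, epochs = 100L, clip = 5.0,
                       patience = 0L, constrain = TRUE, seed = 42L,
                       lowercase = FALSE) {
  structure(list(word_dim = as.integer(word_dim),
                 sense_dim = as.integer(sense_dim),
                 char_dim = as.integer(char_dim),
                 char_hidden = as.integer(char_hidden),
                 hidden = as.integer(hidden),
                 lr = lr, dropout = dropout, epochs = as.integer(epochs),
                 clip = clip, patience = as.integer(patience),
                 constrain = isTRUE(constrain), seed = as.integer(seed),
                 lowercase = isTRUE(lowercase)),
            class = "ns_config")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

#' Initialize a recurrent CRF model
#'
#' @param labels joint label vocabulary ([joint_vocabulary()])
#' @param vocab an `ns_vocab` from [build_vocab()]
#' @param config an `ns_config`
#' @param word_table,sense_table optional pretrained `ns_embeddings`; the
#'   word table fixes the word vectors (they are then not trained)
#' @return an `ns_crf_model`: parameter list + metadata
#' @export
crf_model <- function(labels, vocab, config = crf_config(),
                      word_table = NULL, sense_table = NULL) {
  set.seed(config$seed)
  d_c <- config$char_dim; h_c <- config$char_hidden; H <- config$hidden
  d_w <- if (!is.null(word_table)) word_table$dim else config$word_dim
  d_s <- if (!is.null(sense_table)) sense_table$dim else config$sense_dim
  n_char <- length(vocab$chars) + 1L   # +1: unknown at index 1
  n_word <- length(vocab$words) + 1L
  D <- 2L * h_c + d_w + d_s
  ny <- length(labels)
  lstm_par <- function(d, h) {
    list(Wx = glorot(4L * h, d), Wh = glorot(4L * h, h), b = {
      b <- rep(0, 4L * h); b[(h + 1L):(2L * h)] <- 1  # forget-gate bias 1
      b
    })
  }
  cf <- lstm_par(d_c, h_c); cb <- lstm_par(d_c, h_c)
  tf <- lstm_par(D, H); tb <- lstm_par(D, H)
  trans <- matrix(0, ny + 2L, ny + 2L)
  if (config$constrain) {
    mask <- transition_mask(labels)
    trans[!mask] <- -Inf
  }
  params <- list(
    E_char = matrix(runif(n_char * d_c, -0.25, 0.25), n_char, d_c),
    E_word = matrix(runif(n_word * d_w, -0.25, 0.25), n_word, d_w),
    cf_Wx = cf$Wx, cf_Wh = cf$Wh, cf_b = cf$b,
    cb_Wx = cb$Wx, cb_Wh = cb$Wh, cb_b = cb$b,
    tf_Wx = tf$Wx, tf_Wh = tf$Wh, tf_b = tf$b,
    tb_Wx = tb$Wx, tb_Wh = tb$Wh, tb_b = tb$b,
    W_out = glorot(ny, 2L * H), b_out = rep(0, ny),
    trans = trans)
  structure(list(params = params, labels = labels, vocab = vocab,
                 config = config, word_table = word_table,
                 sense_table = sense_table, sense_dim = d_s),
            class = "ns_crf_model")
}

#' @export
print.ns_crf_model <- function(x, ...) {
  cat(sprintf(
    "<recurrent CRF model> %d joint labels, %d word types, %d char types\n",
    length(x$labels), length(x$vocab$words), length(x$vocab$chars)))
  invisible(x)
}

model_featurize <- function(model, sent) {
  featurize_sentence(sent, model$vocab, word_table = model$word_table,
                     sense_table = model$sense_table,
                     sense_dim = model$sense_dim)
}

#' Emission scores for a sentence
#'
#' Runs the character and token encoders and returns one row of
#' unnormalized scores per token over the joint label vocabulary
#' (deterministic: dropout is disabled outside training).
#'
#' @param model an `ns_crf_model`
#' @param sent an `ns_sentence` (or a pre-featurized sentence list)
#' @return `n_tokens x |Y|` matrix with the joint labels as column names
#' @export
encode_tokens <- function(model, sent) {
  feats <- if (inherits(sent, "ns_sentence")) model_featurize(model, sent)
           else sent
  if (feats$n < 1L) stop("sentence must contain at least one token")
  em <- cpp_emissions(model$params, feats)
  colnames(em) <- model$labels
  em
}
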