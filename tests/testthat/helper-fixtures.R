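# Shared fixtures: the worked clinical example sentence, tiny embedding
# files, and independent brute-force CRF oracles.

ref_text <- "Abdomen blando, depresible, no masas ni megalias, no doloroso."

ref_mentions <- function() {
  list(mention("NegMarker", 28, 30),
       mention("Phrase", 31, 48),
       mention("DISO", 31, 36),
       mention("NegPolItem", 37, 39),
       mention("DISO", 40, 48),
       mention("NegMarker", 50, 52),
       mention("DISO", 53, 61))
}

ref_sentence <- function() {
  s <- ns_tokenize(ref_text)[[1]]
  s$mentions <- ref_mentions()
  s
}

ref_document <- function(id = "negation_iac_3_corr") {
  structure(list(id = id, text = ref_text,
                 sentences = list(ref_sentence())),
            class = "ns_document")
}

ref_outer <- c("O", "O", "O", "O", "O", "W-NegMarker", "V-Phrase",
                "V-Phrase", "V-Phrase", "O", "W-NegMarker", "W-DISO", "O")
ref_inner <- c("O", "O", "O", "O", "O", "W-NegMarker", "W-DISO",
                "W-NegPolItem", "W-DISO", "O", "W-NegMarker", "W-DISO", "O")

keyset <- function(ms) sort(vapply(ms, negscope:::mention_key, ""))

write_vec_file <- function(lines) {
  f <- tempfile(fileext = ".vec")
  writeLines(lines, f, useBytes = TRUE)
  f
}

# ---- independent CRF oracles (exhaustive enumeration) ----------------------

# score of one path, written as plain arithmetic over the definition
oracle_path_score <- function(em, tr, y) {
  n <- nrow(em); ny <- ncol(em)
  s <- tr[ny + 1L, y[1]]
  for (t in seq_len(n)) {
    s <- s + em[t, y[t]]
    if (t > 1L) s <- s + tr[y[t - 1L], y[t]]
  }
  s + tr[y[n], ny + 2L]
}

# all |Y|^n paths (rows) and their scores, enumerated directly from the
# score definition (vectorized over paths so n = 8, |Y| = 6 stays fast)
oracle_enumerate <- function(em, tr) {
  n <- nrow(em); ny <- ncol(em)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ny)), n)))
  sc <- tr[ny + 1L, grid[, 1L]] + tr[cbind(grid[, n], ny + 2L)]
  for (t in seq_len(n)) {
    sc <- sc + em[cbind(t, grid[, t])]
    if (t > 1L) sc <- sc + tr[cbind(grid[, t - 1L], grid[, t])]
  }
  list(paths = grid, scores = sc)
}

oracle_all_paths <- function(em, tr) oracle_enumerate(em, tr)$scores

oracle_logz <- function(em, tr) {
  sc <- oracle_all_paths(em, tr)
  sc <- sc[is.finite(sc)]
  if (length(sc) == 0L) return(-Inf)
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

# unique argmax path; errors on ties (random real scores never tie)
oracle_argmax <- function(em, tr) {
  enum <- oracle_enumerate(em, tr)
  best <- which(enum$scores == max(enum$scores))
  stopifnot(length(best) == 1L)
  unname(enum$paths[best, ])
}

# random CRF instance; with valid = TRUE transitions are all finite
random_crf_instance <- function(n, ny, constrained = FALSE, labels = NULL) {
  em <- matrix(rnorm(n * ny), n, ny)
  tr <- matrix(rnorm((ny + 2L)^2), ny + 2L, ny + 2L)
  if (constrained && !is.null(labels)) {
    tr[!transition_mask(labels)] <- -Inf
  }
  list(em = em, tr = tr)
}
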