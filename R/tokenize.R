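# Rule-based, offset-preserving tokenizer.  The tokenizer is a pluggable
# contract: any function(text) returning a list of data.frames with columns
# text/start/end (0-based, end-exclusive code points) can replace the
# default, e.g. to mimic an external tokenizer's behaviour.

#' Default rule-based sentence splitter and tokenizer
#'
#' Tokens are maximal runs of letters/digits/underscore, or single other
#' non-space characters (punctuation is always its own token).  A sentence
#' break is placed after `.`, `!` or `?` when it is followed by whitespace
#' and an uppercase letter, and at end of text.  Requires no model download
#' and is fully deterministic.
#'
#' @param text UTF-8 character scalar
#' @return list of data.frames, one per sentence, columns `text`, `start`,
#'   `end` (0-based, end-exclusive, code points)
#' @export
default_tokenizer <- function(text) {
  if (is.na(text) || nchar(text) == 0L) return(list())
  m <- gregexpr("[\\p{L}\\p{N}_]+|[^\\p{L}\\p{N}_\\s]", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(list())
  starts <- as.integer(m) - 1L              # to 0-based
  lens <- attr(m, "match.length")
  ends <- starts + lens
  toks <- substring(text, starts + 1L, ends)
  n <- length(toks)

  # sentence break after ./!/? followed by whitespace + uppercase letter
  brk <- logical(n)
  for (i in seq_len(n - 1L)) {
    if (toks[i] %in% c(".", "!", "?")) {
      gap <- slice_text(text, ends[i], starts[i + 1L])
      if (nchar(gap) > 0L && grepl("^\\s+$", gap) &&
          grepl("^\\p{Lu}", toks[i + 1L], perl = TRUE)) {
        brk[i] <- TRUE
      }
    }
  }
  brk[n] <- TRUE
  bounds <- which(brk)
  out <- list()
  lo <- 1L
  for (hi in bounds) {
    idx <- lo:hi
    out[[length(out) + 1L]] <- data.frame(
      text = toks[idx], start = starts[idx], end = ends[idx],
      stringsAsFactors = FALSE)
    lo <- hi + 1L
  }
  out
}

#' Split text into tokenized sentences
#'
#' @param text UTF-8 character scalar; empty text gives an empty list.
#' @param splitter tokenizer function following the contract of
#'   [default_tokenizer()].
#' @return list of `ns_sentence` objects (tokens only, no mentions); token
#'   offsets always reconstruct the exact original substrings.
#' @export
ns_tokenize <- function(text, splitter = default_tokenizer) {
  sents <- splitter(text)
  lapply(sents, function(df) {
    df$index <- seq_len(nrow(df)) - 1L
    s <- df$start[1L]
    e <- df$end[nrow(df)]
    new_sentence(tokens = df, text = slice_text(text, s, e),
                 start = s, end = e)
  })
}
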