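#' @useDynLib negscope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
#' @importFrom utils head tail
"_PACKAGE"

# All character offsets in this package are 0-based, end-exclusive, counted
# in Unicode code points over the *document* text.

#' Slice a string by 0-based, end-exclusive code-point offsets
#' @param text a character scalar
#' @param start,end integer offsets, 0-based, end-exclusive
#' @return the substring `text[start:end)`
#' @export
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

#' Create an entity mention
#'
#' A mention is a typed annotation over one or more (possibly discontinuous)
#' character spans.  Cues, scopes and clinical entities are all mentions;
#' cues and entities may nest inside scopes.
#'
#' @param label entity type, e.g. `"NegMarker"`, `"DISO"`, `"Phrase"`.
#' @param start,end offsets of a single contiguous span (ignored when
#'   `fragments` is given).
#' @param fragments two-column integer matrix of `(start, end)` spans;
#'   more than one row makes the mention discontinuous.
#' @param id document-unique identifier (assigned on write if `NA`).
#' @return an object of class `ns_mention`
#' @export
mention <- function(label, start = NULL, end = NULL, fragments = NULL,
                    id = NA_character_) {
  if (is.null(fragments)) {
    fragments <- cbind(as.integer(start), as.integer(end))
  }
  fragments <- matrix(as.integer(fragments), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  if (nrow(fragments) == 0L) stop("mention needs at least one fragment")
  fragments <- fragments[order(fragments[, 1L]), , drop = FALSE]
  if (any(fragments[, 2L] <= fragments[, 1L])) {
    stop("mention fragments must satisfy end > start")
  }
  if (nrow(fragments) > 1L &&
      any(fragments[-1L, 1L] < fragments[-nrow(fragments), 2L])) {
    stop("mention fragments must be pairwise non-overlapping")
  }
  structure(list(id = id, label = label, fragments = fragments),
            class = "ns_mention")
}

#' @export
format.ns_mention <- function(x, ...) {
  frg <- paste(apply(x$fragments, 1L, function(f) paste(f, collapse = " ")),
               collapse = ";")
  sprintf("%s %s", x$label, frg)
}

#' @export
print.ns_mention <- function(x, ...) {
  cat("<mention>", format(x), "\n")
  invisible(x)
}

mention_key <- function(m) {
  paste0(m$label, "#", paste(t(m$fragments), collapse = ","))
}

mention_span <- function(m) {
  c(m$fragments[1L, 1L], m$fragments[nrow(m$fragments), 2L], use.names = FALSE)
}

#' Split discontinuous mentions into one mention per fragment
#'
#' The tag codec represents each fragment of a discontinuous mention as a
#' separate same-label mention; gold BRAT annotations keep the fragments
#' joined.  This helper maps the joined form onto the codec's view.
#'
#' @param mentions list of [mention()] objects
#' @return list of single-fragment mentions
#' @export
split_discontinuous <- function(mentions) {
  out <- list()
  for (m in mentions) {
    for (i in seq_len(nrow(m$fragments))) {
      out[[length(out) + 1L]] <- mention(m$label,
                                         m$fragments[i, 1L],
                                         m$fragments[i, 2L],
                                         id = m$id)
    }
  }
  out
}

new_sentence <- function(tokens, mentions = list(), text = "",
                         start = NA_integer_, end = NA_integer_,
                         tags = NULL) {
  structure(list(tokens = tokens, mentions = mentions, text = text,
                 start = start, end = end, tags = tags),
            class = "ns_sentence")
}

#' @export
print.ns_sentence <- function(x, ...) {
  cat(sprintf("<sentence> %d tokens, %d mentions: %s\n",
              nrow(x$tokens), length(x$mentions), x$text))
  invisible(x)
}

new_document <- function(id, text, sentences) {
  structure(list(id = id, text = text, sentences = sentences),
            class = "ns_document")
}

#' @export
print.ns_document <- function(x, ...) {
  cat(sprintf("<document %s> %d sentences, %d mentions\n", x$id,
              length(x$sentences),
              sum(vapply(x$sentences, function(s) length(s$mentions), 1L))))
  invisible(x)
}

doc_mentions <- function(doc) {
  unlist(lapply(doc$sentences, `[[`, "mentions"), recursive = FALSE)
}
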