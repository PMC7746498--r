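# BRAT standoff and CoNLL-2003-style I/O.

# the IULA reference encoding example spells one label "NegPolIten"; the
# entity inventory spells it "NegPolItem".  Normalization is configurable.
default_label_map <- c(NegPolIten = "NegPolItem")

read_text_file <- function(path) {
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  enc2utf8(raw)
}

norm_ws <- function(x) gsub("\\s+", " ", trimws(x))

#' Read a BRAT standoff document (.txt + .ann pair)
#'
#' Only T (entity) lines are read; A/R/E and other annotation kinds are
#' skipped with a warning.  Discontinuous spans are separated by `";"` in
#' the offset field.  A mention crossing a sentence boundary is clipped to
#' the sentence containing its first fragment, with a warning.
#'
#' @param text_file path to the `.txt` file (UTF-8)
#' @param ann_file path to the `.ann` file
#' @param splitter tokenizer, see [ns_tokenize()]
#' @param label_map named character vector of label spelling normalizations
#' @param id document id; default is the text file name without extension
#' @return an `ns_document`
#' @export
read_brat <- function(text_file, ann_file, splitter = default_tokenizer,
                      label_map = default_label_map, id = NULL) {
  text <- read_text_file(text_file)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(text_file))
  sents <- ns_tokenize(text, splitter)
  n_text <- nchar(text)

  lines <- readLines(ann_file, encoding = "UTF-8", warn = FALSE)
  mentions <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (!startsWith(ln, "T")) {
      warning(sprintf("%s line %d: skipping non-entity annotation '%s'",
                      basename(ann_file), i, substr(ln, 1L, 1L)))
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop(sprintf("%s line %d: malformed annotation line", basename(ann_file), i))
    }
    body <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
    if (length(body) < 3L) {
      stop(sprintf("%s line %d: expected 'Label start end[;start end]*'",
                   basename(ann_file), i))
    }
    label <- body[1L]
    if (label %in% names(label_map)) label <- unname(label_map[label])
    span_str <- paste(body[-1L], collapse = " ")
    frag_strs <- strsplit(span_str, ";", fixed = TRUE)[[1L]]
    frags <- lapply(frag_strs, function(fs) {
      nums <- suppressWarnings(as.integer(strsplit(trimws(fs), " ")[[1L]]))
      if (length(nums) != 2L || anyNA(nums)) {
        stop(sprintf("%s line %d: bad offset pair '%s'",
                     basename(ann_file), i, fs))
      }
      nums
    })
    frags <- do.call(rbind, frags)
    if (any(frags < 0L) || any(frags[, 2L] > n_text)) {
      stop(sprintf("%s line %d: offset outside document text (length %d)",
                   basename(ann_file), i, n_text))
    }
    m <- mention(label, fragments = frags, id = fields[1L])
    if (length(fields) >= 3L && nzchar(fields[3L])) {
      got <- paste(apply(m$fragments, 1L, function(f)
        slice_text(text, f[1L], f[2L])), collapse = " ")
      if (norm_ws(got) != norm_ws(fields[3L])) {
        warning(sprintf(
          "%s line %d: surface text '%s' does not match text slice '%s'",
          basename(ann_file), i, fields[3L], got))
      }
    }
    mentions[[length(mentions) + 1L]] <- m
  }

  assign_mentions(new_document(id, text, sents), mentions)
}

# Attach mentions to the sentence containing their first fragment; clip
# fragments extending beyond that sentence.
assign_mentions <- function(doc, mentions) {
  sents <- doc$sentences
  if (length(sents) == 0L) {
    if (length(mentions) > 0L) {
      warning("document has no sentences; dropping all mentions")
    }
    return(doc)
  }
  s_start <- vapply(sents, `[[`, 1L, "start")
  s_end <- vapply(sents, `[[`, 1L, "end")
  for (m in mentions) {
    fs <- m$fragments[1L, 1L]
    si <- which(s_start <= fs & fs < s_end)
    if (length(si) == 0L) si <- max(which(s_start <= fs), 1L)
    si <- si[1L]
    frags <- m$fragments
    keep <- frags[, 1L] < s_end[si]
    if (!all(keep) || any(frags[, 2L] > s_end[si])) {
      warning(sprintf(
        "mention %s (%s) crosses a sentence boundary; clipped to sentence %d",
        m$id, m$label, si))
      frags <- frags[keep, , drop = FALSE]
      frags[, 2L] <- pmin(frags[, 2L], s_end[si])
    }
    m$fragments <- frags
    sents[[si]]$mentions[[length(sents[[si]]$mentions) + 1L]] <- m
  }
  doc$sentences <- sents
  doc
}

#' Write a document as BRAT standoff
#'
#' @param doc an `ns_document`
#' @return list with `text` (the document text) and `ann_lines` (character
#'   vector of T lines; ids renumbered T1..Tn in sentence order).
#'   `read_brat(write_brat(doc))` reproduces the mentions exactly up to id
#'   renumbering.
#' @export
write_brat <- function(doc) {
  ms <- doc_mentions(doc)
  lines <- character(length(ms))
  for (i in seq_along(ms)) {
    m <- ms[[i]]
    span <- paste(apply(m$fragments, 1L, paste, collapse = " "),
                  collapse = ";")
    surf <- paste(apply(m$fragments, 1L, function(f)
      slice_text(doc$text, f[1L], f[2L])), collapse = " ")
    lines[i] <- sprintf("T%d\t%s %s\t%s", i, m$label, span, surf)
  }
  list(text = doc$text, ann_lines = lines)
}

#' Write BRAT .txt/.ann files to disk
#' @param doc an `ns_document`
#' @param stem path prefix; writes `<stem>.txt` and `<stem>.ann`
#' @return invisibly, the two paths
#' @export
write_brat_files <- function(doc, stem) {
  b <- write_brat(doc)
  txt <- paste0(stem, ".txt"); ann <- paste0(stem, ".ann")
  writeLines(b$text, txt, useBytes = TRUE, sep = "")
  writeLines(b$ann_lines, ann, useBytes = TRUE)
  invisible(c(txt, ann))
}

#' Write a document in CoNLL-2003-style columns
#'
#' Column layout: token, document id, start offset, end offset, outer tag,
#' inner tag (tab-separated; blank line between sentences).  Tags default
#' to the BMEWO-V encoding of the document's mentions.
#'
#' @param doc an `ns_document`
#' @param layered_tags optional list (one per sentence) of
#'   `list(outer=..., inner=...)` tag vectors; computed with
#'   [bmewov_encode()] when `NULL`.
#' @return character vector of lines
#' @export
write_conll <- function(doc, layered_tags = NULL) {
  out <- character(0)
  for (si in seq_along(doc$sentences)) {
    sent <- doc$sentences[[si]]
    tags <- if (is.null(layered_tags)) bmewov_encode(sent) else
      layered_tags[[si]]
    lines <- sprintf("%s\t%s\t%d\t%d\t%s\t%s",
                     sent$tokens$text, doc$id,
                     sent$tokens$start, sent$tokens$end,
                     tags$outer, tags$inner)
    out <- c(out, lines, "")
  }
  out
}

#' Read CoNLL-2003-style token tables
#'
#' Inverse of [write_conll()]: `read_conll(write_conll(doc))` reproduces the
#' tokens and tag layers exactly.  Document text is reconstructed from the
#' token offsets (gaps filled with spaces).
#'
#' @param lines character vector of lines, or a file path
#' @return list of `ns_document`s, one per document id, with per-sentence
#'   `tags` set and mentions decoded from the tags
#' @export
read_conll <- function(lines) {
  if (length(lines) == 1L && !grepl("\t", lines) && file.exists(lines)) {
    lines <- readLines(lines, encoding = "UTF-8", warn = FALSE)
  }
  sent_rows <- list()
  cur <- list()
  n_tag_cols <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) {
      if (length(cur) > 0L) {
        sent_rows[[length(sent_rows) + 1L]] <- cur
        cur <- list()
      }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L || length(f) > 6L) {
      stop(sprintf("line %d: expected 5 or 6 tab-separated columns, got %d",
                   i, length(f)))
    }
    if (is.na(n_tag_cols)) n_tag_cols <- length(f) - 4L
    if (length(f) - 4L != n_tag_cols) {
      stop(sprintf("line %d: ragged column count (%d tag columns, expected %d)",
                   i, length(f) - 4L, n_tag_cols))
    }
    st <- suppressWarnings(as.integer(f[3L])); en <- suppressWarnings(as.integer(f[4L]))
    if (is.na(st) || is.na(en)) stop(sprintf("line %d: bad offsets", i))
    cur[[length(cur) + 1L]] <- list(tok = f[1L], doc = f[2L], start = st,
                                    end = en, tags = f[5:length(f)])
  }
  if (length(cur) > 0L) sent_rows[[length(sent_rows) + 1L]] <- cur

  doc_ids <- unique(vapply(sent_rows, function(s) s[[1L]]$doc, ""))
  docs <- lapply(doc_ids, function(did) {
    srs <- Filter(function(s) s[[1L]]$doc == did, sent_rows)
    sents <- list()
    max_end <- 0L
    for (rows in srs) max_end <- max(max_end, vapply(rows, `[[`, 1L, "end"))
    chars <- rep(" ", max_end)
    for (rows in srs) {
      for (r in rows) {
        if (nchar(r$tok) != r$end - r$start) {
          stop(sprintf("token '%s' length disagrees with offsets %d %d",
                       r$tok, r$start, r$end))
        }
        tc <- strsplit(r$tok, "")[[1L]]
        chars[(r$start + 1L):r$end] <- tc
      }
    }
    text <- paste(chars, collapse = "")
    for (rows in srs) {
      df <- data.frame(text = vapply(rows, `[[`, "", "tok"),
                       start = vapply(rows, `[[`, 1L, "start"),
                       end = vapply(rows, `[[`, 1L, "end"),
                       stringsAsFactors = FALSE)
      df$index <- seq_len(nrow(df)) - 1L
      outer <- vapply(rows, function(r) r$tags[1L], "")
      inner <- if (length(rows[[1L]]$tags) > 1L)
        vapply(rows, function(r) r$tags[2L], "") else outer
      tags <- list(outer = outer, inner = inner)
      sent <- new_sentence(df, text = slice_text(text, df$start[1L],
                                                 df$end[nrow(df)]),
                           start = df$start[1L], end = df$end[nrow(df)],
                           tags = tags)
      sent$mentions <- bmewov_decode(tags, df)
      sents[[length(sents) + 1L]] <- sent
    }
    new_document(did, text, sents)
  })
  docs
}
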