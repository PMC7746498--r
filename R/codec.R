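# BMEWO-V tag codec.
#
# Shapes: B (begin), M (middle), E (end), W (whole single-token entity),
# V (token of a mention that overlaps/nests other mentions), O (outside).
# A sentence is encoded in two layers: the outer layer holds top-level
# mentions (shape V when they contain inner mentions), the inner layer holds
# the contained mentions; a token inside an outer mention but in no inner
# mention copies its outer tag to the inner layer.  The two layers are
# flattened to one joint label "outer|inner" ("O|O" collapses to "O") so a
# single CRF recognizes cues and scopes in one stage.

TAG_SHAPES <- c("B", "M", "E", "W", "V", "O")

tag_shape <- function(tag) ifelse(tag == "O", "O", substr(tag, 1L, 1L))
tag_label <- function(tag) ifelse(tag == "O", "", substr(tag, 3L, nchar(tag)))

# canonical composite label: "O" when both layers are outside, the plain
# single-layer tag when the inner layer merely copies the outer one, and
# "outer|inner" otherwise
joint_tag <- function(outer, inner) {
  ifelse(outer == inner, outer, paste0(outer, "|", inner))
}

split_joint <- function(joint) {
  outer <- inner <- rep("O", length(joint))
  has <- grepl("|", joint, fixed = TRUE)
  parts <- strsplit(joint[has], "|", fixed = TRUE)
  outer[has] <- vapply(parts, `[[`, "", 1L)
  inner[has] <- vapply(parts, `[[`, "", 2L)
  plain <- !has & joint != "O"
  outer[plain] <- joint[plain]
  inner[plain] <- joint[plain]
  list(outer = outer, inner = inner)
}

# token indices (1-based) covered by a [start,end) character span
span_token_range <- function(tokens, s, e) {
  which(tokens$start < e & tokens$end > s)
}

#' Encode a sentence's mentions as two-layer BMEWO-V tags
#'
#' Discontinuous mentions are first split into one mention per fragment.
#' Mentions may nest to depth 2: a top-level mention that contains others is
#' tagged `V-label` on all of its tokens in the outer layer, and the
#' contained mentions are tagged `B/M/E/W` in the inner layer.  Top-level
#' mentions containing nothing get `B/M/E/W` in the outer layer.  Tokens in
#' no mention are `O` in both layers; tokens inside an outer mention but in
#' no inner mention copy the outer tag to the inner layer.
#'
#' @param sentence an `ns_sentence`
#' @return list with character vectors `outer`, `inner` (one tag per token)
#'   and `joint` (flattened composite labels)
#' @export
bmewov_encode <- function(sentence) {
  tokens <- sentence$tokens
  n <- nrow(tokens)
  outer <- inner <- rep("O", n)
  ms <- split_discontinuous(sentence$mentions)
  if (length(ms) == 0L) {
    return(list(outer = outer, inner = inner, joint = joint_tag(outer, inner)))
  }
  ranges <- lapply(ms, function(m)
    span_token_range(tokens, m$fragments[1L, 1L], m$fragments[1L, 2L]))
  empty <- vapply(ranges, length, 1L) == 0L
  if (any(empty)) {
    stop("mention covers no token: ",
         paste(vapply(ms[empty], format, ""), collapse = "; "))
  }
  k <- length(ms)
  # containment / overlap analysis on token index sets
  contains <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      ri <- ranges[[i]]; rj <- ranges[[j]]
      inter <- length(intersect(ri, rj))
      if (inter == 0L) next
      if (inter == length(rj) && length(rj) < length(ri)) {
        contains[i, j] <- TRUE
      } else if (inter == length(ri) && length(ri) < length(rj)) {
        # handled from the other side
      } else if (inter == length(ri) && inter == length(rj)) {
        stop(sprintf("mentions with identical token spans cannot be nested: %s / %s",
                     format(ms[[i]]), format(ms[[j]])))
      } else if (inter < length(ri) && inter < length(rj)) {
        stop(sprintf("partially overlapping (non-nested) mentions: %s / %s",
                     format(ms[[i]]), format(ms[[j]])))
      }
    }
  }
  contained_by <- lapply(seq_len(k), function(j) which(contains[, j]))
  top <- which(vapply(contained_by, length, 1L) == 0L)
  innr <- setdiff(seq_len(k), top)
  for (j in innr) {
    if (length(contained_by[[j]]) > 1L) {
      stop(sprintf("mention nested deeper than 2 levels (or in two parents): %s",
                   format(ms[[j]])))
    }
    if (any(contains[innr, j])) {
      stop(sprintf("nesting depth > 2 at mention %s", format(ms[[j]])))
    }
  }
  # inner mentions must not share tokens with each other
  if (length(innr) > 1L) {
    all_in <- unlist(ranges[innr])
    if (anyDuplicated(all_in)) {
      stop("two inner mentions share a token (nesting depth limit is 2)")
    }
  }
  shape_run <- function(len) {
    if (len == 1L) "W" else c("B", rep("M", len - 2L), "E")
  }
  for (i in top) {
    r <- ranges[[i]]
    if (any(outer[r] != "O")) {
      stop(sprintf("top-level mentions share a token: %s", format(ms[[i]])))
    }
    if (any(contains[i, ])) {
      outer[r] <- paste0("V-", ms[[i]]$label)
    } else {
      outer[r] <- paste0(shape_run(length(r)), "-", ms[[i]]$label)
    }
  }
  for (j in innr) {
    r <- ranges[[j]]
    inner[r] <- paste0(shape_run(length(r)), "-", ms[[j]]$label)
  }
  copy <- inner == "O" & outer != "O"
  inner[copy] <- outer[copy]
  list(outer = outer, inner = inner, joint = joint_tag(outer, inner))
}

# extract mentions from one tag layer (assumed repaired/valid);
# mask = logical vector of tokens to treat as O (inner-layer copies)
layer_mentions <- function(tags, tokens, mask = NULL) {
  if (!is.null(mask)) tags[mask] <- "O"
  n <- length(tags)
  sh <- tag_shape(tags)
  lb <- tag_label(tags)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (sh[i] == "O") { i <- i + 1L; next }
    if (sh[i] == "V") {                 # maximal same-label V run
      j <- i
      while (j < n && sh[j + 1L] == "V" && lb[j + 1L] == lb[i]) j <- j + 1L
    } else if (sh[i] == "W") {
      j <- i
    } else {                            # B ... E (valid after repair)
      j <- i
      while (j < n && sh[j] != "E") j <- j + 1L
    }
    out[[length(out) + 1L]] <- mention(lb[i], tokens$start[i], tokens$end[j])
    i <- j + 1L
  }
  out
}

#' Decode two-layer BMEWO-V tags into entity mentions
#'
#' Model output may be shape-invalid, so [bmewov_repair()] is applied per
#' layer first.  Maximal same-label V runs in the outer layer become one
#' mention each; `B..E`/`W` groups in each layer become mentions; tokens
#' whose inner tag merely copies the outer tag carry no inner mention; any
#' remaining (label, span) duplicates across layers are emitted once.
#' `bmewov_decode(bmewov_encode(s))` reproduces `s`'s mentions exactly
#' (discontinuous mentions as their per-fragment split).
#'
#' @param tags list with `outer` and `inner` tag vectors (or `joint`)
#' @param tokens the sentence's token data.frame
#' @param repair apply tag repair first (default `TRUE`)
#' @return list of mentions (single-fragment, token-aligned offsets)
#' @export
bmewov_decode <- function(tags, tokens, repair = TRUE) {
  if (is.null(tags$outer)) tags <- split_joint(tags$joint)
  outer <- tags$outer; inner <- tags$inner
  if (repair) {
    outer <- repair_layer(outer)
    inner <- repair_layer(inner)
  }
  res <- layer_mentions(outer, tokens)
  copies <- inner == outer
  res <- c(res, layer_mentions(inner, tokens, mask = copies))
  keys <- vapply(res, mention_key, "")
  res[!duplicated(keys)]
}

# deterministic per-layer repair:
#  - M/E with no open entity of the same label start a new entity (as B)
#  - an entity left open is closed at its last consistent token
#  - a single-token entity is W
repair_layer <- function(tags) {
  n <- length(tags)
  out <- rep("O", n)
  sh <- tag_shape(tags)
  lb <- tag_label(tags)
  open_lab <- NULL
  open_start <- 0L
  close_open <- function(upto) {
    if (is.null(open_lab)) return()
    if (upto == open_start) {
      out[open_start] <<- paste0("W-", open_lab)
    } else {
      out[open_start] <<- paste0("B-", open_lab)
      if (upto > open_start + 1L) {
        out[(open_start + 1L):(upto - 1L)] <<- paste0("M-", open_lab)
      }
      out[upto] <<- paste0("E-", open_lab)
    }
    open_lab <<- NULL
  }
  for (i in seq_len(n)) {
    s <- sh[i]; l <- lb[i]
    if (s == "O") {
      close_open(i - 1L)
    } else if (s == "V") {
      close_open(i - 1L)
      out[i] <- tags[i]
    } else if (s == "W") {
      close_open(i - 1L)
      out[i] <- tags[i]
    } else if (s == "B") {
      close_open(i - 1L)
      open_lab <- l; open_start <- i
    } else if (s == "M") {
      if (is.null(open_lab) || open_lab != l) {
        close_open(i - 1L)
        open_lab <- l; open_start <- i
      }
    } else if (s == "E") {
      if (!is.null(open_lab) && open_lab == l) {
        close_open(i)
      } else {
        close_open(i - 1L)
        open_lab <- l; open_start <- i
      }
    }
  }
  close_open(n)
  out
}

#' Repair a raw joint label sequence
#'
#' Applies the deterministic per-layer repair to any label sequence over the
#' joint vocabulary so the result always satisfies the layered-tag
#' invariants.  Idempotent; output length equals input length.
#'
#' @param joint character vector of composite labels ("outer|inner" or "O")
#' @return repaired joint label vector
#' @export
bmewov_repair <- function(joint) {
  layers <- split_joint(joint)
  joint_tag(repair_layer(layers$outer), repair_layer(layers$inner))
}

# validity check used by property tests: every layer is a sequence of
# O / W / V-runs / proper B (M*) E groups
layer_is_valid <- function(tags) {
  n <- length(tags)
  sh <- tag_shape(tags)
  lb <- tag_label(tags)
  open <- NULL
  for (i in seq_len(n)) {
    if (sh[i] %in% c("O", "W", "V")) {
      if (!is.null(open)) return(FALSE)
    } else if (sh[i] == "B") {
      if (!is.null(open)) return(FALSE)
      open <- lb[i]
    } else if (sh[i] == "M") {
      if (is.null(open) || open != lb[i]) return(FALSE)
    } else if (sh[i] == "E") {
      if (is.null(open) || open != lb[i]) return(FALSE)
      open <- NULL
    } else {
      return(FALSE)
    }
  }
  is.null(open)
}

#' Is a joint tag sequence shape-valid in both layers?
#' @param joint character vector of composite labels
#' @return logical scalar
#' @export
joint_is_valid <- function(joint) {
  layers <- split_joint(joint)
  layer_is_valid(layers$outer) && layer_is_valid(layers$inner)
}

#' Build the joint label vocabulary
#'
#' With a single entity label the vocabulary is the six BMEWO-V tags
#' (`{B,M,E,W,V}-label` plus `O`).  With several labels, the vocabulary is
#' all single-layer labels plus the outer|inner pairs observed in an encoded
#' corpus; ordering is deterministic (sorted, `O` first).
#'
#' @param entity_labels non-empty character vector of entity type names
#' @param corpus optional list of `ns_document`s whose encoded sentences
#'   supply the observed outer|inner pairs
#' @return ordered character vector of joint labels
#' @export
joint_vocabulary <- function(entity_labels, corpus = NULL) {
  entity_labels <- unique(entity_labels)
  if (length(entity_labels) == 0L) stop("entity label set must be non-empty")
  singles <- as.vector(outer(c("B", "M", "E", "W", "V"), entity_labels,
                             function(s, l) paste0(s, "-", l)))
  vocab <- joint_tag(singles, singles)
  if (!is.null(corpus)) {
    for (doc in corpus) {
      for (sent in doc$sentences) {
        vocab <- c(vocab, bmewov_encode(sent)$joint)
      }
    }
  }
  vocab <- setdiff(unique(vocab), "O")
  c("O", sort(vocab))
}
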