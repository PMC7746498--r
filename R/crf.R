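# Linear-chain CRF over the joint BMEWO-V label space.
#
# A path y_1..y_n over labels Y is scored
#   score(y) = T[start, y_1] + sum_t E[t, y_t] + sum_{t>1} T[y_{t-1}, y_t]
#              + T[y_n, stop]
# with emissions E (n x |Y|) and transitions T ((|Y|+2) x (|Y|+2); row
# |Y|+1 = start state, column |Y|+2 = stop state).  Forbidden transitions
# carry -Inf when constraint mode is on.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_trans <- function(emissions, trans) {
  ny <- ncol(emissions)
  if (!is.matrix(trans) || nrow(trans) != ny + 2L || ncol(trans) != ny + 2L) {
    stop(sprintf("transition matrix must be %d x %d (|Y| + start/stop)",
                 ny + 2L, ny + 2L))
  }
}

#' Score one label path under a linear-chain CRF
#'
#' @param emissions numeric matrix, one row per token, one column per joint
#'   label (unnormalized scores)
#' @param trans transition matrix `(|Y|+2) x (|Y|+2)`; row `|Y|+1` is the
#'   start state, column `|Y|+2` the stop state
#' @param y integer label path (1-based column indices) or character labels
#'   matching `colnames(emissions)`
#' @return the path score (a real number)
#' @export
crf_sequence_score <- function(emissions, trans, y) {
  check_trans(emissions, trans)
  n <- nrow(emissions); ny <- ncol(emissions)
  if (is.character(y)) {
    iy <- match(y, colnames(emissions))
    if (anyNA(iy)) stop("unknown label: ", paste(y[is.na(iy)], collapse = ", "))
    y <- iy
  }
  if (length(y) != n) stop("label path length must equal number of tokens")
  if (any(y < 1L | y > ny)) stop("label index out of range")
  start <- ny + 1L; stop_ <- ny + 2L
  s <- trans[start, y[1L]] + sum(emissions[cbind(seq_len(n), y)])
  if (n > 1L) s <- s + sum(trans[cbind(y[-n], y[-1L])])
  s + trans[y[n], stop_]
}

#' Log-partition function of a linear-chain CRF (forward recursion)
#'
#' `log sum over all |Y|^n paths of exp(crf_sequence_score)`, computed in
#' log space.
#'
#' @inheritParams crf_sequence_score
#' @return log Z (a real number)
#' @export
crf_log_partition <- function(emissions, trans) {
  check_trans(emissions, trans)
  n <- nrow(emissions); ny <- ncol(emissions)
  if (n < 1L) stop("need at least one token")
  start <- ny + 1L; stop_ <- ny + 2L
  alpha <- trans[start, seq_len(ny)] + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      alpha <- vapply(seq_len(ny), function(y) {
        logsumexp(alpha + trans[seq_len(ny), y]) + emissions[t, y]
      }, 0)
    }
  }
  logsumexp(alpha + trans[seq_len(ny), stop_])
}

#' Negative log-likelihood of a gold path
#'
#' `crf_log_partition(emissions, trans) - crf_sequence_score(..., gold)`;
#' always `>= 0`.
#'
#' @inheritParams crf_sequence_score
#' @param gold gold label path
#' @return the NLL (a real number)
#' @export
crf_nll <- function(emissions, trans, gold) {
  crf_log_partition(emissions, trans) -
    crf_sequence_score(emissions, trans, gold)
}

#' Viterbi decoding
#'
#' Returns the highest-scoring label path; ties are broken towards the
#' lowest label index.
#'
#' @inheritParams crf_sequence_score
#' @return integer vector of 1-based label indices (with `labels` attribute
#'   when `emissions` has column names)
#' @export
viterbi_decode <- function(emissions, trans) {
  check_trans(emissions, trans)
  n <- nrow(emissions); ny <- ncol(emissions)
  if (n < 1L) stop("need at least one token")
  start <- ny + 1L; stop_ <- ny + 2L
  delta <- trans[start, seq_len(ny)] + emissions[1L, ]
  back <- matrix(0L, n, ny)
  if (n > 1L) {
    for (t in 2:n) {
      nd <- numeric(ny)
      for (y in seq_len(ny)) {
        cand <- delta + trans[seq_len(ny), y]
        b <- which.max(cand)     # which.max returns the first (lowest) index
        back[t, y] <- b
        nd[y] <- cand[b] + emissions[t, y]
      }
      delta <- nd
    }
  }
  fin <- delta + trans[seq_len(ny), stop_]
  y <- integer(n)
  y[n] <- which.max(fin)
  if (n > 1L) {
    for (t in n:2) y[t - 1L] <- back[t, y[t]]
  }
  if (!is.null(colnames(emissions))) {
    attr(y, "labels") <- colnames(emissions)[y]
  }
  y
}

# ---- transition constraints -----------------------------------------------

# per-layer shape rule: from O/W/E/V any of O/B/W/V may follow; from B-x or
# M-x only M-x/E-x may follow.  Start behaves like O; stop is reachable only
# from O/W/E/V.
layer_transition_ok <- function(prev, nxt) {
  ps <- tag_shape(prev); pl <- tag_label(prev)
  nssh <- tag_shape(nxt); nl <- tag_label(nxt)
  if (ps %in% c("B", "M")) {
    return(nssh %in% c("M", "E") && nl == pl)
  }
  nssh %in% c("O", "B", "W", "V")
}

joint_transition_ok <- function(prev_joint, next_joint) {
  p <- split_joint(prev_joint)
  q <- split_joint(next_joint)
  layer_transition_ok(p$outer, q$outer) &&
    layer_transition_ok(p$inner, q$inner)
}

#' Transition constraint mask for a joint vocabulary
#'
#' Entry `[i, j]` is `TRUE` when label `j` may follow label `i` under the
#' BMEWO-V shape rules in *both* layers (e.g. `M` may not follow `O`, an
#' entity may not change label between `B` and `E`, a path may not start
#' with `M`/`E` nor end in `B`/`M`).
#'
#' @param labels joint label vocabulary (from [joint_vocabulary()])
#' @return logical matrix `(|Y|+2) x (|Y|+2)` including start row / stop
#'   column
#' @export
transition_mask <- function(labels) {
  ny <- length(labels)
  ok <- matrix(FALSE, ny + 2L, ny + 2L)
  layers <- lapply(labels, function(l) split_joint(l))
  starts_ok <- vapply(layers, function(p) {
    tag_shape(p$outer) %in% c("O", "B", "W", "V") &&
      tag_shape(p$inner) %in% c("O", "B", "W", "V")
  }, TRUE)
  stops_ok <- vapply(layers, function(p) {
    !(tag_shape(p$outer) %in% c("B", "M")) &&
      !(tag_shape(p$inner) %in% c("B", "M"))
  }, TRUE)
  for (i in seq_len(ny)) {
    for (j in seq_len(ny)) {
      ok[i, j] <- layer_transition_ok(layers[[i]]$outer, layers[[j]]$outer) &&
        layer_transition_ok(layers[[i]]$inner, layers[[j]]$inner)
    }
  }
  ok[ny + 1L, seq_len(ny)] <- starts_ok
  ok[seq_len(ny), ny + 2L] <- stops_ok
  dimnames(ok) <- list(c(labels, "<start>", "<stop>"),
                       c(labels, "<start>", "<stop>"))
  ok
}
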