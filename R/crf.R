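# Linear-chain CRF: the label-sequence-optimization layer.
#
# A tag path y_1..y_n is scored as
#   start[y1] + sum_i E[i, yi] + sum_i T[y_{i-1}, yi] + stop[yn]
# with E the per-token emission scores. Training minimizes the negative
# log-likelihood (log-partition minus gold-path score); the gradient is the
# difference between expected and observed feature counts, computed with
# the forward-backward algorithm in log space. Decoding is Viterbi with
# ties broken toward the lowest tag index.

# Large-but-finite score used to forbid scheme-invalid transitions; finite
# so that log-space arithmetic stays NaN-free even when a whole row is
# masked.
.TRANS_FORBID <- -1e4

#' CRF parameter set
#'
#' @param n_tags number of tags.
#' @param tags optional tag names (row/column names of the transition
#'   matrix).
#' @param init_sd parameters are drawn N(0, init_sd); 0 gives all-zero
#'   parameters.
#' @param seed RNG seed used when `init_sd > 0`.
#' @return list with `trans` (T\[y', y\]: score of y following y'),
#'   `start`, `stop`.
#' @export
crf_parameters <- function(n_tags, tags = NULL, init_sd = 0, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(n) if (init_sd > 0) stats::rnorm(n, 0, init_sd) else numeric(n)
  trans <- matrix(draw(n_tags^2), n_tags, n_tags,
                  dimnames = if (!is.null(tags)) list(tags, tags))
  list(trans = trans, start = stats::setNames(draw(n_tags), tags),
       stop = stats::setNames(draw(n_tags), tags))
}

check_emissions <- function(emissions) {
  if (!is.matrix(emissions) || nrow(emissions) < 1) {
    stopf("emissions must be a matrix with at least one row (token)")
  }
  if (!all(is.finite(emissions))) stopf("non-finite emission scores")
  invisible(emissions)
}

#' Log-partition function of a linear-chain CRF
#'
#' Forward algorithm in log space: the log of the sum over all tag paths
#' of the exponentiated path score.
#'
#' @param emissions n x L matrix of per-token tag scores.
#' @param crf parameter list from [crf_parameters()].
#' @return scalar log-partition value.
#' @export
crf_partition <- function(emissions, crf) {
  check_emissions(emissions)
  n <- nrow(emissions)
  alpha <- crf$start + emissions[1, ]
  if (n > 1) {
    for (i in 2:n) {
      # alpha[y] = logsumexp_y'(alpha[y'] + T[y', y]) + E[i, y]
      alpha <- row_logsumexp(t(alpha + crf$trans)) + emissions[i, ]
    }
  }
  logsumexp(alpha + crf$stop)
}

# Score of one tag path (indices 1..L).
crf_path_score <- function(emissions, crf, y) {
  n <- nrow(emissions)
  s <- crf$start[y[1]] + sum(emissions[cbind(seq_len(n), y)]) + crf$stop[y[n]]
  if (n > 1) s <- s + sum(crf$trans[cbind(y[-n], y[-1])])
  unname(s)
}

#' Negative log-likelihood of a gold tag path
#'
#' `crf_loss = crf_partition - gold path score`; non-negative up to float
#' tolerance. With `grad = TRUE` the forward-backward gradients with
#' respect to the emissions and all CRF parameters are attached.
#'
#' @param emissions n x L emission matrix.
#' @param crf CRF parameters.
#' @param y integer vector of gold tag indices (1..L), or tag names
#'   matching the transition dimnames.
#' @param grad also compute gradients.
#' @return scalar loss, or (with `grad`) a list `loss`, `d_emissions`,
#'   `d_trans`, `d_start`, `d_stop`.
#' @export
crf_loss <- function(emissions, crf, y, grad = FALSE) {
  check_emissions(emissions)
  L <- ncol(emissions)
  if (is.character(y)) {
    y <- match(y, rownames(crf$trans))
  }
  if (anyNA(y) || any(y < 1 | y > L)) stopf("gold tag outside the label set")
  n <- nrow(emissions)
  if (length(y) != n) stopf("gold path length %d != %d tokens", length(y), n)
  if (!grad) {
    return(crf_partition(emissions, crf) - crf_path_score(emissions, crf, y))
  }
  # forward and backward log messages
  log_alpha <- matrix(0, n, L)
  log_alpha[1, ] <- crf$start + emissions[1, ]
  if (n > 1) {
    for (i in 2:n) {
      log_alpha[i, ] <- row_logsumexp(t(log_alpha[i - 1, ] + crf$trans)) +
        emissions[i, ]
    }
  }
  logZ <- logsumexp(log_alpha[n, ] + crf$stop)
  log_beta <- matrix(0, n, L)
  log_beta[n, ] <- crf$stop
  if (n > 1) {
    for (i in (n - 1):1) {
      log_beta[i, ] <- row_logsumexp(crf$trans +
        matrix(emissions[i + 1, ] + log_beta[i + 1, ], L, L, byrow = TRUE))
    }
  }
  node_marg <- exp(log_alpha + log_beta - logZ)  # n x L
  d_emissions <- node_marg
  d_emissions[cbind(seq_len(n), y)] <- d_emissions[cbind(seq_len(n), y)] - 1
  d_trans <- matrix(0, L, L, dimnames = dimnames(crf$trans))
  if (n > 1) {
    for (i in 2:n) {
      pair <- exp(outer(log_alpha[i - 1, ], emissions[i, ] + log_beta[i, ], "+") +
                    crf$trans - logZ)
      d_trans <- d_trans + pair
      d_trans[y[i - 1], y[i]] <- d_trans[y[i - 1], y[i]] - 1
    }
  }
  d_start <- node_marg[1, ]; d_start[y[1]] <- d_start[y[1]] - 1
  d_stop <- node_marg[n, ]; d_stop[y[n]] <- d_stop[y[n]] - 1
  list(loss = logZ - crf_path_score(emissions, crf, y),
       d_emissions = d_emissions, d_trans = d_trans,
       d_start = unname(d_start), d_stop = unname(d_stop))
}

#' Viterbi decoding
#'
#' Returns the tag path with the maximum path score. Ties are broken
#' deterministically toward the lowest tag index at each backpointer.
#'
#' @param emissions n x L emission matrix.
#' @param crf CRF parameters.
#' @return list with `path` (integer tag indices), `tags` (names, when the
#'   transition matrix is named) and `score`.
#' @export
viterbi_decode <- function(emissions, crf) {
  check_emissions(emissions)
  n <- nrow(emissions); L <- ncol(emissions)
  delta <- crf$start + emissions[1, ]
  bp <- matrix(0L, n, L)
  if (n > 1) {
    for (i in 2:n) {
      cand <- delta + crf$trans          # L x L: cand[y', y]
      best <- apply(cand, 2, which.max)  # first max = lowest index
      delta <- cand[cbind(best, seq_len(L))] + emissions[i, ]
      bp[i, ] <- best
    }
  }
  final <- delta + crf$stop
  yn <- which.max(final)
  path <- integer(n)
  path[n] <- yn
  if (n > 1) for (i in n:2) path[i - 1] <- bp[i, path[i]]
  list(path = path,
       tags = if (!is.null(rownames(crf$trans))) rownames(crf$trans)[path],
       score = unname(final[yn]))
}

#' Transition mask for a tagging scheme
#'
#' Additive mask (0 = allowed, large negative = forbidden) over tag-to-tag,
#' start and stop transitions such that every decodable path is
#' grammatical under the scheme: in BIO, `I-X` must follow `B-X`/`I-X`;
#' in BIOES, `I-X`/`E-X` must follow `B-X`/`I-X`, and `B-X` must be
#' continued before `O`/`B`/`S`/stop.
#'
#' @param tagset character vector of tags (containing `O`).
#' @param scheme `"BIOES"` or `"BIO"`.
#' @return list `trans`, `start`, `stop` of additive masks.
#' @export
scheme_transition_mask <- function(tagset, scheme = c("BIOES", "BIO")) {
  scheme <- scheme_match(scheme)
  L <- length(tagset)
  p <- tag_parts(tagset)
  pre <- p[, 1]; typ <- p[, 2]
  allowed_pair <- function(p1, t1, p2, t2) {
    if (scheme == "BIO") {
      if (p2 == "I") return(p1 %in% c("B", "I") && t1 == t2)
      return(TRUE)
    }
    open <- p1 %in% c("B", "I")
    if (p2 %in% c("I", "E")) return(open && t1 == t2)
    !open  # O/B/S may only follow a closed position
  }
  trans <- matrix(0, L, L, dimnames = list(tagset, tagset))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (!allowed_pair(pre[i], typ[i], pre[j], typ[j])) trans[i, j] <- .TRANS_FORBID
  }
  start <- ifelse(pre %in% if (scheme == "BIO") c("O", "B") else c("O", "B", "S"),
                  0, .TRANS_FORBID)
  stop_ <- ifelse(pre %in% if (scheme == "BIO") c("O", "B", "I") else c("O", "E", "S"),
                  0, .TRANS_FORBID)
  list(trans = trans, start = stats::setNames(start, tagset),
       stop = stats::setNames(stop_, tagset))
}

# Tag inventory for a label set under a scheme; O is always first.
scheme_tagset <- function(labels, scheme = c("BIOES", "BIO")) {
  scheme <- scheme_match(scheme)
  pre <- if (scheme == "BIO") c("B", "I") else c("B", "I", "E", "S")
  c("O", as.vector(t(outer(labels, pre, function(l, p) paste0(p, "-", l)))))
}
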