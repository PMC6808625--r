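# CoNLL-style scoring: token tag accuracy plus entity-level precision,
# recall and F1, per label and micro-averaged overall. An entity counts
# as a true positive only when both its label and its exact character
# span match (the strict CoNLL criterion); matching on character offsets
# keeps the comparison robust to tokenization differences in external
# predictions.

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Entity-level evaluation of predicted against gold documents
#'
#' @param gold_docs,pred_docs parallel lists of `ner_document`s; pairing
#'   is by `doc_id`, and both sides must carry identical token tables.
#' @param scheme tagging scheme used for the token-accuracy computation
#'   (accuracy counts `O` tokens, as the CoNLL script does).
#' @param partial_overlap if `TRUE`, a predicted entity also matches a
#'   gold entity of the same label whose span merely overlaps. Never used
#'   for headline numbers; strict matching is the default.
#' @return object of class `ner_eval`: `accuracy`, `overall`
#'   (precision/recall/f1/tp/fp/fn), `per_label` (data.frame).
#' @export
evaluate_ner <- function(gold_docs, pred_docs, scheme = c("BIOES", "BIO"),
                         partial_overlap = FALSE) {
  scheme <- scheme_match(scheme)
  if (inherits(gold_docs, "ner_document")) gold_docs <- list(gold_docs)
  if (inherits(pred_docs, "ner_document")) pred_docs <- list(pred_docs)
  gid <- vapply(gold_docs, `[[`, "", "doc_id")
  pid <- vapply(pred_docs, `[[`, "", "doc_id")
  if (!setequal(gid, pid) || anyDuplicated(gid)) {
    stopf("gold and predicted corpora must contain the same doc_ids exactly once")
  }
  pred_docs <- pred_docs[match(gid, pid)]
  labels <- sort(unique(c(unlist(lapply(gold_docs, function(d) d$entities$label)),
                          unlist(lapply(pred_docs, function(d) d$entities$label)))))
  counts <- matrix(0L, length(labels), 3, dimnames = list(labels, c("tp", "fp", "fn")))
  tok_total <- 0L; tok_correct <- 0L
  for (k in seq_along(gold_docs)) {
    g <- gold_docs[[k]]; p <- pred_docs[[k]]
    if (nrow(g$tokens) != nrow(p$tokens) ||
        any(g$tokens$start != p$tokens$start) ||
        any(g$tokens$end != p$tokens$end)) {
      stopf("document %s: token misalignment between gold and prediction",
            g$doc_id)
    }
    gt <- entities_to_tags(g, scheme)
    pt <- attr(p, "pred_tags") %||% entities_to_tags(p, scheme)
    tok_total <- tok_total + length(gt)
    tok_correct <- tok_correct + sum(gt == pt)
    ge <- g$entities; pe <- p$entities
    gkey <- sprintf("%s:%d:%d", ge$label, ge$start, ge$end)
    pkey <- sprintf("%s:%d:%d", pe$label, pe$start, pe$end)
    if (!partial_overlap) {
      matched_g <- gkey %in% pkey
      matched_p <- pkey %in% gkey
    } else {
      matched_g <- vapply(seq_len(nrow(ge)), function(i)
        any(pe$label == ge$label[i] & pe$start < ge$end[i] & pe$end > ge$start[i]),
        logical(1))
      matched_p <- vapply(seq_len(nrow(pe)), function(i)
        any(ge$label == pe$label[i] & ge$start < pe$end[i] & ge$end > pe$start[i]),
        logical(1))
    }
    for (lab in labels) {
      counts[lab, "tp"] <- counts[lab, "tp"] + sum(matched_p & pe$label == lab)
      counts[lab, "fp"] <- counts[lab, "fp"] + sum(!matched_p & pe$label == lab)
      counts[lab, "fn"] <- counts[lab, "fn"] + sum(!matched_g & ge$label == lab)
    }
  }
  per_label <- do.call(rbind, lapply(labels, function(lab) {
    m <- prf(counts[lab, "tp"], counts[lab, "fp"], counts[lab, "fn"])
    data.frame(label = lab, precision = m$precision, recall = m$recall,
               f1 = m$f1, tp = m$tp, fp = m$fp, fn = m$fn,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_label)) {
    per_label <- data.frame(label = character(), precision = numeric(),
                            recall = numeric(), f1 = numeric(), tp = integer(),
                            fp = integer(), fn = integer(),
                            stringsAsFactors = FALSE)
  }
  overall <- prf(sum(counts[, "tp"]), sum(counts[, "fp"]), sum(counts[, "fn"]))
  structure(list(accuracy = if (tok_total) 100 * tok_correct / tok_total else 0,
                 overall = overall, per_label = per_label,
                 n_tokens = tok_total),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat(report_format(x))
  invisible(x)
}

#' Format an evaluation report
#'
#' Fixed-width table with one overall row (including token accuracy) and
#' one row per label (accuracy left blank, as it is a token-level
#' quantity); percentages with two decimals. `as = "json"` returns the
#' machine-readable twin.
#'
#' @param report `ner_eval` object.
#' @param as `"text"` or `"json"`.
#' @return character scalar.
#' @export
report_format <- function(report, as = c("text", "json")) {
  as <- match.arg(as)
  if (as == "json") {
    return(jsonlite::toJSON(list(
      accuracy = report$accuracy, overall = report$overall,
      per_label = report$per_label), auto_unbox = TRUE, digits = NA))
  }
  fmt <- "%-18s %9s %10s %8s %8s %5s %5s %5s\n"
  num <- function(v) sprintf("%.2f", v)
  out <- sprintf(fmt, "", "Accuracy", "Precision", "Recall", "F1",
                 "TP", "FP", "FN")
  o <- report$overall
  out <- c(out, sprintf(fmt, "Overall", num(report$accuracy), num(o$precision),
                        num(o$recall), num(o$f1), o$tp, o$fp, o$fn))
  for (i in seq_len(nrow(report$per_label))) {
    r <- report$per_label[i, ]
    out <- c(out, sprintf(fmt, r$label, "-", num(r$precision), num(r$recall),
                          num(r$f1), r$tp, r$fp, r$fn))
  }
  paste(out, collapse = "")
}
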