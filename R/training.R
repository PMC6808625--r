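# Corpus splitting, rare-class removal and the minibatch training loop
# with early stopping on development-set entity F1.

#' Split specification
#' @param train,dev,test split fractions (must sum to 1).
#' @param seed RNG seed; the split is deterministic under it.
#' @return list of class `ner_split_spec`.
#' @export
split_spec <- function(train = 0.8, dev = 0.1, test = 0.1, seed = 1L) {
  if (abs(train + dev + test - 1) > 1e-9) stopf("split fractions must sum to 1")
  structure(list(fractions = c(train = train, dev = dev, test = test),
                 seed = as.integer(seed)),
            class = "ner_split_spec")
}

#' Stratified document-level corpus split
#'
#' Greedy iterative stratification for multi-label documents: documents
#' are assigned in order of their rarest still-unassigned label, each to
#' the split with the greatest remaining need for that label (ties by
#' remaining document capacity, then by seeded random order). This
#' approximately preserves every label's global mention proportion in
#' each split while keeping whole documents together.
#'
#' @param docs list of `ner_document`s (at least 10).
#' @param spec a [split_spec()].
#' @return list with `train`, `dev`, `test` document lists and
#'   `assignment`, a factor parallel to `docs`.
#' @export
stratified_split <- function(docs, spec = split_spec()) {
  n <- length(docs)
  if (n < 3) stopf("cannot split %d documents into three non-empty sets", n)
  if (n < 10) warnf("stratified split over only %d documents", n)
  fr <- spec$fractions
  splits <- names(fr)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  # label count matrix: docs x labels
  labels <- sort(unique(unlist(lapply(docs, function(d) d$entities$label))))
  cnt <- matrix(0L, n, length(labels), dimnames = list(NULL, labels))
  for (i in seq_len(n)) {
    t <- table(docs[[i]]$entities$label)
    cnt[i, names(t)] <- as.integer(t)
  }
  # remaining desired mention counts per split and label, and doc capacity
  desire <- outer(fr, colSums(cnt))           # splits x labels
  cap <- fr * n
  assignment <- rep(NA_character_, n)
  order_jitter <- stats::runif(n)             # seeded tie-breaking
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    tot <- colSums(cnt[remaining, , drop = FALSE])
    if (length(labels) && any(tot > 0)) {
      lab <- labels[which(tot == min(tot[tot > 0]) & tot > 0)][1]
      cand <- which(remaining & cnt[, lab] > 0)
    } else {
      lab <- NULL
      cand <- which(remaining)
    }
    cand <- cand[order(order_jitter[cand])]
    for (i in cand) {
      need <- if (is.null(lab)) cap else desire[, lab]
      best <- which(need == max(need))
      if (length(best) > 1) best <- best[which.max(cap[best])]
      s <- splits[best[1]]
      assignment[i] <- s
      desire[s, ] <- desire[s, ] - cnt[i, ]
      cap[s] <- cap[s] - 1
      remaining[i] <- FALSE
    }
  }
  assignment <- factor(assignment, levels = splits)
  out <- lapply(splits, function(s) docs[assignment == s])
  names(out) <- splits
  if (n >= 10 && any(!lengths(out))) {
    stopf("degenerate split: an empty part despite %d documents", n)
  }
  c(out, list(assignment = assignment))
}

#' Remove entity classes from a corpus
#'
#' Entities with the given labels are dropped (their tokens revert to
#' `O`); documents, text and token offsets are untouched. Removal counts
#' are reported via `message()`.
#'
#' @param docs list of `ner_document`s.
#' @param labels_to_drop character vector of labels.
#' @return the corpus with matching entities removed.
#' @export
discard_rare_classes <- function(docs, labels_to_drop) {
  if (!length(labels_to_drop)) return(docs)
  present <- unique(unlist(lapply(docs, function(d) d$entities$label)))
  missing <- setdiff(labels_to_drop, present)
  if (length(missing)) {
    warnf("labels not present in the corpus: %s", paste(missing, collapse = ", "))
  }
  dropped <- 0L
  out <- lapply(docs, function(d) {
    keep <- !d$entities$label %in% labels_to_drop
    dropped <<- dropped + sum(!keep)
    d$entities <- d$entities[keep, , drop = FALSE]
    rownames(d$entities) <- NULL
    d
  })
  message(sprintf("discard_rare_classes: removed %d entities of class {%s}",
                  dropped, paste(intersect(labels_to_drop, present),
                                 collapse = ", ")))
  out
}

#' Early-stopping decision over a development-metric sequence
#'
#' Pure function of the metric history: training stops after the first
#' epoch at which the number of epochs since the last strict improvement
#' (tolerance 1e-6) reaches `patience`. `patience = 0` stops after the
#' first epoch.
#'
#' @param metrics numeric vector of per-epoch dev metrics so far.
#' @param patience non-negative integer.
#' @return list `stop` (logical), `best_epoch`, `best_metric`.
#' @export
early_stop_status <- function(metrics, patience) {
  best <- -Inf; best_epoch <- 0L; since <- 0L
  for (e in seq_along(metrics)) {
    if (metrics[e] > best + 1e-6) {
      best <- metrics[e]; best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
    }
  }
  list(stop = length(metrics) > 0 && since >= patience,
       best_epoch = best_epoch, best_metric = best)
}

#' Training configuration
#' @param patience epochs without dev improvement before stopping.
#' @param max_epochs hard epoch cap.
#' @param batch_size sentences per parameter update.
#' @param optimizer `"sgd"` (default) or `"adam"`.
#' @param lr learning rate.
#' @param clip global gradient-norm clip.
#' @param seed seed for shuffling and dropout.
#' @param target_metric optional dev-F1 level at which training may stop
#'   early (e.g. 100 for a capacity check).
#' @return list of class `ner_train_config`.
#' @export
train_config <- function(patience = 10L, max_epochs = 100L, batch_size = 16L,
                         optimizer = c("sgd", "adam"), lr = NULL, clip = 5,
                         seed = 1L, target_metric = NULL) {
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "sgd") 0.005 else 0.002
  structure(list(patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 lr = lr, clip = clip, seed = as.integer(seed),
                 target_metric = target_metric),
            class = "ner_train_config")
}

#' Train a tagger with early stopping
#'
#' Minibatch training of the BiLSTM-CRF: sentences are shuffled each
#' epoch, gradients averaged per batch, clipped at a global norm, and the
#' development set is scored (entity-level micro F1) after every epoch.
#' Training stops when no strict dev improvement has been seen for
#' `patience` epochs, and the best-epoch parameters are returned.
#'
#' @param model initial `ner_model` (see [ner_model()]).
#' @param train_docs,dev_docs non-empty document lists.
#' @param tc a [train_config()].
#' @param eval_fn dev metric: `function(model, dev_docs) -> numeric`;
#'   defaults to entity-level micro F1 via [evaluate_ner()]. Injectable so
#'   the early-stopping state machine can be exercised in isolation.
#' @param verbose print one line per epoch.
#' @return list `model` (best checkpoint), `history` (data.frame epoch /
#'   mean train loss / dev F1), `best_epoch`.
#' @export
ner_train <- function(model, train_docs, dev_docs, tc = train_config(),
                      eval_fn = NULL, verbose = FALSE) {
  if (!length(train_docs) || !length(dev_docs)) {
    stopf("train and dev sets must be non-empty")
  }
  if (is.null(eval_fn)) {
    eval_fn <- function(model, docs) {
      pred <- predict_documents(model, docs)
      evaluate_ner(docs, pred)$overall$f1
    }
  }
  sents <- prepare_corpus(model, train_docs, with_gold = TRUE)
  sents <- Filter(function(s) length(s$tok_idx) > 0, sents)
  if (!length(sents)) stopf("no non-empty sentences in the training set")
  opt <- make_optimizer(tc$optimizer, lr = tc$lr, clip = tc$clip)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(tc$seed)
  history <- data.frame(epoch = integer(), loss = numeric(), dev_f1 = numeric())
  best_params <- model$params; best_f1 <- -Inf
  metrics <- numeric()
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample.int(length(sents))
    losses <- numeric()
    for (b0 in seq(1, length(ord), by = tc$batch_size)) {
      batch <- ord[b0:min(b0 + tc$batch_size - 1, length(ord))]
      total <- NULL; bl <- 0
      for (si in batch) {
        fwd <- forward_sentence(model, sents[[si]], train = TRUE)
        bk <- backward_sentence(model, sents[[si]], fwd)
        if (!is.finite(bk$loss)) {
          stopf("non-finite loss at epoch %d (sentence of %d tokens); %s",
                epoch, length(sents[[si]]$tok_idx),
                "check learning rate and input encoding")
        }
        total <- accumulate_grads(total, bk$grads)
        bl <- bl + bk$loss
      }
      total <- scale_grads(total, 1 / length(batch))
      model$params <- opt$step(model$params, total)
      losses <- c(losses, bl / length(batch))
    }
    f1 <- eval_fn(model, dev_docs)
    metrics <- c(metrics, f1)
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses), dev_f1 = f1))
    if (verbose) {
      message(sprintf("epoch %3d  loss %8.4f  dev F1 %6.2f", epoch,
                      mean(losses), f1))
    }
    if (f1 > best_f1 + 1e-6) { best_f1 <- f1; best_params <- model$params }
    st <- early_stop_status(metrics, tc$patience)
    if (st$stop) break
    if (!is.null(tc$target_metric) && f1 >= tc$target_metric) break
  }
  model$params <- best_params
  st <- early_stop_status(metrics, tc$patience)
  list(model = model, history = history, best_epoch = st$best_epoch)
}
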