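# Shared fixtures: all corpora and resources are generated in code at
# test time; nothing is read from disk except files the tests write.

# Brute-force linear-chain CRF oracle: enumerate every tag path.
enumerate_paths <- function(n, L) {
  as.matrix(expand.grid(rep(list(seq_len(L)), n)))
}

brute_crf <- function(E, crf) {
  n <- nrow(E); L <- ncol(E)
  paths <- enumerate_paths(n, L)
  scores <- apply(paths, 1, function(y) {
    s <- crf$start[y[1]] + sum(E[cbind(seq_len(n), y)]) + crf$stop[y[n]]
    if (n > 1) s <- s + sum(crf$trans[cbind(y[-n], y[-1])])
    s
  })
  m <- max(scores)
  list(log_partition = m + log(sum(exp(scores - m))),
       best_path = paths[which.max(scores), ],
       best_score = m,
       scores = scores)
}

# Independent strict-span entity matcher (set comparison on
# label/start/end triples), the oracle for evaluate_ner().
brute_match <- function(gold_docs, pred_docs) {
  tp <- 0L; fp <- 0L; fn <- 0L
  pid <- vapply(pred_docs, `[[`, "", "doc_id")
  for (g in gold_docs) {
    p <- pred_docs[[match(g$doc_id, pid)]]
    gk <- paste(g$entities$label, g$entities$start, g$entities$end)
    pk <- paste(p$entities$label, p$entities$start, p$entities$end)
    tp <- tp + sum(pk %in% gk)
    fp <- fp + sum(!pk %in% gk)
    fn <- fn + sum(!gk %in% pk)
  }
  P <- if (tp + fp) 100 * tp / (tp + fp) else 0
  R <- if (tp + fn) 100 * tp / (tp + fn) else 0
  F1 <- if (P + R) 2 * P * R / (P + R) else 0
  list(precision = P, recall = R, f1 = F1, tp = tp, fp = fp, fn = fn)
}

# A small document with aligned entities, built by hand.
fixture_doc <- function(doc_id = "d1") {
  text <- "Se administró lidocaína y receptores de progesterona altos ."
  ents <- data.frame(
    label = c("Normalizables", "Proteins"),
    start = c(14L, 26L), end = c(23L, 52L),
    surface = c("lidocaína", "receptores de progesterona"),
    stringsAsFactors = FALSE)
  ner_document(doc_id, text, entities = ents)
}

# Three documents: one scored perfectly, one with a spurious prediction,
# one with a boundary error.
eval_fixture <- function() {
  g1 <- fixture_doc("e1")
  p1 <- g1
  # gold: 2 entities; predicted: 1 correct + 1 spurious
  g2 <- fixture_doc("e2")
  p2 <- ner_document("e2", g2$text, entities = data.frame(
    label = c("Normalizables", "Unclear"),
    start = c(14L, 53L), end = c(23L, 58L),
    surface = c("lidocaína", "altos"), stringsAsFactors = FALSE))
  # boundary off by one token, label correct
  g3 <- fixture_doc("e3")
  p3 <- ner_document("e3", g3$text, entities = data.frame(
    label = c("Normalizables", "Proteins"),
    start = c(14L, 26L), end = c(23L, 39L),
    surface = c("lidocaína", "receptores de"), stringsAsFactors = FALSE))
  list(gold = list(g1, g2, g3), pred = list(p1, p2, p3))
}

write_temp_gazetteer <- function(terms) {
  f <- tempfile(fileext = ".txt")
  con <- file(f, "wb"); writeLines(enc2utf8(terms), con, useBytes = TRUE)
  close(con)
  f
}

write_temp_affixes <- function(tab = drugner:::synth_affix_table(),
                               header = TRUE) {
  f <- tempfile(fileext = ".tsv")
  lines <- paste(tab$kind, tab$affix_en, tab$affix_es, tab$example_en,
                 tab$drug_class, sep = "\t")
  if (header) lines <- c("type\taffix-en\taffix-es\texample-en\tdrug-class", lines)
  con <- file(f, "wb"); writeLines(enc2utf8(lines), con, useBytes = TRUE)
  close(con)
  f
}

# Model over a generated corpus with desk-scale dimensions.
fixture_model <- function(corpus, train_docs, gazetteer = NULL,
                          use_pos = TRUE, use_gazetteer = !is.null(gazetteer),
                          use_affixes = TRUE, d = 12L, dropout = 0,
                          seed = 7L, scheme = "BIOES") {
  labels <- sort(unique(unlist(lapply(corpus$docs,
                                      function(d) d$entities$label))))
  cfg <- model_config(labels, d_char = d, d_char_lstm = d, d_token = 2L * d,
                      d_token_lstm = 2L * d, dropout_rate = dropout,
                      use_pos = use_pos, use_gazetteer = use_gazetteer,
                      use_affixes = use_affixes, scheme = scheme, seed = seed)
  surf <- unlist(lapply(train_docs, function(d) d$tokens$surface))
  tv <- build_vocab(surf, d = cfg$d_token, seed = seed)
  cv <- build_char_vocab(surf)
  pv <- if (use_pos) {
    pos_vocabulary(unlist(lapply(train_docs, function(d) d$tokens$pos)))
  }
  ner_model(cfg, tv, cv, pos_vocab = pv, gazetteer = gazetteer,
            affixes = if (use_affixes) corpus$affixes)
}
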