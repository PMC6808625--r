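# Stratified splitting, rare-class discarding and the early-stopping
# training loop.

test_that("identical single-entity documents split exactly 80/10/10", {
  docs <- lapply(1:100, function(i) {
    ner_document(sprintf("d%03d", i), "tratamiento con lidocaína .",
                 entities = data.frame(label = "Normalizables", start = 16L,
                                       end = 25L, surface = "lidocaína",
                                       stringsAsFactors = FALSE))
  })
  p <- stratified_split(docs, split_spec(seed = 1))
  expect_identical(lengths(p[c("train", "dev", "test")]),
                   c(train = 80L, dev = 10L, test = 10L))
})

test_that("stratified split preserves label proportions and is deterministic", {
  spec <- corpus_spec(n_docs = 120, sentences_per_doc = 8, seed = 5,
                      label_weights = c(Normalizables = 4398, Proteins = 3009))
  corp <- generate_corpus(spec)
  p1 <- stratified_split(corp$docs, split_spec(seed = 5))
  p2 <- stratified_split(corp$docs, split_spec(seed = 5))
  expect_identical(p1$assignment, p2$assignment)
  expect_false(anyNA(p1$assignment))
  expect_identical(length(unlist(p1[c("train", "dev", "test")],
                                 recursive = FALSE)), 120L)
  glob <- table(unlist(lapply(corp$docs, function(d) d$entities$label)))
  glob <- glob / sum(glob)
  for (s in c("train", "dev", "test")) {
    t <- table(factor(unlist(lapply(p1[[s]], function(d) d$entities$label)),
                      levels = names(glob)))
    expect_lt(max(abs(t / sum(t) - glob)), 0.03)
  }
  expect_error(stratified_split(corp$docs[1:2], split_spec()), "split")
})

test_that("discard_rare_classes removes entities but never touches tokens", {
  corp <- generate_corpus(corpus_spec(n_docs = 80, seed = 23))
  labs <- unique(unlist(lapply(corp$docs, function(d) d$entities$label)))
  expect_true(all(c("No Normalizables", "Unclear") %in% labs))
  suppressMessages(
    out <- discard_rare_classes(corp$docs, c("No Normalizables", "Unclear")))
  left <- unique(unlist(lapply(out, function(d) d$entities$label)))
  expect_setequal(left, c("Normalizables", "Proteins"))
  for (k in seq_along(out)) {
    expect_identical(out[[k]]$text, corp$docs[[k]]$text)
    expect_identical(out[[k]]$tokens, corp$docs[[k]]$tokens)
  }
  suppressMessages(expect_identical(discard_rare_classes(corp$docs, character()),
                                    corp$docs))
  suppressMessages(expect_warning(
    discard_rare_classes(corp$docs, "NoExiste"), "not present"))
  # dropping everything leaves an all-O corpus
  suppressMessages(all_o <- discard_rare_classes(corp$docs, labs))
  expect_identical(sum(vapply(all_o, function(d) nrow(d$entities), 0L)), 0L)
})

test_that("early stopping is a pure function of the metric sequence", {
  expect_true(early_stop_status(c(0.5), 0)$stop)  # patience 0: one epoch
  st <- early_stop_status(c(0.5, 0.6, 0.6, 0.6), 2)
  expect_true(st$stop)
  expect_identical(st$best_epoch, 2L)
  expect_false(early_stop_status(c(0.5, 0.6, 0.6), 2)$stop)
  expect_false(early_stop_status(c(0.5, 0.6, 0.6, 0.7), 2)$stop)
  # improvement must exceed the 1e-6 tolerance
  expect_true(early_stop_status(c(0.5, 0.5 + 1e-9), 1)$stop)
})

test_that("the training loop obeys the injected dev-metric sequence", {
  corp <- generate_corpus(corpus_spec(n_docs = 2, sentences_per_doc = 2,
                                      seed = 3))
  m <- fixture_model(corp, corp$docs, use_pos = FALSE, use_gazetteer = FALSE,
                     use_affixes = FALSE, d = 4L)
  seq_metric <- c(50, 60, 60, 60, 70)
  counter <- new.env(); counter$i <- 0L
  fake_eval <- function(model, docs) {
    counter$i <- counter$i + 1L
    seq_metric[counter$i]
  }
  fit <- ner_train(m, corp$docs, corp$docs,
                   train_config(patience = 2L, max_epochs = 10L, seed = 3),
                   eval_fn = fake_eval)
  expect_identical(nrow(fit$history), 4L)   # stops after epoch 4
  expect_identical(fit$best_epoch, 2L)      # epoch-2 checkpoint retained
  counter$i <- 0L
  fit0 <- ner_train(m, corp$docs, corp$docs,
                    train_config(patience = 0L, max_epochs = 10L, seed = 3),
                    eval_fn = fake_eval)
  expect_identical(nrow(fit0$history), 1L)  # patience 0: exactly one epoch
  expect_error(ner_train(m, list(), corp$docs, train_config()), "non-empty")
})

test_that("training reduces the loss and returns a usable model", {
  spec <- separability_dial(corpus_spec(n_docs = 6, sentences_per_doc = 6,
                                        seed = 29,
                                        entities_per_sentence = 1), "trivial")
  corp <- generate_corpus(spec)
  gaz <- load_gazetteer(write_temp_gazetteer(corp$gazetteer_terms))
  m <- fixture_model(corp, corp$docs, gazetteer = gaz, d = 8L, seed = 29)
  fit <- ner_train(m, corp$docs, corp$docs,
                   train_config(patience = 3L, max_epochs = 6L,
                                optimizer = "adam", lr = 0.01, seed = 29))
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  expect_true(all(is.finite(fit$history$dev_f1)))
  pred <- predict_documents(fit$model, corp$docs[1])
  expect_s3_class(pred[[1]], "ner_document")
})
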