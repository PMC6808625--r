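# Architecture contracts of the BiLSTM-CRF: concatenation widths, LSTM
# gradients, encoding, prediction and persistence.

small_corpus_model <- function(seed = 7, ...) {
  corp <- generate_corpus(corpus_spec(n_docs = 4, sentences_per_doc = 3,
                                      seed = seed))
  gaz <- load_gazetteer(write_temp_gazetteer(corp$gazetteer_terms))
  list(corp = corp, gaz = gaz,
       model = fixture_model(corp, corp$docs, gazetteer = gaz, seed = seed, ...))
}

test_that("concatenated embedding width follows the channel contract", {
  labels <- c("Chem")
  cfg <- model_config(labels, d_token = 100, d_char_lstm = 25,
                      use_pos = TRUE, use_gazetteer = TRUE, use_affixes = TRUE)
  # POS one-hot of dimension 10 (9 tags + UNK): 100 + 50 + 10 + 1 + 1
  expect_identical(embedding_width(cfg, pos_dim = 10L), 162L)
  cfg0 <- model_config(labels, d_token = 100, d_char_lstm = 25,
                       use_pos = FALSE, use_gazetteer = FALSE,
                       use_affixes = FALSE)
  expect_identical(embedding_width(cfg0), 150L)  # base architecture
})

test_that("token-LSTM input rows match the declared width exactly", {
  sm <- small_corpus_model()
  m <- sm$model
  expect_identical(nrow(m$params$tf_Wx),
                   4L * m$config$d_token_lstm)
  expect_identical(ncol(m$params$tf_Wx),
                   embedding_width(m$config, m$pos_vocab$dim))
  m0 <- fixture_model(sm$corp, sm$corp$docs, gazetteer = NULL,
                      use_pos = FALSE, use_gazetteer = FALSE,
                      use_affixes = FALSE)
  expect_identical(ncol(m0$params$tf_Wx), m0$config$d_token + 2L * m0$config$d_char_lstm)
})

test_that("encode produces finite emissions of the right shape", {
  sm <- small_corpus_model()
  tk <- sm$corp$docs[[1]]$tokens
  E <- encode_tokens(sm$model, tk)
  expect_identical(dim(E), c(nrow(tk), length(sm$model$tagset)))
  expect_true(all(is.finite(E)))
  one <- encode_tokens(sm$model, tk[1, , drop = FALSE])
  expect_identical(nrow(one), 1L)
  expect_error(encode_tokens(sm$model, tk[0, ]), "at least one")
})

test_that("LSTM backward matches finite differences", {
  set.seed(31)
  din <- 3; dh <- 4; len <- 6
  X <- matrix(rnorm(din * len), din, len)
  Wx <- matrix(rnorm(4 * dh * din, sd = 0.5), 4 * dh, din)
  Wh <- matrix(rnorm(4 * dh * dh, sd = 0.5), 4 * dh, dh)
  b <- rnorm(4 * dh, sd = 0.1)
  dH <- matrix(rnorm(dh * len), dh, len)
  loss <- function(X, Wx, Wh, b) {
    sum(dH * drugner:::lstm_forward_cpp(X, Wx, Wh, b)$H)
  }
  fw <- drugner:::lstm_forward_cpp(X, Wx, Wh, b)
  g <- drugner:::lstm_backward_cpp(X, Wx, Wh, fw, dH)
  eps <- 1e-6
  num <- function(p, f) {
    out <- p * 0
    for (i in seq_along(p)) {
      p1 <- p; p1[i] <- p1[i] + eps
      p2 <- p; p2[i] <- p2[i] - eps
      out[i] <- (f(p1) - f(p2)) / (2 * eps)
    }
    out
  }
  expect_equal(g$dX, num(X, function(p) loss(p, Wx, Wh, b)), tolerance = 1e-6)
  expect_equal(g$dWx, num(Wx, function(p) loss(X, p, Wh, b)), tolerance = 1e-6)
  expect_equal(g$dWh, num(Wh, function(p) loss(X, Wx, p, b)), tolerance = 1e-6)
  expect_equal(as.numeric(g$db), num(b, function(p) loss(X, Wx, Wh, p)),
               tolerance = 1e-6)
})

test_that("full-network loss gradient matches finite differences", {
  sm <- small_corpus_model()
  m <- sm$model
  sents <- drugner:::prepare_corpus(m, sm$corp$docs)
  with_ent <- which(vapply(sents, function(x) any(x$gold > 1), TRUE))
  s <- sents[[if (length(with_ent)) with_ent[1] else 1L]]
  fwd <- drugner:::forward_sentence(m, s)
  bk <- drugner:::backward_sentence(m, s, fwd)
  loss_of <- function(model) {
    f <- drugner:::forward_sentence(model, s)
    crf_loss(f$emissions, drugner:::model_crf(model), s$gold)
  }
  eps <- 1e-6
  set.seed(41)
  for (nm in c("proj_W", "tf_Wx", "tb_Wh", "cf_Wx", "cb_b", "Echar",
               "trans", "stop")) {
    for (i in sample(length(m$params[[nm]]), 4)) {
      m1 <- m; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("d%s[%d]", nm, i))
    }
  }
})

test_that("disabled channels never touch their resource", {
  corp <- generate_corpus(corpus_spec(n_docs = 3, seed = 19))
  # no gazetteer/affix/pos objects supplied at all: must build and encode
  m <- fixture_model(corp, corp$docs, gazetteer = NULL, use_pos = FALSE,
                     use_gazetteer = FALSE, use_affixes = FALSE)
  expect_silent(E <- encode_tokens(m, corp$docs[[1]]$tokens))
  expect_true(all(is.finite(E)))
  # enabling a channel without its resource is refused
  expect_error(fixture_model(corp, corp$docs, gazetteer = NULL,
                             use_gazetteer = TRUE), "gazetteer")
})

test_that("save/load restores bitwise-identical behaviour and guards resources", {
  sm <- small_corpus_model()
  m <- sm$model
  tk <- sm$corp$docs[[1]]$tokens
  E1 <- encode_tokens(m, tk)
  td <- withr::local_tempdir()
  save_model(m, td)
  m2 <- load_model(td)
  expect_identical(encode_tokens(m2, tk), E1)
  expect_true(file.exists(file.path(td, "model.json")))
  side <- jsonlite::read_json(file.path(td, "model.json"))
  expect_identical(side$config$scheme, "BIOES")
  # missing gazetteer file while the channel is on -> error naming it
  gazpath <- m$gazetteer$path
  file.remove(gazpath)
  expect_error(load_model(td), basename(gazpath), fixed = TRUE)
  expect_silent(load_model(td, check_resources = FALSE))
  # changed gazetteer -> fingerprint warning
  writeLines("otra", gazpath)
  expect_warning(load_model(td), "changed")
  # corrupted parameter file -> clean error
  writeLines("garbage", file.path(td, "parameters.rds"))
  expect_error(load_model(td, check_resources = FALSE), "corrupted")
  # version gate
  td2 <- withr::local_tempdir()
  save_model(m, td2)
  side <- jsonlite::read_json(file.path(td2, "model.json"))
  side$format_version <- "99"
  jsonlite::write_json(side, file.path(td2, "model.json"), auto_unbox = TRUE)
  expect_error(load_model(td2), "version")
})

test_that("prediction is deterministic and grammatical", {
  sm <- small_corpus_model()
  p1 <- predict_documents(sm$model, sm$corp$docs)
  p2 <- predict_documents(sm$model, sm$corp$docs)
  expect_identical(lapply(p1, `[[`, "entities"), lapply(p2, `[[`, "entities"))
  for (d in p1) {
    expect_true(drugner:::tags_valid(attr(d, "pred_tags"), "BIOES"))
  }
})
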