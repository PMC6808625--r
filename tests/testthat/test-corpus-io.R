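# Tokenization, BRAT/CoNLL round trips, tag-scheme conversion.

test_that("tokenizer splits on whitespace and isolates punctuation", {
  expect_identical(nrow(tokenize("")), 0L)
  t1 <- tokenize("receptores de progesterona")
  expect_identical(t1$surface, c("receptores", "de", "progesterona"))
  expect_identical(t1$start, c(0L, 11L, 14L))
  expect_identical(t1$end, c(10L, 13L, 26L))
  expect_identical(tokenize("lidocaína (2%)")$surface,
                   c("lidocaína", "(", "2", "%", ")"))
  # intra-word hyphen and decimal comma stay attached; other punctuation
  # splits
  expect_identical(tokenize("dosis 2,5 mg-kg, fin.")$surface,
                   c("dosis", "2,5", "mg-kg", ",", "fin", "."))
})

test_that("tokenizer offsets always slice the original text", {
  set.seed(11)
  texts <- c(
    "paciente  con\ttratamiento ácido (5,0 mg) y más...",
    "\n\nhola-adiós , [x] 3.4 µg/ml —fin—",
    paste(sample(c(letters, "á", "ñ", " ", ".", "(", ")", "-", ","),
                 300, replace = TRUE), collapse = ""))
  for (tx in texts) {
    tk <- tokenize(tx)
    if (nrow(tk)) {
      expect_identical(substring(tx, tk$start + 1L, tk$end), tk$surface)
      expect_true(all(tk$end > tk$start))
      expect_true(all(diff(tk$start) > 0))
    }
  }
})

test_that("BRAT reader parses text-bound annotations and checks offsets", {
  td <- withr::local_tempdir()
  txt <- file.path(td, "c1.txt"); ann <- file.path(td, "c1.ann")
  writeLines("triglicéridos altos", txt)
  writeLines("T1\tNormalizables 0 13\ttriglicéridos", ann)
  doc <- read_brat(txt, ann)
  expect_identical(nrow(doc$entities), 1L)
  expect_identical(doc$entities$label, "Normalizables")
  expect_identical(doc$entities$start, 0L)
  expect_identical(doc$entities$end, 13L)

  writeLines(character(), ann)
  expect_identical(nrow(read_brat(txt, ann)$entities), 0L)

  writeLines("T1\tNormalizables 0 99\tx", ann)
  expect_error(read_brat(txt, ann), "T1")
  writeLines("T1\tNormalizables 0 5;7 13\tx", ann)
  expect_error(read_brat(txt, ann), "discontinuous")
  # surface mismatch: strict error, lenient warning
  writeLines("T1\tNormalizables 0 13\tOTRACOSA", ann)
  expect_error(read_brat(txt, ann), "does not match")
  expect_warning(read_brat(txt, ann, lenient = TRUE), "does not match")
})

test_that("entity boundaries inside a token error strictly and snap under the expand flag", {
  td <- withr::local_tempdir()
  txt <- file.path(td, "c2.txt"); ann <- file.path(td, "c2.ann")
  writeLines("toma indometacina hoy", txt)
  writeLines("T1\tNormalizables 5 11\tindome", ann)
  doc <- read_brat(txt, ann)  # reading is fine; tagging must fail
  expect_error(entities_to_tags(doc), "align")
  expect_warning(doc2 <- read_brat(txt, ann, expand_boundaries = TRUE),
                 "snapped")
  expect_identical(doc2$entities$start, 5L)
  expect_identical(doc2$entities$end, 17L)
  expect_identical(doc2$entities$surface, "indometacina")
})

test_that("entity spans encode to BIO/BIOES and decode back", {
  doc <- fixture_doc()
  bio <- entities_to_tags(doc, "BIO")
  expect_identical(bio, c("O", "O", "B-Normalizables", "O", "B-Proteins",
                          "I-Proteins", "I-Proteins", "O", "O"))
  bioes <- entities_to_tags(doc, "BIOES")
  expect_identical(bioes, c("O", "O", "S-Normalizables", "O", "B-Proteins",
                            "I-Proteins", "E-Proteins", "O", "O"))
  for (sch in c("BIO", "BIOES")) {
    back <- bio_to_entities(doc$tokens, entities_to_tags(doc, sch), doc$text)
    expect_equal(back, doc$entities)
  }
  expect_identical(nrow(bio_to_entities(doc$tokens, rep("O", 9), doc$text)), 0L)
})

test_that("stray I tags are repaired as span starts", {
  doc <- fixture_doc()
  tags <- c("I-Proteins", "I-Proteins", "O", rep("O", 6))
  ents <- bio_to_entities(doc$tokens, tags, doc$text)
  expect_identical(nrow(ents), 1L)
  expect_identical(ents$start, doc$tokens$start[1])
  expect_identical(ents$end, doc$tokens$end[2])
  # I-X after B-Y starts a new span
  tags2 <- c("B-Proteins", "I-Normalizables", rep("O", 7))
  ents2 <- bio_to_entities(doc$tokens, tags2, doc$text)
  expect_identical(ents2$label, c("Proteins", "Normalizables"))
})

test_that("overlapping entities are rejected", {
  text <- "uno dos tres"
  ents <- data.frame(label = c("A", "B"), start = c(0L, 4L), end = c(7L, 12L),
                     surface = c("uno dos", "dos tres"),
                     stringsAsFactors = FALSE)
  doc <- ner_document("ov", text, entities = ents)
  expect_error(entities_to_tags(doc), "overlap")
})

test_that("CoNLL writer/reader round-trips documents exactly", {
  corp <- generate_corpus(corpus_spec(n_docs = 6, sentences_per_doc = 5,
                                      seed = 21))
  for (sch in c("BIOES", "BIO")) {
    f <- withr::local_tempfile(fileext = ".conll")
    write_conll(corp$docs, f, sch)
    back <- read_conll(f)
    expect_length(back, length(corp$docs))
    for (k in seq_along(back)) {
      expect_identical(back[[k]]$text, corp$docs[[k]]$text)
      expect_identical(back[[k]]$tokens, corp$docs[[k]]$tokens)
      expect_identical(back[[k]]$entities, corp$docs[[k]]$entities)
    }
  }
  expect_length(read_conll(write_conll(list(), withr::local_tempfile())), 0L)
})

test_that("CoNLL reader reports ragged lines and repairs sentence-initial I tags", {
  f <- withr::local_tempfile(lines = c("token\td1\t0\t5"))
  expect_error(read_conll(f), "column")
  f2 <- withr::local_tempfile(lines = c(
    "uno\td1\t0\t3\t_\tI-Proteins", "dos\td1\t4\t7\t_\tI-Proteins", ""))
  docs <- read_conll(f2)
  expect_identical(nrow(docs[[1]]$entities), 1L)
  expect_identical(docs[[1]]$entities$surface, "uno dos")
})

test_that("BRAT write/read reproduces a synthetic corpus byte-stably", {
  corp <- generate_corpus(corpus_spec(n_docs = 5, sentences_per_doc = 4,
                                      seed = 13))
  td <- withr::local_tempdir()
  write_brat_dir(corp$docs, td)
  # byte-stable across two writes
  ann1 <- readLines(file.path(td, "synth0001.ann"))
  write_brat_dir(corp$docs, td)
  expect_identical(readLines(file.path(td, "synth0001.ann")), ann1)
  back <- read_brat_dir(td)
  for (k in seq_along(back)) {
    expect_identical(back[[k]]$text, corp$docs[[k]]$text)
    expect_identical(back[[k]]$entities, corp$docs[[k]]$entities)
    expect_identical(back[[k]]$tokens[, c("surface", "start", "end")],
                     corp$docs[[k]]$tokens[, c("surface", "start", "end")])
  }
  # a document with no entities writes an empty .ann file
  d0 <- ner_document("empty", "sin menciones aquí .")
  write_brat(d0, file.path(td, "empty.txt"), file.path(td, "empty.ann"))
  expect_identical(file.size(file.path(td, "empty.ann")), 0)
})

test_that("sentence splitting breaks at terminal punctuation before a capital", {
  tk <- tokenize("Primera frase . Segunda frase . tercera sigue")
  ids <- split_sentences(tk)
  expect_identical(ids, c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))
})
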