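# Gazetteer, affix and POS feature channels.

test_that("gazetteer lookup is normalized and explodes multi-word terms", {
  f <- write_temp_gazetteer(c("indometacina", "ácido acetilsalicílico",
                              "# comentario", ""))
  g <- load_gazetteer(f)
  expect_identical(gazetteer_feature("indometacina", g), 1L)
  expect_identical(gazetteer_feature("Indometacina", g), 1L)  # lowercased
  expect_identical(gazetteer_feature(c("ácido", "acetilsalicílico"), g),
                   c(1L, 1L))
  expect_identical(gazetteer_feature(c("paciente", "("), g), c(0L, 0L))
  # accent-sensitive by default; strippable on demand
  expect_identical(gazetteer_feature("acido", g), 0L)
  gs <- load_gazetteer(f, strip_accents = TRUE)
  expect_identical(gazetteer_feature("acido", gs), 1L)
})

test_that("empty gazetteer degenerates to a constant-zero feature", {
  f <- write_temp_gazetteer(character())
  expect_warning(g <- load_gazetteer(f), "empty")
  expect_identical(gazetteer_feature(c("x", "y"), g), c(0L, 0L))
  expect_identical(gazetteer_feature("x", NULL), 0L)
})

test_that("affix table parses the 5-column TSV with hyphen stripping", {
  aff <- load_affixes(write_temp_affixes())
  expect_true(all(c("suffix", "prefix", "root") %in% aff$kind))
  caina <- aff[aff$affix_en == "-caine", ]
  expect_identical(caina$kind, "suffix")
  expect_identical(caina$affix_es, "caína")  # leading hyphen stripped
  cef <- aff[aff$affix_en == "cef-", ]
  expect_identical(cef$kind, "prefix")
  expect_identical(cef$affix_es, "cef")
  # headerless file parses identically
  aff2 <- load_affixes(write_temp_affixes(header = FALSE))
  expect_identical(aff$affix_es, aff2$affix_es)
  # format errors
  bad <- withr::local_tempfile(lines = "suffix\t-caine\t-caína")
  expect_error(load_affixes(bad), "5 tab-separated")
  bad2 <- withr::local_tempfile(
    lines = "infix\t-x-\t-x-\tnone\tnone")
  expect_error(load_affixes(bad2), "prefix, suffix, root")
  empty <- withr::local_tempfile(lines = character())
  expect_warning(out <- load_affixes(empty), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("affix matching anchors by kind", {
  aff <- load_affixes(write_temp_affixes())
  expect_identical(affix_feature("lidocaína", aff), 1L)
  expect_identical(affix_feature("Lidocaína", aff), 1L)
  expect_identical(affix_feature("caínalido", aff), 0L)   # suffix anchor
  expect_identical(affix_feature("cefazolina", aff), 1L)  # prefix
  expect_identical(affix_feature("acefato", aff), 0L)     # prefix anchor
  expect_identical(affix_feature("oseltamivir", aff), 1L) # root
  expect_identical(affix_feature("vi", aff), 0L)          # < 3 chars, no root
  expect_identical(affix_feature("caína", aff), 1L)       # bare affix matches
  expect_identical(affix_feature("x", NULL), 0L)
  hit <- affix_feature("lidocaína", aff, which_entry = TRUE)
  expect_identical(aff$affix_es[hit], "caína")
})

test_that("gazetteer and affix flags agree with brute-force oracles on random tokens", {
  corp <- generate_corpus(corpus_spec(n_docs = 8, seed = 31))
  gaz_file <- write_temp_gazetteer(corp$gazetteer_terms)
  g <- load_gazetteer(gaz_file)
  aff <- corp$affixes
  raw_terms <- readLines(gaz_file, encoding = "UTF-8")
  # brute-force: linear scan over the raw term file (plus exploded words)
  exploded <- unlist(strsplit(raw_terms, " "))
  all_terms <- normalize_surface(c(raw_terms, exploded[nchar(exploded) >= 3]))
  tokens <- unlist(lapply(corp$docs, function(d) d$tokens$surface))
  set.seed(99)
  tokens <- c(sample(tokens, 900), sample(raw_terms, 100, replace = TRUE))
  got_g <- gazetteer_feature(tokens, g)
  want_g <- vapply(normalize_surface(tokens),
                   function(t) as.integer(any(all_terms == t)), 0L,
                   USE.NAMES = FALSE)
  expect_identical(got_g, want_g)
  got_a <- affix_feature(tokens, aff)
  want_a <- vapply(normalize_surface(tokens), function(t) {
    as.integer(any(mapply(function(k, a) switch(k,
      prefix = startsWith(t, a),
      suffix = endsWith(t, a),
      root = nchar(t) >= 3 && grepl(a, t, fixed = TRUE)),
      aff$kind, aff$affix_es)))
  }, 0L, USE.NAMES = FALSE)
  expect_identical(got_a, want_a)
})

test_that("POS one-hot sums to one with an UNK slot", {
  v <- pos_vocabulary(c("NC", "V", "ADJ", "NC", NA))
  expect_identical(v$dim, 4L)  # 3 tags + UNK
  oh <- pos_onehot(c("V", "NC", "DESCONOCIDO", NA), v)
  expect_identical(dim(oh), c(4L, 4L))
  expect_identical(rowSums(oh), rep(1, 4))
  expect_identical(oh[3, 4], 1)  # unseen tag -> UNK
  expect_identical(oh[4, 4], 1)  # absent POS -> UNK
})

test_that("feature extraction is deterministic and position-independent", {
  corp <- generate_corpus(corpus_spec(n_docs = 3, seed = 17))
  g <- load_gazetteer(write_temp_gazetteer(corp$gazetteer_terms))
  pv <- pos_vocabulary(unlist(lapply(corp$docs, function(d) d$tokens$pos)))
  tk <- corp$docs[[1]]$tokens
  f1 <- feature_matrix(tk, pv, g, corp$affixes)
  f2 <- feature_matrix(tk, pv, g, corp$affixes)
  expect_identical(f1, f2)
  expect_identical(ncol(f1), pv$dim + 2L)
  # same surface + POS => same feature rows, wherever the token sits
  dup <- which(duplicated(paste(tk$surface, tk$pos)))[1]
  orig <- match(paste(tk$surface, tk$pos)[dup], paste(tk$surface, tk$pos))
  expect_identical(f1[dup, ], f1[orig, ])
  # disabled channels contribute zero width
  expect_identical(ncol(feature_matrix(tk, NULL, g, NULL)), 1L)
  expect_identical(ncol(feature_matrix(tk, NULL, NULL, NULL)), 0L)
})
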