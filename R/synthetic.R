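# Seeded generator of Spanish-like synthetic corpora. Every other module
# is exercised against these corpora: documents carry character-offset
# entity annotations over imbalanced classes, entity surfaces correlate
# with gazetteer membership and drug-like affixes, and the generator
# emits gazetteer/affix files consistent with its own sampling rules.
#
# Surface forms are built from Spanish-plausible syllables (including
# accented vowels and ñ) so that tokenizer and accent-normalization
# behaviour is genuinely exercised; ASCII-only text would leave it
# untested. Linguistic realism beyond that is a non-goal.

.SYL_ONSET <- c("b", "br", "c", "ch", "cl", "d", "dr", "f", "fl", "g", "gr",
                "l", "ll", "m", "n", "ñ", "p", "pr", "r", "s", "t",
                "tr", "v", "z")
.SYL_VOWEL <- c("a", "e", "i", "o", "u", "a", "e", "o",
                "á", "é", "í", "ó", "ú")
.SYL_CODA <- c("", "", "", "", "n", "s", "r", "l")
.FUNCTION_WORDS <- c("el", "la", "los", "las", "de", "en", "con", "por",
                     "para", "se", "que", "una", "tras", "sin")
.POS_TAGS <- c("NC", "NP", "ADJ", "V", "DET", "PREP", "PRON", "ADV", "NUM",
               "PUNCT")

# The affix table the generator emits (and samples affix-bearing entity
# surfaces from). 5-column TSV layout: type, affix-EN, affix-ES,
# example-EN, drug class.
synth_affix_table <- function() {
  structure(data.frame(
    kind = c("suffix", "suffix", "suffix", "prefix", "prefix", "suffix",
             "suffix", "root"),
    affix_es = c("caína", "micina", "ciclina", "cef", "sulfa", "olol",
                 "asa", "vir"),
    affix_en = c("-caine", "-mycin", "-cycline", "cef-", "sulfa-", "-olol",
                 "-ase", "vir"),
    example_en = c("lidocaine", "erythromycin", "doxycycline", "cefazolin",
                   "sulfamethoxazole", "propranolol", "lactase",
                   "oseltamivir"),
    drug_class = c("local anesthetic", "antibiotic", "antibiotic",
                   "cephalosporin", "antibiotic", "beta blocker", "enzyme",
                   "antiviral"),
    stringsAsFactors = FALSE), class = c("ner_affixes", "data.frame"))
}

make_word <- function(nsyl) {
  paste(vapply(seq_len(nsyl), function(i) {
    paste0(sample(.SYL_ONSET, 1), sample(.SYL_VOWEL, 1), sample(.SYL_CODA, 1))
  }, ""), collapse = "")
}

sample_words <- function(n, nsyl = 2:3, avoid = character()) {
  out <- character()
  while (length(out) < n) {
    w <- vapply(sample(nsyl, n, replace = TRUE), make_word, "")
    out <- unique(c(out, setdiff(w, avoid)))
  }
  out[seq_len(n)]
}

#' Specification of a synthetic corpus
#'
#' Defaults describe the package's reference test-bed: 200 documents of
#' ~15 sentences, entity mentions at ~0.5 per sentence (~7.5 per
#' document), class proportions 4398 : 50 : 3009 : 167 over the four
#' mention classes (a heavily imbalanced inventory), and the "easy"
#' separability level: 90% of entity surfaces carry a lexical cue (60%
#' exact gazetteer terms + 30% affix-bearing forms) and 5% of sentences
#' contain a gazetteer distractor outside any entity. Distractors are
#' what keeps the learning problem nontrivial: a model must combine
#' context with the gazetteer flag rather than copy it.
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document.
#' @param sent_len_mean,sent_len_sd token-count distribution per sentence
#'   (normal, truncated at 5).
#' @param label_weights named numeric vector of target mention
#'   proportions per class.
#' @param entities_per_sentence expected entity mentions per sentence.
#' @param gaz_fraction fraction of entities whose surface is an exact
#'   gazetteer term.
#' @param affix_fraction fraction of entities whose surface bears a
#'   listed affix (disjoint from `gaz_fraction`).
#' @param multi_token_fraction fraction of gazetteer-sampled
#'   Normalizables/Proteins entities realized as multi-token forms
#'   ("receptores de X", "ácido X").
#' @param distractor_fraction fraction of sentences carrying one
#'   unannotated gazetteer word.
#' @param background_vocab_size size of the (cue-free) background
#'   vocabulary.
#' @param seed generation seed; byte-identical output under equal seeds.
#' @return list of class `ner_corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 200L, sentences_per_doc = 15L,
                        sent_len_mean = 12, sent_len_sd = 4,
                        label_weights = c("Normalizables" = 4398,
                                          "No Normalizables" = 50,
                                          "Proteins" = 3009,
                                          "Unclear" = 167),
                        entities_per_sentence = 0.5,
                        gaz_fraction = 0.6, affix_fraction = 0.3,
                        multi_token_fraction = 0.25,
                        distractor_fraction = 0.05,
                        background_vocab_size = 400L,
                        seed = 1L) {
  stopifnot(gaz_fraction >= 0, affix_fraction >= 0,
            gaz_fraction + affix_fraction <= 1,
            multi_token_fraction >= 0, multi_token_fraction <= 1,
            distractor_fraction >= 0, distractor_fraction <= 1,
            all(label_weights >= 0), n_docs >= 1)
  if (entities_per_sentence * 3 + 2 > sent_len_mean) {
    stopf("infeasible spec: %.1f entities/sentence cannot fit in sentences of ~%d tokens",
          entities_per_sentence, round(sent_len_mean))
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 sent_len_mean = sent_len_mean, sent_len_sd = sent_len_sd,
                 label_weights = label_weights / sum(label_weights),
                 entities_per_sentence = entities_per_sentence,
                 gaz_fraction = gaz_fraction, affix_fraction = affix_fraction,
                 multi_token_fraction = multi_token_fraction,
                 distractor_fraction = distractor_fraction,
                 background_vocab_size = as.integer(background_vocab_size),
                 seed = as.integer(seed)),
            class = "ner_corpus_spec")
}

#' Adjust a corpus spec to a named separability level
#'
#' `trivial`: every entity is a single-token exact gazetteer term and no
#' gazetteer word appears outside an entity — a rule tagging gazetteer
#' hits is Bayes-optimal (F1 100), the ceiling check for the model.
#' `easy`: 90% cue-bearing entities, 5% distractor sentences. `hard`:
#' 50% cue-bearing, 20% distractor sentences.
#'
#' @param spec `ner_corpus_spec`.
#' @param level `"trivial"`, `"easy"` or `"hard"`.
#' @return modified spec.
#' @export
separability_dial <- function(spec, level = c("easy", "trivial", "hard")) {
  level <- match.arg(level)
  knobs <- switch(level,
    trivial = list(gaz = 1.0, affix = 0.0, distract = 0.0, multi = 0.0),
    easy = list(gaz = 0.6, affix = 0.3, distract = 0.05, multi = 0.25),
    hard = list(gaz = 0.35, affix = 0.15, distract = 0.20, multi = 0.25))
  spec$gaz_fraction <- knobs$gaz
  spec$affix_fraction <- knobs$affix
  spec$distractor_fraction <- knobs$distract
  spec$multi_token_fraction <- knobs$multi
  spec$level <- level
  spec
}

#' Generate a synthetic corpus
#'
#' @param spec a [corpus_spec()].
#' @return object of class `ner_synth_corpus`: `docs` (list of
#'   `ner_document`s with POS tags), `gazetteer_terms` (character vector
#'   as written to the gazetteer file), `affixes` (the affix table),
#'   `term_classes` (named map from normalized gazetteer term to entity
#'   class, the oracle for the dictionary baseline), and `spec`.
#' @export
generate_corpus <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  affixes <- synth_affix_table()
  classes <- names(spec$label_weights)

  # --- vocabulary pools -----------------------------------------------
  # gazetteer terms per class (disjoint), affix-bearing pools, plain
  # (cue-free) entity pools, and a cue-free background vocabulary.
  n_gaz <- c(60L, 8L, 40L, 10L)[seq_along(classes)]
  names(n_gaz) <- classes
  bank <- sample_words(sum(n_gaz) + 80L + 60L +
                         spec$background_vocab_size + 200L)
  # drop words that accidentally carry an affix
  bank <- bank[affix_feature(bank, affixes) == 0]
  take <- function(k) {
    w <- bank[seq_len(k)]
    bank <<- bank[-seq_len(k)]
    w
  }
  gaz_pool <- lapply(n_gaz, take)
  # multi-word gazetteer entries for Normalizables ("ácido X")
  acid_bases <- take(8L)
  acid_terms <- paste("ácido", acid_bases)
  gaz_pool[["Normalizables"]] <- c(gaz_pool[["Normalizables"]], acid_terms)
  # affix-bearing entity surfaces (not in the gazetteer)
  affix_forms <- function(bases, class) {
    pick <- switch(class,
      "Proteins" = c("asa"),
      c("caína", "micina", "ciclina", "olol"))
    pre <- switch(class, "Proteins" = character(), c("cef", "sulfa"))
    unlist(lapply(bases, function(b) {
      if (length(pre) && stats::runif(1) < 0.3) {
        paste0(sample(pre, 1), b)
      } else {
        paste0(b, sample(pick, 1))
      }
    }))
  }
  affix_pool <- list()
  for (cl in classes) {
    nb <- if (cl %in% c("Normalizables", "Proteins")) 25L else 5L
    affix_pool[[cl]] <- affix_forms(take(nb), cl)
  }
  plain_pool <- lapply(stats::setNames(classes, classes),
                       function(cl) take(15L))
  background <- c(take(spec$background_vocab_size), .FUNCTION_WORDS)
  gazetteer_terms <- unlist(gaz_pool, use.names = FALSE)
  gaz_norm <- unique(c(normalize_surface(gazetteer_terms),
                       normalize_surface(unlist(strsplit(gazetteer_terms, " ")))))
  background <- background[!normalize_surface(background) %in% gaz_norm]
  for (cl in classes) {
    plain_pool[[cl]] <- plain_pool[[cl]][
      !normalize_surface(plain_pool[[cl]]) %in% gaz_norm]
  }
  term_classes <- character()
  for (cl in classes) {
    comp <- unlist(strsplit(gaz_pool[[cl]], " "))
    comp <- comp[nchar(comp) >= 3]
    key <- normalize_surface(unique(c(gaz_pool[[cl]], comp)))
    add <- stats::setNames(rep(cl, length(key)), key)
    term_classes <- c(term_classes, add[!names(add) %in% names(term_classes)])
  }

  # --- per-sentence layout ---------------------------------------------
  n_sent <- spec$n_docs * spec$sentences_per_doc
  sent_len <- pmax(5L, round(stats::rnorm(n_sent, spec$sent_len_mean,
                                          spec$sent_len_sd)))
  n_ent_sent <- stats::rpois(n_sent, spec$entities_per_sentence)
  total_ent <- sum(n_ent_sent)
  # exact-proportion class sequence (shuffled), so realized counts track
  # the target ratios up to rounding rather than multinomial noise
  cnt <- floor(spec$label_weights * total_ent)
  rem <- total_ent - sum(cnt)
  if (rem > 0) {
    top <- order(spec$label_weights * total_ent - cnt, decreasing = TRUE)
    cnt[top[seq_len(rem)]] <- cnt[top[seq_len(rem)]] + 1
  }
  class_seq <- sample(rep(classes, times = cnt))
  ent_ptr <- 0L

  pick1 <- function(x) x[sample.int(length(x), 1)]
  sample_entity <- function(cl) {
    u <- stats::runif(1)
    if (u < spec$gaz_fraction) {
      pool <- gaz_pool[[cl]]
      if (cl == "Proteins" && stats::runif(1) < spec$multi_token_fraction) {
        return(paste("receptores de", pick1(pool)))
      }
      multi <- grepl(" ", pool)
      if (any(multi) && stats::runif(1) < spec$multi_token_fraction) {
        return(pick1(pool[multi]))
      }
      return(pick1(pool[!multi]))
    }
    if (u < spec$gaz_fraction + spec$affix_fraction) {
      return(pick1(affix_pool[[cl]]))
    }
    pick1(plain_pool[[cl]])
  }

  docs <- vector("list", spec$n_docs)
  si <- 0L
  for (d in seq_len(spec$n_docs)) {
    words_all <- character(); pos_all <- character()
    ent_rows <- list()
    tok_count <- 0L
    for (s in seq_len(spec$sentences_per_doc)) {
      si <- si + 1L
      L <- sent_len[si]
      words <- sample(background, L, replace = TRUE)
      pos <- sample(.POS_TAGS[1:9], L, replace = TRUE,
                    prob = c(.25, .05, .15, .2, .12, .1, .04, .05, .04))
      pos[words %in% .FUNCTION_WORDS] <- "PREP"
      is_ent <- rep(FALSE, L)
      k <- n_ent_sent[si]
      placed <- 0L
      if (k > 0) {
        tries <- 0L
        while (placed < k && tries < 50L) {
          tries <- tries + 1L
          cl <- class_seq[ent_ptr + placed + 1L]
          surf <- sample_entity(cl)
          w <- strsplit(surf, " ", fixed = TRUE)[[1]]
          wl <- length(w)
          pstart <- if (L - wl <= 2L) 2L else pick1(2:(L - wl))
          span <- pstart:(pstart + wl - 1L)
          if (max(span) > L) next
          # keep one cue-free token between entities (runs of gazetteer
          # hits must correspond to single gold entities)
          guard <- max(1L, pstart - 1L):min(L, max(span) + 1L)
          if (any(is_ent[guard])) next
          words[span] <- w
          pos[span] <- ifelse(w %in% .FUNCTION_WORDS, "PREP",
                              sample(c("NP", "NC"), wl, TRUE, c(.6, .4)))
          is_ent[span] <- TRUE
          ent_rows[[length(ent_rows) + 1L]] <-
            list(class = cl, tok_from = tok_count + pstart,
                 tok_to = tok_count + pstart + wl - 1L)
          placed <- placed + 1L
        }
      }
      ent_ptr <- ent_ptr + placed
      # distractor: one gazetteer word outside any entity
      if (spec$distractor_fraction > 0 &&
          stats::runif(1) < spec$distractor_fraction) {
        free <- which(!is_ent)
        free <- free[free > 1]
        if (length(free)) {
          j <- pick1(free)
          cand <- gazetteer_terms[!grepl(" ", gazetteer_terms)]
          words[j] <- pick1(cand)
        }
      }
      # sentence-initial capital (kept off entity slots by placement)
      substr(words[1], 1, 1) <- toupper(substr(words[1], 1, 1))
      words <- c(words, "."); pos <- c(pos, "PUNCT")
      words_all <- c(words_all, words); pos_all <- c(pos_all, pos)
      tok_count <- tok_count + length(words)
    }
    # assemble text and offsets (single-space joins, single-line text)
    nch <- nchar(words_all)
    start <- cumsum(c(0L, nch[-length(nch)] + 1L))
    end <- start + nch
    text <- paste(words_all, collapse = " ")
    tokens <- data.frame(surface = words_all, start = start, end = end,
                         pos = pos_all, stringsAsFactors = FALSE)
    ents <- if (length(ent_rows)) {
      data.frame(
        label = vapply(ent_rows, `[[`, "", "class"),
        start = start[vapply(ent_rows, `[[`, 0, "tok_from")],
        end = end[vapply(ent_rows, `[[`, 0, "tok_to")],
        stringsAsFactors = FALSE)
    } else {
      data.frame(label = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    }
    if (nrow(ents)) {
      ents <- ents[order(ents$start), , drop = FALSE]
      ents$surface <- text_slice(text, ents$start, ents$end)
      rownames(ents) <- NULL
    } else {
      ents$surface <- character()
    }
    docs[[d]] <- ner_document(sprintf("synth%04d", d), text,
                              entities = ents, tokens = tokens)
  }
  structure(list(docs = docs, gazetteer_terms = gazetteer_terms,
                 affixes = affixes, term_classes = term_classes,
                 spec = spec),
            class = "ner_synth_corpus")
}

#' @export
print.ner_synth_corpus <- function(x, ...) {
  nent <- sum(vapply(x$docs, function(d) nrow(d$entities), 0L))
  cat(sprintf("<ner_synth_corpus: %d docs, %d entities, %d gazetteer terms>\n",
              length(x$docs), nent, length(x$gazetteer_terms)))
  invisible(x)
}

#' Write a synthetic corpus to a directory
#'
#' Emits `brat/` (paired txt+ann), `conll/corpus.conll`,
#' `gazetteer.txt`, `affixes.tsv` and `spec.json`.
#'
#' @param corpus `ner_synth_corpus`.
#' @param dir output directory.
#' @param scheme tagging scheme for the CoNLL file.
#' @return `dir`, invisibly.
#' @export
write_corpus_dir <- function(corpus, dir, scheme = c("BIOES", "BIO")) {
  scheme <- scheme_match(scheme)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_brat_dir(corpus$docs, file.path(dir, "brat"))
  dir.create(file.path(dir, "conll"), showWarnings = FALSE)
  write_conll(corpus$docs, file.path(dir, "conll", "corpus.conll"), scheme)
  con <- file(file.path(dir, "gazetteer.txt"), "wb")
  writeLines(enc2utf8(corpus$gazetteer_terms), con, useBytes = TRUE)
  close(con)
  aff <- corpus$affixes
  lines <- c("type\taffix-en\taffix-es\texample-en\tdrug-class",
             paste(aff$kind, aff$affix_en, aff$affix_es, aff$example_en,
                   aff$drug_class, sep = "\t"))
  con <- file(file.path(dir, "affixes.tsv"), "wb")
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  close(con)
  jsonlite::write_json(unclass(corpus$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Dictionary-rule baseline tagger
#'
#' Marks maximal runs of gazetteer-member tokens as entities, labelled by
#' the class of the run's first term in `term_classes`. On a trivial
#' corpus this rule is Bayes-optimal; on easy/hard corpora the
#' distractors make it err, which is what the learned model must beat.
#'
#' @param docs list of `ner_document`s.
#' @param gazetteer `ner_gazetteer`.
#' @param term_classes named map normalized term -> class (see
#'   [generate_corpus()]).
#' @return list of predicted documents (entities replaced).
#' @export
dictionary_baseline <- function(docs, gazetteer, term_classes) {
  lapply(docs, function(doc) {
    tk <- doc$tokens
    hit <- gazetteer_feature(tk$surface, gazetteer) == 1
    ents <- list()
    i <- 1L; n <- nrow(tk)
    while (i <= n) {
      if (hit[i]) {
        j <- i
        while (j < n && hit[j + 1L]) j <- j + 1L
        key <- normalize_surface(tk$surface[i])
        lab <- term_classes[key]
        if (is.na(lab)) lab <- term_classes[1]
        ents[[length(ents) + 1L]] <- list(label = unname(lab),
                                          start = tk$start[i],
                                          end = tk$end[j])
        i <- j + 1L
      } else i <- i + 1L
    }
    ed <- if (length(ents)) {
      data.frame(label = vapply(ents, `[[`, "", "label"),
                 start = vapply(ents, `[[`, 0L, "start"),
                 end = vapply(ents, `[[`, 0L, "end"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    }
    ed$surface <- text_slice(doc$text, ed$start, ed$end)
    ner_document(doc$doc_id, doc$text, entities = ed, tokens = tk)
  })
}
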