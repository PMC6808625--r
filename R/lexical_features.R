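# The three per-token lexical feature channels concatenated into the
# character-enhanced token embedding: POS one-hot, gazetteer membership,
# and drug-affix match.

#' Load a gazetteer term list
#'
#' Reads a plain-text term list (one term per line; blank lines and `#`
#' comments skipped), normalizes every term, and additionally explodes
#' multi-word terms into their component words of length >= 3 characters
#' — lookup is per token, so a multi-word entry such as
#' "ácido acetilsalicílico" could otherwise never fire.
#'
#' @param path UTF-8 text file, one term per line.
#' @param strip_accents normalization policy; see [normalize_surface()].
#' @param explode_multiword explode multi-word entries into component
#'   words (default `TRUE`).
#' @return object of class `ner_gazetteer`: a hashed environment of terms
#'   plus the normalization policy.
#' @export
load_gazetteer <- function(path, strip_accents = FALSE, explode_multiword = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  terms <- normalize_surface(lines, strip_accents)
  if (explode_multiword) {
    multi <- terms[grepl("\\s", terms)]
    if (length(multi)) {
      words <- unlist(strsplit(multi, "\\s+"))
      terms <- c(terms, words[nchar(words) >= 3])
    }
  }
  terms <- unique(terms)
  if (!length(terms)) {
    warnf("gazetteer file %s is empty; the feature degenerates to constant 0", path)
  }
  env <- new.env(parent = emptyenv(), size = max(length(terms), 1L))
  for (t in terms) assign(t, TRUE, envir = env)
  structure(list(index = env, terms = terms, strip_accents = strip_accents,
                 path = path),
            class = "ner_gazetteer")
}

#' @export
print.ner_gazetteer <- function(x, ...) {
  cat(sprintf("<ner_gazetteer: %d terms, accents %s>\n", length(x$terms),
              if (x$strip_accents) "stripped" else "preserved"))
  invisible(x)
}

#' Gazetteer membership flag for a token surface
#'
#' @param surface character vector of token surfaces.
#' @param gazetteer object from [load_gazetteer()], or `NULL` (always 0).
#' @return integer vector of 0/1 flags: 1 iff the normalized surface is a
#'   gazetteer term.
#' @export
gazetteer_feature <- function(surface, gazetteer) {
  if (is.null(gazetteer) || !length(gazetteer$terms)) {
    return(integer(length(surface)))
  }
  key <- normalize_surface(surface, gazetteer$strip_accents)
  vapply(key, function(k) as.integer(exists(k, envir = gazetteer$index,
                                            inherits = FALSE)),
         integer(1), USE.NAMES = FALSE)
}

.AFFIX_KINDS <- c("prefix", "suffix", "root")

#' Load a drug-affix table
#'
#' Reads the 5-column TSV `type, affix-EN, affix-ES, example-EN, drug
#' class` (header auto-detected). Only the type and the Spanish affix are
#' consumed; the other columns are retained for provenance. Leading and
#' trailing hyphens in the affix cell are stripped — they conventionally
#' mark the anchor side, which must agree with the declared type.
#'
#' @param path UTF-8 TSV path.
#' @return data.frame of class `ner_affixes` with columns `kind`,
#'   `affix_es` plus the source columns.
#' @export
load_affixes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- structure(data.frame(kind = character(), affix_es = character(),
                                affix_en = character(), example_en = character(),
                                drug_class = character(), stringsAsFactors = FALSE),
                     class = c("ner_affixes", "data.frame"), path = path)
  if (!length(lines)) {
    warnf("affix file %s is empty", path)
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 5)) {
    stopf("affix file %s line %d: expected 5 tab-separated columns, got %d",
          path, which(nc < 5)[1], nc[nc < 5][1])
  }
  kind_raw <- tolower(trimws(vapply(parts, `[[`, "", 1)))
  # header auto-detection: a first row whose type column is the literal
  # column name
  if (kind_raw[1] %in% c("type", "kind")) {
    parts <- parts[-1]; kind_raw <- kind_raw[-1]
    if (!length(parts)) return(empty)
  }
  bad <- which(!kind_raw %in% .AFFIX_KINDS)
  if (length(bad)) {
    stopf("affix file %s: unknown affix type %s (accepted: %s)", path,
          dQuote(kind_raw[bad[1]]), paste(.AFFIX_KINDS, collapse = ", "))
  }
  affix_es_raw <- trimws(vapply(parts, `[[`, "", 3))
  affix_es <- normalize_surface(gsub("^-+|-+$", "", affix_es_raw))
  keep <- nzchar(affix_es)
  out <- data.frame(kind = kind_raw, affix_es = affix_es,
                    affix_en = trimws(vapply(parts, `[[`, "", 2)),
                    example_en = trimws(vapply(parts, `[[`, "", 4)),
                    drug_class = trimws(vapply(parts, `[[`, "", 5)),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ner_affixes", "data.frame"), path = path)
}

#' Affix match flag for a token surface
#'
#' Matching is on the lowercased, NFC-normalized surface and is
#' accent-sensitive. Anchoring follows the affix kind: prefix at the
#' start, suffix at the end, root anywhere; a token equal to the bare
#' affix counts as a match, but tokens shorter than 3 characters never
#' match roots (caps false positives on fragments).
#'
#' @param surface character vector of token surfaces.
#' @param affixes data.frame from [load_affixes()], or `NULL` (always 0).
#' @param which_entry if `TRUE`, return the index of the first matching
#'   entry (`NA` for no match) instead of a 0/1 flag.
#' @return integer vector of flags (or entry indices).
#' @export
affix_feature <- function(surface, affixes, which_entry = FALSE) {
  n <- length(surface)
  if (is.null(affixes) || !nrow(affixes)) {
    return(if (which_entry) rep(NA_integer_, n) else integer(n))
  }
  key <- normalize_surface(surface)
  hit <- rep(NA_integer_, n)
  for (j in seq_len(nrow(affixes))) {
    a <- affixes$affix_es[j]
    cand <- which(is.na(hit))
    if (!length(cand)) break
    m <- switch(affixes$kind[j],
      prefix = startsWith(key[cand], a),
      suffix = endsWith(key[cand], a),
      root = nchar(key[cand]) >= 3 & grepl(a, key[cand], fixed = TRUE))
    hit[cand[m]] <- j
  }
  if (which_entry) hit else as.integer(!is.na(hit))
}

#' Build a POS tag vocabulary
#'
#' The vocabulary is frozen at training time and serialized with the
#' model; unseen tags at prediction time map to the reserved UNK slot, so
#' the one-hot dimension is `length(tags) + 1`.
#'
#' @param tags character vector of observed POS tags (NAs dropped).
#' @return object of class `ner_pos_vocab`.
#' @export
pos_vocabulary <- function(tags) {
  tags <- sort(unique(tags[!is.na(tags)]))
  structure(list(tags = tags, dim = length(tags) + 1L), class = "ner_pos_vocab")
}

#' One-hot encode a POS tag
#'
#' @param tag character vector of POS tags (`NA` allowed).
#' @param vocab a `ner_pos_vocab`.
#' @return matrix of dimension `length(tag)` x `vocab$dim`; each row is a
#'   unit vector, with the last column the UNK slot.
#' @export
pos_onehot <- function(tag, vocab) {
  idx <- match(tag, vocab$tags)
  idx[is.na(idx)] <- vocab$dim  # UNK slot
  out <- matrix(0, nrow = length(tag), ncol = vocab$dim)
  out[cbind(seq_along(tag), idx)] <- 1
  out
}

#' Per-token feature matrix for a document
#'
#' Assembles the enabled feature channels into one matrix with a fixed
#' column layout: POS one-hot block (if enabled), gazetteer flag, affix
#' flag. Disabled channels contribute zero columns, not zero values.
#'
#' @param tokens token table of a document.
#' @param pos_vocab `ner_pos_vocab` or `NULL` when the POS channel is off.
#' @param gazetteer `ner_gazetteer` or `NULL` when the channel is off.
#' @param affixes `ner_affixes` or `NULL` when the channel is off.
#' @return numeric matrix, `nrow(tokens)` x (feature width); width 0 when
#'   all channels are disabled.
#' @export
feature_matrix <- function(tokens, pos_vocab = NULL, gazetteer = NULL,
                           affixes = NULL) {
  n <- nrow(tokens)
  blocks <- list()
  if (!is.null(pos_vocab)) blocks$pos <- pos_onehot(tokens$pos, pos_vocab)
  if (!is.null(gazetteer)) {
    blocks$gaz <- matrix(as.numeric(gazetteer_feature(tokens$surface, gazetteer)), ncol = 1)
  }
  if (!is.null(affixes)) {
    blocks$aff <- matrix(as.numeric(affix_feature(tokens$surface, affixes)), ncol = 1)
  }
  if (!length(blocks)) return(matrix(0, nrow = n, ncol = 0))
  do.call(cbind, blocks)
}
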