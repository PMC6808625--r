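# Token/character vocabularies and plain-text embedding loading
# (word2vec-text, GloVe, fastText .vec formats; optional "count dim"
# header auto-detected; gzip accepted transparently).

#' Load pretrained token embeddings from a text file
#'
#' @param path path to a UTF-8 text file, optionally gzip-compressed:
#'   an optional header line `count dim`, then one `word v1 ... vd` line
#'   per vector (space-separated).
#' @param max_skip_fraction lines with an inconsistent dimension are
#'   skipped (with a message); if more than this fraction of lines are
#'   malformed the file is rejected as a format error.
#' @return list with `vectors` (matrix, one row per word, rownames =
#'   words) and `dim`.
#' @export
load_pretrained <- function(path, max_skip_fraction = 0.01) {
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("embedding file %s contains no vectors", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]  # "count dim" header
    if (!length(lines)) stopf("embedding file %s contains no vectors", path)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  nc <- lengths(parts)
  d <- stats::median(nc) - 1L
  ok <- nc == d + 1L
  vals <- suppressWarnings(lapply(parts[ok], function(p) as.numeric(p[-1])))
  num_ok <- !vapply(vals, anyNA, logical(1))
  skipped <- sum(!ok) + sum(!num_ok)
  if (skipped > 0) {
    if (skipped > max_skip_fraction * length(lines)) {
      stopf("embedding file %s: %d of %d lines malformed (dimension %d expected)",
            path, skipped, length(lines), d)
    }
    message(sprintf("load_pretrained: skipped %d malformed line(s) in %s",
                    skipped, path))
  }
  words <- vapply(parts[ok], `[[`, "", 1)[num_ok]
  mat <- do.call(rbind, vals[num_ok])
  dup <- duplicated(words)
  words <- words[!dup]; mat <- mat[!dup, , drop = FALSE]
  if (!length(words)) stopf("embedding file %s contains no vectors", path)
  rownames(mat) <- words
  list(vectors = mat, dim = as.integer(d))
}

#' Write an embedding mapping back to text (round-trip helper)
#' @param emb list as returned by [load_pretrained()].
#' @param path output path.
#' @param header write the `count dim` header line.
#' @export
write_embeddings <- function(emb, path, header = TRUE) {
  lines <- paste(rownames(emb$vectors),
                 apply(emb$vectors, 1, function(v)
                   paste(formatC(v, format = "g", digits = 8), collapse = " ")))
  if (header) lines <- c(paste(nrow(emb$vectors), emb$dim), lines)
  con <- file(path, open = "wb")
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Build a token vocabulary with an embedding matrix
#'
#' The vocabulary is the union of the training tokens and all pretrained
#' words (so pretrained coverage survives into prediction). Rows for
#' pretrained words are copied verbatim; other rows are sampled uniformly
#' in `[-r, r]` with `r = sqrt(3/d)`; the UNK row is the mean of all
#' pretrained vectors, or random when none are supplied. Lookup lowercases
#' by default (embedding releases are typically lowercased); the original
#' surface still feeds the character channel, so case is not lost.
#'
#' @param surfaces character vector of training token surfaces.
#' @param pretrained optional list from [load_pretrained()].
#' @param d embedding dimension (ignored when `pretrained` is given).
#' @param lowercase lowercase surfaces before lookup.
#' @param seed integer seed for the random rows.
#' @return object of class `ner_token_vocab`: `tokens` (ordered, with
#'   `<UNK>` and `<PAD>` last), `matrix` (d x |V|, columns = tokens),
#'   `lowercase`, `d`.
#' @export
build_vocab <- function(surfaces, pretrained = NULL, d = 100, lowercase = TRUE,
                        seed = 1L) {
  norm <- if (lowercase) stringi::stri_trans_tolower(surfaces) else surfaces
  toks <- sort(unique(norm))
  if (!is.null(pretrained)) {
    d <- pretrained$dim
    toks <- union(toks, rownames(pretrained$vectors))
  }
  all <- c(toks, "<UNK>", "<PAD>")
  r <- sqrt(3 / d)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mat <- matrix(stats::runif(d * length(all), -r, r), nrow = d)
  colnames(mat) <- all
  if (!is.null(pretrained)) {
    hit <- intersect(all, rownames(pretrained$vectors))
    mat[, hit] <- t(pretrained$vectors[hit, , drop = FALSE])
    mat[, "<UNK>"] <- colMeans(pretrained$vectors)
  }
  mat[, "<PAD>"] <- 0
  structure(list(tokens = all, matrix = mat, lowercase = lowercase,
                 d = as.integer(d)),
            class = "ner_token_vocab")
}

#' Build a character vocabulary from training surfaces
#' @param surfaces character vector of token surfaces.
#' @return object of class `ner_char_vocab` with `chars` (ordered, plus
#'   `<UNK>` and `<PAD>`).
#' @export
build_char_vocab <- function(surfaces) {
  chars <- sort(unique(unlist(strsplit(surfaces, "", fixed = TRUE))))
  structure(list(chars = c(chars, "<UNK>", "<PAD>")), class = "ner_char_vocab")
}

# Token surface -> column index in the vocabulary matrix (UNK fallback).
vocab_index <- function(vocab, surfaces) {
  key <- if (vocab$lowercase) stringi::stri_trans_tolower(surfaces) else surfaces
  idx <- match(key, vocab$tokens)
  idx[is.na(idx)] <- match("<UNK>", vocab$tokens)
  idx
}

char_index <- function(cvocab, surface) {
  cs <- strsplit(surface, "", fixed = TRUE)[[1]]
  idx <- match(cs, cvocab$chars)
  idx[is.na(idx)] <- match("<UNK>", cvocab$chars)
  idx
}

# Save/restore .Random.seed so seeded construction does not perturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
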