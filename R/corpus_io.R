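# Documents, tokenization with character offsets, BRAT standoff and CoNLL
# readers/writers, and conversion between entity spans and BIO/BIOES tags.
#
# Offsets are 0-based, end-exclusive *character* offsets into the document
# text (the BRAT convention); newlines count as one character.

#' Construct a document
#'
#' A document carries its raw text, a token table with character offsets,
#' and a table of gold entity spans. Tokens are produced by [tokenize()]
#' unless supplied explicitly.
#'
#' @param doc_id document identifier (used as the BRAT/CoNLL file stem).
#' @param text raw document text (UTF-8).
#' @param entities data.frame with columns `label`, `start`, `end`,
#'   `surface`; offsets are 0-based end-exclusive into `text`.
#' @param tokens optional token table (columns `surface`, `start`, `end`,
#'   `pos`); defaults to `tokenize(text)`.
#' @return an object of class `ner_document`.
#' @export
ner_document <- function(doc_id, text, entities = NULL, tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize(text)
  if (is.null(entities)) {
    entities <- data.frame(label = character(), start = integer(),
                           end = integer(), surface = character(),
                           stringsAsFactors = FALSE)
  }
  doc <- structure(list(doc_id = doc_id, text = text, tokens = tokens,
                        entities = entities),
                   class = "ner_document")
  validate_document(doc)
  doc
}

#' @export
print.ner_document <- function(x, ...) {
  cat(sprintf("<ner_document %s: %d chars, %d tokens, %d entities>\n",
              x$doc_id, nchar(x$text), nrow(x$tokens), nrow(x$entities)))
  invisible(x)
}

# Enforce the structural invariants: token offsets strictly increasing and
# non-overlapping, surfaces matching the text, entities inside the text.
validate_document <- function(doc) {
  tk <- doc$tokens
  if (nrow(tk)) {
    if (any(tk$end <= tk$start)) stopf("document %s: empty token span", doc$doc_id)
    if (any(diff(tk$start) <= 0) || any(tk$start[-1] < tk$end[-nrow(tk)])) {
      stopf("document %s: token offsets overlap or are not increasing", doc$doc_id)
    }
    got <- text_slice(doc$text, tk$start, tk$end)
    bad <- which(got != tk$surface)
    if (length(bad)) {
      stopf("document %s: token %d surface %s does not match text slice %s",
            doc$doc_id, bad[1], dQuote(tk$surface[bad[1]]), dQuote(got[bad[1]]))
    }
  }
  en <- doc$entities
  if (nrow(en)) {
    if (any(en$start < 0) || any(en$end > nchar(doc$text)) || any(en$end <= en$start)) {
      stopf("document %s: entity offsets outside [0, %d]", doc$doc_id, nchar(doc$text))
    }
    got <- text_slice(doc$text, en$start, en$end)
    bad <- which(gsub("\n", " ", got) != gsub("\n", " ", en$surface))
    if (length(bad)) {
      stopf("document %s: entity %d surface %s does not match text %s",
            doc$doc_id, bad[1], dQuote(en$surface[bad[1]]), dQuote(got[bad[1]]))
    }
  }
  invisible(doc)
}

#' Tokenize text with character offsets
#'
#' Rule-based tokenizer for Spanish clinical text: splits on Unicode
#' whitespace, then isolates punctuation and symbol characters as
#' single-character tokens. Two exceptions keep clinically meaningful
#' units intact: an intra-word hyphen (letter on both sides) and a decimal
#' comma (digit on both sides) stay attached.
#'
#' @param text arbitrary UTF-8 text.
#' @return data.frame with columns `surface`, `start`, `end`, `pos`
#'   (`pos` is `NA`; offsets are 0-based end-exclusive and satisfy
#'   `substr(text, start + 1, end) == surface`).
#' @examples
#' tokenize("lidocaína (2%)")$surface
#' @export
tokenize <- function(text) {
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), pos = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  text <- enc2utf8(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_ws     <- stringi::stri_detect_charclass(chars, "[\\p{WHITE_SPACE}]")
  is_punct  <- stringi::stri_detect_charclass(chars, "[\\p{P}\\p{S}]")
  is_letter <- stringi::stri_detect_charclass(chars, "[\\p{L}\\p{M}]")
  is_digit  <- stringi::stri_detect_charclass(chars, "[\\p{Nd}]")
  prev <- function(v) c(FALSE, v[-n])
  nxt  <- function(v) c(v[-1], FALSE)
  keep_hyphen <- chars == "-" & prev(is_letter) & nxt(is_letter)
  keep_comma  <- chars == "," & prev(is_digit) & nxt(is_digit)
  isolated <- is_punct & !keep_hyphen & !keep_comma
  keep <- !is_ws
  start_new <- keep & (c(TRUE, is_ws[-n]) | isolated | prev(isolated))
  grp <- cumsum(start_new)
  idx <- which(keep)
  if (!length(idx)) return(empty)
  g <- grp[idx]
  start <- tapply(idx, g, min) - 1L
  end <- tapply(idx, g, max)
  o <- order(start)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  data.frame(surface = text_slice(text, start, end),
             start = start, end = end, pos = NA_character_,
             stringsAsFactors = FALSE)
}

#' Sentence segmentation over a token table
#'
#' A sentence break is placed after a sentence-final `.`, `?` or `!` token
#' that is followed by a gap (whitespace in the original text) and a token
#' starting with an uppercase letter. The document remains the annotation
#' unit; sentences only drive CoNLL blank lines and training minibatches.
#'
#' @param tokens token table as produced by [tokenize()].
#' @return integer vector of sentence ids (1-based), one per token.
#' @export
split_sentences <- function(tokens) {
  n <- nrow(tokens)
  if (!n) return(integer())
  brk <- rep(FALSE, n)
  if (n > 1) {
    final_punct <- tokens$surface %in% c(".", "?", "!")
    gap <- c(tokens$start[-1] > tokens$end[-n], FALSE)
    cap <- c(stringi::stri_detect_regex(substr(tokens$surface[-1], 1, 1), "^\\p{Lu}"), FALSE)
    brk[-n] <- final_punct[-n] & gap[-n] & cap[-n]
  }
  cumsum(c(TRUE, brk[-n]))
}

# ---------------------------------------------------------------------------
# BRAT standoff

#' Read a BRAT standoff document
#'
#' Parses the `.txt` file plus the text-bound (`T`) annotations of the
#' `.ann` file. Relation, event and note lines are ignored. Offsets are
#' checked against the text; discontinuous spans (`start end;start end`)
#' are rejected.
#'
#' @param txt_path path to the raw-text file.
#' @param ann_path path to the standoff annotation file.
#' @param doc_id document id; defaults to the `.txt` file stem.
#' @param lenient if `TRUE`, a surface/text mismatch is downgraded from an
#'   error to a warning (the text slice wins).
#' @param expand_boundaries if `TRUE`, entity boundaries that fall inside a
#'   token are snapped outward to the enclosing token boundaries, with one
#'   warning per adjusted entity. Off by default: silent snapping corrupts
#'   evaluation.
#' @return an `ner_document`.
#' @export
read_brat <- function(txt_path, ann_path, doc_id = NULL,
                      lenient = FALSE, expand_boundaries = FALSE) {
  if (is.null(doc_id)) doc_id <- sub("\\.txt$", "", basename(txt_path))
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  tlines <- grep("^T", lines, value = TRUE)
  ents <- data.frame(label = character(), start = integer(), end = integer(),
                     surface = character(), stringsAsFactors = FALSE)
  if (length(tlines)) {
    parts <- strsplit(tlines, "\t", fixed = TRUE)
    rows <- lapply(parts, function(p) {
      tid <- p[[1]]
      if (length(p) < 2) stopf("annotation %s: missing span field", tid)
      span <- p[[2]]
      if (grepl(";", span, fixed = TRUE)) {
        stopf("annotation %s: discontinuous spans are not supported", tid)
      }
      # label first, then start/end; the label itself may contain spaces
      # (e.g. "No Normalizables")
      m <- regmatches(span, regexec("^(.*\\S) (\\d+) (\\d+)$", span))[[1]]
      if (!length(m)) stopf("annotation %s: malformed span %s", tid, dQuote(span))
      start <- as.integer(m[3]); end <- as.integer(m[4])
      if (end > nchar(text) || start < 0 || end <= start) {
        stopf("annotation %s: offsets [%d,%d) outside text of length %d",
              tid, start, end, nchar(text))
      }
      surface <- if (length(p) >= 3) p[[3]] else text_slice(text, start, end)
      list(tid = tid, label = m[2], start = start, end = end, surface = surface)
    })
    ents <- data.frame(
      label = vapply(rows, `[[`, "", "label"),
      start = vapply(rows, `[[`, 0L, "start"),
      end = vapply(rows, `[[`, 0L, "end"),
      surface = vapply(rows, `[[`, "", "surface"),
      stringsAsFactors = FALSE)
    got <- gsub("\n", " ", text_slice(text, ents$start, ents$end))
    bad <- which(got != gsub("\n", " ", ents$surface))
    if (length(bad)) {
      tid <- vapply(rows, `[[`, "", "tid")
      msg <- sprintf("annotation %s: surface %s does not match text %s",
                     tid[bad[1]], dQuote(ents$surface[bad[1]]), dQuote(got[bad[1]]))
      if (lenient) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
      ents$surface[bad] <- got[bad]
    }
  }
  tokens <- tokenize(text)
  if (expand_boundaries && nrow(ents)) {
    for (i in seq_len(nrow(ents))) {
      s <- ents$start[i]; e <- ents$end[i]
      cover <- which(tokens$end > s & tokens$start < e)
      if (length(cover)) {
        ns <- min(tokens$start[cover]); ne <- max(tokens$end[cover])
        if (ns != s || ne != e) {
          warnf("entity %d (%s) snapped [%d,%d) -> [%d,%d)", i, ents$label[i],
                s, e, ns, ne)
          ents$start[i] <- ns; ents$end[i] <- ne
          ents$surface[i] <- text_slice(text, ns, ne)
        }
      }
    }
  }
  ner_document(doc_id, text, entities = ents, tokens = tokens)
}

#' Write a document as BRAT standoff
#'
#' Inverse of [read_brat()]: `read_brat(write_brat(d))` reproduces text,
#' token offsets and entities exactly (for text without a trailing newline).
#'
#' @param doc an `ner_document`.
#' @param txt_path,ann_path output paths.
#' @export
write_brat <- function(doc, txt_path, ann_path) {
  con <- file(txt_path, open = "wb")
  writeLines(strsplit(doc$text, "\n", fixed = TRUE)[[1]], con, useBytes = TRUE,
             sep = "\n")
  close(con)
  en <- doc$entities
  lines <- character()
  if (nrow(en)) {
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(en)), en$label,
                     en$start, en$end, gsub("\n", " ", en$surface))
  }
  con <- file(ann_path, open = "wb")
  if (length(lines)) writeLines(enc2utf8(lines), con, useBytes = TRUE)
  close(con)
  invisible(doc)
}

# ---------------------------------------------------------------------------
# Entity spans <-> per-token tag sequences

scheme_match <- function(scheme) match.arg(scheme, c("BIOES", "BIO"))

# Token index range [i1, i2] covered by an entity, or an alignment error.
entity_token_range <- function(tokens, start, end, label) {
  i1 <- match(start, tokens$start)
  i2 <- match(end, tokens$end)
  if (is.na(i1) || is.na(i2) || i2 < i1) {
    stopf("entity %s [%d,%d) does not align with token boundaries", label, start, end)
  }
  c(i1, i2)
}

#' Encode entity spans as a per-token tag sequence
#'
#' @param doc an `ner_document` whose entity boundaries coincide with token
#'   boundaries; overlapping entities are an error (no nesting support).
#' @param scheme `"BIOES"` (default) or `"BIO"`.
#' @return character vector of tags, one per token.
#' @export
entities_to_tags <- function(doc, scheme = c("BIOES", "BIO")) {
  scheme <- scheme_match(scheme)
  n <- nrow(doc$tokens)
  tags <- rep("O", n)
  en <- doc$entities
  if (!nrow(en)) return(tags)
  en <- en[order(en$start), , drop = FALSE]
  if (any(en$start[-1] < en$end[-nrow(en)])) {
    stopf("document %s: overlapping entities are not supported", doc$doc_id)
  }
  for (i in seq_len(nrow(en))) {
    r <- entity_token_range(doc$tokens, en$start[i], en$end[i], en$label[i])
    lab <- en$label[i]
    span <- r[1]:r[2]
    if (scheme == "BIO") {
      tags[span] <- paste0("I-", lab)
      tags[r[1]] <- paste0("B-", lab)
    } else if (length(span) == 1L) {
      tags[span] <- paste0("S-", lab)
    } else {
      tags[span] <- paste0("I-", lab)
      tags[r[1]] <- paste0("B-", lab)
      tags[r[2]] <- paste0("E-", lab)
    }
  }
  tags
}

# Split a tag into prefix and type; "O" -> c("O", "").
tag_parts <- function(tags) {
  pre <- sub("-.*$", "", tags)
  typ <- ifelse(pre == tags, "", sub("^[A-Z]+-", "", tags))
  cbind(pre, typ)
}

#' Decode a tag sequence into entity spans
#'
#' Total decoder: malformed sequences (a stray `I-X`/`E-X` with no open
#' `X` span) are repaired by treating the stray tag as `B-X`, the standard
#' CoNLL reading. Character offsets are recovered from the token table.
#'
#' @param tokens token table.
#' @param tags character vector of BIO/BIOES tags aligned with `tokens`.
#' @param text the document text, used to recover entity surfaces.
#' @return entity data.frame (`label`, `start`, `end`, `surface`).
#' @export
bio_to_entities <- function(tokens, tags, text) {
  n <- nrow(tokens)
  stopifnot(length(tags) == n)
  out <- list()
  open_lab <- NULL; open_i <- NA_integer_
  close_open <- function(upto) {
    if (!is.null(open_lab)) {
      out[[length(out) + 1L]] <<- list(label = open_lab,
                                       start = tokens$start[open_i],
                                       end = tokens$end[upto])
      open_lab <<- NULL
    }
  }
  for (i in seq_len(n)) {
    p <- tag_parts(tags[i])
    pre <- p[1, 1]; typ <- p[1, 2]
    if (pre == "O") {
      close_open(i - 1L)
    } else if (pre %in% c("B", "S")) {
      close_open(i - 1L)
      open_lab <- typ; open_i <- i
      if (pre == "S") close_open(i)
    } else { # I or E: continue if compatible, else repair as B
      if (is.null(open_lab) || open_lab != typ) {
        close_open(i - 1L)
        open_lab <- typ; open_i <- i
      }
      if (pre == "E") close_open(i)
    }
  }
  close_open(n)
  if (!length(out)) {
    return(data.frame(label = character(), start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE))
  }
  ents <- data.frame(label = vapply(out, `[[`, "", "label"),
                     start = vapply(out, `[[`, 0L, "start"),
                     end = vapply(out, `[[`, 0L, "end"),
                     stringsAsFactors = FALSE)
  ents$surface <- text_slice(text, ents$start, ents$end)
  ents
}

# Check a tag sequence against its scheme grammar; returns TRUE/FALSE.
tags_valid <- function(tags, scheme = c("BIOES", "BIO")) {
  scheme <- scheme_match(scheme)
  prev_pre <- "O"; prev_typ <- ""
  for (t in c(tags, "O")) {
    p <- tag_parts(t); pre <- p[1, 1]; typ <- p[1, 2]
    if (scheme == "BIO") {
      if (pre == "I" && !(prev_pre %in% c("B", "I") && prev_typ == typ)) return(FALSE)
      if (!pre %in% c("O", "B", "I")) return(FALSE)
    } else {
      open <- prev_pre %in% c("B", "I")
      if (pre %in% c("I", "E") && !(open && prev_typ == typ)) return(FALSE)
      if (pre %in% c("O", "B", "S") && open) return(FALSE)  # unterminated span
      if (!pre %in% c("O", "B", "I", "E", "S")) return(FALSE)
    }
    prev_pre <- pre; prev_typ <- typ
  }
  TRUE
}

# ---------------------------------------------------------------------------
# CoNLL token-per-line format
#
# Columns: token, doc_id, start, end, pos, gold_tag [, pred_tag], separated
# by tabs; "_" marks an absent POS tag; blank line = sentence break;
# "-DOCSTART-" lines are ignored on read.

#' Write documents as a CoNLL token-per-line file
#'
#' @param docs an `ner_document` or list of them.
#' @param path output path.
#' @param scheme tagging scheme for the gold column.
#' @param pred_tags optional list (parallel to `docs`) of predicted tag
#'   vectors, written as a seventh column.
#' @export
write_conll <- function(docs, path, scheme = c("BIOES", "BIO"), pred_tags = NULL) {
  scheme <- scheme_match(scheme)
  if (inherits(docs, "ner_document")) docs <- list(docs)
  out <- character()
  for (k in seq_along(docs)) {
    doc <- docs[[k]]
    tk <- doc$tokens
    if (!nrow(tk)) next
    tags <- entities_to_tags(doc, scheme)
    pos <- ifelse(is.na(tk$pos), "_", tk$pos)
    lines <- paste(tk$surface, doc$doc_id, tk$start, tk$end, pos, tags, sep = "\t")
    if (!is.null(pred_tags)) lines <- paste(lines, pred_tags[[k]], sep = "\t")
    sent <- split_sentences(tk)
    blocks <- split(lines, sent)
    out <- c(out, unlist(lapply(blocks, c, "")))
  }
  con <- file(path, open = "wb")
  writeLines(enc2utf8(out), con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Read a CoNLL token-per-line file
#'
#' Reassembles documents by the `doc_id` column; document text is rebuilt
#' from token offsets with spaces in the gaps (newlines are not
#' representable in this format). Tag sequences are decoded to entities
#' with the stray-I repair of [bio_to_entities()].
#'
#' @param path input path.
#' @return list of `ner_document`s, in order of first appearance; each
#'   carries a `pred_tags` attribute when a prediction column is present.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^-DOCSTART-", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 6 | nc > 7)) {
    stopf("line %d: expected 6 or 7 tab-separated columns, got %d",
          which(nc < 6 | nc > 7)[1], nc[nc < 6 | nc > 7][1])
  }
  has_pred <- nc[1] == 7L
  if (any(nc != nc[1])) stopf("ragged column counts at line %d", which(nc != nc[1])[1])
  tab <- data.frame(surface = vapply(parts, `[[`, "", 1),
                    doc_id = vapply(parts, `[[`, "", 2),
                    start = as.integer(vapply(parts, `[[`, "", 3)),
                    end = as.integer(vapply(parts, `[[`, "", 4)),
                    pos = vapply(parts, `[[`, "", 5),
                    tag = vapply(parts, `[[`, "", 6),
                    stringsAsFactors = FALSE)
  if (has_pred) tab$pred <- vapply(parts, `[[`, "", 7)
  tab$pos[tab$pos == "_"] <- NA_character_
  docs <- list()
  for (id in unique(tab$doc_id)) {
    sub <- tab[tab$doc_id == id, , drop = FALSE]
    # rebuild text: token surfaces at their offsets, spaces in the gaps
    chars <- rep(" ", max(sub$end))
    for (i in seq_len(nrow(sub))) {
      cs <- strsplit(sub$surface[i], "", fixed = TRUE)[[1]]
      chars[(sub$start[i] + 1L):sub$end[i]] <- cs
    }
    text <- paste(chars, collapse = "")
    tokens <- data.frame(surface = sub$surface, start = sub$start,
                         end = sub$end, pos = sub$pos, stringsAsFactors = FALSE)
    ents <- bio_to_entities(tokens, sub$tag, text)
    doc <- ner_document(id, text, entities = ents, tokens = tokens)
    if (has_pred) attr(doc, "pred_tags") <- sub$pred
    docs[[id]] <- doc
  }
  unname(docs)
}

#' Read a directory of BRAT documents
#'
#' @param dir directory containing paired `.txt`/`.ann` files.
#' @param ... passed to [read_brat()].
#' @return list of `ner_document`s sorted by file name.
#' @export
read_brat_dir <- function(dir, ...) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(p) read_brat(p, sub("\\.txt$", ".ann", p), ...))
}

#' Write a corpus as a directory of BRAT documents
#'
#' @param docs list of `ner_document`s.
#' @param dir output directory (created if needed).
#' @export
write_brat_dir <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in docs) {
    write_brat(doc, file.path(dir, paste0(doc$doc_id, ".txt")),
               file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}
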