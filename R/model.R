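# The sequence model: character BiLSTM -> character-enhanced token
# embedding, concatenated with the lexical feature channels (POS one-hot,
# gazetteer flag, affix flag), a token-level BiLSTM, an affine projection
# to tag scores, and a linear-chain CRF on top.
#
# All trainable parameters live in a flat named list of matrices/vectors;
# gradients mirror that structure. The LSTM cell runs in compiled code
# (src/lstm.cpp); composition and backpropagation through the two BiLSTM
# levels happen here.

#' Model configuration
#'
#' @param labels character vector of entity labels (without `O`).
#' @param d_char,d_char_lstm character embedding / character LSTM size.
#' @param d_token,d_token_lstm token embedding / token LSTM size (per
#'   direction).
#' @param dropout_rate dropout on the concatenated embedding and on the
#'   token BiLSTM output, in `[0, 1)`.
#' @param use_pos,use_gazetteer,use_affixes feature-channel switches; a
#'   disabled channel contributes zero width and its resource file is
#'   never read.
#' @param scheme tagging scheme, `"BIOES"` (default) or `"BIO"`.
#' @param mask_transitions forbid scheme-invalid transitions in the CRF
#'   (decoded output is then always decodable to entities).
#' @param lowercase_tokens lowercase surfaces for token-embedding lookup
#'   (the character channel still sees the original case).
#' @param seed seed for all parameter initialization and dropout.
#' @return list of class `ner_model_config`.
#' @export
model_config <- function(labels,
                         d_char = 25L, d_char_lstm = 25L,
                         d_token = 100L, d_token_lstm = 100L,
                         dropout_rate = 0.5,
                         use_pos = TRUE, use_gazetteer = TRUE,
                         use_affixes = TRUE,
                         scheme = c("BIOES", "BIO"),
                         mask_transitions = TRUE,
                         lowercase_tokens = TRUE,
                         seed = 1L) {
  scheme <- scheme_match(scheme)
  stopifnot(length(labels) >= 1, !"O" %in% labels,
            d_char > 0, d_char_lstm > 0, d_token > 0, d_token_lstm > 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(labels = labels, d_char = as.integer(d_char),
                 d_char_lstm = as.integer(d_char_lstm),
                 d_token = as.integer(d_token),
                 d_token_lstm = as.integer(d_token_lstm),
                 dropout_rate = dropout_rate,
                 use_pos = use_pos, use_gazetteer = use_gazetteer,
                 use_affixes = use_affixes, scheme = scheme,
                 mask_transitions = mask_transitions,
                 lowercase_tokens = lowercase_tokens,
                 seed = as.integer(seed)),
            class = "ner_model_config")
}

#' Width of the concatenated token representation
#'
#' `d_token + 2 d_char_lstm` plus the enabled feature channels: POS
#' one-hot (`pos_dim`), gazetteer flag (1), affix flag (1).
#'
#' @param config `ner_model_config`.
#' @param pos_dim dimension of the POS one-hot block (|vocab| + 1).
#' @return integer width.
#' @export
embedding_width <- function(config, pos_dim = 0L) {
  config$d_token + 2L * config$d_char_lstm +
    (if (config$use_pos) as.integer(pos_dim) else 0L) +
    (if (config$use_gazetteer) 1L else 0L) +
    (if (config$use_affixes) 1L else 0L)
}

glorot_mat <- function(nr, nc, fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

lstm_init <- function(d_in, dh) {
  b <- numeric(4 * dh)
  b[(dh + 1):(2 * dh)] <- 1  # forget-gate bias
  list(Wx = glorot_mat(4 * dh, d_in, d_in, dh),
       Wh = glorot_mat(4 * dh, dh, dh, dh),
       b = b)
}

#' Initialize a tagger model
#'
#' @param config `ner_model_config`.
#' @param token_vocab `ner_token_vocab` from [build_vocab()]; its
#'   embedding matrix seeds the (trainable) token-embedding table.
#' @param char_vocab `ner_char_vocab`.
#' @param pos_vocab `ner_pos_vocab` (required iff `config$use_pos`).
#' @param gazetteer,affixes feature resources (required iff the
#'   corresponding channel is enabled).
#' @return object of class `ner_model`.
#' @export
ner_model <- function(config, token_vocab, char_vocab, pos_vocab = NULL,
                      gazetteer = NULL, affixes = NULL) {
  if (config$use_pos && is.null(pos_vocab)) stopf("use_pos requires a pos_vocab")
  if (config$use_gazetteer && is.null(gazetteer)) stopf("use_gazetteer requires a gazetteer")
  if (config$use_affixes && is.null(affixes)) stopf("use_affixes requires an affix table")
  tagset <- scheme_tagset(config$labels, config$scheme)
  L <- length(tagset)
  pos_dim <- if (config$use_pos) pos_vocab$dim else 0L
  d_in_tok <- embedding_width(config, pos_dim)
  d_out <- 2L * config$d_token_lstm
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  r_char <- sqrt(3 / config$d_char)
  params <- list(
    Etok = token_vocab$matrix * 1,  # copy; trained in place
    Echar = matrix(stats::runif(config$d_char * length(char_vocab$chars),
                                -r_char, r_char),
                   nrow = config$d_char,
                   dimnames = list(NULL, char_vocab$chars)))
  cf <- lstm_init(config$d_char, config$d_char_lstm)
  cb <- lstm_init(config$d_char, config$d_char_lstm)
  tf <- lstm_init(d_in_tok, config$d_token_lstm)
  tb <- lstm_init(d_in_tok, config$d_token_lstm)
  params$cf_Wx <- cf$Wx; params$cf_Wh <- cf$Wh; params$cf_b <- cf$b
  params$cb_Wx <- cb$Wx; params$cb_Wh <- cb$Wh; params$cb_b <- cb$b
  params$tf_Wx <- tf$Wx; params$tf_Wh <- tf$Wh; params$tf_b <- tf$b
  params$tb_Wx <- tb$Wx; params$tb_Wh <- tb$Wh; params$tb_b <- tb$b
  params$proj_W <- glorot_mat(L, d_out, d_out, L)
  params$proj_b <- numeric(L)
  params$trans <- matrix(0, L, L, dimnames = list(tagset, tagset))
  params$start <- stats::setNames(numeric(L), tagset)
  params$stop <- stats::setNames(numeric(L), tagset)
  mask <- if (config$mask_transitions) {
    scheme_transition_mask(tagset, config$scheme)
  } else {
    list(trans = matrix(0, L, L, dimnames = list(tagset, tagset)),
         start = stats::setNames(numeric(L), tagset),
         stop = stats::setNames(numeric(L), tagset))
  }
  structure(list(config = config, params = params, tagset = tagset,
                 mask = mask, token_vocab = token_vocab,
                 char_vocab = char_vocab, pos_vocab = pos_vocab,
                 gazetteer = gazetteer, affixes = affixes,
                 resource_fingerprints = list(
                   gazetteer = resource_fingerprint(gazetteer$path %||% NULL),
                   affixes = resource_fingerprint(attr(affixes, "path"))),
                 version = "1"),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf(paste0("<ner_model: %d labels (%s scheme), token dim %d, ",
                     "char LSTM %d, channels pos=%s gaz=%s affix=%s>\n"),
              length(x$config$labels), x$config$scheme, x$config$d_token,
              x$config$d_char_lstm, x$config$use_pos, x$config$use_gazetteer,
              x$config$use_affixes))
  invisible(x)
}

# Effective CRF parameters (mask applied additively).
model_crf <- function(model) {
  list(trans = model$params$trans + model$mask$trans,
       start = model$params$start + model$mask$start,
       stop = model$params$stop + model$mask$stop)
}

# ---------------------------------------------------------------------------
# Sentence preparation: index lookups and feature matrices are computed
# once per document and reused across epochs.

# Encode one document into per-sentence index structures.
prepare_document <- function(model, doc, with_gold = TRUE) {
  tk <- doc$tokens
  if (!nrow(tk)) return(list())
  cfg <- model$config
  feats <- feature_matrix(tk,
    pos_vocab = if (cfg$use_pos) model$pos_vocab,
    gazetteer = if (cfg$use_gazetteer) model$gazetteer,
    affixes = if (cfg$use_affixes) model$affixes)
  tok_idx <- vocab_index(model$token_vocab, tk$surface)
  char_idx <- lapply(tk$surface, char_index, cvocab = model$char_vocab)
  gold <- NULL
  if (with_gold) {
    tags <- entities_to_tags(doc, cfg$scheme)
    gold <- match(tags, model$tagset)
    if (anyNA(gold)) {
      stopf("document %s carries a label outside the model's label set (%s)",
            doc$doc_id, paste(unique(tags[is.na(gold)]), collapse = ", "))
    }
  }
  sent <- split_sentences(tk)
  lapply(split(seq_len(nrow(tk)), sent), function(ix) {
    list(doc_id = doc$doc_id, token_rows = ix,
         tok_idx = tok_idx[ix],
         char_idx = char_idx[ix],
         feats = feats[ix, , drop = FALSE],
         gold = if (with_gold) gold[ix])
  })
}

prepare_corpus <- function(model, docs, with_gold = TRUE) {
  unlist(lapply(docs, prepare_document, model = model, with_gold = with_gold),
         recursive = FALSE)
}

# ---------------------------------------------------------------------------
# Forward pass

# Forward over one prepared sentence. With train = TRUE, inverted-dropout
# masks are sampled from the current RNG stream and cached for backward.
forward_sentence <- function(model, sent, train = FALSE) {
  p <- model$params; cfg <- model$config
  n <- length(sent$tok_idx)
  if (n < 1) stopf("cannot encode an empty token sequence")
  dcl <- cfg$d_char_lstm
  char_caches <- vector("list", n)
  char_out <- matrix(0, 2 * dcl, n)
  for (k in seq_len(n)) {
    Xc <- p$Echar[, sent$char_idx[[k]], drop = FALSE]
    fw <- lstm_forward_cpp(Xc, p$cf_Wx, p$cf_Wh, p$cf_b)
    bw <- lstm_forward_cpp(Xc[, ncol(Xc):1, drop = FALSE], p$cb_Wx, p$cb_Wh, p$cb_b)
    l <- ncol(Xc)
    char_out[, k] <- c(fw$H[, l], bw$H[, l])
    char_caches[[k]] <- list(Xc = Xc, fw = fw, bw = bw)
  }
  E <- rbind(p$Etok[, sent$tok_idx, drop = FALSE], char_out, t(sent$feats))
  drop1 <- NULL
  if (train && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    drop1 <- matrix(stats::rbinom(length(E), 1, keep) / keep, nrow(E), ncol(E))
    E <- E * drop1
  }
  tf <- lstm_forward_cpp(E, p$tf_Wx, p$tf_Wh, p$tf_b)
  tb <- lstm_forward_cpp(E[, n:1, drop = FALSE], p$tb_Wx, p$tb_Wh, p$tb_b)
  Hcat <- rbind(tf$H, tb$H[, n:1, drop = FALSE])
  drop2 <- NULL
  if (train && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    drop2 <- matrix(stats::rbinom(length(Hcat), 1, keep) / keep,
                    nrow(Hcat), ncol(Hcat))
    Hcat <- Hcat * drop2
  }
  S <- p$proj_W %*% Hcat + p$proj_b  # L x n
  list(emissions = t(S), E = E, Hcat = Hcat, tf = tf, tb = tb,
       char_caches = char_caches, drop1 = drop1, drop2 = drop2)
}

#' Emission scores for a token sequence
#'
#' Runs the full encoder (character BiLSTM, token embedding, feature
#' channels, token BiLSTM, projection) without dropout and returns the
#' per-token tag scores.
#'
#' @param model `ner_model`.
#' @param tokens token table (at least one row).
#' @return `n x |tagset|` matrix of finite emission scores, columns named
#'   by tag.
#' @export
encode_tokens <- function(model, tokens) {
  if (!is.data.frame(tokens) || nrow(tokens) < 1) {
    stopf("encode_tokens needs at least one token")
  }
  sents <- prepare_document_tokens(model, tokens)
  out <- do.call(rbind, lapply(sents, function(s)
    forward_sentence(model, s, train = FALSE)$emissions))
  colnames(out) <- model$tagset
  out
}

# prepare_document without gold tags, directly from a token table.
prepare_document_tokens <- function(model, tokens) {
  doc <- structure(list(doc_id = "adhoc", text = "", tokens = tokens,
                        entities = NULL), class = "ner_document")
  prepare_document(model, doc, with_gold = FALSE)
}

# ---------------------------------------------------------------------------
# Backward pass: one sentence, returns loss and a gradient list mirroring
# the parameter list (embedding gradients as dense matrices).

backward_sentence <- function(model, sent, fwd) {
  p <- model$params; cfg <- model$config
  n <- length(sent$tok_idx)
  cl <- crf_loss(fwd$emissions, model_crf(model), sent$gold, grad = TRUE)
  g <- list()
  dS <- t(cl$d_emissions)                   # L x n
  g$proj_W <- dS %*% t(fwd$Hcat)
  g$proj_b <- rowSums(dS)
  dHcat <- t(p$proj_W) %*% dS               # 2dh x n
  if (!is.null(fwd$drop2)) dHcat <- dHcat * fwd$drop2
  dh <- cfg$d_token_lstm
  btf <- lstm_backward_cpp(fwd$E, p$tf_Wx, p$tf_Wh, fwd$tf,
                           dHcat[seq_len(dh), , drop = FALSE])
  Erev <- fwd$E[, n:1, drop = FALSE]
  btb <- lstm_backward_cpp(Erev, p$tb_Wx, p$tb_Wh, fwd$tb,
                           dHcat[dh + seq_len(dh), n:1, drop = FALSE])
  g$tf_Wx <- btf$dWx; g$tf_Wh <- btf$dWh; g$tf_b <- as.numeric(btf$db)
  g$tb_Wx <- btb$dWx; g$tb_Wh <- btb$dWh; g$tb_b <- as.numeric(btb$db)
  dE <- btf$dX + btb$dX[, n:1, drop = FALSE]
  if (!is.null(fwd$drop1)) dE <- dE * fwd$drop1
  dcl <- cfg$d_char_lstm
  g$Etok <- matrix(0, nrow(p$Etok), ncol(p$Etok))
  dtok <- dE[seq_len(cfg$d_token), , drop = FALSE]
  for (k in seq_len(n)) {
    j <- sent$tok_idx[k]
    g$Etok[, j] <- g$Etok[, j] + dtok[, k]
  }
  g$Echar <- matrix(0, nrow(p$Echar), ncol(p$Echar))
  zf <- matrix(0, 4 * dcl, 1)
  g$cf_Wx <- matrix(0, nrow(p$cf_Wx), ncol(p$cf_Wx))
  g$cf_Wh <- matrix(0, nrow(p$cf_Wh), ncol(p$cf_Wh))
  g$cf_b <- numeric(4 * dcl)
  g$cb_Wx <- g$cf_Wx; g$cb_Wh <- g$cf_Wh; g$cb_b <- g$cf_b
  dchar <- dE[cfg$d_token + seq_len(2 * dcl), , drop = FALSE]
  for (k in seq_len(n)) {
    cc <- fwd$char_caches[[k]]
    l <- ncol(cc$Xc)
    dHf <- matrix(0, dcl, l); dHf[, l] <- dchar[seq_len(dcl), k]
    dHb <- matrix(0, dcl, l); dHb[, l] <- dchar[dcl + seq_len(dcl), k]
    bf <- lstm_backward_cpp(cc$Xc, p$cf_Wx, p$cf_Wh, cc$fw, dHf)
    Xrev <- cc$Xc[, l:1, drop = FALSE]
    bb <- lstm_backward_cpp(Xrev, p$cb_Wx, p$cb_Wh, cc$bw, dHb)
    g$cf_Wx <- g$cf_Wx + bf$dWx; g$cf_Wh <- g$cf_Wh + bf$dWh
    g$cf_b <- g$cf_b + as.numeric(bf$db)
    g$cb_Wx <- g$cb_Wx + bb$dWx; g$cb_Wh <- g$cb_Wh + bb$dWh
    g$cb_b <- g$cb_b + as.numeric(bb$db)
    dXc <- bf$dX + bb$dX[, l:1, drop = FALSE]
    idx <- sent$char_idx[[k]]
    for (q in seq_len(l)) {
      g$Echar[, idx[q]] <- g$Echar[, idx[q]] + dXc[, q]
    }
  }
  g$trans <- cl$d_trans
  g$start <- cl$d_start
  g$stop <- cl$d_stop
  list(loss = cl$loss, grads = g)
}

# Sum gradient lists in place.
accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

scale_grads <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

grad_global_norm <- function(g) {
  sqrt(sum(vapply(g, function(m) sum(m * m), numeric(1))))
}

# ---------------------------------------------------------------------------
# Optimizers: plain SGD with global-norm gradient clipping, or Adam.

make_optimizer <- function(kind = c("sgd", "adam"), lr, clip = 5) {
  kind <- match.arg(kind)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  step <- function(params, grads) {
    gn <- grad_global_norm(grads)
    if (is.finite(clip) && gn > clip) grads <- scale_grads(grads, clip / gn)
    state$t <- state$t + 1L
    if (kind == "sgd") {
      for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    } else {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      if (is.null(state$m)) {
        state$m <- lapply(grads, function(x) x * 0)
        state$v <- lapply(grads, function(x) x * 0)
      }
      lr_t <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
      for (nm in names(grads)) {
        state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
        state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
        params[[nm]] <- params[[nm]] -
          lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + eps)
      }
    }
    params
  }
  list(kind = kind, step = step, state = state)
}

# ---------------------------------------------------------------------------
# Prediction

#' Predict entities for documents
#'
#' Viterbi-decodes each sentence under the trained CRF (with the scheme
#' transition mask, so the output is always a valid tag grammar) and
#' converts tags back to character-offset entity spans.
#'
#' @param model trained `ner_model`.
#' @param docs an `ner_document` or list of them.
#' @return list of documents whose `entities` are the predictions; each
#'   carries the predicted tags in attribute `pred_tags`.
#' @export
predict_documents <- function(model, docs) {
  if (inherits(docs, "ner_document")) docs <- list(docs)
  crf <- model_crf(model)
  lapply(docs, function(doc) {
    n <- nrow(doc$tokens)
    tags <- character(n)
    if (n) {
      sents <- prepare_document(model, doc, with_gold = FALSE)
      for (s in sents) {
        fwd <- forward_sentence(model, s, train = FALSE)
        v <- viterbi_decode(fwd$emissions, crf)
        tags[s$token_rows] <- model$tagset[v$path]
      }
    }
    ents <- bio_to_entities(doc$tokens, tags, doc$text)
    out <- ner_document(doc$doc_id, doc$text, entities = ents,
                        tokens = doc$tokens)
    attr(out, "pred_tags") <- tags
    out
  })
}

# ---------------------------------------------------------------------------
# Persistence: an RDS parameter file plus a JSON sidecar describing the
# configuration, label set and resource fingerprints (MD5).

#' Save a model directory
#' @param model `ner_model`.
#' @param dir output directory (created).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "parameters.rds"))
  sidecar <- list(
    format_version = model$version,
    config = unclass(model$config),
    tagset = model$tagset,
    resources = list(
      gazetteer_path = model$gazetteer$path %||% NA,
      affixes_path = attr(model$affixes, "path") %||% NA,
      fingerprints = model$resource_fingerprints))
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Load a model directory
#'
#' Verifies the format version and, for every enabled feature channel,
#' that its resource file still exists (error naming the file if not) and
#' still has the fingerprint recorded at save time (warning on mismatch).
#'
#' @param dir directory written by [save_model()].
#' @param check_resources verify resource files (default `TRUE`).
#' @return `ner_model`.
#' @export
load_model <- function(dir, check_resources = TRUE) {
  side_path <- file.path(dir, "model.json")
  par_path <- file.path(dir, "parameters.rds")
  if (!file.exists(side_path) || !file.exists(par_path)) {
    stopf("%s is not a model directory (missing model.json/parameters.rds)", dir)
  }
  side <- tryCatch(jsonlite::read_json(side_path),
                   error = function(e) stopf("corrupted model sidecar: %s",
                                             conditionMessage(e)))
  if (!identical(side$format_version, "1")) {
    stopf("model format version %s is not supported by this build",
          side$format_version %||% "<missing>")
  }
  model <- tryCatch(readRDS(par_path),
                    error = function(e) stopf("corrupted parameter file: %s",
                                              conditionMessage(e)))
  if (!inherits(model, "ner_model")) stopf("corrupted parameter file")
  if (check_resources) {
    # resources constructed in code (no source path recorded) are stored
    # whole inside the model and need no file check
    check_one <- function(path, recorded_fp, what) {
      if (is.null(path) || is.na(path)) return(invisible())
      if (!file.exists(path)) {
        stopf("model uses the %s channel but its file is missing: %s",
              what, path)
      }
      if (!identical(resource_fingerprint(path), recorded_fp)) {
        warnf("%s file %s changed since the model was saved", what, path)
      }
    }
    if (model$config$use_gazetteer) {
      check_one(model$gazetteer$path, model$resource_fingerprints$gazetteer,
                "gazetteer")
    }
    if (model$config$use_affixes) {
      check_one(attr(model$affixes, "path"),
                model$resource_fingerprints$affixes, "affix")
    }
  }
  model
}
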