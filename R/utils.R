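# Internal helpers shared across modules.

# Slice of `text` at 0-based, end-exclusive character offsets.
text_slice <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

#' Normalize a surface string for dictionary lookup
#'
#' Lowercases and applies Unicode NFC composition. Spanish accents are
#' lexically meaningful and preserved by default; `strip_accents = TRUE`
#' additionally transliterates to the unaccented Latin form, for noisy
#' corpora where accents are unreliable.
#'
#' @param x character vector.
#' @param strip_accents drop diacritics after lowercasing.
#' @return normalized character vector.
#' @export
normalize_surface <- function(x, strip_accents = FALSE) {
  x <- stringi::stri_trans_nfc(x)
  x <- stringi::stri_trans_tolower(x)
  if (strip_accents) {
    x <- stringi::stri_trans_general(x, "Latin-ASCII")
  }
  x
}

# log(sum(exp(x))) along a vector, guarding -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  ok <- is.finite(mx)
  out <- mx
  if (any(ok)) {
    out[ok] <- mx[ok] + log(rowSums(exp(m[ok, , drop = FALSE] - mx[ok])))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MD5 fingerprint of a resource file, NA if the path is missing.
resource_fingerprint <- function(path) {
  if (is.null(path) || is.na(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
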