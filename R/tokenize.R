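#' Amino-acid vocabulary
#'
#' Token ids are frozen: 0 is padding, 1 is the shared id for any special
#' or unknown residue, and 2..21 are the 20 canonical amino acids in
#' alphabetical one-letter order (A, C, D, ..., Y).
#'
#' @return Named integer vector mapping one-letter residue codes to ids.
#' @export
aa_vocab <- function() {
  aas <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  stats::setNames(seq_along(aas) + 1L, aas)
}

PAD_ID <- 0L
UNK_ID <- 1L

#' Vocabulary size (pad + unknown + 20 residues)
#' @export
vocab_size <- function() 22L

#' Tokenize a peptide sequence
#'
#' Encodes an amino-acid string as integer token ids. Each of the 20
#' canonical residues maps to its own id; any other character (selenocysteine,
#' ambiguity codes, `*`, ...) maps to one shared "unknown" id. Sequences
#' longer than `max_len` are truncated with a warning; the padding id (0)
#' is distinct from all residue ids and only ever occurs after `length`.
#'
#' @param sequence Non-empty amino-acid string (case-insensitive).
#' @param max_len Maximum number of residues retained (default 150, the
#'   length bound the classifier is applied to).
#' @param pad If `TRUE` (default), `tokens` is padded with 0 to `max_len`.
#' @return A `token_seq`: list with `tokens` (integer vector) and
#'   `length` (residue count before padding).
#' @export
#' @examples
#' tokenize("MKTACSTW")
tokenize <- function(sequence, max_len = 150L, pad = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) > max_len) {
    warning(
      "sequence of ", length(chars), " residues truncated to max_len = ",
      max_len,
      call. = FALSE
    )
    chars <- chars[seq_len(max_len)]
  }
  vocab <- aa_vocab()
  ids <- unname(vocab[chars])
  ids[is.na(ids)] <- UNK_ID
  n <- length(ids)
  if (pad && n < max_len) {
    ids <- c(ids, rep(PAD_ID, max_len - n))
  }
  structure(
    list(tokens = as.integer(ids), length = n),
    class = "token_seq"
  )
}

#' @export
print.token_seq <- function(x, ...) {
  cat(
    "<token_seq> length", x$length, "of", length(x$tokens),
    "slots\n"
  )
  invisible(x)
}

# Build a B x T id matrix + mask from a character vector of sequences.
# Row b is sequence b; entries are 0-based token ids, 0 = pad.
token_batch <- function(sequences, max_len) {
  toks <- lapply(sequences, tokenize, max_len = max_len, pad = TRUE)
  ids <- do.call(rbind, lapply(toks, `[[`, "tokens"))
  lens <- vapply(toks, `[[`, integer(1), "length")
  t_used <- max(lens)
  ids <- ids[, seq_len(t_used), drop = FALSE]
  mask <- outer(lens, seq_len(t_used), FUN = ">=") * 1
  list(ids = ids, mask = mask, lengths = lens)
}
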