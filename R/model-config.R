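#' Classifier architecture configuration
#'
#' Hyperparameters of the precursor classifier: a Transformer encoder
#' (token + learned positional embeddings, multi-head self-attention),
#' two stacked bidirectional LSTM layers, and a feed-forward
#' classification head over the concatenated max, mean and last outputs
#' of the final Bi-LSTM layer. Defaults are the published architecture:
#' 4 encoder layers with 4 attention heads, 128-dimensional embeddings,
#' 256-dimensional encoder feed-forward networks, 2 Bi-LSTM layers with
#' hidden size 64, a 192-unit head, and dropout 0.4 applied throughout.
#'
#' @param n_encoder_layers Number of Transformer encoder layers.
#' @param n_heads Attention heads per layer; must divide `d_embed`.
#' @param d_embed Embedding / model dimension.
#' @param d_ff_encoder Hidden size of the encoder feed-forward blocks.
#' @param n_lstm_layers Number of stacked Bi-LSTM layers.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param d_ff_head Hidden size of the classification head.
#' @param dropout Dropout probability in `[0, 1)`, applied to attention
#'   weights, encoder sublayer outputs, between LSTM layers, and between
#'   the head's dense layers.
#' @param n_classes Number of output classes (nine RiPP classes plus
#'   non-RiPP).
#' @param max_len Maximum sequence length in residues.
#' @param variant Architecture variant: `"full"` (default), or one of
#'   the ablations `"lstm_only"` (no Transformer encoder),
#'   `"transformer_cls"` (no Bi-LSTM; a prepended CLS token's encoding
#'   feeds the head), `"transformer_max"` (no Bi-LSTM; masked max pooling
#'   of the encoder outputs feeds the head).
#' @return A `ripp_model_config` list.
#' @export
ripp_model_config <- function(n_encoder_layers = 4L,
                              n_heads = 4L,
                              d_embed = 128L,
                              d_ff_encoder = 256L,
                              n_lstm_layers = 2L,
                              lstm_hidden = 64L,
                              d_ff_head = 192L,
                              dropout = 0.4,
                              n_classes = 10L,
                              max_len = 150L,
                              variant = c(
                                "full", "lstm_only",
                                "transformer_cls", "transformer_max"
                              )) {
  variant <- match.arg(variant)
  stopifnot(
    d_embed %% n_heads == 0L,
    dropout >= 0, dropout < 1,
    n_classes >= 2L,
    max_len >= 1L
  )
  structure(
    list(
      n_encoder_layers = as.integer(n_encoder_layers),
      n_heads = as.integer(n_heads),
      d_embed = as.integer(d_embed),
      d_ff_encoder = as.integer(d_ff_encoder),
      n_lstm_layers = as.integer(n_lstm_layers),
      lstm_hidden = as.integer(lstm_hidden),
      d_ff_head = as.integer(d_ff_head),
      dropout = dropout,
      n_classes = as.integer(n_classes),
      max_len = as.integer(max_len),
      variant = variant,
      vocab_size = vocab_size()
    ),
    class = "ripp_model_config"
  )
}

#' @export
print.ripp_model_config <- function(x, ...) {
  cat("<ripp_model_config> variant:", x$variant, "\n")
  cat(
    "  encoder:", x$n_encoder_layers, "layers x", x$n_heads,
    "heads, d =", x$d_embed, ", ff =", x$d_ff_encoder, "\n"
  )
  cat(
    "  bi-lstm:", x$n_lstm_layers, "layers, hidden =", x$lstm_hidden,
    "per direction\n"
  )
  cat(
    "  head:", x$d_ff_head, "->", x$n_classes, "classes; dropout",
    x$dropout, "; max_len", x$max_len, "\n"
  )
  invisible(x)
}
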