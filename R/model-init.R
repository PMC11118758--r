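#' Instantiate a precursor classifier
#'
#' Creates a `ripp_model` with freshly initialized weights. Weight
#' matrices use Xavier-uniform initialization, embeddings use small
#' uniform noise, LSTM forget-gate biases start at 1, and layer-norm
#' gains/offsets start at 1/0. Initialization is fully determined by
#' `seed`, so re-instantiation with the same config and seed is
#' bit-identical.
#'
#' @param config A [ripp_model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `ripp_model` (list with `config` and `params`).
#' @export
ripp_model <- function(config = ripp_model_config(), seed = 1L) {
  stopifnot(inherits(config, "ripp_model_config"))
  params <- withr::with_seed(seed, init_params(config))
  structure(
    list(config = config, params = params),
    class = "ripp_model"
  )
}

#' @export
print.ripp_model <- function(x, ...) {
  cat(
    "<ripp_model>", n_params(x), "parameters, variant",
    x$config$variant, "\n"
  )
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `ripp_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  length(unlist(model$params, use.names = FALSE))
}

xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_params <- function(cfg) {
  d <- cfg$d_embed
  h <- cfg$lstm_hidden
  has_cls <- cfg$variant == "transformer_cls"
  has_encoder <- cfg$variant != "lstm_only"
  has_lstm <- cfg$variant %in% c("full", "lstm_only")

  p <- list()
  n_tok <- cfg$vocab_size + as.integer(has_cls) # extra row = CLS token
  p$tok_emb <- matrix(stats::runif(n_tok * d, -0.05, 0.05), n_tok, d)

  if (has_encoder) {
    n_pos <- cfg$max_len + as.integer(has_cls)
    p$pos_emb <- matrix(stats::runif(n_pos * d, -0.05, 0.05), n_pos, d)
    p$enc <- lapply(seq_len(cfg$n_encoder_layers), function(l) {
      list(
        Wq = xavier(d, d), bq = numeric(d),
        Wk = xavier(d, d), bk = numeric(d),
        Wv = xavier(d, d), bv = numeric(d),
        Wo = xavier(d, d), bo = numeric(d),
        ln1_g = rep(1, d), ln1_b = numeric(d),
        W1 = xavier(d, cfg$d_ff_encoder), b1 = numeric(cfg$d_ff_encoder),
        W2 = xavier(cfg$d_ff_encoder, d), b2 = numeric(d),
        ln2_g = rep(1, d), ln2_b = numeric(d)
      )
    })
  }

  if (has_lstm) {
    p$lstm <- lapply(seq_len(cfg$n_lstm_layers), function(l) {
      d_in <- if (l == 1L) d else 2L * h
      lapply(
        stats::setNames(nm = c("fwd", "bwd")),
        function(dir) {
          b <- numeric(4L * h)
          b[(h + 1L):(2L * h)] <- 1 # forget-gate bias
          list(Wx = xavier(d_in, 4L * h), Wh = xavier(h, 4L * h), b = b)
        }
      )
    })
  }

  pool_dim <- if (has_lstm) 6L * h else d
  p$head <- list(
    W1 = xavier(pool_dim, cfg$d_ff_head), b1 = numeric(cfg$d_ff_head),
    W2 = xavier(cfg$d_ff_head, cfg$n_classes), b2 = numeric(cfg$n_classes)
  )
  p
}
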