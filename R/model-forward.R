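# Forward pass of the precursor classifier.
#
# Batched implementation over a flattened (batch, time) layout: hidden
# states live in (B*T) x d matrices where row b + (t-1)*B holds sequence
# b at position t, so time-step slices are contiguous blocks (fast for
# the LSTM) and per-sequence slices are strided (fine for attention).
# Padded positions are masked out of attention keys, LSTM state updates
# and pooling, which makes outputs invariant to batch composition.

sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

add_bias <- function(X, b) sweep(X, 2L, b, "+")

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- Xc * istd
  list(y = add_bias(sweep(xhat, 2L, g, "*"), b), xhat = xhat, istd = istd)
}

# inverted dropout; returns pre-scaled multiplicative mask
dropout_mask <- function(nr, nc, p) {
  if (p <= 0) {
    return(NULL)
  }
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_mask <- function(X, m) if (is.null(m)) X else X * m

# Forward pass. `ids` is a B x T matrix of 0-based token ids (0 = pad),
# `mask` a B x T 0/1 matrix. Returns probs, logits and (optionally) the
# caches needed for backprop.
ripp_forward <- function(model, ids, mask, training = FALSE,
                         keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  variant <- cfg$variant
  if (max(ids) >= cfg$vocab_size) {
    stop("token id out of vocabulary range", call. = FALSE)
  }

  if (variant == "transformer_cls") {
    # prepend a CLS token (the extra embedding row) at position 1
    ids <- cbind(cfg$vocab_size, ids)
    mask <- cbind(1, mask)
  }
  B <- nrow(ids)
  T <- ncol(ids)
  d <- cfg$d_embed
  drop_p <- if (training) cfg$dropout else 0

  v_flat <- as.vector(ids) # col-major == row order b + (t-1)*B
  X <- p$tok_emb[v_flat + 1L, , drop = FALSE]
  if (variant != "lstm_only") {
    X <- X + p$pos_emb[rep(seq_len(T), each = B), , drop = FALSE]
  }

  m_flat <- as.vector(mask)
  lengths <- rowSums(mask)
  seq_rows <- lapply(seq_len(B), function(b) b + (seq_len(T) - 1L) * B)
  real_cols <- lapply(seq_len(B), function(b) which(mask[b, ] == 1))

  cache <- list(
    ids = ids, mask = mask, v_flat = v_flat, m_flat = m_flat,
    lengths = lengths, seq_rows = seq_rows, B = B, T = T,
    X_emb = X, enc = list(), lstm = list()
  )

  # ---- transformer encoder ----
  if (variant != "lstm_only") {
    dh <- d %/% cfg$n_heads
    head_cols <- lapply(seq_len(cfg$n_heads), function(h) {
      ((h - 1L) * dh + 1L):(h * dh)
    })
    for (l in seq_len(cfg$n_encoder_layers)) {
      lp <- p$enc[[l]]
      lcache <- list(X_in = X)
      Q <- add_bias(X %*% lp$Wq, lp$bq)
      K <- add_bias(X %*% lp$Wk, lp$bk)
      V <- add_bias(X %*% lp$Wv, lp$bv)
      O <- matrix(0, B * T, d)
      A_list <- vector("list", B)
      for (b in seq_len(B)) {
        rows <- seq_rows[[b]]
        pad <- mask[b, ] == 0
        Ab <- vector("list", cfg$n_heads)
        for (hh in seq_len(cfg$n_heads)) {
          cols <- head_cols[[hh]]
          S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) / sqrt(dh)
          if (any(pad)) S[, pad] <- -Inf
          A <- row_softmax(S)
          dm <- dropout_mask(T, T, drop_p)
          A_used <- apply_mask(A, dm)
          O[rows, cols] <- A_used %*% V[rows, cols, drop = FALSE]
          Ab[[hh]] <- list(A = A, dm = dm)
        }
        A_list[[b]] <- Ab
      }
      attn_out <- add_bias(O %*% lp$Wo, lp$bo)
      dm_attn <- dropout_mask(B * T, d, drop_p)
      attn_out_d <- apply_mask(attn_out, dm_attn)
      ln1 <- layernorm_fwd(X + attn_out_d, lp$ln1_g, lp$ln1_b)
      X1 <- ln1$y
      Zff <- add_bias(X1 %*% lp$W1, lp$b1)
      Hff <- pmax(Zff, 0)
      ff_out <- add_bias(Hff %*% lp$W2, lp$b2)
      dm_ff <- dropout_mask(B * T, d, drop_p)
      ff_out_d <- apply_mask(ff_out, dm_ff)
      ln2 <- layernorm_fwd(X1 + ff_out_d, lp$ln2_g, lp$ln2_b)
      X <- ln2$y
      lcache$Q <- Q
      lcache$K <- K
      lcache$V <- V
      lcache$O <- O
      lcache$A_list <- A_list
      lcache$dm_attn <- dm_attn
      lcache$ln1 <- ln1
      lcache$X1 <- X1
      lcache$Zff <- Zff
      lcache$Hff <- Hff
      lcache$dm_ff <- dm_ff
      lcache$ln2 <- ln2
      cache$enc[[l]] <- lcache
      cache$head_cols <- head_cols
      cache$dh <- dh
    }
  }

  # ---- bi-lstm stack ----
  if (variant %in% c("full", "lstm_only")) {
    h <- cfg$lstm_hidden
    H_in <- X
    for (l in seq_len(cfg$n_lstm_layers)) {
      lcache <- list(H_in = H_in)
      if (l > 1L) {
        dm <- dropout_mask(nrow(H_in), ncol(H_in), drop_p)
        H_in <- apply_mask(H_in, dm)
        lcache$dm_in <- dm
      }
      H_out <- matrix(0, B * T, 2L * h)
      for (dir in c("fwd", "bwd")) {
        dp <- p$lstm[[l]][[dir]]
        t_order <- if (dir == "fwd") seq_len(T) else rev(seq_len(T))
        out_cols <- if (dir == "fwd") seq_len(h) else (h + 1L):(2L * h)
        h_prev <- matrix(0, B, h)
        c_prev <- matrix(0, B, h)
        steps <- vector("list", T)
        for (k in seq_len(T)) {
          t <- t_order[k]
          rows_t <- ((t - 1L) * B + 1L):(t * B)
          xt <- H_in[rows_t, , drop = FALSE]
          G <- add_bias(xt %*% dp$Wx + h_prev %*% dp$Wh, dp$b)
          i_g <- sigmoid(G[, seq_len(h), drop = FALSE])
          f_g <- sigmoid(G[, (h + 1L):(2L * h), drop = FALSE])
          g_g <- tanh(G[, (2L * h + 1L):(3L * h), drop = FALSE])
          o_g <- sigmoid(G[, (3L * h + 1L):(4L * h), drop = FALSE])
          c_new <- f_g * c_prev + i_g * g_g
          tanh_c <- tanh(c_new)
          h_new <- o_g * tanh_c
          m <- mask[, t]
          c_t <- m * c_new + (1 - m) * c_prev
          h_t <- m * h_new + (1 - m) * h_prev
          steps[[k]] <- list(
            t = t, i = i_g, f = f_g, g = g_g, o = o_g,
            tanh_c = tanh_c, c_prev = c_prev, h_prev = h_prev
          )
          H_out[rows_t, out_cols] <- h_t
          h_prev <- h_t
          c_prev <- c_t
        }
        lcache[[dir]] <- steps
      }
      cache$lstm[[l]] <- lcache
      H_in <- H_out
    }
    X <- H_in # (B*T) x 2h outputs of the last bi-lstm layer
  }

  # ---- pooling ----
  pool_cache <- list()
  if (variant == "transformer_cls") {
    P <- X[seq_len(B), , drop = FALSE] # CLS is position 1
  } else if (variant == "transformer_max") {
    mp <- masked_max_pool(X, seq_rows, real_cols)
    P <- mp$P
    pool_cache$amax <- mp$amax
  } else {
    mp <- masked_max_pool(X, seq_rows, real_cols)
    group <- rep_len(seq_len(B), B * T)
    mean_pool <- rowsum(X * m_flat, group) / lengths
    last_rows <- seq_len(B) + (lengths - 1L) * B
    P <- cbind(mp$P, mean_pool, X[last_rows, , drop = FALSE])
    pool_cache$amax <- mp$amax
    pool_cache$group <- group
    pool_cache$last_rows <- last_rows
  }
  cache$H_top <- X
  cache$pool <- pool_cache
  cache$P <- P

  # ---- feed-forward head ----
  Z1 <- add_bias(P %*% p$head$W1, p$head$b1)
  R <- pmax(Z1, 0)
  dm_head <- dropout_mask(B, ncol(R), drop_p)
  R_d <- apply_mask(R, dm_head)
  logits <- add_bias(R_d %*% p$head$W2, p$head$b2)
  probs <- row_softmax(logits)
  cache$Z1 <- Z1
  cache$R <- R
  cache$dm_head <- dm_head
  cache$R_d <- R_d

  out <- list(probs = probs, logits = logits)
  if (keep_cache) out$cache <- cache
  out
}

# column-wise max over the real positions of each sequence, plus the
# argmax time index used for backprop routing
masked_max_pool <- function(X, seq_rows, real_cols) {
  B <- length(seq_rows)
  nc <- ncol(X)
  P <- matrix(0, B, nc)
  amax <- matrix(0L, B, nc)
  for (b in seq_len(B)) {
    rows <- seq_rows[[b]][real_cols[[b]]]
    Xb <- X[rows, , drop = FALSE]
    j <- max.col(t(Xb), ties.method = "first")
    P[b, ] <- Xb[cbind(j, seq_len(nc))]
    amax[b, ] <- real_cols[[b]][j]
  }
  list(P = P, amax = amax)
}

#' Class probabilities for peptide sequences
#'
#' Runs the classifier in evaluation mode (no dropout; deterministic) and
#' returns the per-class probability matrix. Output for a given sequence
#' is independent of its batch mates because padded positions are masked
#' from attention and pooling.
#'
#' @param model A `ripp_model`.
#' @param sequences Character vector of amino-acid sequences.
#' @param batch_size Sequences per forward pass.
#' @return Numeric matrix, one row per sequence, columns named by
#'   [ripp_classes()] (truncated/padded to `n_classes`).
#' @export
predict_probs <- function(model, sequences, batch_size = 128L) {
  stopifnot(length(sequences) >= 1L)
  cfg <- model$config
  chunks <- split(
    seq_along(sequences),
    ceiling(seq_along(sequences) / batch_size)
  )
  out <- lapply(chunks, function(ix) {
    tb <- token_batch(sequences[ix], cfg$max_len)
    ripp_forward(model, tb$ids, tb$mask, training = FALSE)$probs
  })
  probs <- do.call(rbind, out)
  colnames(probs) <- ripp_classes()[seq_len(cfg$n_classes)]
  rownames(probs) <- NULL
  probs
}

#' Predict RiPP classes for peptides
#'
#' Tidy prediction interface: takes a data frame of peptides (columns
#' `id` and `sequence`), returns one row per peptide with the predicted
#' class, its probability, the RiPP score (1 - P(non-RiPP)) and the full
#' per-class probabilities.
#'
#' @param object A `ripp_model`.
#' @param new_data Data frame with columns `id` and `sequence`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `predicted_class`, `prob`,
#'   `ripp_score`, and one `p_<class>` column per class.
#' @export
predict.ripp_model <- function(object, new_data, ...) {
  stopifnot(all(c("id", "sequence") %in% names(new_data)))
  probs <- predict_probs(object, new_data$sequence)
  pred_idx <- max.col(probs, ties.method = "first")
  prob_cols <- tibble::as_tibble(probs, .name_repair = "minimal")
  names(prob_cols) <- paste0("p_", gsub("[^a-zA-Z0-9]+", "_", colnames(probs)))
  dplyr::bind_cols(
    tibble::tibble(
      id = new_data$id,
      predicted_class = colnames(probs)[pred_idx],
      prob = probs[cbind(seq_len(nrow(probs)), pred_idx)],
      ripp_score = ripp_score(probs)
    ),
    prob_cols
  )
}
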