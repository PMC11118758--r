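# Backpropagation through the classifier. Mirrors ripp_forward() using
# its cache; returns gradients in the same nested structure as the
# parameter list. Verified against finite differences in the test suite.

layernorm_bwd <- function(dY, g, cache) {
  xhat <- cache$xhat
  istd <- cache$istd
  dxhat <- sweep(dY, 2L, g, "*")
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dX <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

zeros_like <- function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

ripp_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  variant <- cfg$variant
  B <- cache$B
  T <- cache$T
  d <- cfg$d_embed
  g <- rapply(p, zeros_like, how = "replace")

  # ---- head ----
  dR_d <- dlogits %*% t(p$head$W2)
  g$head$W2 <- crossprod(cache$R_d, dlogits)
  g$head$b2 <- colSums(dlogits)
  dR <- apply_mask(dR_d, cache$dm_head)
  dZ1 <- dR * (cache$Z1 > 0)
  g$head$W1 <- crossprod(cache$P, dZ1)
  g$head$b1 <- colSums(dZ1)
  dP <- dZ1 %*% t(p$head$W1)

  # ---- pooling ----
  H_top <- cache$H_top
  dH <- matrix(0, nrow(H_top), ncol(H_top))
  if (variant == "transformer_cls") {
    dH[seq_len(B), ] <- dP
  } else if (variant == "transformer_max") {
    amax <- cache$pool$amax
    for (b in seq_len(B)) {
      rows <- b + (amax[b, ] - 1L) * B
      ix <- cbind(rows, seq_len(ncol(dH)))
      dH[ix] <- dH[ix] + dP[b, ]
    }
  } else {
    nh <- ncol(H_top)
    dmax <- dP[, seq_len(nh), drop = FALSE]
    dmean <- dP[, (nh + 1L):(2L * nh), drop = FALSE]
    dlast <- dP[, (2L * nh + 1L):(3L * nh), drop = FALSE]
    amax <- cache$pool$amax
    for (b in seq_len(B)) {
      rows <- b + (amax[b, ] - 1L) * B
      ix <- cbind(rows, seq_len(nh))
      dH[ix] <- dH[ix] + dmax[b, ]
    }
    grp <- cache$pool$group
    dH <- dH + (dmean[grp, , drop = FALSE] / cache$lengths[grp]) * cache$m_flat
    lr <- cache$pool$last_rows
    dH[lr, ] <- dH[lr, ] + dlast
  }

  # ---- bi-lstm stack ----
  if (variant %in% c("full", "lstm_only")) {
    h <- cfg$lstm_hidden
    for (l in rev(seq_len(cfg$n_lstm_layers))) {
      lcache <- cache$lstm[[l]]
      H_in <- lcache$H_in
      H_in_used <- apply_mask(H_in, lcache$dm_in)
      dH_in <- matrix(0, nrow(H_in), ncol(H_in))
      for (dir in c("fwd", "bwd")) {
        dp <- p$lstm[[l]][[dir]]
        out_cols <- if (dir == "fwd") seq_len(h) else (h + 1L):(2L * h)
        steps <- lcache[[dir]]
        dWx <- zeros_like(dp$Wx)
        dWh <- zeros_like(dp$Wh)
        db <- zeros_like(dp$b)
        dh_next <- matrix(0, B, h)
        dc_next <- matrix(0, B, h)
        for (k in rev(seq_len(T))) {
          st <- steps[[k]]
          t <- st$t
          rows_t <- ((t - 1L) * B + 1L):(t * B)
          m <- cache$mask[, t]
          dh <- dH[rows_t, out_cols, drop = FALSE] + dh_next
          dh_new <- dh * m
          dh_carry <- dh * (1 - m)
          dc_new <- dc_next * m + dh_new * st$o * (1 - st$tanh_c^2)
          dc_prev <- dc_next * (1 - m) + dc_new * st$f
          do_g <- dh_new * st$tanh_c
          di_g <- dc_new * st$g
          df_g <- dc_new * st$c_prev
          dg_g <- dc_new * st$i
          dG <- cbind(
            di_g * st$i * (1 - st$i),
            df_g * st$f * (1 - st$f),
            dg_g * (1 - st$g^2),
            do_g * st$o * (1 - st$o)
          )
          xt <- H_in_used[rows_t, , drop = FALSE]
          dWx <- dWx + crossprod(xt, dG)
          dWh <- dWh + crossprod(st$h_prev, dG)
          db <- db + colSums(dG)
          dH_in[rows_t, ] <- dH_in[rows_t, ] + dG %*% t(dp$Wx)
          dh_next <- dG %*% t(dp$Wh) + dh_carry
          dc_next <- dc_prev
        }
        g$lstm[[l]][[dir]]$Wx <- dWx
        g$lstm[[l]][[dir]]$Wh <- dWh
        g$lstm[[l]][[dir]]$b <- db
      }
      dH <- apply_mask(dH_in, lcache$dm_in)
    }
  }
  dX <- dH # gradient w.r.t. encoder output (or embeddings for lstm_only)

  # ---- transformer encoder ----
  if (variant != "lstm_only") {
    dh_head <- cache$dh
    head_cols <- cache$head_cols
    for (l in rev(seq_len(cfg$n_encoder_layers))) {
      lp <- p$enc[[l]]
      lc <- cache$enc[[l]]
      ln2b <- layernorm_bwd(dX, lp$ln2_g, lc$ln2)
      g$enc[[l]]$ln2_g <- ln2b$dg
      g$enc[[l]]$ln2_b <- ln2b$db
      dsum2 <- ln2b$dX
      dff_out <- apply_mask(dsum2, lc$dm_ff)
      dHff <- dff_out %*% t(lp$W2)
      g$enc[[l]]$W2 <- crossprod(lc$Hff, dff_out)
      g$enc[[l]]$b2 <- colSums(dff_out)
      dZff <- dHff * (lc$Zff > 0)
      g$enc[[l]]$W1 <- crossprod(lc$X1, dZff)
      g$enc[[l]]$b1 <- colSums(dZff)
      dX1 <- dsum2 + dZff %*% t(lp$W1)
      ln1b <- layernorm_bwd(dX1, lp$ln1_g, lc$ln1)
      g$enc[[l]]$ln1_g <- ln1b$dg
      g$enc[[l]]$ln1_b <- ln1b$db
      dsum1 <- ln1b$dX
      dattn_out <- apply_mask(dsum1, lc$dm_attn)
      dO <- dattn_out %*% t(lp$Wo)
      g$enc[[l]]$Wo <- crossprod(lc$O, dattn_out)
      g$enc[[l]]$bo <- colSums(dattn_out)
      dQ <- matrix(0, B * T, d)
      dK <- matrix(0, B * T, d)
      dV <- matrix(0, B * T, d)
      for (b in seq_len(B)) {
        rows <- cache$seq_rows[[b]]
        for (hh in seq_len(cfg$n_heads)) {
          cols <- head_cols[[hh]]
          ac <- lc$A_list[[b]][[hh]]
          A_used <- apply_mask(ac$A, ac$dm)
          dOb <- dO[rows, cols, drop = FALSE]
          Vb <- lc$V[rows, cols, drop = FALSE]
          dA_used <- tcrossprod(dOb, Vb)
          dV[rows, cols] <- crossprod(A_used, dOb)
          dA <- apply_mask(dA_used, ac$dm)
          dS <- ac$A * (dA - rowSums(dA * ac$A))
          dQ[rows, cols] <- dS %*% lc$K[rows, cols, drop = FALSE] / sqrt(dh_head)
          dK[rows, cols] <- crossprod(dS, lc$Q[rows, cols, drop = FALSE]) / sqrt(dh_head)
        }
      }
      X_in <- lc$X_in
      g$enc[[l]]$Wq <- crossprod(X_in, dQ)
      g$enc[[l]]$bq <- colSums(dQ)
      g$enc[[l]]$Wk <- crossprod(X_in, dK)
      g$enc[[l]]$bk <- colSums(dK)
      g$enc[[l]]$Wv <- crossprod(X_in, dV)
      g$enc[[l]]$bv <- colSums(dV)
      dX <- dsum1 + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    }
  }

  # ---- embeddings ----
  # group rows by token id; rowsum returns rows ordered by sorted ids
  tok_ids <- cache$v_flat + 1L
  agg <- rowsum(dX, group = tok_ids)
  g$tok_emb[as.integer(rownames(agg)), ] <- agg
  if (variant != "lstm_only") {
    pos_ids <- rep(seq_len(T), each = B)
    aggp <- rowsum(dX, group = pos_ids)
    g$pos_emb[as.integer(rownames(aggp)), ] <- aggp
  }
  g
}

# gradient of the mean focal loss w.r.t. the logits
focal_loss_grad_logits <- function(probs, class_idx, gamma, eps = 1e-12) {
  n <- nrow(probs)
  ix <- cbind(seq_len(n), class_idx)
  u <- pmax(probs[ix], eps)
  one_mu <- 1 - u
  term1 <- if (gamma > 0) {
    ifelse(one_mu < 1e-12, 0, gamma * one_mu^(gamma - 1) * log(u))
  } else {
    0
  }
  a <- term1 - one_mu^gamma / u # dFL/du
  coef <- a * u # row-wise scalar
  dZ <- -coef * probs
  dZ[ix] <- dZ[ix] + coef
  dZ / n
}
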