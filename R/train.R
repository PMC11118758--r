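#' Training configuration
#'
#' Defaults follow the published training protocol: AdamW with a learning
#' rate warmed up linearly from 0 to 0.001 over the first 10,000 steps and
#' then decayed linearly to 0 over the remaining scheduled steps, a
#' maximum of 200 epochs with early stopping after 50 epochs without
#' validation improvement, batch size 128, and focal loss with gamma = 1.
#'
#' @param peak_lr Peak learning rate.
#' @param warmup_steps Steps of linear warmup (>= 1).
#' @param max_epochs Maximum training epochs.
#' @param patience Epochs without validation improvement before stopping
#'   (`<= max_epochs`).
#' @param batch_size Minibatch size.
#' @param gamma Focal-loss focusing parameter.
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_fraction Fraction of the training records carved out
#'   (stratified) as the validation set monitored for early stopping.
#' @param seed Seed governing initialization, shuffling and dropout.
#' @param track_accuracy If `TRUE`, record training accuracy each epoch
#'   (costs one extra forward pass per epoch).
#' @return A `ripp_train_config` list.
#' @export
ripp_train_config <- function(peak_lr = 0.001,
                              warmup_steps = 10000L,
                              max_epochs = 200L,
                              patience = 50L,
                              batch_size = 128L,
                              gamma = 1,
                              weight_decay = 0.01,
                              val_fraction = 0.1,
                              seed = 1L,
                              track_accuracy = FALSE) {
  stopifnot(warmup_steps >= 1L, patience <= max_epochs, batch_size >= 1L)
  structure(
    list(
      peak_lr = peak_lr, warmup_steps = as.integer(warmup_steps),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      batch_size = as.integer(batch_size), gamma = gamma,
      weight_decay = weight_decay, val_fraction = val_fraction,
      seed = as.integer(seed), track_accuracy = isTRUE(track_accuracy)
    ),
    class = "ripp_train_config"
  )
}

#' Scheduled learning rate
#'
#' Linear warmup from 0 to `peak_lr` over `warmup_steps`, then linear
#' decay to 0 at `total_steps`.
#'
#' @param step Step number (0-based; the rate applied at optimizer step
#'   `step` is `lr_schedule(step, ...)`).
#' @param warmup_steps,total_steps,peak_lr Schedule parameters.
#' @return Learning rate.
#' @export
lr_schedule <- function(step, warmup_steps, total_steps, peak_lr) {
  ifelse(
    step <= warmup_steps,
    peak_lr * step / warmup_steps,
    peak_lr * pmax(0, (total_steps - step) / max(1, total_steps - warmup_steps))
  )
}

# pad a list of unpadded token vectors to a B x T batch
pad_batch <- function(tok_list, lens) {
  t_max <- max(lens)
  B <- length(tok_list)
  ids <- matrix(PAD_ID, B, t_max)
  for (b in seq_len(B)) ids[b, seq_len(lens[b])] <- tok_list[[b]]
  mask <- outer(lens, seq_len(t_max), FUN = ">=") * 1
  list(ids = ids, mask = mask)
}

#' Train the precursor classifier
#'
#' Fits a `ripp_model` on labeled peptides with AdamW, the scheduled
#' learning rate, focal loss, and early stopping on validation loss.
#' A stratified `val_fraction` of the training records is held out as the
#' monitored validation set. With a fixed seed the loss history is
#' reproducible bit-for-bit on CPU.
#'
#' @param data Data frame with columns `sequence` and `class` (labels
#'   from [ripp_classes()]). Records carrying other columns pass through
#'   untouched.
#' @param model_config A [ripp_model_config()].
#' @param train_config A [ripp_train_config()].
#' @return A `ripp_fit`: list with `model` (best-validation weights),
#'   `history` (per-epoch tibble), `classes`, and the two configs.
#' @export
train_ripp <- function(data,
                       model_config = ripp_model_config(),
                       train_config = ripp_train_config()) {
  stopifnot(all(c("sequence", "class") %in% names(data)))
  tc <- train_config
  classes <- ripp_classes()[seq_len(model_config$n_classes)]
  y_all <- as_class_index(data$class, model_config$n_classes)
  if (length(unique(y_all)) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }

  withr::with_seed(tc$seed, {
    n <- nrow(data)
    # stratified validation carve
    val_idx <- integer(0)
    if (tc$val_fraction > 0) {
      val_idx <- unlist(lapply(split(seq_len(n), y_all), function(ix) {
        k <- round(tc$val_fraction * length(ix))
        if (length(ix) >= 2L && k >= 1L) sample(ix, k) else integer(0)
      }), use.names = FALSE)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(y_all[tr_idx])) < 2L) { # carve degraded the data
      tr_idx <- seq_len(n)
      val_idx <- integer(0)
    }

    toks <- lapply(
      data$sequence, tokenize,
      max_len = model_config$max_len, pad = FALSE
    )
    tok_list <- lapply(toks, `[[`, "tokens")
    lens <- vapply(toks, `[[`, integer(1), "length")

    model <- list(
      config = model_config,
      params = init_params(model_config)
    )
    class(model) <- "ripp_model"
    skeleton <- model$params
    theta <- unlist(skeleton, use.names = FALSE)
    m_adam <- numeric(length(theta))
    v_adam <- numeric(length(theta))
    beta1 <- 0.9
    beta2 <- 0.999
    eps_adam <- 1e-8

    n_tr <- length(tr_idx)
    steps_per_epoch <- ceiling(n_tr / tc$batch_size)
    total_steps <- tc$max_epochs * steps_per_epoch
    step <- 0L

    best_monitor <- Inf
    best_theta <- theta
    best_epoch <- 0L
    epochs_no_improve <- 0L
    history <- vector("list", tc$max_epochs)

    eval_loss <- function(idx) {
      # eval-mode mean focal loss over records idx
      chunks <- split(idx, ceiling(seq_along(idx) / tc$batch_size))
      tot <- 0
      for (cix in chunks) {
        bt <- pad_batch(tok_list[cix], lens[cix])
        pr <- ripp_forward(model, bt$ids, bt$mask, training = FALSE)$probs
        tot <- tot + sum(focal_loss(pr, y_all[cix],
          gamma = tc$gamma,
          reduce = "none"
        ))
      }
      tot / length(idx)
    }

    for (epoch in seq_len(tc$max_epochs)) {
      perm <- sample(tr_idx)
      batches <- split(perm, ceiling(seq_along(perm) / tc$batch_size))
      epoch_loss <- 0
      for (bix in batches) {
        bt <- pad_batch(tok_list[bix], lens[bix])
        fw <- ripp_forward(model, bt$ids, bt$mask,
          training = TRUE, keep_cache = TRUE
        )
        yb <- y_all[bix]
        epoch_loss <- epoch_loss +
          focal_loss(fw$probs, yb, gamma = tc$gamma) * length(bix)
        dlogits <- focal_loss_grad_logits(fw$probs, yb, tc$gamma)
        grads <- ripp_backward(model, fw$cache, dlogits)
        gvec <- unlist(grads, use.names = FALSE)
        step <- step + 1L
        lr <- lr_schedule(step, tc$warmup_steps, total_steps, tc$peak_lr)
        m_adam <- beta1 * m_adam + (1 - beta1) * gvec
        v_adam <- beta2 * v_adam + (1 - beta2) * gvec^2
        mhat <- m_adam / (1 - beta1^step)
        vhat <- v_adam / (1 - beta2^step)
        theta <- theta - lr * (mhat / (sqrt(vhat) + eps_adam) +
          tc$weight_decay * theta)
        model$params <- utils::relist(theta, skeleton)
      }
      train_loss <- epoch_loss / n_tr

      monitor <- if (length(val_idx) > 0) eval_loss(val_idx) else train_loss
      train_acc <- NA_real_
      if (tc$track_accuracy) {
        bt <- pad_batch(tok_list[tr_idx], lens[tr_idx])
        pr <- ripp_forward(model, bt$ids, bt$mask, training = FALSE)$probs
        train_acc <- mean(max.col(pr, ties.method = "first") == y_all[tr_idx])
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss,
        val_loss = if (length(val_idx) > 0) monitor else NA_real_,
        train_accuracy = train_acc, lr = lr_schedule(
          step, tc$warmup_steps, total_steps, tc$peak_lr
        )
      )
      if (monitor < best_monitor - 1e-12) {
        best_monitor <- monitor
        best_theta <- theta
        best_epoch <- epoch
        epochs_no_improve <- 0L
      } else {
        epochs_no_improve <- epochs_no_improve + 1L
        if (epochs_no_improve >= tc$patience) break
      }
    }

    model$params <- utils::relist(best_theta, skeleton)
    structure(
      list(
        model = model,
        history = dplyr::bind_rows(history),
        classes = classes,
        best_epoch = best_epoch,
        val_idx = val_idx,
        model_config = model_config,
        train_config = tc
      ),
      class = "ripp_fit"
    )
  })
}

#' @export
print.ripp_fit <- function(x, ...) {
  cat(
    "<ripp_fit>", nrow(x$history), "epochs trained; best epoch",
    x$best_epoch, "\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history
#' @param x A `ripp_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @export
tidy.ripp_fit <- function(x, ...) x$history

#' One-row fit summary
#' @param x A `ripp_fit`.
#' @param ... Unused.
#' @export
glance.ripp_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = if (all(is.na(x$history$val_loss))) {
      NA_real_
    } else {
      min(x$history$val_loss, na.rm = TRUE)
    },
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_params = n_params(x$model),
    variant = x$model_config$variant
  )
}

#' Plot the training history
#' @param object A `ripp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ripp_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$history[, c("epoch", "train_loss", "val_loss")],
    -"epoch",
    names_to = "series", values_to = "loss"
  )
  df <- df[!is.na(df$loss), ]
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "focal loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
predict.ripp_fit <- function(object, new_data, ...) {
  predict(object$model, new_data, ...)
}
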