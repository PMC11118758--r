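# Independent brute-force oracles used by the tests. These deliberately
# re-derive results from first principles (dynamic programming,
# enumeration, closed forms) without calling the package's own
# implementation paths.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Affine-gap global alignment: optimal score plus the max (or min)
# number of matches achievable among optimal-score alignments.
nw_oracle <- function(a, b, sub = .blosum62, go = 11, ge = 1,
                      want_max = TRUE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  better <- function(s1, m1, s2, m2) {
    s1 > s2 + 1e-9 ||
      (abs(s1 - s2) < 1e-9 && (if (want_max) m1 > m2 else m1 < m2))
  }
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  Mm <- matrix(0, n + 1, m + 1)
  Xm <- matrix(0, n + 1, m + 1)
  Ym <- matrix(0, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + ge * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(go + ge * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[A[i - 1], B[j - 1]]
      ismatch <- as.integer(A[i - 1] == B[j - 1])
      bs <- M[i - 1, j - 1]
      bm <- Mm[i - 1, j - 1]
      if (better(X[i - 1, j - 1], Xm[i - 1, j - 1], bs, bm)) {
        bs <- X[i - 1, j - 1]
        bm <- Xm[i - 1, j - 1]
      }
      if (better(Y[i - 1, j - 1], Ym[i - 1, j - 1], bs, bm)) {
        bs <- Y[i - 1, j - 1]
        bm <- Ym[i - 1, j - 1]
      }
      M[i, j] <- bs + s
      Mm[i, j] <- bm + ismatch
      bs <- M[i - 1, j] - go - ge
      bm <- Mm[i - 1, j]
      if (better(X[i - 1, j] - ge, Xm[i - 1, j], bs, bm)) {
        bs <- X[i - 1, j] - ge
        bm <- Xm[i - 1, j]
      }
      if (better(Y[i - 1, j] - go - ge, Ym[i - 1, j], bs, bm)) {
        bs <- Y[i - 1, j] - go - ge
        bm <- Ym[i - 1, j]
      }
      X[i, j] <- bs
      Xm[i, j] <- bm
      bs <- M[i, j - 1] - go - ge
      bm <- Mm[i, j - 1]
      if (better(Y[i, j - 1] - ge, Ym[i, j - 1], bs, bm)) {
        bs <- Y[i, j - 1] - ge
        bm <- Ym[i, j - 1]
      }
      if (better(X[i, j - 1] - go - ge, Xm[i, j - 1], bs, bm)) {
        bs <- X[i, j - 1] - go - ge
        bm <- Xm[i, j - 1]
      }
      Y[i, j] <- bs
      Ym[i, j] <- bm
    }
  }
  cand <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  mm <- c(Mm[n + 1, m + 1], Xm[n + 1, m + 1], Ym[n + 1, m + 1])
  best <- max(cand)
  sel <- mm[abs(cand - best) < 1e-9]
  list(score = best, matches = if (want_max) max(sel) else min(sel))
}

# Maximum achievable matches between two sequences over any alignment
# (free gaps) == longest common subsequence; an upper bound on any
# alignment's match count. Row-vectorized DP.
lcs_matches <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- integer(length(B) + 1)
  for (i in seq_along(A)) {
    cur <- integer(length(B) + 1)
    eq <- A[i] == B
    for (j in seq_along(B)) {
      cur[j + 1] <- max(prev[j] + eq[j], prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[length(B) + 1]
}

# Semi-global edit distance: minimum edits to align `query` fully inside
# `subject` (free ends on the subject). Vectorized over DP anti-rows.
semiglobal_edit <- function(query, subject) {
  Q <- strsplit(query, "")[[1]]
  S <- strsplit(subject, "")[[1]]
  prev <- rep(0L, length(S) + 1) # free start in subject
  for (i in seq_along(Q)) {
    cur <- integer(length(S) + 1)
    cur[1] <- i
    sub_cost <- prev[-length(prev)] + (Q[i] != S)
    del_cost <- prev[-1] + 1L
    for (j in seq_along(S)) {
      cur[j + 1] <- min(sub_cost[j], del_cost[j], cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev) # free end in subject
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force greedy centroid clustering over a precomputed predicate
# matrix ok[i, j] ("i may join a cluster founded by j").
brute_greedy <- function(n, order_idx, ok) {
  reps <- integer(0)
  assign <- integer(n)
  for (i in order_idx) {
    hit <- 0L
    for (r in reps) {
      if (ok[i, r]) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      assign[i] <- i
    } else {
      assign[i] <- hit
    }
  }
  assign
}

# Union-of-intervals total length by position enumeration.
interval_union_bp <- function(start, end) {
  covered <- unique(unlist(mapply(seq, start, end, SIMPLIFY = FALSE)))
  length(covered)
}

# Upper-tail hypergeometric P(X >= k) by direct enumeration of the pmf.
hyper_enum <- function(k, K, n, N) {
  xs <- max(0, k):min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Binary metric oracles from raw truth/prediction vectors, using
# formulations different from the package's TP/FP-count path.
oracle_binary <- function(truth, pred) {
  prec <- mean(truth[pred])
  rec <- mean(pred[truth])
  list(
    accuracy = mean(truth == pred),
    precision = prec,
    recall = rec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    mcc = suppressWarnings(stats::cor(as.numeric(truth), as.numeric(pred)))
  )
}

# AUROC by the Mann-Whitney rank identity (independent of the
# trapezoidal sweep).
oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  np <- sum(labels)
  nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# Multiclass oracles computed from raw label vectors.
oracle_weighted_f1 <- function(truth, pred, classes, weights = "predicted") {
  n <- length(truth)
  sum(vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    denom <- 2 * tp + sum(truth != cl & pred == cl) + sum(truth == cl & pred != cl)
    f1 <- if (denom == 0) 0 else 2 * tp / denom
    w <- if (weights == "predicted") sum(pred == cl) else sum(truth == cl)
    f1 * w / n
  }, numeric(1)))
}

oracle_kappa <- function(truth, pred) {
  tab <- table(truth, pred)
  e1071::classAgreement(tab)$kappa
}

# turn a binary confusion table into probability rows for the evaluator:
# positives get a RiPP class (index 1), negatives non-RiPP (last)
probs_from_pred <- function(pred_pos, n_classes = 10L) {
  probs <- matrix(0.02, length(pred_pos), n_classes)
  idx <- ifelse(pred_pos, 1L, n_classes)
  probs[cbind(seq_along(pred_pos), idx)] <- 1 - 0.02 * (n_classes - 1)
  probs
}

small_model_config <- function(variant = "full") {
  ripp_model_config(
    n_encoder_layers = 2, n_heads = 2, d_embed = 32, d_ff_encoder = 64,
    n_lstm_layers = 2, lstm_hidden = 16, d_ff_head = 32, dropout = 0.2,
    variant = variant
  )
}

tiny_model_config <- function(variant = "full", dropout = 0) {
  ripp_model_config(
    n_encoder_layers = 1, n_heads = 2, d_embed = 8, d_ff_encoder = 12,
    n_lstm_layers = 2, lstm_hidden = 4, d_ff_head = 8, dropout = dropout,
    n_classes = 10, max_len = 80, variant = variant
  )
}
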