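# Training schedule, dataset splitting, metric suite, cross-validation
# and the identity-binned generalization benchmark.

test_that("learning rate warms up linearly to the peak then decays to zero", {
  expect_equal(lr_schedule(0, 10000, 50000, 0.001), 0)
  expect_equal(lr_schedule(10000, 10000, 50000, 0.001), 0.001)
  expect_equal(lr_schedule(5000, 10000, 50000, 0.001), 0.0005)
  expect_equal(lr_schedule(50000, 10000, 50000, 0.001), 0)
  expect_equal(lr_schedule(30000, 10000, 50000, 0.001), 0.0005)
  expect_equal(lr_schedule(60000, 10000, 50000, 0.001), 0) # clamped at 0
})

test_that("training is reproducible and rejects single-class data", {
  fx <- gen_peptide_dataset(
    n_per_class = 8L, classes = c("lanthipeptide", "non-RiPP"), seed = 21
  )
  tc <- ripp_train_config(
    peak_lr = 1e-3, warmup_steps = 4, max_epochs = 3, patience = 3,
    batch_size = 8, seed = 9, val_fraction = 0.1
  )
  cfg <- tiny_model_config()
  f1 <- train_ripp(fx$data, cfg, tc)
  f2 <- train_ripp(fx$data, cfg, tc)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$model$params, f2$model$params)

  single <- fx$data[fx$data$class == "non-RiPP", ]
  expect_error(train_ripp(single, cfg, tc), "2 classes")
})

test_that("dedup_split keeps duplicates out of the test set", {
  recs <- tibble::tibble(
    id = c("a", "a_dup", "b", "c"),
    sequence = c(
      "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
      "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
      "WWPPHHGGNNDDCCEEFFYYMMIIKKRRLLVVSS",
      "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQ"
    ),
    class = c("lanthipeptide", "lanthipeptide", "non-RiPP", "non-RiPP")
  )
  # with test_fraction = 1 every representative goes to test: the
  # duplicate (a non-representative) can never be a test record
  out <- dedup_split(recs, 0.9, test_fraction = 1, seed = 1)
  expect_true(out$split[out$id == "a_dup"] %in% c("train", "excluded"))
  expect_false(out$is_representative[out$id == "a_dup"])
  # every record lands in exactly one split
  expect_true(all(out$split %in% c("train", "test", "excluded")))
  expect_equal(nrow(out), nrow(recs))
})

test_that("dedup_split stratifies all-unique records at the requested fraction", {
  set.seed(30)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  recs <- tibble::tibble(
    id = sprintf("u%02d", 1:40),
    sequence = vapply(
      1:40, function(i) paste(sample(aas, 40, TRUE), collapse = ""),
      character(1)
    ),
    class = rep(c("lanthipeptide", "non-RiPP"), each = 20)
  )
  out <- dedup_split(recs, 0.9, test_fraction = 0.1, seed = 2)
  expect_true(all(out$is_representative)) # all unique
  expect_equal(sum(out$split == "test"), 4) # round(0.1 * 20) per class
  expect_equal(
    as.integer(table(out$class[out$split == "test"])),
    c(2L, 2L)
  )
})

test_that("cross-split identity stays below the threshold (brute force)", {
  fx <- gen_peptide_dataset(
    n_per_class = 22L, classes = c("lanthipeptide", "non-RiPP"),
    n_dup_pairs = 3L, dup_subs = 2L, seed = 17
  )
  out <- dedup_split(fx$data, 0.9, test_fraction = 0.2, seed = 3)
  te <- which(out$split == "test")
  tr <- which(out$split == "train")
  expect_gt(length(te), 0)
  # oracle upper bound: max matches over ANY alignment / shorter length
  worst <- 0
  for (i in te) {
    for (j in tr) {
      ub <- lcs_matches(out$sequence[i], out$sequence[j]) /
        min(nchar(out$sequence[i]), nchar(out$sequence[j]))
      worst <- max(worst, ub)
    }
  }
  expect_lt(worst, 0.9)
})

test_that("evaluation metrics match hand computation on a fixed table", {
  # TP=4, TN=90, FP=1, FN=5
  truth <- c(rep(TRUE, 9), rep(FALSE, 91))
  pred <- c(rep(TRUE, 4), rep(FALSE, 5), TRUE, rep(FALSE, 90))
  probs <- probs_from_pred(pred)
  ev <- evaluate_predictions(
    ifelse(truth, "lanthipeptide", "non-RiPP"), probs
  )
  expect_equal(ev$binary$accuracy, 94 / 100)
  expect_equal(ev$binary$precision, 4 / 5)
  expect_equal(ev$binary$recall, 4 / 9)
  expect_equal(ev$binary$f1, 2 * 4 / (2 * 4 + 1 + 5))
  mcc_hand <- (4 * 90 - 1 * 5) / sqrt((4 + 1) * (4 + 5) * (90 + 1) * (90 + 5))
  expect_equal(ev$binary$mcc, mcc_hand)
})

test_that("perfect predictions score one on every metric", {
  y <- c("lanthipeptide", "thiopeptide", "non-RiPP", "non-RiPP")
  probs <- matrix(0.001, 4, 10)
  probs[cbind(1:4, c(5L, 9L, 10L, 10L))] <- 1 - 0.009
  ev <- evaluate_predictions(y, probs)
  expect_equal(ev$binary$accuracy, 1)
  expect_equal(ev$binary$mcc, 1)
  expect_equal(ev$binary$auroc, 1)
  expect_equal(ev$multiclass$accuracy, 1)
  expect_equal(ev$multiclass$cohens_kappa, 1)
  expect_equal(ev$multiclass$weighted_f1, 1)
})

test_that("all-majority predictions trigger the zero-denominator sentinels", {
  truth <- c(rep("lanthipeptide", 10), rep("non-RiPP", 90))
  probs <- probs_from_pred(rep(FALSE, 100)) # everything called non-RiPP
  ev <- evaluate_predictions(truth, probs)
  expect_equal(ev$binary$accuracy, 0.9)
  expect_equal(ev$binary$mcc, 0) # sentinel, flagged
  expect_true("mcc" %in% ev$flags)
  expect_equal(ev$multiclass$cohens_kappa, 0)
  expect_error(
    evaluate_predictions(truth[1:5], probs),
    "same number"
  )
})

test_that("weighted F1 uses predicted-class counts as printed, true counts behind the flag", {
  truth <- c("lanthipeptide", "lanthipeptide", "thiopeptide", "non-RiPP")
  pred_idx <- c(5L, 9L, 9L, 10L) # one lanthi misread as thiopeptide
  probs <- matrix(0.001, 4, 10)
  probs[cbind(1:4, pred_idx)] <- 1 - 0.009
  ev_pred <- evaluate_predictions(truth, probs, weights = "predicted")
  ev_true <- evaluate_predictions(truth, probs, weights = "true")
  # hand computation: per-class F1 (lanthi 2/3, thio 2/3, nonRiPP 1)
  f1_lan <- 2 * 1 / (2 * 1 + 0 + 1)
  f1_thi <- 2 * 1 / (2 * 1 + 1 + 0)
  expect_equal(
    ev_pred$multiclass$weighted_f1,
    (1 * f1_lan + 2 * f1_thi + 1 * 1) / 4
  ) # predicted counts 1, 2, 1
  expect_equal(
    ev_true$multiclass$weighted_f1,
    (2 * f1_lan + 1 * f1_thi + 1 * 1) / 4
  ) # true counts 2, 1, 1
})

test_that("a random scorer attains chance-level AUROC", {
  set.seed(77)
  n <- 2000
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  scores <- stats::runif(n)
  au <- rippmine:::auroc(scores, labels)
  expect_gt(au, 0.45)
  expect_lt(au, 0.55)
})

test_that("cross-validation folds partition records and the summary is the fold mean", {
  fx <- gen_peptide_dataset(
    n_per_class = 50L, classes = c("lanthipeptide", "non-RiPP"), seed = 8
  )
  tc <- ripp_train_config(
    peak_lr = 1e-3, warmup_steps = 2, max_epochs = 1, patience = 1,
    batch_size = 32, seed = 4, val_fraction = 0
  )
  cv <- crossvalidate_ripp(fx$data, tiny_model_config(), tc, k = 10)
  expect_equal(nrow(cv$folds), 100)
  expect_equal(sort(unique(cv$folds$fold)), 1:10)
  expect_equal(as.integer(table(cv$folds$fold)), rep(10L, 10)) # each tested once
  expect_equal(
    cv$summary$accuracy,
    mean(cv$per_fold$accuracy)
  )
  expect_warning(
    crossvalidate_ripp(fx$data[c(1:3, 51:100), ], tiny_model_config(), tc, k = 10),
    "fewer than k"
  )
})

test_that("cross-validation on separable synthetic data reaches high AUROC", {
  fx <- gen_peptide_dataset(
    n_per_class = 40L,
    classes = c("lanthipeptide", "non-RiPP", "cyanobactin"), seed = 3
  )
  tc <- ripp_train_config(
    peak_lr = 2e-3, warmup_steps = 20, max_epochs = 8, patience = 8,
    batch_size = 32, seed = 2, val_fraction = 0.1
  )
  cv <- crossvalidate_ripp(fx$data, small_model_config(), tc, k = 3)
  expect_gte(cv$summary$auroc, 0.95)
})

test_that("identity-binned evaluation recovers planted identity structure", {
  set.seed(55)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  train <- tibble::tibble(
    id = sprintf("t%02d", 1:10),
    sequence = vapply(
      1:10, function(i) paste(sample(aas, 50, TRUE), collapse = ""),
      character(1)
    ),
    class = rep(c("lanthipeptide", "non-RiPP"), 5)
  )
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(aas, ch[p]), 1)
    paste(ch, collapse = "")
  }
  test_set <- tibble::tibble(
    id = c("identical", "mut5", "far"),
    sequence = c(
      train$sequence[1], # identity 1 -> top bin
      mut(train$sequence[2], 5), # ~90% -> (0.8, 0.9] or top bin
      paste(rep("W", 50), collapse = "") # no real hit -> lowest bin
    ),
    class = c("lanthipeptide", "non-RiPP", "non-RiPP")
  )
  m <- ripp_model(tiny_model_config(), seed = 6)
  out <- identity_binned_eval(train, test_set, m)
  expect_true("(0.9,1]" %in% out$bin)
  expect_true(all(out$n >= 1))
  # empty bins are absent, not zero rows
  expect_lte(nrow(out), 3)
  # the saturated-mutation record lands in the lowest occupied bin
  expect_true(any(out$bin %in% c("[0,0.1]", "(0.1,0.2]", "(0.2,0.3]", "(0.3,0.4]")))
})
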