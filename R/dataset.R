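# Dataset dereplication/splitting, tenfold cross-validation and the
# identity-binned generalization benchmark.

#' Dereplicate and split labeled peptides
#'
#' Clusters all sequences at `identity_threshold` (greedy clustering with
#' coverage of the shorter sequence), keeps one representative per
#' cluster (the founding, longest member), samples a stratified
#' `test_fraction` of the representatives as the test set, and uses the
#' remaining representatives together with all their cluster members as
#' the training set. Members of clusters whose representative went to the
#' test set are excluded entirely, which guarantees that no test sequence
#' is `>= identity_threshold` similar to any training sequence.
#'
#' @param records Data frame with columns `id`, `sequence`, `class`.
#' @param identity_threshold Clustering identity in (0, 1]; default 0.9.
#' @param test_fraction Fraction of representatives sampled (per class)
#'   into the test set.
#' @param seed Seed for the stratified sample.
#' @param min_coverage Coverage threshold for the dereplication
#'   clustering (default 0.9 of the shorter sequence).
#' @return The input tibble with added columns `cluster`,
#'   `is_representative`, and `split` (`"train"`, `"test"`, or
#'   `"excluded"` for non-representative members of test clusters).
#' @export
dedup_split <- function(records, identity_threshold = 0.9,
                        test_fraction = 0.1, seed = 1L,
                        min_coverage = 0.9) {
  stopifnot(
    all(c("id", "sequence", "class") %in% names(records)),
    nrow(records) >= 1L,
    identity_threshold > 0, identity_threshold <= 1
  )
  cl <- greedy_cluster(
    records[, c("id", "sequence")],
    cluster_params(
      min_identity = identity_threshold,
      min_coverage = min_coverage, align = "local"
    )
  )
  out <- dplyr::bind_cols(
    records,
    cl[, c("cluster", "is_representative")]
  )
  reps <- which(out$is_representative)
  test_reps <- withr::with_seed(seed, {
    unlist(lapply(split(reps, out$class[reps]), function(ix) {
      k <- round(test_fraction * length(ix))
      if (k < 1L) {
        message(
          "class '", out$class[ix[1]],
          "' has too few representatives to stratify; kept in training"
        )
        return(integer(0))
      }
      sample(ix, k)
    }), use.names = FALSE)
  })
  test_clusters <- out$cluster[test_reps]
  split <- rep("train", nrow(out))
  in_test_cluster <- out$cluster %in% test_clusters
  split[in_test_cluster] <- "excluded"
  split[test_reps] <- "test"
  out$split <- split
  out
}

#' Stratified k-fold cross-validation
#'
#' Trains and evaluates the classifier on stratified folds; each record
#' is tested exactly once. When a class has fewer members than `k` its
#' members are spread over as many folds as possible with a warning.
#'
#' @param records Data frame with `sequence` and `class` columns.
#' @param model_config A [ripp_model_config()].
#' @param train_config A [ripp_train_config()]; its seed also fixes the
#'   fold assignment.
#' @param k Number of folds (>= 2), default 10.
#' @return A `ripp_cv`: list with `folds` (tibble record/fold),
#'   `reports` (per-fold `ripp_metrics`), and `summary` (mean of the
#'   per-fold metrics).
#' @export
crossvalidate_ripp <- function(records,
                               model_config = ripp_model_config(),
                               train_config = ripp_train_config(),
                               k = 10L) {
  stopifnot(k >= 2L, all(c("sequence", "class") %in% names(records)))
  n <- nrow(records)
  y <- as_class_index(records$class, model_config$n_classes)
  if (min(table(y)) < k) {
    warning("some classes have fewer than k members; ",
      "stratification degrades for those classes",
      call. = FALSE
    )
  }
  fold <- integer(n)
  withr::with_seed(train_config$seed, {
    for (ix in split(seq_len(n), y)) {
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  reports <- lapply(seq_len(k), function(f) {
    tr <- records[fold != f, , drop = FALSE]
    te <- records[fold == f, , drop = FALSE]
    if (nrow(te) == 0L) {
      return(NULL)
    }
    fit <- train_ripp(tr, model_config, train_config)
    probs <- predict_probs(fit$model, te$sequence)
    evaluate_predictions(te$class, probs)
  })
  reports <- Filter(Negate(is.null), reports)
  per_fold <- purrr::map_dfr(reports, glance)
  structure(
    list(
      folds = tibble::tibble(record = seq_len(n), fold = fold),
      reports = reports,
      per_fold = dplyr::mutate(per_fold, fold = seq_len(nrow(per_fold)), .before = 1),
      summary = dplyr::summarise(
        per_fold,
        dplyr::across(dplyr::everything(), mean)
      )
    ),
    class = "ripp_cv"
  )
}

#' @export
print.ripp_cv <- function(x, ...) {
  cat("<ripp_cv>", length(x$reports), "folds; mean metrics:\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ripp_cv <- function(x, ...) x$per_fold

#' @export
glance.ripp_cv <- function(x, ...) x$summary

#' Identity-binned generalization benchmark
#'
#' Partitions the test set by the global sequence identity of each test
#' record to its most similar training sequence and reports the metric
#' suite per identity bin (deciles by default). Records with no
#' positive-scoring hit fall into the lowest bin. Empty bins are absent
#' from the output rather than reported as zero.
#'
#' @param trainset,testset Data frames with `sequence` and `class`.
#' @param model A `ripp_model` or `ripp_fit`.
#' @param breaks Bin edges on the identity fraction, default deciles.
#' @return Tibble with one row per non-empty bin: `bin`, `n`, and the
#'   binary metric columns.
#' @export
identity_binned_eval <- function(trainset, testset, model,
                                 breaks = seq(0, 1, by = 0.1)) {
  stopifnot(nrow(trainset) >= 1L, nrow(testset) >= 1L)
  if (inherits(model, "ripp_fit")) model <- model$model
  best_id <- vapply(testset$sequence, function(s) {
    st <- aln_stats(
      align_pairs(trainset$sequence, s, type = "global", alphabet = "protein"),
      trainset$sequence, s
    )
    max(st$identity)
  }, numeric(1), USE.NAMES = FALSE)
  bin <- cut(pmin(pmax(best_id, 0), 1), breaks,
    include.lowest = TRUE, right = TRUE
  )
  probs <- predict_probs(model, testset$sequence)
  purrr::map_dfr(levels(bin)[tabulate(bin, nbins = nlevels(bin)) > 0], function(bl) {
    ix <- which(bin == bl)
    g <- glance(evaluate_predictions(testset$class[ix], probs[ix, , drop = FALSE]))
    dplyr::bind_cols(tibble::tibble(bin = bl, n = length(ix)), g)
  })
}
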