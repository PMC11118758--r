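# Metatranscriptomic read-alignment filtering, family-level abundance
# aggregation, prevalence filtering and hypergeometric module enrichment.

#' Filter read alignments and resolve insert assignments
#'
#' Alignments must pass all of: alignment score >= 120, percent identity
#' >= 95, and >= 45 bases aligned (all inclusive). For paired data an
#' insert is kept only if both mates map (to the same gene); an insert is
#' ambiguous — and dropped — iff its best insert-level score ties across
#' more than one target gene. Each retained insert contributes a count of
#' one to exactly one gene. The result is independent of the input row
#' order.
#'
#' @param alns Data frame with columns `read` (insert id), `mate`
#'   (`"R1"`/`"R2"`/`"unpaired"`), `target`, `score`, `identity`
#'   (percent), `aligned_bases`, and `sample`.
#' @param paired Whether the library is paired-end.
#' @param min_score,min_identity,min_aligned Thresholds (120, 95, 45).
#' @return Tibble `sample`, `read`, `target` of retained insert
#'   assignments.
#' @export
filter_read_alignments <- function(alns, paired = TRUE,
                                   min_score = 120,
                                   min_identity = 95,
                                   min_aligned = 45) {
  needed <- c("read", "mate", "target", "score", "identity", "aligned_bases")
  stopifnot(all(needed %in% names(alns)))
  if (!"sample" %in% names(alns)) alns$sample <- "S1"
  passing <- alns |>
    tibble::as_tibble() |>
    dplyr::filter(
      .data$score >= min_score,
      .data$identity >= min_identity,
      .data$aligned_bases >= min_aligned
    )
  if (nrow(passing) == 0) {
    return(tibble::tibble(
      sample = character(), read = character(), target = character()
    ))
  }
  # insert-level score per (read, target): sum over mates, best per mate
  per_target <- passing |>
    dplyr::group_by(.data$sample, .data$read, .data$target, .data$mate) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::group_by(.data$sample, .data$read, .data$target) |>
    dplyr::summarise(
      score = sum(.data$score),
      n_mates = dplyr::n_distinct(.data$mate),
      .groups = "drop"
    )
  if (paired) {
    per_target <- dplyr::filter(per_target, .data$n_mates >= 2L)
  }
  if (nrow(per_target) == 0) {
    return(tibble::tibble(
      sample = character(), read = character(), target = character()
    ))
  }
  per_target |>
    dplyr::group_by(.data$sample, .data$read) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::summarise(
      target = if (dplyr::n() == 1L) .data$target[1] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$target)) |> # ambiguous ties dropped
    dplyr::arrange(.data$sample, .data$read)
}

#' Aggregate retained inserts into a family count matrix
#'
#' Sums all inserts mapped to member genes of each family: the count for
#' (family, sample) is the number of retained inserts assigned to any
#' gene whose nonredundant gene cluster belongs to that family. Column
#' sums equal the retained inserts per sample (conservation).
#'
#' @param assignments Output of [filter_read_alignments()] (`sample`,
#'   `read`, `target`).
#' @param gene_map Data frame with columns `gene`, `cluster`, `family`
#'   (a total mapping; clusters are built externally at 95% identity /
#'   90% coverage of the shorter gene).
#' @return Tibble in wide form: `family` plus one integer column per
#'   sample.
#' @export
aggregate_family_counts <- function(assignments, gene_map) {
  stopifnot(all(c("gene", "family") %in% names(gene_map)))
  missing <- setdiff(unique(assignments$target), gene_map$gene)
  if (length(missing) > 0) {
    stop("unmapped gene id(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  samples <- sort(unique(assignments$sample))
  long <- assignments |>
    dplyr::left_join(gene_map, by = c(target = "gene")) |>
    dplyr::count(.data$family, .data$sample)
  wide <- tidyr::pivot_wider(
    long,
    names_from = "sample", values_from = "n", values_fill = 0L
  )
  # ensure every sample column exists even if empty
  for (s in samples) {
    if (!s %in% names(wide)) wide[[s]] <- 0L
  }
  dplyr::arrange(
    wide[, c("family", samples), drop = FALSE],
    .data$family
  )
}

#' Prevalence filter on a count matrix
#'
#' Keeps features (rows) detected — nonzero — in at least `min_samples`
#' samples (inclusive).
#'
#' @param counts Wide count tibble (first column the feature id, the
#'   rest numeric sample columns) or a numeric matrix.
#' @param min_samples Minimum number of samples with nonzero counts
#'   (default 6).
#' @return Filtered object of the same shape.
#' @export
prevalence_filter <- function(counts, min_samples = 6L) {
  if (is.matrix(counts)) {
    return(counts[rowSums(counts > 0) >= min_samples, , drop = FALSE])
  }
  num <- vapply(counts, is.numeric, logical(1))
  nz <- rowSums(as.matrix(counts[, num, drop = FALSE]) > 0)
  counts[nz >= min_samples, , drop = FALSE]
}

#' Hypergeometric enrichment of a category in a module
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at
#' least `k = |module intersect category|` category members in a module
#' of size `n` drawn from a universe of size `N` containing `K` category
#' members.
#'
#' @param module_members,category_members,universe Character vectors of
#'   ids; module and category must be subsets of the universe.
#' @return List with `k`, `K`, `n`, `N` and `p_value`.
#' @export
#' @examples
#' # all 5 category members inside a 5-member module from a 10-universe
#' hypergeom_enrich(letters[1:5], letters[1:5], letters[1:10])$p_value
hypergeom_enrich <- function(module_members, category_members, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  module_members <- unique(module_members)
  category_members <- unique(category_members)
  stopifnot(
    all(module_members %in% universe),
    all(category_members %in% universe)
  )
  k <- length(intersect(module_members, category_members))
  K <- length(category_members)
  n <- length(module_members)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_value = p)
}
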