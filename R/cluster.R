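# Pairwise identity and greedy incremental (UCLUST-like) clustering,
# used for training-set dereplication, RiPP family construction and
# vOTU grouping.

# replace residues absent from BLOSUM62 by X so alignment never errors;
# unknowns then score as mismatches
sanitize_protein <- function(x) {
  gsub("[^ACDEFGHIKLMNPQRSTVWYBZX*]", "X", toupper(x))
}

align_pairs <- function(patterns, subject, type, alphabet) {
  if (alphabet == "protein") {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(sanitize_protein(patterns)),
      subject = Biostrings::AAString(sanitize_protein(subject)),
      type = type, substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE
    )
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(toupper(patterns)),
      subject = Biostrings::DNAString(toupper(subject)),
      type = type, substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1
    )
  }
}

# identity = matches / alignment columns; coverage = aligned span of the
# shorter sequence / shorter length
aln_stats <- function(aln, patterns, subject) {
  ncol_aln <- Biostrings::nchar(aln)
  ident <- Biostrings::nmatch(aln) / ncol_aln
  span_p <- Biostrings::width(Biostrings::pattern(aln))
  span_s <- Biostrings::width(Biostrings::subject(aln))
  len_p <- nchar(patterns)
  len_s <- nchar(subject)
  shorter_span <- ifelse(len_p <= len_s, span_p, span_s)
  shorter_len <- pmin(len_p, len_s)
  list(
    identity = ident, coverage = shorter_span / shorter_len,
    score = Biostrings::score(aln)
  )
}

#' Pairwise sequence identity
#'
#' Aligns two sequences (global Needleman-Wunsch or local
#' Smith-Waterman; BLOSUM62 with gap open 11 / extend 1 for proteins,
#' match 1 / mismatch -1 / gap open 2 extend 1 for nucleotides) and
#' reports identity as matches over alignment columns, plus the coverage
#' of the shorter sequence by the aligned span. Characters outside the
#' scoring alphabet are treated as mismatching unknowns.
#'
#' @param a,b Sequences (non-empty strings).
#' @param mode `"global"` (used by the generalization benchmark) or
#'   `"local"` (used by clustering).
#' @param alphabet `"protein"` or `"dna"`.
#' @return List with `identity`, `coverage`, `score`.
#' @export
#' @examples
#' pairwise_identity("AAAA", "AATA")$identity # 0.75
pairwise_identity <- function(a, b, mode = c("global", "local"),
                              alphabet = c("protein", "dna")) {
  mode <- match.arg(mode)
  alphabet <- match.arg(alphabet)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  aln <- align_pairs(a, b, type = mode, alphabet = alphabet)
  st <- aln_stats(aln, a, b)
  lapply(st, unname)
}

#' Clustering parameters
#'
#' @param min_identity Minimum identity fraction in (0, 1] for a sequence
#'   to join a cluster.
#' @param min_coverage Minimum coverage fraction in (0, 1].
#' @param coverage_mode How coverage is measured; `"shorter-sequence"`
#'   (aligned span over the shorter sequence's length, mirroring
#'   coverage-mode-2 semantics of the external clustering tools) is the
#'   only mode currently implemented.
#' @param align Alignment type used for candidate comparisons.
#' @param alphabet Sequence alphabet.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(min_identity = 0.6, min_coverage = 0.6,
                           coverage_mode = "shorter-sequence",
                           align = c("local", "global"),
                           alphabet = c("protein", "dna")) {
  stopifnot(
    min_identity > 0, min_identity <= 1,
    min_coverage > 0, min_coverage <= 1
  )
  coverage_mode <- match.arg(coverage_mode, "shorter-sequence")
  structure(
    list(
      min_identity = min_identity, min_coverage = min_coverage,
      coverage_mode = coverage_mode, align = match.arg(align),
      alphabet = match.arg(alphabet)
    ),
    class = "cluster_params"
  )
}

#' Greedy incremental clustering
#'
#' UCLUST-like centroid clustering: sequences are sorted by length
#' (descending, ties by input order) and each sequence joins the
#' earliest-founded representative it matches at both the identity and
#' coverage thresholds, otherwise it founds a new cluster. Deterministic
#' given the input order.
#'
#' @param data Data frame with columns `id` and `sequence`, or a
#'   character vector of sequences (names become ids).
#' @param params A [cluster_params()]. The defaults (0.6/0.6) are the
#'   RiPP-family thresholds; dereplication uses 0.9/0.9.
#' @return Tibble with columns `id`, `cluster` (integer), `representative`
#'   (the founding member's id), `is_representative`.
#' @export
greedy_cluster <- function(data, params = cluster_params()) {
  if (is.character(data)) {
    ids <- if (is.null(names(data))) paste0("seq", seq_along(data)) else names(data)
    data <- tibble::tibble(id = ids, sequence = unname(data))
  }
  stopifnot(all(c("id", "sequence") %in% names(data)), nrow(data) >= 1L)
  ord <- order(-nchar(data$sequence), seq_len(nrow(data)))
  cluster_of <- integer(nrow(data))
  rep_idx <- integer(0) # row indices of representatives, founding order
  for (i in ord) {
    assigned <- 0L
    if (length(rep_idx) > 0) {
      aln <- align_pairs(
        data$sequence[rep_idx], data$sequence[i],
        type = params$align, alphabet = params$alphabet
      )
      st <- aln_stats(aln, data$sequence[rep_idx], data$sequence[i])
      ok <- which(st$identity >= params$min_identity &
        st$coverage >= params$min_coverage)
      if (length(ok) > 0) assigned <- ok[1] # earliest-founded wins
    }
    if (assigned == 0L) {
      rep_idx <- c(rep_idx, i)
      cluster_of[i] <- length(rep_idx)
    } else {
      cluster_of[i] <- assigned
    }
  }
  tibble::tibble(
    id = data$id,
    cluster = cluster_of,
    representative = data$id[rep_idx[cluster_of]],
    is_representative = seq_len(nrow(data)) %in% rep_idx
  )
}

#' Cluster viral contigs into vOTUs
#'
#' Greedy centroid clustering of contigs from precomputed ANI records:
#' contigs are sorted by length (descending) and each contig joins the
#' earliest-founded centroid against which it has a record with
#' `ani >= ani_min` and `af >= af_min` (both boundaries inclusive, per
#' the species-rank 95% ANI / 85% AF definition). Self-records are
#' ignored.
#'
#' @param records Data frame with columns `query`, `target`, `ani`, `af`
#'   (`af` = fraction of the query aligned).
#' @param lengths Data frame with columns `contig`, `length`, covering
#'   every contig to cluster.
#' @param ani_min,af_min Inclusive thresholds.
#' @return Tibble with `contig`, `cluster`, `representative`.
#' @export
votu_cluster <- function(records, lengths, ani_min = 0.95, af_min = 0.85) {
  stopifnot(
    all(c("query", "target", "ani", "af") %in% names(records)),
    all(c("contig", "length") %in% names(lengths))
  )
  records <- dplyr::filter(records, .data$query != .data$target)
  ord <- lengths$contig[order(-lengths$length, seq_len(nrow(lengths)))]
  reps <- character(0)
  assign <- character(length(ord))
  names(assign) <- ord
  key <- paste(records$query, records$target, sep = "\r")
  best <- tapply(seq_len(nrow(records)), key, function(ix) {
    ix[which.max(records$ani[ix])]
  })
  for (ctg in ord) {
    hit <- NA_character_
    for (r in reps) {
      ix <- best[[paste(ctg, r, sep = "\r")]]
      if (!is.null(ix) && !is.na(ix) &&
        records$ani[ix] >= ani_min && records$af[ix] >= af_min) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, ctg)
      assign[ctg] <- ctg
    } else {
      assign[ctg] <- hit
    }
  }
  tibble::tibble(
    contig = ord,
    cluster = match(assign, reps),
    representative = unname(assign)
  )
}

#' Best-hit identity search
#'
#' For each query, reports the identity of its best database hit. When a
#' precomputed hit table is supplied (`hits` with columns `query`,
#' `target`, `evalue`, `identity`), the hit with the lowest e-value is
#' reported (ties broken by higher identity), as in a BLASTP search.
#' Otherwise local alignments against every database sequence are
#' computed and the best-scoring hit is reported (ties by identity).
#' Queries with no hit get identity 0 and `no_hit = TRUE`.
#'
#' @param queries Data frame with `id`, `sequence` (or character vector).
#' @param database Data frame with `id`, `sequence` (or character
#'   vector); ignored when `hits` is given.
#' @param hits Optional precomputed hit table.
#' @param alphabet Sequence alphabet for alignment.
#' @return Tibble `query`, `target`, `identity`, `no_hit`.
#' @export
identity_search <- function(queries, database = NULL, hits = NULL,
                            alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (is.character(queries)) {
    qid <- if (is.null(names(queries))) paste0("q", seq_along(queries)) else names(queries)
    queries <- tibble::tibble(id = qid, sequence = unname(queries))
  }
  if (!is.null(hits)) {
    out <- hits |>
      dplyr::group_by(.data$query) |>
      dplyr::arrange(.data$evalue, dplyr::desc(.data$identity),
        .by_group = TRUE
      ) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select("query", "target", "identity")
    res <- dplyr::left_join(
      tibble::tibble(query = queries$id), out,
      by = "query"
    )
    return(dplyr::mutate(res,
      no_hit = is.na(.data$identity),
      identity = dplyr::coalesce(.data$identity, 0)
    ))
  }
  if (is.character(database)) {
    did <- if (is.null(names(database))) paste0("d", seq_along(database)) else names(database)
    database <- tibble::tibble(id = did, sequence = unname(database))
  }
  stopifnot(nrow(database) >= 1L)
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    aln <- align_pairs(database$sequence, queries$sequence[i],
      type = "local", alphabet = alphabet
    )
    st <- aln_stats(aln, database$sequence, queries$sequence[i])
    best <- order(-st$score, -st$identity)[1]
    no_hit <- st$score[best] <= 0
    tibble::tibble(
      query = queries$id[i],
      target = if (no_hit) NA_character_ else database$id[best],
      identity = if (no_hit) 0 else st$identity[best],
      no_hit = no_hit
    )
  })
}

#' Mean maximum identity of families against a database
#'
#' For every member of each family the maximum identity against the
#' database is found (local alignment), then averaged over the family's
#' members: the mean maximum sequence identity of the family.
#'
#' @param members Data frame with `id`, `sequence`, `family`.
#' @param database Data frame with `id`, `sequence`.
#' @param alphabet Sequence alphabet.
#' @return Tibble `family`, `n_members`, `mean_max_identity`.
#' @export
family_identity <- function(members, database,
                            alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  max_ident <- vapply(seq_len(nrow(members)), function(i) {
    aln <- align_pairs(database$sequence, members$sequence[i],
      type = "local", alphabet = alphabet
    )
    st <- aln_stats(aln, database$sequence, members$sequence[i])
    ok <- st$score > 0
    if (!any(ok)) 0 else max(st$identity[ok])
  }, numeric(1))
  tibble::tibble(family = members$family, max_identity = max_ident) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      mean_max_identity = mean(.data$max_identity),
      .groups = "drop"
    )
}

#' Pairwise Tanimoto statistics of binary fingerprints
#'
#' Tanimoto coefficient `T(a, b) = |a AND b| / |a OR b|` for every
#' unordered pair, plus the average over all distinct pairs. A pair in
#' which both fingerprints are all-zero is assigned 0 with a warning.
#'
#' @param fingerprints 0/1 matrix (rows = items) or data frame with `id`
#'   and `bits` (a string of 0/1 characters).
#' @return List with `tanimoto` (symmetric matrix, unit diagonal for
#'   non-zero fingerprints) and `average` (mean over distinct pairs).
#' @export
tanimoto_stats <- function(fingerprints) {
  if (is.data.frame(fingerprints)) {
    m <- do.call(rbind, lapply(
      strsplit(fingerprints$bits, "", fixed = TRUE),
      as.integer
    ))
    rownames(m) <- fingerprints$id
    fingerprints <- m
  }
  stopifnot(is.matrix(fingerprints), all(fingerprints %in% c(0, 1)))
  X <- fingerprints
  inter <- tcrossprod(X)
  ones <- rowSums(X)
  uni <- outer(ones, ones, "+") - inter
  Tm <- inter / uni
  if (any(uni == 0)) {
    warning("all-zero fingerprint pair(s); Tanimoto set to 0",
      call. = FALSE
    )
    Tm[uni == 0] <- 0
  }
  avg <- if (nrow(X) < 2) NA_real_ else mean(Tm[upper.tri(Tm)])
  list(tanimoto = Tm, average = avg)
}
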