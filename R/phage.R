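# Viral-contig triage, alternative genetic-code selection, and
# host-phage pair calling from CRISPR-spacer, tRNA and prophage evidence.

#' Triage contigs as putative viral
#'
#' Decision tree combining a similarity tool's flag, the BUSCO ratio,
#' viral-protein-family (VPF) hits, and a k-mer score rescue, followed by
#' hallmark/completeness removal: a contig is putative viral iff it was
#' flagged by the similarity tool AND (BUSCO ratio < 0.067 OR >= 3 VPF
#' hits); otherwise it is rescued iff its k-mer score > 0.9 with
#' p < 0.05. Putative virals are then rejected iff they have no hallmark
#' gene or their completeness is "Not-determined". The `reason` column
#' records the deciding branch.
#'
#' @param records Data frame with columns `contig`, `flagged` (logical,
#'   similarity tool), `busco_ratio`, `vpf_hits`, `virfinder_score`,
#'   `virfinder_p` (the latter two may be `NA`), `hallmark_genes`,
#'   `completeness_status` (`"determined"`/`"not-determined"`).
#' @param rescue_scope Whether the k-mer rescue applies to `"all"`
#'   contigs failing the first rule (default) or only to `"unflagged"`
#'   ones.
#' @return Tibble: input plus `viral` (logical) and `reason`.
#' @export
triage_viral <- function(records, rescue_scope = c("all", "unflagged")) {
  rescue_scope <- match.arg(rescue_scope)
  needed <- c(
    "contig", "flagged", "busco_ratio", "vpf_hits",
    "hallmark_genes", "completeness_status"
  )
  stopifnot(all(needed %in% names(records)))
  r <- tibble::as_tibble(records)
  vf_ok <- !is.na(r$virfinder_score) & !is.na(r$virfinder_p) &
    r$virfinder_score > 0.9 & r$virfinder_p < 0.05
  primary <- r$flagged & (r$busco_ratio < 0.067 | r$vpf_hits >= 3L)
  rescue_pool <- if (rescue_scope == "all") !primary else !r$flagged
  rescued <- rescue_pool & vf_ok
  putative <- primary | rescued
  nd <- tolower(r$completeness_status) == "not-determined"
  removed <- putative & (r$hallmark_genes == 0L | nd)
  viral <- putative & !removed
  reason <- dplyr::case_when(
    viral & primary & r$busco_ratio < 0.067 ~ "similarity+busco",
    viral & primary ~ "similarity+vpf",
    viral ~ "kmer-rescue",
    removed & r$hallmark_genes == 0L ~ "removed:no-hallmark",
    removed ~ "removed:completeness-not-determined",
    !r$flagged & !vf_ok ~ "not-flagged",
    TRUE ~ "flagged-but-failed-busco-vpf"
  )
  dplyr::mutate(r, viral = viral, reason = reason)
}

#' Select the genetic code of a viral contig
#'
#' Given cumulative coding scores (sum of per-gene coding potential) of a
#' contig under the standard code (11) and alternative codes (25, 15,
#' 90), the alternative code is selected iff its cumulative score is the
#' strictly highest AND at least 20% greater than the standard code's
#' (score >= 1.2 x score(11), boundary inclusive); otherwise code 11 is
#' kept. The choice is invariant to rescaling all scores by a positive
#' constant.
#'
#' @param scores Data frame with columns `contig`, `code`, `score`; a
#'   code-11 score is required per contig.
#' @return Tibble `contig`, `code` (selected), `score`.
#' @export
select_genetic_code <- function(scores) {
  stopifnot(all(c("contig", "code", "score") %in% names(scores)))
  scores |>
    dplyr::group_by(.data$contig) |>
    dplyr::group_modify(function(df, key) {
      std <- df$score[df$code == 11L]
      if (length(std) != 1L) {
        stop("contig '", key$contig, "' lacks a standard-code (11) score",
          call. = FALSE
        )
      }
      alt <- df[df$code != 11L, , drop = FALSE]
      pick <- 11L
      pick_score <- std
      if (nrow(alt) > 0) {
        best <- alt[which.max(alt$score), ]
        strictly_highest <- best$score > max(df$score[df$code != best$code])
        if (strictly_highest && best$score >= 1.2 * std) {
          pick <- best$code
          pick_score <- best$score
        }
      }
      tibble::tibble(code = as.integer(pick), score = pick_score)
    }) |>
    dplyr::ungroup()
}

# minimum edit distance (<= max_diff) at which `query` occurs in
# `subject` on either strand; NA when beyond max_diff
min_edit_hit <- function(query, subject, max_diff) {
  q <- Biostrings::DNAString(query)
  s <- Biostrings::DNAString(subject)
  for (k in 0:max_diff) {
    hit_f <- Biostrings::matchPattern(q, s,
      max.mismatch = k, with.indels = TRUE
    )
    if (length(hit_f) > 0) {
      return(list(dist = k, strand = "+"))
    }
    hit_r <- Biostrings::matchPattern(
      Biostrings::reverseComplement(q), s,
      max.mismatch = k, with.indels = TRUE
    )
    if (length(hit_r) > 0) {
      return(list(dist = k, strand = "-"))
    }
  }
  NULL
}

#' Match CRISPR spacers to phage contigs
#'
#' Exhaustive near-exact search: a spacer matches a phage contig when its
#' best alignment spans the full spacer with at most `max_diff` combined
#' mismatch and gap bases, on either strand. One match per
#' (spacer, phage) pair is retained at the minimum distance.
#'
#' @param spacers Data frame with `id`, `host`, `sequence` (spacers are
#'   typically 20-60 bp).
#' @param phages Data frame with `id`, `sequence` (contigs).
#' @param max_diff Maximum bases difference (default 2).
#' @return Tibble `spacer`, `host`, `phage`, `distance`, `strand`.
#' @export
match_spacers <- function(spacers, phages, max_diff = 2L) {
  stopifnot(
    all(c("id", "host", "sequence") %in% names(spacers)),
    all(c("id", "sequence") %in% names(phages))
  )
  short <- nchar(spacers$sequence) < 8L
  if (any(short)) {
    warning(sum(short), " spacer(s) shorter than a typical seed; ",
      "scanned exhaustively",
      call. = FALSE
    )
  }
  res <- list()
  for (i in seq_len(nrow(spacers))) {
    for (j in seq_len(nrow(phages))) {
      hit <- min_edit_hit(spacers$sequence[i], phages$sequence[j], max_diff)
      if (!is.null(hit)) {
        res[[length(res) + 1L]] <- tibble::tibble(
          spacer = spacers$id[i], host = spacers$host[i],
          phage = phages$id[j], distance = hit$dist, strand = hit$strand
        )
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(
      spacer = character(), host = character(), phage = character(),
      distance = integer(), strand = character()
    ))
  }
  dplyr::bind_rows(res)
}

#' Match host and viral tRNAs
#'
#' Viral tRNAs matching any promiscuous sequence (Levenshtein distance
#' `<= max_diff`) are removed first; the remaining viral tRNAs are then
#' matched to host tRNAs at `<= max_diff` difference, each match yielding
#' a host-phage pair.
#'
#' @param host_trnas Data frame with `id`, `host`, `sequence`.
#' @param viral_trnas Data frame with `id`, `phage`, `sequence`.
#' @param promiscuous Character vector of promiscuous viral tRNA
#'   sequences (highly conserved across bacteria; excluded as evidence).
#' @param max_diff Maximum edit distance (default 2).
#' @return Tibble `host`, `phage`, `host_trna`, `viral_trna`, `distance`.
#' @export
match_trnas <- function(host_trnas, viral_trnas,
                        promiscuous = character(), max_diff = 2L) {
  keep <- rep(TRUE, nrow(viral_trnas))
  if (length(promiscuous) > 0 && nrow(viral_trnas) > 0) {
    d <- utils::adist(viral_trnas$sequence, promiscuous)
    keep <- apply(d, 1, min) > max_diff
  }
  vt <- viral_trnas[keep, , drop = FALSE]
  if (nrow(vt) == 0 || nrow(host_trnas) == 0) {
    return(tibble::tibble(
      host = character(), phage = character(), host_trna = character(),
      viral_trna = character(), distance = integer()
    ))
  }
  d <- utils::adist(host_trnas$sequence, vt$sequence)
  idx <- which(d <= max_diff, arr.ind = TRUE)
  tibble::tibble(
    host = host_trnas$host[idx[, 1]],
    phage = vt$phage[idx[, 2]],
    host_trna = host_trnas$id[idx[, 1]],
    viral_trna = vt$id[idx[, 2]],
    distance = d[idx]
  )
}

# union of intervals (overlapping or adjacent merged); returns total bp
merge_total <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end),
    min.gapwidth = 1L
  )
  sum(IRanges::width(ir))
}

#' Call prophage-based host-phage links
#'
#' From host-vs-viral contig alignments: HSPs at identity >= 0.70 are
#' kept; overlapping or adjacent host-side spans are merged and the
#' candidate passes iff the merged region totals >= 2500 bp. It is then
#' required that the merged viral-side spans cover >= 30% of the viral
#' contig and that >= 30% of the host contig lies outside the merged
#' prophage region (all boundaries inclusive).
#'
#' @param alns Data frame of HSPs with columns `host`, `phage`,
#'   `host_start`, `host_end`, `viral_start`, `viral_end`, `identity`
#'   (fraction), `host_length`, `viral_length`.
#' @param min_identity,min_region_bp,min_viral_cov,min_host_outside
#'   Thresholds (defaults 0.70, 2500, 0.30, 0.30).
#' @return Tibble `host`, `phage`, `region_bp`, `viral_cov`,
#'   `host_outside` for passing pairs.
#' @export
call_prophage_links <- function(alns, min_identity = 0.70,
                                min_region_bp = 2500L,
                                min_viral_cov = 0.30,
                                min_host_outside = 0.30) {
  needed <- c(
    "host", "phage", "host_start", "host_end", "viral_start",
    "viral_end", "identity", "host_length", "viral_length"
  )
  stopifnot(all(needed %in% names(alns)))
  if (any(alns$host_length <= 0 | alns$viral_length <= 0)) {
    stop("zero-length contig in alignment table", call. = FALSE)
  }
  alns |>
    dplyr::filter(.data$identity >= min_identity) |>
    dplyr::group_by(.data$host, .data$phage) |>
    dplyr::summarise(
      region_bp = merge_total(.data$host_start, .data$host_end),
      viral_cov = merge_total(.data$viral_start, .data$viral_end) /
        .data$viral_length[1],
      host_outside = (.data$host_length[1] - .data$region_bp) /
        .data$host_length[1],
      .groups = "drop"
    ) |>
    dplyr::filter(
      .data$region_bp >= min_region_bp,
      .data$viral_cov >= min_viral_cov,
      .data$host_outside >= min_host_outside
    )
}

#' Merge host-phage pairs across evidence channels
#'
#' Deduplicates (host, phage) pairs found by the CRISPR-spacer, tRNA and
#' prophage channels, concatenating the evidence labels, and reports the
#' per-channel pair counts.
#'
#' @param crispr,trna,prophage Pair tables with at least `host`, `phage`
#'   columns (e.g. from [match_spacers()], [match_trnas()],
#'   [call_prophage_links()]); any may be `NULL` or empty.
#' @return List with `pairs` (tibble `host`, `phage`, `evidence`) and
#'   `channel_counts` (named integer vector of deduplicated pair counts
#'   per channel).
#' @export
build_network <- function(crispr = NULL, trna = NULL, prophage = NULL) {
  chans <- list(crispr = crispr, trna = trna, prophage = prophage)
  tabs <- purrr::imap(chans, function(df, nm) {
    if (is.null(df) || nrow(df) == 0) {
      return(NULL)
    }
    dplyr::distinct(
      tibble::tibble(host = df$host, phage = df$phage, evidence = nm)
    )
  })
  tabs <- Filter(Negate(is.null), tabs)
  counts <- vapply(c("crispr", "trna", "prophage"), function(nm) {
    if (is.null(tabs[[nm]])) 0L else nrow(tabs[[nm]])
  }, integer(1))
  if (length(tabs) == 0) {
    return(list(
      pairs = tibble::tibble(
        host = character(), phage = character(), evidence = character()
      ),
      channel_counts = counts
    ))
  }
  pairs <- dplyr::bind_rows(tabs) |>
    dplyr::group_by(.data$host, .data$phage) |>
    dplyr::summarise(
      evidence = paste(sort(unique(.data$evidence)), collapse = ","),
      .groups = "drop"
    )
  list(pairs = pairs, channel_counts = counts)
}
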