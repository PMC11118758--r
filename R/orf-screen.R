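# Small-ORF admission rules applied to gene calls from an external
# caller (Prodigal-style dialect: partial flags and rbs_motif attribute).

#' Small-ORF screening policy
#'
#' A small ORF is admitted when it has a complete start and stop codon,
#' a length between `min_len_bp` and `max_len_bp` (inclusive; the span
#' includes the stop codon), and a ribosomal binding site — unless the
#' contig's phylum is one of the exempt taxa, where a large fraction of
#' genes lack Shine-Dalgarno sequences.
#'
#' @param min_len_bp,max_len_bp Inclusive length bounds in bp (45/450).
#' @param rbs_required Whether an RBS is required outside exempt taxa.
#' @param rbs_exempt_taxa Phyla exempt from the RBS requirement.
#' @return A `screen_policy` list.
#' @export
screen_policy <- function(min_len_bp = 45L, max_len_bp = 450L,
                          rbs_required = TRUE,
                          rbs_exempt_taxa = c(
                            "Cyanobacteria", "Chlorobi", "Chlamydiae",
                            "Ignavibacteriae", "Verrucomicrobia"
                          )) {
  stopifnot(min_len_bp <= max_len_bp, length(rbs_exempt_taxa) >= 1L)
  structure(
    list(
      min_len_bp = as.integer(min_len_bp),
      max_len_bp = as.integer(max_len_bp),
      rbs_required = isTRUE(rbs_required),
      rbs_exempt_taxa = rbs_exempt_taxa
    ),
    class = "screen_policy"
  )
}

has_rbs <- function(rbs_motif) {
  !is.na(rbs_motif) & rbs_motif != "" & tolower(rbs_motif) != "none"
}

#' Filter small ORFs by the admission rules
#'
#' Keeps a call iff it has a complete start AND stop (both partial flags
#' clear, Prodigal `partial=00`), its length is within the policy bounds,
#' and it has an RBS motif or the taxon is RBS-exempt (case-insensitive
#' phylum match; an unknown taxon requires an RBS). Every rejected call
#' carries the first failing rule. The kept and rejected sets partition
#' the input and the filter is idempotent.
#'
#' @param calls Data frame of gene calls with columns `id`,
#'   `partial_start`, `partial_stop` (logical: TRUE = truncated),
#'   `length_bp`, `rbs_motif`, and optionally `strand`.
#' @param taxon Phylum label of the source contigs, or `NA`.
#' @param policy A [screen_policy()].
#' @return Tibble: the input plus `kept` (logical) and `reject_reason`
#'   (`NA` for kept calls; otherwise `"partial"`, `"length"` or `"rbs"`).
#' @export
filter_small_orfs <- function(calls, taxon = NA_character_,
                              policy = screen_policy()) {
  needed <- c("id", "partial_start", "partial_stop", "length_bp", "rbs_motif")
  stopifnot(all(needed %in% names(calls)))
  if ("strand" %in% names(calls) &&
    !all(calls$strand %in% c("+", "-"))) {
    stop("unknown strand symbol; expected '+' or '-'", call. = FALSE)
  }
  exempt <- !is.na(taxon) &&
    tolower(taxon) %in% tolower(policy$rbs_exempt_taxa)
  reason <- dplyr::case_when(
    calls$partial_start | calls$partial_stop ~ "partial",
    calls$length_bp < policy$min_len_bp |
      calls$length_bp > policy$max_len_bp ~ "length",
    policy$rbs_required & !exempt & !has_rbs(calls$rbs_motif) ~ "rbs",
    TRUE ~ NA_character_
  )
  dplyr::mutate(
    tibble::as_tibble(calls),
    kept = is.na(reason), reject_reason = reason
  )
}

#' Read Prodigal-dialect gene calls from GFF3
#'
#' Parses a GFF3 file written in the Prodigal attribute dialect
#' (`ID=`, `partial=`, `rbs_motif=`) into the tidy gene-call table used
#' by [filter_small_orfs()]. Coordinates are kept 1-based inclusive as
#' in the file; `length_bp` is `end - start + 1`.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `id`, `contig`, `start`, `end`, `strand`,
#'   `partial_start`, `partial_stop`, `rbs_motif`, `length_bp`.
#' @export
read_gene_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  attrs <- vapply(f, `[`, character(1), 9L)
  partial <- vapply(attrs, function(a) {
    m <- regmatches(a, regexpr("partial=[0-9]{2}", a))
    if (length(m) == 0) "00" else sub("partial=", "", m)
  }, character(1), USE.NAMES = FALSE)
  rbs <- vapply(attrs, function(a) {
    m <- regmatches(a, regexpr("rbs_motif=[^;]*", a))
    if (length(m) == 0) NA_character_ else sub("rbs_motif=", "", m)
  }, character(1), USE.NAMES = FALSE)
  id <- vapply(attrs, function(a) {
    m <- regmatches(a, regexpr("ID=[^;]*", a))
    if (length(m) == 0) NA_character_ else sub("ID=", "", m)
  }, character(1), USE.NAMES = FALSE)
  start <- as.integer(vapply(f, `[`, character(1), 4L))
  end <- as.integer(vapply(f, `[`, character(1), 5L))
  tibble::tibble(
    id = id,
    contig = vapply(f, `[`, character(1), 1L),
    start = start,
    end = end,
    strand = vapply(f, `[`, character(1), 7L),
    partial_start = substr(partial, 1, 1) == "1",
    partial_stop = substr(partial, 2, 2) == "1",
    rbs_motif = rbs,
    length_bp = end - start + 1L
  )
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' GFF-style coordinates are 1-based inclusive at I/O boundaries; some
#' internal interval arithmetic uses 0-based half-open.
#'
#' @param start,end Coordinates.
#' @return A list with converted `start`, `end`.
#' @export
to_zero_based <- function(start, end) list(start = start - 1L, end = end)

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) list(start = start + 1L, end = end)
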