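# Genomic-context validity engine: domain-hit filtering, intrinsic
# amino-acid rules, the four exclusive validity levels, family
# confidence, and MGE/defense gene categorization.

#' Load per-class context rules
#'
#' Reads the per-class rule table (class-defining domains, intrinsic
#' residue requirements, PTM/AA eligibility) from a YAML file. The
#' package default marks several classes' residue requirements as
#' provisional; supply your own file to override.
#'
#' @param path YAML file; defaults to the rules shipped with the package.
#' @return A named list of per-class rules (class `ripp_rules`).
#' @export
ripp_class_rules <- function(path = system.file("extdata",
                               "ripp_class_rules.yaml",
                               package = "rippmine"
                             )) {
  raw <- yaml::read_yaml(path)$classes
  structure(raw, class = "ripp_rules")
}

#' Filter domain hits by source-specific significance rules
#'
#' Profile-search (HMM) hits are kept iff `score > 0` (strict). PSSM
#' (RPS-BLAST-style) hits are kept iff `evalue <= 0.001` AND the aligned
#' fraction of the PSSM length is `>= 0.8` (both boundaries inclusive);
#' a PSSM hit with a missing fraction is rejected with a warning.
#' Keyword-derived hits pass through unchanged.
#'
#' @param hits Data frame with columns `gene`, `domain`, `name`,
#'   `source` (`"profile"`, `"pssm"` or `"keyword"`), `score`, `evalue`,
#'   `fraction` (of profile/PSSM length covered).
#' @return The kept hits as a tibble.
#' @export
filter_domain_hits <- function(hits) {
  stopifnot(all(c("source") %in% names(hits)))
  hits <- tibble::as_tibble(hits)
  bad_frac <- hits$source == "pssm" & is.na(hits$fraction)
  if (any(bad_frac)) {
    warning(sum(bad_frac), " PSSM hit(s) missing the profile-length ",
      "fraction were rejected",
      call. = FALSE
    )
  }
  keep <- dplyr::case_when(
    hits$source == "profile" ~ hits$score > 0,
    hits$source == "pssm" ~ !is.na(hits$fraction) &
      hits$evalue <= 0.001 & hits$fraction >= 0.8,
    hits$source == "keyword" ~ TRUE,
    TRUE ~ FALSE
  )
  hits[keep, , drop = FALSE]
}

#' Check a precursor's intrinsic amino-acid requirement
#'
#' Evaluates the class residue predicate: the sequence must contain at
#' least one residue from every residue group of its class (e.g.
#' lanthipeptides need Cys AND Ser-or-Thr). Classes without a
#' requirement return `TRUE` vacuously but carry
#' `attr(, "no_requirement") = TRUE` and are ineligible for the PTM and
#' AA validity levels.
#'
#' @param sequence Amino-acid string.
#' @param ripp_class Class label.
#' @param rules A [ripp_class_rules()] table.
#' @return Logical scalar with attribute `no_requirement`.
#' @export
check_intrinsic_aa <- function(sequence, ripp_class,
                               rules = ripp_class_rules()) {
  rule <- rules[[ripp_class]]
  if (is.null(rule)) stop("no rules for class '", ripp_class, "'", call. = FALSE)
  groups <- rule$residue_groups
  no_req <- !isTRUE(rule$intrinsic_aa_required) || length(groups) == 0
  if (no_req) {
    return(structure(TRUE, no_requirement = TRUE))
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  ok <- all(vapply(groups, function(g) any(unlist(g) %in% chars), logical(1)))
  structure(ok, no_requirement = FALSE)
}

# does any hit row match any of the given domain identifiers?
# exact match on accession, case-insensitive substring on the name
match_domains <- function(hits, domains) {
  if (nrow(hits) == 0 || length(domains) == 0) {
    return(logical(nrow(hits)))
  }
  acc <- hits$domain
  nm <- if ("name" %in% names(hits)) hits$name else rep("", nrow(hits))
  Reduce(`|`, lapply(domains, function(d) {
    acc == d | grepl(d, nm, ignore.case = TRUE, fixed = FALSE)
  }))
}

#' Assign the four exclusive validity levels to predicted precursors
#'
#' For each precursor the gene neighborhood is the set of genes on the
#' same contig within `window` gene ranks up/downstream (the precursor
#' gene itself included). Levels cascade exclusively:
#' * **PTM** — a class-defining domain occurs among the neighborhood's
#'   (filtered) domain hits AND the intrinsic residue predicate holds;
#'   classes without intrinsic amino acids can never reach PTM or AA.
#' * **RiPP-related** — otherwise, any RiPP-related domain (transporters
#'   etc., the configurable `related_genes` list) occurs on the precursor
#'   or its neighbors.
#' * **AA** — otherwise, the residue predicate holds.
#' * **None** — otherwise.
#'
#' @param precursors Data frame with `id` (gene id), `class`, `sequence`.
#' @param genes Gene table with `id`, `contig`, and gene order given by
#'   row order within contig (or a `rank` column).
#' @param hits Filtered domain hits (see [filter_domain_hits()]).
#' @param rules A [ripp_class_rules()] table.
#' @param related_genes Character vector of RiPP-related domain
#'   accessions/names.
#' @param window Neighborhood half-width in genes (default 10).
#' @return Tibble `id`, `level` (factor PTM > RiPP-related > AA > None),
#'   `ptm_evidence`, `related_evidence`, `aa_ok`.
#' @export
assign_validity <- function(precursors, genes, hits,
                            rules = ripp_class_rules(),
                            related_genes = character(),
                            window = 10L) {
  stopifnot(
    all(c("id", "class", "sequence") %in% names(precursors)),
    all(c("id", "contig") %in% names(genes))
  )
  if (!"rank" %in% names(genes)) {
    genes <- genes |>
      dplyr::group_by(.data$contig) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  purrr::map_dfr(seq_len(nrow(precursors)), function(i) {
    pid <- precursors$id[i]
    gi <- which(genes$id == pid)
    if (length(gi) == 0) {
      stop("precursor '", pid, "' absent from the gene table", call. = FALSE)
    }
    gi <- gi[1]
    nbr <- genes[genes$contig == genes$contig[gi] &
      abs(genes$rank - genes$rank[gi]) <= window, ]
    nhits <- hits[hits$gene %in% nbr$id, , drop = FALSE]
    rule <- rules[[precursors$class[i]]]
    if (is.null(rule)) {
      stop("no rules for class '", precursors$class[i], "'", call. = FALSE)
    }
    aa <- check_intrinsic_aa(precursors$sequence[i], precursors$class[i], rules)
    eligible <- !isTRUE(attr(aa, "no_requirement"))
    ptm_hits <- nhits[match_domains(nhits, unlist(rule$defining_domains)), ,
      drop = FALSE
    ]
    rel_hits <- nhits[match_domains(nhits, related_genes), , drop = FALSE]
    level <- if (eligible && nrow(ptm_hits) > 0 && isTRUE(as.logical(aa))) {
      "PTM"
    } else if (nrow(rel_hits) > 0) {
      "RiPP-related"
    } else if (eligible && isTRUE(as.logical(aa))) {
      "AA"
    } else {
      "None"
    }
    tibble::tibble(
      id = pid,
      level = factor(level, levels = c("PTM", "RiPP-related", "AA", "None")),
      ptm_evidence = paste(unique(ptm_hits$domain), collapse = ";"),
      related_evidence = paste(unique(rel_hits$domain), collapse = ";"),
      aa_ok = as.logical(aa)
    )
  })
}

#' Family confidence from member validity
#'
#' A RiPP family is `"high"` confidence iff at least one member's
#' neighborhood carries PTM or RiPP-related genes within the ten-gene
#' window (validity level PTM or RiPP-related); otherwise `"low"`.
#'
#' @param families Data frame with `id`, `family`.
#' @param assignments Validity assignments from [assign_validity()]
#'   (columns `id`, `level`); every family member must be assigned.
#' @return Tibble `family`, `confidence`.
#' @export
family_confidence <- function(families, assignments) {
  stopifnot(nrow(families) >= 1L)
  joined <- dplyr::left_join(families, assignments, by = "id")
  if (anyNA(joined$level)) {
    stop("every family member needs a validity assignment", call. = FALSE)
  }
  joined |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      confidence = ifelse(
        any(.data$level %in% c("PTM", "RiPP-related")), "high", "low"
      ),
      .groups = "drop"
    )
}

#' Categorize neighbor genes as defense / phage / other MGE
#'
#' Keyword categorization of gene annotations with the precedence
#' Defense-related > Phage-related > Other MGE-related > other. Matching
#' is case-insensitive on whole words (tokens split at non-alphanumeric
#' characters, so "virus" does not match "virulence"). Defense is also
#' triggered by membership of a domain accession in the supplied defense
#' Pfam list.
#'
#' @param annotation Character vector of annotation texts (may be empty
#'   strings).
#' @param accessions Optional character vector (same length) of domain
#'   accessions checked against `defense_pfams`.
#' @param defense_pfams Configurable defense Pfam accession list.
#' @param defense_keywords,phage_keywords,mge_keywords Keyword sets.
#' @return Character vector of categories.
#' @export
classify_gene_category <- function(annotation, accessions = NULL,
                                   defense_pfams = character(),
                                   defense_keywords = c("CRISPR", "BREX"),
                                   phage_keywords = c(
                                     "phage", "virus", "viral", "integrase"
                                   ),
                                   mge_keywords = c(
                                     "transposase", "transposon", "recombinase"
                                   )) {
  toks <- lapply(
    strsplit(tolower(annotation), "[^a-z0-9]+"),
    function(x) x[nzchar(x)]
  )
  has_word <- function(tok, words) any(tok %in% tolower(words))
  vapply(seq_along(annotation), function(i) {
    in_pfam <- !is.null(accessions) && accessions[i] %in% defense_pfams
    if (in_pfam || has_word(toks[[i]], defense_keywords)) {
      "Defense-related"
    } else if (has_word(toks[[i]], phage_keywords)) {
      "Phage-related"
    } else if (has_word(toks[[i]], mge_keywords)) {
      "Other MGE-related"
    } else {
      "other"
    }
  }, character(1))
}
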