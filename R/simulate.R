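# Deterministic synthetic-fixture generators. Every generator is a pure
# function of its seed (byte-identical reruns) and returns the planted
# ground truth in a manifest alongside the data. The class composition
# profiles are synthetic inventions that guarantee learnability and rule
# coverage; they are not estimates of real RiPP composition.

AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# invented per-class preferred-residue sets; preferred residues carry
# `pref_mass` of the sampling probability
class_profiles <- function() {
  list(
    "autoinducing peptide" = c("F", "Y", "W", "L"),
    "bacterial head-to-tail cyclized peptide" = c("A", "G", "P", "V"),
    "cyanobactin" = c("N", "Q", "H", "M"),
    "graspetide" = c("D", "E", "K", "S"),
    "lanthipeptide" = c("C", "S", "T", "A"),
    "lasso peptide" = c("G", "E", "D", "R"),
    "other RiPPs" = c("I", "L", "K", "R"),
    "rSAM-modified peptide" = c("C", "G", "K", "Y"),
    "thiopeptide" = c("S", "C", "T", "W"),
    "non-RiPP" = character(0) # uniform background
  )
}

sample_peptide <- function(len, preferred, pref_mass = 0.7) {
  w <- rep((1 - pref_mass) / (20 - length(preferred)), 20)
  names(w) <- AA20
  if (length(preferred) > 0) {
    w[preferred] <- pref_mass / length(preferred)
  } else {
    w[] <- 1 / 20
  }
  paste(sample(AA20, len, replace = TRUE, prob = w), collapse = "")
}

mutate_seq <- function(x, n_subs, alphabet = AA20) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), min(n_subs, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a labeled synthetic peptide dataset
#'
#' Emulates the structure of a precursor training set: each RiPP class
#' draws residues from a class-specific compositional bias (leader of
#' `leader_len` residues plus a core of `core_len` range), non-RiPP
#' peptides from a uniform background, which makes the classes
#' statistically separable. Lanthipeptide-like records are guaranteed to
#' contain Cys and Ser/Thr (inserted if absent). Optional near-duplicate
#' pairs are planted at a controlled number of substitutions for
#' dereplication tests.
#'
#' @param n_per_class Records per class.
#' @param classes Which classes to generate (default all ten).
#' @param leader_len Leader length (residues).
#' @param core_len Two-element range of core lengths.
#' @param n_dup_pairs Number of planted near-duplicate pairs.
#' @param dup_subs Substitutions applied to each planted duplicate.
#' @param seed Seed; same seed gives byte-identical output.
#' @return List with `data` (tibble `id`, `sequence`, `class`) and
#'   `manifest` (planted duplicate pairs and generation parameters).
#' @export
gen_peptide_dataset <- function(n_per_class = 25L,
                                classes = ripp_classes(),
                                leader_len = 20L,
                                core_len = c(20L, 40L),
                                n_dup_pairs = 0L,
                                dup_subs = 2L,
                                seed = 1L) {
  stopifnot(length(classes) >= 2L, all(classes %in% ripp_classes()))
  profiles <- class_profiles()
  withr::with_seed(seed, {
    recs <- purrr::map_dfr(classes, function(cl) {
      pref <- profiles[[cl]]
      seqs <- vapply(seq_len(n_per_class), function(i) {
        len <- leader_len + sample(core_len[1]:core_len[2], 1)
        s <- sample_peptide(len, pref)
        if (cl == "lanthipeptide") {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          if (!"C" %in% ch) ch[sample(length(ch), 1)] <- "C"
          if (!any(c("S", "T") %in% ch)) {
            free <- which(ch != "C")
            ch[sample(free, 1)] <- "S"
          }
          s <- paste(ch, collapse = "")
        }
        s
      }, character(1))
      tibble::tibble(
        id = sprintf("%s_%03d", gsub("[^a-zA-Z0-9]+", "_", cl), seq_len(n_per_class)),
        sequence = seqs, class = cl
      )
    })
    dups <- NULL
    if (n_dup_pairs > 0) {
      src <- sample(nrow(recs), n_dup_pairs)
      dups <- tibble::tibble(
        id = paste0("dup_", recs$id[src]),
        sequence = vapply(recs$sequence[src], mutate_seq, character(1),
          n_subs = dup_subs
        ),
        class = recs$class[src]
      )
      recs <- dplyr::bind_rows(recs, dups)
    }
    list(
      data = recs,
      manifest = list(
        seed = seed, n_per_class = n_per_class, classes = classes,
        dup_pairs = if (is.null(dups)) {
          tibble::tibble(original = character(), duplicate = character())
        } else {
          tibble::tibble(
            original = sub("^dup_", "", dups$id), duplicate = dups$id
          )
        }
      )
    )
  })
}

#' Generate a genome-neighborhood fixture with known validity levels
#'
#' Builds toy contigs each carrying one predicted precursor and planted
#' domain hits at controlled gene offsets (including the ten-gene window
#' boundary), spanning every branch of the validity cascade. The
#' manifest records the expected level per precursor, derived
#' constructively from the planted evidence.
#'
#' @param seed Seed.
#' @return List with `genes`, `hits`, `precursors`, `related_genes`, and
#'   `manifest` (tibble `id`, `expected_level`).
#' @export
gen_genome_fixture <- function(seed = 1L) {
  withr::with_seed(seed, {
    lan_domain <- "PF05147"
    rel_domain <- "ABC_tran"
    related_genes <- c(rel_domain, "PF00005")
    seq_with <- function(with_cs) {
      s <- sample_peptide(30, c("A", "G", "L", "V"))
      if (with_cs) paste0(s, "CST") else gsub("[CST]", "A", s)
    }
    cases <- list(
      # offset of planted defining domain (NA = none), has related
      # domain, residues present, class, expected level
      list("p01", 3L, FALSE, TRUE, "lanthipeptide", "PTM"),
      list("p02", 10L, FALSE, TRUE, "lanthipeptide", "PTM"),
      list("p03", 11L, FALSE, TRUE, "lanthipeptide", "AA"),
      list("p04", NA, TRUE, TRUE, "lanthipeptide", "RiPP-related"),
      list("p05", NA, FALSE, TRUE, "lanthipeptide", "AA"),
      list("p06", NA, FALSE, FALSE, "lanthipeptide", "None"),
      list("p07", 2L, FALSE, FALSE, "lanthipeptide", "None"),
      list("p08", 2L, TRUE, FALSE, "lanthipeptide", "RiPP-related"),
      list("p09", 0L, FALSE, TRUE, "lanthipeptide", "PTM"), # on precursor
      list("p10", -10L, FALSE, TRUE, "lanthipeptide", "PTM"),
      list("p11", -11L, FALSE, TRUE, "lanthipeptide", "AA"),
      list("p12", 5L, TRUE, TRUE, "lanthipeptide", "PTM"),
      # classes without intrinsic amino acids: never PTM or AA
      list("p13", 3L, FALSE, TRUE, "cyanobactin", "None"),
      list("p14", 3L, TRUE, TRUE, "cyanobactin", "RiPP-related"),
      list("p15", NA, FALSE, TRUE, "autoinducing peptide", "None"),
      list("p16", NA, TRUE, TRUE, "other RiPPs", "RiPP-related"),
      # rSAM (provisional rule: needs C)
      list("p17", 4L, FALSE, TRUE, "rSAM-modified peptide", "PTM"),
      list("p18", NA, FALSE, TRUE, "rSAM-modified peptide", "AA"),
      list("p19", 7L, TRUE, TRUE, "lanthipeptide", "PTM"),
      list("p20", NA, FALSE, FALSE, "thiopeptide", "None")
    )
    genes <- list()
    hits <- list()
    precursors <- list()
    manifest <- list()
    for (cs in cases) {
      id <- cs[[1]]
      offset <- cs[[2]]
      has_rel <- cs[[3]]
      has_aa <- cs[[4]]
      cl <- cs[[5]]
      expected <- cs[[6]]
      contig <- paste0("ctg_", id)
      ranks <- -12:12
      gid <- function(o) if (o == 0L) id else sprintf("%s_g%+03d", id, o)
      genes[[id]] <- tibble::tibble(
        contig = contig, id = vapply(ranks, gid, character(1))
      )
      if (!is.na(offset)) {
        dom <- switch(cl,
          "lanthipeptide" = lan_domain,
          "cyanobactin" = "PF00082",
          "rSAM-modified peptide" = "PF04055",
          "thiopeptide" = "PF02624",
          "PF00000"
        )
        hits[[paste0(id, "_ptm")]] <- tibble::tibble(
          gene = gid(offset), domain = dom, name = dom,
          source = "profile", score = 25.0, evalue = 1e-10, fraction = 0.95
        )
      }
      if (has_rel) {
        hits[[paste0(id, "_rel")]] <- tibble::tibble(
          gene = gid(1L), domain = rel_domain, name = "ABC transporter",
          source = "pssm", score = 50.0, evalue = 1e-6, fraction = 0.9
        )
      }
      aa_needed <- switch(cl,
        "rSAM-modified peptide" = ,
        "thiopeptide" = ,
        "lanthipeptide" = TRUE,
        FALSE
      )
      sq <- if (aa_needed) seq_with(has_aa) else seq_with(FALSE)
      if (cl == "rSAM-modified peptide" && has_aa) sq <- paste0(sq, "C")
      precursors[[id]] <- tibble::tibble(id = id, class = cl, sequence = sq)
      manifest[[id]] <- tibble::tibble(id = id, expected_level = expected)
    }
    list(
      genes = dplyr::bind_rows(genes),
      hits = dplyr::bind_rows(hits),
      precursors = dplyr::bind_rows(precursors),
      related_genes = related_genes,
      manifest = dplyr::bind_rows(manifest)
    )
  })
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a host-phage fixture with planted evidence
#'
#' Builds host and phage contigs with planted CRISPR spacers (copied
#' from phages at controlled substitution distances), shared tRNAs
#' (controlled differences, including a promiscuous decoy), prophage
#' alignment records (controlled span/identity/coverage), a viral triage
#' feature table spanning the full 32-row decision truth table, and a
#' genetic-code score table spanning the 1.2x boundary. The manifest
#' records every expected host-phage pair per evidence channel and the
#' expected triage verdicts and code selections.
#'
#' @param seed Seed.
#' @param n_extra_spacers Additional spacers planted at distances 0-3
#'   (cycled) beyond the three canonical ones.
#' @return List with `hosts`, `phages`, `spacers`, `host_trnas`,
#'   `viral_trnas`, `promiscuous`, `features`, `code_scores`,
#'   `prophage_alns`, `manifest`.
#' @export
gen_phage_fixture <- function(seed = 1L, n_extra_spacers = 0L) {
  withr::with_seed(seed, {
    dna <- c("A", "C", "G", "T")
    phages <- tibble::tibble(
      id = paste0("P", 1:4),
      sequence = vapply(c(6000L, 6500L, 7000L, 5500L), random_dna, character(1))
    )
    hosts <- tibble::tibble(
      id = c("H1", "H2"),
      sequence = vapply(c(10000L, 9000L), random_dna, character(1))
    )
    take <- function(seqs, id, at, len) substr(seqs$sequence[seqs$id == id], at, at + len - 1L)

    sp <- list(
      tibble::tibble(
        id = "S1", host = "H1",
        sequence = take(phages, "P1", 1000L, 32L), dist = 0L, phage = "P1"
      ),
      tibble::tibble(
        id = "S2", host = "H1",
        sequence = mutate_seq(take(phages, "P2", 2000L, 32L), 2L, dna),
        dist = 2L, phage = "P2"
      ),
      tibble::tibble(
        id = "S3", host = "H2",
        sequence = mutate_seq(take(phages, "P3", 1500L, 32L), 3L, dna),
        dist = 3L, phage = "P3"
      )
    )
    if (n_extra_spacers > 0) {
      dists <- rep_len(0:3, n_extra_spacers)
      for (i in seq_len(n_extra_spacers)) {
        ph <- sample(phages$id, 1)
        at <- sample(1000:4000, 1)
        sp[[length(sp) + 1L]] <- tibble::tibble(
          id = sprintf("SX%03d", i),
          host = sample(hosts$id, 1),
          sequence = mutate_seq(take(phages, ph, at, 32L), dists[i], dna),
          dist = dists[i], phage = ph
        )
      }
    }
    spacers <- dplyr::bind_rows(sp)

    trna_base <- random_dna(75L)
    promiscuous <- random_dna(75L)
    host_trnas <- tibble::tibble(
      id = c("ht1", "ht2"), host = c("H2", "H1"),
      sequence = c(trna_base, random_dna(75L))
    )
    viral_trnas <- tibble::tibble(
      id = c("vt1", "vt2", "vt3"),
      phage = c("P4", "P1", "P3"),
      sequence = c(
        mutate_seq(trna_base, 1L, dna), # pair with H2 at distance 1
        promiscuous, # removed as promiscuous
        mutate_seq(trna_base, 3L, dna) # distance 3: no pair
      )
    )

    prophage_alns <- dplyr::bind_rows(
      tibble::tibble(
        host = "H1", phage = "P2", host_start = 2000L, host_end = 4999L,
        viral_start = 1L, viral_end = 3000L, identity = 0.85,
        host_length = 10000L, viral_length = 6500L
      ),
      tibble::tibble(
        host = "H2", phage = "P4", host_start = 100L, host_end = 2598L,
        viral_start = 1L, viral_end = 2499L, identity = 0.95,
        host_length = 9000L, viral_length = 5500L
      ), # 2499 bp: below the region threshold
      tibble::tibble(
        host = "H2", phage = "P1",
        host_start = c(3000L, 4000L), host_end = c(4999L, 5999L),
        viral_start = c(1L, 1001L), viral_end = c(2000L, 3000L),
        identity = c(0.8, 0.8), host_length = 9000L, viral_length = 6000L
      ) # overlapping HSPs merging to 3000 bp
    )

    # triage truth table: all 2^5 combinations
    grid <- expand.grid(
      flagged = c(TRUE, FALSE), busco_low = c(TRUE, FALSE),
      vpf_high = c(TRUE, FALSE), vf_pass = c(TRUE, FALSE),
      hallmark = c(TRUE, FALSE)
    )
    features <- tibble::tibble(
      contig = sprintf("V%02d", seq_len(nrow(grid))),
      flagged = grid$flagged,
      busco_ratio = ifelse(grid$busco_low, 0.05, 0.10),
      vpf_hits = ifelse(grid$vpf_high, 3L, 0L),
      virfinder_score = ifelse(grid$vf_pass, 0.95, 0.5),
      virfinder_p = ifelse(grid$vf_pass, 0.01, 0.5),
      hallmark_genes = ifelse(grid$hallmark, 2L, 0L),
      completeness_status = "determined"
    )
    expected_viral <- (
      (grid$flagged & (grid$busco_low | grid$vpf_high)) |
        (!(grid$flagged & (grid$busco_low | grid$vpf_high)) & grid$vf_pass)
    ) & grid$hallmark

    code_scores <- dplyr::bind_rows(
      tibble::tibble(contig = "P1", code = c(11L, 25L), score = c(100, 120)),
      tibble::tibble(contig = "P2", code = c(11L, 25L), score = c(100, 119)),
      tibble::tibble(
        contig = "P3", code = c(11L, 25L, 15L),
        score = c(100, 130, 140)
      ),
      tibble::tibble(contig = "P4", code = 11L, score = 80)
    )
    expected_codes <- tibble::tibble(
      contig = c("P1", "P2", "P3", "P4"), code = c(25L, 11L, 15L, 11L)
    )

    expected_pairs <- dplyr::bind_rows(
      dplyr::filter(spacers, .data$dist <= 2L) |>
        dplyr::transmute(
          host = .data$host, phage = .data$phage, evidence = "crispr"
        ) |>
        dplyr::distinct(),
      tibble::tibble(host = "H2", phage = "P4", evidence = "trna"),
      tibble::tibble(
        host = c("H1", "H2"), phage = c("P2", "P1"), evidence = "prophage"
      )
    )

    list(
      hosts = hosts, phages = phages,
      spacers = spacers[, c("id", "host", "sequence")],
      spacer_truth = spacers,
      host_trnas = host_trnas, viral_trnas = viral_trnas,
      promiscuous = promiscuous,
      features = features, code_scores = code_scores,
      prophage_alns = prophage_alns,
      manifest = list(
        expected_pairs = expected_pairs,
        expected_viral = tibble::tibble(
          contig = features$contig, viral = expected_viral
        ),
        expected_codes = expected_codes
      )
    )
  })
}

#' Generate a metatranscriptomic expression fixture
#'
#' Plants a known family-by-sample count matrix (with block-correlated
#' expression across samples) and emits the read-alignment table that
#' reproduces it exactly after filtering: each planted insert passes all
#' thresholds, and controlled decoys straddle each threshold (score 119,
#' identity 94.9, 44 aligned bases), tie ambiguously across two genes, or
#' map single-ended.
#'
#' @param n_families Number of families (two genes each).
#' @param n_samples Number of samples.
#' @param block_size Families per correlated expression block.
#' @param seed Seed.
#' @return List with `alignments`, `gene_map`, `manifest` (planted
#'   `counts` matrix tibble, decoy read ids, block membership).
#' @export
gen_expression_fixture <- function(n_families = 8L, n_samples = 8L,
                                   block_size = 4L, seed = 1L) {
  withr::with_seed(seed, {
    fams <- sprintf("F%02d", seq_len(n_families))
    gene_map <- tibble::tibble(
      gene = sprintf("g%02d_%d", rep(seq_len(n_families), each = 2), 1:2),
      cluster = sprintf("c%02d_%d", rep(seq_len(n_families), each = 2), 1:2),
      family = rep(fams, each = 2)
    )
    block <- (seq_len(n_families) - 1L) %/% block_size + 1L
    n_blocks <- max(block)
    latent <- matrix(
      stats::runif(n_blocks * n_samples, 2, 40), n_blocks, n_samples
    )
    counts <- matrix(0L, n_families, n_samples,
      dimnames = list(fams, sprintf("s%02d", seq_len(n_samples)))
    )
    for (f in seq_len(n_families)) {
      scale_f <- stats::runif(1, 0.5, 2)
      mu <- latent[block[f], ] * scale_f
      counts[f, ] <- pmax(0L, as.integer(round(
        mu + stats::rnorm(n_samples, 0, 0.5)
      )))
    }
    alns <- list()
    for (f in seq_len(n_families)) {
      for (s in seq_len(n_samples)) {
        k <- counts[f, s]
        if (k == 0) next
        gsel <- sample(gene_map$gene[gene_map$family == fams[f]], k,
          replace = TRUE
        )
        for (r in seq_len(k)) {
          rid <- sprintf("rd_%s_%02d_%02d", fams[f], s, r)
          alns[[length(alns) + 1L]] <- tibble::tibble(
            read = rid, mate = c("R1", "R2"), target = gsel[r],
            score = round(stats::runif(2, 130, 200)),
            identity = round(stats::runif(2, 96, 100), 1),
            aligned_bases = sample(50:100, 2, replace = TRUE),
            sample = sprintf("s%02d", s)
          )
        }
      }
    }
    # decoys, all in sample s01 (none may survive filtering)
    decoy <- function(rid, target, score, identity, bases, mate = c("R1", "R2")) {
      tibble::tibble(
        read = rid, mate = mate, target = target, score = score,
        identity = identity, aligned_bases = bases, sample = "s01"
      )
    }
    decoys <- dplyr::bind_rows(
      decoy("dx_lowscore", "g01_1", 119, 99, 60),
      decoy("dx_lowident", "g01_1", 150, 94.9, 60),
      decoy("dx_short", "g01_1", 150, 99, 44),
      decoy("dx_single", "g01_1", 150, 99, 60, mate = "R1"),
      dplyr::bind_rows(
        decoy("dx_ambig", "g01_1", 150, 99, 60),
        decoy("dx_ambig", "g02_1", 150, 99, 60)
      )
    )
    list(
      alignments = dplyr::bind_rows(dplyr::bind_rows(alns), decoys),
      gene_map = gene_map,
      manifest = list(
        counts = tibble::as_tibble(counts, rownames = "family"),
        decoy_reads = unique(decoys$read),
        block = tibble::tibble(family = fams, block = block),
        retained_per_sample = colSums(counts)
      )
    )
  })
}
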