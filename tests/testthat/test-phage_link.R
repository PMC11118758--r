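# Viral triage, genetic-code selection and the three host-phage
# evidence channels.

test_that("the triage decision table matches the exhaustive truth-table fixture", {
  fx <- gen_phage_fixture(seed = 1)
  out <- triage_viral(fx$features)
  expect_equal(nrow(out), 32)
  expect_equal(out$viral, fx$manifest$expected_viral$viral)
})

test_that("triage boundary values and removals behave as specified", {
  row <- function(...) {
    base <- tibble::tibble(
      contig = "v", flagged = TRUE, busco_ratio = 0.05, vpf_hits = 0L,
      virfinder_score = NA_real_, virfinder_p = NA_real_,
      hallmark_genes = 2L, completeness_status = "determined"
    )
    dplyr::mutate(base, ...)
  }
  expect_true(triage_viral(row())$viral) # busco < 0.067
  expect_false(triage_viral(row(busco_ratio = 0.067))$viral) # strict <
  expect_true(triage_viral(row(busco_ratio = 0.10, vpf_hits = 3L))$viral)
  expect_false(triage_viral(row(busco_ratio = 0.10, vpf_hits = 2L))$viral)
  # rescue requires score > 0.9 AND p < 0.05
  resc <- row(
    flagged = FALSE, virfinder_score = 0.95, virfinder_p = 0.01
  )
  expect_true(triage_viral(resc)$viral)
  expect_false(triage_viral(dplyr::mutate(resc, virfinder_score = 0.9))$viral)
  expect_false(triage_viral(dplyr::mutate(resc, virfinder_p = 0.05))$viral)
  # hallmark and completeness removals
  expect_false(triage_viral(row(hallmark_genes = 0L))$viral)
  out <- triage_viral(row(completeness_status = "Not-determined"))
  expect_false(out$viral)
  expect_match(out$reason, "completeness")
  # rescue scope flag: unflagged-only mode ignores flagged failures
  fl_fail <- row(busco_ratio = 0.5, virfinder_score = 0.95, virfinder_p = 0.01)
  expect_true(triage_viral(fl_fail, rescue_scope = "all")$viral)
  expect_false(triage_viral(fl_fail, rescue_scope = "unflagged")$viral)
})

test_that("genetic-code selection sits exactly on the 1.2x boundary and is scale-invariant", {
  sc <- function(codes, scores) {
    tibble::tibble(contig = "c", code = codes, score = scores)
  }
  expect_equal(select_genetic_code(sc(c(11L, 25L), c(100, 120)))$code, 25L)
  expect_equal(select_genetic_code(sc(c(11L, 25L), c(100, 119)))$code, 11L)
  expect_equal(
    select_genetic_code(sc(c(11L, 25L, 15L), c(100, 130, 140)))$code, 15L
  )
  # ties between alternatives are not "strictly highest"
  expect_equal(
    select_genetic_code(sc(c(11L, 25L, 15L), c(100, 140, 140)))$code, 11L
  )
  # scale invariance
  for (mult in c(0.01, 1, 37)) {
    expect_equal(
      select_genetic_code(sc(c(11L, 25L, 15L), c(100, 130, 140) * mult))$code,
      15L
    )
  }
  expect_error(select_genetic_code(sc(25L, 100)), "standard-code")
})

test_that("spacer matching finds planted spacers up to two edits, both strands", {
  set.seed(41)
  phage <- tibble::tibble(
    id = "P1",
    sequence = paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  )
  core <- substr(phage$sequence, 1001, 1032)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }
  spacers <- tibble::tibble(
    id = c("s0", "s2", "s3", "src"),
    host = "H1",
    sequence = c(core, mut(core, 2), mut(core, 3), revcomp(core))
  )
  out <- match_spacers(spacers, phage)
  expect_setequal(out$spacer, c("s0", "s2", "src"))
  expect_equal(out$distance[out$spacer == "s0"], 0L)
  expect_equal(out$distance[out$spacer == "s2"], 2L)
  expect_equal(out$strand[out$spacer == "src"], "-")
  # distances agree with the semi-global edit-distance oracle
  for (k in seq_len(nrow(out))) {
    sp <- spacers$sequence[spacers$id == out$spacer[k]]
    d_or <- min(
      semiglobal_edit(sp, phage$sequence),
      semiglobal_edit(revcomp(sp), phage$sequence)
    )
    expect_equal(out$distance[k], d_or)
  }
  expect_warning(
    match_spacers(
      tibble::tibble(id = "tiny", host = "H", sequence = "ACGTA"), phage
    ),
    "seed"
  )
})

test_that("tRNA matching removes promiscuous sequences first", {
  fx <- gen_phage_fixture(seed = 2)
  out <- match_trnas(fx$host_trnas, fx$viral_trnas, fx$promiscuous)
  expect_equal(nrow(out), 1)
  expect_equal(out$host, "H2")
  expect_equal(out$phage, "P4")
  expect_equal(out$distance, 1)
  # without promiscuous removal the decoy is still no pair (random seq)
  out2 <- match_trnas(fx$host_trnas, fx$viral_trnas, character(0))
  expect_false("P1" %in% out2$phage)
  # 3-nt difference: no pair either way
  expect_false("P3" %in% out$phage)
})

test_that("prophage links honor inclusive thresholds and interval merging", {
  aln <- function(...) {
    base <- tibble::tibble(
      host = "H", phage = "P", host_start = 1000L, host_end = 3499L,
      viral_start = 1L, viral_end = 2500L, identity = 0.70,
      host_length = 10000L, viral_length = 8000L
    )
    dplyr::mutate(base, ...)
  }
  # exactly 2500 bp at exactly 70% identity, viral cov 2500/8000 >= 0.3
  # needs viral_length adjusted: make viral length 8000 -> cov 0.3125
  expect_equal(nrow(call_prophage_links(aln())), 1)
  expect_equal(nrow(call_prophage_links(aln(identity = 0.699))), 0)
  expect_equal(nrow(call_prophage_links(aln(host_end = 3498L))), 0) # 2499 bp
  # viral coverage boundary: 2400/8000 = 0.3 exactly
  expect_equal(
    nrow(call_prophage_links(aln(viral_end = 2400L))), 1
  )
  expect_equal(
    nrow(call_prophage_links(aln(viral_end = 2399L))), 0
  )
  # host outside boundary: host length such that outside is exactly 30%
  ok <- aln(host_length = 3572L) # (3572 - 2500) / 3572 = 0.3001..
  expect_equal(nrow(call_prophage_links(ok)), 1)
  bad <- aln(host_length = 3570L) # outside 0.2997
  expect_equal(nrow(call_prophage_links(bad)), 0)
  expect_error(call_prophage_links(aln(host_length = 0L)), "zero-length")

  # two overlapping HSPs merge into one region
  two <- tibble::tibble(
    host = "H", phage = "P",
    host_start = c(2000L, 4000L), host_end = c(4999L, 5999L),
    viral_start = c(1L, 2001L), viral_end = c(2000L, 4000L),
    identity = 0.8, host_length = 12000L, viral_length = 8000L
  )
  out <- call_prophage_links(two)
  expect_equal(out$region_bp, 4000L)
  expect_equal(out$region_bp, interval_union_bp(two$host_start, two$host_end))
})

test_that("interval merging equals a brute-force union oracle on random sets", {
  set.seed(47)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    start <- sample(1:500, n)
    end <- start + sample(5:100, n, replace = TRUE)
    expect_equal(
      rippmine:::merge_total(start, end),
      interval_union_bp(start, end)
    )
  }
})

test_that("the network deduplicates pairs across evidence channels", {
  cr <- tibble::tibble(host = c("H1", "H1"), phage = c("P1", "P2"))
  tr <- tibble::tibble(host = "H1", phage = "P2")
  pp <- tibble::tibble(host = "H2", phage = "P3")
  net <- build_network(cr, tr, pp)
  expect_equal(nrow(net$pairs), 3)
  expect_equal(
    net$pairs$evidence[net$pairs$host == "H1" & net$pairs$phage == "P2"],
    "crispr,trna"
  )
  expect_equal(unname(net$channel_counts), c(2L, 1L, 1L))
  empty <- build_network()
  expect_equal(nrow(empty$pairs), 0)
  expect_equal(unname(empty$channel_counts), c(0L, 0L, 0L))
})

test_that("the phage fixture's planted pairs are recovered end to end", {
  fx <- gen_phage_fixture(seed = 3)
  sm <- match_spacers(fx$spacers, fx$phages)
  tm <- match_trnas(fx$host_trnas, fx$viral_trnas, fx$promiscuous)
  pl <- call_prophage_links(fx$prophage_alns)
  net <- build_network(sm, tm, pl)
  expected <- fx$manifest$expected_pairs |>
    dplyr::distinct(host, phage) |>
    dplyr::arrange(host, phage)
  got <- dplyr::arrange(net$pairs[, c("host", "phage")], host, phage)
  expect_equal(as.data.frame(got), as.data.frame(expected))
})
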