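# Pairwise identity, greedy clustering, vOTU clustering, identity
# search and Tanimoto statistics, checked against brute-force oracles.

test_that("pairwise identity handles trivial and boundary cases", {
  pid <- pairwise_identity("MKTACSTWMKTACSTW", "MKTACSTWMKTACSTW")
  expect_equal(pid$identity, 1)
  expect_equal(pid$coverage, 1)
  expect_equal(pairwise_identity("AAAA", "AATA")$identity, 0.75)
  # symmetry of global identity
  a <- "MKTAYIAKQRQISFVK"
  b <- "MKTAYIAKQRQISFVR"
  expect_equal(
    pairwise_identity(a, b)$identity,
    pairwise_identity(b, a)$identity
  )
  # non-residue characters are treated as mismatching unknowns
  pid2 <- pairwise_identity("AJJA", "AKKA")
  expect_lt(pid2$identity, 1)
  expect_error(pairwise_identity("", "AAA"))
})

test_that("global identity agrees with an independent DP oracle", {
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:8) {
    a <- paste(sample(aas, 30, TRUE), collapse = "")
    b <- paste(sample(aas, 30, TRUE), collapse = "")
    st <- pairwise_identity(a, b, mode = "global")
    hi <- nw_oracle(a, b, want_max = TRUE)
    lo <- nw_oracle(a, b, want_max = FALSE)
    expect_equal(st$score, hi$score) # optimal score is unique
    # the implementation's match count must be achievable at the
    # optimal score (optimal alignments are not unique)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
    nm <- Biostrings::nmatch(aln)
    expect_gte(nm, lo$matches)
    expect_lte(nm, hi$matches)
  }
})

test_that("greedy clustering matches a brute-force oracle on planted families", {
  set.seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) ch[p] <- sample(setdiff(aas, ch[p]), 1)
    paste(ch, collapse = "")
  }
  founders <- vapply(
    1:3, function(i) paste(sample(aas, 40, TRUE), collapse = ""),
    character(1)
  )
  seqs <- unlist(lapply(founders, function(f) {
    c(f, vapply(1:6, function(k) mut(f, sample(3:10, 1)), character(1)))
  }))
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  params <- cluster_params(min_identity = 0.6, min_coverage = 0.6)
  out <- greedy_cluster(seqs, params)

  # brute-force oracle: same greedy semantics from an independently
  # computed predicate matrix
  n <- length(seqs)
  ok <- matrix(FALSE, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      st <- pairwise_identity(seqs[i], seqs[j], mode = "local")
      ok[i, j] <- st$identity >= 0.6 && st$coverage >= 0.6
    }
  }
  ord <- order(-nchar(seqs), seq_len(n))
  oracle <- brute_greedy(n, ord, ok)
  expect_equal(out$representative, names(seqs)[oracle])
  # 3 planted families recovered
  expect_equal(length(unique(out$cluster)), 3)
})

test_that("clustering at threshold 1.0 groups exactly the duplicates", {
  seqs <- c(
    a = "MKTAYIAKQRQISFVK", b = "MKTAYIAKQRQISFVK",
    c = "WWPPHHGGNNDDCCEE", d = "MKTAYIAKQRQISFVR"
  )
  out <- greedy_cluster(seqs, cluster_params(1.0, 1.0))
  expect_equal(out$cluster[out$id == "a"], out$cluster[out$id == "b"])
  expect_equal(length(unique(out$cluster)), 3)
  # two unrelated sequences at 0.9 stay apart
  out2 <- greedy_cluster(seqs[c("a", "c")], cluster_params(0.9, 0.9))
  expect_equal(length(unique(out2$cluster)), 2)
  # all-identical set collapses to one cluster
  out3 <- greedy_cluster(rep("MKTACSTW", 5), cluster_params(0.9, 0.9))
  expect_equal(length(unique(out3$cluster)), 1)
})

test_that("vOTU clustering honors the inclusive 95/85 boundaries and the oracle", {
  lens <- tibble::tibble(contig = c("A", "B", "C"), length = c(300, 200, 100))
  rec <- tibble::tibble(
    query = c("B", "C"), target = c("A", "A"),
    ani = c(0.95, 0.96), af = c(0.85, 0.80)
  )
  out <- votu_cluster(rec, lens)
  expect_equal(out$representative[out$contig == "B"], "A") # boundary joins
  expect_equal(out$representative[out$contig == "C"], "C") # af too low

  # 10-contig random fixture vs brute-force greedy oracle
  set.seed(31)
  n <- 10
  ids <- sprintf("c%02d", 1:n)
  lens2 <- tibble::tibble(contig = ids, length = sample(1000:9000, n))
  pairs <- expand.grid(query = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$query != pairs$target, ]
  pairs$ani <- round(stats::runif(nrow(pairs), 0.90, 1.0), 3)
  pairs$af <- round(stats::runif(nrow(pairs), 0.7, 1.0), 3)
  out2 <- votu_cluster(tibble::as_tibble(pairs), lens2)
  ok <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    if (pairs$ani[r] >= 0.95 && pairs$af[r] >= 0.85) {
      ok[pairs$query[r], pairs$target[r]] <- TRUE
    }
  }
  ord <- order(-lens2$length, seq_len(n))
  oracle <- brute_greedy(n, ord, ok)
  expect_equal(
    out2$representative[match(ids, out2$contig)],
    ids[oracle]
  )
})

test_that("identity search reports the best hit and family mean-max identity", {
  db <- tibble::tibble(
    id = c("d1", "d2"),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQ", "WWPPHHGGNNDDCCEE")
  )
  q <- tibble::tibble(id = "q1", sequence = db$sequence[1])
  out <- identity_search(q, db)
  expect_equal(out$identity, 1)
  expect_equal(out$target, "d1")
  expect_false(out$no_hit)

  # precomputed hit table: lowest e-value wins, ties by identity
  hits <- tibble::tibble(
    query = c("q1", "q1", "q2"),
    target = c("t1", "t2", "t3"),
    evalue = c(1e-5, 1e-8, 1e-3),
    identity = c(0.9, 0.5, 0.7)
  )
  out2 <- identity_search(
    tibble::tibble(id = c("q1", "q2", "q3"), sequence = "AAA"),
    hits = hits
  )
  expect_equal(out2$identity[out2$query == "q1"], 0.5) # lowest e-value
  expect_true(out2$no_hit[out2$query == "q3"])
  expect_equal(out2$identity[out2$query == "q3"], 0)

  # family of two with member maxima 1.0 and 0.5 -> mean-max 0.75
  members <- tibble::tibble(
    id = c("m1", "m2"), family = "F1",
    sequence = c(db$sequence[1], "MKTAYIAKQRCCCCCCCCCCCC")
  )
  fam <- family_identity(members, db)
  m2max <- max(
    pairwise_identity(members$sequence[2], db$sequence[1], "local")$identity,
    pairwise_identity(members$sequence[2], db$sequence[2], "local")$identity
  )
  expect_equal(fam$mean_max_identity, (1 + m2max) / 2)
})

test_that("tanimoto statistics match direct set computation", {
  fp <- rbind(
    a = c(1, 1, 0, 0),
    b = c(1, 0, 1, 0),
    c = c(1, 1, 0, 0),
    d = c(0, 0, 0, 1)
  )
  ts <- tanimoto_stats(fp)
  expect_equal(ts$tanimoto["a", "b"], 1 / 3)
  expect_equal(ts$tanimoto["a", "c"], 1) # identical non-zero
  expect_equal(ts$tanimoto["a", "d"], 0) # disjoint
  expect_equal(ts$tanimoto, t(ts$tanimoto)) # symmetric
  expect_equal(unname(diag(ts$tanimoto)), rep(1, 4))
  pairs <- c(
    1 / 3, 1, 0, # ab ac ad
    1 / 3, 0, # bc bd
    0 # cd
  )
  expect_equal(ts$average, mean(pairs))
  # both-zero vectors warn and get 0
  expect_warning(tz <- tanimoto_stats(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_equal(unname(tz$tanimoto[1, 2]), 0)
  # bitstring data-frame input
  df <- tibble::tibble(id = c("x", "y"), bits = c("1100", "1010"))
  expect_equal(unname(tanimoto_stats(df)$tanimoto[1, 2]), 1 / 3)
})
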