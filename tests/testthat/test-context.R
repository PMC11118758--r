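# Domain-hit filtering, intrinsic amino acids, validity levels, family
# confidence and MGE categorization.

test_that("domain hits are filtered by source-specific boundary rules", {
  hits <- tibble::tibble(
    gene = letters[1:6],
    domain = paste0("D", 1:6), name = paste0("D", 1:6),
    source = c("profile", "profile", "pssm", "pssm", "pssm", "keyword"),
    score = c(0, 0.1, 50, 50, 50, NA),
    evalue = c(1e-5, 1e-5, 0.001, 5e-4, 0.002, NA),
    fraction = c(NA, NA, 0.80, 0.79, 0.95, NA)
  )
  kept <- filter_domain_hits(hits)
  # profile: score 0 rejected (strict >), 0.1 kept
  # pssm: e = 0.001 & fraction 0.80 kept (inclusive); 0.79 rejected;
  #       e = 0.002 rejected; keyword passes through
  expect_equal(kept$gene, c("b", "c", "f"))
  hits$fraction[3] <- NA
  expect_warning(k2 <- filter_domain_hits(hits), "missing")
  expect_equal(k2$gene, c("b", "f"))
})

test_that("intrinsic amino-acid predicates follow the class rules", {
  expect_true(check_intrinsic_aa("MKAACSTW", "lanthipeptide"))
  expect_false(check_intrinsic_aa("MKAAGGW", "lanthipeptide"))
  expect_true(check_intrinsic_aa("MKAACGG", "lanthipeptide") == FALSE) # C but no S/T
  aip <- check_intrinsic_aa("MKAAGGW", "autoinducing peptide")
  expect_true(aip)
  expect_true(attr(aip, "no_requirement"))
  cyano <- check_intrinsic_aa("AAAA", "cyanobactin")
  expect_true(attr(cyano, "no_requirement"))
  expect_error(check_intrinsic_aa("AAA", "no-such-class"), "no rules")
})

test_that("the validity cascade matches the constructed 20-case manifest", {
  fx <- gen_genome_fixture(seed = 1)
  hits <- filter_domain_hits(fx$hits)
  va <- assign_validity(fx$precursors, fx$genes, hits,
    related_genes = fx$related_genes
  )
  cmp <- dplyr::inner_join(va, fx$manifest, by = "id")
  expect_equal(nrow(cmp), 20)
  expect_equal(as.character(cmp$level), cmp$expected_level)
  # levels are exclusive and exhaustive
  expect_true(all(!is.na(cmp$level)))
})

test_that("validity levels cascade on hand-built neighborhoods", {
  genes <- tibble::tibble(
    contig = "c1", id = c("g1", "g2", "prec", "g3", "g4")
  )
  prec <- tibble::tibble(
    id = "prec", class = "lanthipeptide", sequence = "MKAACSTW"
  )
  lanc <- tibble::tibble(
    gene = "g4", domain = "PF05147", name = "LANC_like",
    source = "profile", score = 30, evalue = 1e-9, fraction = 0.9
  )
  abc <- tibble::tibble(
    gene = "g1", domain = "ABC_tran", name = "ABC transporter",
    source = "profile", score = 30, evalue = 1e-9, fraction = 0.9
  )
  rel <- "ABC_tran"
  expect_equal(
    as.character(assign_validity(prec, genes, lanc, related_genes = rel)$level),
    "PTM"
  )
  expect_equal(
    as.character(assign_validity(prec, genes, abc, related_genes = rel)$level),
    "RiPP-related"
  )
  empty <- lanc[0, ]
  expect_equal(
    as.character(assign_validity(prec, genes, empty, related_genes = rel)$level),
    "AA"
  )
  prec_noc <- dplyr::mutate(prec, sequence = "MKAAGSW") # no Cys
  expect_equal(
    as.character(assign_validity(prec_noc, genes, empty, related_genes = rel)$level),
    "None"
  )
  expect_error(
    assign_validity(
      dplyr::mutate(prec, id = "ghost"), genes, lanc,
      related_genes = rel
    ),
    "absent"
  )
})

test_that("adding a class-defining domain never lowers the level", {
  fx <- gen_genome_fixture(seed = 1)
  hits <- filter_domain_hits(fx$hits)
  va0 <- assign_validity(fx$precursors, fx$genes, hits,
    related_genes = fx$related_genes
  )
  # plant a lanthipeptide-defining domain next to every precursor
  extra <- tibble::tibble(
    gene = paste0(fx$precursors$id, "_g+01"),
    domain = "PF05147", name = "LANC_like",
    source = "profile", score = 40, evalue = 1e-12, fraction = 0.9
  )
  # only lanthipeptide rows can be upgraded by this domain; check all
  lan <- fx$precursors$class == "lanthipeptide"
  va1 <- assign_validity(fx$precursors, fx$genes,
    dplyr::bind_rows(hits, extra),
    related_genes = fx$related_genes
  )
  rank_of <- function(l) match(as.character(l), c("None", "AA", "RiPP-related", "PTM"))
  expect_true(all(rank_of(va1$level[lan]) >= rank_of(va0$level[lan])))
})

test_that("family confidence requires a PTM- or related-bearing member", {
  fams <- tibble::tibble(
    id = c("p1", "p2", "p3", "q1", "q2", "r1"),
    family = c("F1", "F1", "F1", "F2", "F2", "F3")
  )
  asg <- tibble::tibble(
    id = fams$id,
    level = factor(
      c("PTM", "None", "None", "AA", "None", "PTM"),
      levels = c("PTM", "RiPP-related", "AA", "None")
    )
  )
  out <- family_confidence(fams, asg)
  expect_equal(
    out$confidence[match(c("F1", "F2", "F3"), out$family)],
    c("high", "low", "high")
  )
  expect_error(family_confidence(fams[0, ], asg), "")
  expect_error(
    family_confidence(dplyr::mutate(fams, id = paste0(id, "_x")), asg),
    "assignment"
  )
})

test_that("gene categorization applies whole-word keywords with precedence", {
  expect_equal(
    classify_gene_category(c(
      "site-specific integrase",
      "CRISPR-associated protein Cas9",
      "IS3 family transposase",
      "hypothetical protein",
      "virulence factor", # 'virus' must not match inside 'virulence'
      "prophage integrase with transposase domain", # phage > MGE
      "BREX system phage defence protein", # defense > phage
      ""
    )),
    c(
      "Phage-related", "Defense-related", "Other MGE-related", "other",
      "other", "Phage-related", "Defense-related", "other"
    )
  )
  # defense Pfam list triggers defense regardless of text
  expect_equal(
    classify_gene_category("hypothetical protein",
      accessions = "PF01420",
      defense_pfams = c("PF01420")
    ),
    "Defense-related"
  )
  # every input maps to exactly one category
  set.seed(5)
  anns <- c("phage tail fiber", "recombinase A", "CRISPR", "xyz", "viral coat")
  out <- classify_gene_category(anns)
  expect_equal(length(out), 5)
  expect_true(all(out %in% c(
    "Defense-related", "Phage-related", "Other MGE-related", "other"
  )))
})
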