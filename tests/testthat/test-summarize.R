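fake_consequences <- function() {
  tibble::tribble(
    ~contig, ~pos, ~ref, ~alt, ~vclass, ~gene_id, ~region, ~effect,
    ~aa_ref, ~aa_pos, ~aa_alt, ~n_aa_changed, ~primary,
    "c1", 10L, "A", "T", "SNP", "g1", "CDS", "AAC", "K", 4L, "M", 1L, TRUE,
    "c1", 30L, "C", "G", "SNP", "g1", "CDS", "AAC", "P", 11L, "R", 1L, TRUE,
    "c1", 50L, "G", "GT", "insertion", "g1", "CDS", "frameshift",
    NA, NA, NA, 0L, TRUE,
    "c1", 70L, "T", "C", "SNP", "g2", "intron", "none", NA, NA, NA, 0L, TRUE,
    "c1", 90L, "GA", "G", "deletion", "g2", "CDS", "frameshift",
    NA, NA, NA, 0L, TRUE,
    "c1", 110L, "A", "G", "SNP", "g2", "splice_site", "VCSS",
    NA, NA, NA, 0L, TRUE,
    "c1", 130L, "T", "A", "SNP", "g3", "CDS", "synonymous", "L", 2L, "L", 0L, TRUE,
    "c1", 150L, "C", "A", "SNP", NA, "intergenic", "none", NA, NA, NA, 0L, TRUE
  )
}

test_that("per-gene summaries partition counts by effect", {
  prot <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         protein_length = c(20L, 100L, 50L))
  gs <- per_gene_summary(fake_consequences(), prot)
  expect_equal(nrow(gs), 3) # intergenic row carries no gene
  g1 <- gs[gs$gene_id == "g1", ]
  expect_equal(g1$n_AAC, 2)
  expect_equal(g1$n_insertion, 1)
  expect_equal(g1$n_frameshift, 1)
  expect_equal(g1$degree_of_affection, 10) # 2 of 20 residues
  g2 <- gs[gs$gene_id == "g2", ]
  expect_equal(g2$n_AAC, 0)
  expect_equal(g2$n_deletion, 1)
  expect_equal(g2$n_VCSS, 1)
  # gene with only non-AAC variants still present, zero AAC count
  expect_equal(gs$n_AAC[gs$gene_id == "g3"], 0)
  expect_warning(per_gene_summary(fake_consequences()), "protein length")
})

test_that("AAC binning matches direct filtering, including the tails", {
  gs <- tibble::tibble(gene_id = paste0("g", 1:5),
                       n_AAC = c(3L, 7L, 55L, 120L, 0L))
  bins <- bin_by_aac(gs)
  closed <- bins[!bins$tail, ]
  expect_equal(closed$n, c(2L, 0L, 1L, 1L))
  expect_equal(sum(closed$n), sum(gs$n_AAC >= 1)) # partition of the selection
  tails <- bins[bins$tail, ]
  expect_equal(tails$n, c(sum(gs$n_AAC >= 50), sum(gs$n_AAC >= 100)))
  expect_equal(closed$pct, c(50, 0, 25, 25))
  # empty input: all-zero bins
  empty <- bin_by_aac(gs[0, ])
  expect_true(all(empty$n == 0))
})

test_that("affection classes are exhaustive with the stated boundary closure", {
  gs <- tibble::tibble(degree_of_affection = c(4, 7, 12))
  expect_equal(affection_classes(gs)$n, c(1L, 1L, 1L))
  # boundary membership: 5 in the lowest class, 10 in the middle class
  edge <- tibble::tibble(degree_of_affection = c(5, 10))
  expect_equal(affection_classes(edge)$n, c(1L, 1L, 0L))
  # classes always partition the selection
  set.seed(3)
  rnd <- tibble::tibble(degree_of_affection = runif(40, 0, 20))
  expect_equal(sum(affection_classes(rnd)$n), 40)
})

test_that("family rollup normalizes by size and conserves class tallies", {
  gs <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    n_variants = c(6L, 0L, 4L),
    n_AAC = c(5L, 0L, 2L), n_insertion = c(0L, 0L, 1L),
    n_deletion = c(1L, 0L, 0L), n_frameshift = c(0L, 0L, 1L),
    n_VCSS = c(0L, 0L, 1L)
  )
  fams <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g3"),
                         family = c("GH5_5", "GH5_5", "AA3_2", "CBM13"))
  fr <- family_rollup(gs, fams)
  gh5 <- fr[fr$family == "GH5_5", ]
  expect_equal(gh5$n_genes, 2)
  expect_equal(gh5$variants_per_gene, 3) # 6 variants over 2 members
  expect_equal(gh5$genes_with_variants, 1)
  # multi-family gene contributes to both rollups
  expect_equal(fr$total_variants[fr$family == "AA3_2"], 4)
  expect_equal(fr$total_variants[fr$family == "CBM13"], 4)
  expect_equal(fr$class, c("AA", "CBM", "GH"))
  tally <- family_class_tally(fr)
  expect_equal(sum(tally$n_genes), sum(fr$n_genes))
  # unknown prefixes are grouped and flagged
  expect_warning(
    fr2 <- family_rollup(gs, tibble::tibble(gene_id = "g1", family = "XY9")),
    "unknown family prefix")
  expect_equal(fr2$class, "other")
})

test_that("overview percentages recompute exactly from numerator/denominator pairs", {
  # printed-table arithmetic reproduces bit-exactly under half-up rounding
  expect_equal(share_pct(660566, 686403), 96.24)
  expect_equal(share_pct(25837, 686403), 3.76)
  expect_equal(share_pct(16299, 686403), 2.37)
  expect_equal(share_pct(10027, 12541), 79.95)
  expect_equal(share_pct(929, 12541), 7.41)
  expect_equal(share_pct(1233, 12541), 9.83)
  expect_equal(share_pct(954, 12541), 7.61)
  expect_equal(share_pct(984, 12541), 7.85)
  expect_equal(share_pct(293, 317), 92.43)
  expect_equal(share_pct(17, 317), 5.36)
  expect_equal(share_pct(30, 317), 9.46)
  expect_equal(share_pct(33, 317), 10.41)
  expect_equal(share_pct(20, 317), 6.31)

  ov <- overview_table(fake_consequences(), gene_total = 10,
                       families = tibble::tibble(gene_id = "g1", family = "GH5"),
                       family_total = 2)
  all_rows <- ov[ov$scope == "all", ]
  expect_equal(all_rows$n_variants[all_rows$category == "total"], 8)
  expect_equal(all_rows$n_variants[all_rows$category == "SNP"], 6)
  expect_equal(all_rows$n_variants[all_rows$category == "indel"], 2)
  expect_equal(all_rows$pct_variants[all_rows$category == "SNP"],
               share_pct(6, 8))
  expect_equal(all_rows$n_genes[all_rows$category == "AAC"], 1)
  expect_equal(all_rows$pct_genes[all_rows$category == "AAC"], 10)
  fam_rows <- ov[ov$scope == "family", ]
  expect_equal(fam_rows$n_variants[fam_rows$category == "total"], 3)
  expect_equal(fam_rows$pct_genes[fam_rows$category == "AAC"], 50)
  # zero denominator reports an undefined percentage, not a crash
  ov0 <- overview_table(fake_consequences(), gene_total = 0)
  expect_true(all(is.na(ov0$pct_genes[!is.na(ov0$n_genes)])))
})

test_that("identity and density summaries follow their closed forms", {
  expect_equal(genome_identity(660566, 42500000), 98.4)
  expect_equal(genome_identity(0, 1000), 100)
  expect_error(genome_identity(10, 5), "exceeds")
  expect_equal(variant_density(686403, 42500000), 61.9)
  expect_equal(variant_density(1000, 60000), 60)
  expect_true(is.na(variant_density(0, 1000)))
  # halving the genome halves the spacing
  expect_equal(variant_density(100, 30000), variant_density(100, 60000) / 2)
  # identity formula agrees with direct per-column comparison of an
  # ungapped aligned pair
  a <- "ACGTACGTAC"
  b <- "ACGAACGTAT"
  nsnp <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(genome_identity(nsnp, nchar(a)),
               round_half_up(100 * mean(strsplit(a, "")[[1]] ==
                                          strsplit(b, "")[[1]]), 1))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # worked example: N=20, K=5, n=4, x>=3 -> 155/4845
  expect_equal(hyper_upper_tail(3, 5, 4, 20), 155 / 4845, tolerance = 1e-12)
  expect_equal(hyper_upper_tail(3, 5, 4, 20), oracle_hyper_tail(3, 5, 4, 20),
               tolerance = 1e-12)
  # x = 0: certainty
  expect_equal(hyper_upper_tail(0, 5, 4, 20), 1)
  # drawing the whole population: x = K with probability one
  expect_equal(hyper_upper_tail(5, 5, 20, 20), 1)
  expect_error(hyper_upper_tail(6, 5, 4, 20), "exceeds")

  groups <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g9", "g4"),
                           group = c("kinase", "kinase", "kinase", "kinase",
                                     "F-box"))
  et <- enrichment_test(c("g1", "g2", "g3", "g7"), groups, population_size = 20)
  expect_equal(et$p_value[et$group == "kinase"],
               hyper_upper_tail(3, 4, 4, 20))
  expect_equal(et$overlap[et$group == "F-box"], 0)
  expect_equal(et$p_value[et$group == "F-box"], 1)
  et_adj <- enrichment_test(c("g1", "g2"), groups, 20, p_adjust = TRUE)
  expect_true("p_adjusted" %in% names(et_adj))
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(1.5), 2)
  expect_equal(round_half_up(2.5), 3) # base round() would give 2
  expect_equal(round_half_up(96.235, 2), 96.24)
})
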