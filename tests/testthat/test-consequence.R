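# Gene used throughout: plus-strand, two exons with a GT..AG intron.
# contig: 10C | ATG GCT AAA | GT..(16A)..AG | GAT CCG TAA | 12C
cons_fixture <- function() {
  base <- paste(rep("C", 60), collapse = "")
  s <- base
  substr(s, 11, 19) <- "ATGGCTAAA"
  substr(s, 20, 39) <- paste0("GT", paste(rep("A", 16), collapse = ""), "AG")
  substr(s, 40, 48) <- "GATCCGTAA"
  genome <- make_genome(c(c1 = s))
  model <- one_gene_model("gene1", "c1", "+", iv(c(11, 40), c(19, 48)),
                          iv(c(11, 40), c(19, 48)))
  list(genome = genome, model = model)
}

classify1 <- function(fx, pos, ref, alt, ...) {
  classify_variants(variants_tbl("c1", pos, ref, alt), fx$model, fx$genome, ...)
}

test_that("coding substitutions are typed by codon comparison", {
  fx <- cons_fixture()
  # GCT -> GCA (codon 2, wobble): synonymous
  syn <- classify1(fx, 16, "T", "A")
  expect_equal(syn$region, "CDS")
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$aa_ref, "A")
  expect_equal(syn$aa_alt, "A")
  # GCT -> GAT: Ala -> Asp at protein position 2
  aac <- classify1(fx, 15, "C", "A")
  expect_equal(aac$effect, "AAC")
  expect_equal(aac$aa_ref, "A")
  expect_equal(aac$aa_pos, 2L)
  expect_equal(aac$aa_alt, "D")
  expect_equal(aac$n_aa_changed, 1L)
  # AAA -> TAA at codon 3: stop gained
  sg <- classify1(fx, 17, "A", "T")
  expect_equal(sg$effect, "stop_gained")
  # terminal TAA -> CAA: stop lost
  sl <- classify1(fx, 46, "T", "C")
  expect_equal(sl$effect, "stop_lost")
})

test_that("CDS indels split into frameshift vs in-frame by length mod 3", {
  fx <- cons_fixture()
  del1 <- classify1(fx, 14, "GCT", "G") # 2-base deletion
  expect_equal(del1$effect, "frameshift")
  del3 <- classify1(fx, 13, "GGCT", "G") # 3-base deletion
  expect_equal(del3$effect, "inframe_deletion")
  ins1 <- classify1(fx, 14, "G", "GA")
  expect_equal(ins1$effect, "frameshift")
  ins3 <- classify1(fx, 14, "G", "GAAA") # 3-base insertion: no frameshift
  expect_equal(ins3$effect, "inframe_insertion")
})

test_that("the consensus splice-site window defines VCSS, with precedence over intron", {
  fx <- cons_fixture()
  # intron is 20..39; consensus positions 20,21,38,39
  contig <- as.character(fx$genome[[1]])
  for (p in c(20, 21, 38, 39)) {
    refb <- substr(contig, p, p)
    v <- classify1(fx, p, refb, ifelse(refb == "C", "G", "C"))
    expect_equal(v$region, "splice_site")
    expect_equal(v$effect, "VCSS")
  }
  # intron interior stays intronic
  mid <- classify1(fx, 25, "A", "G")
  expect_equal(mid$region, "intron")
  expect_equal(mid$effect, "none")
  # a deletion reaching into the consensus from the exon is VCSS
  span <- classify1(fx, 18, "AAG", "A") # deletes 19 (exon) and 20 (G of GT)
  expect_equal(span$effect, "VCSS")
  # window width is configurable
  wide <- classify_variants(variants_tbl("c1", 23, "A", "G"), fx$model,
                            fx$genome, splice_window = 4)
  expect_equal(wide$effect, "VCSS")
})

test_that("UTR and intergenic variants are placed by position and strand", {
  base <- paste(rep("C", 60), collapse = "")
  s <- base
  substr(s, 21, 29) <- "ATGAAATAA"
  genome <- make_genome(c(c1 = s))
  # exon 16..34 wider than CDS 21..29: flanks are UTR
  plus <- one_gene_model("gp", "c1", "+", iv(16, 34), iv(21, 29))
  five <- classify_variants(variants_tbl("c1", 18, "C", "G"), plus, genome)
  expect_equal(five$region, "five_prime_UTR")
  three <- classify_variants(variants_tbl("c1", 32, "C", "G"), plus, genome)
  expect_equal(three$region, "three_prime_UTR")
  # same geometry on the minus strand swaps the labels
  s2 <- base
  substr(s2, 21, 29) <- "TTATTTCAT" # revcomp of ATGAAATAA
  minus <- one_gene_model("gm", "c1", "-", iv(16, 34), iv(21, 29))
  g2 <- make_genome(c(c1 = s2))
  five_m <- classify_variants(variants_tbl("c1", 32, "C", "G"), minus, g2)
  expect_equal(five_m$region, "five_prime_UTR")
  # outside any gene
  inter <- classify_variants(variants_tbl("c1", 5, "C", "G"), plus, genome)
  expect_equal(inter$region, "intergenic")
  expect_true(is.na(inter$gene_id))
})

test_that("MNVs count one AAC per changed codon", {
  fx <- cons_fixture()
  # GCT AAA -> GAT GAA: block substitution over codons 2-3 (positions 15..17)
  mnv <- classify1(fx, 15, "CTA", "ATG")
  expect_equal(mnv$vclass, "MNV")
  expect_equal(mnv$effect, "AAC")
  expect_equal(mnv$n_aa_changed, 2L)
  # block substitution with no protein change
  syn <- classify1(fx, 16, "TA", "CA") # GCT->GCC (syn), AAA->AAA
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$n_aa_changed, 0L)
})

test_that("classification agrees with the rebuild-and-diff oracle on small genes", {
  fx <- cons_fixture()
  set.seed(42)
  contig <- as.character(fx$genome[[1]])
  cds_pos <- c(11:19, 40:48)
  for (p in sample(cds_pos, 12, replace = TRUE)) {
    refb <- substr(contig, p, p)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    got <- classify1(fx, p, refb, altb)
    want <- oracle_sub_effect(fx$genome, fx$model, p, refb, altb)
    expect_equal(got$effect, want$effect,
                 info = sprintf("SNP %s>%s at %d", refb, altb, p))
  }
  # and on a minus-strand mirror of the same construction
  B <- nchar(contig)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", contig), "")[[1]]), collapse = "")
  mirror_iv <- function(df) {
    out <- data.frame(start = B - df$end + 1, end = B - df$start + 1)
    out[order(out$start), ]
  }
  g_rc <- make_genome(c(c1 = rc))
  m_rc <- one_gene_model("gene1", "c1", "-", mirror_iv(fx$model$exons[[1]]),
                         mirror_iv(fx$model$cds[[1]]))
  for (p in sample(cds_pos, 8, replace = TRUE)) {
    refb <- substr(contig, p, p)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    plus_eff <- classify1(fx, p, refb, altb)$effect
    pm <- B - p + 1
    ref_m <- substr(rc, pm, pm)
    alt_m <- chartr("ACGT", "TGCA", altb)
    minus_eff <- classify_variants(variants_tbl("c1", pm, ref_m, alt_m),
                                   m_rc, g_rc)$effect
    expect_equal(minus_eff, plus_eff,
                 info = sprintf("mirrored SNP at %d", p))
  }
})

test_that("primary records conserve totals and respect the severity order", {
  cfg <- sim_config(seed = 21, n_genes = 10, contig_length = 20000,
                    family_spec = c(GH5 = 2), group_spec = c(kinase = 2),
                    splice_site_variants = 4)
  sim <- simulate_strain_pair(cfg)
  v <- sim$derived$truth[, c("contig", "pos", "ref", "alt", "vclass")]
  cc <- classify_variants(v, sim$reference$models, sim$reference$genome)
  pri <- dplyr::filter(cc, primary)
  # exactly one primary row per variant
  expect_equal(nrow(pri), nrow(v))
  # region counts over primary records partition the variant total
  expect_equal(sum(table(pri$region)), nrow(v))
  # SNPs never produce frameshifts; indels never produce AAC/synonymous
  expect_false(any(cc$vclass == "SNP" & cc$effect == "frameshift"))
  expect_false(any(cc$vclass %in% c("insertion", "deletion") &
                     cc$effect %in% c("AAC", "synonymous")))
  # empty input yields an empty table
  expect_equal(nrow(classify_variants(v[0, ], sim$reference$models,
                                      sim$reference$genome)), 0)
})
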