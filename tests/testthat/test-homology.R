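test_that("local alignment reproduces worked examples and is symmetric", {
  sch <- scoring_scheme("nucleotide", match = 1, mismatch = -1,
                        gap_open = 2, gap_extend = 1)
  # identical sequences: score = length, identity 100
  ident <- align_local("ACGTACGT", "ACGTACGT", sch)
  expect_equal(ident$score, 8)
  expect_equal(ident$identity, 100)
  # one terminal mismatch: the optimal local alignment drops it
  expect_equal(align_local("ACGT", "ACGA", sch)$score, 3)
  # disjoint alphabets: empty alignment, no hit
  none <- align_local("AAAA", "CCCC", sch)
  expect_equal(none$score, 0)
  expect_equal(none$aligned_length, 0)
  # symmetry of the score under argument swap
  set.seed(1)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
    expect_equal(align_local(a, b, sch)$score, align_local(b, a, sch)$score)
  }
})

test_that("alignment scores match the brute-force oracle on short panels", {
  sch <- scoring_scheme("nucleotide", match = 1, mismatch = -1,
                        gap_open = 2, gap_extend = 1)
  set.seed(7)
  panel <- c("ACGT", "ACGA", "AAAA", "CCCC", "ACGTACGTACGT", "TTACGG",
             "GATTACA", "GCGCGC",
             replicate(6, paste(sample(c("A", "C", "G", "T"),
                                       sample(3:12, 1), TRUE), collapse = "")))
  pairs <- utils::combn(seq_along(panel), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- panel[pairs[1, k]]; b <- panel[pairs[2, k]]
    expect_equal(align_local(a, b, sch)$score, oracle_sw(a, b, sch),
                 info = paste(a, b))
  }
  # also for protein scoring
  sp <- scoring_scheme("protein")
  prot <- c("MKVLA", "MKVIA", "WWWW", "ACDEFG", "MKV")
  pp <- utils::combn(seq_along(prot), 2)
  for (k in seq_len(ncol(pp))) {
    a <- prot[pp[1, k]]; b <- prot[pp[2, k]]
    expect_equal(align_local(a, b, sp)$score, oracle_sw(a, b, sp),
                 info = paste(a, b))
  }
})

test_that("e-values follow the Karlin-Altschul form", {
  sch <- scoring_scheme("protein", karlin_lambda = 0.267, karlin_K = 0.041)
  # direct formula evaluation
  expect_equal(hit_evalue(50, 100, 100, sch),
               0.041 * 100 * 100 * exp(-0.267 * 50))
  # monotone decreasing in score, vanishing at large S
  e <- hit_evalue(c(10, 20, 40, 400), 100, 100, sch)
  expect_true(all(diff(e) < 0))
  expect_lt(e[4], 1e-40)
  # doubling the database length doubles E at fixed score
  expect_equal(hit_evalue(30, 100, 200, sch), 2 * hit_evalue(30, 100, 100, sch))
  expect_error(hit_evalue(10, 0, 100, sch), "positive")
})

test_that("best hits rank by score, e-value, identity, then target id", {
  sch <- scoring_scheme("nucleotide")
  q <- c(q1 = "ACGTACGTACGTACGTACGT")
  targets <- c(perfect = "ACGTACGTACGTACGTACGT",
               off = "TTTTTTTTTTGGGGGGGG")
  bh <- best_hits(q, targets, sch, e_threshold = 1)
  expect_equal(bh$target_id, "perfect")
  expect_equal(bh$identity, 100)

  # no target passes a strict threshold -> hitless query
  none <- best_hits(c(q1 = "ACGT"), c(t1 = "ACGT"), sch, e_threshold = 1e-30)
  expect_true(is.na(none$target_id))

  # equal scores: higher identity wins (gapped vs mismatched variant)
  q2 <- c(q1 = "AAAACCCCGGGGTTTTAAAACCCC")
  mismatched <- "AAAACCCCGGGGTTTTAAAACCTT"  # two terminal mismatches: trimmed
  gapped <- "AAAACCCCGGGGTTAAAACCCC"        # two-base deletion
  bh2 <- best_hits(q2, c(a_mm = mismatched, b_gap = gapped), sch,
                   e_threshold = 1)
  sc <- purrr::map_dbl(c(a_mm = mismatched, b_gap = gapped),
                       ~ align_local(q2, .x, sch)$score)
  if (sc[["a_mm"]] == sc[["b_gap"]]) {
    ids <- purrr::map_dbl(c(a_mm = mismatched, b_gap = gapped),
                          ~ align_local(q2, .x, sch)$identity)
    expect_equal(bh2$target_id, names(which.max(ids)))
  } else {
    expect_equal(bh2$target_id, names(which.max(sc)))
  }
})

test_that("reciprocal best hits satisfy identity and symmetry properties", {
  cfg <- sim_config(seed = 17, n_genes = 8, contig_length = 15000,
                    family_spec = c(GH5 = 2), group_spec = c(kinase = 2))
  r <- simulate_reference(cfg)
  cds <- spliced_cds(r$models, r$genome)
  setA <- setNames(cds$cds_seq, cds$gene_id)
  # RBH of a set against itself is the identity pairing
  self <- reciprocal_best_hits(setA, setA)
  expect_equal(nrow(self), length(setA))
  expect_equal(self$id_a, self$id_b)
  # symmetry under swapping inputs; pair count bounded by the smaller set
  setB <- setNames(cds$cds_seq[1:5], paste0("b_", cds$gene_id[1:5]))
  ab <- reciprocal_best_hits(setA, setB)
  ba <- reciprocal_best_hits(setB, setA)
  expect_lte(nrow(ab), 5)
  expect_setequal(paste(ab$id_a, ab$id_b), paste(ba$id_b, ba$id_a))
  # one-sided best hit without reciprocity yields no pair
  dup <- c(setA[1:2], dup1 = unname(setA[1]))
  one <- reciprocal_best_hits(dup[2], dup[c(1, 3)])
  expect_lte(nrow(one), 1)
})

test_that("two-stage presence calling separates CDS, genome-only and absent genes", {
  cfg <- sim_config(seed = 19, n_genes = 10, contig_length = 20000,
                    family_spec = c(GH5 = 2), group_spec = c(kinase = 2),
                    deleted_gene_ids = "g007")
  sim <- simulate_strain_pair(cfg)
  cds <- spliced_cds(sim$reference$models, sim$reference$genome)
  queries <- setNames(cds$cds_seq, cds$gene_id)
  # drop one surviving gene from the target CDS set: it remains in the genome
  target_cds <- sim$derived$derived_cds
  target_cds <- target_cds[setdiff(names(target_cds), "g003")]
  pa <- presence_absence(queries, target_cds, sim$derived$genome)
  expect_equal(pa$status[pa$gene_id == "g007"], "absent")
  expect_equal(pa$status[pa$gene_id == "g003"], "present_in_genome_only")
  others <- pa$gene_id[!pa$gene_id %in% c("g003", "g007")]
  expect_true(all(pa$status[pa$gene_id %in% others] == "present_in_cds"))
})
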