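#' Simulation configuration
#'
#' Parameters for the synthetic strain pair: a multi-contig reference with
#' intron-containing genes on both strands (canonical GT..AG splice sites),
#' a skewed family table, and a derived strain carrying SNPs and short indels
#' at configurable rates plus optional whole-gene deletions.
#'
#' Default rates mirror the study conditions the simulator emulates: one
#' variant per 60 bp split 96% SNP : 4% indel, i.e. `snp_rate = 0.96/60` and
#' `indel_rate = 0.04/60` per basepair.
#'
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param n_contigs,contig_length genome shape (contigs all `contig_length` bp).
#' @param n_genes number of genes, packed with intergenic spacers >= 20 bp.
#' @param introns_per_gene integer range `c(lo, hi)`.
#' @param exon_length,intron_length integer ranges in bp (`intron_length[1]`
#'   must be >= 8 so the GT/AG consensus plus interior exists).
#' @param family_spec named integer vector: family label -> member count.
#' @param group_spec named integer vector: functional group -> member count.
#' @param snp_rate,indel_rate per-bp probabilities.
#' @param indel_length_weights sampling weights for indel lengths 1..6.
#' @param splice_site_variants number of SNPs injected explicitly into
#'   consensus splice-site dinucleotides (random placement rarely hits the
#'   4-bp window at toy scale).
#' @param deleted_gene_ids genes excised wholesale (with flanks) from the
#'   derived strain.
#' @param min_spacing minimum distance between injected variants (keeps
#'   consequences independent).
#' @param boundary_margin variants are kept this far from every region
#'   boundary so each one's truth label is unambiguous.
#' @param deletion_flank bp removed on each side of a deleted gene.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 1L,
                       contig_length = 100000L,
                       n_genes = 50L,
                       introns_per_gene = c(0L, 3L),
                       exon_length = c(60L, 300L),
                       intron_length = c(20L, 80L),
                       family_spec = c(AA3_2 = 5L, GH5_5 = 4L, GH3 = 3L,
                                       CBM13 = 2L, GT2 = 2L),
                       group_spec = c("F-box" = 6L, kinase = 8L),
                       snp_rate = 0.96 / 60,
                       indel_rate = 0.04 / 60,
                       indel_length_weights = rep(1, 6),
                       splice_site_variants = 10L,
                       deleted_gene_ids = character(),
                       min_spacing = 10L,
                       boundary_margin = 10L,
                       deletion_flank = 10L) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
    introns_per_gene = as.integer(introns_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    family_spec = family_spec, group_spec = group_spec,
    snp_rate = snp_rate, indel_rate = indel_rate,
    indel_length_weights = indel_length_weights,
    splice_site_variants = as.integer(splice_site_variants),
    deleted_gene_ids = deleted_gene_ids,
    min_spacing = as.integer(min_spacing),
    boundary_margin = as.integer(boundary_margin),
    deletion_flank = as.integer(deletion_flank)
  )
  if (cfg$snp_rate < 0 || cfg$snp_rate > 1 || cfg$indel_rate < 0 || cfg$indel_rate > 1) {
    stopf("rates must lie in [0, 1]")
  }
  if (cfg$intron_length[1] < 8L) stopf("intron_length must be >= 8")
  if (sum(cfg$family_spec) > cfg$n_genes || sum(cfg$group_spec) > cfg$n_genes) {
    stopf("family/group member counts exceed n_genes")
  }
  class(cfg) <- "sim_config"
  cfg
}

# uniform integer in [lo, hi], safe for lo == hi (unlike sample())
rint <- function(lo, hi) lo + floor(stats::runif(1) * (hi - lo + 1))

rand_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

#' Generate a synthetic reference strain
#'
#' Builds the reference genome, complete gene models (ATG start, terminal
#' stop, spliced CDS length divisible by 3, introns flanked GT..AG), a family
#' table and a functional-group table. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   ([gene_models] tibble), `families`, `groups` (tibbles), `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- purrr::map(seq_len(config$n_genes), function(j) {
      build_sim_gene(sprintf("g%03d", j), config)
    })
    # pack genes onto contigs, round-robin
    contig_of <- rep(seq_len(config$n_contigs), length.out = config$n_genes)
    contig_seqs <- character(config$n_contigs)
    placed <- list()
    for (ci in seq_len(config$n_contigs)) {
      mine <- which(contig_of == ci)
      cursor <- 1L
      parts <- character()
      for (j in mine) {
        spacer <- rint(20L, 200L)
        parts <- c(parts, rand_dna(spacer))
        cursor <- cursor + spacer
        g <- genes[[j]]
        g$offset <- cursor
        g$contig <- sprintf("ctg%02d", ci)
        placed[[length(placed) + 1L]] <- g
        parts <- c(parts, g$block)
        cursor <- cursor + nchar(g$block)
      }
      tail_len <- config$contig_length - (cursor - 1L)
      if (tail_len < 20L) {
        stopf("genes do not fit on contig %d (need %d bp, have %d)",
              ci, cursor - 1L + 20L, config$contig_length)
      }
      parts <- c(parts, rand_dna(tail_len))
      contig_seqs[ci] <- paste(parts, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(setNames(contig_seqs,
                                                sprintf("ctg%02d", seq_len(config$n_contigs))))

    models <- dplyr::bind_rows(purrr::map(placed, function(g) {
      iv <- g$exons_local
      abs_iv <- data.frame(start = iv$start + g$offset - 1L,
                           end = iv$end + g$offset - 1L)
      cd <- add_phases(abs_iv, g$strand)
      tibble::tibble(gene_id = g$gene_id, contig = g$contig, strand = g$strand,
                     exons = list(abs_iv), cds = list(cd))
    }))
    models <- gene_models(models$gene_id, models$contig, models$strand,
                          models$exons, models$cds, complete = TRUE)
    validate_gene_models(models, genome)

    ids <- models$gene_id
    pool <- sample(ids)
    fam_rows <- purrr::imap(as.list(config$family_spec), function(n, fam) {
      take <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      tibble::tibble(gene_id = take, family = fam)
    })
    families <- dplyr::bind_rows(fam_rows) |> dplyr::arrange(.data$gene_id)
    grp_pool <- sample(ids)
    grp_rows <- purrr::imap(as.list(config$group_spec), function(n, grp) {
      take <- grp_pool[seq_len(n)]
      grp_pool <<- grp_pool[-seq_len(n)]
      tibble::tibble(gene_id = take, group = grp)
    })
    groups <- dplyr::bind_rows(grp_rows) |> dplyr::arrange(.data$gene_id)

    list(genome = genome, models = models, families = families,
         groups = groups, config = config)
  })
}

# One gene: random coding sequence split into exons with GT..AG introns,
# returned as a genomic block (already reverse-complemented for minus strand)
# plus exon intervals local to the block (1-based, genomic order).
build_sim_gene <- function(gene_id, config) {
  n_introns <- rint(config$introns_per_gene[1], config$introns_per_gene[2])
  n_exons <- n_introns + 1L
  exon_len <- purrr::map_int(seq_len(n_exons), function(i) {
    as.integer(rint(config$exon_length[1], config$exon_length[2]))
  })
  total <- sum(exon_len)
  # trim last exon so the CDS is a whole number of codons (>= ATG + 1 + stop)
  exon_len[n_exons] <- exon_len[n_exons] - total %% 3L
  total <- sum(exon_len)
  n_codons <- total %/% 3L
  cds_seq <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1))
  intron_seq <- purrr::map_chr(seq_len(n_introns), function(i) {
    len <- rint(config$intron_length[1], config$intron_length[2])
    paste0("GT", rand_dna(len - 4L), "AG")
  })
  cuts <- cumsum(exon_len)
  sense_parts <- character()
  sense_exons <- data.frame(start = integer(), end = integer())
  pos <- 0L
  for (i in seq_len(n_exons)) {
    a <- if (i == 1) 1L else cuts[i - 1] + 1L
    b <- cuts[i]
    sense_parts <- c(sense_parts, substr(cds_seq, a, b))
    sense_exons <- rbind(sense_exons,
                         data.frame(start = pos + 1L, end = pos + (b - a + 1L)))
    pos <- pos + (b - a + 1L)
    if (i < n_exons) {
      sense_parts <- c(sense_parts, intron_seq[i])
      pos <- pos + nchar(intron_seq[i])
    }
  }
  block <- paste(sense_parts, collapse = "")
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") {
    B <- nchar(block)
    block <- revcomp_chr(block)
    sense_exons <- data.frame(start = B - sense_exons$end + 1L,
                              end = B - sense_exons$start + 1L)
    sense_exons <- sense_exons[order(sense_exons$start), , drop = FALSE]
  }
  list(gene_id = gene_id, strand = strand, block = block,
       exons_local = sense_exons)
}

add_phases <- function(cd, strand) {
  ord <- if (strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
  phase <- integer(nrow(cd))
  running <- 0L
  for (j in ord) {
    phase[j] <- (3L - (running %% 3L)) %% 3L
    running <- running + (cd$end[j] - cd$start[j] + 1L)
  }
  cd$phase <- phase
  cd
}

#' Derive a mutated strain with truth-labelled variants
#'
#' Injects SNPs and short indels at the configured per-bp rates, explicit
#' splice-site SNPs, and whole-gene deletions, then applies everything to
#' produce the derived genome. Every injected variant is recorded with a
#' truth label computed from its placement: substitution effects by rebuilding
#' the mutant coding sequence and diffing the full translated proteins
#' (independent of the classification engine), indel effects from the net
#' length change, splice-site hits from the injection site itself.
#'
#' Injection sites keep `min_spacing` bp apart and `boundary_margin` bp clear
#' of region boundaries, and indel alleles are generated already
#' left-normalized, so truth labels survive the reader's normalization pass.
#'
#' @param reference result of [simulate_reference()].
#' @param config optional [sim_config()]; defaults to the reference's own.
#' @return list with `genome` (mutated [Biostrings::DNAStringSet]), `truth`
#'   (tibble of variants with `region`/`effect`/`gene_id` truth columns),
#'   `deleted_genes`, `derived_cds` ([Biostrings::DNAStringSet] of surviving
#'   genes' coding sequences as present in the derived strain).
#' @export
derive_strain <- function(reference, config = reference$config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- reference$genome
  models <- reference$models
  with_seed(config$seed + 1L, {
    ann <- build_contig_annotation(genome, models, config)
    truth <- list()

    # explicit splice-site SNPs
    sp_sites <- pick_splice_sites(models, config)
    for (k in seq_len(nrow(sp_sites))) {
      p <- sp_sites$pos[k]; contig <- sp_sites$contig[k]
      refb <- substr(ann[[contig]]$seq, p, p)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        contig = contig, pos = p, ref = refb, alt = altb, vclass = "SNP",
        gene_id = sp_sites$gene_id[k], region = "splice_site", effect = "VCSS"
      )
      ann[[contig]]$blocked <- block_window(ann[[contig]]$blocked, p, config$min_spacing)
    }

    total_len <- genome_size(genome)
    n_snp <- stats::rbinom(1, total_len, config$snp_rate)
    n_indel <- stats::rbinom(1, total_len, config$indel_rate)

    sites <- draw_sites(ann, n_indel + n_snp, config)
    indel_sites <- utils::head(sites, n_indel)
    snp_sites <- sites[seq_len(nrow(sites)) > n_indel, , drop = FALSE]

    gene_cache <- build_gene_cache(models, genome)
    for (k in seq_len(nrow(indel_sites))) {
      contig <- indel_sites$contig[k]; p <- indel_sites$pos[k]
      truth[[length(truth) + 1L]] <- make_indel(ann[[contig]], contig, p, config)
    }
    for (k in seq_len(nrow(snp_sites))) {
      contig <- snp_sites$contig[k]; p <- snp_sites$pos[k]
      truth[[length(truth) + 1L]] <- make_snp(ann[[contig]], contig, p, gene_cache)
    }
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth)) {
      truth <- dplyr::arrange(truth, .data$contig, .data$pos)
    } else {
      truth <- tibble::tibble(contig = character(), pos = integer(),
                              ref = character(), alt = character(),
                              vclass = character(), gene_id = character(),
                              region = character(), effect = character())
    }

    derived <- apply_variants(genome, models, truth, config)
    list(genome = derived$genome, truth = truth,
         deleted_genes = config$deleted_gene_ids,
         derived_cds = derived$derived_cds)
  })
}

block_window <- function(blocked, p, w) {
  n <- length(blocked)
  blocked[max(1L, p - w):min(n, p + w)] <- TRUE
  blocked
}

# Per-contig lookup vectors: region/gene at every position, plus eligibility
# masks for variant placement.
build_contig_annotation <- function(genome, models, config) {
  m <- config$boundary_margin
  ann <- purrr::map(names(genome), function(contig) {
    n <- length(genome[[contig]])
    list(seq = as.character(genome[[contig]]),
         region = rep("intergenic", n),
         gene = rep(NA_character_, n),
         eligible = rep(TRUE, n),
         blocked = rep(FALSE, n))
  })
  names(ann) <- names(genome)
  for (i in seq_len(nrow(models))) {
    contig <- models$contig[i]
    g <- models$gene_id[i]
    ex <- models$exons[[i]]
    a <- ann[[contig]]
    span <- c(min(ex$start), max(ex$end))
    boundaries <- unique(c(ex$start, ex$end))
    for (j in seq_len(nrow(ex))) {
      a$region[ex$start[j]:ex$end[j]] <- "CDS"
      a$gene[ex$start[j]:ex$end[j]] <- g
    }
    if (nrow(ex) > 1) {
      for (j in seq_len(nrow(ex) - 1)) {
        is_ <- ex$end[j] + 1L; ie <- ex$start[j + 1] - 1L
        a$region[is_:ie] <- "intron"
        a$gene[is_:ie] <- g
        a$region[c(is_, is_ + 1L, ie - 1L, ie)] <- "splice_site"
        boundaries <- c(boundaries, is_, ie)
      }
    }
    for (b in unique(boundaries)) {
      a$eligible[max(1L, b - m):min(length(a$eligible), b + m)] <- FALSE
    }
    if (g %in% config$deleted_gene_ids) {
      lo <- max(1L, span[1] - config$deletion_flank - m)
      hi <- min(length(a$eligible), span[2] + config$deletion_flank + m)
      a$eligible[lo:hi] <- FALSE
    }
    ann[[contig]] <- a
  }
  for (contig in names(ann)) {
    n <- length(ann[[contig]]$eligible)
    ann[[contig]]$eligible[c(seq_len(min(m, n)), seq(max(1L, n - m + 1L), n))] <- FALSE
    ann[[contig]]$eligible[ann[[contig]]$region == "splice_site"] <- FALSE
  }
  ann
}

pick_splice_sites <- function(models, config) {
  cand <- list()
  for (i in seq_len(nrow(models))) {
    if (models$gene_id[i] %in% config$deleted_gene_ids) next
    ex <- models$exons[[i]]
    if (nrow(ex) < 2) next
    for (j in seq_len(nrow(ex) - 1)) {
      is_ <- ex$end[j] + 1L; ie <- ex$start[j + 1] - 1L
      cand[[length(cand) + 1L]] <- tibble::tibble(
        gene_id = models$gene_id[i], contig = models$contig[i],
        pos = c(is_, is_ + 1L, ie - 1L, ie)
      )
    }
  }
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0 || config$splice_site_variants == 0) {
    return(tibble::tibble(gene_id = character(), contig = character(), pos = integer()))
  }
  take <- min(config$splice_site_variants, nrow(cand))
  cand[sample.int(nrow(cand), take), , drop = FALSE]
}

# Draw up to n placement sites from the eligible pool, greedily enforcing the
# spacing constraint.
draw_sites <- function(ann, n, config) {
  pool <- dplyr::bind_rows(purrr::imap(ann, function(a, contig) {
    tibble::tibble(contig = contig, pos = which(a$eligible & !a$blocked))
  }))
  if (nrow(pool) == 0 || n == 0) {
    return(tibble::tibble(contig = character(), pos = integer()))
  }
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  blocked <- purrr::map(ann, "blocked")
  keep <- logical(nrow(pool))
  taken <- 0L
  for (k in seq_len(nrow(pool))) {
    if (taken == n) break
    contig <- pool$contig[k]; p <- pool$pos[k]
    if (blocked[[contig]][p]) next
    keep[k] <- TRUE
    taken <- taken + 1L
    blocked[[contig]] <- block_window(blocked[[contig]], p, config$min_spacing)
  }
  pool[keep, , drop = FALSE]
}

make_snp <- function(a, contig, p, gene_cache) {
  refb <- substr(a$seq, p, p)
  altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
  region <- a$region[p]
  g <- a$gene[p]
  effect <- "none"
  if (region == "CDS") {
    effect <- snp_truth_label(gene_cache[[g]], p, altb)
  }
  tibble::tibble(contig = contig, pos = p, ref = refb, alt = altb,
                 vclass = "SNP", gene_id = g, region = region, effect = effect)
}

# Plain-R translation and reverse complement: the truth labels must come from
# machinery independent of the classification engine (which goes through
# Biostrings), and these run thousands of times per simulation.
translate_plain <- function(seq) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

revcomp_plain <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# Per-gene reference pieces and protein, cached once per derive_strain run.
build_gene_cache <- function(models, genome) {
  cache <- purrr::map(seq_len(nrow(models)), function(i) {
    cd <- models$cds[[i]]
    contig_seq <- as.character(genome[[models$contig[i]]])
    pieces <- purrr::map2_chr(cd$start, cd$end,
                              function(s, e) substr(contig_seq, s, e))
    seq <- paste(pieces, collapse = "")
    if (models$strand[i] == "-") seq <- revcomp_plain(seq)
    list(cd = cd, strand = models$strand[i], pieces = pieces,
         ref_protein = translate_plain(seq))
  })
  setNames(cache, models$gene_id)
}

# Truth label for a coding substitution, by rebuilding the entire mutant
# spliced CDS from the exon pieces and diffing the full translations.
# Deliberately independent of the engine's coordinate-map/codon path.
snp_truth_label <- function(gc, p, altb) {
  pieces <- gc$pieces
  hit <- which(gc$cd$start <= p & p <= gc$cd$end)
  off <- p - gc$cd$start[hit] + 1L
  substr(pieces[hit], off, off) <- altb
  mut <- paste(pieces, collapse = "")
  if (gc$strand == "-") mut <- revcomp_plain(mut)
  pm <- translate_plain(mut)
  d <- which(gc$ref_protein != pm)
  if (length(d) == 0) return("synonymous")
  if (pm[d[1]] == "*") return("stop_gained")
  if (gc$ref_protein[d[1]] == "*") return("stop_lost")
  "AAC"
}

make_indel <- function(a, contig, p, config) {
  region <- a$region[p]
  g <- a$gene[p]
  is_ins <- stats::runif(1) < 0.5
  lens <- sample(1:6, 6, prob = config$indel_length_weights)
  anchor <- substr(a$seq, p, p)
  if (is_ins) {
    L <- lens[1]
    last <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1)
    ins <- if (L > 1) paste0(rand_dna(L - 1L), last) else last
    ref <- anchor
    alt <- paste0(anchor, ins)
    vclass <- "insertion"
  } else {
    # pick a deletion length whose final deleted base differs from the anchor
    # (the record is then already left-normalized)
    L <- NA_integer_
    for (cand in lens) {
      if (substr(a$seq, p + cand, p + cand) != anchor) { L <- cand; break }
    }
    if (is.na(L)) { # homopolymer context; fall back to an insertion
      L <- lens[1]
      last <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1)
      ins <- if (L > 1) paste0(rand_dna(L - 1L), last) else last
      ref <- anchor
      alt <- paste0(anchor, ins)
      vclass <- "insertion"
      is_ins <- TRUE
    } else {
      ref <- substr(a$seq, p, p + L)
      alt <- anchor
      vclass <- "deletion"
    }
  }
  effect <- "none"
  if (region == "CDS") {
    if (L %% 3L != 0L) {
      effect <- "frameshift"
    } else {
      effect <- if (is_ins) "inframe_insertion" else "inframe_deletion"
    }
  }
  tibble::tibble(contig = contig, pos = p, ref = ref, alt = alt,
                 vclass = vclass, gene_id = g, region = region, effect = effect)
}

# Apply the injected variants (and whole-gene excisions) to the reference,
# tracking the coordinate shift so surviving genes' derived coding sequences
# can be extracted exactly.
apply_variants <- function(genome, models, truth, config) {
  out_seqs <- character(length(genome))
  names(out_seqs) <- names(genome)
  derived_cds <- list()
  for (contig in names(genome)) {
    chars <- strsplit(as.character(genome[[contig]]), "")[[1]]
    n <- length(chars)
    keep <- rep(TRUE, n)
    ins <- character(n)
    tv <- truth[truth$contig == contig, , drop = FALSE]
    for (k in seq_len(nrow(tv))) {
      p <- tv$pos[k]
      if (tv$vclass[k] == "SNP") {
        chars[p] <- tv$alt[k]
      } else if (tv$vclass[k] == "deletion") {
        L <- nchar(tv$ref[k]) - 1L
        keep[(p + 1L):(p + L)] <- FALSE
      } else {
        ins[p] <- substr(tv$alt[k], 2L, nchar(tv$alt[k]))
      }
    }
    # position of original base p in the mutated contig
    cum_new <- cumsum(ifelse(keep, 1L, 0L) + nchar(ins))
    new_pos_of <- function(p) if (p == 1L) 1L else cum_new[p - 1L] + 1L

    mine <- which(models$contig == contig)
    for (i in mine) {
      g <- models$gene_id[i]
      if (g %in% config$deleted_gene_ids) next
      cd <- models$cds[[i]]
      new_iv <- data.frame(start = purrr::map_int(cd$start, ~ as.integer(new_pos_of(.x))),
                           end = purrr::map_int(cd$end, ~ as.integer(cum_new[.x])))
      derived_cds[[g]] <- list(contig = contig, iv = new_iv,
                               strand = models$strand[i])
    }
    # whole-gene excisions (in mutated coordinates), applied by masking
    mut_parts <- chars
    mut_parts[!keep] <- ""
    mut_parts <- paste0(mut_parts, ins)
    mut <- paste(mut_parts, collapse = "")
    for (i in mine) {
      g <- models$gene_id[i]
      if (!g %in% config$deleted_gene_ids) next
      ex <- models$exons[[i]]
      lo <- max(1L, min(ex$start) - config$deletion_flank)
      hi <- min(n, max(ex$end) + config$deletion_flank)
      # no variants fall in deleted spans, so reference offsets map directly
      cut <- c(new_pos_of(lo), cum_new[hi])
      mut <- paste0(substr(mut, 1L, cut[1] - 1L),
                    strrep("#", cut[2] - cut[1] + 1L),
                    substr(mut, cut[2] + 1L, nchar(mut)))
    }
    # resolve derived CDS before removing excision placeholders
    for (g in names(derived_cds)) {
      dc <- derived_cds[[g]]
      if (is.character(dc)) next
      if (dc$contig != contig) next
      seq <- paste(purrr::map2_chr(dc$iv$start, dc$iv$end,
                                   function(s, e) substr(mut, s, e)), collapse = "")
      if (dc$strand == "-") seq <- revcomp_chr(seq)
      derived_cds[[g]] <- seq
    }
    out_seqs[contig] <- gsub("#", "", mut, fixed = TRUE)
  }
  list(
    genome = Biostrings::DNAStringSet(out_seqs),
    derived_cds = Biostrings::DNAStringSet(unlist(derived_cds))
  )
}

#' Simulate a reference/derived strain pair
#'
#' Convenience wrapper running [simulate_reference()] then [derive_strain()].
#'
#' @param config a [sim_config()].
#' @return list with `reference`, `derived`, `config`.
#' @export
simulate_strain_pair <- function(config = sim_config()) {
  reference <- simulate_reference(config)
  derived <- derive_strain(reference, config)
  list(reference = reference, derived = derived, config = config)
}

#' Write a simulated strain pair to disk
#'
#' Emits `reference.fasta`, `genes.gff3`, `families.tsv`, `groups.tsv`,
#' `derived.fasta`, `derived_cds.fasta`, `truth.vcf` and `truth_labels.tsv`
#' under `dir` — everything needed to run the pipeline from files.
#'
#' @param sim result of [simulate_strain_pair()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- sim$reference
  write_genome(ref$genome, file.path(dir, "reference.fasta"))
  write_gene_models(ref$models, file.path(dir, "genes.gff3"))
  utils::write.table(ref$families, file.path(dir, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$groups, file.path(dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genome(sim$derived$genome, file.path(dir, "derived.fasta"))
  write_genome(sim$derived$derived_cds, file.path(dir, "derived_cds.fasta"))
  write_variants_vcf(sim$derived$truth[, c("contig", "pos", "ref", "alt")],
                     file.path(dir, "truth.vcf"), genome = ref$genome)
  utils::write.table(sim$derived$truth, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
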