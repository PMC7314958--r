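#' Variant consequence classification
#'
#' The analytical core of the package: every variant is assigned a genomic
#' region (CDS, intron, UTRs, splice site, intergenic) and, where it touches
#' coding sequence or a consensus splice site, a coding effect:
#'
#' * `synonymous` / `AAC` (amino acid change) / `stop_gained` / `stop_lost`
#'   for substitutions, by comparing reference and alternate codon
#'   translations;
#' * `frameshift` vs `inframe_insertion` / `inframe_deletion` for CDS indels,
#'   by net length change modulo 3;
#' * `VCSS` (variant in consensus splice site) for any variant whose
#'   reference interval touches the GT/AG consensus dinucleotides at the
#'   intron boundaries (window width configurable);
#' * `complex` for variants straddling an exon/intron boundary without
#'   touching the consensus — counted in region totals only.
#'
#' A variant overlapping several genes yields one record per gene; one record
#' per variant is flagged `primary` using the severity order
#' frameshift > stop_gained > stop_lost > VCSS > AAC > in-frame indel >
#' synonymous > region-only, so genome-level tallies are deterministic.
#'
#' @param variants tibble from [read_variants()] (normalized, with `vclass`).
#' @param models a [gene_models] tibble.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param splice_window integer; how many intron bases at each boundary count
#'   as consensus splice site (default 2 = the GT/AG dinucleotides).
#' @return tibble with columns `contig`, `pos`, `ref`, `alt`, `vclass`,
#'   `gene_id`, `region`, `effect`, `aa_ref`, `aa_pos`, `aa_alt`,
#'   `n_aa_changed`, `primary`.
#' @export
classify_variants <- function(variants, models, genome, splice_window = 2L) {
  empty <- tibble::tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), vclass = character(), gene_id = character(),
    region = character(), effect = character(), aa_ref = character(),
    aa_pos = integer(), aa_alt = character(), n_aa_changed = integer(),
    primary = logical()
  )
  if (nrow(variants) == 0) return(empty)

  ann <- build_gene_annotation(models, genome, splice_window)

  variants <- variants |>
    dplyr::mutate(
      .vid = dplyr::row_number(),
      .aff_start = dplyr::case_when(
        vclass == "deletion" ~ pos + 1L,
        TRUE ~ pos
      ),
      .aff_end = dplyr::case_when(
        vclass %in% c("SNP", "MNV", "deletion") ~ pos + nchar(ref) - 1L,
        TRUE ~ pos # insertion: anchor base
      )
    )

  # variant-to-gene overlap on gene spans
  vgr <- GenomicRanges::GRanges(
    variants$contig,
    IRanges::IRanges(variants$.aff_start, variants$.aff_end)
  )
  ggr <- GenomicRanges::GRanges(
    ann$spans$contig,
    IRanges::IRanges(ann$spans$span_start, ann$spans$span_end)
  )
  hits <- GenomicRanges::findOverlaps(vgr, ggr, ignore.strand = TRUE)

  rows <- purrr::map2(
    S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits),
    function(vi, gi) {
      classify_one(variants[vi, ], ann$genes[[gi]])
    }
  )
  hit_tbl <- dplyr::bind_rows(rows)
  orphan <- setdiff(variants$.vid,
                    if (nrow(hit_tbl)) hit_tbl$.vid else integer())
  if (length(orphan)) {
    hit_tbl <- dplyr::bind_rows(
      hit_tbl,
      variants |>
        dplyr::filter(.data$.vid %in% orphan) |>
        dplyr::transmute(
          .vid = .data$.vid, contig = .data$contig, pos = .data$pos,
          ref = .data$ref, alt = .data$alt, vclass = .data$vclass,
          gene_id = NA_character_, region = "intergenic", effect = "none",
          aa_ref = NA_character_, aa_pos = NA_integer_,
          aa_alt = NA_character_, n_aa_changed = 0L
        )
    )
  }

  severity <- c(
    frameshift = 1, stop_gained = 2, stop_lost = 3, VCSS = 4, AAC = 5,
    inframe_insertion = 6, inframe_deletion = 6, synonymous = 7,
    complex = 8, none = 9
  )
  hit_tbl |>
    dplyr::mutate(.rank = severity[.data$effect]) |>
    dplyr::arrange(.data$.vid, .data$.rank, .data$gene_id) |>
    dplyr::group_by(.data$.vid) |>
    dplyr::mutate(primary = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".vid", -".rank")
}

# Precompute per-gene lookup structures: gene spans for overlap search and,
# per gene, exon/CDS intervals, splice windows, spliced CDS and the genomic
# position -> coding offset map.
build_gene_annotation <- function(models, genome, splice_window = 2L) {
  genes <- purrr::map(seq_len(nrow(models)), function(i) {
    model <- models[i, ]
    ex <- model$exons[[1]]
    cd <- model$cds[[1]]
    seq <- spliced_cds_one(model, genome)
    pos_map <- cds_position_map(cd, model$strand)
    offset_of <- setNames(seq_along(pos_map), pos_map)
    introns <- NULL
    if (nrow(ex) > 1) {
      introns <- data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
    }
    sw <- NULL
    if (!is.null(introns) && nrow(introns) > 0) {
      w <- as.integer(splice_window)
      sw <- data.frame(
        start = c(introns$start, pmax(introns$end - w + 1L, introns$start)),
        end = c(pmin(introns$start + w - 1L, introns$end), introns$end)
      )
    }
    list(
      gene_id = model$gene_id, contig = model$contig, strand = model$strand,
      exons = ex, cds = cd, introns = introns, splice_windows = sw,
      cds_seq = seq, offset_of = offset_of,
      cds_min = min(cd$start), cds_max = max(cd$end)
    )
  })
  spans <- tibble::tibble(
    gene_id = models$gene_id,
    contig = models$contig,
    span_start = purrr::map_int(models$exons, ~ min(.x$start)),
    span_end = purrr::map_int(models$exons, ~ max(.x$end))
  )
  list(genes = genes, spans = spans)
}

intersects_any <- function(s, e, iv) {
  !is.null(iv) && nrow(iv) > 0 && any(iv$start <= e & s <= iv$end)
}

classify_one <- function(v, gene) {
  s <- v$.aff_start
  e <- v$.aff_end
  base <- tibble::tibble(
    .vid = v$.vid, contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
    vclass = v$vclass, gene_id = gene$gene_id, region = NA_character_,
    effect = NA_character_, aa_ref = NA_character_, aa_pos = NA_integer_,
    aa_alt = NA_character_, n_aa_changed = 0L
  )

  if (intersects_any(s, e, gene$splice_windows)) {
    base$region <- "splice_site"
    base$effect <- "VCSS"
    return(base)
  }
  if (intersects_any(s, e, gene$cds)) {
    base$region <- "CDS"
    return(classify_cds(base, v, gene))
  }
  if (intersects_any(s, e, gene$exons)) {
    before <- e < gene$cds_min
    after <- s > gene$cds_max
    base$region <- if (before) {
      if (gene$strand == "+") "five_prime_UTR" else "three_prime_UTR"
    } else if (after) {
      if (gene$strand == "+") "three_prime_UTR" else "five_prime_UTR"
    } else {
      "CDS" # exotic straddle; keep region, no coding call
    }
    base$effect <- if (base$region == "CDS") "complex" else "none"
    return(base)
  }
  base$region <- "intron"
  base$effect <- "none"
  base
}

classify_cds <- function(base, v, gene) {
  if (v$vclass == "SNP") {
    off <- gene$offset_of[as.character(v$pos)]
    if (is.na(off)) { base$effect <- "complex"; return(base) }
    return(snp_effect(base, gene, off, v$alt))
  }
  if (v$vclass == "MNV") {
    return(mnv_effect(base, v, gene))
  }
  len_change <- abs(nchar(v$alt) - nchar(v$ref))
  if (v$vclass == "deletion") {
    offs <- gene$offset_of[as.character(seq(v$pos + 1L, v$pos + nchar(v$ref) - 1L))]
    if (anyNA(offs)) { base$effect <- "complex"; return(base) }
    base$effect <- if (len_change %% 3L != 0L) "frameshift" else "inframe_deletion"
    return(base)
  }
  # insertion anchored inside the CDS
  base$effect <- if (len_change %% 3L != 0L) "frameshift" else "inframe_insertion"
  base
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

snp_effect <- function(base, gene, off, alt) {
  alt_b <- if (gene$strand == "-") comp_base(alt) else alt
  ci <- (off - 1L) %/% 3L + 1L
  cpos <- (off - 1L) %% 3L + 1L
  if (3L * ci > nchar(gene$cds_seq)) { base$effect <- "complex"; return(base) }
  ref_codon <- substr(gene$cds_seq, 3L * ci - 2L, 3L * ci)
  alt_codon <- ref_codon
  substr(alt_codon, cpos, cpos) <- alt_b
  aa_ref <- unname(codon_aa(ref_codon))
  aa_alt <- unname(codon_aa(alt_codon))
  base$aa_ref <- aa_ref
  base$aa_pos <- as.integer(ci)
  base$aa_alt <- aa_alt
  if (aa_ref == aa_alt) {
    base$effect <- "synonymous"
  } else if (aa_alt == "*") {
    base$effect <- "stop_gained"
    base$n_aa_changed <- 1L
  } else if (aa_ref == "*") {
    base$effect <- "stop_lost"
    base$n_aa_changed <- 1L
  } else {
    base$effect <- "AAC"
    base$n_aa_changed <- 1L
  }
  base
}

# Block substitution: substitute each reference base, translate every touched
# codon, count changed amino acids (each changed codon counts as one AAC).
mnv_effect <- function(base, v, gene) {
  gpos <- seq(v$pos, v$pos + nchar(v$ref) - 1L)
  offs <- gene$offset_of[as.character(gpos)]
  if (anyNA(offs)) { base$effect <- "complex"; return(base) }
  alt_bases <- strsplit(v$alt, "")[[1]]
  if (gene$strand == "-") alt_bases <- comp_base(alt_bases)
  mut <- gene$cds_seq
  for (k in seq_along(offs)) {
    substr(mut, offs[k], offs[k]) <- alt_bases[k]
  }
  cis <- sort(unique((offs - 1L) %/% 3L + 1L))
  cis <- cis[3L * cis <= nchar(gene$cds_seq)]
  changed <- 0L
  gained_stop <- FALSE
  lost_stop <- FALSE
  one_change <- NULL
  for (ci in cis) {
    rc <- substr(gene$cds_seq, 3L * ci - 2L, 3L * ci)
    ac <- substr(mut, 3L * ci - 2L, 3L * ci)
    ra <- unname(codon_aa(rc)); aa <- unname(codon_aa(ac))
    if (ra != aa) {
      changed <- changed + 1L
      if (aa == "*") gained_stop <- TRUE
      if (ra == "*") lost_stop <- TRUE
      one_change <- c(ra, ci, aa)
    }
  }
  base$n_aa_changed <- changed
  if (changed == 0L) {
    base$effect <- "synonymous"
  } else if (gained_stop) {
    base$effect <- "stop_gained"
  } else if (lost_stop) {
    base$effect <- "stop_lost"
  } else {
    base$effect <- "AAC"
  }
  if (changed == 1L && !is.null(one_change)) {
    base$aa_ref <- one_change[1]
    base$aa_pos <- as.integer(one_change[2])
    base$aa_alt <- one_change[3]
  }
  base
}

#' SNP/indel composition of a variant set
#'
#' Multi-nucleotide substitutions are decomposed into per-base SNPs for
#' counting (each differing base counts once), so SNP + indel counts
#' partition the variant total.
#'
#' @param variants tibble with `ref`, `alt`, `vclass`.
#' @return tibble with `n_variants` (= `n_snp + n_indel` after MNV
#'   decomposition), `n_snp`, `n_indel`.
#' @export
variant_class_counts <- function(variants) {
  mnv_bases <- 0L
  is_mnv <- variants$vclass == "MNV"
  if (any(is_mnv)) {
    mnv_bases <- sum(purrr::map2_int(
      variants$ref[is_mnv], variants$alt[is_mnv],
      function(r, a) sum(strsplit(r, "")[[1]] != strsplit(a, "")[[1]])
    ))
  }
  n_snp <- sum(variants$vclass == "SNP") + mnv_bases
  n_indel <- sum(variants$vclass %in% c("insertion", "deletion"))
  tibble::tibble(
    n_variants = n_snp + n_indel,
    n_snp = n_snp,
    n_indel = n_indel
  )
}
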