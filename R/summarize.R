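#' Per-gene variant burden
#'
#' Rolls the consequence table up to one row per gene: AAC count (stop
#' gains/losses are counted inside the AAC tally, matching the generic
#' "amino acid change" category; block substitutions contribute one AAC per
#' changed codon), CDS insertion/deletion counts, frameshifts, splice-site
#' hits, and the degree of affection — the AAC count as a percentage of the
#' protein length. Genes whose only variants are intronic or UTR still appear
#' with zero effect counts, so region tallies conserve totals.
#'
#' @param consequences tibble from [classify_variants()]; all gene-linked
#'   records are used (a variant overlapping two genes counts in both).
#' @param proteins optional tibble with `gene_id`, `protein_length` (amino
#'   acids), e.g. from [spliced_cds()]; without it `degree_of_affection` is
#'   `NA` with a warning.
#' @return tibble with `gene_id`, `n_variants`, `n_AAC`, `n_insertion`,
#'   `n_deletion`, `n_frameshift`, `n_VCSS`, `protein_length`,
#'   `degree_of_affection`.
#' @export
per_gene_summary <- function(consequences, proteins = NULL) {
  aac_effects <- c("AAC", "stop_gained", "stop_lost")
  out <- consequences |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_AAC = sum(.data$n_aa_changed[.data$effect %in% aac_effects]),
      n_insertion = sum(.data$vclass == "insertion" & .data$region == "CDS" &
                          .data$effect != "complex"),
      n_deletion = sum(.data$vclass == "deletion" & .data$region == "CDS" &
                         .data$effect != "complex"),
      n_frameshift = sum(.data$effect == "frameshift"),
      n_VCSS = sum(.data$effect == "VCSS"),
      .groups = "drop"
    )
  if (!is.null(proteins)) {
    out <- dplyr::left_join(out,
                            dplyr::select(proteins, "gene_id", "protein_length"),
                            by = "gene_id")
    if (anyNA(out$protein_length)) {
      rlang::warn("protein length missing for some genes; degree_of_affection omitted there")
    }
  } else {
    rlang::warn("no protein lengths supplied; degree_of_affection omitted")
    out$protein_length <- NA_integer_
  }
  out |>
    dplyr::mutate(degree_of_affection = 100 * .data$n_AAC / .data$protein_length)
}

#' Bin genes by AAC count
#'
#' Histogram of genes with at least one amino acid change, binned by AAC
#' count, plus the open-ended tail bins (>= 50, >= 100 by default).
#' Percentages are relative to the number of genes with AACs.
#'
#' @param summaries tibble from [per_gene_summary()].
#' @param breaks ascending lower bin edges; default `c(1, 11, 50, 100)`
#'   giving bins 1–10, 11–49, 50–99, >= 100.
#' @param tails lower bounds of the open-ended tail bins reported in
#'   addition.
#' @return tibble with `bin`, `n`, `pct` (half-up, 2 decimals); tail rows are
#'   marked in the `tail` column and overlap the closed bins.
#' @export
bin_by_aac <- function(summaries, breaks = c(1, 11, 50, 100),
                       tails = c(50, 100)) {
  stopifnot(!is.unsorted(breaks, strictly = TRUE))
  with_aac <- summaries$n_AAC[summaries$n_AAC >= 1]
  denom <- length(with_aac)
  upper <- c(breaks[-1] - 1, Inf)
  closed <- tibble::tibble(
    bin = purrr::map2_chr(breaks, upper, function(lo, hi) {
      if (is.finite(hi)) sprintf("%d-%d", lo, as.integer(hi)) else sprintf(">=%d", lo)
    }),
    n = purrr::map2_int(breaks, upper,
                        ~ sum(with_aac >= .x & with_aac <= .y)),
    tail = FALSE
  )
  tail_tbl <- tibble::tibble(
    bin = sprintf(">=%d", tails),
    n = purrr::map_int(tails, ~ sum(with_aac >= .x)),
    tail = TRUE
  )
  dplyr::bind_rows(closed, tail_tbl) |>
    dplyr::mutate(pct = share_pct(.data$n, denom))
}

#' Degree-of-affection classes
#'
#' Partitions a selection of genes (typically those with >= 50 AACs) into
#' three exhaustive, disjoint classes of degree of affection:
#' `<=5%`, `(5,10]%` and `>10%` by default. Boundary membership follows the
#' class closures: a gene at exactly 5% falls in the lowest class, one at
#' exactly 10% in the middle class.
#'
#' @param summaries tibble with a `degree_of_affection` column (restrict it
#'   to the selection of interest before calling).
#' @param cuts two ascending cut points in percent (default `c(5, 10)`).
#' @return tibble with `class`, `n`.
#' @export
affection_classes <- function(summaries, cuts = c(5, 10)) {
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2])
  d <- summaries$degree_of_affection
  tibble::tibble(
    class = c(sprintf("<=%g%%", cuts[1]),
              sprintf("(%g,%g]%%", cuts[1], cuts[2]),
              sprintf(">%g%%", cuts[2])),
    n = c(sum(d <= cuts[1]),
          sum(d > cuts[1] & d <= cuts[2]),
          sum(d > cuts[2]))
  )
}

#' Per-family variant burden
#'
#' Joins per-gene summaries onto a family annotation and aggregates per
#' family: member count, members with any variant, total variants, the
#' size-normalized rate `variants_per_gene`, and members carrying each effect
#' class. Genes annotated to several families contribute to each; family
#' members without any variant still count in `n_genes`.
#'
#' @param summaries tibble from [per_gene_summary()].
#' @param families tibble with `gene_id`, `family`.
#' @return tibble with one row per family plus a `class` column derived from
#'   the family-label prefix (AA, GH, GT, CE, PL, CBM, EXP; anything else is
#'   grouped under `"other"` with a warning).
#' @export
family_rollup <- function(summaries, families) {
  joined <- families |>
    dplyr::distinct(.data$family, .data$gene_id) |>
    dplyr::left_join(summaries, by = "gene_id")
  out <- joined |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      genes_with_variants = sum(!is.na(.data$n_variants) & .data$n_variants > 0),
      total_variants = sum(.data$n_variants, na.rm = TRUE),
      genes_with_aac = sum(.data$n_AAC > 0, na.rm = TRUE),
      genes_with_insertion = sum(.data$n_insertion > 0, na.rm = TRUE),
      genes_with_deletion = sum(.data$n_deletion > 0, na.rm = TRUE),
      genes_with_frameshift = sum(.data$n_frameshift > 0, na.rm = TRUE),
      genes_with_vcss = sum(.data$n_VCSS > 0, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      variants_per_gene = .data$total_variants / .data$n_genes,
      class = family_class(.data$family)
    )
  if (any(out$class == "other")) {
    rlang::warn(sprintf("unknown family prefix for: %s",
                        paste(out$family[out$class == "other"], collapse = ", ")))
  }
  out
}

family_class <- function(family) {
  ifelse(grepl("^(CBM|EXP|GH|GT|PL|CE|AA)", family),
         sub("^(CBM|EXP|GH|GT|PL|CE|AA).*$", "\\1", family),
         "other")
}

#' Class-level tallies from a family rollup
#'
#' @param rollup tibble from [family_rollup()].
#' @return per-class sums of gene and variant counts.
#' @export
family_class_tally <- function(rollup) {
  rollup |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_families = dplyr::n(),
      n_genes = sum(.data$n_genes),
      genes_with_variants = sum(.data$genes_with_variants),
      total_variants = sum(.data$total_variants),
      genes_with_aac = sum(.data$genes_with_aac),
      .groups = "drop"
    )
}

#' Genome-wide and family-wide variant overview
#'
#' The two-column overview table: per category (total variants, SNPs, indels,
#' then AACs / CDS deletions / CDS insertions / frameshifts through indels /
#' VCSSs with their affected-gene counts) the totals over all variants and
#' over variants in family-annotated genes. Percentages are computed from
#' explicitly supplied denominators — the reference annotation's gene total
#' and the family-list gene total — never inferred from the data, and are
#' rounded half-up to 2 decimals.
#'
#' @param consequences tibble from [classify_variants()].
#' @param gene_total reference CDS gene count (denominator for affected-gene
#'   percentages over all genes).
#' @param families optional tibble with `gene_id`, `family` selecting the
#'   family-annotated gene subset.
#' @param family_total family-list gene count (denominator for the family
#'   columns); defaults to the number of distinct annotated genes.
#' @return tibble with `category`, `scope` (`all` / `family`), `n_variants`,
#'   `n_genes`, `pct_variants` (share of the scope's variant total),
#'   `pct_genes` (share of the scope's gene denominator).
#' @export
overview_table <- function(consequences, gene_total, families = NULL,
                           family_total = NULL) {
  primary <- dplyr::filter(consequences, .data$primary)
  scopes <- list(all = primary)
  denoms <- c(all = gene_total)
  if (!is.null(families)) {
    fam_genes <- unique(families$gene_id)
    scopes$family <- dplyr::filter(primary, .data$gene_id %in% fam_genes)
    denoms["family"] <- family_total %||% length(fam_genes)
  }
  total_all <- variant_class_counts(primary)$n_variants

  one_scope <- function(tbl, scope_name) {
    den <- denoms[[scope_name]]
    cls <- variant_class_counts(tbl)
    aac_effects <- c("AAC", "stop_gained", "stop_lost")
    cat_rows <- tibble::tribble(
      ~category, ~n_variants, ~n_genes,
      "total", cls$n_variants, dplyr::n_distinct(tbl$gene_id[!is.na(tbl$gene_id)]),
      "SNP", cls$n_snp, NA_integer_,
      "indel", cls$n_indel, NA_integer_,
      "AAC", sum(tbl$n_aa_changed[tbl$effect %in% aac_effects]),
      dplyr::n_distinct(tbl$gene_id[tbl$effect %in% aac_effects]),
      "deletion_in_cds", sum(tbl$vclass == "deletion" & tbl$region == "CDS" &
                               tbl$effect != "complex"),
      dplyr::n_distinct(tbl$gene_id[tbl$vclass == "deletion" & tbl$region == "CDS" &
                                      tbl$effect != "complex"]),
      "insertion_in_cds", sum(tbl$vclass == "insertion" & tbl$region == "CDS" &
                                tbl$effect != "complex"),
      dplyr::n_distinct(tbl$gene_id[tbl$vclass == "insertion" & tbl$region == "CDS" &
                                      tbl$effect != "complex"]),
      "frameshift", sum(tbl$effect == "frameshift"),
      dplyr::n_distinct(tbl$gene_id[tbl$effect == "frameshift"]),
      "VCSS", sum(tbl$effect == "VCSS"),
      dplyr::n_distinct(tbl$gene_id[tbl$effect == "VCSS"])
    )
    cat_rows |>
      dplyr::mutate(
        scope = scope_name,
        pct_variants = share_pct(.data$n_variants, total_all),
        pct_genes = share_pct(.data$n_genes, den)
      )
  }
  purrr::imap(scopes, one_scope) |>
    dplyr::bind_rows() |>
    dplyr::select("category", "scope", "n_variants", "n_genes",
                  "pct_variants", "pct_genes")
}

#' Genome identity from SNP count
#'
#' `100 * (1 - snp_count / genome_size)`, rounded half-up to one decimal —
#' the headline identity figure of a strain comparison.
#'
#' @param snp_count number of single-nucleotide differences.
#' @param genome_size_bp assembly size in bp.
#' @return percentage.
#' @export
genome_identity <- function(snp_count, genome_size_bp) {
  if (genome_size_bp <= 0) stopf("genome size must be positive")
  if (snp_count > genome_size_bp) stopf("SNP count exceeds genome size")
  round_half_up(100 * (1 - snp_count / genome_size_bp), 1)
}

#' Average distance between variants
#'
#' Basepairs per variant: `genome_size / total_variants`, one decimal.
#'
#' @param total_variants variant count (> 0 for a defined value).
#' @param genome_size_bp assembly size in bp.
#' @return bp per variant, or `NA` when there are no variants.
#' @export
variant_density <- function(total_variants, genome_size_bp) {
  if (total_variants == 0) return(NA_real_)
  round_half_up(genome_size_bp / total_variants, 1)
}

#' Hypergeometric upper tail
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' population of `N` containing `K` group members.
#'
#' @param x observed overlap.
#' @param K group size.
#' @param n selection size.
#' @param N population size.
#' @return upper-tail probability.
#' @export
hyper_upper_tail <- function(x, K, n, N) {
  if (x > min(n, K)) stopf("overlap %d exceeds min(selection, group)", x)
  if (K > N || n > N) stopf("group/selection larger than population")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overrepresentation test for functional groups
#'
#' One-sided hypergeometric test of whether a gene selection (e.g. genes with
#' >= 50 AACs) is enriched for each functional group. Raw p-values by
#' default; Benjamini–Hochberg adjustment available but off, since single
#' raw bounds are the convention for this kind of screen.
#'
#' @param selected_genes character vector of selected gene ids.
#' @param groups tibble with `gene_id`, `group`.
#' @param population_size explicit gene universe size (the enrichment
#'   population is a modelling choice, so it is a required argument).
#' @param p_adjust apply Benjamini–Hochberg across groups.
#' @return tibble with `group`, `population`, `group_size`, `selection_size`,
#'   `overlap`, `p_value` (and `p_adjusted` if requested).
#' @export
enrichment_test <- function(selected_genes, groups, population_size,
                            p_adjust = FALSE) {
  selected_genes <- unique(selected_genes)
  n <- length(selected_genes)
  if (n > population_size) stopf("selection larger than population")
  out <- groups |>
    dplyr::distinct(.data$group, .data$gene_id) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      group_size = dplyr::n(),
      overlap = sum(.data$gene_id %in% selected_genes),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      population = population_size,
      selection_size = n,
      p_value = purrr::map2_dbl(.data$overlap, .data$group_size,
                                ~ hyper_upper_tail(.x, .y, n, population_size))
    ) |>
    dplyr::select("group", "population", "group_size", "selection_size",
                  "overlap", "p_value")
  if (p_adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
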