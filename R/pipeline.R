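#' Pipeline configuration
#'
#' Collects the file paths, denominators and thresholds for a full
#' comparison run. Referenced files are checked up front so a bad path fails
#' before any computation.
#'
#' @param genome,gff3,vcf input paths (required).
#' @param families,groups optional two-column TSV paths (gene id to family /
#'   functional group).
#' @param gene_total reference CDS gene count used as the percentage
#'   denominator; defaults to the number of gene models.
#' @param family_total family-list gene total; defaults to the distinct
#'   annotated genes.
#' @param splice_window consensus splice-site window (intron bases per
#'   boundary).
#' @param aac_breaks,aac_tails bin edges for the AAC histogram.
#' @param affection_cuts degree-of-affection class cuts, percent.
#' @param selection_min_aac AAC threshold defining the high-burden gene
#'   selection used for affection classes and enrichment.
#' @param enrichment_population population size for the hypergeometric test;
#'   defaults to `gene_total`.
#' @param out_dir optional output directory; when set, all result tables and
#'   a `report.json` are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, gff3, vcf, families = NULL, groups = NULL,
                            gene_total = NULL, family_total = NULL,
                            splice_window = 2L,
                            aac_breaks = c(1, 11, 50, 100),
                            aac_tails = c(50, 100),
                            affection_cuts = c(5, 10),
                            selection_min_aac = 50,
                            enrichment_population = NULL,
                            out_dir = NULL) {
  for (p in c(genome, gff3, vcf, families, groups)) {
    if (!file.exists(p)) stopf("configuration error: input file not found: %s", p)
  }
  structure(
    list(genome = genome, gff3 = gff3, vcf = vcf, families = families,
         groups = groups, gene_total = gene_total, family_total = family_total,
         splice_window = as.integer(splice_window), aac_breaks = aac_breaks,
         aac_tails = aac_tails, affection_cuts = affection_cuts,
         selection_min_aac = selection_min_aac,
         enrichment_population = enrichment_population, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full comparison pipeline
#'
#' classify -> summarize (-> enrichment), from files to a result bundle.
#' Deterministic: rerunning with the same configuration reproduces every
#' table byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return object of class `strain_comparison`: a list with `consequences`,
#'   `gene_summary`, `aac_bins`, `affection`, `family_summary`, `overview`,
#'   `enrichment` (or `NULL`), `params`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- read_genome(config$genome)
  models <- read_gene_models(config$gff3, genome)
  variants <- read_variants(config$vcf, genome)
  families <- if (!is.null(config$families)) {
    read_family_table(config$families, gene_universe = models$gene_id)
  }
  groups <- if (!is.null(config$groups)) {
    read_group_table(config$groups, gene_universe = models$gene_id)
  }
  gene_total <- config$gene_total %||% nrow(models)
  family_total <- config$family_total %||%
    if (!is.null(families)) dplyr::n_distinct(families$gene_id) else NULL

  consequences <- classify_variants(variants, models, genome,
                                    splice_window = config$splice_window)
  proteins <- spliced_cds(models, genome)
  gene_summary <- per_gene_summary(consequences, proteins)
  aac_bins <- bin_by_aac(gene_summary, breaks = config$aac_breaks,
                         tails = config$aac_tails)
  selection <- dplyr::filter(gene_summary, .data$n_AAC >= config$selection_min_aac)
  affection <- affection_classes(selection, cuts = config$affection_cuts)
  family_summary <- if (!is.null(families)) family_rollup(gene_summary, families)
  overview <- overview_table(consequences, gene_total, families, family_total)
  enrichment <- if (!is.null(groups)) {
    enrichment_test(selection$gene_id, groups,
                    config$enrichment_population %||% gene_total)
  }

  cls <- variant_class_counts(dplyr::filter(consequences, .data$primary))
  res <- structure(
    list(consequences = consequences, gene_summary = gene_summary,
         aac_bins = aac_bins, affection = affection,
         family_summary = family_summary, overview = overview,
         enrichment = enrichment,
         params = list(
           gene_total = gene_total, family_total = family_total,
           splice_window = config$splice_window,
           selection_min_aac = config$selection_min_aac,
           genome_size = genome_size(genome),
           n_variants = cls$n_variants, n_snp = cls$n_snp,
           n_indel = cls$n_indel,
           identity_pct = genome_identity(cls$n_snp, genome_size(genome)),
           bp_per_variant = variant_density(cls$n_variants, genome_size(genome))
         )),
    class = "strain_comparison"
  )
  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

write_report <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(tbl, name) {
    if (!is.null(tbl)) {
      utils::write.table(tbl, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(res$consequences, "consequences.tsv")
  wt(res$gene_summary, "gene_summary.tsv")
  wt(res$aac_bins, "gene_bins.tsv")
  wt(res$affection, "affection_classes.tsv")
  wt(res$family_summary, "families.tsv")
  wt(res$overview, "overview.tsv")
  wt(res$enrichment, "enrichment.tsv")
  jsonlite::write_json(
    c(res$params, list(version = as.character(utils::packageVersion("straindiff")))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.strain_comparison <- function(x, ...) {
  p <- x$params
  cat("strain comparison\n")
  cat(sprintf("  variants: %d (%d SNPs, %d indels)\n",
              p$n_variants, p$n_snp, p$n_indel))
  cat(sprintf("  genome identity: %.1f%%; one variant per %.1f bp\n",
              p$identity_pct, p$bp_per_variant))
  cat(sprintf("  genes with any linked variant: %d of %d\n",
              nrow(x$gene_summary), p$gene_total))
  invisible(x)
}

#' Tidy a strain comparison
#'
#' @param x a `strain_comparison`.
#' @param ... unused.
#' @return the per-variant consequence tibble.
#' @exportS3Method generics::tidy
tidy.strain_comparison <- function(x, ...) x$consequences

#' One-row summary of a strain comparison
#'
#' @param x a `strain_comparison`.
#' @param ... unused.
#' @return one-row tibble of headline totals.
#' @exportS3Method generics::glance
glance.strain_comparison <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    n_variants = p$n_variants, n_snp = p$n_snp, n_indel = p$n_indel,
    snp_pct = share_pct(p$n_snp, p$n_variants),
    indel_pct = share_pct(p$n_indel, p$n_variants),
    identity_pct = p$identity_pct, bp_per_variant = p$bp_per_variant,
    genes_affected = nrow(x$gene_summary), gene_total = p$gene_total
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
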