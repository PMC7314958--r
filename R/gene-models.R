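#' Construct a gene-model table
#'
#' One row per gene (the pipeline treats genes and transcripts 1:1). Exon and
#' CDS intervals are 1-based closed, stored in genomic (ascending) order
#' regardless of strand; splicing reorders them for translation.
#'
#' @param gene_id,contig,strand character/`+`/`-` vectors, one per gene.
#' @param exons list of data frames with `start`, `end`.
#' @param cds list of data frames with `start`, `end`, `phase`.
#' @param protein_id optional character vector.
#' @param complete logical; complete models must have spliced CDS length
#'   divisible by 3.
#' @return tibble of class `gene_models`.
#' @export
gene_models <- function(gene_id, contig, strand, exons, cds,
                        protein_id = NA_character_, complete = TRUE) {
  tbl <- tibble::tibble(
    gene_id = as.character(gene_id),
    contig = as.character(contig),
    strand = as.character(strand),
    exons = purrr::map(exons, normalize_intervals),
    cds = purrr::map(cds, normalize_intervals),
    protein_id = protein_id,
    complete = complete
  )
  class(tbl) <- c("gene_models", class(tbl))
  tbl
}

normalize_intervals <- function(df) {
  df <- as.data.frame(df)
  df <- df[order(df$start), , drop = FALSE]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if ("phase" %in% names(df)) df$phase <- as.integer(df$phase)
  rownames(df) <- NULL
  if (any(df$end < df$start)) stopf("interval with end < start")
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)])) {
    stopf("overlapping intervals in gene model")
  }
  df
}

spliced_len <- function(iv) sum(iv$end - iv$start + 1L)

#' Validate gene models against a genome
#'
#' Checks that intervals lie within their contig, that CDS intervals are
#' contained in the exon union, that GFF3 phases are consistent with the
#' running CDS length in translation order, and that complete models have a
#' spliced CDS length divisible by 3.
#'
#' @param models a [gene_models] tibble.
#' @param genome reference [Biostrings::DNAStringSet].
#' @return `models`, invisibly; errors on the first violation.
#' @export
validate_gene_models <- function(models, genome) {
  widths <- setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(models))) {
    g <- models$gene_id[i]
    contig <- models$contig[i]
    if (!contig %in% names(genome)) stopf("gene %s: unknown contig %s", g, contig)
    ex <- models$exons[[i]]
    cd <- models$cds[[i]]
    if (max(ex$end) > widths[contig] || min(ex$start) < 1) {
      stopf("gene %s: exon outside contig bounds", g)
    }
    # every CDS interval must sit inside some exon
    inside <- purrr::map_lgl(seq_len(nrow(cd)), function(j) {
      any(ex$start <= cd$start[j] & cd$end[j] <= ex$end)
    })
    if (!all(inside)) stopf("gene %s: CDS interval outside exons", g)
    len <- spliced_len(cd)
    if (isTRUE(models$complete[i]) && len %% 3L != 0L) {
      stopf("gene %s: complete model with CDS length %d not divisible by 3", g, len)
    }
    if ("phase" %in% names(cd) && !all(is.na(cd$phase))) {
      ord <- if (models$strand[i] == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
      running <- 0L
      for (j in ord) {
        expected <- (3L - (running %% 3L)) %% 3L
        if (!is.na(cd$phase[j]) && cd$phase[j] != expected) {
          stopf("gene %s: CDS phase %d inconsistent with running length (expected %d)",
                g, cd$phase[j], expected)
        }
        running <- running + (cd$end[j] - cd$start[j] + 1L)
      }
    }
  }
  invisible(models)
}

#' Read gene models from GFF3
#'
#' Imports a Maker-style GFF3 (gene/mRNA/exon/CDS features with ID/Parent
#' attributes) via [rtracklayer::import()] and builds one model per gene.
#' When a gene has several mRNAs the one with the longest spliced CDS is kept
#' (ties broken by lexicographically smallest mRNA ID).
#'
#' @param path GFF3 file.
#' @param genome reference [Biostrings::DNAStringSet] used for validation.
#' @return a [gene_models] tibble.
#' @export
read_gene_models <- function(path, genome) {
  if (!file.exists(path)) stopf("GFF3 not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- purrr::map_chr(as.list(gr$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  })
  mrna_idx <- which(typ == "mRNA")
  if (length(mrna_idx) == 0) stopf("%s: no mRNA features", path)
  gene_of <- setNames(parents[mrna_idx], ids[mrna_idx])
  if (anyNA(gene_of)) stopf("%s: mRNA without Parent gene", path)

  rows <- purrr::map(mrna_idx, function(mi) {
    mid <- ids[mi]
    kids <- which(parents == mid)
    ex <- kids[typ[kids] == "exon"]
    cd <- kids[typ[kids] == "CDS"]
    if (length(cd) == 0) return(NULL)
    if (length(ex) == 0) ex <- cd # CDS-only annotations: exons default to CDS
    phase <- suppressWarnings(as.integer(as.character(gr$phase[cd])))
    list(
      gene_id = unname(gene_of[mid]),
      mrna_id = mid,
      contig = as.character(GenomicRanges::seqnames(gr))[mi],
      strand = as.character(BiocGenerics::strand(gr))[mi],
      exons = data.frame(start = BiocGenerics::start(gr)[ex],
                         end = BiocGenerics::end(gr)[ex]),
      cds = data.frame(start = BiocGenerics::start(gr)[cd],
                       end = BiocGenerics::end(gr)[cd],
                       phase = phase)
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) stopf("%s: no mRNA with CDS features", path)

  tbl <- tibble::tibble(
    gene_id = purrr::map_chr(rows, "gene_id"),
    mrna_id = purrr::map_chr(rows, "mrna_id"),
    contig = purrr::map_chr(rows, "contig"),
    strand = purrr::map_chr(rows, "strand"),
    exons = purrr::map(rows, "exons"),
    cds = purrr::map(rows, "cds"),
    cds_len = purrr::map_int(rows, ~ as.integer(spliced_len(.x$cds)))
  )
  # one transcript per gene: longest spliced CDS, tie -> smallest mRNA id
  tbl <- tbl |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$cds_len), .data$mrna_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)

  models <- gene_models(
    gene_id = tbl$gene_id, contig = tbl$contig, strand = tbl$strand,
    exons = tbl$exons, cds = tbl$cds, protein_id = tbl$mrna_id,
    complete = TRUE
  )
  validate_gene_models(models, genome)
}

#' Write gene models as GFF3
#'
#' @param models a [gene_models] tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    g <- models$gene_id[i]
    contig <- models$contig[i]
    strand <- models$strand[i]
    ex <- models$exons[[i]]
    cd <- models$cds[[i]]
    span <- c(min(ex$start), max(ex$end))
    mid <- paste0(g, ".t1")
    lines <- c(
      lines,
      sprintf("%s\tstraindiff\tgene\t%d\t%d\t.\t%s\t.\tID=%s", contig, span[1], span[2], strand, g),
      sprintf("%s\tstraindiff\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              contig, span[1], span[2], strand, mid, g),
      sprintf("%s\tstraindiff\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              contig, ex$start, ex$end, strand, mid, seq_len(nrow(ex)), mid)
    )
    # phase in translation order
    ord <- if (strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
    phase <- integer(nrow(cd))
    running <- 0L
    for (j in ord) {
      phase[j] <- (3L - (running %% 3L)) %% 3L
      running <- running + (cd$end[j] - cd$start[j] + 1L)
    }
    lines <- c(lines,
               sprintf("%s\tstraindiff\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                       contig, cd$start, cd$end, strand, phase, mid, mid))
  }
  writeLines(lines, path)
  invisible(path)
}

# Genomic positions of the CDS bases of one model, in translation (5'->3' of
# the mRNA) order. Element k is the genomic coordinate of coding base k.
cds_position_map <- function(cds, strand) {
  pos <- unlist(purrr::map2(cds$start, cds$end, seq), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

#' Spliced CDS sequences and proteins
#'
#' Extracts the spliced coding sequence of each gene model (minus-strand
#' models reverse-complemented), optionally trimming a nonzero phase on the
#' first coding exon, and translates it with the standard genetic code.
#'
#' @param models a [gene_models] tibble.
#' @param genome reference [Biostrings::DNAStringSet].
#' @return tibble with `gene_id`, `cds_seq`, `cds_length`, `protein`,
#'   `protein_length` (stop codon excluded from the length).
#' @export
spliced_cds <- function(models, genome) {
  out <- purrr::map(seq_len(nrow(models)), function(i) {
    seq <- spliced_cds_one(models[i, ], genome)
    prot <- translate_cds(seq)
    aa_len <- nchar(sub("\\*$", "", prot))
    tibble::tibble(gene_id = models$gene_id[i], cds_seq = seq,
                   cds_length = nchar(seq), protein = prot,
                   protein_length = aa_len)
  })
  dplyr::bind_rows(out)
}

spliced_cds_one <- function(model, genome) {
  cd <- model$cds[[1]]
  contig <- model$contig
  pieces <- purrr::map2_chr(cd$start, cd$end, function(s, e) genome_slice(genome, contig, s, e))
  seq <- paste(pieces, collapse = "")
  if (model$strand == "-") seq <- revcomp_chr(seq)
  # phase of the first coding exon (translation order) trims partial codon
  if ("phase" %in% names(cd) && nrow(cd) > 0) {
    first <- if (model$strand == "+") 1L else nrow(cd)
    ph <- cd$phase[first]
    if (!is.na(ph) && ph > 0) seq <- substr(seq, ph + 1L, nchar(seq))
  }
  seq
}

#' Translate a coding sequence
#'
#' Standard genetic code (translation table 1). Internal stop codons are
#' permitted and appear as `*` in the protein.
#'
#' @param seq character vector of nucleotide sequences; each length must be a
#'   multiple of 3 (empty strings allowed).
#' @return character vector of amino acid sequences.
#' @export
translate_cds <- function(seq) {
  purrr::map_chr(seq, function(s) {
    if (nchar(s) == 0) return("")
    if (nchar(s) %% 3L != 0L) stopf("CDS length %d is not a multiple of 3", nchar(s))
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  })
}
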