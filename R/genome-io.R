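#' Read a genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] with the validation the rest of the
#' pipeline relies on: sequences are uppercased, contig ids must be unique and
#' sequences non-empty, and only A/C/G/T/N are accepted.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet], one element per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("genome FASTA not found: %s", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stopf("failed to parse FASTA %s: %s", path, conditionMessage(e))
  )
  if (length(raw) == 0) stopf("FASTA %s contains no sequences", path)
  # first whitespace-delimited token is the contig id
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    stopf("duplicate contig id in %s: %s", path,
          paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  }
  chr <- toupper(as.character(raw))
  if (any(nchar(chr) == 0)) stopf("empty sequence in %s", path)
  if (any(grepl("[^ACGTN]", chr))) stopf("non-ACGTN character in %s", path)
  Biostrings::DNAStringSet(chr)
}

#' Write a genome to FASTA
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output file; lines wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, width = 80L)
  invisible(path)
}

#' Total genome size in basepairs
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return integer total of all contig lengths.
#' @export
genome_size <- function(genome) sum(Biostrings::width(genome))

# 1-based inclusive slice of a contig
genome_slice <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stopf("unknown contig: %s", contig)
  w <- length(genome[[contig]])
  if (start < 1 || end > w) stopf("slice %d..%d outside contig %s (1..%d)", start, end, contig, w)
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

classify_vclass <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == 1 & la == 1 ~ "SNP",
    la > lr ~ "insertion",
    lr > la ~ "deletion",
    TRUE ~ "MNV"
  )
}

#' Left-normalize variant records
#'
#' Shifts each record to its smallest position with a minimal shared
#' prefix/suffix (the standard left-alignment of indels), so that equivalent
#' representations compare equal. Idempotent.
#'
#' @param variants tibble with `contig`, `pos`, `ref`, `alt`.
#' @param genome reference [Biostrings::DNAStringSet] (needed to extend left
#'   through repeat context).
#' @return the input tibble with normalized `pos`/`ref`/`alt` and a refreshed
#'   `vclass` column.
#' @export
normalize_variants <- function(variants, genome) {
  norm1 <- function(contig, pos, ref, alt) {
    repeat {
      lr <- nchar(ref); la <- nchar(alt)
      # trim shared last base, extending left when an allele would empty
      if (lr > 0 && la > 0 && substr(ref, lr, lr) == substr(alt, la, la) &&
          (lr > 1 || la > 1)) {
        ref <- substr(ref, 1, lr - 1)
        alt <- substr(alt, 1, la - 1)
        if (nchar(ref) == 0 || nchar(alt) == 0) {
          if (pos == 1) { # cannot extend further left; re-anchor and stop
            base <- genome_slice(genome, contig, pos, pos)
            ref <- paste0(base, ref); alt <- paste0(base, alt)
            break
          }
          pos <- pos - 1
          base <- genome_slice(genome, contig, pos, pos)
          ref <- paste0(base, ref)
          alt <- paste0(base, alt)
        }
        next
      }
      # trim shared leading base while both alleles keep >= 1 base
      if (nchar(ref) >= 2 && nchar(alt) >= 2 &&
          substr(ref, 1, 1) == substr(alt, 1, 1)) {
        ref <- substr(ref, 2, nchar(ref))
        alt <- substr(alt, 2, nchar(alt))
        pos <- pos + 1
        next
      }
      break
    }
    list(pos = pos, ref = ref, alt = alt)
  }
  out <- purrr::pmap(
    list(variants$contig, variants$pos, variants$ref, variants$alt),
    norm1
  )
  variants$pos <- purrr::map_int(out, ~ as.integer(.x$pos))
  variants$ref <- purrr::map_chr(out, "ref")
  variants$alt <- purrr::map_chr(out, "alt")
  variants$vclass <- classify_vclass(variants$ref, variants$alt)
  variants
}

check_ref_alleles <- function(variants, genome) {
  if (nrow(variants) == 0) return(invisible(variants))
  obs <- purrr::pmap_chr(
    list(variants$contig, variants$pos, variants$ref),
    function(contig, pos, ref) genome_slice(genome, contig, pos, pos + nchar(ref) - 1L)
  )
  bad <- which(obs != variants$ref)
  if (length(bad)) {
    b <- bad[1]
    stopf("REF mismatch at %s:%d (VCF says %s, genome has %s)",
          variants$contig[b], variants$pos[b], variants$ref[b], obs[b])
  }
  invisible(variants)
}

#' Read variants from a VCF
#'
#' Parses a VCF 4.x file via [vcfR::read.vcfR()], splits multiallelic records
#' into one row per ALT allele, left-normalizes every record and verifies the
#' REF allele against the reference genome. Genotype/INFO fields are ignored.
#'
#' @param path VCF file (plain text).
#' @param genome reference [Biostrings::DNAStringSet].
#' @return tibble with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `vclass` (`SNP`, `insertion`, `deletion`, `MNV`).
#' @export
read_variants <- function(path, genome) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          vclass = character()))
  }
  out <- tibble::tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT)
  ) |>
    tidyr::separate_longer_delim("alt", delim = ",")
  out <- normalize_variants(out, genome)
  check_ref_alleles(out, genome)
  out
}

#' Write variants as VCF 4.2
#'
#' Minimal sites-only writer (CHROM POS ID REF ALT QUAL FILTER INFO) used by
#' the simulator to emit truth variant sets as plain text.
#'
#' @param variants tibble with `contig`, `pos`, `ref`, `alt`.
#' @param path output file.
#' @param genome optional genome whose contig lengths populate `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=straindiff")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome), Biostrings::width(genome)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  variants$contig, variants$pos, variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_two_col_tsv <- function(path, value_name) {
  if (!file.exists(path)) stopf("table not found: %s", path)
  if (length(readLines(path, n = 1)) == 0) {
    return(tibble::tibble(gene_id = character(), !!value_name := character()))
  }
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0) {
    return(tibble::tibble(gene_id = character(), !!value_name := character()))
  }
  if (ncol(raw) < 2) stopf("%s: expected two tab-separated columns", path)
  # tolerate an optional header row
  if (tolower(raw[1, 1]) %in% c("gene_id", "gene", "id")) raw <- raw[-1, , drop = FALSE]
  tibble::tibble(gene_id = raw[[1]], !!value_name := raw[[2]]) |>
    dplyr::distinct()
}

#' Read a gene-family annotation table
#'
#' Two-column TSV `gene_id<TAB>family` (e.g. CAZy family labels such as
#' `GH5_5`, `AA3_2`, `CBM13`), optional header. Duplicate rows collapse; a
#' gene may carry several family labels.
#'
#' @param path TSV file.
#' @param gene_universe optional character vector of known gene ids; annotated
#'   genes missing from it are reported with a warning (and kept — the check
#'   is advisory, not fatal).
#' @return tibble with columns `gene_id`, `family`; unknown ids (if any) are
#'   attached as attribute `"unknown_genes"`.
#' @export
read_family_table <- function(path, gene_universe = NULL) {
  tbl <- read_two_col_tsv(path, "family")
  check_universe(tbl, gene_universe)
}

#' Read a functional-group table
#'
#' Same format as [read_family_table()]: `gene_id<TAB>group` with labels such
#' as `F-box`, `kinase`, `WD repeat`.
#'
#' @inheritParams read_family_table
#' @return tibble with columns `gene_id`, `group`.
#' @export
read_group_table <- function(path, gene_universe = NULL) {
  tbl <- read_two_col_tsv(path, "group")
  check_universe(tbl, gene_universe)
}

check_universe <- function(tbl, gene_universe) {
  if (!is.null(gene_universe)) {
    unknown <- setdiff(tbl$gene_id, gene_universe)
    if (length(unknown)) {
      rlang::warn(sprintf("%d annotated gene id(s) absent from gene universe: %s",
                          length(unknown),
                          paste(utils::head(unknown, 5), collapse = ", ")))
      attr(tbl, "unknown_genes") <- unknown
    }
  }
  tbl
}

#' Family sizes
#'
#' @param families tibble from [read_family_table()].
#' @return tibble `family`, `n_genes`.
#' @export
family_sizes <- function(families) {
  families |>
    dplyr::distinct(.data$family, .data$gene_id) |>
    dplyr::count(.data$family, name = "n_genes")
}
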