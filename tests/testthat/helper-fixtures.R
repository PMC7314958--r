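# Shared builders for tiny hand-constructed genomes/models, plus independent
# brute-force oracles used to cross-check the package's implementations.

make_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

write_fasta_tmp <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  lines <- unlist(purrr::imap(seqs, function(s, n) c(paste0(">", n), s)))
  writeLines(lines, path)
  path
}

write_vcf_tmp <- function(rows) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

write_tsv_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A single-gene model on a given contig; intervals as data frames.
one_gene_model <- function(gene_id, contig, strand, exons, cds, complete = TRUE) {
  gene_models(gene_id = gene_id, contig = contig, strand = strand,
              exons = list(exons), cds = list(cds), complete = complete)
}

iv <- function(start, end, phase = NULL) {
  df <- data.frame(start = start, end = end)
  if (!is.null(phase)) df$phase <- phase
  df
}

# ---- Smith–Waterman brute-force oracle -------------------------------------
# Independent "last aligned pair" recursion: M[i,j] is the best score of any
# local alignment whose final column aligns a[i] with b[j]; gaps between
# consecutive aligned pairs cost open + len * ext per run. Exercises every
# alignment implicitly; O(n^2 m^2), fine for the short oracle panel.
oracle_sw <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  gap <- function(L) if (L == 0) 0 else scheme$gap_open + L * scheme$gap_extend
  sub <- function(x, y) scheme$matrix[x, y]
  M <- matrix(-Inf, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best_prev <- 0
      for (ii in seq_len(i - 1)) {
        for (jj in seq_len(j - 1)) {
          cand <- M[ii, jj] - gap(i - ii - 1) - gap(j - jj - 1)
          if (cand > best_prev) best_prev <- cand
        }
      }
      M[i, j] <- sub(av[i], bv[j]) + best_prev
    }
  }
  max(0, M)
}

# ---- hypergeometric enumeration oracle -------------------------------------
# P(X >= x) by enumerating every possible selection of size n from N genes of
# which the first K are group members.
oracle_hyper_tail <- function(x, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= x)
}

# ---- substitution-consequence oracle ---------------------------------------
# Applies a SNP/MNV to the contig, re-extracts the spliced CDS with unchanged
# coordinates, translates both proteins entirely and diffs them.
oracle_sub_effect <- function(genome, model, pos, ref, alt) {
  contig <- as.character(genome[[model$contig]])
  stopifnot(substr(contig, pos, pos + nchar(ref) - 1) == ref)
  mutated <- paste0(substr(contig, 1, pos - 1), alt,
                    substr(contig, pos + nchar(ref), nchar(contig)))
  extract <- function(src) {
    cd <- model$cds[[1]]
    s <- paste(purrr::map2_chr(cd$start, cd$end,
                               function(a, b) substr(src, a, b)), collapse = "")
    if (model$strand == "-") {
      s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    }
    s
  }
  p_ref <- strsplit(translate_cds(extract(contig)), "")[[1]]
  p_alt <- strsplit(translate_cds(extract(mutated)), "")[[1]]
  d <- which(p_ref != p_alt)
  if (length(d) == 0) return(list(effect = "synonymous", n_changed = 0L))
  effect <- if (any(p_alt[d] == "*")) "stop_gained"
  else if (any(p_ref[d] == "*")) "stop_lost"
  else "AAC"
  list(effect = effect, n_changed = length(d))
}

# classify a variant tibble built inline
variants_tbl <- function(contig, pos, ref, alt) {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
                 vclass = straindiff:::classify_vclass(ref, alt))
}
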