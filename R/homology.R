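#' Alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin–Altschul parameters used to scale raw Smith–Waterman scores into
#' e-values. The nucleotide default is +1/−2 with gap open 5 / extend 2; the
#' protein default is BLOSUM62 with gap open 11 / extend 1. A gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' Karlin–Altschul parameters are fixed per scheme (they rank hits at desk
#' scale; they are not publication statistics): nucleotide lambda = 1.28,
#' K = 0.46; protein lambda = 0.267, K = 0.041.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch nucleotide scores (ignored for protein mode).
#' @param gap_open,gap_extend positive gap penalties.
#' @param karlin_lambda,karlin_K positive reals for e-value scaling; defaults
#'   depend on `mode`.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 1, mismatch = -2,
                           gap_open = NULL, gap_extend = NULL,
                           karlin_lambda = NULL, karlin_K = NULL) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = FALSE)
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    karlin_lambda <- karlin_lambda %||% 1.28
    karlin_K <- karlin_K %||% 0.46
  } else {
    mat <- get_blosum62()
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    karlin_lambda <- karlin_lambda %||% 0.267
    karlin_K <- karlin_K %||% 0.041
  }
  if (gap_open <= 0 || gap_extend <= 0) stopf("gap penalties must be positive")
  structure(
    list(mode = mode, matrix = mat, gap_open = gap_open,
         gap_extend = gap_extend, karlin_lambda = karlin_lambda,
         karlin_K = karlin_K),
    class = "scoring_scheme"
  )
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

as_seq_chr <- function(x) {
  if (methods::is(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    x
  } else {
    stopf("sequences must be a character vector or an XStringSet")
  }
}

#' Local alignment of two sequences
#'
#' Optimal Smith–Waterman local alignment with affine gaps (full dynamic
#' programming via [Biostrings::pairwiseAlignment()] — no heuristic seeding).
#' When no positively scoring alignment exists the score is reported as 0
#' with an empty alignment.
#'
#' @param a,b sequences (character or `XString`/`XStringSet` of length 1).
#' @param scheme a [scoring_scheme()].
#' @return tibble with `score`, `identity` (% identical columns over the
#'   optimal traceback; `NA` for an empty alignment) and `aligned_length`.
#' @export
align_local <- function(a, b, scheme = scoring_scheme()) {
  a <- as_seq_chr(a)[1]
  b <- as_seq_chr(b)[1]
  pa <- pairwise_local(a, b, scheme)
  sc <- as.numeric(Biostrings::score(pa))
  if (sc <= 0) {
    return(tibble::tibble(score = 0, identity = NA_real_, aligned_length = 0L))
  }
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  tibble::tibble(
    score = sc,
    identity = 100 * Biostrings::nmatch(pa) / alen,
    aligned_length = alen
  )
}

pairwise_local <- function(pattern, subject, scheme) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
}

#' Karlin–Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments scoring at least `S` between a random query of length `m` and a
#' database of length `n`. Monotonically decreasing in `S`, linear in either
#' length.
#'
#' @param score raw alignment score.
#' @param query_len,db_len positive sequence lengths.
#' @param scheme a [scoring_scheme()] carrying `karlin_lambda`, `karlin_K`.
#' @return numeric expectation.
#' @export
hit_evalue <- function(score, query_len, db_len, scheme = scoring_scheme()) {
  if (any(query_len <= 0) || any(db_len <= 0)) stopf("lengths must be positive")
  scheme$karlin_K * query_len * db_len * exp(-scheme$karlin_lambda * score)
}

#' Best hit per query
#'
#' Aligns every query against every target and keeps, per query, the top hit
#' with `E <= e_threshold`, ranked by higher score, then lower e-value, then
#' higher identity, then lexicographically smallest target id. Queries with
#' no passing hit are reported with `NA` target.
#'
#' @param queries,targets named character vectors or `XStringSet`s.
#' @param scheme a [scoring_scheme()].
#' @param e_threshold significance cut-off (default 1e-5).
#' @return tibble with `query_id`, `target_id`, `score`, `evalue`,
#'   `identity`, `aligned_length`.
#' @export
best_hits <- function(queries, targets, scheme = scoring_scheme(),
                      e_threshold = 1e-5) {
  q <- as_seq_chr(queries)
  t <- as_seq_chr(targets)
  if (is.null(names(q))) names(q) <- paste0("q", seq_along(q))
  if (is.null(names(t))) names(t) <- paste0("t", seq_along(t))
  db_len <- sum(nchar(t))

  hits <- purrr::imap(as.list(t), function(tseq, tid) {
    pa <- pairwise_local(q, tseq, scheme)
    sc <- as.numeric(Biostrings::score(pa))
    alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
    tibble::tibble(
      query_id = names(q), target_id = tid, score = sc,
      identity = ifelse(sc > 0, 100 * Biostrings::nmatch(pa) / alen, NA_real_),
      aligned_length = ifelse(sc > 0, alen, 0L)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      score = pmax(.data$score, 0),
      evalue = hit_evalue(.data$score, nchar(q)[.data$query_id], db_len, scheme)
    )

  best <- hits |>
    dplyr::filter(.data$score > 0, .data$evalue <= e_threshold) |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$score), .data$evalue,
                   dplyr::desc(.data$identity), .data$target_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)

  missing <- setdiff(names(q), best$query_id)
  if (length(missing)) {
    best <- dplyr::bind_rows(
      best,
      tibble::tibble(query_id = missing, target_id = NA_character_,
                     score = NA_real_, identity = NA_real_,
                     aligned_length = NA_integer_, evalue = NA_real_)
    )
  }
  best |>
    dplyr::select("query_id", "target_id", "score", "evalue", "identity",
                  "aligned_length") |>
    dplyr::arrange(.data$query_id)
}

#' Reciprocal best hits
#'
#' `(a, b)` is an ortholog pair iff `b` is the best hit of `a` against set B
#' and `a` is the best hit of `b` against set A. Symmetric in its inputs;
#' `reciprocal_best_hits(A, A)` is the identity pairing.
#'
#' @param set_a,set_b named sequence sets.
#' @inheritParams best_hits
#' @return tibble with `id_a`, `id_b`, `score_ab`, `evalue_ab`, `identity_ab`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, scheme = scoring_scheme(),
                                 e_threshold = 1e-5) {
  ab <- best_hits(set_a, set_b, scheme, e_threshold)
  ba <- best_hits(set_b, set_a, scheme, e_threshold)
  ab |>
    dplyr::filter(!is.na(.data$target_id)) |>
    dplyr::inner_join(
      ba |>
        dplyr::filter(!is.na(.data$target_id)) |>
        dplyr::select(b_query = "query_id", b_target = "target_id"),
      by = c("target_id" = "b_query", "query_id" = "b_target")
    ) |>
    dplyr::transmute(
      id_a = .data$query_id, id_b = .data$target_id,
      score_ab = .data$score, evalue_ab = .data$evalue,
      identity_ab = .data$identity
    ) |>
    dplyr::arrange(.data$id_a)
}

#' Two-stage gene presence/absence calling
#'
#' Stage 1 searches each query gene against the target strain's CDS set;
#' queries without a significant hit are re-searched against the target's
#' full genome assembly (stage 2). A gene is `present_in_cds` on a stage-1
#' hit, `present_in_genome_only` on a stage-2 hit, and `absent` when no
#' significant e-value can be retrieved by either method.
#'
#' @param query_genes named sequence set (nucleotide CDS of the genes to
#'   probe, e.g. a CAZy gene list).
#' @param target_cds named sequence set of the target strain's CDSs.
#' @param target_genome [Biostrings::DNAStringSet] of the target assembly.
#' @inheritParams best_hits
#' @return tibble with `gene_id`, `status`, `stage1_target`, `stage1_evalue`,
#'   `stage2_target`, `stage2_evalue`.
#' @export
presence_absence <- function(query_genes, target_cds, target_genome,
                             scheme = scoring_scheme(), e_threshold = 1e-5) {
  s1 <- best_hits(query_genes, target_cds, scheme, e_threshold)
  res <- s1 |>
    dplyr::transmute(
      gene_id = .data$query_id,
      status = ifelse(is.na(.data$target_id), NA_character_, "present_in_cds"),
      stage1_target = .data$target_id, stage1_evalue = .data$evalue,
      stage2_target = NA_character_, stage2_evalue = NA_real_
    )
  misses <- res$gene_id[is.na(res$status)]
  if (length(misses)) {
    q <- as_seq_chr(query_genes)[misses]
    # genes can sit on either strand of the assembly: search both
    gen <- as_seq_chr(target_genome)
    both <- c(gen, setNames(purrr::map_chr(gen, revcomp_chr),
                            paste0(names(gen), ":rev")))
    s2 <- best_hits(q, both, scheme, e_threshold)
    for (i in seq_len(nrow(s2))) {
      j <- which(res$gene_id == s2$query_id[i])
      if (!is.na(s2$target_id[i])) {
        res$status[j] <- "present_in_genome_only"
        res$stage2_target[j] <- s2$target_id[i]
        res$stage2_evalue[j] <- s2$evalue[i]
      } else {
        res$status[j] <- "absent"
      }
    }
  }
  dplyr::arrange(res, .data$gene_id)
}
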