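#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for every percentage the package
#' reports so that printed tables recompute bit-exactly from their
#' numerator/denominator pairs. Base R's `round()` rounds half to even,
#' which disagrees on exact .5 boundaries.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.345, 2) # 2.35
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against representation error just below .5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage share, rounded half-up
#'
#' @param count numerator.
#' @param total denominator; must be supplied explicitly (denominators are
#'   never inferred from the data).
#' @param digits decimal places (default 2, matching overview tables).
#' @return percentage `100 * count / total`, or `NA` when `total` is zero.
#' @export
#' @examples
#' share_pct(660566, 686403) # 96.24
share_pct <- function(count, total, digits = 2) {
  out <- round_half_up(100 * count / total, digits)
  out[rep_len(total == 0, length(out))] <- NA_real_
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps the simulator free of global
# RNG side effects.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# reverse complement of a plain character string (ACGTN)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))
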