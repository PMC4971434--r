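#' @useDynLib contigvar, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "ref", "alt", "type", "sample_id", "key_",
  "region", "gene_id", "effect", "n_syn", "n_nonsyn", "dnds", "positive_flag",
  "snp_count", "indel_count", "length_bp", "ref_pos", "contig_pos", "strand",
  "run_id", "diag", "ref_end", "contig_end", "len", "prio", "start", "end",
  "value", "count", "qpos", "contig_id", "N", "V1", "s", "e", "si", "qi",
  "location", "shared", "effect_intended", "region_intended", "off",
  "ref_chrom", "snp_rate", "indel_rate"
))

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed report tables in this field
#' use conventional half-up rounding (e.g. 0.505 -> 0.51), so summary rates go
#' through this helper.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case preserved)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

cv_log <- function(...) {
  message("[contigvar] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic RNG scope: run expr with a given seed, restore previous state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
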