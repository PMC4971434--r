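#' Bundled published summary counts
#'
#' The package ships the printed summary counts of a published sesame
#' landrace-vs-variety genome comparison ("Baizhima" and "Mishuozhima" draft
#' assemblies against the "Zhongzhi13" reference): per-linkage-group variant
#' counts and lengths, the directed substitution spectrum, the 1-10 bp InDel
#' length spectrum, the genomic-location table and the headline shared/coding
#' counts. These printed counts are inputs from which every derived quantity
#' (per-kb rates, averages, roll-ups, sharing percentages) can be recomputed
#' and checked.
#'
#' @return list with `lg`, `spectrum`, `indel_lengths`, `region`, `headline`
#'   data.tables
#' @export
published_tables <- function() {
  d <- system.file("extdata", package = "contigvar")
  rd <- function(f) data.table::fread(file.path(d, f), sep = "\t")
  list(lg = rd("sesame_lg_counts.tsv"),
       spectrum = rd("sesame_substitution_spectrum.tsv"),
       indel_lengths = rd("sesame_indel_lengths.tsv"),
       region = rd("sesame_region_counts.tsv"),
       headline = rd("sesame_headline_counts.tsv"))
}

#' Recompute derived quantities from the published counts
#'
#' Recomputes, from printed counts and lengths only, the per-kb rates and
#' average/total rows of the per-linkage-group table, the mRNA/Total roll-ups
#' of the genomic-location table, the two-sample sharing percentages and the
#' coding-SNP identity, and compares them against the printed values.
#'
#' @param tbl output of [published_tables()]
#' @return list of recomputed tables and logical checks
#' @export
recompute_published <- function(tbl = published_tables()) {
  lg <- data.table::copy(tbl$lg)
  rate_cols <- list(c("snp_baizhima", "rate_snp_baizhima"),
                    c("snp_mishuozhima", "rate_snp_mishuozhima"),
                    c("indel_baizhima", "rate_indel_baizhima"),
                    c("indel_mishuozhima", "rate_indel_mishuozhima"))
  rates_ok <- TRUE
  recomputed <- data.table::copy(lg)
  for (rc in rate_cols) {
    r <- round_half_up(1000 * lg[[rc[1]]] / lg$length_bp, 2)
    recomputed[[rc[2]]] <- r
    rates_ok <- rates_ok && all(r == lg[[rc[2]]])
  }
  avg <- list(
    length_bp = round_half_up(mean(lg$length_bp), 2),
    counts = vapply(rate_cols, function(rc) round_half_up(mean(lg[[rc[1]]]), 2),
                    numeric(1)),
    rates = vapply(rate_cols, function(rc)
      round_half_up(mean(1000 * lg[[rc[1]]] / lg$length_bp), 2), numeric(1)))
  totals <- vapply(rate_cols, function(rc) sum(lg[[rc[1]]]), numeric(1))
  names(avg$counts) <- names(avg$rates) <- names(totals) <-
    vapply(rate_cols, `[[`, character(1), 1)

  reg <- tbl$region
  region_roll <- lapply(stats::setNames(names(reg)[-1], names(reg)[-1]),
                        function(cn) {
    x <- stats::setNames(reg[[cn]], reg$location)
    list(mrna = sum(x[c("UTR5", "CDS", "UTR3", "Intron")]),
         total = sum(x[c("UTR5", "CDS", "UTR3", "Intron")]) + x[["Intergenic"]],
         printed_mrna = x[["mRNA"]], printed_total = x[["Total"]])
  })
  h <- stats::setNames(tbl$headline$value, tbl$headline$quantity)
  venn_pct <- function(a, b, shared)
    as.integer(round_half_up(100 * shared / (a + b - shared), 0))
  list(lg_recomputed = recomputed, rates_ok = rates_ok, average = avg,
       totals = totals, region_roll = region_roll, headline = h,
       snp_shared_pct = venn_pct(totals[["snp_baizhima"]],
                                 totals[["snp_mishuozhima"]],
                                 h[["shared_snps"]]),
       indel_union = totals[["indel_baizhima"]] + totals[["indel_mishuozhima"]] -
         h[["shared_indels"]],
       coding_snp_identity = h[["synonymous_snps"]] + h[["nonsynonymous_snps"]])
}
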