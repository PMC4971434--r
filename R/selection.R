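#' Per-gene count-based dN/dS
#'
#' For every (gene, sample) with at least one classified coding SNP, counts
#' synonymous and non-synonymous SNPs and reports their raw count ratio.
#' "Non-synonymous" includes every amino-acid-sequence-changing SNP
#' (nonsynonymous, stop_gained, start_lost, stop_lost); large-effect classes
#' are additionally reported separately elsewhere. The ratio is intentionally
#' NOT site-normalized (see `site_normalized` for a Nei-Gojobori-style
#' per-site correction, clearly labelled as a methodological extension).
#'
#' @param effects output of [classify_effects()]
#' @param site_normalized if TRUE, scale the count ratio by the ratio of
#'   synonymous to non-synonymous site opportunities (requires `genes` and `g`)
#' @param genes,g gene models and genome (only for `site_normalized = TRUE`)
#' @return `data.table` with columns gene_id, sample_id, n_syn, n_nonsyn,
#'   dnds (2 decimals, NA when n_syn = 0) and positive_flag
#'   (n_nonsyn > n_syn)
#' @export
gene_dnds <- function(effects, site_normalized = FALSE, genes = NULL, g = NULL) {
  cds_snps <- effects[type == "SNP" & region == "CDS" & !is.na(effect)]
  stats <- cds_snps[, .(
    n_syn = sum(effect == "synonymous"),
    n_nonsyn = sum(effect %in% c("nonsynonymous", LARGE_EFFECT_SNP))),
    by = .(gene_id, sample_id)]
  scale <- 1
  if (site_normalized) {
    stopifnot(!is.null(genes), !is.null(g))
    stats[, dnds := NA_real_]
    for (i in seq_len(nrow(stats))) {
      sites <- syn_nonsyn_sites(genes[[stats$gene_id[i]]], g)
      if (stats$n_syn[i] > 0) {
        data.table::set(stats, i, "dnds", round_half_up(
          (stats$n_nonsyn[i] / sites["nonsyn"]) /
            (stats$n_syn[i] / sites["syn"]), 2))
      }
    }
  } else {
    stats[, dnds := ifelse(n_syn > 0, round_half_up(n_nonsyn / n_syn, 2), NA_real_)]
  }
  stats[, positive_flag := n_nonsyn > n_syn]
  data.table::setorder(stats, gene_id, sample_id)
  stats[]
}

# expected synonymous / non-synonymous site counts of a gene (equal-rate
# mutation model over the reference CDS)
syn_nonsyn_sites <- function(gene, g) {
  cds <- cds_sequence(gene, g)
  n <- nchar(cds)
  syn <- 0
  bases <- c("A", "C", "G", "T")
  for (off in 0:(n - 1)) {
    ci <- off %/% 3L
    old <- substr(cds, 3 * ci + 1, 3 * ci + 3)
    refb <- substr(cds, off + 1, off + 1)
    for (b in setdiff(bases, refb)) {
      cl <- classify_snp_at_offset(cds, off, b)
      if (cl == "synonymous") syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = n - syn)
}

#' Pooled non-synonymous-to-synonymous ratio of a gene set
#'
#' @param stats output of [gene_dnds()]
#' @param gene_ids character vector of member genes (ids absent from `stats`
#'   are logged and ignored)
#' @param name set label
#' @return list with `name`, `n_nonsyn`, `n_syn`, `ratio` (pooled
#'   sum(n_nonsyn)/sum(n_syn), NA when pooled n_syn = 0)
#' @export
geneset_ratio <- function(stats, gene_ids, name = "set") {
  if (length(gene_ids) == 0) stop("geneset_ratio: empty gene set")
  missing <- setdiff(gene_ids, stats$gene_id)
  if (length(missing) > 0)
    cv_log("gene set '", name, "': ", length(missing), " id(s) not scored")
  s <- stats[gene_id %in% gene_ids]
  nn <- sum(s$n_nonsyn); ns <- sum(s$n_syn)
  list(name = name, n_nonsyn = nn, n_syn = ns,
       ratio = if (ns > 0) round_half_up(nn / ns, 2) else NA_real_)
}

#' Rapidly diverging positively selected genes
#'
#' Positive-selection membership is decided by `n_nonsyn > n_syn` (equivalent
#' to dN/dS > 1 where defined, and total-order-free of division for
#' zero-synonymous genes); the filter then keeps genes with strictly more
#' than `min_snps` classified coding SNPs.
#'
#' @param stats output of [gene_dnds()]
#' @param min_snps threshold (strict; default 10)
#' @return `data.table` subset of `stats`
#' @export
rapid_divergence_filter <- function(stats, min_snps = 10) {
  stopifnot(min_snps >= 0)
  stats[positive_flag == TRUE & (n_syn + n_nonsyn) > min_snps][]
}
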