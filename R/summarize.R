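#' Per-chromosome variant counts and per-kb rates
#'
#' One row per chromosome and sample with SNP/InDel counts and rates
#' (1000 x count / length, rounded half-up to 2 decimals), followed by an
#' "Average" row (arithmetic mean of per-chromosome counts and the UNWEIGHTED
#' mean of the per-chromosome unrounded rates, both to 2 decimals) and a
#' "Total" count row. The unweighted average rate matches how such tables are
#' conventionally printed, even though it differs from total/length.
#'
#' @param v a `cv_variants` table (>= 1 sample)
#' @param g a `cv_genome`
#' @return `data.table` with columns chrom, length_bp, sample_id, snp_count,
#'   snp_rate_per_kb, indel_count, indel_rate_per_kb
#' @export
per_chromosome_summary <- function(v, g) {
  lens <- genome_lengths(g)
  if (nrow(v) > 0 && any(!(v$chrom %in% names(lens))))
    stop("variant(s) on chromosome absent from genome: ",
         paste(unique(setdiff(v$chrom, names(lens))), collapse = ", "))
  samples <- sort(unique(v$sample_id))
  if (length(samples) == 0) samples <- "sample"
  grid <- data.table::CJ(chrom = names(lens), sample_id = samples)
  cnt <- v[, .(snp_count = sum(type == "SNP"),
               indel_count = sum(type != "SNP")), by = .(chrom, sample_id)]
  out <- merge(grid, cnt, by = c("chrom", "sample_id"), all.x = TRUE)
  out[is.na(snp_count), snp_count := 0L]
  out[is.na(indel_count), indel_count := 0L]
  out[, length_bp := as.numeric(lens[chrom])]
  out[, `:=`(snp_rate = 1000 * snp_count / length_bp,
             indel_rate = 1000 * indel_count / length_bp)]
  data.table::setorder(out, sample_id, chrom)
  avg <- out[, .(chrom = "Average", length_bp = round_half_up(mean(length_bp), 2),
                 snp_count = round_half_up(mean(snp_count), 2),
                 snp_rate = round_half_up(mean(snp_rate), 2),
                 indel_count = round_half_up(mean(indel_count), 2),
                 indel_rate = round_half_up(mean(indel_rate), 2)),
             by = sample_id]
  tot <- out[, .(chrom = "Total", length_bp = sum(length_bp),
                 snp_count = sum(snp_count), snp_rate = NA_real_,
                 indel_count = sum(indel_count), indel_rate = NA_real_),
             by = sample_id]
  out[, `:=`(snp_rate = round_half_up(snp_rate, 2),
             indel_rate = round_half_up(indel_rate, 2))]
  res <- data.table::rbindlist(list(out, avg, tot), use.names = TRUE)
  data.table::setnames(res, c("snp_rate", "indel_rate"),
                       c("snp_rate_per_kb", "indel_rate_per_kb"))
  data.table::setcolorder(res, c("chrom", "length_bp", "sample_id", "snp_count",
                                 "snp_rate_per_kb", "indel_count",
                                 "indel_rate_per_kb"))
  res[]
}

#' Two-sample shared/unique variant summary
#'
#' Membership is decided by normalized variant-key equality. The shared
#' percentage is 100 x |A n B| / |A u B|, rounded to the nearest integer for
#' the headline figure.
#'
#' @param va,vb normalized `cv_variants` tables for the two samples
#' @return `data.table` with one row per variant class (SNP, InDel) and
#'   columns a_only, b_only, shared, union_size, shared_pct
#' @export
venn <- function(va, vb) {
  one <- function(cls) {
    ka <- unique(variant_key(va[if (cls == "SNP") type == "SNP" else type != "SNP"]))
    kb <- unique(variant_key(vb[if (cls == "SNP") type == "SNP" else type != "SNP"]))
    sh <- length(intersect(ka, kb))
    un <- length(union(ka, kb))
    data.table::data.table(
      class = cls, a_only = length(ka) - sh, b_only = length(kb) - sh,
      shared = sh, union_size = un,
      shared_pct = if (un > 0) as.integer(round_half_up(100 * sh / un, 0)) else NA_integer_)
  }
  data.table::rbindlist(list(one("SNP"), one("InDel")))
}

assert_identity <- function(ok, what) {
  if (!isTRUE(ok)) stop("conservation identity violated: ", what)
  invisible(TRUE)
}

#' Full report bundle
#'
#' Runs region annotation, effect classification, selection statistics and the
#' chromosome/spectrum/sharing summaries for one or two samples, re-checks all
#' cross-table conservation identities, and (optionally) writes the report
#' tables as TSV.
#'
#' @param g reference `cv_genome`
#' @param genes named list of `cv_gene`
#' @param variants a `cv_variants` table with one or two sample labels
#'   (normalized; [normalize_variants()] is applied defensively)
#' @param outdir optional output directory for TSV tables
#' @return list with elements `lg_summary`, `region_summary`, `spectrum`,
#'   `indel_lengths`, `dnds`, `large_effect`, `venn` (two-sample runs only)
#' @export
full_report <- function(g, genes, variants, outdir = NULL) {
  v <- normalize_variants(validate_variants(variants, g), g)
  idx <- build_region_index(genes, g)
  ann <- annotate_variants(v, idx)
  eff <- classify_effects(ann, genes, g)
  samples <- sort(unique(v$sample_id))

  lg <- per_chromosome_summary(v, g)
  reg <- region_summary(eff)
  spec <- lapply(stats::setNames(samples, samples), function(s)
    substitution_spectrum(v[sample_id == s & type == "SNP"]))
  ilen <- lapply(stats::setNames(samples, samples), function(s)
    indel_length_spectrum(v[sample_id == s & type != "SNP"]))
  dnds <- gene_dnds(eff)
  large <- eff[effect %in% c(LARGE_EFFECT_SNP, LARGE_EFFECT_INDEL)][
    , .(chrom, pos, ref, alt, type, sample_id, gene_id, effect)]
  data.table::setorder(large, gene_id, sample_id, chrom, pos)

  # conservation identities (each failure names the identity)
  for (s in samples) {
    n_snp <- nrow(v[sample_id == s & type == "SNP"])
    n_ind <- nrow(v[sample_id == s & type != "SNP"])
    lg_tot <- lg[chrom == "Total" & sample_id == s]
    assert_identity(lg_tot$snp_count == n_snp,
                    paste0("per-chromosome SNP total = SNP count [", s, "]"))
    assert_identity(sum(spec[[s]]) == n_snp,
                    paste0("substitution spectrum sum = SNP count [", s, "]"))
    assert_identity(sum(ilen[[s]]) == n_ind,
                    paste0("InDel length spectrum sum = InDel count [", s, "]"))
    rc <- reg[[paste0("SNP_", s)]]
    assert_identity(rc[5] == sum(rc[1:4]),
                    paste0("region table mRNA = UTR5+CDS+UTR3+Intron [", s, "]"))
    assert_identity(rc[7] == rc[5] + rc[6],
                    paste0("region table Total = mRNA+Intergenic [", s, "]"))
    assert_identity(rc[7] == n_snp,
                    paste0("region table SNP Total = SNP count [", s, "]"))
    ic <- reg[[paste0("InDel_", s)]]
    assert_identity(ic[5] == sum(ic[1:4]) && ic[7] == ic[5] + ic[6],
                    paste0("region table InDel additivity [", s, "]"))
    n_cds_classified <- nrow(eff[sample_id == s & type == "SNP" &
                                   region == "CDS" & !is.na(effect)])
    dd <- dnds[sample_id == s]
    assert_identity(sum(dd$n_syn) + sum(dd$n_nonsyn) == n_cds_classified,
                    paste0("synonymous + non-synonymous = classified CDS SNPs [", s, "]"))
  }
  vn <- NULL
  if (length(samples) == 2) {
    vn <- venn(v[sample_id == samples[1]], v[sample_id == samples[2]])
    for (r in seq_len(nrow(vn))) {
      assert_identity(vn$union_size[r] == vn$a_only[r] + vn$b_only[r] + vn$shared[r],
                      paste0("Venn union = A-only + B-only + shared [", vn$class[r], "]"))
    }
  }

  res <- list(lg_summary = lg, region_summary = reg, spectrum = spec,
              indel_lengths = ilen, dnds = dnds, large_effect = large,
              venn = vn, effects = eff)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) data.table::fwrite(x, file.path(outdir, f), sep = "\t")
    w(lg, "lg_summary.tsv")
    w(reg, "region_summary.tsv")
    spec_dt <- data.table::data.table(substitution = names(spec[[1]]))
    for (s in samples) spec_dt[, (s) := spec[[s]]]
    w(spec_dt, "substitution_spectrum.tsv")
    ilen_dt <- data.table::data.table(indel_bp = names(ilen[[1]]))
    for (s in samples) ilen_dt[, (s) := ilen[[s]]]
    w(ilen_dt, "indel_length_spectrum.tsv")
    w(dnds, "dnds.tsv")
    w(large, "large_effect_genes.tsv")
    if (!is.null(vn)) w(vn, "venn.tsv")
  }
  invisible(res)
}
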