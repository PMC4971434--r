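REGION_LEVELS <- c("UTR5", "CDS", "UTR3", "intron", "intergenic")

#' Build a genomic region index from gene models
#'
#' Maps every position covered by an mRNA to exactly one region class (CDS,
#' 5'UTR, 3'UTR or intron); positions outside all mRNA spans are intergenic.
#' Where gene models overlap, CDS beats UTR beats intron, and remaining ties
#' go to the lexicographically smaller gene id.
#'
#' @param genes named list of `cv_gene`
#' @param g optional `cv_genome` supplying the chromosome universe (required
#'   for unknown-chromosome errors at query time)
#' @return an object of class `cv_region_index`
#' @export
build_region_index <- function(genes, g = NULL) {
  segs <- list()
  for (gn in genes) {
    grab <- function(seg, region, prio) {
      if (nrow(seg) == 0) return(NULL)
      data.table::data.table(chrom = gn$chrom, start = seg[, 1], end = seg[, 2],
                             region = region, gene_id = gn$gene_id, prio = prio)
    }
    part <- data.table::rbindlist(list(
      grab(gn$cds_segments, "CDS", 1L),
      grab(gn$utr5_segments, "UTR5", 2L),
      grab(gn$utr3_segments, "UTR3", 2L),
      grab(introns(gn), "intron", 3L)))
    # partition check: segments tile the mRNA span without overlap
    if (nrow(part) > 0) {
      data.table::setorder(part, start)
      if (any(part$start[-1] <= part$end[-nrow(part)]))
        stop("gene ", gn$gene_id, ": region classes overlap within the mRNA")
      covered <- sum(part$end - part$start + 1L)
      if (covered != gn$mrna_span[2] - gn$mrna_span[1] + 1L)
        stop("gene ", gn$gene_id, ": region classes do not partition the mRNA span")
    }
    segs[[length(segs) + 1L]] <- part
  }
  dt <- if (length(segs)) data.table::rbindlist(segs) else
    data.table::data.table(chrom = character(0), start = integer(0),
                           end = integer(0), region = character(0),
                           gene_id = character(0), prio = integer(0))
  by_chrom <- split(dt, by = "chrom")
  ir <- lapply(by_chrom, function(d) IRanges::IRanges(d$start, d$end))
  idx <- list(dt = dt, by_chrom = by_chrom, ir = ir,
              chroms = if (!is.null(g)) names(g$seq) else NULL,
              lengths = if (!is.null(g)) genome_lengths(g) else NULL)
  class(idx) <- "cv_region_index"
  idx
}

# region query base: SNP -> pos; InDel -> first altered reference base
# (pos + 1, capped at the chromosome end for terminal insertions)
region_query_pos <- function(v, idx) {
  qp <- v$pos
  ind <- v$type != "SNP"
  qp[ind] <- qp[ind] + 1L
  if (!is.null(idx$lengths)) {
    cap <- idx$lengths[v$chrom]
    qp <- pmin(qp, cap)
  }
  as.integer(qp)
}

#' Assign variants to genomic regions
#'
#' SNPs are classified by their position; InDels by the first altered
#' reference base (the base after the VCF anchor). Input order is preserved.
#'
#' @param v a normalized `cv_variants` table
#' @param idx a [build_region_index()] object
#' @return the table with `region` and `gene_id` columns added
#' @export
annotate_variants <- function(v, idx) {
  stopifnot(inherits(idx, "cv_region_index"))
  out <- data.table::copy(v)
  if (nrow(out) == 0) {
    out[, `:=`(region = character(0), gene_id = character(0))]
    return(out[])
  }
  if (!is.null(idx$chroms) && any(!(out$chrom %in% idx$chroms)))
    stop("variant(s) on unknown chromosome: ",
         paste(unique(setdiff(out$chrom, idx$chroms)), collapse = ", "))
  out[, qpos := region_query_pos(out, idx)]
  out[, `:=`(region = "intergenic", gene_id = NA_character_)]
  for (cc in names(idx$by_chrom)) {
    sel <- which(out$chrom == cc)
    if (length(sel) == 0) next
    q <- IRanges::IRanges(out$qpos[sel], out$qpos[sel])
    hits <- IRanges::findOverlaps(q, idx$ir[[cc]])
    if (length(hits) == 0) next
    h <- data.table::data.table(qi = S4Vectors::queryHits(hits),
                                si = S4Vectors::subjectHits(hits))
    d <- idx$by_chrom[[cc]]
    h[, `:=`(prio = d$prio[si], region = d$region[si], gene_id = d$gene_id[si])]
    data.table::setorder(h, qi, prio, gene_id)
    h <- h[!duplicated(qi)]
    out[sel[h$qi], `:=`(region = h$region, gene_id = h$gene_id)]
  }
  out[, qpos := NULL]
  out[]
}

#' Region summary table
#'
#' Counts variants per region class, sample and variant class (SNP vs InDel),
#' with derived roll-up rows: mRNA = UTR5 + CDS + UTR3 + intron and
#' Total = mRNA + intergenic.
#'
#' @param annotated output of [annotate_variants()] (>= 1 sample)
#' @return `data.table` with one row per location class (UTR5, CDS, UTR3,
#'   Intron, mRNA, Intergenic, Total) and one column per sample x class
#' @export
region_summary <- function(annotated) {
  samples <- sort(unique(annotated$sample_id))
  if (length(samples) == 0) samples <- "sample"
  out <- data.table::data.table(
    location = c("UTR5", "CDS", "UTR3", "Intron", "mRNA", "Intergenic", "Total"))
  for (s in samples) {
    for (cls in c("SNP", "InDel")) {
      vv <- annotated[sample_id == s &
                        (if (cls == "SNP") type == "SNP" else type != "SNP")]
      cnt <- function(r) sum(vv$region == r)
      mrna <- cnt("UTR5") + cnt("CDS") + cnt("UTR3") + cnt("intron")
      col <- c(cnt("UTR5"), cnt("CDS"), cnt("UTR3"), cnt("intron"),
               mrna, cnt("intergenic"), mrna + cnt("intergenic"))
      out[, (paste0(cls, "_", s)) := col]
    }
  }
  out[]
}
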