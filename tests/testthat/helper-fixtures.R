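# Fixtures are built in code; no binary data anywhere.

# deterministic toy genome with one two-exon plus-strand gene
toy_genome <- function() {
  # layout on chr1 (1-based):
  #   1-100   intergenic
  # 101-130   5'UTR
  # 131-202   CDS exon 1 (72 bp, starts ATG)
  # 203-302   intron
  # 303-380   CDS exon 2 (78 bp, ends TAA)
  # 381-450   3'UTR
  # 451-600   intergenic
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  cds1 <- paste(c("ATG", sample(non_stop, 23, replace = TRUE)), collapse = "")
  cds2 <- paste(c(sample(non_stop, 25, replace = TRUE), "TAA"), collapse = "")
  seq <- paste0(rand(100), rand(30), cds1, rand(100), cds2, rand(70), rand(150))
  g <- genome(c(chr1 = seq))
  gene <- gene_model("gtoy", "chr1", "+",
                     cds_segments = rbind(c(131L, 202L), c(303L, 380L)),
                     utr5_segments = rbind(c(101L, 130L)),
                     utr3_segments = rbind(c(381L, 450L)))
  genes <- flag_non_canonical(list(gtoy = gene), g)
  list(genome = g, genes = genes)
}

# mirror of toy_genome: reverse-complemented chromosome, minus-strand gene
toy_genome_mirror <- function(fw = toy_genome()) {
  L <- genome_lengths(fw$genome)[["chr1"]]
  g <- genome(c(chr1 = revcomp(fw$genome$seq[["chr1"]])))
  mir <- function(seg) {
    m <- cbind(L - seg[, 2] + 1L, L - seg[, 1] + 1L)
    m[order(m[, 1]), , drop = FALSE]
  }
  gn <- fw$genes$gtoy
  gene <- gene_model("gtoy", "chr1", "-",
                     cds_segments = mir(gn$cds_segments),
                     utr5_segments = mir(gn$utr5_segments),
                     utr3_segments = mir(gn$utr3_segments))
  list(genome = g, genes = flag_non_canonical(list(gtoy = gene), g),
       mirror_pos = function(p) L - p + 1L)
}

small_sim_config <- function(seed = 5, ...) {
  simulation_config(seed = seed, n_chroms = 1L, chrom_length_bp = 120000L,
                    n_genes = 25L, ...)
}

# --- independent oracles -----------------------------------------------------

# exhaustive best colinear-subset weight (chain oracle, n <= 12)
brute_force_chain_weight <- function(anchors) {
  n <- nrow(anchors)
  rs <- anchors$ref_pos; re <- rs + anchors$len - 1L
  cs <- anchors$contig_pos; ce <- cs + anchors$len - 1L
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) < 1) next
    sel <- sel[order(rs[sel])]
    ok <- TRUE
    if (length(sel) > 1) {
      for (i in 2:length(sel)) {
        a <- sel[i - 1]; b <- sel[i]
        if (!(re[a] < rs[b] && ce[a] < cs[b])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(anchors$len[sel]))
  }
  best
}

# leftmost equivalent anchored representation of an InDel, by enumeration of
# candidate placements whose application reproduces the mutated sequence
brute_force_normalize <- function(v, g) {
  s <- g$seq[[v$chrom]]
  mutated <- apply_variants(g, v)$seq[[v$chrom]]
  L <- abs(nchar(v$ref) - nchar(v$alt))
  is_del <- nchar(v$ref) > nchar(v$alt)
  hits <- list()
  for (p in seq_len(nchar(s) - if (is_del) L else 0L)) {
    cand <- if (is_del) {
      variant_table(v$chrom, p, substr(s, p, p + L), substr(s, p, p),
                    v$sample_id[1])
    } else {
      # the inserted string at anchor p is uniquely determined by the
      # mutated sequence; a mismatching anchor base rules the placement out
      if (substr(mutated, p, p) != substr(s, p, p)) next
      variant_table(v$chrom, p, substr(s, p, p),
                    substr(mutated, p, p + L), v$sample_id[1])
    }
    if (identical(apply_variants(g, cand)$seq[[v$chrom]], mutated)) {
      hits[[length(hits) + 1L]] <- cand
    }
  }
  hits[[which.min(vapply(hits, function(h) h$pos, integer(1)))]]
}

# whole-protein re-translation classifier (effects oracle)
oracle_snp_effect <- function(v, gene, g) {
  stopifnot(v$type == "SNP")
  mut <- apply_variants(g, v)
  cds_old <- cds_sequence(gene, g)
  cds_new <- cds_sequence(gene, mut)
  tr <- function(x) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(x), if.fuzzy.codon = "X")),
    "")[[1]]
  aa_old <- tr(cds_old); aa_new <- tr(cds_new)
  n <- length(aa_new)
  if (aa_new[1] != "M") return("start_lost")
  if (aa_new[n] != "*") return("stop_lost")
  if (any(aa_new[-n] == "*")) return("stop_gained")
  if (identical(aa_old, aa_new)) "synonymous" else "nonsynonymous"
}
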