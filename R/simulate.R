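#' Simulation configuration
#'
#' The stated world for the synthetic data generator: a small plant-like
#' genome with annotated canonical genes, two derived "landrace" genomes
#' carrying transition-biased SNPs and geometric-length InDels with a shared
#' mutation core, and draft-assembly-style contig fragmentation. Defaults
#' mirror the magnitudes of a sesame landrace-vs-variety comparison scaled to
#' a toy genome (rates ~4 SNPs/kb and ~1.4 InDels/kb, ts/tv ~1.9, ~46%
#' shared variants, contigs tens of kb with a 200 bp minimum).
#'
#' @param seed integer RNG seed (all outputs are pure functions of the config)
#' @param n_chroms,chrom_length_bp genome shape
#' @param n_genes,mean_exons_per_gene gene complement
#' @param snp_rate_per_kb,indel_rate_per_kb per-landrace mutation rates
#' @param ts_tv_ratio transition/transversion bias
#' @param indel_geom_p,max_indel_len geometric InDel length distribution
#'   (support 1..max_indel_len)
#' @param shared_fraction fraction of the mutation union common to both
#'   landraces
#' @param contig_mean_len_bp,contig_gap_frac,min_contig_len_bp,revcomp_fraction
#'   fragmentation parameters
#' @param large_effect_quota named integer vector of forced per-sample counts
#'   per effect class (stop_gained, start_lost, stop_lost, frameshift,
#'   start_codon_indel, stop_codon_indel)
#' @param min_spacing_bp hard-core minimum distance between mutations (keeps
#'   truth/recovery comparison exact)
#' @param cut_margin_bp contig cut points keep this distance from truth
#'   variants
#' @return a `cv_sim_config` list
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L, chrom_length_bp = 500000L,
                              n_genes = 120L, mean_exons_per_gene = 3,
                              snp_rate_per_kb = 4, indel_rate_per_kb = 1.4,
                              ts_tv_ratio = 1.9, indel_geom_p = 0.45,
                              max_indel_len = 50L, shared_fraction = 0.46,
                              contig_mean_len_bp = 40000L, contig_gap_frac = 0,
                              min_contig_len_bp = 200L, revcomp_fraction = 0.5,
                              large_effect_quota = integer(0),
                              min_spacing_bp = 60L, cut_margin_bp = 100L) {
  cfg <- as.list(environment())
  stopifnot(snp_rate_per_kb >= 0, indel_rate_per_kb >= 0,
            shared_fraction >= 0, shared_fraction <= 1,
            ts_tv_ratio > 0, indel_geom_p > 0, indel_geom_p < 1,
            n_chroms >= 1, chrom_length_bp >= 1000)
  if (length(cfg$large_effect_quota) > 0) {
    bad <- setdiff(names(cfg$large_effect_quota),
                   c(LARGE_EFFECT_SNP, LARGE_EFFECT_INDEL))
    if (length(bad)) stop("unknown large-effect class(es): ",
                          paste(bad, collapse = ", "))
    if (sum(cfg$large_effect_quota) * 2 > n_genes)
      stop("large_effect_quota infeasible for ", n_genes, " genes")
  }
  class(cfg) <- "cv_sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

random_dna <- function(n, probs = c(A = 0.325, C = 0.175, G = 0.175, T = 0.325)) {
  paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# split total into k parts, each >= minpart
split_len <- function(total, k, minpart) {
  if (k == 1) return(total)
  free <- total - k * minpart
  cuts <- sort(sample.int(free + 1L, k - 1L, replace = TRUE) - 1L)
  diff(c(0L, cuts, free)) + minpart
}

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

#' Simulate a reference genome with annotated genes
#'
#' Chromosomes are random DNA (AT-rich, plant-like) into which canonical
#' protein-coding genes are packed with positive intergenic spacing. Every
#' CDS starts with ATG, is in frame, free of internal stop codons and ends at
#' a stop codon; multi-exon genes carry introns, and each transcript has 5'
#' and 3' UTRs. Deterministic given the config seed.
#'
#' @param config a [simulation_config()]
#' @return list with `genome` (a `cv_genome`) and `genes` (named `cv_gene` list)
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, {
    seqs <- stats::setNames(
      vapply(seq_len(config$n_chroms), function(i)
        random_dna(config$chrom_length_bp), character(1)),
      sprintf("chr%02d", seq_len(config$n_chroms)))
    genes <- list()
    per_chrom <- table(factor(rep(seq_len(config$n_chroms),
                                  length.out = config$n_genes),
                              levels = seq_len(config$n_chroms)))
    gi <- 0L
    for (ci in seq_len(config$n_chroms)) {
      chrom <- names(seqs)[ci]
      cursor <- sample(300:800, 1)
      for (j in seq_len(per_chrom[ci])) {
        gi <- gi + 1L
        gid <- sprintf("g%04d", gi)
        built <- build_gene(gid, chrom, cursor, config)
        if (built$end > config$chrom_length_bp - 300L) {
          stop("infeasible packing: ", config$n_genes, " genes do not fit in ",
               config$chrom_length_bp, " bp chromosomes")
        }
        substr(seqs[[ci]], built$start, built$end) <- built$seq
        genes[[gid]] <- built$gene
        cursor <- built$end + sample(300:1500, 1)
      }
    }
    g <- genome(seqs)
    list(genome = g, genes = flag_non_canonical(genes, g))
  })
}

# construct one gene at a given genomic start; returns sequence + model
build_gene <- function(gid, chrom, start, config) {
  n_ex <- max(1L, stats::rpois(1, max(0, config$mean_exons_per_gene - 1)) + 1L)
  n_codons <- sample(100:300, 1)
  cds_len <- 3L * n_codons
  chunks <- split_len(cds_len, n_ex, 9L)
  u5 <- sample(30:150, 1); u3 <- sample(60:250, 1)
  intr <- if (n_ex > 1) sample(80:300, n_ex - 1, replace = TRUE) else integer(0)
  strand <- sample(c("+", "-"), 1)
  cds_seq <- paste(c("ATG",
                     sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
                     sample(STOP_CODONS, 1)), collapse = "")
  # transcript-space layout, 1-based
  t_cds <- matrix(0L, n_ex, 2)
  cur <- u5 + 1L
  pieces <- c(random_dna(u5))
  cds_cur <- 1L
  for (e in seq_len(n_ex)) {
    t_cds[e, ] <- c(cur, cur + chunks[e] - 1L)
    pieces <- c(pieces, substr(cds_seq, cds_cur, cds_cur + chunks[e] - 1L))
    cds_cur <- cds_cur + chunks[e]
    cur <- cur + chunks[e]
    if (e < n_ex) {
      pieces <- c(pieces, random_dna(intr[e]))
      cur <- cur + intr[e]
    }
  }
  pieces <- c(pieces, random_dna(u3))
  L <- cur + u3 - 1L
  t_u5 <- matrix(c(1L, u5), 1)
  t_u3 <- matrix(c(L - u3 + 1L, L), 1)
  seq_fwd <- paste(pieces, collapse = "")
  to_genomic <- function(seg) {
    if (strand == "+") seg + start - 1L
    else as_segments(cbind(start + (L - seg[, 2]), start + (L - seg[, 1])))
  }
  gene <- gene_model(gene_id = gid, chrom = chrom, strand = strand,
                     cds_segments = to_genomic(t_cds),
                     utr5_segments = to_genomic(t_u5),
                     utr3_segments = to_genomic(t_u3),
                     mrna_span = c(start, start + L - 1L))
  list(gene = gene, start = start, end = start + L - 1L,
       seq = if (strand == "-") revcomp(seq_fwd) else seq_fwd)
}

# --- mutation machinery ------------------------------------------------------

# genomic position of each CDS offset (transcript order)
genomic_cds_positions <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds_segments)), function(i)
    gene$cds_segments[i, 1]:gene$cds_segments[i, 2]))
  if (gene$strand == "-") rev(pos) else pos
}

translate_cds <- function(cds) {
  n <- nchar(cds)
  unname(Biostrings::GENETIC_CODE[substring(cds, seq(1, n, 3), seq(3, n, 3))])
}

# effect of a mutated CDS, judged from whole-protein comparison
classify_from_proteins <- function(aa_old, aa_new) {
  n <- length(aa_new)
  if (aa_new[1] != "M") return("start_lost")
  if (!identical(aa_new[n], "*")) return("stop_lost")
  if (n > 1 && any(aa_new[-n] == "*")) return("stop_gained")
  if (identical(aa_old, aa_new)) "synonymous" else "nonsynonymous"
}

# classify a CDS SNP by re-translating the whole CDS
snp_effect_by_translation <- function(cds, aa_old, off, alt_tx) {
  new_cds <- cds
  substr(new_cds, off + 1, off + 1) <- alt_tx
  ci <- off %/% 3L
  aa_new <- aa_old
  aa_new[ci + 1L] <- unname(Biostrings::GENETIC_CODE[
    substr(new_cds, 3 * ci + 1, 3 * ci + 3)])
  classify_from_proteins(aa_old, aa_new)
}

# left/right placement-stability checks against homopolymer ambiguity
deletion_stable <- function(s, pos, len) {
  L <- nchar(s)
  pos + len + 1L <= L &&
    substr(s, pos, pos) != substr(s, pos + len, pos + len) &&
    substr(s, pos + 1L, pos + 1L) != substr(s, pos + len + 1L, pos + len + 1L)
}
insertion_stable <- function(s, pos, ins) {
  l <- nchar(ins)
  substr(ins, l, l) != substr(s, pos, pos) &&
    substr(ins, 1L, 1L) != substr(s, pos + 1L, pos + 1L)
}

# positions in [lo, hi] with pairwise gaps >= spacing (stars-and-bars)
spaced_positions <- function(n, lo, hi, spacing) {
  if (n <= 0) return(integer(0))
  free <- (hi - lo) - (n - 1L) * spacing
  if (free < 0) stop("mutation rate infeasible at the configured spacing")
  sort(sample.int(free + 1L, n, replace = TRUE) - 1L) +
    lo + (seq_len(n) - 1L) * spacing
}

# simulator-local region lookup (interval arithmetic on the gene models,
# independent of the IRanges-based annotation path)
sim_region_of <- function(genes_chrom, qpos) {
  for (gn in genes_chrom) {
    if (qpos < gn$mrna_span[1] || qpos > gn$mrna_span[2]) next
    inseg <- function(seg) nrow(seg) > 0 &&
      any(qpos >= seg[, 1] & qpos <= seg[, 2])
    if (inseg(gn$cds_segments)) return(list(region = "CDS", gene = gn))
    if (inseg(gn$utr5_segments)) return(list(region = "UTR5", gene = gn))
    if (inseg(gn$utr3_segments)) return(list(region = "UTR3", gene = gn))
    return(list(region = "intron", gene = gn))
  }
  list(region = "intergenic", gene = NULL)
}

#' Mutate a reference genome into landrace genomes with a truth set
#'
#' Generates a union of non-overlapping mutations (hard-core spacing) with a
#' shared core, transition-biased SNP alleles and geometric InDel lengths,
#' forces any configured large-effect quota per sample, applies the variants,
#' and returns the mutated genomes plus a machine-readable truth table with
#' intended region and effect classes.
#'
#' @param ref output of [simulate_reference()] (list with genome and genes)
#' @param config a [simulation_config()]
#' @param samples two sample labels
#' @return list with `genomes` (named list of `cv_genome`) and `truth`
#'   (a `cv_variants` table with extra columns shared, region_intended,
#'   effect_intended)
#' @export
mutate_genome <- function(ref, config, samples = c("landraceA", "landraceB")) {
  stopifnot(length(samples) == 2)
  g <- ref$genome; genes <- ref$genes
  with_seed(config$seed + 1000L, {
    sf <- config$shared_fraction
    spacing <- config$min_spacing_bp
    margin <- 200L
    genes_by_chrom <- split(genes, vapply(genes, `[[`, character(1), "chrom"))
    occupied <- lapply(g$seq, function(x) empty_segments())
    recs <- list()
    add_rec <- function(chrom, pos, refa, alta, sample_ids, shared, effect) {
      qpos <- if (nchar(refa) == 1 && nchar(alta) == 1) pos else pos + 1L
      reg <- sim_region_of(genes_by_chrom[[chrom]] %||% list(), qpos)$region
      for (s in sample_ids) {
        recs[[length(recs) + 1L]] <<- data.table::data.table(
          chrom = chrom, pos = pos, ref = refa, alt = alta, sample_id = s,
          shared = shared, region_intended = reg, effect_intended = effect)
      }
      occupied[[chrom]] <<- rbind(
        occupied[[chrom]],
        c(pos - spacing, pos + nchar(refa) + spacing))
    }

    # forced large-effect variants, per sample, in distinct canonical genes
    quota <- config$large_effect_quota
    if (length(quota) > 0) {
      canon <- names(genes)[!vapply(genes, `[[`, logical(1), "non_canonical")]
      pool <- sample(canon)
      take <- 0L
      for (s in samples) {
        for (cls in names(quota)) {
          for (q in seq_len(quota[[cls]])) {
            placed <- FALSE
            while (!placed) {
              take <- take + 1L
              if (take > length(pool))
                stop("large-effect quota unplaceable for class ", cls)
              v <- make_large_effect_variant(genes[[pool[take]]], cls, g)
              if (!is.null(v)) {
                add_rec(v$chrom, v$pos, v$ref, v$alt, s, FALSE, cls)
                placed <- TRUE
              }
            }
          }
        }
      }
    }

    # random union events
    u_factor <- 2 / (1 + sf)
    for (chrom in names(g$seq)) {
      L <- nchar(g$seq[[chrom]])
      s <- g$seq[[chrom]]
      n_snp <- stats::rbinom(1, L, min(1, config$snp_rate_per_kb / 1000 * u_factor))
      n_ind <- stats::rbinom(1, L, min(1, config$indel_rate_per_kb / 1000 * u_factor))
      pos <- spaced_positions(n_snp + n_ind, margin, L - margin, spacing)
      occ <- occupied[[chrom]]
      if (nrow(occ) > 0) {
        hit <- vapply(pos, function(p)
          any(p >= occ[, 1] - config$max_indel_len & p <= occ[, 2]), logical(1))
        pos <- pos[!hit]
      }
      is_snp <- seq_along(pos) %in% sample(seq_along(pos), min(n_snp, length(pos)))
      ts_prob <- config$ts_tv_ratio / (config$ts_tv_ratio + 1)
      for (i in seq_along(pos)) {
        p <- pos[i]
        refb <- substr(s, p, p)
        who <- if (stats::runif(1) < sf) samples else
          if (stats::runif(1) < 0.5) samples[1] else samples[2]
        shared <- length(who) == 2
        if (is_snp[i]) {
          alt <- if (stats::runif(1) < ts_prob) TS_PARTNER[[refb]] else
            sample(setdiff(BASES, c(refb, TS_PARTNER[[refb]])), 1)
          reg <- sim_region_of(genes_by_chrom[[chrom]] %||% list(), p)
          eff <- "noncoding"
          if (reg$region == "CDS" && !reg$gene$non_canonical) {
            gene <- reg$gene
            cds <- cds_sequence(gene, g)
            gp <- genomic_cds_positions(gene)
            off <- match(p, gp) - 1L
            alt_tx <- if (gene$strand == "-") COMPLEMENT[[alt]] else alt
            eff <- snp_effect_by_translation(cds, translate_cds(cds), off, alt_tx)
          }
          add_rec(chrom, p, refb, alt, who, shared, eff)
        } else {
          ind <- make_random_indel(s, p, config)
          if (is.null(ind)) next
          reg <- sim_region_of(genes_by_chrom[[chrom]] %||% list(), p + 1L)
          eff <- if (reg$region == "CDS" && !reg$gene$non_canonical) {
            classify_indel_offsets(
              if (nchar(ind$ref) > 1) "deletion" else "insertion",
              p, nchar(ind$ref), nchar(ind$alt), reg$gene)
          } else "noncoding"
          add_rec(chrom, p, ind$ref, ind$alt, who, shared, eff)
        }
      }
    }
    truth <- if (length(recs) == 0) {
      data.table::data.table(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             sample_id = character(0), shared = logical(0),
                             region_intended = character(0),
                             effect_intended = character(0))
    } else data.table::rbindlist(recs)
    truth[, type := infer_var_type(ref, alt)]
    data.table::setcolorder(truth, c("chrom", "pos", "ref", "alt", "type",
                                     "sample_id"))
    data.table::setattr(truth, "class", c("cv_variants", class(truth)))
    data.table::setorder(truth, sample_id, chrom, pos)
    genomes <- lapply(stats::setNames(samples, samples), function(smp)
      apply_variants(g, truth[sample_id == smp]))
    list(genomes = genomes, truth = truth[])
  })
}

make_random_indel <- function(s, p, config) {
  L <- nchar(s)
  is_del <- stats::runif(1) < 0.5
  len0 <- min(config$max_indel_len, stats::rgeom(1, config$indel_geom_p) + 1L)
  if (is_del) {
    len <- len0
    while (len >= 1L && !deletion_stable(s, p, len)) len <- len - 1L
    if (len >= 1L && p + len <= L)
      return(list(ref = substr(s, p, p + len), alt = substr(s, p, p)))
    # no shift-stable deletion here: fall back to an insertion so the
    # realized InDel count tracks the configured rate
  }
  for (try in 1:10) {
    ins <- random_dna(len0, probs = c(A = .25, C = .25, G = .25, T = .25))
    if (insertion_stable(s, p, ins))
      return(list(ref = substr(s, p, p), alt = paste0(substr(s, p, p), ins)))
  }
  NULL
}

# construct one forced large-effect variant inside a gene; NULL if the gene
# offers no stable placement for the class
make_large_effect_variant <- function(gene, cls, g) {
  if (gene$non_canonical) return(NULL)
  cds <- cds_sequence(gene, g)
  n <- nchar(cds)
  gp <- genomic_cds_positions(gene)
  s <- g$seq[[gene$chrom]]
  tx2g_base <- function(b) if (gene$strand == "-") COMPLEMENT[[b]] else b
  mk_snp <- function(off, alt_tx) {
    p <- gp[off + 1L]
    list(chrom = gene$chrom, pos = p, ref = substr(s, p, p),
         alt = tx2g_base(alt_tx))
  }
  if (cls == "stop_gained") {
    for (ci in sample(1:(n %/% 3L - 2L))) {
      old <- substr(cds, 3 * ci + 1, 3 * ci + 3)
      for (w in sample(0:2)) for (b in sample(BASES)) {
        if (b == substr(old, w + 1, w + 1)) next
        new <- old; substr(new, w + 1, w + 1) <- b
        if (new %in% STOP_CODONS) return(mk_snp(3L * ci + w, b))
      }
    }
    return(NULL)
  }
  if (cls == "start_lost") {
    w <- sample(0:2, 1)
    old <- substr(cds, w + 1, w + 1)
    return(mk_snp(w, sample(setdiff(BASES, old), 1)))
  }
  if (cls == "stop_lost") {
    old <- substr(cds, n - 2, n)
    for (w in sample(0:2)) for (b in sample(BASES)) {
      if (b == substr(old, w + 1, w + 1)) next
      new <- old; substr(new, w + 1, w + 1) <- b
      if (!(new %in% STOP_CODONS)) return(mk_snp(n - 3L + w, b))
    }
    return(NULL)
  }
  if (cls == "frameshift") {
    for (off in sample(9:(n - 13L))) {
      gpos <- gp[off + 1L]
      p <- gpos - 1L  # anchor
      if (p < 1) next
      # single-base deletion of a CDS-internal base; must stay mid-CDS
      if (deletion_stable(s, p, 1L) &&
          !is.na(off) && off > 2L && off < n - 3L)
        return(list(chrom = gene$chrom, pos = p,
                    ref = substr(s, p, p + 1L), alt = substr(s, p, p)))
    }
    return(NULL)
  }
  if (cls %in% c("start_codon_indel", "stop_codon_indel")) {
    offs <- if (cls == "start_codon_indel") c(0L, 1L) else c(n - 3L, n - 2L)
    for (off in sample(offs)) {
      gpair <- sort(gp[c(off + 1L, off + 2L)])
      p <- gpair[1]  # insertion anchored between two in-codon bases
      for (try in 1:8) {
        ins <- sample(BASES, 1)
        if (insertion_stable(s, p, ins))
          return(list(chrom = gene$chrom, pos = p, ref = substr(s, p, p),
                      alt = paste0(substr(s, p, p), ins)))
      }
    }
    return(NULL)
  }
  stop("unknown large-effect class: ", cls)
}

#' Simulate coding SNPs with controlled class odds
#'
#' Places `n` SNPs at distinct CDS positions of canonical genes. With
#' `p_nonsyn` set, each SNP's alternate allele is chosen so that the SNP is
#' synonymous with probability `1 - p_nonsyn` and amino-acid-changing
#' otherwise (positions offering no allele of the drawn class are redrawn).
#' Intended effect classes are determined by whole-CDS re-translation,
#' independently of the per-codon classifier.
#'
#' @param ref output of [simulate_reference()]
#' @param n number of SNPs
#' @param p_nonsyn probability of an amino-acid-changing SNP (NULL: alternate
#'   alleles drawn uniformly)
#' @param sample_id sample label
#' @param seed RNG seed
#' @return a `cv_variants` table with an `effect_intended` column
#' @export
simulate_cds_snps <- function(ref, n, p_nonsyn = NULL,
                              sample_id = "landraceA", seed = 1L) {
  g <- ref$genome
  canon <- Filter(function(x) !x$non_canonical, ref$genes)
  with_seed(seed + 5000L, {
    pool <- data.table::rbindlist(lapply(canon, function(gn) {
      gp <- genomic_cds_positions(gn)
      data.table::data.table(gene_id = gn$gene_id, chrom = gn$chrom,
                             pos = gp, off = seq_along(gp) - 1L)
    }))
    if (nrow(pool) < n) stop("not enough CDS positions for ", n, " SNPs")
    cds_cache <- lapply(canon, cds_sequence, g = g)
    aa_cache <- lapply(cds_cache, translate_cds)
    pool <- pool[sample(nrow(pool))]
    out <- vector("list", n)
    got <- 0L; i <- 0L
    # unbiased class steering: the desired class is drawn once per SNP and
    # kept until a position offering it turns up; positions offering only the
    # other class are banked for later draws of that class
    bank <- list(syn = list(), nonsyn = list())
    classify_pos <- function(row) {
      gid <- row$gene_id
      cds <- cds_cache[[gid]]; aa <- aa_cache[[gid]]
      ref_tx <- substr(cds, row$off + 1, row$off + 1)
      alts_tx <- setdiff(BASES, ref_tx)
      cls <- vapply(alts_tx, function(b)
        snp_effect_by_translation(cds, aa, row$off, b), character(1))
      list(row = row, alts = alts_tx, cls = cls)
    }
    next_for <- function(want) {   # want: "syn", "nonsyn" or NULL
      if (!is.null(want) && length(bank[[want]]) > 0) {
        item <- bank[[want]][[length(bank[[want]])]]
        bank[[want]][[length(bank[[want]])]] <<- NULL
        return(item)
      }
      repeat {
        i <<- i + 1L
        if (i > nrow(pool)) stop("exhausted CDS positions while placing SNPs")
        item <- classify_pos(pool[i])
        if (is.null(want)) return(item)
        ok <- if (want == "syn") any(item$cls == "synonymous") else
          any(item$cls != "synonymous")
        if (ok) return(item)
        other <- if (want == "syn") "nonsyn" else "syn"
        bank[[other]][[length(bank[[other]]) + 1L]] <<- item
      }
    }
    while (got < n) {
      want <- if (is.null(p_nonsyn)) NULL else
        if (stats::runif(1) >= p_nonsyn) "syn" else "nonsyn"
      item <- next_for(want)
      gn <- canon[[item$row$gene_id]]
      cds <- cds_cache[[item$row$gene_id]]
      cls <- item$cls; alts_tx <- item$alts
      pick <- if (is.null(want)) sample(3, 1) else {
        cand <- which(if (want == "syn") cls == "synonymous" else
          cls != "synonymous")
        cand[sample.int(length(cand), 1)]
      }
      alt_tx <- alts_tx[pick]
      off <- item$row$off
      ref_tx <- substr(cds, off + 1, off + 1)
      refb <- if (gn$strand == "-") COMPLEMENT[[ref_tx]] else ref_tx
      altb <- if (gn$strand == "-") COMPLEMENT[[alt_tx]] else alt_tx
      got <- got + 1L
      out[[got]] <- data.table::data.table(
        chrom = item$row$chrom, pos = item$row$pos, ref = refb, alt = altb,
        sample_id = sample_id, gene_id = item$row$gene_id,
        effect_intended = cls[pick])
    }
    v <- data.table::rbindlist(out)
    v[, type := "SNP"]
    data.table::setcolorder(v, c("chrom", "pos", "ref", "alt", "type",
                                 "sample_id"))
    data.table::setattr(v, "class", c("cv_variants", class(v)))
    v[]
  })
}

# truth-variant neighbourhoods in MUTATED-genome coordinates (for cut avoidance)
truth_avoid_intervals <- function(truth_sample, margin) {
  out <- list()
  for (cc in unique(truth_sample$chrom)) {
    tv <- truth_sample[chrom == cc][order(pos)]
    delta <- cumsum(c(0L, nchar(tv$alt) - nchar(tv$ref)))[seq_len(nrow(tv))]
    mstart <- tv$pos + delta
    out[[cc]] <- cbind(mstart - margin, mstart + nchar(tv$alt) + margin)
  }
  out
}

#' Fragment a genome into draft-assembly-style contigs
#'
#' Contigs tile each chromosome left to right with configurable inter-contig
#' gaps; no emitted contig is shorter than the configured minimum (200 bp by
#' default, mirroring standard draft-assembly reporting); a configurable
#' fraction is reverse-complemented. The placement map is exact.
#'
#' @param g the (mutated) `cv_genome` to fragment
#' @param config a [simulation_config()]
#' @param avoid optional named list (per chromosome) of interval matrices the
#'   cut points must not fall into (e.g. truth-variant neighbourhoods)
#' @param seed RNG seed
#' @return list with `contigs` (named character vector) and `placements`
#'   (`data.table`: contig_id, chrom, start, end, strand; coordinates on `g`)
#' @export
fragment_into_contigs <- function(g, config, avoid = NULL, seed = 1L) {
  with_seed(seed + 9000L, {
    contigs <- character(0)
    pl <- list()
    for (cc in names(g$seq)) {
      L <- nchar(g$seq[[cc]])
      av <- avoid[[cc]]
      cur <- 1L
      i <- 0L
      while (cur <= L) {
        len <- max(config$min_contig_len_bp,
                   round(stats::runif(1, 0.6, 1.4) * config$contig_mean_len_bp))
        end <- min(L, cur + len - 1L)
        if (!is.null(av) && end < L) {
          while (any(end >= av[, 1] & end <= av[, 2]) && end < L)
            end <- end + 1L
        }
        if (end - cur + 1L >= config$min_contig_len_bp) {
          i <- i + 1L
          id <- sprintf("ctg_%s_%04d", cc, i)
          sq <- substr(g$seq[[cc]], cur, end)
          strand <- if (stats::runif(1) < config$revcomp_fraction) "-" else "+"
          if (strand == "-") sq <- revcomp(sq)
          contigs[[id]] <- sq
          pl[[length(pl) + 1L]] <- data.table::data.table(
            contig_id = id, chrom = cc, start = cur, end = end, strand = strand)
        }
        gap <- if (config$contig_gap_frac > 0)
          round(config$contig_gap_frac * config$contig_mean_len_bp *
                  stats::runif(1, 0.5, 1.5)) else 0L
        cur <- end + 1L + gap
      }
    }
    list(contigs = contigs,
         placements = data.table::rbindlist(pl))
  })
}

#' Simulate a full two-landrace dataset
#'
#' Reference + gene models, two mutated landrace genomes with truth VCF-style
#' tables, and contig fragmentation of each landrace. With `outdir` set, the
#' standard file bundle is written (ref.fa, genes.gff3, landrace FASTAs,
#' contig FASTAs, truth VCFs, placements.tsv).
#'
#' @param config a [simulation_config()]
#' @param outdir optional output directory
#' @return list with `reference` (genome + genes), `genomes`, `truth`,
#'   `contigs` (per sample), `placements` (per sample)
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  ref <- simulate_reference(config)
  mut <- mutate_genome(ref, config)
  samples <- names(mut$genomes)
  frags <- lapply(seq_along(samples), function(i) {
    s <- samples[i]
    fragment_into_contigs(
      mut$genomes[[s]], config,
      avoid = truth_avoid_intervals(mut$truth[sample_id == s],
                                    config$cut_margin_bp),
      seed = config$seed + i)
  })
  names(frags) <- samples
  res <- list(reference = ref, genomes = mut$genomes, truth = mut$truth,
              contigs = lapply(frags, `[[`, "contigs"),
              placements = lapply(frags, `[[`, "placements"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ref$genome, file.path(outdir, "ref.fa"))
    write_gff3(ref$genes, file.path(outdir, "genes.gff3"))
    for (s in samples) {
      write_fasta(mut$genomes[[s]], file.path(outdir, paste0(s, ".fa")))
      write_fasta(genome(res$contigs[[s]]),
                  file.path(outdir, paste0("contigs_", s, ".fa")))
      write_vcf(mut$truth[sample_id == s], ref$genome,
                file.path(outdir, paste0("truth_", s, ".vcf")))
    }
    pl <- data.table::rbindlist(lapply(samples, function(s)
      cbind(sample_id = s, res$placements[[s]])))
    data.table::fwrite(pl, file.path(outdir, "placements.tsv"), sep = "\t")
  }
  res
}
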