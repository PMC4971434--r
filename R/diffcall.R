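#' Build a unique k-mer anchor index for a genome
#'
#' Indexes every k-mer of the reference; k-mers occurring more than once in
#' the reference (on either strand) are disqualified as seeds, mirroring
#' maximal-unique-match anchoring.
#'
#' @param g a `cv_genome`
#' @param k seed length in bp (>= 11)
#' @return an object of class `cv_anchor_index`
#' @export
build_anchor_index <- function(g, k = 21) {
  stopifnot(inherits(g, "cv_genome"), k >= 11)
  idx <- list(ptr = cpp_build_kmer_index(g$seq, as.integer(k)),
              chroms = names(g$seq), k = as.integer(k))
  class(idx) <- "cv_anchor_index"
  idx
}

#' Find unique-seed anchors between a contig and the reference
#'
#' Returns seeds of length `k` occurring exactly once in the reference and
#' exactly once in the contig, on either strand. Positions are 1-based starts
#' on the forward strands of both sequences.
#'
#' @param g a `cv_genome` or a prebuilt [build_anchor_index()] object
#' @param contig contig sequence (character scalar)
#' @param k seed length (ignored when `g` is an index)
#' @return `data.table` with columns ref_chrom, ref_pos, contig_pos, len, strand
#' @export
find_anchors <- function(g, contig, k = 21) {
  idx <- if (inherits(g, "cv_anchor_index")) g else build_anchor_index(g, k)
  if (nchar(contig) < idx$k) {
    return(data.table::data.table(ref_chrom = character(0), ref_pos = integer(0),
                                  contig_pos = integer(0), len = integer(0),
                                  strand = character(0)))
  }
  r <- cpp_find_anchors(idx$ptr, toupper(contig))
  data.table::data.table(
    ref_chrom = idx$chroms[r$chrom_idx], ref_pos = r$ref_pos,
    contig_pos = r$contig_pos, len = idx$k,
    strand = ifelse(r$strand > 0, "+", "-"))
}

# merge per-diagonal runs of adjacent anchors into maximal exact matches;
# expects single-strand anchors (forward-oriented contig)
merge_anchor_runs <- function(anchors) {
  if (nrow(anchors) == 0) return(anchors)
  a <- data.table::copy(anchors)
  a[, diag := ref_pos - contig_pos]
  data.table::setorder(a, ref_chrom, diag, contig_pos)
  brk <- c(TRUE, diff(a$contig_pos) != 1L | diff(a$diag) != 0L |
             a$ref_chrom[-1] != a$ref_chrom[-nrow(a)])
  a[, run_id := cumsum(brk)]
  runs <- a[, .(ref_chrom = ref_chrom[1], ref_pos = ref_pos[1],
                contig_pos = contig_pos[1],
                len = contig_pos[.N] - contig_pos[1] + len[.N],
                strand = strand[1]), by = run_id]
  runs[, run_id := NULL]
  runs[]
}

#' Select the best colinear anchor chain
#'
#' Weighted longest-increasing-subsequence over anchors: maximizes total
#' anchored length among subsets strictly increasing and non-overlapping in
#' both reference and contig coordinates (one chromosome). Ties are broken by
#' smaller total diagonal drift, then by leftmost reference position.
#'
#' @param anchors anchor `data.table` (as from [find_anchors()], one strand)
#' @return the retained anchors, ordered along the chain
#' @export
chain_anchors <- function(anchors) {
  if (nrow(anchors) == 0) stop("chain_anchors: no anchors")
  # chain within the chromosome holding the most anchored sequence
  wt <- anchors[, .(w = sum(len)), by = ref_chrom]
  a <- anchors[ref_chrom == wt$ref_chrom[which.max(wt$w)]]
  data.table::setorder(a, ref_pos, contig_pos)
  n <- nrow(a)
  rs <- a$ref_pos; re <- a$ref_pos + a$len - 1L
  cs <- a$contig_pos; ce <- a$contig_pos + a$len - 1L
  dg <- rs - cs
  w <- as.numeric(a$len)
  best <- w; drift <- rep(0, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    j <- which(re[1:(i - 1)] < rs[i] & ce[1:(i - 1)] < cs[i])
    if (length(j) == 0) next
    cand_w <- best[j] + w[i]
    cand_d <- drift[j] + abs(dg[i] - dg[j])
    o <- order(-cand_w, cand_d)[1]
    if (cand_w[o] > best[i] ||
        (cand_w[o] == best[i] && cand_d[o] < drift[i])) {
      best[i] <- cand_w[o]; drift[i] <- cand_d[o]; prev[i] <- j[o]
    }
  }
  endi <- order(-best, drift, rs)[1]
  path <- integer(0); i <- endi
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  a[path]
}

#' Banded global alignment of an inter-anchor gap
#'
#' Aligns the reference and contig substrings between consecutive chain
#' anchors with unit mismatch/gap costs. If no path fits in the band the
#' segment is flagged unaligned and contributes no variants.
#'
#' @param ref_sub,contig_sub the two substrings
#' @param band_width band half-width; the effective band is
#'   `max(band_width, 2 * abs(length difference))`
#' @param free_ref_prefix,free_ref_suffix allow unpenalized skipping of
#'   reference sequence at the segment edges (tail alignment)
#' @return list with elements `aligned`, `cost`, `ref_aln`, `contig_aln`,
#'   `ref_used` (1-based bounds of the consumed reference substring)
#' @export
align_gap <- function(ref_sub, contig_sub, band_width = 50,
                      free_ref_prefix = FALSE, free_ref_suffix = FALSE) {
  band <- max(band_width, 2L * abs(nchar(ref_sub) - nchar(contig_sub)))
  r <- cpp_banded_align(ref_sub, contig_sub, as.integer(band),
                        free_ref_prefix, free_ref_suffix)
  if (!isTRUE(r$aligned)) return(list(aligned = FALSE))
  list(aligned = TRUE, cost = r$cost, ref_aln = r$a_aln, contig_aln = r$b_aln,
       ref_used = c(r$a_start, r$a_end))
}

# walk alignment columns and emit raw variant records.
# ref_start: genomic position of the first consumed reference base;
# left_flank: genomic position of the reference base immediately before the
# segment (anchor base for edge InDel runs); must be >= 1 when gaps can touch
# the segment start.
emit_segment_variants <- function(ref_aln, contig_aln, chrom, ref_start, g) {
  ra <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  ca <- strsplit(contig_aln, "", fixed = TRUE)[[1]]
  ncol <- length(ra)
  out <- list()
  rpos <- ref_start - 1L   # genomic position of last consumed ref base
  i <- 1L
  while (i <= ncol) {
    if (ra[i] != "-" && ca[i] != "-") {
      rpos <- rpos + 1L
      if (ra[i] != ca[i]) {
        out[[length(out) + 1L]] <- list(chrom, rpos, ra[i], ca[i])
      }
      i <- i + 1L
    } else if (ca[i] == "-") {          # gap run in contig: deletion
      j <- i
      while (j <= ncol && ca[j] == "-") j <- j + 1L
      run <- paste(ra[i:(j - 1L)], collapse = "")
      anchor_pos <- rpos
      anchor <- if (anchor_pos >= 1L) get_seq(g, chrom, anchor_pos, anchor_pos) else NULL
      if (!is.null(anchor)) {
        out[[length(out) + 1L]] <- list(chrom, anchor_pos,
                                        paste0(anchor, run), anchor)
      }
      rpos <- rpos + (j - i)
      i <- j
    } else {                            # gap run in reference: insertion
      j <- i
      while (j <= ncol && ra[j] == "-") j <- j + 1L
      run <- paste(ca[i:(j - 1L)], collapse = "")
      anchor_pos <- rpos
      anchor <- if (anchor_pos >= 1L) get_seq(g, chrom, anchor_pos, anchor_pos) else NULL
      if (!is.null(anchor)) {
        out[[length(out) + 1L]] <- list(chrom, anchor_pos,
                                        anchor, paste0(anchor, run))
      }
      i <- j
    }
  }
  out
}

#' Emit variants from alignment segments
#'
#' Each mismatch column becomes one SNP (multi-base mismatch runs are split
#' per base); each gap run becomes one InDel of the run's length. Variants are
#' left-normalized and duplicates collapsed by variant key.
#'
#' @param segments list of segments: each a list with `chrom`, `ref_start`
#'   (genomic position of the first reference base of the segment), `ref_aln`,
#'   `contig_aln`
#' @param sample_id sample label
#' @param g a `cv_genome`
#' @return a `cv_variants` table
#' @export
emit_variants <- function(segments, sample_id, g) {
  recs <- list()
  for (seg in segments) {
    recs <- c(recs, emit_segment_variants(seg$ref_aln, seg$contig_aln,
                                          seg$chrom, seg$ref_start, g))
  }
  if (length(recs) == 0) return(variant_table())
  v <- variant_table(
    chrom = vapply(recs, `[[`, character(1), 1),
    pos = vapply(recs, function(x) as.integer(x[[2]]), integer(1)),
    ref = vapply(recs, `[[`, character(1), 3),
    alt = vapply(recs, `[[`, character(1), 4),
    sample_id = sample_id)
  v <- normalize_variants(v, g)
  v[!duplicated(variant_key(v))]
}

# per-contig calling: anchors -> orientation -> chain -> gap + tail alignment
call_contig <- function(g, idx, contig, sample_id, band_width = 50,
                        min_anchors = 2L) {
  anchors <- find_anchors(idx, contig)
  if (nrow(anchors) == 0) return(NULL)
  # orientation by majority anchor vote; reverse-complement and re-anchor
  if (sum(anchors$strand == "-") > sum(anchors$strand == "+")) {
    contig <- revcomp(contig)
    anchors <- find_anchors(idx, contig)
  }
  anchors <- anchors[strand == "+"]
  if (nrow(anchors) == 0) return(NULL)
  runs <- merge_anchor_runs(anchors)
  chain <- chain_anchors(runs)
  if (nrow(chain) < min_anchors) return(NULL)
  chrom <- chain$ref_chrom[1]
  clen <- nchar(contig)
  glen <- genome_lengths(g)[[chrom]]
  segs <- list()
  add_seg <- function(a, b, a_start, free_pre = FALSE, free_suf = FALSE) {
    if (nchar(a) == 0 && nchar(b) == 0) return()
    al <- align_gap(a, b, band_width, free_pre, free_suf)
    if (!isTRUE(al$aligned)) return()
    segs[[length(segs) + 1L]] <<- list(
      chrom = chrom, ref_start = a_start + al$ref_used[1] - 1L,
      ref_aln = al$ref_aln, contig_aln = al$contig_aln)
  }
  # left tail
  if (chain$contig_pos[1] > 1) {
    t <- chain$contig_pos[1] - 1L
    ws <- max(1L, chain$ref_pos[1] - t - band_width)
    if (chain$ref_pos[1] > 1L) {
      add_seg(get_seq(g, chrom, ws, chain$ref_pos[1] - 1L),
              substr(contig, 1, t), ws, free_pre = TRUE)
    }
  }
  # inter-anchor gaps
  if (nrow(chain) > 1) {
    for (i in seq_len(nrow(chain) - 1L)) {
      rs <- chain$ref_pos[i] + chain$len[i]
      re <- chain$ref_pos[i + 1L] - 1L
      cs <- chain$contig_pos[i] + chain$len[i]
      ce <- chain$contig_pos[i + 1L] - 1L
      if (re < rs && ce < cs) next
      add_seg(if (re >= rs) get_seq(g, chrom, rs, re) else "",
              if (ce >= cs) substr(contig, cs, ce) else "", rs)
    }
  }
  # right tail
  last <- nrow(chain)
  cend <- chain$contig_pos[last] + chain$len[last] - 1L
  rend <- chain$ref_pos[last] + chain$len[last] - 1L
  if (cend < clen && rend < glen) {
    t <- clen - cend
    we <- min(glen, rend + t + band_width)
    add_seg(get_seq(g, chrom, rend + 1L, we),
            substr(contig, cend + 1L, clen), rend + 1L, free_suf = TRUE)
  }
  emit_variants(segs, sample_id, g)
}

#' Call variants from assembled contigs against a reference genome
#'
#' The full anchoring / chaining / banded-alignment pipeline, applied per
#' contig, with per-contig orientation by majority anchor vote. Variants seen
#' in several overlapping contigs are collapsed by key; loci where overlapping
#' contigs disagree on the allele are dropped and logged. Contigs with fewer
#' than two chained anchors contribute no variants and are reported unplaced.
#'
#' @param g reference `cv_genome`
#' @param contigs named character vector of contig sequences
#' @param sample_id sample label for all emitted variants
#' @param k anchor seed length (default 21)
#' @param band_width alignment band half-width (default 50; widened to twice
#'   the length difference per gap when needed)
#' @return list with `variants` (a normalized `cv_variants` table),
#'   `unplaced` (contig ids) and `n_conflicts`
#' @export
call_variants <- function(g, contigs, sample_id, k = 21, band_width = 50) {
  idx <- build_anchor_index(g, k)
  unplaced <- character(0)
  parts <- list()
  for (nm in names(contigs)) {
    v <- call_contig(g, idx, contigs[[nm]], sample_id, band_width)
    if (is.null(v)) unplaced <- c(unplaced, nm) else parts[[nm]] <- v
  }
  if (length(parts) == 0) {
    return(list(variants = variant_table(), unplaced = unplaced,
                n_conflicts = 0L))
  }
  v <- data.table::rbindlist(parts)
  v <- v[!duplicated(variant_key(v))]
  # conflicting alleles from overlapping contigs: same anchored site,
  # different alternate
  v[, key_ := paste(chrom, pos, ref, sep = ":")]
  dup <- v[, .N, by = key_][N > 1, key_]
  n_conf <- length(dup)
  if (n_conf > 0) {
    cv_log("dropped ", n_conf, " site(s) with conflicting alleles ",
           "between overlapping contigs")
    v <- v[!(key_ %in% dup)]
  }
  v[, key_ := NULL]
  data.table::setorder(v, chrom, pos)
  if (length(unplaced) > 0) {
    cv_log(length(unplaced), " contig(s) unplaced (no usable anchor chain)")
  }
  list(variants = v[], unplaced = unplaced, n_conflicts = n_conf)
}
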