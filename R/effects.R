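EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "stop_gained", "start_lost",
                   "stop_lost", "frameshift", "inframe_indel",
                   "start_codon_indel", "stop_codon_indel", "noncoding")

LARGE_EFFECT_SNP <- c("stop_gained", "start_lost", "stop_lost")
LARGE_EFFECT_INDEL <- c("frameshift", "start_codon_indel", "stop_codon_indel")

# genetic code, translation table 1
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(ifelse(is.na(aa), "X", aa))
}

# CDS offsets are 0-based along the spliced CDS in transcript orientation
# (offset 0 = first base of the start codon).

# map genomic positions to CDS offsets for one gene; NA when outside CDS
cds_offsets <- function(gene, pos) {
  seg <- gene$cds_segments
  lens <- seg[, 2] - seg[, 1] + 1L
  cum <- cumsum(c(0L, lens))[seq_len(nrow(seg))]
  off <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(seg))) {
    hit <- pos >= seg[i, 1] & pos <= seg[i, 2]
    off[hit] <- cum[i] + (pos[hit] - seg[i, 1])
  }
  if (gene$strand == "-") {
    total <- sum(lens)
    off <- ifelse(is.na(off), NA_integer_, total - 1L - off)
  }
  off
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify a coding SNP at codon level
#'
#' Strand-aware codon extraction against the reference CDS, standard genetic
#' code. Classes: `synonymous`, `nonsynonymous`, `stop_gained` (non-stop to
#' stop before the terminal codon), `start_lost` (change in codon 1 destroying
#' ATG), `stop_lost` (terminal stop to non-stop).
#'
#' @param v one-row `cv_variants` table (a SNP in the gene's CDS)
#' @param gene a canonical `cv_gene`
#' @param g a `cv_genome`
#' @return effect class string
#' @export
classify_cds_snp <- function(v, gene, g) {
  stopifnot(nrow(v) == 1, v$type == "SNP")
  cds <- cds_sequence(gene, g)
  off <- cds_offsets(gene, v$pos)
  if (is.na(off)) stop("SNP at ", v$chrom, ":", v$pos, " is not in the CDS of ",
                       gene$gene_id)
  classify_snp_at_offset(cds, off,
                         if (gene$strand == "-") COMPLEMENT[[v$alt]] else v$alt,
                         if (gene$strand == "-") COMPLEMENT[[v$ref]] else v$ref)
}

classify_snp_at_offset <- function(cds, off, alt_base, ref_base = NULL) {
  n <- nchar(cds)
  if (!is.null(ref_base) && substr(cds, off + 1, off + 1) != ref_base)
    stop("internal error: variant/codon bookkeeping mismatch")
  ci <- off %/% 3L              # 0-based codon index
  last_ci <- n %/% 3L - 1L
  old <- substr(cds, 3 * ci + 1, 3 * ci + 3)
  new <- old
  substr(new, off - 3 * ci + 1, off - 3 * ci + 1) <- alt_base
  if (ci == 0L) return(if (new == "ATG") "synonymous" else "start_lost")
  old_stop <- old %in% STOP_CODONS
  new_stop <- new %in% STOP_CODONS
  if (ci == last_ci) {
    if (old_stop && !new_stop) return("stop_lost")
    if (old_stop && new_stop) return("synonymous")
  }
  if (!old_stop && new_stop) return("stop_gained")
  if (translate_codon(old) == translate_codon(new)) "synonymous" else "nonsynonymous"
}

#' Classify a coding InDel
#'
#' Precedence: overlapping codon 1 -> `start_codon_indel`; overlapping the
#' terminal stop codon -> `stop_codon_indel`; otherwise `frameshift` when the
#' length change is not a multiple of 3, else `inframe_indel`. Deletions
#' overlap a codon through any deleted base; insertions through an insertion
#' point strictly inside the codon.
#'
#' @param v one-row `cv_variants` table (InDel whose first altered base is in
#'   the gene's CDS)
#' @param gene a canonical `cv_gene`
#' @param g a `cv_genome`
#' @return effect class string
#' @export
classify_cds_indel <- function(v, gene, g) {
  stopifnot(nrow(v) == 1, v$type %in% c("insertion", "deletion"))
  classify_indel_offsets(v$type[1], v$pos[1], nchar(v$ref[1]), nchar(v$alt[1]),
                         gene)
}

classify_indel_offsets <- function(type, pos, nref, nalt, gene) {
  total <- cds_length(gene)
  if (type == "deletion") {
    len <- nref - 1L
    offs <- cds_offsets(gene, (pos + 1L):(pos + len))
    offs <- offs[!is.na(offs)]
    if (length(offs) == 0) stop("InDel does not touch the CDS of ", gene$gene_id)
    if (any(offs <= 2L)) return("start_codon_indel")
    if (any(offs >= total - 3L)) return("stop_codon_indel")
  } else {
    len <- nalt - 1L
    flank <- cds_offsets(gene, c(pos, pos + 1L))
    inside <- flank[!is.na(flank)]
    if (length(inside) == 0) stop("InDel does not touch the CDS of ", gene$gene_id)
    if (length(inside) == 2) {
      if (all(inside <= 2L)) return("start_codon_indel")
      if (all(inside >= total - 3L)) return("stop_codon_indel")
    }
  }
  if (len %% 3L != 0L) "frameshift" else "inframe_indel"
}

#' Classify coding effects for annotated variants
#'
#' Adds an `effect` column: CDS SNPs get one of the codon-level classes, CDS
#' InDels one of the InDel classes, everything else `noncoding`. Variants in
#' non-canonical genes are excluded from classification (effect `NA`, logged).
#'
#' @param annotated output of [annotate_variants()]
#' @param genes named list of `cv_gene`
#' @param g a `cv_genome`
#' @return the table with an `effect` column added
#' @export
classify_effects <- function(annotated, genes, g) {
  out <- data.table::copy(annotated)
  out[, effect := "noncoding"]
  sel <- which(out$region == "CDS")
  if (length(sel) == 0) return(out[])
  cds_cache <- new.env(parent = emptyenv())
  n_skip <- 0L
  for (i in sel) {
    gene <- genes[[out$gene_id[i]]]
    if (is.null(gene)) stop("unknown gene_id: ", out$gene_id[i])
    if (isTRUE(gene$non_canonical)) {
      data.table::set(out, i, "effect", NA_character_)
      n_skip <- n_skip + 1L
      next
    }
    if (out$type[i] == "SNP") {
      key <- gene$gene_id
      cds <- if (!is.null(cds_cache[[key]])) cds_cache[[key]] else
        (cds_cache[[key]] <- cds_sequence(gene, g))
      off <- cds_offsets(gene, out$pos[i])
      alt <- if (gene$strand == "-") COMPLEMENT[[out$alt[i]]] else out$alt[i]
      rb <- if (gene$strand == "-") COMPLEMENT[[out$ref[i]]] else out$ref[i]
      data.table::set(out, i, "effect", classify_snp_at_offset(cds, off, alt, rb))
    } else {
      data.table::set(out, i, "effect",
                      classify_indel_offsets(out$type[i], out$pos[i],
                                             nchar(out$ref[i]),
                                             nchar(out$alt[i]), gene))
    }
  }
  if (n_skip > 0) cv_log(n_skip, " CDS variant(s) in non-canonical genes left unclassified")
  out[]
}

#' Directed substitution spectrum
#'
#' Counts of the 12 directed substitution types X>Y on the reference strand.
#' The counts always sum to the number of input SNPs.
#'
#' @param v a `cv_variants` table containing only SNPs
#' @return named integer vector with the 12 keys "A>C", ..., "T>G"
#' @export
substitution_spectrum <- function(v) {
  if (nrow(v) > 0 && any(v$type != "SNP"))
    stop("substitution_spectrum: input contains non-SNP variants")
  bases <- c("A", "C", "G", "T")
  keys <- as.vector(outer(bases, bases, function(x, y) paste0(x, ">", y)))
  keys <- keys[substr(keys, 1, 1) != substr(keys, 3, 3)]
  keys <- sort(keys)
  obs <- table(factor(paste0(v$ref, ">", v$alt), levels = keys))
  stats::setNames(as.integer(obs), keys)
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' InDel length spectrum
#'
#' Counts of InDels by length (`abs(nchar(ref) - nchar(alt))`), in buckets
#' 1..10 bp plus a ">=11" bucket, matching the conventional report layout.
#'
#' @param v a `cv_variants` table containing only InDels
#' @return named integer vector ("1".."10", ">=11")
#' @export
indel_length_spectrum <- function(v) {
  if (nrow(v) > 0 && any(v$type == "SNP"))
    stop("indel_length_spectrum: input contains SNPs")
  len <- abs(nchar(v$ref) - nchar(v$alt))
  lab <- ifelse(len >= 11, ">=11", as.character(len))
  obs <- table(factor(lab, levels = c(as.character(1:10), ">=11")))
  stats::setNames(as.integer(obs), names(obs))
}
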