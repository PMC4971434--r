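#' Gene model
#'
#' Strand-aware transcript structure used for region assignment and codon
#' lookups. All segment matrices are n x 2 (start, end), 1-based inclusive,
#' sorted in genomic order and non-overlapping within each list.
#'
#' @param gene_id transcript/gene identifier
#' @param chrom chromosome id
#' @param strand "+" or "-"
#' @param cds_segments,utr5_segments,utr3_segments,exon_segments integer
#'   matrices with columns start, end (may have zero rows except CDS)
#' @param mrna_span length-2 integer vector
#' @return an object of class `cv_gene`
#' @export
gene_model <- function(gene_id, chrom, strand, cds_segments,
                       utr5_segments = empty_segments(),
                       utr3_segments = empty_segments(),
                       exon_segments = NULL,
                       mrna_span = NULL) {
  stopifnot(strand %in% c("+", "-"))
  cds_segments <- as_segments(cds_segments)
  utr5_segments <- as_segments(utr5_segments)
  utr3_segments <- as_segments(utr3_segments)
  if (nrow(cds_segments) == 0) stop("gene ", gene_id, ": empty CDS")
  if (is.null(exon_segments)) {
    exon_segments <- merge_segments(rbind(cds_segments, utr5_segments, utr3_segments))
  } else exon_segments <- as_segments(exon_segments)
  if (is.null(mrna_span)) {
    mrna_span <- c(min(exon_segments[, 1]), max(exon_segments[, 2]))
  }
  for (nm in c("cds_segments", "utr5_segments", "utr3_segments", "exon_segments")) {
    seg <- get(nm)
    if (nrow(seg) > 1 && any(seg[-1, 1] <= seg[-nrow(seg), 2]))
      stop("gene ", gene_id, ": ", nm, " unsorted or overlapping")
    if (nrow(seg) > 0 && (min(seg[, 1]) < mrna_span[1] || max(seg[, 2]) > mrna_span[2]))
      stop("gene ", gene_id, ": ", nm, " outside mRNA span")
  }
  g <- list(gene_id = gene_id, chrom = chrom, strand = strand,
            cds_segments = cds_segments, utr5_segments = utr5_segments,
            utr3_segments = utr3_segments, exon_segments = exon_segments,
            mrna_span = as.integer(mrna_span), non_canonical = FALSE)
  class(g) <- "cv_gene"
  g
}

empty_segments <- function() matrix(integer(0), ncol = 2,
                                    dimnames = list(NULL, c("start", "end")))

as_segments <- function(x) {
  if (is.null(x) || length(x) == 0) return(empty_segments())
  m <- matrix(as.integer(x), ncol = 2, dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1]), , drop = FALSE]
}

merge_segments <- function(m) {
  m <- as_segments(m)
  if (nrow(m) <= 1) return(m)
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2] + 1L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

#' Intron segments of a gene model
#'
#' Introns are the gaps between exons within the mRNA span.
#' @param gene a `cv_gene`
#' @return segment matrix (possibly zero rows)
#' @export
introns <- function(gene) {
  ex <- gene$exon_segments
  if (nrow(ex) <= 1) return(empty_segments())
  as_segments(cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L))
}

#' Concatenated CDS length of a gene model
#' @param gene a `cv_gene`
#' @return integer, bp
#' @export
cds_length <- function(gene) sum(gene$cds_segments[, 2] - gene$cds_segments[, 1] + 1L)

#' Spliced CDS sequence of a gene (transcript orientation)
#'
#' Concatenates CDS segments in genomic order and reverse-complements for
#' minus-strand genes, so the result starts at the start codon.
#' @param gene a `cv_gene`
#' @param g a `cv_genome`
#' @return character scalar
#' @export
cds_sequence <- function(gene, g) {
  parts <- apply(gene$cds_segments, 1, function(s) get_seq(g, gene$chrom, s[1], s[2]))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Flag non-canonical gene models
#'
#' A well-formed gene has CDS length divisible by 3, a translated CDS starting
#' with ATG and ending at a stop codon. Violations are logged and the gene is
#' flagged `non_canonical`; such genes are excluded from effect classification.
#'
#' @param genes list of `cv_gene`
#' @param g a `cv_genome`
#' @return the gene list with `non_canonical` flags set
#' @export
flag_non_canonical <- function(genes, g) {
  n_bad <- 0L
  for (i in seq_along(genes)) {
    s <- cds_sequence(genes[[i]], g)
    n <- nchar(s)
    ok <- n >= 6 && n %% 3 == 0 &&
      substr(s, 1, 3) == "ATG" &&
      substr(s, n - 2, n) %in% STOP_CODONS &&
      !grepl("N", s, fixed = TRUE)
    if (!ok) {
      genes[[i]]$non_canonical <- TRUE
      n_bad <- n_bad + 1L
    }
  }
  if (n_bad > 0) cv_log(n_bad, " gene model(s) flagged non-canonical")
  genes
}

#' Read gene models from GFF3
#'
#' Expects the conventional gene -> mRNA -> exon/CDS/five_prime_UTR/
#' three_prime_UTR hierarchy and returns one gene model per mRNA. When UTR
#' features are absent they are derived as exon minus CDS, with the 5'/3' side
#' determined by strand.
#'
#' @param path GFF3 file path
#' @param g optional `cv_genome` for coordinate bounds checking
#' @return named list of `cv_gene`
#' @export
read_gff3 <- function(path, g = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  feat <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(feat) == 0) {
    warning("no features in GFF3 file: ", path)
    return(stats::setNames(list(), character(0)))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  strd <- as.character(GenomicRanges::strand(gr))

  is_mrna <- typ %in% c("mRNA", "transcript")
  mrna_ids <- id[is_mrna]
  if (anyDuplicated(stats::na.omit(mrna_ids))) stop("duplicate mRNA IDs in ", path)
  child <- typ %in% c("CDS", "exon", "five_prime_UTR", "three_prime_UTR")
  orphan <- child & !(parent %in% mrna_ids)
  if (any(orphan)) {
    stop("feature(s) of type ", paste(unique(typ[orphan]), collapse = ","),
         " without a parent mRNA in ", path)
  }
  if (!is.null(g)) {
    lens <- genome_lengths(g)
    if (any(!(chr %in% names(lens)))) stop("GFF3 references unknown chromosome")
    if (any(st < 1 | en > lens[chr])) stop("GFF3 coordinates out of genome bounds")
  }
  genes <- list()
  for (k in which(is_mrna)) {
    mid <- id[k]
    sel <- which(parent == mid)
    seg <- function(t) {
      i <- sel[typ[sel] == t]
      if (!length(i)) return(empty_segments())
      as_segments(cbind(st[i], en[i]))
    }
    cds <- seg("CDS")
    if (nrow(cds) == 0) stop("mRNA ", mid, " has no CDS features")
    ex <- seg("exon")
    u5 <- seg("five_prime_UTR"); u3 <- seg("three_prime_UTR")
    if (nrow(u5) == 0 && nrow(u3) == 0 && nrow(ex) > 0) {
      utr <- derive_utrs(ex, cds, strd[k])
      u5 <- utr$utr5; u3 <- utr$utr3
    }
    genes[[mid]] <- gene_model(
      gene_id = mid, chrom = chr[k], strand = strd[k],
      cds_segments = cds, utr5_segments = u5, utr3_segments = u3,
      exon_segments = if (nrow(ex)) ex else NULL,
      mrna_span = c(st[k], en[k]))
  }
  if (!is.null(g)) genes <- flag_non_canonical(genes, g)
  genes
}

# exon minus CDS, split into 5' and 3' sides by strand
derive_utrs <- function(exons, cds, strand) {
  cds_lo <- min(cds[, 1]); cds_hi <- max(cds[, 2])
  left <- right <- empty_segments()
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1]; e <- exons[i, 2]
    if (s < cds_lo) left <- rbind(left, c(s, min(e, cds_lo - 1L)))
    if (e > cds_hi) right <- rbind(right, c(max(s, cds_hi + 1L), e))
  }
  left <- as_segments(left); right <- as_segments(right)
  if (strand == "+") list(utr5 = left, utr3 = right) else list(utr5 = right, utr3 = left)
}

#' Write gene models to GFF3
#'
#' Serializes the gene -> mRNA -> exon/CDS/UTR hierarchy produced by the
#' simulator (or read by [read_gff3()]) as GFF3 with ID/Parent attributes.
#'
#' @param genes named list of `cv_gene`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  row <- function(chrom, type, s, e, strand, attrs) {
    sprintf("%s\tcontigvar\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s, e, strand, attrs)
  }
  for (gn in genes) {
    gid <- paste0(gn$gene_id, ".g")
    out <- c(
      row(gn$chrom, "gene", gn$mrna_span[1], gn$mrna_span[2], gn$strand,
          paste0("ID=", gid)),
      row(gn$chrom, "mRNA", gn$mrna_span[1], gn$mrna_span[2], gn$strand,
          paste0("ID=", gn$gene_id, ";Parent=", gid)))
    emit <- function(seg, type) {
      if (nrow(seg) == 0) return(character(0))
      vapply(seq_len(nrow(seg)), function(i)
        row(gn$chrom, type, seg[i, 1], seg[i, 2], gn$strand,
            paste0("Parent=", gn$gene_id)), character(1))
    }
    out <- c(out, emit(gn$exon_segments, "exon"), emit(gn$cds_segments, "CDS"),
             emit(gn$utr5_segments, "five_prime_UTR"),
             emit(gn$utr3_segments, "three_prime_UTR"))
    writeLines(out, con)
  }
  invisible(path)
}
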