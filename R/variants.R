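#' Variant table constructor
#'
#' Variants are stored in a `data.table` with one row per variant and columns
#' `chrom`, `pos` (1-based; for InDels the VCF-style anchor base), `ref`,
#' `alt`, `type` (SNP/insertion/deletion) and `sample_id`. InDel alleles carry
#' the shared anchor base as their first character.
#'
#' @param chrom,pos,ref,alt vectors describing the variants
#' @param sample_id sample label (recycled)
#' @return a `data.table` of class `cv_variants`
#' @export
variant_table <- function(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          sample_id = character(0)) {
  v <- data.table::data.table(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    sample_id = if (length(chrom) && length(sample_id) == 1)
      rep(as.character(sample_id), length(chrom)) else as.character(sample_id))
  v[, type := infer_var_type(ref, alt)]
  data.table::setcolorder(v, c("chrom", "pos", "ref", "alt", "type", "sample_id"))
  data.table::setattr(v, "class", c("cv_variants", class(v)))
  v[]
}

#' Classify allele pairs as SNP / insertion / deletion
#' @param ref,alt allele strings
#' @return character vector
#' @export
infer_var_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep(NA_character_, length(ref))
  out[nr == 1 & na == 1 & ref != alt] <- "SNP"
  ins <- nr == 1 & na > 1
  del <- na == 1 & nr > 1
  out[ins] <- "insertion"
  out[del] <- "deletion"
  bad <- is.na(out)
  if (any(bad)) {
    stop("invalid allele pair(s), e.g. ", ref[bad][1], ">", alt[bad][1],
         " (multi-nucleotide substitutions are not a supported variant type)")
  }
  anchor_bad <- (ins | del) & substr(ref, 1, 1) != substr(alt, 1, 1)
  if (any(anchor_bad)) stop("InDel allele(s) lack a shared anchor base")
  out
}

#' Validate variants against a genome
#'
#' Checks reference-consistency (`ref` matches the genome at `pos`) and the
#' no-N invariant. Variants touching N bases are dropped with a logged count;
#' reference mismatches are an error.
#'
#' @param v a `cv_variants` table
#' @param g a `cv_genome`
#' @param exclude_masked drop variants whose reference span overlaps
#'   soft-masked bases (default FALSE: soft-masked positions are allowed)
#' @return the validated (possibly filtered) table
#' @export
validate_variants <- function(v, g, exclude_masked = FALSE) {
  if (nrow(v) == 0) return(v)
  if (any(!(v$chrom %in% names(g$seq))))
    stop("variant(s) on unknown chromosome: ",
         paste(unique(setdiff(v$chrom, names(g$seq))), collapse = ", "))
  obs <- substr_genome(g, v$chrom, v$pos, v$pos + nchar(v$ref) - 1L)
  mism <- obs != v$ref
  if (any(mism)) {
    i <- which(mism)[1]
    stop("reference mismatch at ", v$chrom[i], ":", v$pos[i],
         " (expected ", v$ref[i], ", genome has ", obs[i], ")")
  }
  hasN <- grepl("N", v$ref, fixed = TRUE) | grepl("N", v$alt, fixed = TRUE)
  if (any(hasN)) {
    cv_log("dropped ", sum(hasN), " variant(s) touching N bases")
    v <- v[!hasN]
  }
  if (exclude_masked) {
    drop <- vapply(seq_len(nrow(v)), function(i) {
      m <- g$mask[[v$chrom[i]]]
      length(m) > 0 && any(m >= v$pos[i] & m <= v$pos[i] + nchar(v$ref[i]) - 1L)
    }, logical(1))
    if (any(drop)) {
      cv_log("dropped ", sum(drop), " variant(s) in soft-masked sequence")
      v <- v[!drop]
    }
  }
  v
}

# vectorized multi-chromosome substr
substr_genome <- function(g, chrom, start, end) {
  out <- character(length(chrom))
  for (cc in unique(chrom)) {
    i <- chrom == cc
    s <- g$seq[[cc]]
    out[i] <- substring(s, start[i], pmin(end[i], nchar(s)))
  }
  out
}

#' Left-align and trim InDels
#'
#' Canonicalizes InDel placement (parsimony-trimmed, shifted to the leftmost
#' equivalent position within repeat context) so that cross-sample sharing is
#' well-defined. SNPs pass through unchanged; the operation is idempotent.
#'
#' @param v a `cv_variants` table
#' @param g a `cv_genome`
#' @return the normalized table (same row order)
#' @export
normalize_variants <- function(v, g) {
  if (nrow(v) == 0) return(v)
  v <- data.table::copy(v)
  idx <- which(v$type != "SNP")
  for (i in idx) {
    nv <- normalize_one(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], g)
    data.table::set(v, i, "pos", nv$pos)
    data.table::set(v, i, "ref", nv$ref)
    data.table::set(v, i, "alt", nv$alt)
  }
  v[, type := infer_var_type(ref, alt)]
  v[]
}

normalize_one <- function(chrom, pos, ref, alt, g) {
  s <- g$seq[[chrom]]
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 && substr(ref, nr, nr) == substr(alt, na, na)) {
      if (nr == 1 || na == 1) {
        if (pos == 1) break
        pos <- pos - 1L
        b <- substr(s, pos, pos)
        ref <- paste0(b, substr(ref, 1, nr - 1))
        alt <- paste0(b, substr(alt, 1, na - 1))
      } else {
        ref <- substr(ref, 1, nr - 1)
        alt <- substr(alt, 1, na - 1)
      }
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Canonical variant keys
#'
#' Two variants from different samples are "shared" iff their keys (chrom,
#' normalized position, ref, alt) are equal. Callers are expected to normalize
#' first (see [normalize_variants()]).
#'
#' @param v a `cv_variants` table
#' @return character vector of keys
#' @export
variant_key <- function(v) {
  if (nrow(v) == 0) return(character(0))
  sprintf("%s:%d:%s>%s", v$chrom, v$pos, v$ref, v$alt)
}

#' Apply variants to a genome
#'
#' Rebuilds each chromosome with the (non-overlapping) variants applied; used
#' by the simulator and by truth-consistency checks.
#'
#' @param g a `cv_genome`
#' @param v a `cv_variants` table (one sample)
#' @return a new `cv_genome`
#' @export
apply_variants <- function(g, v) {
  out <- g$seq
  if (nrow(v) > 0) {
    spans <- v[, .(chrom, s = pos + (type != "insertion"),
                   e = pos + nchar(ref) - 1L)]
    data.table::setorder(spans, chrom, s)
    ov <- spans[, any(s[-1] <= e[-.N] ), by = chrom]$V1
    if (any(ov)) stop("apply_variants: overlapping variants")
    for (cc in unique(v$chrom)) {
      vv <- v[chrom == cc][order(pos)]
      s <- out[[cc]]
      pieces <- character(2 * nrow(vv) + 1)
      cur <- 1L
      for (i in seq_len(nrow(vv))) {
        p <- vv$pos[i]; r <- vv$ref[i]; a <- vv$alt[i]
        pieces[2 * i - 1] <- substr(s, cur, p - 1L)
        pieces[2 * i] <- a
        cur <- p + nchar(r)
      }
      pieces[2 * nrow(vv) + 1] <- substr(s, cur, nchar(s))
      out[[cc]] <- paste(pieces, collapse = "")
    }
  }
  genome(out)
}

#' Write variants to VCF 4.2
#'
#' Haploid assembly-derived calls are written as homozygous `1/1` records with
#' contig headers taken from the genome. Reference mismatches are an error
#' listing the offending record.
#'
#' @param v a `cv_variants` table (one sample)
#' @param g a `cv_genome`
#' @param path output path
#' @param sample_name sample column name (default: the table's single sample)
#' @return `path`, invisibly
#' @export
write_vcf <- function(v, g, path, sample_name = NULL) {
  v <- validate_variants(v, g)
  sample_name <- sample_name %||%
    (if (nrow(v) > 0) v$sample_id[1] else "sample")
  lens <- genome_lengths(g)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=contigvar",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_name), collapse = "\t"))
  vv <- v[order(match(chrom, names(lens)), pos)]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1/1",
                  vv$chrom, vv$pos, vv$ref, vv$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Minimal VCF reader for the single-sample files this package writes;
#' `read_vcf(write_vcf(v))` is the identity on the variant key set.
#'
#' @param path VCF path
#' @param sample_id optional override for the sample label
#' @return a `cv_variants` table
#' @export
read_vcf <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  chromline <- grep("^#CHROM", lines)
  if (length(chromline) != 1) stop("malformed VCF (missing #CHROM header): ", path)
  cols <- strsplit(lines[chromline], "\t", fixed = TRUE)[[1]]
  smp <- sample_id %||% (if (length(cols) >= 10) cols[10] else "sample")
  body <- lines[-seq_len(chromline)]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(variant_table())
  f <- data.table::fread(text = body, header = FALSE, sep = "\t",
                         colClasses = list(character = 1))
  variant_table(chrom = f[[1]], pos = f[[2]], ref = f[[4]], alt = f[[5]],
                sample_id = smp)
}
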