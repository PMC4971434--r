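#' Genome container
#'
#' A genome is a set of chromosome (or contig) sequences over {A,C,G,T,N},
#' stored uppercase, together with a soft-mask recording which input bases were
#' lowercase. Coordinates are 1-based inclusive throughout the package.
#'
#' @param seqs named character vector of DNA sequences
#' @param mask optional named list of integer vectors: soft-masked (lowercase)
#'   positions per sequence
#' @return an object of class `cv_genome` with elements `seq` (named uppercase
#'   character vector) and `mask`
#' @export
genome <- function(seqs, mask = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "")) stop("all sequences must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  up <- toupper(seqs)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    stop("sequence ", ids[bad][1], " contains characters outside {A,C,G,T,N}")
  }
  if (is.null(mask)) mask <- stats::setNames(vector("list", length(ids)), ids)
  g <- list(seq = up, mask = mask)
  class(g) <- "cv_genome"
  g
}

#' @export
print.cv_genome <- function(x, ...) {
  cat("cv_genome:", length(x$seq), "sequence(s),",
      format(sum(nchar(x$seq)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g a `cv_genome`
#' @return named integer vector of lengths in bp
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "cv_genome"))
  vapply(g$seq, nchar, integer(1))
}

#' Extract a subsequence (1-based inclusive)
#' @param g a `cv_genome`
#' @param chrom chromosome id
#' @param start,end 1-based inclusive bounds
#' @return character scalar
#' @export
get_seq <- function(g, chrom, start, end) {
  s <- g$seq[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  if (start < 1 || end > nchar(s) || start > end + 1)
    stop("out-of-bounds request ", chrom, ":", start, "-", end)
  if (start > end) return("")
  substr(s, start, end)
}

#' Read a FASTA file
#'
#' Sequences are uppercased; lowercase (soft-masked) input bases are preserved
#' as a per-base mask. Malformed records raise a parse error naming the
#' offending line.
#'
#' @param path FASTA file path
#' @return a `cv_genome`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("FASTA parse error at line ", nonblank[1], ": expected '>' header")
  seqline <- !startsWith(lines, ">") & nzchar(trimws(lines))
  badseq <- which(seqline & grepl("[^ACGTNacgtn]", lines))
  if (length(badseq) > 0)
    stop("FASTA parse error at line ", badseq[1], ": invalid sequence characters")
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.character(ss)
  names(raw) <- ids
  mask <- lapply(raw, function(s) {
    m <- gregexpr("[acgtn]", s)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  })
  genome(raw, mask = mask)
}

#' Write a genome to FASTA
#'
#' Soft-masked positions are written back as lowercase, so
#' `read_fasta(write_fasta(g))` is the identity on sequence content and mask.
#'
#' @param g a `cv_genome`
#' @param path output path
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(g, path, width = 70) {
  stopifnot(inherits(g, "cv_genome"))
  out <- g$seq
  for (id in names(out)) {
    m <- g$mask[[id]]
    if (length(m)) {
      ch <- strsplit(out[[id]], "", fixed = TRUE)[[1]]
      ch[m] <- tolower(ch[m])
      out[[id]] <- paste(ch, collapse = "")
    }
  }
  ss <- Biostrings::BStringSet(out)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
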