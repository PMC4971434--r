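Package: contigvar
Title: Variant Discovery and Annotation from Assembled Contigs of Closely Related Genomes
Version: 0.1.0
Authors@R:
    person("OCRI", "Bioinformatics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls SNPs and small InDels between a reference genome and
    near-identical draft assemblies (contigs) using unique k-mer anchoring,
    colinear chain selection and banded global alignment; assigns variants to
    genomic regions (5'UTR, CDS, 3'UTR, intron, intergenic), classifies coding
    effects including large-effect variants (premature stop, start/stop codon
    changes, frameshifts), computes count-based per-gene dN/dS, and produces
    per-linkage-group rate tables, substitution and InDel length spectra, and
    two-sample shared/unique variant summaries. Includes a deterministic
    synthetic-data generator with a machine-readable truth set for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    withr
Config/testthat/edition: 3
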