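test_that("simulated references are canonical, packed and deterministic", {
  cfg <- small_sim_config(seed = 4)
  ref <- simulate_reference(cfg)
  expect_length(ref$genes, cfg$n_genes)
  expect_false(any(vapply(ref$genes, `[[`, logical(1), "non_canonical")))
  # every translated CDS begins M and ends at a stop, with no internal stop
  for (gn in ref$genes[sample(length(ref$genes), 5)]) {
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds_sequence(gn, ref$genome)))), "")[[1]]
    expect_equal(aa[1], "M")
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
  # non-overlapping loci with positive intergenic spacing
  spans <- t(vapply(ref$genes, `[[`, integer(2), "mrna_span"))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2] + 1))
  # determinism: same config -> byte-identical FASTA + GFF3
  ref2 <- simulate_reference(cfg)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); f2 <- file.path(d, "b.fa")
  write_fasta(ref$genome, f1); write_fasta(ref2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- file.path(d, "a.gff3"); g2 <- file.path(d, "b.gff3")
  write_gff3(ref$genes, g1); write_gff3(ref2$genes, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("infeasible gene packing raises a config error", {
  cfg <- simulation_config(seed = 1, n_chroms = 1, chrom_length_bp = 20000L,
                           n_genes = 40L)
  expect_error(simulate_reference(cfg), "infeasible packing")
})

test_that("zero mutation rates yield identical genomes and empty truth", {
  cfg <- small_sim_config(seed = 2, snp_rate_per_kb = 0, indel_rate_per_kb = 0)
  ref <- simulate_reference(cfg)
  mut <- mutate_genome(ref, cfg)
  expect_equal(nrow(mut$truth), 0)
  expect_identical(mut$genomes$landraceA$seq, ref$genome$seq)
})

test_that("truth reapplication reconstructs the mutated genomes exactly", {
  cfg <- small_sim_config(seed = 6)
  sim <- simulate_dataset(cfg)
  for (s in names(sim$genomes)) {
    re <- apply_variants(sim$reference$genome, sim$truth[sample_id == s])
    expect_identical(re$seq, sim$genomes[[s]]$seq)
  }
})

test_that("realized SNP counts and transition fraction match the config", {
  # spec'd check: ts/tv 3.0 at ~5 SNPs/kb over 1 Mb -> transition fraction
  # 0.75 within +/- 0.02
  cfg <- simulation_config(seed = 12, n_chroms = 2, chrom_length_bp = 500000L,
                           n_genes = 100L, snp_rate_per_kb = 5,
                           ts_tv_ratio = 3.0)
  ref <- simulate_reference(cfg)
  mut <- mutate_genome(ref, cfg)
  L <- sum(genome_lengths(ref$genome))
  for (s in c("landraceA", "landraceB")) {
    snps <- mut$truth[sample_id == s & type == "SNP"]
    expected <- cfg$snp_rate_per_kb / 1000 * L
    sigma <- sqrt(expected)
    expect_lt(abs(nrow(snps) - expected), 3 * sigma)
    is_ts <- paste0(snps$ref, ">", snps$alt) %in%
      c("A>G", "G>A", "C>T", "T>C")
    expect_lt(abs(mean(is_ts) - 0.75), 0.02)
  }
})

test_that("large-effect quotas are placed and classified as intended", {
  # zero background rates: the truth set contains exactly the forced variants
  cfg <- small_sim_config(
    seed = 9, snp_rate_per_kb = 0, indel_rate_per_kb = 0,
    large_effect_quota = c(stop_gained = 2, start_lost = 1, stop_lost = 1,
                           frameshift = 2, start_codon_indel = 1,
                           stop_codon_indel = 1))
  sim <- simulate_dataset(cfg)
  g <- sim$reference$genome; genes <- sim$reference$genes
  forA <- sim$truth[sample_id == "landraceA"]
  expect_equal(nrow(forA), 8)
  expect_equal(sum(forA$effect_intended == "stop_gained"), 2)
  # downstream classification must agree with the forced classes
  ann <- annotate_variants(
    normalize_variants(forA[, .(chrom, pos, ref, alt, type, sample_id)], g),
    build_region_index(genes, g))
  eff <- classify_effects(ann, genes, g)
  forced <- which(forA$effect_intended %in%
                    c("stop_gained", "start_lost", "stop_lost", "frameshift",
                      "start_codon_indel", "stop_codon_indel") & !forA$shared)
  expect_equal(eff$effect[forced], forA$effect_intended[forced])
})

test_that("quota infeasible for the gene count raises a config error", {
  expect_error(simulation_config(n_genes = 4L,
                                 large_effect_quota = c(stop_gained = 3)),
               "infeasible")
})

test_that("fragmentation tiles the genome, respects 200 bp rule, deterministic", {
  cfg <- small_sim_config(seed = 10, contig_mean_len_bp = 6000L)
  ref <- simulate_reference(cfg)
  fr <- fragment_into_contigs(ref$genome, cfg, seed = 3)
  expect_true(all(nchar(fr$contigs) >= cfg$min_contig_len_bp))
  # gap fraction 0: contigs concatenate to the full chromosome
  pl <- fr$placements[order(start)]
  expect_equal(pl$start[1], 1L)
  expect_equal(pl$end[nrow(pl)], genome_lengths(ref$genome)[["chr01"]])
  expect_true(all(pl$start[-1] == pl$end[-nrow(pl)] + 1L))
  rebuilt <- paste(vapply(seq_len(nrow(pl)), function(i) {
    sq <- fr$contigs[[pl$contig_id[i]]]
    if (pl$strand[i] == "-") revcomp(sq) else sq
  }, character(1)), collapse = "")
  expect_identical(rebuilt, ref$genome$seq[["chr01"]])
  # determinism
  fr2 <- fragment_into_contigs(ref$genome, cfg, seed = 3)
  expect_identical(fr$contigs, fr2$contigs)
  # strand mixture is exercised
  expect_true(all(c("+", "-") %in% pl$strand))
})

test_that("shared fraction controls the two-sample variant overlap", {
  cfg <- small_sim_config(seed = 21, shared_fraction = 0.3)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  ka <- variant_key(tr[sample_id == "landraceA"])
  kb <- variant_key(tr[sample_id == "landraceB"])
  obs <- length(intersect(ka, kb)) / length(union(ka, kb))
  expect_lt(abs(obs - 0.3), 0.05)
})
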