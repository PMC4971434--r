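# build a minimal one-exon plus-strand gene whose CDS we control exactly
codon_gene <- function(codons) {
  cds <- paste(codons, collapse = "")
  seq <- paste0("TTTTTTTTTT", cds, "TTTTTTTTTT")
  g <- genome(c(c1 = seq))
  gene <- gene_model("g1", "c1", "+",
                     cds_segments = rbind(c(11L, 10L + nchar(cds))),
                     utr5_segments = rbind(c(6L, 10L)),
                     utr3_segments = rbind(c(11L + nchar(cds),
                                             15L + nchar(cds))))
  list(g = g, gene = flag_non_canonical(list(g1 = gene), g)$g1)
}

test_that("codon-level SNP classes follow the standard genetic code", {
  fx <- codon_gene(c("ATG", "TGG", "CTT", "AAA", "TAA"))
  snp <- function(pos, alt) variant_table("c1", pos,
                                          substr(fx$g$seq[["c1"]], pos, pos),
                                          alt, "s")
  # TGG (Trp) third base G>A -> TGA: stop gained (codon 2: positions 14-16)
  expect_equal(classify_cds_snp(snp(16, "A"), fx$gene, fx$g), "stop_gained")
  # CTT third base T>C -> CTC, Leu>Leu: synonymous (codon 3: 17-19)
  expect_equal(classify_cds_snp(snp(19, "C"), fx$gene, fx$g), "synonymous")
  # start codon ATG G>A -> ATA: start lost (codon 1: 11-13)
  expect_equal(classify_cds_snp(snp(13, "A"), fx$gene, fx$g), "start_lost")
  # AAA first base A>C -> CAA, Lys>Gln: nonsynonymous (codon 4: 20-22)
  expect_equal(classify_cds_snp(snp(20, "C"), fx$gene, fx$g), "nonsynonymous")
  # terminal TAA second base A>C -> TCA: stop lost (codon 5: 23-25)
  expect_equal(classify_cds_snp(snp(24, "C"), fx$gene, fx$g), "stop_lost")
  # terminal TAA third base A>G -> TAG: stop-to-stop is synonymous
  expect_equal(classify_cds_snp(snp(25, "G"), fx$gene, fx$g), "synonymous")
})

test_that("coding InDel classes follow the declared precedence", {
  fx <- codon_gene(c("ATG", "TGG", "CTT", "AAA", "CCC", "GGA", "TAA"))
  s <- fx$g$seq[["c1"]]
  del <- function(pos, len) variant_table("c1", pos, substr(s, pos, pos + len),
                                          substr(s, pos, pos), "x")
  ins <- function(pos, insseq) variant_table("c1", pos, substr(s, pos, pos),
                                             paste0(substr(s, pos, pos), insseq), "x")
  # 2 bp deletion mid-CDS (codon 3) -> frameshift
  expect_equal(classify_cds_indel(del(16, 2), fx$gene, fx$g), "frameshift")
  # 3 bp deletion mid-CDS -> inframe
  expect_equal(classify_cds_indel(del(16, 3), fx$gene, fx$g), "inframe_indel")
  # 1 bp insertion inside ATG -> start_codon_indel, not frameshift
  expect_equal(classify_cds_indel(ins(11, "C"), fx$gene, fx$g),
               "start_codon_indel")
  expect_equal(classify_cds_indel(ins(12, "C"), fx$gene, fx$g),
               "start_codon_indel")
  # insertion between codons 1 and 2 is not inside the start codon
  expect_equal(classify_cds_indel(ins(13, "C"), fx$gene, fx$g), "frameshift")
  # deletion overlapping the terminal stop codon (positions 29-31)
  expect_equal(classify_cds_indel(del(28, 2), fx$gene, fx$g),
               "stop_codon_indel")
  # deletion overlapping codon 1 wins over stop/frame rules
  expect_equal(classify_cds_indel(del(11, 2), fx$gene, fx$g),
               "start_codon_indel")
})

test_that("effect classes are invariant under genome mirroring", {
  fw <- toy_genome()
  mir <- toy_genome_mirror(fw)
  s <- fw$genome$seq[["chr1"]]
  set.seed(31)
  cds_pos <- c(131:202, 303:380)
  for (p in sample(cds_pos, 25)) {
    refb <- substr(s, p, p)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    v <- variant_table("chr1", p, refb, altb, "s")
    cls_fw <- classify_cds_snp(v, fw$genes$gtoy, fw$genome)
    # mirrored variant: complementary alleles at the mirrored position
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    vm <- variant_table("chr1", mir$mirror_pos(p), comp[[refb]], comp[[altb]], "s")
    cls_mir <- classify_cds_snp(vm, mir$genes$gtoy, mir$genome)
    expect_equal(cls_mir, cls_fw, info = paste("pos", p))
  }
})

test_that("per-codon classification agrees with re-translation on both strands", {
  cfg <- small_sim_config(seed = 41)
  ref <- simulate_reference(cfg)
  v <- simulate_cds_snps(ref, n = 300, sample_id = "s", seed = 7)
  idx <- build_region_index(ref$genes, ref$genome)
  eff <- classify_effects(
    annotate_variants(v[, .(chrom, pos, ref, alt, type, sample_id)], idx),
    ref$genes, ref$genome)
  expect_equal(eff$effect, v$effect_intended)
  # spot-check a handful against the in-test whole-protein oracle
  for (i in sample(nrow(v), 20)) {
    expect_equal(eff$effect[i],
                 oracle_snp_effect(v[i], ref$genes[[v$gene_id[i]]], ref$genome),
                 info = variant_key(v[i]))
  }
})

test_that("substitution spectrum counts all 12 types and conserves totals", {
  one <- variant_table("c1", 1, "G", "A", "s")
  sp <- substitution_spectrum(one)
  expect_length(sp, 12)
  expect_equal(sum(sp), 1)
  expect_equal(sp[["G>A"]], 1)
  empty <- substitution_spectrum(variant_table())
  expect_length(empty, 12)
  expect_equal(sum(empty), 0)
  expect_error(substitution_spectrum(variant_table("c1", 1, "G", "GA", "s")),
               "non-SNP")
  # transition dominance at ts/tv = 3
  cfg <- small_sim_config(seed = 43, ts_tv_ratio = 3.0)
  sim <- simulate_dataset(cfg)
  snps <- sim$truth[sample_id == "landraceA" & type == "SNP",
                    .(chrom, pos, ref, alt, type, sample_id)]
  sp2 <- substitution_spectrum(snps)
  expect_equal(sum(sp2), nrow(snps))
  expect_setequal(names(sort(sp2, decreasing = TRUE))[1:4],
                  c("A>G", "G>A", "C>T", "T>C"))
})

test_that("InDel length spectrum buckets 1-10 and >=11 and conserves totals", {
  v <- rbind(variant_table("c1", 1, "GAAA", "G", "s"),
             variant_table("c1", 9, "G", "GTTT", "s"))
  sp <- indel_length_spectrum(v)
  expect_equal(sp[["3"]], 2)
  expect_equal(sum(sp), 2)
  long <- variant_table("c1", 1, paste(rep("A", 13), collapse = ""), "A", "s")
  expect_equal(indel_length_spectrum(long)[[">=11"]], 1)
  expect_error(indel_length_spectrum(variant_table("c1", 1, "G", "A", "s")),
               "SNPs")
  # geometric simulator: 1 bp bucket largest
  cfg <- small_sim_config(seed = 44)
  sim <- simulate_dataset(cfg)
  ind <- sim$truth[sample_id == "landraceA" & type != "SNP",
                   .(chrom, pos, ref, alt, type, sample_id)]
  sp3 <- indel_length_spectrum(ind)
  expect_equal(sum(sp3), nrow(ind))
  expect_equal(which.max(sp3), c(`1` = 1L))
})

test_that("CDS SNP classes partition: syn + nonsyn family = all classified", {
  cfg <- small_sim_config(seed = 45)
  sim <- simulate_dataset(cfg)
  g <- sim$reference$genome; genes <- sim$reference$genes
  idx <- build_region_index(genes, g)
  ann <- annotate_variants(
    sim$truth[, .(chrom, pos, ref, alt, type, sample_id)], idx)
  eff <- classify_effects(ann, genes, g)
  cds_snps <- eff[type == "SNP" & region == "CDS" & !is.na(effect)]
  expect_true(all(cds_snps$effect %in% c("synonymous", "nonsynonymous",
                                         "stop_gained", "start_lost",
                                         "stop_lost")))
  expect_equal(sum(cds_snps$effect == "synonymous") +
                 sum(cds_snps$effect %in% c("nonsynonymous", "stop_gained",
                                            "start_lost", "stop_lost")),
               nrow(cds_snps))
})
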