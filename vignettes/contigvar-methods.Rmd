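---
title: "Methods: assembly-to-reference variant discovery, annotation and selection scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly-to-reference variant discovery, annotation and selection scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigvar)
```

## Scope and model

`contigvar` re-implements, as one tested pipeline, the comparison of draft
genome assemblies of crop landraces against a high-quality reference of a
modern variety of the same species. The two genomes are assumed to be
*near-identical* (percent-level divergence, as between sesame accessions):
variation is modelled as isolated SNPs and short InDels on a colinear
backbone, and the calling stage is built around that assumption. Structural
rearrangements, CNVs and inversions are out of scope; a diverged-species
whole-genome aligner would be the wrong tool here and vice versa.

Coordinates are 1-based inclusive everywhere (GFF3/VCF convention). InDels
use the VCF anchored-allele representation and are left-aligned
(parsimony-trimmed, shifted to the leftmost equivalent placement) before any
cross-sample comparison — without a canonical placement the shared/unique
(Venn) counts would depend on the aligner's arbitrary gap placement.

## Calling: anchors, chains, banded alignment

**Anchoring.** A seed of length *k* (default 21) is an anchor when it occurs
exactly once in the whole reference — counting both strands, via canonical
k-mer hashing — and exactly once in the contig. This is the
maximal-unique-match idea behind standard whole-genome anchoring tools,
reduced to its k-mer form; uniqueness on both sides is what keeps repeats
from generating false placements. k = 21 makes random collisions negligible
(4^21 ≈ 4·10^12) while staying short enough that anchors tile the gaps
between nearby variants; the source material names its anchoring tool but no
parameters, so these are package defaults, not reproductions.

**Orientation and chaining.** Contigs are oriented by majority anchor vote
and re-anchored after reverse complementation. Anchors on a shared diagonal
are merged into maximal runs, then the best chain is the weighted
longest-increasing-subsequence: the colinear, non-overlapping subset with
maximum total anchored length, ties broken by minimal total diagonal drift,
then leftmost reference position. Contigs with fewer than two chained
anchors contribute no variants and are reported unplaced — a guard against
spurious single-seed placements; this mirrors the unalignable fraction
(repetitive sequence) that such comparisons always report.

**Alignment.** Each inter-anchor gap pair is aligned by banded global
dynamic programming with unit mismatch/gap costs. The band is strict
(|offset from the main diagonal| ≤ band); a gap whose length difference
exceeds the band is flagged unaligned and emits nothing. `align_gap` widens
the effective band to `max(band_width, 2 × |length difference|)` (default
band_width 50), so the unaligned path is reserved for pathological segments.
Contig tails beyond the terminal anchors are aligned semi-globally (free
reference prefix or suffix over an oversized reference window) so variants
near contig edges are still recovered — without this, fragmenting a genome
into contigs would silently lose every variant within ~k bp of a cut.

**Tie-breaking (a load-bearing detail).** Unit costs make many alignments
cost-equivalent. During backward traceback the aligner prefers gap moves
over diagonal moves, which yields contiguous, leftmost-placed gap runs.
Diagonal-first traceback — the textbook default — will happily split one
2 bp deletion into two 1 bp deletions around an interior matching base at
identical cost, which changes the variant representation and breaks
cross-sample keys. Variant-level left-alignment then canonicalizes whatever
residual placement freedom remains.

**Emission.** Mismatch columns become SNPs, one per position (multi-base
mismatch runs are split, because counts downstream are per-position and the
substitution spectrum is defined on single bases); each gap run becomes one
InDel of the run's length. Calls from overlapping contigs are collapsed by
normalized key; loci where overlapping contigs disagree on the allele are
dropped and logged (the source analysis is silent on conflicts; dropping is
the conservative choice).

## Annotation and effects

Region classes partition each mRNA: UTR5 ∪ CDS ∪ UTR3 ∪ intron, with
everything outside mRNA spans intergenic; the index construction asserts the
partition and refuses malformed gene models. "mRNA" in the summary table is
a roll-up row (sum of the four sub-rows), not a fifth class. Overlapping
gene models — which a one-transcript-per-gene annotation never exercises —
are resolved deterministically: CDS beats UTR beats intron, remaining ties
go to the smaller gene id. InDels are assigned by their first altered
reference base (the base after the VCF anchor); an InDel is counted in
exactly one region.

CDS SNPs are classified against the reference codon, strand-aware, standard
genetic code only: synonymous, nonsynonymous, stop_gained (non-stop → stop
before the terminal codon), start_lost (any change destroying the ATG),
stop_lost (terminal stop → non-stop); a terminal stop → stop change is
synonymous. Multiple SNPs in one codon are classified independently against
the reference codon, matching a per-variant script design. CDS InDels:
overlapping codon 1 → start_codon_indel, else overlapping the terminal stop
→ stop_codon_indel, else frameshift when length mod 3 ≠ 0, else
inframe_indel — precedence in that order, so a 1 bp insertion inside the ATG
is a start-codon InDel, not a frameshift. Genes whose CDS is not canonical
(length not divisible by 3, missing ATG or terminal stop, internal N) are
flagged, logged and excluded from effect classification.

## Selection scan

Per-gene dN/dS is the **raw count ratio** n_nonsyn / n_syn. This follows the
source computation verbatim and is *not* site-normalized: with roughly 3×
more non-synonymous than synonymous sites per codon, a neutral gene shows a
count ratio near 3, so these ratios are comparable across genes of similar
composition but are not the evolutionary ω. A Nei–Gojobori-style per-site
normalization is available behind `site_normalized = TRUE` and clearly
labelled a methodological extension. "Non-synonymous" includes stop_gained,
start_lost and stop_lost (every amino-acid-sequence-changing SNP); the
large-effect classes are additionally catalogued separately, and the
overlap rule is declared here because the source reports both figures
without stating one.

Zero-synonymous genes get dN/dS = NA; positive-selection membership is
decided by n_nonsyn > n_syn, which is division-free, agrees with
dN/dS > 1 wherever the ratio is defined, and keeps high-nonsyn/zero-syn
genes (the strongest candidates) in the list. Gene-set ratios pool counts
(Σ n_nonsyn / Σ n_syn) rather than averaging per-gene ratios: pooling is
the only reading that reproduces ratio-of-totals arithmetic, and it is
robust to zero-denominator member genes. The rapid-divergence filter is
strict on both conditions: flagged genes with strictly more than
`min_snps = 10` classified coding SNPs.

## Summaries and conservation identities

Rates are 1000 × count / length, rounded half-up to 2 decimals (base R's
round-half-even would disagree with printed tables). The per-chromosome
table's "Average" row reports the **unweighted mean of per-chromosome
rates** — not total count over total length. This is statistically unusual
(it weights a 5 Mb and a 25 Mb chromosome equally) but it is the only
definition consistent with the published table this package recomputes, so
it is the implemented and documented one; the Total row carries the summed
counts. Sharing is computed on normalized variant keys; the headline
percentage is 100 × |A∩B| / |A∪B| rounded to the nearest integer.

`full_report()` re-derives every table from one variant set and asserts the
cross-table conservation identities before writing anything: spectrum sums
equal SNP totals, region-table mRNA/Total roll-ups are additive, per-
chromosome totals equal region totals, Venn components sum to the union, and
synonymous + non-synonymous equals the classified coding-SNP count. A
violation is a hard error naming the identity. Notably, the published
tables themselves violate one of these by a hair (the printed substitution
spectrum sums are 5 and 7 short of the printed SNP totals, presumably a
late filtering step), so the identity is asserted on pipeline output, not
on the bundled printed counts.

## The synthetic-data generator: what it emulates, and what not

The generator is first-class, tested code. Its defaults state the world the
pipeline is validated in, scaled from the published sesame comparison to a
toy genome that runs in seconds: two chromosomes of 0.1–0.5 Mb (1 Mb total
in the acceptance run), ~4 SNPs/kb and ~1.4 InDels/kb per landrace (the
published per-LG range is 1.15–8.65 SNPs/kb and 0.5–3.2 InDels/kb),
transition/transversion ratio 1.9 (recomputed from the published spectrum,
≈1.85), geometric InDel lengths with p = 0.45 (matching the published
1 bp : 2 bp ratio ≈ 0.53; the published tail beyond 10 bp is unspecified, so
the tail is configurable and nothing is asserted about it), 46% of the
mutation union shared between the two landraces, AT-rich (65%) random
background, contigs of tens of kb with a 200 bp minimum and ~half
reverse-complemented. Genes are canonical by construction: ATG start,
in-frame stop, no internal stops, UTRs and introns, non-overlapping loci
with positive intergenic spacing.

Three deliberate idealizations keep the truth/recovery comparison *exact*,
and bound what a green end-to-end test establishes:

1. **Hard-core spacing** (60 bp minimum between mutations) guarantees unique
   anchor seeds between neighbouring variants, so every inter-anchor gap
   contains at most one mutation.
2. **Shift-stable InDel placement**: candidate InDels that could be slid or
   split within homopolymer/repeat context are re-drawn (deletions may fall
   back to insertions so realized counts track the configured rate).
   Ambiguous placements are exercised separately in the normalization tests,
   where a brute-force enumeration oracle defines the expected leftmost
   form.
3. **Cut-point avoidance**: contig cuts keep 100 bp from truth-variant
   spans. Real assemblies break in repeats, not preferentially inside
   variants; without this rule a variant bisected by a cut is genuinely
   unobservable from either fragment and recall = 1.0 would be an
   impossible target for reasons unrelated to the caller.

Consequently the generator does **not** emulate: repetitive or transposon
sequence (anchoring in repeats is exercised only negatively, via unplaced
contigs), sequencing or assembly base errors, clustered mutations,
heterozygosity, or large structural variation. A perfect recovery score
certifies the anchoring/chaining/alignment/emission/normalization machinery
on clean near-identical sequence — it does not certify robustness to
repeat-rich genomes.

Determinism is contractual: every generator output is a pure function of the
configuration (the seed included); seeds for sub-stages are derived by fixed
offsets, and RNG state is restored on exit.

For the selection-scan recovery test, `simulate_cds_snps()` steers coding
SNP classes to configured odds. The desired class is drawn once per SNP and
held until a position offering it is found (positions offering only the
other class are banked for later draws): naive redraw-on-rejection sampling
would bias the realized odds, because only ~36% of CDS positions offer any
synonymous alternative. Intended classes are decided by whole-CDS
re-translation — an independent route from the per-codon classifier they are
later compared against.

## Numerical and degenerate-input choices

* Rounding: half-up at 2 decimals for rates and ratios, nearest integer for
  the headline shared percentage.
* Variants touching N bases are dropped with a logged count; soft-masked
  (lowercase) reference bases are allowed by default and excludable via
  `exclude_masked = TRUE` (the source excluded repeats from alignability,
  not from variant calling).
* Empty inputs yield empty, fully-keyed outputs (all-zero spectra with all
  12 substitution keys, all-zero region tables), never errors.
* `apply_variants` refuses overlapping variants; the region index refuses
  gene models whose classes fail to partition the mRNA span; `full_report`
  fails hard on any conservation-identity violation.
* The chain oracle, alignment oracle (Levenshtein distance via
  `utils::adist`), normalization oracle (exhaustive placement enumeration)
  and effect oracle (whole-protein re-translation) are all independent of
  the code paths they check.

## Known limitations

* dN/dS counts are unnormalized by design (see above); do not compare them
  against site-normalized ω from codon-model software.
* The caller assumes near-identity; divergence beyond a few percent will
  fragment chains and inflate the unplaced fraction.
* InDels longer than the band (default ≥ 50 bp after widening) in a single
  gap are not called; the "structural variations" bucket of the source
  analysis is not separately classified.
* Only translation table 1 is supported; non-canonical transcripts are
  excluded from effect classification rather than guessed at.
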