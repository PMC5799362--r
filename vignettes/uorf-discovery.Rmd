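---
title: "Methods: uORF discovery, screen filtering and variant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uORF discovery, screen filtering and variant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfscan)
```

## The model

A uORF is defined by a translational initiation codon (uAUG) in the
transcript leader sequence and a subsequent in-frame termination codon
(uStop; TAA, TAG or TGA).  `uorfscan` operates on the *spliced* leader:
for a plus-strand transcript the TLS is the concatenation of exon pieces
in `[txStart, cdsStart)`; for a minus-strand transcript it is the reverse
complement of the exon pieces in `[cdsEnd, txEnd)`, read in transcript
orientation.  Alongside the sequence we keep a per-base coordinate map
(spliced offset → genomic position), which makes two things exact rather
than approximate: Kozak windows are assembled correctly across splice
junctions, and every discovered codon projects back to genomic blocks
(one block per exon segment, so a uAUG split 2|1 by an intron is a
two-block BED record whose sizes sum to 3).

The scan itself is a single left-to-right pass: every ATG fully inside
the TLS opens a uORF; its uStop is the *first* in-frame stop fully inside
the TLS downstream (first-in-scan makes "closest" tie-breaking vacuous,
and the procedure is fully deterministic).  If no such stop exists the
uORF is retained with `cds_overlapping = TRUE` — its ORF continues into
or past the CDS — and it contributes no entry to the uStop catalog.
Because consecutive in-frame uAUGs may share one termination codon, the
unique-uStop set is never larger than the unique-uAUG set; shared stops
are grouped by `shared_stop_group`.

Two catalog modes exist because two questions are asked of the catalog:
`by-genomic-position` deduplicates identical codons across isoforms
(genome-wide tallies must not double-count shared exons), while
`per-transcript` keeps one entry per isoform (screen target bookkeeping,
and the right join target for per-transcript effect classification).

### Kozak scoring

The optimal initiation context is `GCCGCCAUGR`.  Only the two core
positions are scored: −3 (three bases upstream of the A of AUG) and +4
(the first base after the AUG — a TLS base for internal uAUGs, the first
CDS base when the uAUG abuts the CDS).  The default rule counts a purine
(R = A/G) as a match, mirroring the `R` of the optimal context; an
exact-G rule is available for stricter scoring and is recorded in every
output header.  Strength is strong/intermediate/weak for 2/1/0 core
matches and `undetermined` when either core position is unavailable
(uAUG closer than 3 nt to the 5′ end).  We deliberately do not score
positions −6..−4: the published strength classes count 0/1/2 *core*
matches only, and extending the match set would silently change class
boundaries.  N never matches anything, and codons containing N are never
starts or stops — conservative behaviour on masked sequence.

## The screen filter

Per site and sample the filter sees base counts over A/C/G/T/DEL and
applies, in order:

1. **coverage**: total < `min_reads` (default 10, inclusive) →
   `low_coverage`;
2. **deviation**: the non-reference read fraction must *exceed*
   `min_deviation` (default 0.10, strict — exactly 10 % is `no_call`).
   The threshold is motivated by tumor purity: a heterozygous mutation in
   a sample with 50 % malignant cells deviates at 25 % in expectation,
   so 10 % leaves headroom for purity and subclonality while rejecting
   the error floor;
3. **noise exclusion**: a triggered site whose non-reference reads are
   scattered (≥ 2 distinct alternates and the top alternate below
   `noise_top_alt_fraction` = 2/3 of non-reference reads) is
   `excluded_noise`.  This codifies a manual review step; 2/3 is chosen
   so the canonical scattered pattern (7 reference + 1 + 1 + 1) is
   excluded while any clean 25 % single-alternate heterozygote passes.
   Deletions count toward the deviation and may be the top alternate;
   ties between equally supported alternates break deterministically in
   the order A, C, G, T, DEL.

Every site receives exactly one status, and because all rules are ratios
gated by one absolute threshold, scaling all counts by k ≥ 1 never turns
a candidate into `no_call`.  Candidates matching a known-polymorphism
catalog on (contig, position, alternate) are re-labelled `known_snp`;
matching is allele-aware.

`coverage_summary()` reports the design arithmetic (|sites| × |samples|
cells, absent cells = 0 reads), the fraction of cells at ≥ `min_reads`,
and the read share of the top q % of sites (default 5) — the standard
summary of amplicon-efficiency skew in pooled PCR screens.

## WES-side variant annotation

Caller VCFs (plus-strand alleles, 1-based positions) are normalised on
input: positions to 0-based, multi-allelic records split, ref/alt longer
than 1 bp flagged `complex` (reported, never silently dropped — screens
do find functional deletions, but codon-level classification is defined
for SNVs).  The analysis chain is subset → consensus → gate → classify:

* **subset**: variants join the catalog's per-base site table; a variant
  may pair with elements of several isoforms (one pairing per hit).  Zero
  contig-name overlap between variants and catalog aborts as an assembly
  mismatch — fail-loud is a design rule here, because silent coordinate
  drift is the dominant failure mode when mixing annotation sources.  For
  the same reason classification re-fetches the reference codon from the
  genome and hard-errors if the VCF ref allele disagrees.
* **consensus**: variants keyed by (contig, pos, ref, alt, sample pair)
  are kept when supported by ≥ `required` distinct callers; the default
  is *all* callers present — the maximum-specificity rule.  `required = 1`
  is the deduplicated union and output size is monotone non-increasing in
  `required`.
* **coverage gate**: ≥ 10 reads in both tumor and matched normal;
  positions missing from either count table fail with reason
  `uncovered`.
* **classify**: the alt allele is complemented onto the transcript strand
  and substituted into the codon.  Any single-base change of ATG is a
  loss (and always yields a near-cognate codon, which is why
  `near_cognate` is recorded — such codons can retain residual initiation
  activity); stop→stop is `stop_retained` (by the genetic code TAA has
  two single-base stop neighbours, TAG and TGA one each), stop→sense is
  `loss_of_uStop`; Kozak-window hits re-evaluate strength before and
  after.

`tabulate_effects()` counts on a genomically deduplicated roll-up (one
record per sample/contig/pos/alt, classified by the highest-priority
element hit: uAUG > uStop > uKozak), so a variant under a codon shared by
isoforms — or sitting in both a uAUG and a neighbouring uORF's Kozak
window — is counted once.  How such variants "should" be counted is
genuinely underdetermined; genomic dedup is this package's documented
choice, and the per-pairing table is returned untouched for anyone who
wants the other convention.  Recurrence means an identical
(contig, pos, alt) in ≥ 2 sample pairs; the novel/known split is
catalog-driven, never a network query.

## The synthetic-data generator

The generator's job is to emulate the *inputs* of such a study well
enough that every stage has an exact ground truth.  `make_transcripts()`
writes transcripts into the genome sequence: per transcript the TLS is
assembled from background sequence plus planted uORF blocks (ATG + body
codons + stop), then scrubbed so that no ATG other than the planted ones
survives — body codons are drawn from a restricted codon set (sense,
non-ATG, C/G third base) so neither starts nor in-frame stops can form
across junctions, which is what makes the manifest an *exact* oracle for
discovery rather than a statistical one.  Supported plants: plain uORFs,
in-frame uAUG pairs sharing one stop, CDS-overlapping uORFs (uAUG abutting
the CDS), non-coding decoys, minus-strand transcripts, and uAUG codons
split by an intron.  Kozak core bases are pinned to a requested class and
the manifest records the realized class (for a CDS-overlapping uORF the
+4 base is the main ORF's A, a purine, so "weak" is unattainable there).
Defaults: 50 transcripts, 20 % non-coding, TLS 50–500 nt, 1–4 exons,
introns 60–200 nt, 55 % of ordinary coding transcripts carry uORFs (the
approximate human prevalence of AUG-initiated uORFs in transcript
leaders), half the transcripts on the minus strand.

`plant_variants()` places SNVs on distinct host uORFs (start losses never
re-create ATG by construction; stop losses are drawn from sense
substitutions; Kozak variants avoid positions that coincide with any
codon; background variants avoid the whole catalog), one sample pair per
variant — the non-recurrent situation.  `emit_caller_vcfs()` thins the
truth per caller by independent Bernoulli draws.  `simulate_base_counts()`
draws a per-site log-normal sequencing rate (meanlog = log 103,
sdlog = 1.5 by default), Poisson depth per cell, and binomial allele
counts: at a planted heterozygous cell the alternate succeeds with
probability `purity/2·(1−e) + e/3`, everything else is uniform error at
rate `e`.  Under this model the expected covered fraction has a closed
form (`expected_covered_fraction()`, Poisson tail integrated over the
log-normal) and the expected read share of the top q % of sites is
`pnorm(sdlog − qnorm(1−q))` — about 44 % on the top 5 % at sdlog 1.5,
i.e. the strong amplicon skew such screens show.  One global seed fans
out to per-stage seeds by stable string hashing (`child_seed()`), so any
stage can be re-run in isolation and identical seeds give byte-identical
files.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: mapping and alignment artefacts, PCR chimeras
and strand bias, multi-nucleotide and long deletion/repeat variants
(handled only as catalog annotations, as in the screen's known-variant
partition), isoform families sharing exons (constructed fixtures cover
that case in tests), and the joint coverage statistics of a real pooled
screen.  On the last point: a single log-normal cannot simultaneously
reproduce a median of ~100 reads, ~80 % of cells at ≥ 10 reads and ~45 %
of reads on the top 5 % of sites; the defaults reproduce the median and
the skew, and the coverage checks compare simulation to the model's own
analytic expectation, not to any published cohort figure.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open everywhere; conversion happens
only at the VCF/TSV boundary (1-based) — one convention, one conversion
point.  Empty TLS (length 0) is legal and yields no uORFs; leaders
shorter than 3 nt scan to nothing; an empty feature list writes an empty
BED successfully.  refGene parsing accepts both the 15- and 16-column
(leading `bin`) dialects, auto-detected by column count with an explicit
override, and rejects malformed rows (exon count mismatch,
cdsStart > cdsEnd, unsorted or overlapping exons) with the row index.
IUPAC ambiguity codes other than N collapse to N on FASTA input.
Duplicate FASTA headers and duplicate design sites are errors, not
warnings.

## Problem sizes

The test suite and acceptance runs use: 110+ random leaders of length
0–1000 at GC 30–70 % against a naive quadratic oracle; synthetic genomes
of 2 × 120 kb (400 kb for the cohort run); 40–120 transcripts per
generated study; a planted cohort of 22 start-loss + 31 stop-loss + 8
known-SNP + 5 Kozak + 30 background variants through the 4-caller
consensus; screen simulations at the design target depth (log-normal
median 1000, 30-read floor) for recovery checks, at median 103 for skew
summaries, and at fixed depth 10^4 for the purity arithmetic, whose
mean heterozygote deviation across 20 sites must sit within ±0.01 of
0.25.  The full suite runs in well under a minute on one CPU.

## Known limitations

Near-cognate (non-AUG) initiation sites are not scanned; stops are only
sought within the TLS (a uAUG's stop inside the CDS is represented by the
`cds_overlapping` flag, not located); codons straddling the TLS/CDS
boundary are not considered start candidates; indel consequences on uORF
structure (lengthening/frameshift) are reported `complex` but not
resolved; and the screen filter models single-base substitutions and
single-base deletions only — long repeat/deletion loci belong in the
known-variant catalog.
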