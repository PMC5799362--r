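# uorfscan

Upstream open reading frames (uORFs) are short ORFs in the transcript
leader sequence (TLS, the 5′ UTR): an upstream AUG (uAUG) followed by an
in-frame stop codon (uStop) before — or, for CDS-overlapping uORFs, not
before — the main coding sequence.  Scanning ribosomes frequently initiate
at uAUGs, so most uORFs repress translation of the downstream CDS; a point
mutation that deletes a uAUG or uStop, or that rewires the Kozak context
around the uAUG, can de-repress a proto-oncogene.  `uorfscan` is an R
toolkit for hunting such variants:

* **Discovery** — from a genome FASTA and a UCSC refGene-style transcript
  table, extract every coding transcript's spliced TLS, find all uAUGs and,
  for each, the closest in-frame uStop (TAA/TAG/TGA) fully inside the TLS;
  uAUGs without an in-TLS stop are kept and flagged CDS-overlapping.
  Coordinates are projected back to the genome through a splice-aware map,
  so codons split by introns come out as multi-block BED records.
* **Kozak classification** — the context `GCCGCC AUG R` is optimal; only
  the two core positions are scored, −3 and +4 (the base after the AUG).
  With the default purine rule a position matches on A/G: two matches =
  strong, one = intermediate, none = weak, and a truncated window is
  `undetermined`.
* **Screen filter** — the candidate-mutation caller for MID-tagged amplicon
  deep sequencing: a site qualifies with ≥ 10 reads and calls when more
  than 10 % of reads deviate from the reference (a heterozygous mutation at
  50 % tumor purity is expected at 25 % deviation); scattered multi-allelic
  noise (e.g. 7 reference reads + 1 each of C/G/T) is excluded, and known
  polymorphisms are partitioned off against a catalog.
* **WES annotation** — subset per-caller somatic VCFs to the uORF codon
  (and optionally Kozak window) positions, keep the all-caller consensus,
  gate on tumor/normal coverage, and classify each SNV as `loss_of_uAUG`
  (always a near-cognate codon), `loss_of_uStop`, `stop_retained`,
  `kozak_alteration`, or `complex` for indels.
* **Synthetic data** — seeded generators for every input (genome,
  transcripts with planted uORFs, caller VCFs, base counts with
  configurable depth skew, purity and error rate) plus a ground-truth
  manifest, so the whole pipeline is testable offline.

## Worked example

The package ships a synthetic reconstruction of five Sanger-verified uORF
mutations (the codon and context changes of the published BLK, EPHB1,
JAK2, MAP2K6 and CHD1L variants, on small synthetic contigs):

```r
library(uorfscan)
ex <- verified_mutation_example()
catalog <- annotate_genome(ex$models, ex$genome, dedupe = "per-transcript")
catalog
#> uorf_catalog: 5 uORF(s) across 5 transcript(s); 5 unique uAUG codon(s), 5 unique uStop codon(s) [per-transcript]

hits    <- subset_to_catalog(ex$variants, catalog, kozak_window = TRUE)
effects <- classify_effect(hits, catalog, ex$genome)
effects[, c("tx_id", "element", "ref_codon", "alt_codon", "classification")]
#>       tx_id element ref_codon alt_codon   classification
#> 1  NM_CHD1L  uKozak         G         T kozak_alteration
#> 2 NM_MAP2K6    uAUG       ATG       ACG     loss_of_uAUG
#> 3  NM_EPHB1    uAUG       ATG       GTG     loss_of_uAUG
#> 4    NM_BLK    uAUG       ATG       ATT     loss_of_uAUG
#> 5   NM_JAK2    uAUG       ATG       ATA     loss_of_uAUG

tabulate_effects(effects)$summary
#>     loss_of_uAUG    loss_of_uStop    stop_retained kozak_alteration
#>                4                0                0                1
#>             none          complex
#>                0                0
```

Four start losses — each a near-cognate codon (GTG, ACG, ATA, ATT) — and
one Kozak alteration.  The screen filter reads the same way:

```r
call_site("A", c(A = 28, G = 12))[, c("total", "deviation", "top_alt", "status")]
#>   total deviation top_alt    status
#> 1    40       0.3       G candidate

call_site("A", c(A = 7, C = 1, G = 1, T = 1))$status
#> [1] "excluded_noise"
```

A 30 % deviation with one clean alternate is a candidate; the same
deviation scattered over three bases is excluded as sequencing noise.

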