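test_that("subsetting pairs variants with every element they hit", {
  loc <- build_locus("CCATGCCCTAACC", strand = "+")
  cat_ <- annotate_genome(loc$models, loc$genome, dedupe = "per-transcript")
  uaug_mid <- loc$tx_start + 3L                   # middle base of the uAUG
  v <- data.frame(contig = "c1", pos = c(uaug_mid, loc$tx_start + 13L),
                  ref = c("T", "C"), alt = c("C", "T"), complex = FALSE,
                  sample_pair = "S1", caller_id = "x", stringsAsFactors = FALSE)
  hits <- subset_to_catalog(v, cat_, kozak_window = FALSE)
  expect_equal(nrow(hits), 1)                     # second variant outside codons
  expect_equal(hits$element, "uAUG")
  expect_equal(hits$codon_pos, 2L)

  # Kozak window widens the match region
  hits2 <- subset_to_catalog(data.frame(contig = "c1", pos = loc$tx_start + 5L,
                                        ref = "C", alt = "A", complex = FALSE,
                                        sample_pair = "S1", caller_id = "x"),
                             cat_, kozak_window = TRUE)
  expect_equal(hits2$element, "uKozak")
  expect_equal(hits2$kozak_rel, 4L)

  # one codon shared by two isoforms: one pairing per transcript
  models <- rbind(loc$models, loc$models)
  models$tx_id <- c("TX1", "TX2")
  models$exon_starts <- rep(loc$models$exon_starts, 2)
  models$exon_ends <- rep(loc$models$exon_ends, 2)
  class(models) <- class(loc$models)
  cat2 <- annotate_genome(models, loc$genome, dedupe = "per-transcript")
  hits3 <- subset_to_catalog(v[1, ], cat2)
  expect_equal(sort(hits3$tx_id), c("TX1", "TX2"))

  # disjoint contig names mean the annotation and calls disagree on assembly
  v_bad <- v; v_bad$contig <- "chrZ"
  expect_error(subset_to_catalog(v_bad, cat_), "assembly mismatch")
})

test_that("consensus keeps variants shared by the required caller count", {
  base <- data.frame(contig = "c1", pos = 10L, ref = "A", alt = "G",
                     complex = FALSE, sample_pair = "S1",
                     stringsAsFactors = FALSE)
  four <- do.call(rbind, lapply(c("a", "b", "c", "d"),
                                function(k) cbind(base, caller_id = k)))
  three <- four[four$caller_id != "d", ]
  expect_equal(nrow(consensus_variants(four)), 1)
  got <- consensus_variants(four)
  expect_equal(got$n_callers, 4L)
  expect_equal(got$callers, "a,b,c,d")
  # 3 of 4 callers with required = 4 drops the variant
  three$pos <- 20L
  both <- rbind(four, three)
  expect_equal(consensus_variants(both, required = 4)$pos, 10L)
  expect_equal(sort(consensus_variants(both, required = 3)$pos), c(10L, 20L))
})

test_that("consensus equals the union at required = 1 and shrinks monotonically", {
  sim <- make_transcripts(make_genome(91), 91, n = 40)
  pv <- plant_variants(sim, 91, n_start_loss = 10, n_stop_loss = 10,
                       n_background = 20)
  sens <- c(a = 0.95, b = 0.9, c = 0.8, d = 0.7)
  vcfs <- emit_caller_vcfs(pv$variants, sim$genome, 91, sensitivities = sens)
  all_calls <- do.call(rbind, vcfs)
  # enumeration oracle: per-variant caller support counted directly
  key <- paste(all_calls$contig, all_calls$pos, all_calls$ref, all_calls$alt,
               all_calls$sample_pair)
  support <- tapply(all_calls$caller_id, key, function(x) length(unique(x)))
  sizes <- vapply(1:4, function(r) nrow(consensus_variants(all_calls, r)),
                  integer(1))
  expect_equal(sizes, vapply(1:4, function(r) sum(support >= r), integer(1)))
  expect_equal(sizes[1], length(unique(key)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("coverage gate requires the threshold in tumor AND normal", {
  v <- data.frame(contig = "c1", pos = c(5L, 6L, 7L), ref = "A", alt = "G",
                  sample_pair = "S1", stringsAsFactors = FALSE)
  mk <- function(pos, n) data.frame(sample = "S1", contig = "c1", pos = pos,
                                    ref = "A", A = n, C = 0L, G = 0L, T = 0L,
                                    DEL = 0L, stringsAsFactors = FALSE)
  tumor <- mk(c(5L, 6L), c(12L, 12L))
  normal <- mk(c(5L, 6L), c(10L, 9L))
  out <- coverage_gate(v, tumor, normal)
  expect_equal(out$covered, c(TRUE, FALSE, FALSE))
  expect_equal(out$cover_reason, c("ok", "below_min_reads", "uncovered"))
})

test_that("codon substitutions classify per the genetic code, both strands", {
  for (strand in c("+", "-")) {
    for (stop_codon in c("TAA", "TAG", "TGA")) {
      tls <- paste0("CCTCCC", "ATG", "CCG", stop_codon, "CC")
      loc <- build_locus(tls, strand = strand)
      cat_ <- annotate_genome(loc$models, loc$genome, dedupe = "per-transcript")
      sites <- expand_catalog_sites(cat_)
      for (i in seq_len(nrow(sites))) {
        gref <- genome_fetch(loc$genome, "c1", sites$pos[i], sites$pos[i] + 1)
        for (alt in setdiff(c("A", "C", "G", "T"), gref)) {
          v <- data.frame(contig = "c1", pos = sites$pos[i], ref = gref,
                          alt = alt, complex = FALSE, sample_pair = "S1",
                          caller_id = "x", stringsAsFactors = FALSE)
          eff <- classify_effect(subset_to_catalog(v, cat_), cat_, loc$genome)
          expect_equal(nrow(eff), 1)
          if (eff$element == "uAUG") {
            expect_equal(eff$ref_codon, "ATG")
            expect_equal(eff$classification, "loss_of_uAUG")
            expect_true(eff$near_cognate)        # single change off ATG
          } else {
            expect_equal(eff$ref_codon, stop_codon)
            expect_equal(eff$classification,
                         if (eff$alt_codon %in% c("TAA", "TAG", "TGA"))
                           "stop_retained" else "loss_of_uStop")
          }
        }
      }
    }
  }
})

test_that("stop-to-stop neighbour counts follow the genetic code", {
  # enumerated over all 9 single-base substitutions per stop codon:
  # TAA has two stop neighbours (TAG, TGA); TAG and TGA have one (TAA)
  neigh <- function(codon) {
    n <- 0L
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substring(codon, p, p))) {
      alt <- codon; substring(alt, p, p) <- b
      if (alt %in% c("TAA", "TAG", "TGA")) n <- n + 1L
    }
    n
  }
  expect_equal(vapply(c("TAA", "TAG", "TGA"), neigh, integer(1)),
               c(TAA = 2L, TAG = 1L, TGA = 1L))
})

test_that("Table-2-style worked example yields 4 uAUG losses and 1 Kozak change", {
  ex <- verified_mutation_example()
  cat_ <- annotate_genome(ex$models, ex$genome, dedupe = "per-transcript")
  hits <- subset_to_catalog(ex$variants, cat_, kozak_window = TRUE)
  eff <- classify_effect(hits, cat_, ex$genome)
  tab <- tabulate_effects(eff)
  expect_equal(tab$summary[["loss_of_uAUG"]], 4L)
  expect_equal(tab$summary[["kozak_alteration"]], 1L)
  expect_equal(sum(tab$summary), 5L)
  # mutant codons as printed: GTG (EPHB1), ACG (MAP2K6), ATA (JAK2), ATT (BLK)
  expect_setequal(eff$alt_codon[eff$element == "uAUG"],
                  c("GTG", "ACG", "ATA", "ATT"))
  chd1l <- eff[eff$element == "uKozak", ]
  expect_equal(chd1l$kozak_before, "intermediate")
  expect_equal(chd1l$kozak_after, "intermediate")
})

test_that("a reference-allele mismatch aborts instead of warning", {
  loc <- build_locus("CCATGCCCTAACC")
  cat_ <- annotate_genome(loc$models, loc$genome, dedupe = "per-transcript")
  v <- data.frame(contig = "c1", pos = loc$tx_start + 2L, ref = "C", alt = "G",
                  complex = FALSE, sample_pair = "S1", caller_id = "x",
                  stringsAsFactors = FALSE)   # genome has A here
  expect_error(classify_effect(subset_to_catalog(v, cat_), cat_, loc$genome),
               "reference mismatch")
})

test_that("complex variants are reported, not dropped", {
  loc <- build_locus("CCATGCCCTAACC")
  cat_ <- annotate_genome(loc$models, loc$genome, dedupe = "per-transcript")
  v <- data.frame(contig = "c1", pos = loc$tx_start + 2L, ref = "AT", alt = "A",
                  complex = TRUE, sample_pair = "S1", caller_id = "x",
                  stringsAsFactors = FALSE)
  eff <- classify_effect(subset_to_catalog(v, cat_), cat_, loc$genome)
  expect_equal(eff$classification, "complex")
})

test_that("mirrored plus/minus constructions classify identically", {
  tls <- "CCTCCCATGCCGTGACC"
  locp <- build_locus(tls, strand = "+")
  locm <- build_locus(tls, strand = "-")
  catp <- annotate_genome(locp$models, locp$genome, dedupe = "per-transcript")
  catm <- annotate_genome(locm$models, locm$genome, dedupe = "per-transcript")
  # substitute codon position 2 of the uAUG: T -> C on the transcript strand
  sp <- expand_catalog_sites(catp); sp <- sp[sp$element == "uAUG" & sp$codon_pos == 2, ]
  sm <- expand_catalog_sites(catm); sm <- sm[sm$element == "uAUG" & sm$codon_pos == 2, ]
  vp <- data.frame(contig = "c1", pos = sp$pos, ref = "T", alt = "C",
                   complex = FALSE, sample_pair = "S1", caller_id = "x",
                   stringsAsFactors = FALSE)
  vm <- data.frame(contig = "c1", pos = sm$pos, ref = "A", alt = "G",
                   complex = FALSE, sample_pair = "S1", caller_id = "x",
                   stringsAsFactors = FALSE)   # plus-strand alleles, complemented
  ep <- classify_effect(subset_to_catalog(vp, catp), catp, locp$genome)
  em <- classify_effect(subset_to_catalog(vm, catm), catm, locm$genome)
  expect_equal(ep$alt_codon, "ACG")
  expect_equal(em$alt_codon, "ACG")
  expect_equal(ep$classification, em$classification)
})

test_that("effect tabulation handles empty input and rolls up isoform hits", {
  empty <- classify_effect(
    subset_to_catalog(data.frame(contig = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0),
                                 complex = logical(0),
                                 sample_pair = character(0),
                                 caller_id = character(0)),
                      annotate_genome(build_locus("CCATGCCCTAACC")$models,
                                      build_locus("CCATGCCCTAACC")$genome,
                                      dedupe = "per-transcript")),
    annotate_genome(build_locus("CCATGCCCTAACC")$models,
                    build_locus("CCATGCCCTAACC")$genome,
                    dedupe = "per-transcript"),
    build_locus("CCATGCCCTAACC")$genome)
  tab0 <- tabulate_effects(empty)
  expect_true(all(tab0$summary == 0))

  # one variant hitting a codon shared by two isoforms counts once
  loc <- build_locus("CCATGCCCTAACC")
  models <- rbind(loc$models, loc$models)
  models$tx_id <- c("TX1", "TX2")
  models$exon_starts <- rep(loc$models$exon_starts, 2)
  models$exon_ends <- rep(loc$models$exon_ends, 2)
  class(models) <- class(loc$models)
  cat2 <- annotate_genome(models, loc$genome, dedupe = "per-transcript")
  v <- data.frame(contig = "c1", pos = loc$tx_start + 2L, ref = "A", alt = "G",
                  complex = FALSE, sample_pair = "S1", caller_id = "x",
                  stringsAsFactors = FALSE)
  eff <- classify_effect(subset_to_catalog(v, cat2), cat2, loc$genome)
  expect_equal(nrow(eff), 2)                     # one per isoform
  tab <- tabulate_effects(eff)
  expect_equal(sum(tab$summary), 1L)             # rolled up genomically
  expect_equal(tab$summary[["loss_of_uAUG"]], 1L)
})
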