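test_that("coding filter drops transcripts without an annotated CDS", {
  sim <- make_transcripts(make_genome(51), 51, n = 50, p_noncoding = 0.2)
  expect_equal(sum(!sim$models$coding), 10)
  kept <- suppressMessages(filter_coding(sim$models))
  expect_equal(nrow(kept), 40)
  expect_identical(kept$tx_id, sim$models$tx_id[sim$models$coding])
  expect_warning(suppressMessages(filter_coding(sim$models[!sim$models$coding, ])),
                 "no coding")
})

test_that("leader extraction splices out introns on both strands", {
  # single exon, plus strand: identity splice
  loc <- build_locus("ACGTAA", strand = "+")
  lead <- extract_leader(get_model(loc$models, 1), loc$genome)
  expect_equal(lead$sequence, "ACGTAA")
  expect_equal(lead$coord_map, seq.int(loc$tx_start, length.out = 6))
  expect_equal(lead$cds_next_base, "A")          # CDS starts ATG

  # minus strand: per-base brute-force oracle on the raw contig string
  loc2 <- build_locus("CCGTAACCGG", strand = "-")
  lead2 <- extract_leader(get_model(loc2$models, 1), loc2$genome)
  expect_equal(lead2$sequence, "CCGTAACCGG")
  contig <- unclass(loc2$genome)[["c1"]]
  per_base <- vapply(seq_along(lead2$coord_map), function(i) {
    chartr("ACGT", "TGCA", substring(contig, lead2$coord_map[i] + 1,
                                     lead2$coord_map[i] + 1))
  }, character(1))
  expect_equal(paste(per_base, collapse = ""), lead2$sequence)
  expect_true(all(diff(lead2$coord_map) == -1))  # descending for minus

  # intron interrupting the TLS: intronic bases absent from the sequence
  m <- get_model(loc$models, 1)
  m$exon_count <- 2L
  # split the single exon: [tx_start, tx_start+3) + intron of 10 + rest
  m$exon_starts <- c(m$tx_start, m$tx_start + 13L)
  m$exon_ends <- c(m$tx_start + 3L, m$tx_end + 10L)
  m$cds_start <- m$cds_start + 10L
  m$cds_end <- m$cds_end + 10L
  m$tx_end <- m$tx_end + 10L
  contig1 <- unclass(loc$genome)[["c1"]]
  spliced_genome <- genome_sequence(c(c1 = paste0(
    substring(contig1, 1, m$tx_start + 3),
    paste(rep("G", 10), collapse = ""),
    substring(contig1, m$tx_start + 4))))
  lead3 <- extract_leader(m, spliced_genome)
  expect_equal(lead3$sequence, "ACGTAA")
  expect_equal(length(lead3$coord_map), 6)
  expect_equal(lead3$coord_map[4] - lead3$coord_map[3], 11L)

  # CDS start outside every exon is a model-inconsistency error
  bad <- get_model(loc$models, 1)
  bad$cds_start <- bad$tx_end + 5L
  bad$cds_end <- bad$tx_end + 20L
  expect_error(extract_leader(bad, loc$genome), "not covered")
})

test_that("uORF scan finds minimal, shared-stop and CDS-overlapping uORFs", {
  u1 <- scan_uorfs(make_leader("ATGTAA"))
  expect_equal(nrow(u1), 1)
  expect_equal(u1$uaug_offset, 0L)
  expect_equal(u1$ustop_offset, 3L)
  expect_equal(u1$length_nt, 6L)

  # two in-frame uAUGs sharing one stop: unique uStop count < uAUG count
  u2 <- scan_uorfs(make_leader("ATGATGTGA"))
  expect_equal(u2$uaug_offset, c(0L, 3L))
  expect_equal(u2$ustop_offset, c(6L, 6L))
  expect_equal(length(unique(u2$shared_stop_group)), 1)

  # no in-frame stop before the CDS: flagged overlapping, no uStop
  u3 <- scan_uorfs(make_leader("CATGCC"))
  expect_equal(nrow(u3), 1)
  expect_true(u3$cds_overlapping)
  expect_true(is.na(u3$ustop_offset))

  # codons containing N never match
  expect_equal(nrow(scan_uorfs(make_leader("ATNTAA"))), 0)
  u4 <- scan_uorfs(make_leader("ATGTNATAA"))
  expect_equal(u4$ustop_offset, 6L)              # TNA skipped, TAA taken

  expect_equal(nrow(scan_uorfs(make_leader(""))), 0)
  expect_equal(nrow(scan_uorfs(make_leader("AT"))), 0)
})

test_that("scan matches the naive quadratic oracle on random leaders", {
  set.seed(101)
  for (i in 1:120) {
    len <- sample(0:1000, 1)
    gc <- runif(1, 0.3, 0.7)
    s <- random_tls(len, gc)
    expect_same_uorfs(scan_uorfs(make_leader(s)), naive_scan(s))
  }
})

test_that("removing the 5'-most TLS base only drops or keeps suffix uORFs", {
  set.seed(303)
  for (i in 1:40) {
    s <- random_tls(sample(30:300, 1), runif(1, 0.3, 0.7))
    full <- scan_uorfs(make_leader(s))
    trimmed <- scan_uorfs(make_leader(substring(s, 2)))
    if (nrow(trimmed)) {
      # every uORF of the trimmed leader maps onto one of the full leader
      expect_true(all((trimmed$uaug_offset + 1L) %in% full$uaug_offset))
    }
  }
})

test_that("Kozak context scores core positions -3/+4 with boundary handling", {
  # the published CHD1L-type context: -3 = T (no match), +4 = A (purine)
  lead <- make_leader("CCTTGTGTATGACCTAACC")    # uAUG at offset 8, context ttgTgtATGA
  kz <- kozak_context(lead, 8L)
  expect_equal(kz$window, "ttgTgtATGA")
  expect_equal(kz$core_matches, 1L)
  expect_equal(kz$strength, "intermediate")

  # optimal context
  lead2 <- make_leader("GCCGCCATGGCCTAA")
  kz2 <- kozak_context(lead2, 6L)
  expect_equal(kz2$window, "gccGccATGG")
  expect_equal(kz2$core_matches, 2L)
  expect_equal(kz2$strength, "strong")

  # -3 unavailable: undetermined regardless of +4
  kz3 <- kozak_context(make_leader("CATGGCCTAA"), 1L)
  expect_equal(kz3$strength, "undetermined")
  expect_true(is.na(kz3$core_matches))
  expect_match(kz3$window, "^\\.")

  # uAUG abutting the CDS takes +4 from the first CDS base
  lead4 <- make_leader("GCCGCCATG", cds_next = "G")
  expect_equal(kozak_context(lead4, 6L)$strength, "strong")
  lead5 <- make_leader("GCCGCCATG", cds_next = "C")
  expect_equal(kozak_context(lead5, 6L)$strength, "intermediate")

  # exact-G rule demotes purine A at +4
  kzG <- kozak_context(lead, 8L, kozak_policy("exact-G", "exact-G"))
  expect_equal(kzG$strength, "weak")
})

test_that("catalog deduplicates isoform-shared codons by genomic position", {
  loc <- build_locus("CCATGCCCTAACC", strand = "+")
  models <- rbind(loc$models, loc$models)        # two isoforms, identical TLS
  models$tx_id <- c("TX1", "TX2")
  models$exon_starts <- rep(loc$models$exon_starts, 2)
  models$exon_ends <- rep(loc$models$exon_ends, 2)
  class(models) <- class(loc$models)
  cat_g <- annotate_genome(models, loc$genome, dedupe = "by-genomic-position")
  expect_equal(nrow(cat_g$uorfs), 2)             # full catalog keeps both
  expect_equal(nrow(cat_g$uaug_sites), 1)        # codon counted once
  expect_equal(nrow(cat_g$ustop_sites), 1)
  cat_t <- annotate_genome(models, loc$genome, dedupe = "per-transcript")
  expect_equal(nrow(cat_t$uaug_sites), 2)
})

test_that("catalog counts match the generator's truth manifest exactly", {
  sim <- make_transcripts(make_genome(61), 61, n = 50, n_shared_stop_pairs = 3,
                          n_cds_overlap = 2, n_intron_split = 2)
  cat_ <- annotate_genome(sim$models, sim$genome, dedupe = "per-transcript")
  m <- sim$manifest$uorfs
  expect_equal(nrow(cat_$uorfs), nrow(m))
  key <- function(d) sort(paste(d$tx_id, d$uaug_offset, d$ustop_offset,
                                d$cds_overlapping, d$kozak_strength))
  expect_equal(key(cat_$uorfs), key(m))
  # shared-stop pairs collapse in the uStop set
  expect_equal(nrow(cat_$uorfs) - sum(cat_$uorfs$cds_overlapping) -
                 nrow(cat_$ustop_sites), 3)
  expect_lte(nrow(cat_$ustop_sites), nrow(cat_$uaug_sites))
})

test_that("discovered codon blocks re-splice to their codon on the transcript strand", {
  sim <- make_transcripts(make_genome(71), 71, n = 40, n_intron_split = 4)
  cat_ <- annotate_genome(sim$models, sim$genome, dedupe = "per-transcript")
  u <- cat_$uorfs
  expect_gt(sum(u$strand == "-"), 0)
  expect_gt(sum(vapply(u$uaug_blocks, nrow, integer(1)) > 1), 0)
  for (i in seq_len(nrow(u))) {
    expect_equal(uorfscan:::fetch_blocks(sim$genome, u$contig[i],
                                         u$uaug_blocks[[i]], u$strand[i]),
                 "ATG")
    if (!u$cds_overlapping[i]) {
      expect_equal(uorfscan:::fetch_blocks(sim$genome, u$contig[i],
                                           u$ustop_blocks[[i]], u$strand[i]),
                   u$ustop_codon[i])
    }
  }
})
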