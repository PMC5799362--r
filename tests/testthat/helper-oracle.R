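# Independent oracles and fixture builders used across the suite.

# Deliberately naive quadratic uORF scanner: character-by-character, no
# shared code with the package implementation.  Returns a data frame of
# (uaug_offset, ustop_offset, cds_overlapping) in 0-based spliced coords.
naive_scan <- function(s) {
  L <- nchar(s)
  out <- data.frame(uaug_offset = integer(0), ustop_offset = integer(0),
                    cds_overlapping = logical(0))
  if (L < 3) return(out)
  for (o in 0:(L - 3)) {
    if (substring(s, o + 1, o + 3) != "ATG") next
    found <- NA_integer_
    j <- o + 3
    while (j + 3 <= L) {
      cod <- substring(s, j + 1, j + 3)
      if (cod %in% c("TAA", "TAG", "TGA")) { found <- j; break }
      j <- j + 3
    }
    out <- rbind(out, data.frame(uaug_offset = o, ustop_offset = found,
                                 cds_overlapping = is.na(found)))
  }
  out
}

# random TLS with given GC fraction
random_tls <- function(len, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# in-memory leader over a contiguous plus-strand stretch starting at gstart
make_leader <- function(seq, gstart = 0L, cds_next = "A", tx_id = "t1") {
  structure(list(tx_id = tx_id, gene = tx_id, contig = "c1", strand = "+",
                 sequence = seq,
                 coord_map = seq.int(gstart, length.out = nchar(seq)),
                 cds_next_base = cds_next,
                 cds_next_gpos = gstart + nchar(seq)),
            class = "transcript_leader")
}

# build a one-transcript genome around a given TLS (plus a fixed minimal
# CDS), on either strand; returns list(genome, models, tls_gstart)
build_locus <- function(tls, strand = "+", contig = "c1", pad = 30L) {
  cds <- "ATGGCCGCCTGA"
  utr3 <- "CCTCC"
  tx_seq <- paste0(tls, cds, utr3)
  plus_seq <- if (strand == "+") tx_seq else uorfscan::revcomp(tx_seq)
  pad_seq <- paste(rep("C", pad), collapse = "")
  contig_seq <- paste0(pad_seq, plus_seq, pad_seq)
  tx_start <- pad
  tx_end <- pad + nchar(tx_seq)
  if (strand == "+") {
    cds_start <- tx_start + nchar(tls)
    cds_end <- cds_start + nchar(cds)
  } else {
    cds_end <- tx_end - nchar(tls)
    cds_start <- cds_end - nchar(cds)
  }
  models <- data.frame(tx_id = "TX1", gene = "G1", contig = contig,
                       strand = strand, tx_start = tx_start, tx_end = tx_end,
                       cds_start = cds_start, cds_end = cds_end,
                       exon_count = 1L, stringsAsFactors = FALSE)
  models$exon_starts <- list(tx_start)
  models$exon_ends <- list(tx_end)
  models$coding <- TRUE
  class(models) <- c("transcript_models", class(models))
  g <- uorfscan::genome_sequence(stats::setNames(contig_seq, contig))
  list(genome = g, models = models, tx_start = tx_start)
}

expect_same_uorfs <- function(found, oracle) {
  expect_equal(nrow(found), nrow(oracle))
  if (nrow(found)) {
    expect_equal(found$uaug_offset, oracle$uaug_offset)
    expect_equal(found$ustop_offset, oracle$ustop_offset)
    expect_equal(found$cds_overlapping, oracle$cds_overlapping)
  }
}
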