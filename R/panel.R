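# Screen design bookkeeping: the three target gene sets of the uORF
# amplicon screen, and a fully synthetic reconstruction of the five
# Sanger-verified uORF mutations used as a worked classification example.

#' The screen's target gene panel
#'
#' The amplicon screen interrogated uORF initiation sites of three gene
#' sets: uORF-bearing human tyrosine kinases (83 genes), previously
#' validated proto-oncogenes (46) and candidate genes post-transcriptionally
#' induced in cancer cell lines (3) — 132 target genes in total.  The full
#' membership is not redistributed here; the panel is represented with a
#' handful of exemplar symbols from the published mutation/SNP tables and
#' synthetic placeholder identifiers for the remainder, which preserves
#' every set size and the union arithmetic.
#'
#' @param n_tk,n_onc,n_cand set sizes.
#' @return a named list of three disjoint character vectors.
#' @export
target_panel <- function(n_tk = 83, n_onc = 46, n_cand = 3) {
  tk_known <- c("EPHB1", "JAK2", "BLK", "EPHA3", "KDR", "MUSK", "PTK2B", "TYK2")
  onc_known <- c("MDM2", "STAT6", "CHD1L", "YEATS4", "MAP2K6", "CAMKK2", "NRP2")
  fill <- function(known, n, prefix) {
    known <- known[seq_len(min(length(known), n))]
    c(known, sprintf("%s%03d", prefix, seq_len(n - length(known))))
  }
  list(tyrosine_kinases = fill(tk_known, n_tk, "SYNTK"),
       proto_oncogenes = fill(onc_known, n_onc, "SYNONC"),
       candidates = fill(character(0), n_cand, "SYNCAND"))
}

#' Summarise a target panel
#' @param panel list of gene-symbol vectors, e.g. from [target_panel()].
#' @return a list with per-set sizes and the size of the union.
#' @export
panel_summary <- function(panel) {
  list(set_sizes = vapply(panel, length, integer(1)),
       n_union = length(unique(unlist(panel))))
}

#' Synthetic reconstruction of the five verified uORF mutations
#'
#' Builds five small single-exon loci that reproduce, base for base, the
#' codon and Kozak contexts of the five Sanger-verified uORF mutations
#' (four uAUG losses — the BLK ATG>ATT, EPHB1 ATG>GTG, JAK2 ATG>ATA and
#' MAP2K6 ATG>ACG codon changes — and the CHD1L Kozak -1 G>T change in
#' the context `ttgTgtATGA`), each with its variant record.  Coordinates
#' are synthetic (each locus sits near the start of a small contig named
#' after the gene's chromosome); the ref/alt alleles and transcript-strand
#' codon changes match the verified set.  Intended for worked examples and
#' tests of the effect classifier.
#'
#' @return a list: `genome`, `models`, `variants`.
#' @export
verified_mutation_example <- function() {
  pre <- "CCTCCTCC"        # TLS 5' pad, ATG- and context-free
  tail <- "CCTCC"
  cds <- "ATGGCCGCCTGA"    # minimal main ORF
  utr3 <- "CCTCC"
  pad <- "CCTCC"

  loci <- list(
    # gene  contig   ctx6      uorf body+stop  variant: codon pos / kozak rel, plus-strand ref>alt
    BLK    = list(contig = "chr8",  ctx6 = "CCTCCC", body = "CCCTAA",
                  kind = "uAUG", codon_pos = 3L, alt = "T", sample = "CA1"),
    EPHB1  = list(contig = "chr3",  ctx6 = "CCTCCC", body = "CCCTAA",
                  kind = "uAUG", codon_pos = 1L, alt = "G", sample = "MC1"),
    JAK2   = list(contig = "chr9",  ctx6 = "CCTCCC", body = "CCCTAA",
                  kind = "uAUG", codon_pos = 3L, alt = "A", sample = "NHL1"),
    MAP2K6 = list(contig = "chr17", ctx6 = "CCTCCC", body = "CCCTAA",
                  kind = "uAUG", codon_pos = 2L, alt = "C", sample = "CA2"),
    CHD1L  = list(contig = "chr1",  ctx6 = "TTGTGG", body = "ACCTAA",
                  kind = "uKozak", kozak_rel = -1L, alt = "T", sample = "CX1"))

  contigs <- character(0)
  model_rows <- list()
  var_rows <- list()
  for (g in names(loci)) {
    lc <- loci[[g]]
    tls <- paste0(pre, lc$ctx6, "ATG", lc$body, tail)
    seqs <- paste0(pad, tls, cds, utr3, pad)
    contigs[lc$contig] <- seqs
    tx_start <- nchar(pad)
    tx_end <- tx_start + nchar(tls) + nchar(cds) + nchar(utr3)
    cds_start <- tx_start + nchar(tls)
    uaug_off <- nchar(pre) + nchar(lc$ctx6)      # spliced offset of the uAUG
    model_rows[[g]] <- list(tx_id = paste0("NM_", g), gene = g,
                            contig = lc$contig, strand = "+",
                            tx_start = tx_start, tx_end = tx_end,
                            cds_start = cds_start,
                            cds_end = cds_start + nchar(cds),
                            exon_count = 1L,
                            exon_starts = tx_start, exon_ends = tx_end)
    vpos <- if (lc$kind == "uAUG") {
      tx_start + uaug_off + lc$codon_pos - 1L
    } else {
      tx_start + uaug_off + lc$kozak_rel
    }
    var_rows[[g]] <- data.frame(
      contig = lc$contig, pos = vpos,
      ref = substring(seqs, vpos + 1, vpos + 1), alt = lc$alt,
      complex = FALSE, sample_pair = lc$sample, caller_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, lapply(model_rows, function(r)
    data.frame(r[setdiff(names(r), c("exon_starts", "exon_ends"))],
               stringsAsFactors = FALSE)))
  models$exon_starts <- lapply(model_rows, function(r) r$exon_starts)
  models$exon_ends <- lapply(model_rows, function(r) r$exon_ends)
  models$coding <- TRUE
  rownames(models) <- NULL
  class(models) <- c("transcript_models", class(models))
  list(genome = genome_sequence(contigs), models = models,
       variants = do.call(rbind, c(var_rows, list(make.row.names = FALSE))))
}
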