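# WES-side analysis: subset caller VCFs to uORF codon (and optionally
# Kozak window) positions, take the multi-caller consensus, gate on
# tumor/normal coverage, and classify each variant's consequence on the
# uAUG, uStop or uKozak element it hits.

EFFECT_CLASSES <- c("loss_of_uAUG", "loss_of_uStop", "stop_retained",
                    "kozak_alteration", "none", "complex")

#' Subset variants to uORF element positions
#'
#' Joins a variant table against the per-base site table of a catalog
#' (see [expand_catalog_sites()]).  A variant hitting elements of several
#' transcripts yields one pairing per hit.  With `kozak_window = TRUE` the
#' seven Kozak window positions (-6..-1, +4) of every uAUG are matched as
#' `uKozak` hits in addition to the codons themselves.  As a guard against
#' annotation/variant assembly mixups, zero overlap between the contig
#' names of the two inputs is an error.
#'
#' @param variants variant data frame (see [read_vcf()]).
#' @param catalog a `uorf_catalog` from [annotate_genome()].
#' @param kozak_window match Kozak window positions too?
#' @return a data frame with one row per (variant, element) pairing.
#' @export
subset_to_catalog <- function(variants, catalog, kozak_window = FALSE) {
  sites <- expand_catalog_sites(catalog, kozak_window = kozak_window)
  if (nrow(variants) && nrow(sites) &&
      !length(intersect(unique(variants$contig), unique(sites$contig)))) {
    stop("assembly mismatch: no contig names shared between variants and catalog")
  }
  hits <- merge(variants, sites, by = c("contig", "pos"))
  hits[order(hits$contig, hits$pos, hits$tx_id, hits$element), , drop = FALSE]
}

#' Multi-caller consensus of somatic variants
#'
#' Variants are matched on (contig, pos, ref, alt, sample_pair) and kept
#' when reported by at least `required` distinct callers (default: every
#' caller present in the input — the maximum-specificity "shared by all
#' platforms" rule).  `consensus_variants(required = 1)` is the
#' de-duplicated union, and the output shrinks monotonically as `required`
#' grows.
#'
#' @param variants variant data frame with a `caller_id` column (rbind the
#'   per-caller [read_vcf()] outputs).
#' @param required minimum number of supporting callers, or `NULL` for all.
#' @return one row per retained variant, with `n_callers` and a
#'   comma-separated `callers` column.
#' @export
consensus_variants <- function(variants, required = NULL) {
  callers <- sort(unique(variants$caller_id))
  if (is.null(required)) required <- length(callers)
  if (nrow(variants) == 0) {
    variants$n_callers <- integer(0); variants$callers <- character(0)
    return(variants)
  }
  key <- paste(variants$contig, variants$pos, variants$ref, variants$alt,
               variants$sample_pair, sep = "|")
  supp <- lapply(split(variants$caller_id, key), function(x) sort(unique(x)))
  first <- variants[!duplicated(key), , drop = FALSE]
  fkey <- key[!duplicated(key)]
  first$n_callers <- vapply(supp[fkey], length, integer(1))
  first$callers <- vapply(supp[fkey], paste, character(1), collapse = ",")
  first$caller_id <- NULL
  out <- first[first$n_callers >= required, , drop = FALSE]
  out[order(out$contig, out$pos, out$alt, out$sample_pair), , drop = FALSE]
}

#' Tumor/normal coverage gate
#'
#' A variant passes when its position is covered by at least `min_reads`
#' reads in both the tumor and the matched normal sample.  Positions
#' absent from a count table fail with reason `"uncovered"`.
#'
#' @param variants variant data frame.
#' @param tumor_counts,normal_counts base-count data frames keyed by
#'   (`sample`, `contig`, `pos`); `sample` must equal the variant's
#'   `sample_pair`.
#' @param min_reads inclusive threshold.
#' @return `variants` with logical `covered` and character `cover_reason`.
#' @export
coverage_gate <- function(variants, tumor_counts, normal_counts, min_reads = 10L) {
  total_at <- function(counts) {
    if (nrow(counts) == 0) return(setNames(integer(0), character(0)))
    tot <- rowSums(counts[, c(BASES, "DEL")])
    setNames(as.integer(tot), paste(counts$sample, counts$contig, counts$pos,
                                    sep = "|"))
  }
  tt <- total_at(tumor_counts)
  nt <- total_at(normal_counts)
  key <- paste(variants$sample_pair, variants$contig, variants$pos, sep = "|")
  t_cov <- tt[key]; n_cov <- nt[key]
  covered <- !is.na(t_cov) & !is.na(n_cov) &
    t_cov >= min_reads & n_cov >= min_reads
  reason <- rep("ok", length(covered))
  reason[is.na(t_cov) | is.na(n_cov)] <- "uncovered"
  reason[!covered & reason == "ok"] <- "below_min_reads"
  variants$covered <- covered
  variants$cover_reason <- reason
  variants
}

#' Classify variant consequences on uORF elements
#'
#' For each (variant, element) pairing from [subset_to_catalog()] the
#' reference codon is re-fetched from the genome through the element's
#' genomic blocks and re-spliced on the transcript strand; a mismatch
#' between the VCF reference allele and the genome base is a hard error
#' (silent coordinate drift must never pass).  VCF alleles are plus-strand
#' and are complemented onto the transcript strand before substitution.
#'
#' Classification: a uAUG hit whose alternate codon is no longer ATG is
#' `loss_of_uAUG` (for single-base substitutions the alternate is always a
#' near-cognate codon, recorded in `near_cognate`); a uStop hit is
#' `stop_retained` when the alternate codon is still one of TAA/TAG/TGA
#' and `loss_of_uStop` otherwise; a Kozak window hit is
#' `kozak_alteration`, with strength re-evaluated before and after the
#' substitution.  Multi-nucleotide variants are reported as `complex`,
#' never silently dropped.
#'
#' @param hits output of [subset_to_catalog()].
#' @param catalog the `uorf_catalog` used for subsetting.
#' @param genome a [genome_sequence()].
#' @param policy a [kozak_policy()].
#' @return an effects data frame: variant identity, `element`, `tx_id`,
#'   `ref_codon`, `alt_codon`, `classification`, `near_cognate`,
#'   `kozak_before`, `kozak_after`.
#' @export
classify_effect <- function(hits, catalog, genome, policy = kozak_policy()) {
  n <- nrow(hits)
  out <- data.frame(
    contig = hits$contig, pos = hits$pos, ref = hits$ref, alt = hits$alt,
    sample_pair = if ("sample_pair" %in% names(hits)) hits$sample_pair
                  else rep(NA_character_, n),
    tx_id = hits$tx_id, element = hits$element,
    ref_codon = rep(NA_character_, n), alt_codon = rep(NA_character_, n),
    classification = rep(NA_character_, n), near_cognate = rep(NA, n),
    kozak_before = rep(NA_character_, n), kozak_after = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  u <- catalog$uorfs
  for (i in seq_len(n)) {
    gref <- genome_base(genome, hits$contig[i], hits$pos[i])
    if (gref != hits$ref[i] && !hits$complex[i]) {
      stop(sprintf("reference mismatch at %s:%d: VCF says %s, genome says %s",
                   hits$contig[i], hits$pos[i] + 1L, hits$ref[i], gref))
    }
    if (hits$complex[i]) {
      out$classification[i] <- "complex"
      next
    }
    strand <- hits$strand[i]
    alt_tx <- if (strand == "-") complement_base(hits$alt[i]) else hits$alt[i]
    row <- hits$uorf_row[i]
    if (hits$element[i] %in% c("uAUG", "uStop")) {
      blocks <- if (hits$element[i] == "uAUG") u$uaug_blocks[[row]]
                else u$ustop_blocks[[row]]
      ref_codon <- fetch_blocks(genome, hits$contig[i], blocks, strand)
      expected <- if (hits$element[i] == "uAUG") "ATG" else u$ustop_codon[row]
      if (!identical(ref_codon, expected)) {
        stop(sprintf("catalog/genome disagreement for %s %s: codon %s vs %s",
                     hits$tx_id[i], hits$element[i], ref_codon, expected))
      }
      cp <- hits$codon_pos[i]
      alt_codon <- ref_codon
      substring(alt_codon, cp, cp) <- alt_tx
      out$ref_codon[i] <- ref_codon
      out$alt_codon[i] <- alt_codon
      if (hits$element[i] == "uAUG") {
        out$classification[i] <- if (alt_codon != "ATG") "loss_of_uAUG" else "none"
        out$near_cognate[i] <- hamming(alt_codon, "ATG") == 1
      } else {
        out$classification[i] <-
          if (alt_codon %in% STOP_CODONS) {
            if (alt_codon == ref_codon) "none" else "stop_retained"
          } else "loss_of_uStop"
      }
    } else {  # uKozak
      win <- u$kozak_window[row]
      rel <- hits$kozak_rel[i]
      slot <- if (rel == 4L) 10L else rel + 7L   # window index: -6..-1 -> 1..6
      before_chars <- strsplit(win, NULL)[[1]]
      ref_tx <- if (strand == "-") complement_base(hits$ref[i]) else hits$ref[i]
      if (toupper(before_chars[slot]) != ref_tx) {
        stop(sprintf("catalog/genome disagreement in Kozak window of %s at %+d",
                     hits$tx_id[i], rel))
      }
      after_chars <- before_chars
      after_chars[slot] <- if (slot %in% c(4L, 10L)) toupper(alt_tx)
                           else tolower(alt_tx)
      strength_of <- function(chars) {
        kozak_strength_of(c(kozak_base_match(toupper(chars[4]), policy$minus3),
                            kozak_base_match(toupper(chars[10]), policy$plus4)))
      }
      out$ref_codon[i] <- ref_tx
      out$alt_codon[i] <- alt_tx
      out$classification[i] <-
        if (alt_tx == ref_tx) "none" else "kozak_alteration"
      out$kozak_before[i] <- strength_of(before_chars)
      out$kozak_after[i] <- strength_of(after_chars)
    }
  }
  out
}

fetch_blocks <- function(genome, contig, blocks, strand) {
  pieces <- vapply(seq_len(nrow(blocks)), function(i)
    genome_fetch(genome, contig, blocks[i, 1], blocks[i, 2]), character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Summarise classified effects
#'
#' Counts effects per classification and per sample, finds recurrent
#' positions (identical contig/pos/alt seen in two or more sample pairs)
#' and partitions variants into known and novel against an optional
#' known-variant catalog.  Because one variant may pair with elements of
#' several isoforms, counting is done on the genomically de-duplicated
#' roll-up: one record per (sample, contig, pos, alt), classified by the
#' highest-priority element it hits (uAUG > uStop > uKozak).
#'
#' @param effects output of [classify_effect()].
#' @param known optional data frame (`contig`, `pos`, `alt`) of known
#'   variants.
#' @return a list: `summary` (named counts over all classes), `by_sample`,
#'   `recurrent`, `n_novel`, `n_known`, `rolled` (the roll-up table).
#' @export
tabulate_effects <- function(effects, known = NULL) {
  if (nrow(effects)) {
    prio <- match(effects$element, c("uAUG", "uStop", "uKozak"))
    ord <- order(effects$sample_pair, effects$contig, effects$pos, effects$alt,
                 prio)
    eff <- effects[ord, , drop = FALSE]
    key <- paste(eff$sample_pair, eff$contig, eff$pos, eff$alt, sep = "|")
    rolled <- eff[!duplicated(key), , drop = FALSE]
  } else {
    rolled <- effects
  }
  summary <- table(factor(rolled$classification, levels = EFFECT_CLASSES))
  by_sample <- if (nrow(rolled)) {
    as.data.frame(table(sample_pair = rolled$sample_pair,
                        classification = factor(rolled$classification,
                                                levels = EFFECT_CLASSES)),
                  stringsAsFactors = FALSE)
  } else {
    empty_df(sample_pair = character(0), classification = character(0),
             Freq = integer(0))
  }
  pos_key <- paste(rolled$contig, rolled$pos, rolled$alt, sep = "|")
  rec_tab <- tapply(rolled$sample_pair, pos_key,
                    function(x) length(unique(x)))
  recurrent <- names(rec_tab)[rec_tab >= 2]
  if (!is.null(known) && nrow(rolled)) {
    kkey <- paste(known$contig, known$pos, known$alt, sep = "|")
    is_known <- pos_key %in% kkey
  } else {
    is_known <- rep(FALSE, nrow(rolled))
  }
  novel_summary <- table(factor(rolled$classification[!is_known],
                                levels = EFFECT_CLASSES))
  list(summary = setNames(as.integer(summary), names(summary)),
       novel_summary = setNames(as.integer(novel_summary), names(novel_summary)),
       by_sample = by_sample, recurrent = recurrent,
       n_known = sum(is_known), n_novel = sum(!is_known), rolled = rolled)
}
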