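# Candidate-mutation filter for MID-tagged amplicon deep-sequencing
# screens: per-site base-count thresholds, multi-allelic noise exclusion,
# known-SNP partition and coverage summaries.

#' Screen filter thresholds
#'
#' The screen calls a site when it is covered by at least `min_reads`
#' patient-specific reads (default 10, inclusive) and more than
#' `min_deviation` of reads deviate from the reference base (default 0.10,
#' strict: a deviation of exactly 10\% is not a call).  The rationale for
#' the 10\% trigger is tumor purity: a heterozygous mutation in a sample
#' containing 50\% malignant cells yields an expected 25\% read deviation.
#' Sites that trigger but spread their non-reference reads over several
#' bases (e.g. 7 reference reads and one read each of the three other
#' bases) are almost always sequencing noise; the filter codifies that
#' manual exclusion as: at least two distinct alternate bases observed and
#' the top alternate below `noise_top_alt_fraction` (default 2/3) of
#' non-reference reads.
#'
#' @param min_reads minimum total reads, inclusive.
#' @param min_deviation non-reference read fraction that must be exceeded.
#' @param noise_top_alt_fraction minimum share of non-reference reads the
#'   top alternate base must reach when several alternates are seen.
#' @return a `screen_thresholds` list.
#' @export
screen_thresholds <- function(min_reads = 10L, min_deviation = 0.10,
                              noise_top_alt_fraction = 2 / 3) {
  stopifnot(min_reads >= 1, min_deviation > 0, min_deviation < 1,
            noise_top_alt_fraction > 0, noise_top_alt_fraction <= 1)
  structure(list(min_reads = as.integer(min_reads),
                 min_deviation = min_deviation,
                 noise_top_alt_fraction = noise_top_alt_fraction),
            class = "screen_thresholds")
}

ALT_ORDER <- c("A", "C", "G", "T", "DEL")  # deterministic tie-break order

#' Apply the screen filter to base-count sites
#'
#' Every site receives exactly one status:
#' `low_coverage` (total below `min_reads`), `no_call` (deviation not above
#' `min_deviation`), `excluded_noise` (triggered, but non-reference reads
#' scattered over several bases, see [screen_thresholds()]), or
#' `candidate`.  Deletions (`DEL`) count toward the deviation and can be
#' the top alternate.  Ties between equally supported alternates break
#' deterministically in the order A, C, G, T, DEL.
#'
#' @param counts base-count data frame (see [read_base_counts()]).
#' @param thresholds a [screen_thresholds()].
#' @return `counts` with added columns `deviation`, `top_alt`,
#'   `top_alt_fraction_of_nonref`, `n_alt_bases`, `status`.
#' @export
call_sites <- function(counts, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  if (any(!counts$ref %in% BASES)) {
    stop("ref base must be one of A/C/G/T (row ",
         which(!counts$ref %in% BASES)[1], ")")
  }
  cnt <- as.matrix(counts[, ALT_ORDER])
  total <- rowSums(cnt)
  ref_n <- cnt[cbind(seq_len(nrow(cnt)), match(counts$ref, ALT_ORDER))]
  nonref <- total - ref_n
  deviation <- ifelse(total > 0, nonref / total, 0)

  alt_cnt <- cnt
  alt_cnt[cbind(seq_len(nrow(cnt)), match(counts$ref, ALT_ORDER))] <- -1L
  top_idx <- apply(alt_cnt, 1, which.max)          # first max: A<C<G<T<DEL
  top_alt <- ALT_ORDER[top_idx]
  top_n <- alt_cnt[cbind(seq_len(nrow(cnt)), top_idx)]
  top_frac <- ifelse(nonref > 0, top_n / nonref, NA_real_)
  n_alt <- rowSums(alt_cnt > 0)

  status <- rep("candidate", nrow(counts))
  noisy <- n_alt >= 2 & top_frac < thresholds$noise_top_alt_fraction
  status[noisy] <- "excluded_noise"
  status[deviation <= thresholds$min_deviation] <- "no_call"
  status[total < thresholds$min_reads] <- "low_coverage"

  counts$total <- as.integer(total)
  counts$deviation <- deviation
  counts$top_alt <- ifelse(nonref > 0, top_alt, NA_character_)
  counts$top_alt_fraction_of_nonref <- top_frac
  counts$n_alt_bases <- as.integer(n_alt)
  counts$status <- status
  counts
}

#' Call a single site
#'
#' Convenience wrapper around [call_sites()] for one site given as a named
#' count vector.
#'
#' @param ref reference base.
#' @param counts named numeric vector over `A`, `C`, `G`, `T` (and
#'   optionally `DEL`; missing bases count 0).
#' @param thresholds a [screen_thresholds()].
#' @param sample,contig,pos optional site identity.
#' @return a one-row data frame as from [call_sites()].
#' @export
call_site <- function(ref, counts, thresholds = screen_thresholds(),
                      sample = "s", contig = "c", pos = 0L) {
  full <- setNames(rep(0L, 5), ALT_ORDER)
  full[names(counts)] <- counts
  df <- data.frame(sample = sample, contig = contig, pos = pos, ref = ref,
                   A = full[["A"]], C = full[["C"]], G = full[["G"]],
                   T = full[["T"]], DEL = full[["DEL"]],
                   stringsAsFactors = FALSE)
  call_sites(df, thresholds)
}

#' Partition candidate calls into known SNPs and novel candidates
#'
#' A candidate matching the known-variant catalog on (contig, position,
#' alternate allele) is re-labelled `known_snp`; everything else is
#' unchanged.  The partition is exhaustive and disjoint.  Matching is
#' allele-aware: a different alternate at a catalogued position stays
#' novel.
#'
#' @param calls output of [call_sites()].
#' @param catalog data frame with columns `contig`, `pos` (0-based) and
#'   `alt` (use `read_vcf()` on a known-polymorphism VCF).
#' @return `calls` with `status == "known_snp"` where matched.
#' @export
partition_known <- function(calls, catalog) {
  if (nrow(calls) == 0 || is.null(catalog) || nrow(catalog) == 0) return(calls)
  key <- paste(calls$contig, calls$pos, calls$top_alt, sep = "|")
  known <- paste(catalog$contig, catalog$pos, catalog$alt, sep = "|")
  hit <- calls$status == "candidate" & key %in% known
  calls$status[hit] <- "known_snp"
  calls
}

#' Coverage summary over a screen design
#'
#' The design enumerates the expected site-by-sample grid; cells absent
#' from the count table count as zero reads.  Reports the total number of
#' cells (`|sites| x |samples|`), the fraction of cells covered by at
#' least `min_reads` reads, and the share of all reads falling on the top
#' `top_q` percent of sites (sites ranked by their total read count across
#' samples) — the standard summary of amplicon-efficiency skew.
#'
#' @param counts base-count data frame (may be empty).
#' @param design data frame with columns `site_id`, `contig`, `pos`.
#' @param samples character vector of expected sample ids.
#' @param thresholds a [screen_thresholds()].
#' @param top_q percentage of top-covered sites for the read-share statistic.
#' @return a list: `n_sites`, `n_samples`, `n_cells`, `covered_fraction`,
#'   `top_share`, `site_totals`.
#' @export
coverage_summary <- function(counts, design, samples,
                             thresholds = screen_thresholds(), top_q = 5) {
  n_sites <- nrow(design)
  n_samples <- length(samples)
  n_cells <- n_sites * n_samples
  site_key <- paste(design$contig, design$pos, sep = "|")
  if (anyDuplicated(site_key)) stop("duplicate sites in design")
  if (nrow(counts)) {
    counts <- counts[counts$sample %in% samples &
                       paste(counts$contig, counts$pos, sep = "|") %in% site_key, ,
                     drop = FALSE]
    cell_total <- rowSums(counts[, c(BASES, "DEL")])
    covered_cells <- sum(cell_total >= thresholds$min_reads)
    site_totals <- tapply(cell_total,
                          factor(paste(counts$contig, counts$pos, sep = "|"),
                                 levels = site_key),
                          sum, default = 0)
  } else {
    covered_cells <- 0L
    site_totals <- setNames(rep(0, n_sites), site_key)
  }
  total_reads <- sum(site_totals)
  n_top <- ceiling(n_sites * top_q / 100)
  top_share <- if (total_reads > 0) {
    sum(sort(site_totals, decreasing = TRUE)[seq_len(n_top)]) / total_reads
  } else NA_real_
  list(n_sites = n_sites, n_samples = n_samples, n_cells = n_cells,
       covered_fraction = if (n_cells > 0) covered_cells / n_cells else NA_real_,
       top_q = top_q, top_share = top_share,
       site_totals = setNames(as.numeric(site_totals), design$site_id))
}

#' Analytic expectations for the simulated depth model
#'
#' Under the generator's depth model (per-site Poisson rate drawn from a
#' log-normal, optional amplicon dropout), `expected_covered_fraction` is
#' the probability that a cell reaches `min_reads` reads, obtained by
#' integrating the Poisson tail over the log-normal rate;
#' `expected_top_share` is the expected share of reads on the top `q`
#' percent of sites, which for a log-normal rate distribution is
#' `pnorm(sdlog - qnorm(1 - q))`.
#'
#' @param meanlog,sdlog log-normal parameters of the per-site rate.
#' @param min_reads coverage threshold.
#' @param dropout per-cell amplicon dropout probability.
#' @return a probability.
#' @export
expected_covered_fraction <- function(meanlog, sdlog, min_reads = 10,
                                      dropout = 0) {
  f <- function(lam) {
    stats::dlnorm(lam, meanlog, sdlog) *
      stats::ppois(min_reads - 1, lam, lower.tail = FALSE)
  }
  p <- stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
  (1 - dropout) * p
}

#' @rdname expected_covered_fraction
#' @param q top fraction of sites (e.g. `0.05`).
#' @export
expected_top_share <- function(sdlog, q = 0.05) {
  stats::pnorm(sdlog - stats::qnorm(1 - q))
}
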