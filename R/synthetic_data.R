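# Seeded generators for every input the pipeline consumes: a synthetic
# genome, transcript models with planted uORFs written into the genome
# sequence, planted point variants with caller VCFs, and per-site base
# counts with configurable depth, tumor purity and sequencing-error noise.
# Every generator returns (or extends) a ground-truth manifest so each
# pipeline stage can be tested against exact expectations, and identical
# seeds reproduce byte-identical files.

resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

SENSE_CODONS <- {
  all3 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all3, STOP_CODONS)
}
# codons safe to use inside planted uORF bodies: sense, not ATG, and with a
# C/G third base so that no ATG or stop can form across codon junctions
SAFE_CODONS <- {
  ok <- SENSE_CODONS[substring(SENSE_CODONS, 3, 3) %in% c("C", "G")]
  setdiff(ok, "ATG")
}

#' Generate a random genome
#'
#' Contig sequences are i.i.d. draws over A/C/G/T at the requested GC
#' content; with contigs of at least a few kilobases the realised GC is
#' within a binomial error of the request.  Identical seeds give identical
#' sequences.
#'
#' @param seed integer seed.
#' @param n_contigs number of contigs.
#' @param lengths contig lengths (recycled to `n_contigs`); at least 1000.
#' @param gc target GC fraction.
#' @return a [genome_sequence()] with contigs `ctg01`, `ctg02`, ...
#' @export
make_genome <- function(seed, n_contigs = 2, lengths = 120000, gc = 0.45) {
  stopifnot(all(lengths >= 1000), gc > 0, gc < 1)
  lengths <- rep_len(lengths, n_contigs)
  set.seed(child_seed(seed, "make_genome"))
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  contigs <- vapply(seq_len(n_contigs), function(i)
    paste(sample(BASES, lengths[i], replace = TRUE, prob = prob), collapse = ""),
    character(1))
  names(contigs) <- sprintf("ctg%02d", seq_len(n_contigs))
  genome_sequence(contigs)
}

## ---- transcript generation ----------------------------------------------

# one planted uORF element spec; body lengths in codons
plan_uorf_block <- function(kind, kozak_class, body_range = 1:5) {
  list(kind = kind, kozak_class = kozak_class,
       body1 = resample(body_range), body2 = resample(1:3),
       stop_codon = resample(STOP_CODONS))
}

# assemble the planted block string and per-block uAUG/uStop offsets
build_block <- function(plan) {
  first_codon <- function(match_plus4) {
    pool <- if (match_plus4) SAFE_CODONS[startsWith(SAFE_CODONS, "G")]
            else SAFE_CODONS[substring(SAFE_CODONS, 1, 1) %in% c("C", "T")]
    resample(pool)
  }
  body <- function(n, match_plus4) {
    if (n == 0) return(character(0))
    c(first_codon(match_plus4), if (n > 1) resample(SAFE_CODONS, n - 1, replace = TRUE))
  }
  plus4_match <- switch(plan$kozak_class, strong = TRUE, intermediate = NA,
                        weak = FALSE)
  minus3_match <- switch(plan$kozak_class, strong = TRUE, weak = FALSE,
                         intermediate = NA)
  if (plan$kozak_class == "intermediate") {
    # exactly one core match; which one is random
    plus4_match <- runif(1) < 0.5
    minus3_match <- !plus4_match
  }
  if (plan$kind == "overlap") {
    # uAUG abuts the CDS: +4 is the first CDS base (A of the main ATG),
    # which matches the purine rule, so only the -3 base is free
    return(list(seq = "ATG", uaugs = 0L, ustop = NA_integer_,
                minus3_match = minus3_match))
  }
  if (plan$kind == "shared") {
    b1 <- body(plan$body1, plus4_match)
    # the second uAUG's -3 base is the third base of the preceding codon;
    # its +4 base is the first base of body2 — both left to chance here
    b2 <- body(plan$body2, runif(1) < 0.5)
    seq <- paste0("ATG", paste(b1, collapse = ""), "ATG",
                  paste(b2, collapse = ""), plan$stop_codon)
    uaugs <- c(0L, 3L + 3L * plan$body1)
    ustop <- 3L + 3L * plan$body1 + 3L + 3L * plan$body2
    return(list(seq = seq, uaugs = uaugs, ustop = ustop,
                minus3_match = minus3_match))
  }
  b1 <- body(plan$body1, plus4_match)
  seq <- paste0("ATG", paste(b1, collapse = ""), plan$stop_codon)
  list(seq = seq, uaugs = 0L, ustop = 3L + 3L * plan$body1,
       minus3_match = minus3_match)
}

scrub_atg <- function(ch, intended0, protected) {
  for (iter in 1:50) {
    s <- paste(ch, collapse = "")
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    hits <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
    bad <- setdiff(hits, intended0)
    if (!length(bad)) return(ch)
    for (b in bad) {
      done <- FALSE
      for (j in c(3L, 2L, 1L)) {
        idx <- b + j
        if (!protected[idx]) { ch[idx] <- "C"; done <- TRUE; break }
      }
      if (!done) stop("cannot scrub unplanted ATG at protected position ", b)
    }
  }
  stop("ATG scrub did not converge")
}

#' Generate transcript models with planted uORFs
#'
#' Builds `n` transcripts (a configurable fraction non-coding decoys),
#' writes their sequence into the genome, and returns the updated genome,
#' a `transcript_models` table and a ground-truth manifest of every
#' planted uORF.  Supported plants: plain uORFs, in-frame uAUG pairs
#' sharing one termination codon, CDS-overlapping uORFs (uAUG abutting the
#' CDS with no in-TLS stop), minus-strand transcripts, and uAUG codons
#' split by an intron.  Leader sequences are scrubbed so they contain no
#' ATG other than the planted ones, making the manifest an exact oracle
#' for discovery.  uORF prevalence among the remaining coding transcripts
#' defaults to 0.55, the approximate fraction of human transcript leaders
#' carrying at least one AUG-initiated uORF.
#'
#' @param genome a [genome_sequence()] (will be modified and returned).
#' @param seed integer seed.
#' @param n number of transcripts.
#' @param p_noncoding fraction of non-coding decoy transcripts.
#' @param p_uorf probability that an ordinary coding transcript carries
#'   uORFs at all.
#' @param max_uorfs maximum plain uORFs per transcript.
#' @param n_shared_stop_pairs transcripts carrying an in-frame uAUG pair
#'   sharing one stop.
#' @param n_cds_overlap transcripts carrying a CDS-overlapping uORF.
#' @param n_intron_split transcripts whose (first) planted uAUG codon is
#'   split by an intron.
#' @param tls_len_range,exon_count_range,intron_len_range,cds_codon_range,utr3_len_range
#'   structural ranges (nt, counts, nt, codons, nt).
#' @param p_minus fraction of minus-strand transcripts.
#' @param kozak_mix sampling weights for requested Kozak classes
#'   (strong/intermediate/weak).
#' @return a list: `genome`, `models`, `manifest`.
#' @export
make_transcripts <- function(genome, seed, n = 50, p_noncoding = 0.2,
                             p_uorf = 0.55, max_uorfs = 3,
                             n_shared_stop_pairs = 2, n_cds_overlap = 2,
                             n_intron_split = 2,
                             tls_len_range = c(50, 500),
                             exon_count_range = c(1, 4),
                             intron_len_range = c(60, 200),
                             cds_codon_range = c(30, 80),
                             utr3_len_range = c(20, 100),
                             p_minus = 0.5,
                             kozak_mix = c(strong = 0.25, intermediate = 0.4,
                                           weak = 0.35)) {
  set.seed(child_seed(seed, "make_transcripts"))
  n_nc <- round(p_noncoding * n)
  n_cod <- n - n_nc
  if (n_cod < n_shared_stop_pairs + n_cds_overlap + n_intron_split) {
    stop("not enough coding transcripts for the requested special plants")
  }
  coding_idx <- sort(resample(seq_len(n), n_cod))
  special <- rep("plain", n)
  sp <- coding_idx
  take <- function(k) { out <- sp[seq_len(k)]; sp <<- sp[-seq_len(k)]; out }
  if (n_shared_stop_pairs > 0) special[take(n_shared_stop_pairs)] <- "shared"
  if (n_cds_overlap > 0) special[take(n_cds_overlap)] <- "overlap"
  if (n_intron_split > 0) special[take(n_intron_split)] <- "intron_split"

  gc_bg <- c(0.275, 0.225, 0.225, 0.275)
  rand_bases <- function(k) sample(BASES, k, replace = TRUE, prob = gc_bg)
  cursors <- setNames(rep(50L, length(genome)), names(genome))
  lens <- contig_lengths(genome)
  contigs_chr <- unclass(genome)

  models_rows <- list()
  uorf_rows <- list()
  tx_rows <- list()

  for (i in seq_len(n)) {
    tx_id <- sprintf("TX%03d", i)
    gene <- sprintf("GENE%03d", i)
    is_coding <- i %in% coding_idx
    strand <- if (runif(1) < p_minus) "-" else "+"
    tls_len <- resample(seq(tls_len_range[1], tls_len_range[2]))

    # --- plan planted uORFs for this transcript
    plans <- list()
    if (is_coding) {
      kind <- special[i]
      if (kind == "shared") {
        plans <- list(plan_uorf_block("shared", resample(names(kozak_mix),
                                                         prob = kozak_mix)))
      } else if (kind == "overlap") {
        plans <- list(plan_uorf_block("overlap", resample(names(kozak_mix),
                                                          prob = kozak_mix)))
      } else if (kind == "intron_split" || runif(1) < p_uorf) {
        k <- resample(seq_len(max_uorfs))
        plans <- lapply(seq_len(k), function(j)
          plan_uorf_block("plain", resample(names(kozak_mix), prob = kozak_mix)))
      }
    }
    blocks <- lapply(plans, build_block)

    # --- lay blocks out in the TLS (overlap block pinned to the 3' end)
    min_len <- 6L
    for (b in blocks) min_len <- min_len + nchar(b$seq) + 12L
    tls_len <- max(tls_len, min_len + 6L)
    tls <- rand_bases(tls_len)
    protected <- rep(FALSE, tls_len)
    intended0 <- integer(0)
    cursor <- 6L + resample(0:6)
    placed <- list()
    for (j in seq_along(blocks)) {
      b <- blocks[[j]]
      w <- nchar(b$seq)
      if (plans[[j]]$kind == "overlap") {
        off <- tls_len - w            # uAUG abuts the CDS
      } else {
        off <- cursor
        cursor <- cursor + w + 6L + resample(0:6)
      }
      tls[(off + 1):(off + w)] <- strsplit(b$seq, NULL)[[1]]
      protected[(off + 1):(off + w)] <- TRUE
      # pin the -3 base to the requested core match (purine rule)
      m3pos <- off - 3L
      if (m3pos >= 0 && !is.na(b$minus3_match)) {
        tls[m3pos + 1] <- if (b$minus3_match) resample(c("A", "G"))
                          else resample(c("C", "T"))
        protected[m3pos + 1] <- TRUE
      }
      placed[[j]] <- list(off = off, block = b)
      intended0 <- c(intended0, off + b$uaugs)
    }
    if (is_coding) tls <- scrub_atg(tls, intended0, protected)

    # --- CDS and 3' UTR
    if (is_coding) {
      n_cod_cds <- resample(seq(cds_codon_range[1], cds_codon_range[2]))
      cds <- paste0("ATG", paste(resample(SENSE_CODONS, n_cod_cds, replace = TRUE),
                                 collapse = ""), resample(STOP_CODONS))
    } else {
      cds <- ""
    }
    utr3 <- paste(rand_bases(resample(seq(utr3_len_range[1], utr3_len_range[2]))),
                  collapse = "")
    spliced <- paste0(paste(tls, collapse = ""), cds, utr3)
    Tsp <- nchar(spliced)
    cds_sp <- c(tls_len, tls_len + nchar(cds))   # spliced half-open CDS

    # --- exon structure (transcript orientation)
    n_ex <- resample(seq(exon_count_range[1], exon_count_range[2]))
    forced_cut <- integer(0)
    if (is_coding && special[i] == "intron_split" && length(placed)) {
      n_ex <- max(n_ex, 2L)
      forced_cut <- placed[[1]]$off + resample(1:2)  # split the uAUG codon
    }
    cuts <- integer(0)
    if (n_ex > 1) {
      pool <- setdiff(seq_len(Tsp - 1L), forced_cut)
      cuts <- sort(c(forced_cut, resample(pool, n_ex - 1L - length(forced_cut))))
    }
    bounds <- c(0L, cuts, Tsp)
    exon_lens <- diff(bounds)
    intron_lens <- if (n_ex > 1) {
      resample(seq(intron_len_range[1], intron_len_range[2]), n_ex - 1L,
               replace = TRUE)
    } else integer(0)
    splice_starts <- cumsum(c(0L, exon_lens))[seq_len(n_ex)]
    geno_starts <- cumsum(c(0L, exon_lens[-n_ex] + intron_lens))
    Tgen <- sum(exon_lens) + sum(intron_lens)
    t_of <- function(s) {                       # spliced -> tx-oriented genomic
      e <- findInterval(s, splice_starts)
      geno_starts[e] + (s - splice_starts[e])
    }

    # --- transcript-oriented genomic sequence, then plus strand
    segs <- character(2 * n_ex - 1)
    for (e in seq_len(n_ex)) {
      segs[2 * e - 1] <- substring(spliced, splice_starts[e] + 1,
                                   splice_starts[e] + exon_lens[e])
      if (e < n_ex) segs[2 * e] <- paste(rand_bases(intron_lens[e]), collapse = "")
    }
    gt <- paste(segs, collapse = "")
    plus_seq <- if (strand == "+") gt else revcomp(gt)

    # --- place on a contig
    placed_contig <- NA_character_
    for (nm in names(cursors)) {
      if (cursors[[nm]] + Tgen + 50L <= lens[[nm]]) { placed_contig <- nm; break }
    }
    if (is.na(placed_contig)) stop("genome too small for transcript ", tx_id)
    tx_start <- cursors[[placed_contig]]
    substr(contigs_chr[[placed_contig]], tx_start + 1, tx_start + Tgen) <- plus_seq
    cursors[[placed_contig]] <- tx_start + Tgen + 50L + resample(50:250)
    tx_end <- tx_start + Tgen

    g_of <- function(s) {                       # spliced -> plus-strand genomic
      if (strand == "+") tx_start + t_of(s) else tx_start + (Tgen - 1L - t_of(s))
    }
    # exon list in plus coordinates, ascending
    ex_plus <- t(vapply(seq_len(n_ex), function(e) {
      a <- geno_starts[e]; b <- geno_starts[e] + exon_lens[e]
      if (strand == "+") c(tx_start + a, tx_start + b)
      else c(tx_start + Tgen - b, tx_start + Tgen - a)
    }, integer(2)))
    ord <- order(ex_plus[, 1])
    ex_plus <- ex_plus[ord, , drop = FALSE]
    if (is_coding) {
      if (strand == "+") {
        cds_start_g <- g_of(cds_sp[1]); cds_end_g <- g_of(cds_sp[2] - 1L) + 1L
      } else {
        cds_start_g <- g_of(cds_sp[2] - 1L); cds_end_g <- g_of(cds_sp[1]) + 1L
      }
    } else {
      cds_start_g <- tx_end; cds_end_g <- tx_end
    }
    models_rows[[i]] <- list(tx_id = tx_id, gene = gene, contig = placed_contig,
                             strand = strand, tx_start = tx_start, tx_end = tx_end,
                             cds_start = cds_start_g, cds_end = cds_end_g,
                             exon_count = n_ex,
                             exon_starts = ex_plus[, 1], exon_ends = ex_plus[, 2])

    # --- manifest entries for planted uORFs (coordinates computed from the
    #     generator's own layout, independently of the discovery pipeline)
    if (is_coding && length(placed)) {
      cds_first <- "A"                          # CDS starts with ATG
      tls_chr <- tls
      kz_of <- function(o) {
        m3 <- if (o - 3 >= 0) tls_chr[o - 2] else "."
        p4 <- if (o + 3 < tls_len) tls_chr[o + 4] else cds_first
        m <- c(kozak_base_match(m3, "purine"), kozak_base_match(p4, "purine"))
        kozak_strength_of(m)
      }
      for (p in placed) {
        b <- p$block
        for (uu in seq_along(b$uaugs)) {
          o <- p$off + b$uaugs[uu]
          so <- if (is.na(b$ustop)) NA_integer_ else p$off + b$ustop
          kg <- vapply(c(-6:-1, 4L), function(r) {
            idx <- o + ifelse(r == 4L, 3L, r)
            if (idx < 0) NA_integer_ else g_of(idx)
          }, integer(1))
          uorf_rows[[length(uorf_rows) + 1L]] <- list(
            tx_id = tx_id, gene = gene, contig = placed_contig, strand = strand,
            uaug_offset = o, ustop_offset = so,
            cds_overlapping = is.na(b$ustop),
            length_nt = if (is.na(so)) NA_integer_ else so + 3L - o,
            ustop_codon = if (is.na(so)) NA_character_
                          else substring(paste(tls_chr, collapse = ""), so + 1, so + 3),
            kozak_strength = kz_of(o),
            shared_stop_group = if (is.na(so)) NA_character_
                                else paste0(tx_id, ":stop", so),
            uaug_gpos = vapply(o:(o + 2L), g_of, integer(1)),
            ustop_gpos = if (is.na(so)) integer(0)
                         else vapply(so:(so + 2L), g_of, integer(1)),
            kozak_gpos = kg)
        }
      }
      # construction check: the leader must contain exactly the planted uORFs
      check_planted_leader(paste(tls_chr, collapse = ""),
                           vapply(uorf_rows[vapply(uorf_rows, function(r)
                             r$tx_id == tx_id, logical(1))],
                             `[[`, integer(1), "uaug_offset"), tx_id)
    }
    tx_rows[[i]] <- list(tx_id = tx_id, contig = placed_contig, strand = strand,
                         coding = is_coding, special = special[i],
                         tls_len = tls_len,
                         n_uorfs = if (is_coding && length(placed))
                           sum(vapply(blocks, function(b) length(b$uaugs),
                                      integer(1))) else 0L)
  }

  models <- do.call(rbind, lapply(models_rows, function(r) {
    data.frame(r[setdiff(names(r), c("exon_starts", "exon_ends"))],
               stringsAsFactors = FALSE)
  }))
  models$exon_starts <- lapply(models_rows, `[[`, "exon_starts")
  models$exon_ends <- lapply(models_rows, `[[`, "exon_ends")
  models$coding <- models$cds_start < models$cds_end
  class(models) <- c("transcript_models", class(models))

  uorfs <- if (length(uorf_rows)) {
    df <- do.call(rbind, lapply(uorf_rows, function(r)
      data.frame(r[setdiff(names(r), c("uaug_gpos", "ustop_gpos", "kozak_gpos"))],
                 stringsAsFactors = FALSE)))
    df$uaug_gpos <- lapply(uorf_rows, `[[`, "uaug_gpos")
    df$ustop_gpos <- lapply(uorf_rows, `[[`, "ustop_gpos")
    df$kozak_gpos <- lapply(uorf_rows, `[[`, "kozak_gpos")
    df
  } else NULL

  genome_out <- genome_sequence(contigs_chr)
  manifest <- list(seed = seed,
                   params = list(n = n, p_noncoding = p_noncoding,
                                 p_uorf = p_uorf,
                                 n_shared_stop_pairs = n_shared_stop_pairs,
                                 n_cds_overlap = n_cds_overlap,
                                 n_intron_split = n_intron_split),
                   transcripts = do.call(rbind, lapply(tx_rows, function(r)
                     data.frame(r, stringsAsFactors = FALSE))),
                   uorfs = uorfs)
  list(genome = genome_out, models = models, manifest = manifest)
}

# a generator-side sanity check that the assembled leader contains exactly
# the planted uAUGs (scrubbing and block layout must agree)
check_planted_leader <- function(tls, planted0, tx_id) {
  hits <- gregexpr("ATG", tls, fixed = TRUE)[[1]]
  hits <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  if (!setequal(hits, planted0)) {
    stop("generator inconsistency in ", tx_id, ": leader ATGs ",
         paste(hits, collapse = ","), " vs planted ",
         paste(planted0, collapse = ","))
  }
  invisible(TRUE)
}

## ---- variant planting ----------------------------------------------------

#' Plant point variants on the uORF truth set
#'
#' Chooses host uORFs from the manifest (without replacement, one variant
#' per host element) and emits plus-strand SNVs: start-loss variants
#' substitute one base of a uAUG (any single-base change destroys the ATG
#' and always yields a near-cognate codon), stop-loss variants are drawn
#' from the sense substitutions of a uStop, stop-retained decoys from the
#' stop-to-stop substitutions, Kozak variants hit a window position that
#' does not collide with any codon, known-SNP plants mirror start-loss
#' variants but are returned separately as a polymorphism catalog, and
#' background variants avoid every catalog position.  Each variant is
#' assigned its own sample pair (the screen's non-recurrent situation).
#'
#' @param sim result of [make_transcripts()].
#' @param seed integer seed.
#' @param n_start_loss,n_stop_loss,n_kozak,n_stop_retained,n_background,n_known_snp
#'   variant counts.
#' @return a list: `variants` (plus-strand variant table with `element`
#'   and `intended_class`), `known` (the known-SNP catalog subset),
#'   `samples`, and `manifest` (input manifest extended with the plants).
#' @export
plant_variants <- function(sim, seed, n_start_loss = 22, n_stop_loss = 31,
                           n_kozak = 0, n_stop_retained = 0,
                           n_background = 0, n_known_snp = 0) {
  set.seed(child_seed(seed, "plant_variants"))
  u <- sim$manifest$uorfs
  genome <- sim$genome
  if (is.null(u)) stop("no planted uORFs available to host variants")

  codon_keys <- unique(unlist(lapply(seq_len(nrow(u)), function(i)
    paste(u$contig[i], c(u$uaug_gpos[[i]], u$ustop_gpos[[i]])))))
  elem_keys <- unique(c(codon_keys, unlist(lapply(seq_len(nrow(u)), function(i) {
    kg <- u$kozak_gpos[[i]]
    paste(u$contig[i], kg[!is.na(kg)])
  }))))

  start_hosts_all <- seq_len(nrow(u))
  stop_hosts_all <- which(!u$cds_overlapping)
  if (length(start_hosts_all) < n_start_loss + n_known_snp) {
    stop("not enough uAUG hosts: need ", n_start_loss + n_known_snp,
         ", have ", length(start_hosts_all))
  }
  if (length(stop_hosts_all) < n_stop_loss + n_stop_retained) {
    stop("not enough uStop hosts: need ", n_stop_loss + n_stop_retained,
         ", have ", length(stop_hosts_all))
  }
  picked_start <- resample(start_hosts_all, n_start_loss + n_known_snp)
  picked_stop <- resample(stop_hosts_all, n_stop_loss + n_stop_retained)
  kozak_hosts_all <- setdiff(seq_len(nrow(u)), integer(0))
  rows <- list()

  add_row <- function(contig, gpos, ref_plus, alt_plus, tx_id, element,
                      intended, detail = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, pos = gpos, ref = ref_plus, alt = alt_plus,
      tx_id = tx_id, element = element, intended_class = intended,
      detail = detail, stringsAsFactors = FALSE)
  }
  tx_to_plus <- function(base, strand) if (strand == "-") complement_base(base) else base

  codon_variant <- function(idx, element, alt_filter, intended) {
    r <- u[idx, ]
    codon <- if (element == "uAUG") "ATG" else r$ustop_codon
    gpos_vec <- if (element == "uAUG") r$uaug_gpos[[1]] else r$ustop_gpos[[1]]
    cand <- list()
    for (p in 1:3) {
      refb <- substring(codon, p, p)
      for (b in setdiff(BASES, refb)) {
        alt_codon <- codon
        substring(alt_codon, p, p) <- b
        if (alt_filter(alt_codon)) cand[[length(cand) + 1L]] <- c(p, b)
      }
    }
    pick <- cand[[resample(seq_along(cand))]]
    p <- as.integer(pick[1]); tx_alt <- pick[2]
    gpos <- gpos_vec[p]
    ref_plus <- genome_base(genome, r$contig, gpos)
    stopifnot(ref_plus == tx_to_plus(substring(codon, p, p), r$strand))
    add_row(r$contig, gpos, ref_plus, tx_to_plus(tx_alt, r$strand),
            r$tx_id, element, intended, p)
  }

  for (idx in picked_start[seq_len(n_start_loss)]) {
    codon_variant(idx, "uAUG", function(ac) ac != "ATG", "loss_of_uAUG")
  }
  known_idx <- if (n_known_snp > 0)
    picked_start[n_start_loss + seq_len(n_known_snp)] else integer(0)
  for (idx in known_idx) {
    codon_variant(idx, "uAUG", function(ac) ac != "ATG", "known_snp")
  }
  for (idx in picked_stop[seq_len(n_stop_loss)]) {
    codon_variant(idx, "uStop", function(ac) !ac %in% STOP_CODONS,
                  "loss_of_uStop")
  }
  retained_idx <- if (n_stop_retained > 0)
    picked_stop[n_stop_loss + seq_len(n_stop_retained)] else integer(0)
  for (idx in retained_idx) {
    r <- u[idx, ]
    ok <- vapply(STOP_CODONS, function(sc)
      sc != r$ustop_codon && hamming(sc, r$ustop_codon) == 1, logical(1))
    if (!any(ok)) next  # codon with no single-base stop neighbour
    codon_variant(idx, "uStop",
                  function(ac) ac %in% STOP_CODONS && ac != r$ustop_codon,
                  "stop_retained")
  }
  if (n_kozak > 0) {
    hosts <- setdiff(kozak_hosts_all, c(picked_start, picked_stop))
    chosen <- 0L
    for (idx in resample(hosts, length(hosts))) {
      if (chosen >= n_kozak) break
      r <- u[idx, ]
      kg <- r$kozak_gpos[[1]]
      rel <- c(-6:-1, 4L)
      usable <- which(!is.na(kg) & !(paste(r$contig, kg) %in% codon_keys))
      if (!length(usable)) next
      k <- resample(usable)
      gpos <- kg[k]
      ref_plus <- genome_base(genome, r$contig, gpos)
      alt_plus <- resample(setdiff(BASES, ref_plus))
      add_row(r$contig, gpos, ref_plus, alt_plus, r$tx_id, "uKozak",
              "kozak_alteration", rel[k])
      chosen <- chosen + 1L
    }
    if (chosen < n_kozak) stop("could not place ", n_kozak, " Kozak variants")
  }
  if (n_background > 0) {
    lens <- contig_lengths(genome)
    placed <- 0L
    guard <- 0L
    bg_pos <- character(0)
    while (placed < n_background && guard < 50 * n_background) {
      guard <- guard + 1L
      ctg <- resample(names(lens))
      gpos <- resample(seq_len(lens[[ctg]]) - 1L)
      key <- paste(ctg, gpos)
      if (key %in% elem_keys) next
      if (any(vapply(rows, function(r) r$contig == ctg && r$pos == gpos,
                     logical(1)))) next
      if (key %in% bg_pos) next
      ref_plus <- genome_base(genome, ctg, gpos)
      if (ref_plus == "N") next
      add_row(ctg, gpos, ref_plus, resample(setdiff(BASES, ref_plus)),
              NA_character_, "background", "none")
      bg_pos <- c(bg_pos, key)
      placed <- placed + 1L
    }
    if (placed < n_background) stop("could not place background variants")
  }
  variants <- do.call(rbind, rows)
  variants$sample_pair <- sprintf("S%03d", seq_len(nrow(variants)))
  variants$complex <- FALSE
  known <- variants[variants$intended_class == "known_snp", , drop = FALSE]
  manifest <- sim$manifest
  manifest$variants <- variants
  list(variants = variants, known = known,
       samples = variants$sample_pair, manifest = manifest)
}

## ---- pseudo-caller VCFs --------------------------------------------------

#' Emit per-caller VCFs with configurable sensitivity
#'
#' Each planted variant is included in each pseudo-caller's VCF by an
#' independent seeded Bernoulli draw at that caller's sensitivity; false
#' positives are drawn outside the truth set.  With all sensitivities 1
#' and no false positives, the all-caller consensus equals the truth set.
#'
#' @param variants variant table from [plant_variants()].
#' @param genome the [genome_sequence()] (for false-positive ref alleles).
#' @param seed integer seed.
#' @param sensitivities named numeric vector in (0, 1], one per caller.
#' @param n_fp false positives per caller.
#' @param dir output directory (created); one `caller_<name>.vcf` each.
#' @return named list of per-caller variant data frames (with `caller_id`).
#' @export
emit_caller_vcfs <- function(variants, genome, seed,
                             sensitivities = c(sniper = 1, varscan = 1,
                                               mutect = 1, muse = 1),
                             n_fp = 0, dir = NULL) {
  stopifnot(!is.null(names(sensitivities)),
            all(sensitivities > 0), all(sensitivities <= 1))
  set.seed(child_seed(seed, "emit_caller_vcfs"))
  truth_key <- paste(variants$contig, variants$pos)
  lens <- contig_lengths(genome)
  out <- list()
  for (cid in names(sensitivities)) {
    keep <- runif(nrow(variants)) <= sensitivities[[cid]]
    df <- variants[keep, c("contig", "pos", "ref", "alt", "sample_pair"),
                   drop = FALSE]
    if (n_fp > 0) {
      fp <- 0L
      while (fp < n_fp) {
        ctg <- resample(names(lens))
        gpos <- resample(seq_len(lens[[ctg]]) - 1L)
        if (paste(ctg, gpos) %in% truth_key) next
        refb <- genome_base(genome, ctg, gpos)
        if (refb == "N") next
        df <- rbind(df, data.frame(
          contig = ctg, pos = gpos, ref = refb,
          alt = resample(setdiff(BASES, refb)),
          sample_pair = resample(unique(variants$sample_pair)),
          stringsAsFactors = FALSE))
        fp <- fp + 1L
      }
    }
    df <- df[order(df$contig, df$pos, df$alt), , drop = FALSE]
    df$caller_id <- rep(cid, nrow(df))
    df$complex <- nchar(df$ref) != 1 | nchar(df$alt) != 1
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_vcf(df, file.path(dir, paste0("caller_", cid, ".vcf")),
                genome = genome)
    }
    out[[cid]] <- df
  }
  out
}

## ---- base-count simulation ----------------------------------------------

#' Build the screen's site design from a truth manifest
#'
#' One design site per genomic base of every planted uAUG codon plus,
#' optionally, the Kozak window positions — the positions an
#' amplicon-based screen of uORF initiation sites interrogates.
#'
#' @param manifest manifest from [make_transcripts()] / [plant_variants()].
#' @param genome the matching [genome_sequence()].
#' @param kozak_window include Kozak window positions?
#' @return a design data frame: `site_id`, `contig`, `pos`, `ref`.
#' @export
make_screen_design <- function(manifest, genome, kozak_window = TRUE) {
  u <- manifest$uorfs
  rows <- list()
  for (i in seq_len(nrow(u))) {
    g <- u$uaug_gpos[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sprintf("%s|uaug|%d", u$tx_id[i], seq_along(g)),
      contig = u$contig[i], pos = g, stringsAsFactors = FALSE)
    if (kozak_window) {
      kg <- u$kozak_gpos[[i]]
      ok <- !is.na(kg)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("%s|kozak|%d", u$tx_id[i], which(ok)),
        contig = u$contig[i], pos = kg[ok], stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, rows)
  design <- design[!duplicated(paste(design$contig, design$pos)), , drop = FALSE]
  design$ref <- vapply(seq_len(nrow(design)), function(i)
    genome_base(genome, design$contig[i], design$pos[i]), character(1))
  design
}

#' Simulate per-site base counts for a screen
#'
#' Per-site sequencing rates are drawn log-normal (`meanlog`, `sdlog`) to
#' reproduce the strong amplicon-efficiency skew of pooled PCR screens;
#' each site-by-sample cell draws a Poisson depth at its site's rate
#' (clamped below at `min_depth` if requested, zeroed with probability
#' `dropout`).  At a planted heterozygous variant cell the alternate
#' allele count is binomial with success probability
#' `purity/2 * (1 - e) + e/3`: a fully heterozygous clone at tumor purity
#' 0.5 gives an expected read deviation of 0.25.  All other base calls are
#' uniform sequencing errors at rate `e`.
#'
#' @param design design table from [make_screen_design()].
#' @param samples character vector of sample ids.
#' @param variants optional plus-strand variant table (`sample_pair`,
#'   `contig`, `pos`, `alt`); only single-base alternates are simulated.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal depth parameters (defaults mirror a
#'   median per-cell coverage of about 103 with heavy skew).
#' @param purity tumor cell fraction in (0, 1].
#' @param error_rate per-base sequencing error rate.
#' @param min_depth lower clamp on simulated depth.
#' @param dropout per-cell amplicon dropout probability.
#' @return a base-count data frame (internal 0-based `pos`).
#' @export
simulate_base_counts <- function(design, samples, variants = NULL, seed = 1,
                                 meanlog = log(103), sdlog = 1.5,
                                 purity = 0.5, error_rate = 0.005,
                                 min_depth = 0, dropout = 0) {
  stopifnot(purity > 0, purity <= 1, error_rate >= 0, error_rate < 1)
  set.seed(child_seed(seed, "simulate_base_counts"))
  ns <- nrow(design)
  lambda <- stats::rlnorm(ns, meanlog, sdlog)
  grid <- design[rep(seq_len(ns), times = length(samples)), , drop = FALSE]
  grid$sample <- rep(samples, each = ns)
  depth <- stats::rpois(nrow(grid), rep(lambda, times = length(samples)))
  depth <- pmax(depth, min_depth)
  if (dropout > 0) depth[runif(length(depth)) < dropout] <- 0L

  e3 <- error_rate / 3
  cnt <- matrix(0L, nrow(grid), 5, dimnames = list(NULL, ALT_ORDER))
  vkey <- if (!is.null(variants) && nrow(variants)) {
    snv <- variants[variants$alt %in% BASES & variants$ref %in% BASES, ,
                    drop = FALSE]
    setNames(snv$alt, paste(snv$sample_pair, snv$contig, snv$pos, sep = "|"))
  } else character(0)
  gkey <- paste(grid$sample, grid$contig, grid$pos, sep = "|")
  valt <- unname(vkey[gkey])
  is_var <- !is.na(valt)

  q_alt <- purity / 2 * (1 - error_rate) + e3
  alt_n <- integer(nrow(grid))
  alt_n[is_var] <- stats::rbinom(sum(is_var), depth[is_var], q_alt)
  for (b in BASES) {
    err_rows <- which(grid$ref != b & (!is_var | valt != b))
    cnt[err_rows, b] <- stats::rbinom(length(err_rows), depth[err_rows], e3)
  }
  cnt[cbind(which(is_var), match(valt[is_var], ALT_ORDER))] <- alt_n[is_var]
  used <- rowSums(cnt)
  ref_col <- match(grid$ref, ALT_ORDER)
  cnt[cbind(seq_len(nrow(grid)), ref_col)] <- pmax(depth - used, 0L)
  storage.mode(cnt) <- "integer"
  out <- data.frame(sample = grid$sample, contig = grid$contig, pos = grid$pos,
                    ref = grid$ref, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cnt))
  out$total <- as.integer(rowSums(cnt))
  rownames(out) <- NULL
  out
}

## ---- manifest I/O and one-call orchestration ------------------------------

#' Write / read a ground-truth manifest as JSON
#' @param manifest manifest list.
#' @param path JSON path.
#' @return `read_manifest`: the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
}

#' Generate a full synthetic study and write every input file
#'
#' One-call orchestration used by the command line: genome, transcript
#' table, planted variants, per-caller VCFs, known-SNP catalog, screen
#' design, base counts and the truth manifest, all under `out_dir`.
#' Identical seeds reproduce identical bytes.
#'
#' @param seed integer seed; fans out per stage via [child_seed()].
#' @param out_dir output directory.
#' @param n_transcripts,n_start_loss,n_stop_loss,n_kozak,n_background,n_known_snp
#'   headline generator parameters; everything else uses the generator
#'   defaults.
#' @param sensitivities per-caller sensitivities for [emit_caller_vcfs()].
#' @param ... passed to [make_transcripts()].
#' @return invisibly, a list with all in-memory objects and file paths.
#' @export
simulate_study <- function(seed, out_dir, n_transcripts = 50,
                           n_start_loss = 22, n_stop_loss = 31, n_kozak = 5,
                           n_background = 20, n_known_snp = 3,
                           sensitivities = c(sniper = 1, varscan = 1,
                                             mutect = 1, muse = 1), ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  genome0 <- make_genome(seed)
  sim <- make_transcripts(genome0, seed, n = n_transcripts, ...)
  pv <- plant_variants(sim, seed, n_start_loss = n_start_loss,
                       n_stop_loss = n_stop_loss, n_kozak = n_kozak,
                       n_background = n_background, n_known_snp = n_known_snp)
  callers <- emit_caller_vcfs(pv$variants, sim$genome, seed,
                              sensitivities = sensitivities, dir = out_dir)
  design <- make_screen_design(pv$manifest, sim$genome)
  counts <- simulate_base_counts(design, pv$samples, pv$variants, seed)
  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    refgene = file.path(out_dir, "refgene.txt"),
    truth = file.path(out_dir, "truth.json"),
    variants = file.path(out_dir, "variants.vcf"),
    known = file.path(out_dir, "known_snps.vcf"),
    design = file.path(out_dir, "design.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    samples = file.path(out_dir, "samples.txt"))
  write_genome_fasta(sim$genome, paths$fasta)
  write_refgene(sim$models, paths$refgene)
  write_manifest(pv$manifest, paths$truth)
  write_vcf(pv$variants, paths$variants, genome = sim$genome)
  write_vcf(pv$known, paths$known, genome = sim$genome)
  write_tsv_header(design, paths$design, params = list(seed = seed))
  write_base_counts(counts, paths$counts, params = list(seed = seed))
  writeLines(pv$samples, paths$samples)
  invisible(list(genome = sim$genome, models = sim$models,
                 manifest = pv$manifest, variants = pv$variants,
                 known = pv$known, callers = callers, design = design,
                 counts = counts, samples = pv$samples, paths = paths))
}
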