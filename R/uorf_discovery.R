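# uORF discovery: per coding transcript, extract the spliced transcript
# leader sequence (TLS), scan it for uAUG codons and the closest in-frame
# uStop (TAA/TAG/TGA), classify the Kozak context of every uAUG, and
# project all elements back to genomic coordinates through the splice-aware
# coordinate map.

#' Kozak match policy
#'
#' Only the two core Kozak positions are scored: -3 (three bases upstream
#' of the A of AUG) and +4 (the first base after the AUG).  The optimal
#' context is `GCCGCCAUGR`; by default a position matches when it carries a
#' purine (R = A or G), with an exact-G rule available for stricter
#' scoring.  N never matches.
#'
#' @param minus3,plus4 `"purine"` or `"exact-G"`.
#' @return a `kozak_policy` list.
#' @export
kozak_policy <- function(minus3 = c("purine", "exact-G"),
                         plus4 = c("purine", "exact-G")) {
  structure(list(minus3 = match.arg(minus3), plus4 = match.arg(plus4)),
            class = "kozak_policy")
}

kozak_base_match <- function(base, rule) {
  if (is.na(base) || base == "." || base == "N") return(NA)
  if (rule == "purine") base %in% c("A", "G") else base == "G"
}

kozak_strength_of <- function(matches) {
  if (any(is.na(matches))) return("undetermined")
  c("weak", "intermediate", "strong")[sum(matches) + 1L]
}

#' Keep only coding transcripts
#'
#' Transcripts without an annotated CDS (`cds_start == cds_end`) cannot
#' host a uORF and are removed before leader extraction; the number removed
#' is reported as a message.
#'
#' @param models `transcript_models` data frame.
#' @return the coding subset, input order preserved.
#' @export
filter_coding <- function(models) {
  keep <- models$coding
  n_drop <- sum(!keep)
  if (n_drop > 0) message(n_drop, " non-coding transcript(s) removed")
  if (!any(keep)) warning("no coding transcripts remain")
  models[keep, , drop = FALSE]
}

#' Extract the spliced transcript leader sequence (TLS)
#'
#' The TLS is the spliced transcript sequence strictly upstream of the CDS
#' start codon, in transcript orientation, with all intronic sequence
#' removed.  Alongside the sequence a bidirectional coordinate map is
#' built: `coord_map[i]` is the 0-based genomic position of spliced base
#' `i` (ascending for plus-strand, descending for minus-strand
#' transcripts).  The first CDS base (the Kozak +4 position of a uAUG that
#' abuts the CDS) is carried separately.
#'
#' @param model a single transcript as returned by [get_model()].
#' @param genome a [genome_sequence()].
#' @return a `transcript_leader` list: `tx_id`, `gene`, `contig`, `strand`,
#'   `sequence`, `coord_map`, `cds_next_base`, `cds_next_gpos`.
#' @export
extract_leader <- function(model, genome) {
  if (!model$coding) stop("transcript ", model$tx_id, " is non-coding")
  es <- model$exon_starts
  ee <- model$exon_ends
  if (model$strand == "+") {
    first_cds <- model$cds_start
  } else {
    first_cds <- model$cds_end - 1L
  }
  if (!any(es <= first_cds & first_cds < ee)) {
    stop("transcript ", model$tx_id, ": CDS start not covered by any exon")
  }
  if (model$strand == "+") {
    s <- pmin(ee, model$cds_start)
    keep <- s > es
    pieces <- cbind(es[keep], s[keep])
    gpos <- if (nrow(pieces)) {
      unlist(lapply(seq_len(nrow(pieces)),
                    function(i) seq.int(pieces[i, 1], pieces[i, 2] - 1L)))
    } else integer(0)
    seq <- paste(vapply(seq_len(nrow(pieces)), function(i)
      genome_fetch(genome, model$contig, pieces[i, 1], pieces[i, 2]),
      character(1)), collapse = "")
    cds_next_gpos <- model$cds_start
    cds_next_base <- genome_base(genome, model$contig, cds_next_gpos)
  } else {
    s <- pmax(es, model$cds_end)
    keep <- ee > s
    pieces <- cbind(s[keep], ee[keep])
    gplus <- if (nrow(pieces)) {
      unlist(lapply(seq_len(nrow(pieces)),
                    function(i) seq.int(pieces[i, 1], pieces[i, 2] - 1L)))
    } else integer(0)
    plus_seq <- paste(vapply(seq_len(nrow(pieces)), function(i)
      genome_fetch(genome, model$contig, pieces[i, 1], pieces[i, 2]),
      character(1)), collapse = "")
    seq <- revcomp(plus_seq)
    gpos <- rev(gplus)
    cds_next_gpos <- model$cds_end - 1L
    cds_next_base <- complement_base(genome_base(genome, model$contig, cds_next_gpos))
  }
  stopifnot(nchar(seq) == length(gpos))
  structure(list(tx_id = model$tx_id, gene = model$gene, contig = model$contig,
                 strand = model$strand, sequence = seq,
                 coord_map = as.integer(gpos),
                 cds_next_base = cds_next_base,
                 cds_next_gpos = as.integer(cds_next_gpos)),
            class = "transcript_leader")
}

#' Project a spliced leader interval to genomic blocks
#'
#' Maps the 0-based half-open spliced interval `[from, to)` through the
#' leader's coordinate map and merges runs of adjacent genomic positions
#' into 0-based half-open blocks (sorted ascending, i.e. BED order, for
#' both strands).  A codon split by an intron yields more than one block.
#'
#' @param leader a `transcript_leader`.
#' @param from,to 0-based half-open spliced offsets.
#' @return integer matrix with columns `start`, `end`.
#' @export
spliced_to_blocks <- function(leader, from, to) {
  L <- nchar(leader$sequence)
  stopifnot(from >= 0, to <= L, from <= to)
  if (from == to) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  g <- leader$coord_map[(from + 1L):to]
  step <- if (leader$strand == "+") 1L else -1L
  brk <- which(diff(g) != step)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(g))
  m <- t(vapply(seq_along(starts), function(i) {
    run <- g[starts[i]:ends[i]]
    c(min(run), max(run) + 1L)
  }, integer(2)))
  m <- m[order(m[, 1]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Classify the Kozak context of a uAUG
#'
#' Assembles the context window covering spliced positions -6..-1 and +4
#' relative to the A of the AUG.  The +4 base is the next spliced base
#' after the AUG: a TLS base for internal uAUGs, or the first CDS base when
#' the uAUG abuts the CDS.  Positions upstream of the transcript 5' end
#' are reported as `"."` and make the strength `undetermined`.  Strength is
#' `strong` with both core positions (-3, +4) matching, `intermediate` with
#' one, `weak` with none.  The window string follows the field's rendering:
#' core positions uppercase, flanking bases lowercase, e.g. `ttgTgtATGA`.
#'
#' @param leader a `transcript_leader`.
#' @param uaug_offset 0-based spliced offset of the A of an ATG in the TLS.
#' @param policy a [kozak_policy()].
#' @return a list: `window`, `core_matches` (0-2, `NA` if undetermined),
#'   `strength`, `minus3`, `plus4`, `positions` (genomic positions of
#'   -6..-1 and +4, `NA` where unavailable).
#' @export
kozak_context <- function(leader, uaug_offset, policy = kozak_policy()) {
  L <- nchar(leader$sequence)
  o <- uaug_offset
  stopifnot(o >= 0, o + 3 <= L)
  if (substring(leader$sequence, o + 1, o + 3) != "ATG") {
    stop("no ATG at spliced offset ", o, " of ", leader$tx_id)
  }
  rel <- c(-6:-1)
  up_idx <- o + rel                       # 0-based spliced indices
  up <- ifelse(up_idx >= 0,
               substring(leader$sequence, up_idx + 1, up_idx + 1), ".")
  up_gpos <- rep(NA_integer_, length(up_idx))
  ok_up <- up_idx >= 0
  up_gpos[ok_up] <- leader$coord_map[up_idx[ok_up] + 1]
  if (o + 3 < L) {
    p4 <- substring(leader$sequence, o + 4, o + 4)
    p4_gpos <- leader$coord_map[o + 4]
  } else {
    p4 <- if (is.na(leader$cds_next_base)) "." else leader$cds_next_base
    p4_gpos <- leader$cds_next_gpos
  }
  m3 <- kozak_base_match(up[rel == -3], policy$minus3)
  m4 <- kozak_base_match(p4, policy$plus4)
  matches <- c(m3, m4)
  disp <- tolower(up)
  disp[rel == -3] <- toupper(up[rel == -3])
  window <- paste0(paste(disp, collapse = ""), "ATG", toupper(p4))
  list(window = window,
       core_matches = if (any(is.na(matches))) NA_integer_ else sum(matches),
       strength = kozak_strength_of(matches),
       minus3 = up[rel == -3], plus4 = p4,
       positions = as.integer(c(up_gpos, p4_gpos)))
}

#' Scan a transcript leader for uORFs
#'
#' Finds every ATG lying fully inside the TLS, 5' to 3'.  For each uAUG the
#' first in-frame stop codon (TAA, TAG, TGA) fully inside the TLS and
#' downstream of the uAUG is assigned as its uStop; uAUGs with no in-TLS
#' in-frame stop are retained with `cds_overlapping = TRUE` (their ORF runs
#' into or past the CDS) and carry no uStop.  Codons containing N never
#' match.  uORFs sharing one termination codon get a common
#' `shared_stop_group`.  The scan is deterministic; output is ordered by
#' `uaug_offset`.
#'
#' @param leader a `transcript_leader`.
#' @param policy a [kozak_policy()].
#' @return a data frame with one row per uORF: spliced offsets, length,
#'   `cds_overlapping`, Kozak annotation, and genomic block list columns
#'   `uaug_blocks`, `ustop_blocks`, `span_blocks`, `kozak_gpos`.
#' @export
scan_uorfs <- function(leader, policy = kozak_policy()) {
  s <- leader$sequence
  L <- nchar(s)
  empty <- empty_df(tx_id = character(0), gene = character(0),
                    contig = character(0), strand = character(0),
                    uaug_offset = integer(0), ustop_offset = integer(0),
                    cds_overlapping = logical(0), length_nt = integer(0),
                    shared_stop_group = character(0), ustop_codon = character(0),
                    kozak_window = character(0), kozak_core_matches = integer(0),
                    kozak_strength = character(0))
  empty$uaug_blocks <- list(); empty$ustop_blocks <- list()
  empty$span_blocks <- list(); empty$kozak_gpos <- list()
  if (L < 3) return(empty)
  ch <- strsplit(s, NULL)[[1]]
  n3 <- L - 2L
  cods <- paste0(ch[1:n3], ch[2:(n3 + 1L)], ch[3:(n3 + 2L)])
  atg <- which(cods == "ATG")              # 1-based codon start
  if (!length(atg)) return(empty)
  stop_at <- which(cods %in% STOP_CODONS)
  rows <- lapply(atg, function(a) {
    cand <- stop_at[stop_at >= a + 3L & (stop_at - a) %% 3L == 0L]
    o <- a - 1L                            # 0-based uAUG offset
    if (length(cand)) {
      j <- cand[1] - 1L                    # 0-based uStop offset
      list(uaug_offset = o, ustop_offset = j, cds_overlapping = FALSE,
           length_nt = j + 3L - o)
    } else {
      list(uaug_offset = o, ustop_offset = NA_integer_, cds_overlapping = TRUE,
           length_nt = NA_integer_)
    }
  })
  df <- data.frame(
    tx_id = leader$tx_id, gene = leader$gene, contig = leader$contig,
    strand = leader$strand,
    uaug_offset = vapply(rows, `[[`, integer(1), "uaug_offset"),
    ustop_offset = vapply(rows, `[[`, integer(1), "ustop_offset"),
    cds_overlapping = vapply(rows, `[[`, logical(1), "cds_overlapping"),
    length_nt = vapply(rows, `[[`, integer(1), "length_nt"),
    stringsAsFactors = FALSE)
  df$shared_stop_group <- ifelse(is.na(df$ustop_offset), NA_character_,
                                 paste0(leader$tx_id, ":stop", df$ustop_offset))
  df$ustop_codon <- ifelse(is.na(df$ustop_offset), NA_character_,
                           substring(s, df$ustop_offset + 1, df$ustop_offset + 3))
  kz <- lapply(df$uaug_offset, function(o) kozak_context(leader, o, policy))
  df$kozak_window <- vapply(kz, `[[`, character(1), "window")
  df$kozak_core_matches <- vapply(kz, `[[`, integer(1), "core_matches")
  df$kozak_strength <- vapply(kz, `[[`, character(1), "strength")
  df$uaug_blocks <- lapply(df$uaug_offset,
                           function(o) spliced_to_blocks(leader, o, o + 3L))
  df$ustop_blocks <- lapply(seq_len(nrow(df)), function(i) {
    if (is.na(df$ustop_offset[i])) {
      matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
    } else {
      spliced_to_blocks(leader, df$ustop_offset[i], df$ustop_offset[i] + 3L)
    }
  })
  df$span_blocks <- lapply(seq_len(nrow(df)), function(i) {
    to <- if (is.na(df$ustop_offset[i])) L else df$ustop_offset[i] + 3L
    spliced_to_blocks(leader, df$uaug_offset[i], to)
  })
  df$kozak_gpos <- lapply(kz, `[[`, "positions")
  df
}

#' Build a genome-wide uORF catalog
#'
#' Runs [filter_coding()], [extract_leader()] and [scan_uorfs()] over all
#' transcript models and assembles the full catalog plus the unique uAUG
#' and uStop genomic codon sets.  With `dedupe = "by-genomic-position"`
#' identical codons shared across isoforms are counted once (the right mode
#' for genome-wide tallies); `"per-transcript"` keeps one entry per
#' transcript (the right mode for screen target bookkeeping).  uAUGs
#' flagged `cds_overlapping` never contribute to the uStop set, and the
#' unique uStop set always satisfies `|uStop| <= |uAUG|` because in-frame
#' uAUGs may share one termination codon.
#'
#' @param models `transcript_models` data frame.
#' @param genome a [genome_sequence()].
#' @param policy a [kozak_policy()].
#' @param dedupe `"by-genomic-position"` or `"per-transcript"`.
#' @return a `uorf_catalog` list: `uorfs` (full per-transcript table),
#'   `uaug_sites`, `ustop_sites` (deduplicated codon tables), `policy`,
#'   `dedupe`.
#' @export
annotate_genome <- function(models, genome, policy = kozak_policy(),
                            dedupe = c("by-genomic-position", "per-transcript")) {
  dedupe <- match.arg(dedupe)
  coding <- suppressMessages(filter_coding(models))
  parts <- lapply(seq_len(nrow(coding)), function(i) {
    leader <- extract_leader(get_model(coding, i), genome)
    scan_uorfs(leader, policy)
  })
  uorfs <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(uorfs)) uorfs <- scan_uorfs(
    structure(list(tx_id = "", gene = "", contig = "", strand = "+",
                   sequence = "", coord_map = integer(0),
                   cds_next_base = NA, cds_next_gpos = NA_integer_),
              class = "transcript_leader"))
  uorfs$uaug_key <- paste(uorfs$contig, uorfs$strand,
                          vapply(uorfs$uaug_blocks, blocks_to_str, character(1)),
                          sep = "|")
  uorfs$ustop_key <- ifelse(
    uorfs$cds_overlapping, NA_character_,
    paste(uorfs$contig, uorfs$strand,
          vapply(uorfs$ustop_blocks, blocks_to_str, character(1)), sep = "|"))
  if (dedupe == "by-genomic-position") {
    uaug_sites <- uorfs[!duplicated(uorfs$uaug_key), , drop = FALSE]
    st <- uorfs[!uorfs$cds_overlapping, , drop = FALSE]
    ustop_sites <- st[!duplicated(st$ustop_key), , drop = FALSE]
  } else {
    uaug_sites <- uorfs[!duplicated(paste(uorfs$tx_id, uorfs$uaug_offset)), ,
                        drop = FALSE]
    st <- uorfs[!uorfs$cds_overlapping, , drop = FALSE]
    ustop_sites <- st[!duplicated(paste(st$tx_id, st$ustop_offset)), , drop = FALSE]
  }
  structure(list(uorfs = uorfs, uaug_sites = uaug_sites,
                 ustop_sites = ustop_sites, policy = policy, dedupe = dedupe),
            class = "uorf_catalog")
}

#' @export
print.uorf_catalog <- function(x, ...) {
  cat(sprintf(paste0("uorf_catalog: %d uORF(s) across %d transcript(s); ",
                     "%d unique uAUG codon(s), %d unique uStop codon(s) [%s]\n"),
              nrow(x$uorfs), length(unique(x$uorfs$tx_id)),
              nrow(x$uaug_sites), nrow(x$ustop_sites), x$dedupe))
  invisible(x)
}

#' Write catalog outputs (TSV + BED)
#'
#' Emits `<prefix>.uorfs.tsv` (full catalog), `<prefix>.uorfs.bed` (BED12,
#' one record per uORF span), `<prefix>.uaug.bed` and `<prefix>.ustop.bed`
#' (codons; intron-split codons appear as 12-column records).  BED names
#' are `transcript|element|spliced-offset`.
#'
#' @param catalog a `uorf_catalog`.
#' @param prefix output path prefix.
#' @param lengths optional contig lengths for range checks.
#' @return invisibly, the vector of paths written.
#' @export
write_uorf_catalog <- function(catalog, prefix, lengths = NULL) {
  u <- catalog$uorfs
  tsv <- paste0(prefix, ".uorfs.tsv")
  cols <- c("tx_id", "gene", "contig", "strand", "uaug_offset", "ustop_offset",
            "cds_overlapping", "length_nt", "kozak_window",
            "kozak_core_matches", "kozak_strength", "shared_stop_group",
            "uaug_blocks", "ustop_blocks", "span_blocks")
  write_tsv_header(u[, cols], tsv,
                   params = list(kozak_minus3 = catalog$policy$minus3,
                                 kozak_plus4 = catalog$policy$plus4,
                                 dedupe = catalog$dedupe))
  feat <- function(df, element, blocks_col, offset_col) {
    keep <- vapply(df[[blocks_col]], nrow, integer(1)) > 0
    df <- df[keep, , drop = FALSE]
    out <- data.frame(contig = df$contig,
                      name = paste(df$tx_id, element, df[[offset_col]], sep = "|"),
                      strand = df$strand, stringsAsFactors = FALSE)
    out$blocks <- df[[blocks_col]]
    out
  }
  bed12 <- paste0(prefix, ".uorfs.bed")
  write_bed(feat(u, "uorf", "span_blocks", "uaug_offset"), bed12,
            flavor = "bed12-uorfs", lengths = lengths)
  uaug_bed <- paste0(prefix, ".uaug.bed")
  write_bed(feat(catalog$uaug_sites, "uaug", "uaug_blocks", "uaug_offset"),
            uaug_bed, flavor = "bed6-codons", lengths = lengths)
  ustop_bed <- paste0(prefix, ".ustop.bed")
  write_bed(feat(catalog$ustop_sites, "ustop", "ustop_blocks", "ustop_offset"),
            ustop_bed, flavor = "bed6-codons", lengths = lengths)
  invisible(c(tsv, bed12, uaug_bed, ustop_bed))
}

#' Expand a catalog into a per-base site table
#'
#' One row per (transcript, element, genomic base): the join target for
#' subsetting variants to uORF elements.  `codon_pos` is the 1-based
#' position within the codon in transcript orientation for uAUG/uStop
#' rows; `kozak_rel` is the window position (-6..-1, 4) for uKozak rows.
#'
#' @param catalog a `uorf_catalog`.
#' @param kozak_window also emit the 7 Kozak window positions per uAUG?
#' @return a data frame keyed by (`contig`, `pos`).
#' @export
expand_catalog_sites <- function(catalog, kozak_window = FALSE) {
  u <- catalog$uorfs
  out <- list()
  codon_positions <- function(blocks, strand) {
    g <- unlist(lapply(seq_len(nrow(blocks)),
                       function(i) seq.int(blocks[i, 1], blocks[i, 2] - 1L)))
    if (strand == "-") rev(sort(g)) else sort(g)
  }
  for (i in seq_len(nrow(u))) {
    g <- codon_positions(u$uaug_blocks[[i]], u$strand[i])
    out[[length(out) + 1L]] <- data.frame(
      contig = u$contig[i], pos = g, tx_id = u$tx_id[i], element = "uAUG",
      strand = u$strand[i], uorf_row = i, codon_pos = seq_along(g),
      kozak_rel = NA_integer_, ref_codon = "ATG", stringsAsFactors = FALSE)
    if (!u$cds_overlapping[i]) {
      gs <- codon_positions(u$ustop_blocks[[i]], u$strand[i])
      out[[length(out) + 1L]] <- data.frame(
        contig = u$contig[i], pos = gs, tx_id = u$tx_id[i], element = "uStop",
        strand = u$strand[i], uorf_row = i, codon_pos = seq_along(gs),
        kozak_rel = NA_integer_,
        ref_codon = u$ustop_codon[i], stringsAsFactors = FALSE)
    }
    if (kozak_window) {
      kg <- u$kozak_gpos[[i]]
      rel <- c(-6:-1, 4L)
      ok <- !is.na(kg)
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = u$contig[i], pos = kg[ok], tx_id = u$tx_id[i],
          element = "uKozak", strand = u$strand[i], uorf_row = i,
          codon_pos = NA_integer_, kozak_rel = rel[ok],
          ref_codon = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(empty_df(contig = character(0), pos = integer(0),
                    tx_id = character(0), element = character(0),
                    strand = character(0), uorf_row = integer(0),
                    codon_pos = integer(0), kozak_rel = integer(0),
                    ref_codon = character(0)))
  }
  do.call(rbind, out)
}

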