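# Readers/writers for the standard flat formats the pipeline touches
# (FASTA, refGene tab table, BED6/BED12, VCF 4.x, per-site base-count TSV)
# and strand-aware sequence access.  All internal coordinates are 0-based
# half-open; conversion to 1-based happens only at the VCF and TSV
# boundaries.

#' Construct a genome sequence object
#'
#' A `genome_sequence` is a named character vector of uppercase DNA strings
#' over `{A,C,G,T,N}`, one element per contig.  IUPAC ambiguity codes other
#' than N are collapsed to N so that codon matching stays conservative on
#' masked or ambiguous sequence.
#'
#' @param contigs named character vector of DNA strings.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(contigs) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig name(s): ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  }
  x <- toupper(contigs)
  # non-ACGTN IUPAC letters become N; anything else is a format error
  bad <- grepl("[^ACGTNRYSWKMBDHV]", x)
  if (any(bad)) {
    stop("non-IUPAC character in contig(s): ",
         paste(names(x)[bad], collapse = ", "))
  }
  x <- gsub("[RYSWKMBDHV]", "N", x)
  structure(x, class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence: %d contig(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x)) cat(sprintf("  %s  %d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Lengths of the contigs of a genome
#' @param genome a `genome_sequence`.
#' @return named integer vector.
#' @export
contig_lengths <- function(genome) setNames(nchar(unclass(genome)), names(genome))

#' Read / write a genome FASTA
#'
#' Reading uppercases all sequence (soft-masked lowercase is kept, as
#' uppercase) and rejects duplicate headers.  Writing wraps at 70 columns;
#' write/read round-trips are identity on the sequences.
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta`: a [genome_sequence()].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA header(s) in '", path, "': ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  genome_sequence(setNames(as.character(set), nms))
}

#' @rdname read_genome_fasta
#' @param genome a [genome_sequence()].
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Fetch a genomic subsequence, strand-aware
#'
#' Coordinates are 0-based half-open.  On the minus strand the reverse
#' complement of the plus-strand subsequence is returned, so
#' `fetch(+) == revcomp(fetch(-))` for every interval.
#'
#' @param genome a [genome_sequence()].
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return a single DNA string.
#' @export
genome_fetch <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- nchar(genome[[contig]])
  if (start < 0 || end > len || start > end) {
    stop(sprintf("interval [%d,%d) outside contig %s (length %d)",
                 start, end, contig, len))
  }
  s <- substring(genome[[contig]], start + 1, end)
  if (strand == "-") revcomp(s) else s
}

genome_base <- function(genome, contig, pos) {
  genome_fetch(genome, contig, pos, pos + 1L)
}

## ---- refGene transcript table -------------------------------------------

REFGENE_COLS <- c("name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
                  "cdsEnd", "exonCount", "exonStarts", "exonEnds", "score",
                  "name2", "cdsStartStat", "cdsEndStat", "exonFrames")

#' Parse a UCSC refGene-style transcript table
#'
#' Accepts both circulating dialects: 16 columns (leading `bin` column, as
#' dumped from the UCSC database) and 15 columns (without `bin`);
#' auto-detected by column count unless overridden.  Exon intervals are
#' 0-based half-open as in the source table and minus-strand transcripts
#' keep genomic-ascending exon order.  A transcript is coding iff
#' `cdsStart < cdsEnd`.
#'
#' @param path tab-separated transcript table.
#' @param dialect `"auto"`, `"refgene-with-bin"` or `"refgene-no-bin"`.
#' @return a `transcript_models` data frame with one row per transcript and
#'   list columns `exon_starts`/`exon_ends`.
#' @export
read_refgene <- function(path, dialect = c("auto", "refgene-with-bin",
                                           "refgene-no-bin")) {
  dialect <- match.arg(dialect)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#", colClasses = "character")
  ncol_raw <- ncol(raw)
  has_bin <- switch(dialect,
    "auto" = ncol_raw == 16,
    "refgene-with-bin" = TRUE,
    "refgene-no-bin" = FALSE)
  if (dialect == "auto" && !ncol_raw %in% c(15, 16)) {
    stop("cannot auto-detect refGene dialect: ", ncol_raw, " columns")
  }
  if (has_bin) raw <- raw[, -1, drop = FALSE]
  if (ncol(raw) != 15) stop("expected 15 refGene data columns, got ", ncol(raw))
  names(raw) <- REFGENE_COLS

  parse_ints <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  n <- nrow(raw)
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    es <- parse_ints(raw$exonStarts[i])
    ee <- parse_ints(raw$exonEnds[i])
    cnt <- as.integer(raw$exonCount[i])
    if (length(es) != cnt || length(ee) != cnt) {
      stop(sprintf("row %d (%s): exonCount %d does not match exon lists (%d/%d)",
                   i, raw$name[i], cnt, length(es), length(ee)))
    }
    if (as.integer(raw$cdsStart[i]) > as.integer(raw$cdsEnd[i])) {
      stop(sprintf("row %d (%s): cdsStart > cdsEnd", i, raw$name[i]))
    }
    if (is.unsorted(es, strictly = TRUE) || any(ee <= es) ||
        (cnt > 1 && any(es[-1] < ee[-cnt]))) {
      stop(sprintf("row %d (%s): exons must be sorted and non-overlapping",
                   i, raw$name[i]))
    }
    exon_starts[[i]] <- es
    exon_ends[[i]] <- ee
  }
  models <- data.frame(
    tx_id = raw$name, gene = raw$name2, contig = raw$chrom,
    strand = raw$strand,
    tx_start = as.integer(raw$txStart), tx_end = as.integer(raw$txEnd),
    cds_start = as.integer(raw$cdsStart), cds_end = as.integer(raw$cdsEnd),
    exon_count = as.integer(raw$exonCount),
    stringsAsFactors = FALSE)
  models$exon_starts <- exon_starts
  models$exon_ends <- exon_ends
  models$coding <- models$cds_start < models$cds_end
  class(models) <- c("transcript_models", class(models))
  models
}

#' @rdname read_refgene
#' @param models a `transcript_models` data frame.
#' @param bin write the leading `bin` column (16-column dialect)?
#' @export
write_refgene <- function(models, path, bin = TRUE) {
  join <- function(xs) vapply(xs, function(v) paste0(paste(v, collapse = ","), ","),
                              character(1))
  out <- data.frame(
    name = models$tx_id, chrom = models$contig, strand = models$strand,
    txStart = models$tx_start, txEnd = models$tx_end,
    cdsStart = models$cds_start, cdsEnd = models$cds_end,
    exonCount = models$exon_count,
    exonStarts = join(models$exon_starts), exonEnds = join(models$exon_ends),
    score = 0L, name2 = models$gene,
    cdsStartStat = ifelse(models$coding, "cmpl", "unk"),
    cdsEndStat = ifelse(models$coding, "cmpl", "unk"),
    exonFrames = vapply(models$exon_count,
                        function(k) paste0(paste(rep("-1", k), collapse = ","), ","),
                        character(1)),
    stringsAsFactors = FALSE)
  if (bin) out <- cbind(bin = 0L, out)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select one transcript model as a plain list
#' @param models `transcript_models` data frame.
#' @param which row index or transcript id.
#' @return a list with one field per column (exon lists unwrapped).
#' @export
get_model <- function(models, which) {
  i <- if (is.character(which)) match(which, models$tx_id) else which
  if (is.na(i) || i < 1 || i > nrow(models)) stop("no such transcript: ", which)
  m <- lapply(models, function(col) if (is.list(col)) col[[i]] else col[[i]])
  m
}

## ---- BED ----------------------------------------------------------------

#' Write genomic features as BED
#'
#' `features` is a data frame with columns `contig`, `name`, `strand` and a
#' list column `blocks` of 0-based half-open block matrices (see
#' [blocks_to_str()]).  Flavor `bed12-uorfs` writes one 12-column line per
#' feature; `bed6-codons` writes 6 columns for single-block codons and
#' falls back to 12 columns for codons split across an intron, so block
#' structure is never lost.
#'
#' @param features feature data frame.
#' @param path output path.
#' @param flavor `"bed12-uorfs"` or `"bed6-codons"`.
#' @param lengths optional named contig lengths for range checking.
#' @return invisibly, `path`.
#' @export
write_bed <- function(features, path, flavor = c("bed12-uorfs", "bed6-codons"),
                      lengths = NULL) {
  flavor <- match.arg(flavor)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(features) == 0) return(invisible(path))
  for (i in seq_len(nrow(features))) {
    b <- features$blocks[[i]]
    if (is.unsorted(b[, 1], strictly = TRUE) && nrow(b) > 1) {
      stop("blocks must be sorted ascending (feature ", features$name[i], ")")
    }
    if (!is.null(lengths)) {
      len <- lengths[[features$contig[i]]]
      if (is.null(len) || any(b[, 1] < 0) || any(b[, 2] > len)) {
        stop("block outside contig ", features$contig[i],
             " for feature ", features$name[i])
      }
    }
    cs <- min(b[, 1]); ce <- max(b[, 2])
    if (flavor == "bed6-codons" && nrow(b) == 1) {
      line <- paste(features$contig[i], cs, ce, features$name[i], 0,
                    features$strand[i], sep = "\t")
    } else {
      line <- paste(features$contig[i], cs, ce, features$name[i], 0,
                    features$strand[i], cs, ce, "0", nrow(b),
                    paste0(paste(b[, 2] - b[, 1], collapse = ","), ","),
                    paste0(paste(b[, 1] - cs, collapse = ","), ","),
                    sep = "\t")
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' Accepts mixed 6- and 12-column lines; 12-column lines are expanded back
#' into block matrices.
#'
#' @param path BED path.
#' @return a feature data frame (`contig`, `name`, `strand`, `blocks`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) stop("BED line ", k, ": fewer than 6 fields")
    cs <- as.integer(f[2])
    if (length(f) >= 12) {
      sizes <- as.integer(strsplit(f[11], ",")[[1]])
      starts <- as.integer(strsplit(f[12], ",")[[1]])
      b <- cbind(start = cs + starts, end = cs + starts + sizes)
    } else {
      b <- cbind(start = cs, end = as.integer(f[3]))
    }
    out[[k]] <- list(contig = f[1], name = f[4], strand = f[6], blocks = b)
  }
  df <- data.frame(contig = vapply(out, `[[`, "", "contig"),
                   name = vapply(out, `[[`, "", "name"),
                   strand = vapply(out, `[[`, "", "strand"),
                   stringsAsFactors = FALSE)
  df$blocks <- lapply(out, `[[`, "blocks")
  df
}

## ---- VCF ----------------------------------------------------------------

#' Read a VCF into a variant table
#'
#' Positions are converted from the file's 1-based convention to internal
#' 0-based coordinates.  Multi-allelic records are split into one row per
#' alternate allele.  Records with ref or alt longer than one base are kept
#' but flagged `complex`; their consequence classification is limited.  A
#' `SAMPLE=` key in INFO (as written by the synthetic generator) is parsed
#' into `sample_pair`.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sample_pair,caller_id optional labels attached to every record.
#' @return data frame with columns `contig`, `pos` (0-based), `ref`, `alt`,
#'   `complex`, `sample_pair`, `caller_id`.
#' @export
read_vcf <- function(path, sample_pair = NA_character_, caller_id = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  n <- nrow(fix)
  if (n == 0) {
    out <- empty_df(contig = character(0), pos = integer(0), ref = character(0),
                    alt = character(0), complex = logical(0),
                    sample_pair = character(0), caller_id = character(0))
    return(out)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    sp <- sample_pair
    if (is.na(sp) && !is.na(info[i])) {
      m <- regmatches(info[i], regexpr("(?:^|;)SAMPLE=([^;]+)", info[i]))
      if (length(m)) sp <- sub("^;?SAMPLE=", "", m)
    }
    rows[[i]] <- data.frame(
      contig = unname(fix[i, "CHROM"]),
      pos = unname(as.integer(fix[i, "POS"])) - 1L,
      ref = unname(toupper(fix[i, "REF"])),
      alt = unname(toupper(alts)),
      sample_pair = unname(sp), caller_id = caller_id,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out$complex <- nchar(out$ref) != 1L | nchar(out$alt) != 1L
  out[, c("contig", "pos", "ref", "alt", "complex", "sample_pair", "caller_id")]
}

#' Write a variant table as VCF 4.2
#'
#' The inverse of [read_vcf()] on the fields the pipeline uses; internal
#' 0-based positions are emitted 1-based.  `sample_pair` and any `info`
#' column are carried in INFO.
#'
#' @param variants variant data frame (as from [read_vcf()]).
#' @param path output path.
#' @param genome optional [genome_sequence()]; adds `##contig` header lines.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##source=uorfscan-%s", packageVersion("uorfscan")), con)
  if (!is.null(genome)) {
    for (nm in names(genome)) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>", nm, nchar(genome[[nm]])), con)
    }
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants)) {
    info <- rep(".", nrow(variants))
    if ("sample_pair" %in% names(variants)) {
      has <- !is.na(variants$sample_pair)
      info[has] <- paste0("SAMPLE=", variants$sample_pair[has])
    }
    if ("info" %in% names(variants)) {
      extra <- !is.na(variants$info) & nzchar(variants$info)
      info[extra] <- ifelse(info[extra] == ".", variants$info[extra],
                            paste0(info[extra], ";", variants$info[extra]))
    }
    lines <- paste(variants$contig, variants$pos + 1L, ".", variants$ref,
                   variants$alt, ".", "PASS", info, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

## ---- base-count TSV ------------------------------------------------------

BASE_COUNT_COLS <- c("sample", "contig", "pos", "ref", "A", "C", "G", "T", "DEL")

#' Read / write per-site base-count tables
#'
#' The TSV carries one row per (sample, site): header
#' `sample contig pos ref A C G T DEL` with `pos` 1-based in the file and
#' 0-based internally.  Counts must be non-negative and `ref` one of
#' A/C/G/T.
#'
#' @param path TSV path.
#' @return `read_base_counts`: data frame with the columns above plus
#'   `total`.
#' @export
read_base_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(BASE_COUNT_COLS, names(df))
  if (length(missing)) {
    stop("base-count file missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, BASE_COUNT_COLS]
  if (any(!df$ref %in% BASES)) {
    stop("ref base must be one of A/C/G/T (row ",
         which(!df$ref %in% BASES)[1], ")")
  }
  cnt <- as.matrix(df[, c(BASES, "DEL")])
  if (any(is.na(cnt)) || any(cnt < 0)) stop("counts must be non-negative integers")
  df$pos <- as.integer(df$pos) - 1L
  df$total <- as.integer(rowSums(cnt))
  df
}

#' @rdname read_base_counts
#' @param counts base-count data frame (internal 0-based `pos`).
#' @param params optional named list recorded in the header.
#' @export
write_base_counts <- function(counts, path, params = NULL) {
  out <- counts[, BASE_COUNT_COLS[BASE_COUNT_COLS %in% names(counts)]]
  out$pos <- out$pos + 1L
  write_tsv_header(out, path, params)
}
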