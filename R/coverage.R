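#' Clip ligation-artifact homopolymers from reads
#'
#' The 3'-poly-A ligation used in dRNA-seq library construction can leave a
#' non-genomic poly-A tail at the read 3' end (or poly-T head after reverse
#' complementing). A trailing A-run longer than the longest A-run observed in
#' the genome, or a leading T-run longer than the longest genomic T-run, is
#' taken to be an artifact and the whole run is removed. Reads shorter than
#' `min_len` after clipping are dropped.
#'
#' @param seq character vector of read sequences.
#' @param max_polyA longest A-run observed in the genome; trailing runs
#'   strictly longer than this are removed entirely.
#' @param max_polyT longest genomic T-run; leading runs strictly longer are
#'   removed entirely.
#' @param min_len minimum read length after clipping.
#' @return Character vector of clipped reads, `NA` where a read was dropped
#'   (too short or empty input).
#' @export
#' @examples
#' clip_read("ACGTACGTACGTACGTACGTAAAAA", max_polyA = 4, max_polyT = 4)
clip_read <- function(seq, max_polyA, max_polyT, min_len = 20L) {
  seq <- as.character(seq)
  lead <- attr(regexpr("^T+", seq), "match.length")
  keep_lead <- lead > max_polyT
  seq[keep_lead] <- substring(seq[keep_lead], lead[keep_lead] + 1L)
  trail <- attr(regexpr("A+$", seq), "match.length")
  keep_trail <- trail > max_polyA
  seq[keep_trail] <- substring(seq[keep_trail], 1L,
                               nchar(seq[keep_trail]) - trail[keep_trail])
  seq[nchar(seq) < min_len] <- NA_character_
  seq
}

#' Longest homopolymer run of a base in a genome
#'
#' @param genome a [Biostrings::DNAString] or character scalar.
#' @param base single base, e.g. `"A"`.
#' @return Integer, the longest run length (0 if the base is absent).
#' @export
max_homopolymer_run <- function(genome, base) {
  s <- as.character(genome)
  m <- gregexpr(paste0(base, "+"), s)[[1L]]
  if (m[1L] == -1L) return(0L)
  max(attr(m, "match.length"))
}

check_alignment_records <- function(records) {
  need <- c("read_id", "read_length", "replicon", "start", "end", "strand",
            "mismatches", "gaps", "evalue", "score")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("alignment records lack columns: ", paste(missing, collapse = ", "))
  }
  stopifnot(all(records$start <= records$end))
  invisible(records)
}

#' Filter read alignments
#'
#' A record is kept when the alignment spans at least `min_frac` of the read
#' length, has at most `max_mm` mismatches, no gaps, and an e-value at most
#' `max_evalue`. Reads with any alignment overlapping an rDNA region are
#' discarded entirely, as are reads whose best score is attained by more
#' than one record (ambiguous multi-mappers); for reads with a unique best
#' record only that record is retained.
#'
#' @param records data frame of alignment records (columns `read_id`,
#'   `read_length`, `replicon`, `start`, `end`, `strand`, `mismatches`,
#'   `gaps`, `evalue`, `score`).
#' @param rdna_regions optional data frame (`replicon`, `start`, `end`) of
#'   rRNA operon intervals.
#' @param min_frac minimum alignment length as a fraction of read length.
#' @param max_mm maximum mismatches.
#' @param max_evalue maximum e-value.
#' @return The kept records (same columns), one row per retained read.
#' @export
filter_alignments <- function(records, rdna_regions = NULL,
                              min_frac = 0.8, max_mm = 4, max_evalue = 1e-4) {
  if (!nrow(records)) return(records)
  check_alignment_records(records)
  aln_len <- records$end - records$start + 1L
  ok <- aln_len >= min_frac * records$read_length &
    records$mismatches <= max_mm &
    records$gaps == 0 &
    records$evalue <= max_evalue
  records <- records[ok, , drop = FALSE]
  if (!nrow(records)) return(records)

  if (!is.null(rdna_regions) && nrow(rdna_regions)) {
    hit <- rep(FALSE, nrow(records))
    for (k in seq_len(nrow(rdna_regions))) {
      hit <- hit | (records$replicon == rdna_regions$replicon[k] &
                      records$start <= rdna_regions$end[k] &
                      records$end >= rdna_regions$start[k])
    }
    bad_reads <- unique(records$read_id[hit])
    records <- records[!(records$read_id %in% bad_reads), , drop = FALSE]
    if (!nrow(records)) return(records)
  }

  # multi-record reads: keep the unique best-scoring record, drop ties
  dup_ids <- unique(records$read_id[duplicated(records$read_id)])
  if (length(dup_ids)) {
    multi <- records$read_id %in% dup_ids
    keep_multi <- records[multi, , drop = FALSE]
    picked <- lapply(split(seq_len(nrow(keep_multi)), keep_multi$read_id),
                     function(idx) {
                       sc <- keep_multi$score[idx]
                       best <- idx[sc == max(sc)]
                       if (length(best) > 1L) integer(0) else best
                     })
    records <- rbind(records[!multi, , drop = FALSE],
                     keep_multi[unlist(picked), , drop = FALSE])
  }
  rownames(records) <- NULL
  records
}

empty_track <- function(replicon_lengths) {
  cov <- list()
  for (r in names(replicon_lengths)) {
    for (s in c("+", "-")) cov[[paste0(r, "|", s)]] <- numeric(replicon_lengths[[r]])
  }
  cov
}

#' Strand-specific normalized 5'-end coverage from kept alignments
#'
#' The 5' end of a read is its alignment start on the plus strand and its
#' alignment end on the minus strand. Raw per-position 5'-end counts are
#' scaled by `min(library_sizes) / library_size` so that every library's
#' genome-wide total equals the smallest library's raw total.
#'
#' @param records_by_library named list of kept alignment-record data frames
#'   (one per library, e.g. the output of [filter_alignments()]).
#' @param replicon_lengths named integer vector of replicon lengths.
#' @param library_sizes optional named vector of mapped-read totals per
#'   library; defaults to the number of kept records.
#' @return Named list of coverage tracks; each track is a list with
#'   `library_id`, `size`, `norm_factor` and `cov`, the latter a list of
#'   numeric vectors keyed `"<replicon>|<strand>"`.
#' @export
coverage_from_alignments <- function(records_by_library, replicon_lengths,
                                     library_sizes = NULL) {
  if (is.null(library_sizes)) {
    library_sizes <- vapply(records_by_library, nrow, integer(1))
  }
  if (any(library_sizes <= 0)) stop("zero-size library")
  min_size <- min(library_sizes)
  tracks <- list()
  for (lib in names(records_by_library)) {
    rec <- records_by_library[[lib]]
    cov <- empty_track(replicon_lengths)
    if (nrow(rec)) {
      pos5 <- ifelse(rec$strand == "+", rec$start, rec$end)
      key <- paste0(rec$replicon, "|", rec$strand)
      for (k in unique(key)) {
        sel <- key == k
        t <- tabulate(pos5[sel], nbins = length(cov[[k]]))
        cov[[k]] <- cov[[k]] + t
      }
    }
    f <- min_size / library_sizes[[lib]]
    cov <- lapply(cov, function(v) v * f)
    tracks[[lib]] <- list(library_id = lib, size = library_sizes[[lib]],
                          norm_factor = f, cov = cov)
  }
  tracks
}

#' Read 12-column tabular alignments
#'
#' Reads BLAST-style tabular records (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore, with an optional 13th
#' qlen column) into the alignment-record data frame used by
#' [filter_alignments()]. Subject coordinates with `sstart > send` encode a
#' minus-strand hit. When the qlen column is absent the read length is taken
#' as the largest observed query end per read.
#'
#' @param path path to the tabular file.
#' @return Alignment-record data frame.
#' @export
read_alignments_tabular <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (!ncol(d) %in% c(12L, 13L)) stop("expected 12 or 13 tab-separated columns")
  names(d)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore")
  minus <- d$sstart > d$send
  read_length <- if (ncol(d) == 13L) d[[13L]] else
    stats::ave(d$qend, d$qseqid, FUN = max)
  data.frame(
    read_id = d$qseqid, read_length = read_length, replicon = d$sseqid,
    start = ifelse(minus, d$send, d$sstart),
    end = ifelse(minus, d$sstart, d$send),
    strand = ifelse(minus, "-", "+"),
    mismatches = d$mismatch, gaps = d$gapopen,
    evalue = d$evalue, score = d$bitscore, stringsAsFactors = FALSE
  )
}

#' Read SAM alignments
#'
#' Parses the standard columns of a SAM file (header lines skipped) into the
#' alignment-record data frame used by [filter_alignments()]. Mismatches are
#' taken from the `NM` tag minus inserted/deleted bases, gaps from
#' insertion/deletion CIGAR operations, and the score from the `AS` tag when
#' present (otherwise read length minus mismatches). SAM records carry no
#' e-value; a value of 0 is used so the e-value filter never removes them.
#'
#' @param path path to a SAM text file.
#' @return Alignment-record data frame (unmapped records excluded).
#' @export
read_alignments_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(), read_length = integer(),
                      replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), gaps = integer(),
                      evalue = numeric(), score = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- get(6L)
  seqs <- get(10L)
  cigar_sum <- function(cig, ops) {
    vapply(cig, function(cg) {
      m <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
      if (m[1L] == -1L) return(0L)
      toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
      op <- substring(toks, nchar(toks))
      n <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
      sum(n[op %in% ops])
    }, integer(1), USE.NAMES = FALSE)
  }
  ref_span <- cigar_sum(cigar, c("M", "D", "N", "=", "X"))
  indel <- cigar_sum(cigar, c("I", "D"))
  n_gap_ops <- vapply(cigar, function(cg) {
    length(gregexpr("[ID]", cg)[[1L]][gregexpr("[ID]", cg)[[1L]] > 0])
  }, integer(1), USE.NAMES = FALSE)
  tag_val <- function(tag) {
    vapply(f, function(x) {
      hit <- grep(paste0("^", tag, ":i:"), x, value = TRUE)
      if (length(hit)) as.numeric(sub(paste0(tag, ":i:"), "", hit[1L])) else NA_real_
    }, numeric(1))
  }
  nm <- tag_val("NM")
  as <- tag_val("AS")
  start <- as.integer(get(4L))
  rl <- nchar(seqs)
  mism <- ifelse(is.na(nm), 0, pmax(nm - indel, 0))
  out <- data.frame(
    read_id = get(1L), read_length = rl, replicon = get(3L),
    start = start, end = start + ref_span - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mismatches = mism, gaps = n_gap_ops,
    evalue = 0, score = ifelse(is.na(as), rl - mism, as),
    stringsAsFactors = FALSE
  )
  out[mapped, , drop = FALSE]
}

#' Write a coverage track as strand-specific BedGraph
#'
#' @param track one element of [coverage_from_alignments()] output.
#' @param dir output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_coverage_bedgraph <- function(track, dir) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("write_coverage_bedgraph() needs the rtracklayer package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in names(track$cov)) {
    v <- track$cov[[k]]
    nz <- which(v != 0)
    if (!length(nz)) next
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    gr <- GenomicRanges::GRanges(parts[1L], IRanges::IRanges(nz, nz),
                                 score = v[nz])
    f <- file.path(dir, sprintf("%s_%s.bedgraph", track$library_id,
                                ifelse(parts[2L] == "+", "fwd", "rev")))
    rtracklayer::export(gr, f, format = "bedGraph")
    paths <- c(paths, f)
  }
  invisible(paths)
}
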