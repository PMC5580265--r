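#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()].
#' Proteins are scored with BLOSUM62, gap open 10, gap extend 0.5 (the
#' classical `needle` defaults); nucleotide alignments use match 5 /
#' mismatch -4 with the same gap penalties. Identity is the number of
#' identical columns divided by the alignment length (gap columns included),
#' as a percentage.
#'
#' @param seq_a,seq_b character scalars (or XString objects).
#' @param type `"protein"` or `"dna"`.
#' @return List with `aligned_a`, `aligned_b` (gapped strings), `identity`
#'   (percent) and `score`.
#' @export
#' @examples
#' global_align("ACDE", "ACDF")$identity
global_align <- function(seq_a, seq_b, type = c("protein", "dna")) {
  type <- match.arg(type)
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  if (type == "protein") {
    mat <- get_blosum62()
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  }
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  ident <- 100 * sum(ca == cb & ca != "-") / length(ca)
  list(aligned_a = a, aligned_b = b, identity = ident,
       score = Biostrings::score(pa))
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Calibrate the candidate-hit score threshold
#'
#' The internal all-vs-all similarity search has no e-value; instead a
#' global-alignment score threshold is calibrated so that randomly shuffled
#' sequence pairs never pass. `n` cross-species pairs are drawn, each
#' sequence's residues are permuted, and the threshold is the maximum score
#' observed among these null pairs plus a safety margin.
#'
#' @param proteome_a,proteome_b [Biostrings::AAStringSet] objects.
#' @param n number of shuffled null pairs.
#' @param margin added to the maximum null score.
#' @return Numeric score threshold.
#' @export
calibrate_score_threshold <- function(proteome_a, proteome_b, n = 300,
                                      margin = 1) {
  ia <- sample.int(length(proteome_a), n, replace = TRUE)
  ib <- sample.int(length(proteome_b), n, replace = TRUE)
  shuffle <- function(s) {
    paste(sample(strsplit(as.character(s), "")[[1L]]), collapse = "")
  }
  mat <- get_blosum62()
  sa <- Biostrings::AAStringSet(vapply(ia, function(i) shuffle(proteome_a[[i]]),
                                       character(1)))
  sb <- Biostrings::AAStringSet(vapply(ib, function(i) shuffle(proteome_b[[i]]),
                                       character(1)))
  sc <- vapply(seq_len(n), function(k) {
    Biostrings::pairwiseAlignment(sa[[k]], sb[[k]], substitutionMatrix = mat,
                                  gapOpening = 10, gapExtension = 0.5,
                                  type = "global", scoreOnly = TRUE)
  }, numeric(1))
  max(sc) + margin
}

all_vs_all_scores <- function(proteome_a, proteome_b) {
  mat <- get_blosum62()
  scores <- matrix(0, length(proteome_a), length(proteome_b),
                   dimnames = list(names(proteome_a), names(proteome_b)))
  for (j in seq_along(proteome_b)) {
    scores[, j] <- Biostrings::pairwiseAlignment(
      proteome_a, proteome_b[[j]], substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5, type = "global", scoreOnly = TRUE)
  }
  scores
}

# unique-argmax helper: index of the single maximum, or NA on ties
unique_which_max <- function(x) {
  m <- max(x)
  idx <- which(x == m)
  if (length(idx) == 1L) idx else NA_integer_
}

#' Detect single-copy orthologous gene pairs
#'
#' Candidate cross-species protein hits come either from an internal
#' all-vs-all global-alignment score search (scores below a null-calibrated
#' threshold discarded, see [calibrate_score_threshold()]) or from external
#' BLAST-style tabular hits filtered at `min_local_identity` and
#' `ortho_max_evalue`. Reciprocal best hits are kept when each gene's best
#' score is unique (tied best hits mark a family as not single-copy and its
#' genes are excluded). Surviving pairs are aligned globally and pairs below
#' `min_global_identity` percent identity are dropped. For every retained
#' pair the protein alignment is expanded to a codon alignment through the
#' CDS, and the two `utr_threshold` nt upstream regions are aligned as
#' nucleotides.
#'
#' @param annot_a,annot_b `genome_annotation` objects (ORF data frames with
#'   `gene_id`, `start`, `end`, `strand`, `cds`, `protein`, plus `genome`).
#' @param cfg a [pipeline_config()].
#' @param hits optional external hit table (data frame with `qseqid`,
#'   `sseqid`, `pident`, `evalue`, `bitscore`; query = species a).
#' @return List of class `ortholog_set`: `pairs` (list of `ortholog_pair`
#'   objects) and `table` (gene_a, gene_b, protein_identity).
#' @export
build_single_copy_orthologs <- function(annot_a, annot_b,
                                        cfg = pipeline_config(),
                                        hits = NULL) {
  orfs_a <- annot_a$orfs; orfs_b <- annot_b$orfs
  if (anyDuplicated(orfs_a$gene_id) || anyDuplicated(orfs_b$gene_id)) {
    stop("duplicate gene ids")
  }
  pa <- Biostrings::AAStringSet(setNames(orfs_a$protein, orfs_a$gene_id))
  pb <- Biostrings::AAStringSet(setNames(orfs_b$protein, orfs_b$gene_id))

  if (is.null(hits)) {
    scores <- all_vs_all_scores(pa, pb)
    thr <- calibrate_score_threshold(pa, pb)
    scores[scores < thr] <- -Inf
  } else {
    scores <- matrix(-Inf, length(pa), length(pb),
                     dimnames = list(names(pa), names(pb)))
    keep <- hits$pident >= cfg$min_local_identity &
      hits$evalue <= cfg$ortho_max_evalue &
      hits$qseqid %in% rownames(scores) & hits$sseqid %in% colnames(scores)
    h <- hits[keep, , drop = FALSE]
    for (k in seq_len(nrow(h))) {
      scores[h$qseqid[k], h$sseqid[k]] <-
        max(scores[h$qseqid[k], h$sseqid[k]], h$bitscore[k])
    }
  }

  best_b_for_a <- apply(scores, 1L, function(x)
    if (all(!is.finite(x))) NA_integer_ else unique_which_max(x))
  best_a_for_b <- apply(scores, 2L, function(x)
    if (all(!is.finite(x))) NA_integer_ else unique_which_max(x))
  pairs_idx <- which(!is.na(best_b_for_a) &
                       best_a_for_b[best_b_for_a] == seq_along(best_b_for_a))
  ga <- rownames(scores)[pairs_idx]
  gb <- colnames(scores)[best_b_for_a[pairs_idx]]
  # single-copy guard: a gene may appear in at most one retained pair
  ok <- !(duplicated(ga) | duplicated(ga, fromLast = TRUE) |
            duplicated(gb) | duplicated(gb, fromLast = TRUE))
  ga <- ga[ok]; gb <- gb[ok]

  pairs <- list()
  for (k in seq_along(ga)) {
    ra <- orfs_a[orfs_a$gene_id == ga[k], ]
    rb <- orfs_b[orfs_b$gene_id == gb[k], ]
    aln <- global_align(ra$protein, rb$protein, type = "protein")
    if (aln$identity < cfg$min_global_identity) next
    utr_a <- utr_sequence(annot_a$genome, ra, cfg$utr_threshold)
    utr_b <- utr_sequence(annot_b$genome, rb, cfg$utr_threshold)
    utr_aln <- if (utr_a$len && utr_b$len) {
      global_align(utr_a$seq, utr_b$seq, type = "dna")
    } else {
      list(aligned_a = "", aligned_b = "", identity = NA_real_, score = NA_real_)
    }
    pairs[[length(pairs) + 1L]] <- structure(list(
      gene_a = ga[k], gene_b = gb[k],
      protein_identity = aln$identity,
      protein_alignment = aln,
      codon_alignment = expand_codon_alignment(aln, ra$cds, rb$cds),
      utr_alignment = utr_aln,
      utr_len_a = utr_a$len, utr_len_b = utr_b$len,
      orf_a = ra, orf_b = rb
    ), class = "ortholog_pair")
  }
  tab <- if (length(pairs)) {
    data.frame(
      gene_a = vapply(pairs, `[[`, character(1), "gene_a"),
      gene_b = vapply(pairs, `[[`, character(1), "gene_b"),
      protein_identity = vapply(pairs, `[[`, numeric(1), "protein_identity"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene_a = character(), gene_b = character(),
               protein_identity = numeric())
  }
  structure(list(pairs = pairs, table = tab), class = "ortholog_set")
}

# 5'-UTR window of a gene, 5'->3' on the gene strand, truncated at the
# replicon edge. Returns the sequence and its realized length.
utr_sequence <- function(genome, orf, utr_threshold) {
  L <- length(genome)
  if (orf$strand == "+") {
    from <- max(1L, orf$start - utr_threshold); to <- orf$start - 1L
    if (to < from) return(list(seq = "", len = 0L))
    list(seq = as.character(genome[from:to]), len = to - from + 1L)
  } else {
    from <- orf$end + 1L; to <- min(L, orf$end + utr_threshold)
    if (to < from) return(list(seq = "", len = 0L))
    s <- Biostrings::reverseComplement(genome[from:to])
    list(seq = as.character(s), len = to - from + 1L)
  }
}

# Expand a gapped protein alignment into a codon alignment using the CDSs
# (stop codon excluded). Each protein column becomes three nucleotide
# columns; a gap column becomes "---".
expand_codon_alignment <- function(protein_aln, cds_a, cds_b) {
  expand_row <- function(aligned, cds) {
    chars <- strsplit(aligned, "")[[1L]]
    naa <- sum(chars != "-")
    if (nchar(cds) < 3L * (naa + 1L)) stop("CDS/protein length mismatch")
    codons <- substring(cds, 3L * seq_len(naa) - 2L, 3L * seq_len(naa))
    out <- character(length(chars))
    ci <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") out[i] <- "---" else {
        ci <- ci + 1L
        out[i] <- codons[ci]
      }
    }
    paste(out, collapse = "")
  }
  list(aligned_a = expand_row(protein_aln$aligned_a, cds_a),
       aligned_b = expand_row(protein_aln$aligned_b, cds_b))
}

#' Build coordinate maps between genomic positions and alignment columns
#'
#' For an ortholog pair, returns maps that translate genomic coordinates
#' into codon-alignment columns (for internal/antisense TSSs) and
#' UTR-alignment columns (for genic TSSs), per species.
#'
#' @param pair an `ortholog_pair` from [build_single_copy_orthologs()].
#' @return A list of class `aln_coord_map` with `codon` and `utr` sub-maps;
#'   use [map_coordinate_to_column()] to query it.
#' @export
codon_alignment_map <- function(pair) {
  col_index <- function(aligned, unit = 1L) {
    chars <- strsplit(aligned, "")[[1L]]
    nongap <- which(chars != "-")
    if (unit == 1L) return(nongap)
    # codon row: each non-gap column holds `unit` nucleotides
    as.vector(vapply(nongap, function(cc) (cc - 1L) * unit + seq_len(unit),
                     integer(unit)))
  }
  codon_cols_a <- col_index(pair$protein_alignment$aligned_a, 3L)
  codon_cols_b <- col_index(pair$protein_alignment$aligned_b, 3L)
  utr_cols_a <- col_index(pair$utr_alignment$aligned_a)
  utr_cols_b <- col_index(pair$utr_alignment$aligned_b)
  structure(list(
    pair = pair,
    codon = list(a = codon_cols_a, b = codon_cols_b),
    utr = list(a = utr_cols_a, b = utr_cols_b)
  ), class = "aln_coord_map")
}

#' Map a genomic position to an alignment column
#'
#' Translates a genomic coordinate into a column of the codon alignment
#' (`region = "cds"`) or the 5'-UTR alignment (`region = "utr"`) of an
#' ortholog pair. Positions in regions where the partner row is gapped map
#' to their own non-gap column. Positions outside the aligned region (e.g. a
#' genic TSS beyond the UTR window, or a position in the stop codon, which
#' the codon alignment excludes) are not mappable and return `NA`.
#'
#' @param map an `aln_coord_map` from [codon_alignment_map()].
#' @param species `"a"` or `"b"`.
#' @param genomic_position 1-based genomic coordinate.
#' @param region `"cds"` or `"utr"`.
#' @return Integer alignment column, or `NA_integer_` when not mappable.
#' @export
map_coordinate_to_column <- function(map, species = c("a", "b"),
                                     genomic_position,
                                     region = c("cds", "utr")) {
  species <- match.arg(species)
  region <- match.arg(region)
  orf <- if (species == "a") map$pair$orf_a else map$pair$orf_b
  if (region == "cds") {
    k <- if (orf$strand == "+") genomic_position - orf$start + 1L else
      orf$end - genomic_position + 1L
    cols <- map$codon[[species]]
    if (is.na(k) || k < 1L || k > length(cols)) return(NA_integer_)
    cols[[k]]
  } else {
    ulen <- if (species == "a") map$pair$utr_len_a else map$pair$utr_len_b
    # UTR window ends immediately before the start codon; index 1 is the
    # window's farthest-upstream nucleotide in gene orientation
    k <- if (orf$strand == "+") genomic_position - (orf$start - ulen) + 1L else
      (orf$end + ulen) - genomic_position + 1L
    cols <- map$utr[[species]]
    if (is.na(k) || k < 1L || k > length(cols)) return(NA_integer_)
    cols[[k]]
  }
}

#' Write an ortholog table as TSV
#'
#' @param ortho an `ortholog_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(ortho, path) {
  write.table(ortho$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
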