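#' Species-specific 5'-UTR threshold from mean intergenic distance
#'
#' Computes the mean gap between consecutive ORFs on the same replicon
#' (gap = next start - previous end - 1; overlapping ORFs contribute 0).
#' With fewer than two ORFs on every replicon there is no gap to average
#' and the fixed 1000 nt default is returned.
#'
#' @param annotation a `genome_annotation` (or any list with an `orfs` data
#'   frame holding `replicon`, `start`, `end`).
#' @param default value returned when no intergenic gap exists.
#' @return Mean intergenic distance in nt.
#' @export
derive_utr_threshold <- function(annotation, default = 1000) {
  orfs <- annotation$orfs
  if (is.null(orfs) || !nrow(orfs)) stop("empty annotation")
  gaps <- unlist(lapply(split(orfs, orfs$replicon), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2L) return(numeric(0))
    pmax(d$start[-1L] - d$end[-nrow(d)] - 1L, 0)
  }))
  if (!length(gaps)) return(default)
  mean(gaps)
}

#' Classify TSSs by position relative to ORFs
#'
#' Each TSS is assigned every class that applies: genic (`g`) when a
#' same-strand ORF starts within `utr_threshold` nt downstream (distance
#' strictly positive, measured to the strand-aware start codon); internal
#' (`i`) when the TSS lies inside a same-strand ORF; antisense (`a`) when it
#' lies inside an opposite-strand ORF. A TSS fitting no class is intergenic
#' (`n`). The class set is rendered in the fixed order g, a, i (e.g. `"gi"`
#' for a genic-internal TSS). A genic TSS is associated with the nearest
#' qualifying downstream ORF only; internal and antisense TSSs with the ORF
#' containing them. ORFs are assumed non-overlapping within a strand.
#'
#' @param tss data frame with `replicon`, `position`, `strand` (e.g. from
#'   [unify_conditions()]).
#' @param orfs ORF data frame (`gene_id`, `replicon`, `start`, `end`,
#'   `strand`).
#' @param utr_threshold genic distance cutoff in nt.
#' @return `tss` with added columns `class_set`, `orf_g`, `orf_i`, `orf_a`.
#' @export
classify_tss <- function(tss, orfs, utr_threshold = 1000) {
  n <- nrow(tss)
  class_set <- character(n)
  orf_g <- orf_i <- orf_a <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    pos <- tss$position[j]; strd <- tss$strand[j]; repl <- tss$replicon[j]
    o <- orfs[orfs$replicon == repl, , drop = FALSE]
    same <- o$strand == strd
    inside <- o$start <= pos & pos <= o$end
    cls <- character(0)
    if (any(same & inside)) {
      cls <- c(cls, "i")
      orf_i[j] <- o$gene_id[same & inside][1L]
    }
    if (any(!same & inside)) {
      cls <- c(cls, "a")
      orf_a[j] <- o$gene_id[!same & inside][1L]
    }
    dist <- if (strd == "+") o$start - pos else pos - o$end
    qual <- same & dist > 0 & dist <= utr_threshold
    if (any(qual)) {
      cls <- c(cls, "g")
      orf_g[j] <- o$gene_id[qual][which.min(dist[qual])]
    }
    class_set[j] <- if (length(cls)) {
      paste(intersect(c("g", "a", "i"), cls), collapse = "")
    } else "n"
  }
  tss$class_set <- class_set
  tss$orf_g <- orf_g
  tss$orf_i <- orf_i
  tss$orf_a <- orf_a
  tss
}

#' Scan an upstream window for the -10 box consensus
#'
#' Searches for the Pribnow hexamer `T A N N N [T/A]` within a window of
#' offsets upstream of a TSS. The input string is oriented walking away from
#' the TSS: its first character is the nucleotide immediately upstream, so a
#' reported offset is the hexamer's distance (nt) from the TSS.
#'
#' @param upstream_seq character scalar, the upstream window (position 1 =
#'   nt immediately upstream of the TSS).
#' @param window integer length-2 vector, inclusive offset range scanned for
#'   the hexamer start.
#' @return Data frame with columns `offset` and `hexamer` (zero rows when
#'   nothing matches or the window lies outside the sequence).
#' @export
#' @examples
#' scan_pribnow("GGGGGGTACGGT", window = c(1, 12))
scan_pribnow <- function(upstream_seq, window = c(1, 20)) {
  upstream_seq <- as.character(upstream_seq)
  offs <- seq(window[1L], window[2L])
  offs <- offs[offs >= 1L & offs + 5L <= nchar(upstream_seq)]
  if (!length(offs)) {
    return(data.frame(offset = integer(), hexamer = character()))
  }
  hex <- substring(upstream_seq, offs, offs + 5L)
  hit <- grepl("^TA[ACGT]{3}[TA]$", hex)
  data.frame(offset = offs[hit], hexamer = hex[hit], stringsAsFactors = FALSE)
}

#' Extract the upstream window of a TSS in scan orientation
#'
#' Returns the `n` nt upstream of a TSS on the TSS strand, ordered walking
#' away from the TSS (position 1 = nt immediately upstream), the orientation
#' expected by [scan_pribnow()]. Truncated at replicon edges.
#'
#' @param genome a [Biostrings::DNAString].
#' @param position,strand TSS coordinate and strand.
#' @param n window length in nt.
#' @return Character scalar.
#' @export
upstream_sequence <- function(genome, position, strand, n = 20L) {
  L <- length(genome)
  if (strand == "+") {
    from <- max(1L, position - n); to <- position - 1L
    if (to < from) return("")
    s <- as.character(genome[from:to])
    paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  } else {
    from <- position + 1L; to <- min(L, position + n)
    if (to < from) return("")
    s <- Biostrings::complement(genome[from:to])
    as.character(s)
  }
}

#' Write per-class BED6 files for a classified TSS table
#'
#' @param tss classified TSS data frame (with `class_set`).
#' @param dir output directory.
#' @return Paths written, invisibly.
#' @export
write_class_bed <- function(tss, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in c("g", "a", "i", "n")) {
    sel <- if (cl == "n") tss$class_set == "n" else grepl(cl, tss$class_set)
    d <- tss[sel, , drop = FALSE]
    if (!nrow(d)) next
    bed <- data.frame(d$replicon, d$position - 1L, d$position, d$tss_id,
                      round(d$step_height, 2), d$strand)
    f <- file.path(dir, sprintf("tss_%s.bed", cl))
    write.table(bed, f, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
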