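#' Greedy one-to-one matching of TSSs by alignment-column distance
#'
#' Candidate pairs within `max_col_dist` alignment columns (gap columns
#' included) are accepted greedily by ascending distance, ties broken by the
#' smaller species-a column (then the smaller species-b column); each TSS
#' joins at most one pair. TSSs left unmatched are singletons.
#'
#' @param cols_a,cols_b named numeric vectors: TSS id -> alignment column
#'   (one ortholog pair, one class).
#' @param max_col_dist maximum column distance for an orthologous pair.
#' @return List with `pairs` (data frame `tss_a`, `tss_b`, `col_a`, `col_b`,
#'   `column_distance`) and `singletons` (data frame `tss_id`, `species`).
#' @export
match_orthologous_tss <- function(cols_a, cols_b, max_col_dist = 35) {
  empty_pairs <- data.frame(tss_a = character(), tss_b = character(),
                            col_a = integer(), col_b = integer(),
                            column_distance = integer(),
                            stringsAsFactors = FALSE)
  singles <- function(used_a, used_b) {
    sa <- setdiff(names(cols_a), used_a)
    sb <- setdiff(names(cols_b), used_b)
    data.frame(tss_id = c(sa, sb),
               species = c(rep("a", length(sa)), rep("b", length(sb))),
               stringsAsFactors = FALSE)
  }
  if (!length(cols_a) || !length(cols_b)) {
    return(list(pairs = empty_pairs, singletons = singles(character(0),
                                                          character(0))))
  }
  cand <- expand.grid(ia = seq_along(cols_a), ib = seq_along(cols_b))
  cand$dist <- abs(cols_a[cand$ia] - cols_b[cand$ib])
  cand <- cand[cand$dist <= max_col_dist, , drop = FALSE]
  cand <- cand[order(cand$dist, cols_a[cand$ia], cols_b[cand$ib]), ,
               drop = FALSE]
  used_a <- logical(length(cols_a)); used_b <- logical(length(cols_b))
  picked <- integer(0)
  for (r in seq_len(nrow(cand))) {
    ia <- cand$ia[r]; ib <- cand$ib[r]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      picked <- c(picked, r)
    }
  }
  pairs <- if (length(picked)) {
    data.frame(tss_a = names(cols_a)[cand$ia[picked]],
               tss_b = names(cols_b)[cand$ib[picked]],
               col_a = unname(cols_a[cand$ia[picked]]),
               col_b = unname(cols_b[cand$ib[picked]]),
               column_distance = unname(cand$dist[picked]),
               stringsAsFactors = FALSE)
  } else empty_pairs
  list(pairs = pairs,
       singletons = singles(pairs$tss_a, pairs$tss_b))
}

#' Nucleotide identity of two TSS locus windows
#'
#' Extracts the window of `flank` nt on each side of a TSS (2*flank + 1 nt,
#' truncated at replicon edges) on the TSS strand in both species, aligns
#' the two windows globally, and returns the percent identity over the
#' alignment length.
#'
#' @param genome_a,genome_b [Biostrings::DNAString] genomes.
#' @param pos_a,strand_a,pos_b,strand_b TSS coordinates and strands.
#' @param flank flank size in nt.
#' @return Percent identity (numeric scalar).
#' @export
locus_identity <- function(genome_a, pos_a, strand_a,
                           genome_b, pos_b, strand_b, flank = 35) {
  win <- function(genome, pos, strand) {
    L <- length(genome)
    from <- max(1L, pos - flank); to <- min(L, pos + flank)
    s <- genome[from:to]
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }
  global_align(win(genome_a, pos_a, strand_a),
               win(genome_b, pos_b, strand_b), type = "dna")$identity
}

# TSSs of one species associated with a given gene for a given class.
# g: via the nearest-downstream-ORF association; i: containing same-strand
# ORF; a: containing opposite-strand (sense) ORF.
tss_for_gene_class <- function(tss, gene_id, class) {
  col <- paste0("orf_", class)
  tss[!is.na(tss[[col]]) & tss[[col]] == gene_id, , drop = FALSE]
}

#' Positional orthologous TSS pairs for an ortholog set
#'
#' For every single-copy ortholog pair and every TSS class (g, a, i), TSSs
#' associated with the pair's genes are relocated into the shared alignment:
#' genic TSSs into the 5'-UTR alignment, internal and antisense TSSs into
#' the codon alignment (antisense TSSs through the sense ORF's coordinates).
#' TSSs at most `max_col_dist` alignment columns apart are matched greedily
#' into orthologous pairs; the rest are singletons. TSSs whose position
#' falls outside the aligned region are not mappable and are excluded. A
#' multi-class TSS participates in the matching of each of its classes. For
#' every matched pair the nucleotide identity of the two +/-`locus_flank` nt
#' TSS locus windows is computed.
#'
#' @param tss_a,tss_b classified unified TSS tables (from [classify_tss()]).
#' @param ortho an `ortholog_set` from [build_single_copy_orthologs()].
#' @param annot_a,annot_b the two `genome_annotation` objects.
#' @param cfg a [pipeline_config()].
#' @return Data frame with one row per orthologous pair or singleton:
#'   `gene_a`, `gene_b`, `class`, `tss_a`, `pos_a`, `tss_b`, `pos_b`,
#'   `column_distance`, `locus_identity`, `pair_status`.
#' @export
ortho_tss_pairs <- function(tss_a, tss_b, ortho, annot_a, annot_b,
                            cfg = pipeline_config()) {
  rows <- list()
  for (pair in ortho$pairs) {
    map <- codon_alignment_map(pair)
    for (cl in c("g", "a", "i")) {
      da <- tss_for_gene_class(tss_a, pair$gene_a, cl)
      db <- tss_for_gene_class(tss_b, pair$gene_b, cl)
      if (!nrow(da) && !nrow(db)) next
      region <- if (cl == "g") "utr" else "cds"
      ca <- vapply(da$position, function(p)
        map_coordinate_to_column(map, "a", p, region), integer(1))
      cb <- vapply(db$position, function(p)
        map_coordinate_to_column(map, "b", p, region), integer(1))
      keep_a <- !is.na(ca); keep_b <- !is.na(cb)
      da <- da[keep_a, , drop = FALSE]; ca <- ca[keep_a]
      db <- db[keep_b, , drop = FALSE]; cb <- cb[keep_b]
      if (!nrow(da) && !nrow(db)) next
      m <- match_orthologous_tss(setNames(ca, da$tss_id),
                                 setNames(cb, db$tss_id),
                                 max_col_dist = cfg$max_col_dist)
      if (nrow(m$pairs)) {
        pa <- da[match(m$pairs$tss_a, da$tss_id), ]
        pb <- db[match(m$pairs$tss_b, db$tss_id), ]
        li <- vapply(seq_len(nrow(m$pairs)), function(i) {
          locus_identity(annot_a$genome, pa$position[i], pa$strand[i],
                         annot_b$genome, pb$position[i], pb$strand[i],
                         flank = cfg$locus_flank)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = pair$gene_a, gene_b = pair$gene_b, class = cl,
          tss_a = m$pairs$tss_a, pos_a = pa$position,
          tss_b = m$pairs$tss_b, pos_b = pb$position,
          column_distance = m$pairs$column_distance,
          locus_identity = li, pair_status = "ortholog",
          stringsAsFactors = FALSE
        )
      }
      if (nrow(m$singletons)) {
        s <- m$singletons
        sp_a <- s$species == "a"
        pos <- integer(nrow(s))
        pos[sp_a] <- da$position[match(s$tss_id[sp_a], da$tss_id)]
        pos[!sp_a] <- db$position[match(s$tss_id[!sp_a], db$tss_id)]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = pair$gene_a, gene_b = pair$gene_b, class = cl,
          tss_a = ifelse(sp_a, s$tss_id, NA_character_),
          pos_a = ifelse(sp_a, pos, NA_integer_),
          tss_b = ifelse(sp_a, NA_character_, s$tss_id),
          pos_b = ifelse(sp_a, NA_integer_, pos),
          column_distance = NA_integer_, locus_identity = NA_real_,
          pair_status = ifelse(sp_a, "singleton_a", "singleton_b"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      class = character(), tss_a = character(),
                      pos_a = integer(), tss_b = character(),
                      pos_b = integer(), column_distance = integer(),
                      locus_identity = numeric(), pair_status = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
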