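#' @importFrom stats rnorm rpois runif setNames dnorm
#' @importFrom utils write.table
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")
# AT-rich base composition typical of the cyanobacterial genomes emulated here
BASE_PROBS <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)

sense_codons <- function() {
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all, STOP_CODONS)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE, prob = BASE_PROBS), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds)))
  sub("\\*$", "", aa)
}

# Per-site substitution at rate d; within CDS regions the first and last codon
# are kept intact and any codon mutated into a stop reverts, so every ORF
# still translates cleanly.
mutate_genome_chars <- function(chars, orfs, d) {
  if (d <= 0) return(chars)
  n <- length(chars)
  hit <- which(runif(n) < d)
  if (length(hit)) {
    cur <- chars[hit]
    sub <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), character(1))
    chars[hit] <- sub
  }
  for (k in seq_len(nrow(orfs))) {
    span <- orfs$start[k]:orfs$end[k]
    ref <- orfs$cds[k]
    got <- paste(chars[span], collapse = "")
    if (orfs$strand[k] == "-") got <- revcomp_chr(got)
    len <- nchar(ref)
    ncod <- len / 3L
    ref_cod <- substring(ref, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    got_cod <- substring(got, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    got_cod[1L] <- ref_cod[1L]
    got_cod[ncod] <- ref_cod[ncod]
    mid <- seq(2L, ncod - 1L)
    bad <- mid[got_cod[mid] %in% STOP_CODONS]
    got_cod[bad] <- ref_cod[bad]
    fixed <- paste(got_cod, collapse = "")
    if (orfs$strand[k] == "-") fixed <- revcomp_chr(fixed)
    chars[span] <- strsplit(fixed, "", fixed = TRUE)[[1L]]
  }
  chars
}

#' Generate the planted two-species ground truth
#'
#' Builds two linear replicons with identical gene layout: single-copy
#' orthologous ORFs separated by intergenic spacers, with the second species
#' derived from the first by per-site substitution at the configured
#' divergence (no indels, so homologous coordinates coincide). TSS loci of
#' the genic (g), internal (i), antisense (a) and intergenic (n) classes are
#' planted per gene; each g/i/a locus is orthologous (present in both species
#' at the homologous position) with probability `fraction_ortho_tss`,
#' otherwise lineage specific. Each locus carries per-condition transcription
#' levels; a configured fraction of orthologous loci receives a consistent
#' extreme log2 fold change of the same sign in both species.
#'
#' @param cfg a [sim_config()] object.
#' @return A list of class `synthetic_truth` with elements `annotations`
#'   (two `genome_annotation` lists: `genome` as a [Biostrings::DNAString],
#'   `orfs` data frame with CDS and protein sequences), `tss` (one row per
#'   planted site and species), `ortholog_genes`, and
#'   `consistent_candidates` (the planted extreme orthologous TSS pairs).
#' @export
#' @examples
#' truth <- generate_truth(sim_config(n_ortholog_pairs = 10, seed = 7))
#' nrow(truth$ortholog_genes)
generate_truth <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_ortholog_pairs
  sense <- sense_codons()

  spacer <- sample(cfg$spacer_range[1]:cfg$spacer_range[2], n, replace = TRUE)
  naa <- sample(cfg$aa_len_range[1]:cfg$aa_len_range[2], n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cds <- vapply(naa, function(k) {
    paste0("ATG", paste(sample(sense, k, replace = TRUE), collapse = ""),
           sample(STOP_CODONS, 1L))
  }, character(1))
  len <- nchar(cds)
  start <- integer(n); end <- integer(n); cursor <- 0L
  for (i in seq_len(n)) {
    start[i] <- cursor + spacer[i] + 1L
    end[i] <- start[i] + len[i] - 1L
    cursor <- end[i]
  }
  L <- cursor + cfg$tail_len

  seg <- character(2L * n + 1L)
  for (i in seq_len(n)) {
    seg[2L * i - 1L] <- random_dna(spacer[i])
    seg[2L * i] <- if (strand[i] == "+") cds[i] else revcomp_chr(cds[i])
  }
  seg[2L * n + 1L] <- random_dna(cfg$tail_len)
  chars_a <- strsplit(paste(seg, collapse = ""), "", fixed = TRUE)[[1L]]
  stopifnot(length(chars_a) == L)

  orfs_a <- data.frame(
    gene_id = sprintf("SA%04d", seq_len(n)), replicon = "chr_A",
    start = start, end = end, strand = strand, cds = cds,
    protein = translate_cds(cds), stringsAsFactors = FALSE
  )
  chars_b <- mutate_genome_chars(chars_a, orfs_a, cfg$divergence)
  cds_b <- vapply(seq_len(n), function(i) {
    s <- paste(chars_b[start[i]:end[i]], collapse = "")
    if (strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
  orfs_b <- data.frame(
    gene_id = sprintf("SB%04d", seq_len(n)), replicon = "chr_B",
    start = start, end = end, strand = strand, cds = cds_b,
    protein = translate_cds(cds_b), stringsAsFactors = FALSE
  )

  annot_a <- structure(list(species = "species_a", replicon = "chr_A",
                            genome = Biostrings::DNAString(paste(chars_a, collapse = "")),
                            orfs = orfs_a), class = "genome_annotation")
  annot_b <- structure(list(species = "species_b", replicon = "chr_B",
                            genome = Biostrings::DNAString(paste(chars_b, collapse = "")),
                            orfs = orfs_b), class = "genome_annotation")

  ident <- vapply(seq_len(n), function(i) {
    pa <- strsplit(orfs_a$protein[i], "")[[1L]]
    pb <- strsplit(orfs_b$protein[i], "")[[1L]]
    100 * mean(pa == pb)
  }, numeric(1))
  ortholog_genes <- data.frame(gene_a = orfs_a$gene_id, gene_b = orfs_b$gene_id,
                               protein_identity = ident, stringsAsFactors = FALSE)

  # upstream room available for a gTSS of gene i (the spacer on its 5' side)
  avail_up <- ifelse(strand == "+", spacer, c(spacer[-1L], cfg$tail_len))

  draw_offset <- function(gene, class, avoid = NULL) {
    repeat {
      o <- switch(class,
        g = sample(20:max(21L, min(200L, avail_up[gene] - 10L)), 1L),
        i = ,
        a = sample(30:(len[gene] - 30L), 1L)
      )
      if (is.null(avoid) || all(abs(o - avoid) > 50L)) return(o)
    }
  }
  locus_pos <- function(gene, class, offset) {
    if (class == "g") {
      if (strand[gene] == "+") start[gene] - offset else end[gene] + offset
    } else {
      if (strand[gene] == "+") start[gene] + offset else end[gene] - offset
    }
  }
  locus_strand <- function(gene, class) {
    s <- strand[gene]
    if (class == "a") c("+" = "-", "-" = "+")[[s]] else s
  }

  frac_ortho <- function(cl) {
    f <- cfg$fraction_ortho_tss
    if (length(f) > 1L) f[[cl]] else f
  }
  loci <- list()
  for (i in seq_len(n)) {
    for (cl in c("g", "i", "a")) {
      p <- switch(cl, g = cfg$p_gtss, i = cfg$p_itss, a = cfg$p_atss)
      if (runif(1) < p) {
        o <- draw_offset(i, cl)
        ortho <- runif(1) < frac_ortho(cl)
        loci[[length(loci) + 1L]] <- list(
          gene = i, class = cl, offset = o, ortho = ortho,
          species = if (ortho) "both" else sample(c("a", "b"), 1L)
        )
      }
    }
  }
  # extra lineage-specific sites at (gene, class) slots free in that species
  used <- vapply(loci, function(x) paste(x$gene, x$class), character(1))
  for (sp in c("a", "b")) {
    occupied <- used[vapply(loci, function(x) x$species %in% c("both", sp), logical(1))]
    free <- setdiff(as.vector(outer(seq_len(n), c("g", "i", "a"), paste)), occupied)
    pick <- sample(free, min(cfg$n_lineage_specific_tss, length(free)))
    for (slot in pick) {
      parts <- strsplit(slot, " ")[[1L]]
      g <- as.integer(parts[1L]); cl <- parts[2L]
      other <- Filter(function(x) x$gene == g && x$class == cl, loci)
      avoid <- if (length(other)) vapply(other, `[[`, numeric(1), "offset") else NULL
      loci[[length(loci) + 1L]] <- list(gene = g, class = cl,
                                        offset = draw_offset(g, cl, avoid),
                                        ortho = FALSE, species = sp)
    }
  }
  # intergenic sites in the gene-free tail, spaced apart
  tail_grid <- seq(end[n] + 200L, L - 100L, by = 80L)
  for (sp in c("a", "b")) {
    for (p in sample(tail_grid, min(cfg$n_intergenic_tss, length(tail_grid)))) {
      loci[[length(loci) + 1L]] <- list(gene = NA_integer_, class = "n",
                                        offset = NA_integer_, pos = p,
                                        ortho = FALSE, species = sp)
    }
  }

  nl <- length(loci)
  h_lo <- cfg$step_height_range[1]; h_hi <- cfg$step_height_range[2]
  rows <- vector("list", 2L * nl)
  cand <- list()
  k <- 0L
  for (j in seq_len(nl)) {
    x <- loci[[j]]
    pos <- if (x$class == "n") x$pos else locus_pos(x$gene, x$class, x$offset)
    strd <- if (x$class == "n") "+" else locus_strand(x$gene, x$class)
    extreme <- FALSE
    if (x$ortho && runif(1) < cfg$planted_extreme_fraction) {
      extreme <- TRUE
      h <- runif(1, (h_lo + h_hi) / 2, h_hi)
      sgn <- if (runif(1) < 0.7) 1 else -1
      fc <- c(a = sgn * runif(1, 4, 5), b = sgn * runif(1, 4, 5))
    } else {
      h <- runif(1, h_lo, h_hi)
      if (x$ortho) {
        common <- rnorm(1, 0, 0.4)
        fc <- common + c(a = rnorm(1, 0, 0.2), b = rnorm(1, 0, 0.2))
      } else {
        fc <- c(a = rnorm(1, 0, 0.45), b = rnorm(1, 0, 0.45))
      }
    }
    locus_id <- sprintf("locus%04d", j)
    species <- if (x$species == "both") c("a", "b") else x$species
    ids <- sprintf("%s_tss%04d", c(a = "SA", b = "SB")[species], j)
    names(ids) <- species
    for (sp in species) {
      k <- k + 1L
      hs <- h * 2^rnorm(1, 0, 0.1)
      rows[[k]] <- data.frame(
        site_id = ids[[sp]], locus_id = locus_id,
        species = c(a = "species_a", b = "species_b")[[sp]],
        replicon = c(a = "chr_A", b = "chr_B")[[sp]],
        gene_id = if (is.na(x$gene)) NA_character_ else
          c(a = orfs_a$gene_id[x$gene], b = orfs_b$gene_id[x$gene])[[sp]],
        class = x$class, strand = strd, position = pos,
        height = hs, fc = fc[[sp]],
        level_branchless = hs * 2^(fc[[sp]] / 2),
        level_true_branching = hs * 2^(-fc[[sp]] / 2),
        ortho = x$ortho,
        partner_site = if (x$ortho) ids[[setdiff(c("a", "b"), sp)]] else NA_character_,
        extreme = extreme, stringsAsFactors = FALSE
      )
    }
    if (extreme) {
      cand[[length(cand) + 1L]] <- data.frame(
        locus_id = locus_id, site_a = ids[["a"]], site_b = ids[["b"]],
        class = x$class, stringsAsFactors = FALSE
      )
    }
  }
  tss <- do.call(rbind, rows[seq_len(k)])
  stopifnot(all(tss$position >= 1 & tss$position <= L))
  consistent_candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(locus_id = character(), site_a = character(),
               site_b = character(), class = character())

  structure(list(
    annotations = list(species_a = annot_a, species_b = annot_b),
    tss = tss, ortholog_genes = ortholog_genes,
    consistent_candidates = consistent_candidates,
    replicon_length = L, cfg = cfg
  ), class = "synthetic_truth")
}

#' Planted TSS loci
#'
#' One row per planted locus (an orthologous pair counts once), with its
#' class, orthology status and extreme-consistency flag.
#'
#' @param truth a [generate_truth()] object.
#' @return A data frame with columns `locus_id`, `class`, `ortho`, `extreme`.
#' @export
planted_loci <- function(truth) {
  tss <- truth$tss
  first <- !duplicated(tss$locus_id)
  data.frame(locus_id = tss$locus_id[first], class = tss$class[first],
             ortho = tss$ortho[first], extreme = tss$extreme[first],
             stringsAsFactors = FALSE)
}

jitter_positions <- function(pos, sd, L) {
  if (sd <= 0 || length(pos) == 0L) return(pos)
  off <- -3:3
  p <- dnorm(off, 0, sd)
  pmin(pmax(pos + sample(off, length(pos), replace = TRUE, prob = p), 1L), L)
}

aggregate_ends <- function(strand, pos) {
  if (length(pos) == 0L) {
    return(data.frame(strand = character(), pos = integer(), count = integer()))
  }
  key <- paste(strand, pos)
  t <- table(key)
  parts <- strsplit(names(t), " ", fixed = TRUE)
  data.frame(strand = vapply(parts, `[[`, character(1), 1L),
             pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
             count = as.integer(t), stringsAsFactors = FALSE)
}

#' Simulate dRNA-seq libraries from the planted truth
#'
#' Emits, per species, four 5'-end libraries following the TEX-by-condition
#' design: TEX(+) and TEX(-) in each of the two phenotypic conditions. At
#' each planted TSS the TEX(+) library receives reads at the planted
#' per-condition level; the TEX(-) library receives the same signal divided
#' by the TEX enrichment ratio, emulating exonuclease depletion of primary
#' 5' ends in the untreated library. Uniform Poisson background is added on
#' both strands and read 5' ends receive truncated Gaussian positional
#' jitter. Each library carries both an aggregated 5'-end count table and
#' per-read alignment records (including a small admixture of
#' short-alignment and multi-mapping decoy reads that the alignment filters
#' are expected to remove).
#'
#' @param truth a [generate_truth()] object.
#' @param cfg the [sim_config()] used to generate `truth`.
#' @param seed integer seed for the library realization (independent of the
#'   truth seed).
#' @return A list of class `sim_libraries`: `libraries` (named list; each
#'   with `library_id`, `species`, `condition`, `tex_state`, `replicon`,
#'   `ends`, `alignments`) and `info` (one-row-per-library data frame).
#' @export
simulate_libraries <- function(truth, cfg = truth$cfg, seed = cfg$seed + 1000L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  L <- truth$replicon_length
  libs <- list()
  lib_sizes <- cfg$library_sizes
  li <- 0L
  for (sp in c("species_a", "species_b")) {
    sites <- truth$tss[truth$tss$species == sp, ]
    for (cond in CONDITIONS) {
      lev <- if (cond == "branchless") sites$level_branchless else
        sites$level_true_branching
      for (tex in TEX_STATES) {
        li <- li + 1L
        lam <- if (tex == "plus") lev else {
          if (is.infinite(cfg$tex_enrichment)) rep(0, length(lev)) else
            lev / cfg$tex_enrichment
        }
        bg_mass <- cfg$background_noise_rate * 2 * L
        if (!is.null(lib_sizes)) {
          N <- lib_sizes[((li - 1L) %% length(lib_sizes)) + 1L]
          w <- c(lam, bg_mass)
          draw <- sample.int(length(w), N, replace = TRUE, prob = w)
          counts <- tabulate(draw, nbins = length(w))
          site_counts <- counts[seq_along(lam)]
          nbg <- counts[length(w)]
        } else if (cfg$count_noise) {
          site_counts <- rpois(length(lam), lam)
          nbg <- rpois(1L, bg_mass)
        } else {
          site_counts <- round(lam)
          nbg <- round(bg_mass)
        }
        pos <- jitter_positions(rep(sites$position, site_counts),
                                cfg$jitter_sd, L)
        strd <- rep(sites$strand, site_counts)
        if (nbg > 0L) {
          pos <- c(pos, sample.int(L, nbg, replace = TRUE))
          strd <- c(strd, sample(c("+", "-"), nbg, replace = TRUE))
        }
        lib_id <- paste(sp, cond, tex, sep = ".")
        ends <- aggregate_ends(strd, pos)
        libs[[lib_id]] <- list(
          library_id = lib_id, species = sp, condition = cond,
          tex_state = tex, replicon = sites$replicon[1L],
          ends = ends,
          alignments = simulate_alignment_records(ends, L, sites$replicon[1L],
                                                  lib_id, cfg)
        )
      }
    }
  }
  info <- do.call(rbind, lapply(libs, function(x) data.frame(
    library_id = x$library_id, species = x$species, condition = x$condition,
    tex_state = x$tex_state, n_ends = sum(x$ends$count),
    stringsAsFactors = FALSE
  )))
  rownames(info) <- NULL
  structure(list(libraries = libs, info = info), class = "sim_libraries")
}

# Expand an aggregated 5'-end table into per-read alignment records, plus
# decoy reads that fail the span filter and reads with two equal-best hits.
simulate_alignment_records <- function(ends, L, replicon, lib_id, cfg,
                                       read_len = 50L) {
  n <- sum(ends$count)
  if (n == 0L) {
    return(data.frame(read_id = character(), read_length = integer(),
                      replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), gaps = integer(),
                      evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  pos <- rep(ends$pos, ends$count)
  strand <- rep(ends$strand, ends$count)
  mm <- sample(0:3, n, replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05))
  rec <- data.frame(
    read_id = sprintf("%s_r%07d", lib_id, seq_len(n)),
    read_length = read_len,
    replicon = replicon,
    start = ifelse(strand == "+", pos, pmax(pos - (read_len - 1L), 1L)),
    end = ifelse(strand == "+", pmin(pos + (read_len - 1L), L), pos),
    strand = strand, mismatches = mm, gaps = 0L,
    evalue = 1e-20, score = 100 - 2 * mm, stringsAsFactors = FALSE
  )
  nd <- round(cfg$decoy_fraction * n)
  if (nd > 0L) {
    p <- sample.int(L - 40L, nd, replace = TRUE)
    rec <- rbind(rec, data.frame(
      read_id = sprintf("%s_d%07d", lib_id, seq_len(nd)),
      read_length = read_len, replicon = replicon,
      start = p, end = p + 29L,
      strand = sample(c("+", "-"), nd, replace = TRUE),
      mismatches = 0L, gaps = 0L, evalue = 1e-20, score = 60,
      stringsAsFactors = FALSE
    ))
  }
  nm2 <- round(cfg$multimap_fraction * n)
  if (nm2 > 0L) {
    p1 <- sample.int(L - 60L, nm2, replace = TRUE)
    p2 <- sample.int(L - 60L, nm2, replace = TRUE)
    ids <- sprintf("%s_m%07d", lib_id, seq_len(nm2))
    dup <- data.frame(
      read_id = rep(ids, 2L), read_length = read_len, replicon = replicon,
      start = c(p1, p2), end = c(p1, p2) + (read_len - 1L),
      strand = "+", mismatches = 0L, gaps = 0L, evalue = 1e-20, score = 100,
      stringsAsFactors = FALSE
    )
    rec <- rbind(rec, dup)
  }
  rec
}

#' Write a simulated study to disk
#'
#' Writes genome and proteome FASTA, ORF GFF3, per-library strand-specific
#' 5'-end BedGraph tracks, and TSV truth tables into `dir`.
#'
#' @param truth a [generate_truth()] object.
#' @param libs a [simulate_libraries()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, libs, dir) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("write_simulation() needs the rtracklayer package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(truth$annotations)) {
    an <- truth$annotations[[sp]]
    g <- Biostrings::DNAStringSet(setNames(list(an$genome), an$replicon))
    Biostrings::writeXStringSet(g, file.path(dir, paste0(sp, "_genome.fa")))
    prot <- Biostrings::AAStringSet(setNames(an$orfs$protein, an$orfs$gene_id))
    Biostrings::writeXStringSet(prot, file.path(dir, paste0(sp, "_proteome.fa")))
    gr <- GenomicRanges::GRanges(
      seqnames = an$replicon,
      ranges = IRanges::IRanges(an$orfs$start, an$orfs$end),
      strand = an$orfs$strand, type = "CDS", ID = an$orfs$gene_id,
      phase = 0L
    )
    rtracklayer::export(gr, file.path(dir, paste0(sp, "_orfs.gff3")), format = "gff3")
  }
  for (lib in libs$libraries) {
    for (s in c("+", "-")) {
      e <- lib$ends[lib$ends$strand == s, ]
      if (!nrow(e)) next
      gr <- GenomicRanges::GRanges(lib$replicon, IRanges::IRanges(e$pos, e$pos),
                                   score = e$count)
      f <- file.path(dir, sprintf("%s_%s.bedgraph", lib$library_id,
                                  ifelse(s == "+", "fwd", "rev")))
      rtracklayer::export(gr, f, format = "bedGraph")
    }
  }
  write.table(truth$tss, file.path(dir, "planted_tss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$ortholog_genes, file.path(dir, "ortholog_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
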