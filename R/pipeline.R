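#' Run the per-species TSS inference pipeline
#'
#' Filters each library's read alignments, builds normalized strand-specific
#' 5'-end coverage, calls TSSs per condition from the TEX(+)/TEX(-) track
#' pair, clusters them, unifies the conditions and classifies the unified
#' TSSs against the ORF annotation.
#'
#' @param libs list of library objects for one species (each with
#'   `library_id`, `condition`, `tex_state`, `alignments`), e.g. the
#'   per-species subset of [simulate_libraries()] output.
#' @param annotation the species' `genome_annotation`.
#' @param cfg a [pipeline_config()].
#' @param rdna_regions optional rRNA operon intervals passed to
#'   [filter_alignments()].
#' @return List with `tss` (classified unified TSS table), `tracks`
#'   (normalized coverage tracks keyed by library id) and `meta` (library
#'   metadata).
#' @export
run_species_pipeline <- function(libs, annotation, cfg = pipeline_config(),
                                 rdna_regions = NULL) {
  meta <- do.call(rbind, lapply(libs, function(x) data.frame(
    library_id = x$library_id, condition = x$condition,
    tex_state = x$tex_state, stringsAsFactors = FALSE
  )))
  kept <- lapply(libs, function(x) {
    filter_alignments(x$alignments, rdna_regions = rdna_regions,
                      min_frac = cfg$min_aln_frac,
                      max_mm = cfg$max_mismatches,
                      max_evalue = cfg$max_evalue)
  })
  names(kept) <- vapply(libs, `[[`, character(1), "library_id")
  replicon_lengths <- setNames(length(annotation$genome), annotation$replicon)
  tracks <- coverage_from_alignments(kept, replicon_lengths)

  track_for <- function(cond, tex) {
    id <- meta$library_id[meta$condition == cond & meta$tex_state == tex]
    stopifnot(length(id) == 1L)
    tracks[[id]]
  }
  conds <- unique(meta$condition)
  per_cond <- list(); tex_plus <- list()
  for (cond in conds) {
    tp <- track_for(cond, "plus")
    tm <- track_for(cond, "minus")
    called <- call_tss(tp, tm, min_step = cfg$min_step,
                       min_enrich = cfg$min_enrich)
    per_cond[[cond]] <- cluster_tss(called, distance = cfg$cluster_distance)
    tex_plus[[cond]] <- tp
  }
  tss <- unify_conditions(per_cond, tex_plus, window = cfg$unify_window)
  tss <- classify_tss(tss, annotation$orfs, utr_threshold = cfg$utr_threshold)
  list(tss = tss, tracks = tracks, meta = meta)
}

#' Run the full two-species comparative TSS study
#'
#' Executes the whole analysis on a simulated (or equivalently structured)
#' study: per-species TSS inference and classification, single-copy ortholog
#' detection, positional orthologous TSS matching, fold-change consistency
#' screening, and the conservation statistics (per-class count table,
#' pairwise Fisher tests with FDR, linear-trend test over protein-identity
#' bins, Wilcoxon signed-rank of locus vs protein identity).
#'
#' @param truth a [generate_truth()] object (supplies the two annotations).
#' @param libs a [simulate_libraries()] object.
#' @param cfg a [pipeline_config()].
#' @return List of class `tss_study` with elements `tss` (per species),
#'   `orthologs`, `pairs`, `records`, `candidates`, `class_table`,
#'   `fisher`, `trend`, `wilcoxon`.
#' @export
run_comparative_study <- function(truth, libs, cfg = pipeline_config()) {
  by_species <- split(libs$libraries,
                      vapply(libs$libraries, `[[`, character(1), "species"))
  res_a <- run_species_pipeline(by_species$species_a,
                                truth$annotations$species_a, cfg)
  res_b <- run_species_pipeline(by_species$species_b,
                                truth$annotations$species_b, cfg)
  orthologs <- build_single_copy_orthologs(truth$annotations$species_a,
                                           truth$annotations$species_b, cfg)
  pairs <- ortho_tss_pairs(res_a$tss, res_b$tss, orthologs,
                           truth$annotations$species_a,
                           truth$annotations$species_b, cfg)
  records <- consistency_records(pairs, res_a$tss, res_b$tss,
                                 combine_stat = cfg$combine_stat)
  candidates <- select_consistent_candidates(records,
                                             fraction = cfg$candidate_fraction)
  class_table <- class_count_table_from_pairs(pairs)
  tabs <- list(
    "g_vs_a" = conservation_contingency(class_table, "g", "a"),
    "g_vs_i" = conservation_contingency(class_table, "g", "i"),
    "a_vs_i" = conservation_contingency(class_table, "a", "i")
  )
  fisher <- fisher_conservation_fdr(tabs)
  trend <- tryCatch({
    bins <- tss_conservation_by_identity(pairs, orthologs$table,
                                         breaks = seq(30, 100, by = 10))
    trend_test_linear(bins$n_ortholog, bins$n_total)
  }, error = function(e) NULL)
  wilcoxon <- lapply(setNames(c("g", "a", "i"), c("g", "a", "i")),
                     function(cl) {
    d <- pairs[pairs$class == cl & pairs$pair_status == "ortholog" &
                 !is.na(pairs$locus_identity), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    prot <- orthologs$table$protein_identity[match(d$gene_a,
                                                   orthologs$table$gene_a)]
    wilcoxon_paired(d$locus_identity, prot)
  })
  structure(list(
    tss = list(species_a = res_a$tss, species_b = res_b$tss),
    orthologs = orthologs, pairs = pairs, records = records,
    candidates = candidates, class_table = class_table,
    fisher = fisher, trend = trend, wilcoxon = wilcoxon, cfg = cfg
  ), class = "tss_study")
}

#' Evaluate a study against the planted truth
#'
#' Measures parameter recovery of the full pipeline on a synthetic study:
#' the fraction of planted TSSs with a called TSS within `tol` nt on the
#' same strand, the fraction of planted orthologous TSS pairs recovered as
#' matched pairs (both members within `tol` nt), the number of matched
#' pairs whose members do not descend from planted partner sites (false
#' matches), the number of matched pairs exceeding the column-distance
#' cutoff, and the fraction of planted extreme-consistent pairs present in
#' the candidate set.
#'
#' @param study a [run_comparative_study()] result.
#' @param truth the [generate_truth()] object.
#' @param tol positional tolerance in nt.
#' @return List of recovery metrics.
#' @export
evaluate_recovery <- function(study, truth, tol = 5) {
  near <- function(tss, site) {
    sel <- tss$replicon == site$replicon & tss$strand == site$strand &
      abs(tss$position - site$position) <= tol
    any(sel)
  }
  planted <- truth$tss
  called <- rbind(
    cbind(study$tss$species_a[c("replicon", "position", "strand")]),
    cbind(study$tss$species_b[c("replicon", "position", "strand")])
  )
  rec <- vapply(seq_len(nrow(planted)), function(i)
    near(called, planted[i, ]), logical(1))
  tss_recovery <- mean(rec)

  # map called TSS ids to planted site ids (nearest within tol)
  site_of <- function(tss_tab, species) {
    ps <- planted[planted$species == species, ]
    vapply(seq_len(nrow(tss_tab)), function(i) {
      d <- abs(ps$position - tss_tab$position[i])
      sel <- which(ps$strand == tss_tab$strand[i] & d <= tol)
      if (!length(sel)) return(NA_character_)
      ps$site_id[sel[which.min(d[sel])]]
    }, character(1))
  }
  map_a <- setNames(site_of(study$tss$species_a, "species_a"),
                    study$tss$species_a$tss_id)
  map_b <- setNames(site_of(study$tss$species_b, "species_b"),
                    study$tss$species_b$tss_id)

  mp <- study$pairs[study$pairs$pair_status == "ortholog", , drop = FALSE]
  key <- paste(mp$tss_a, mp$tss_b)
  mp1 <- mp[!duplicated(key), , drop = FALSE]
  origin_a <- map_a[mp1$tss_a]
  origin_b <- map_b[mp1$tss_b]
  partner_of <- setNames(planted$partner_site, planted$site_id)
  is_true <- !is.na(origin_a) & !is.na(origin_b) &
    !is.na(partner_of[origin_a]) & partner_of[origin_a] == origin_b
  n_false_matches <- sum(!is_true)

  planted_pairs <- planted[planted$species == "species_a" & planted$ortho &
                             planted$class %in% c("g", "a", "i"), ]
  pair_rec <- vapply(seq_len(nrow(planted_pairs)), function(i) {
    sa <- planted_pairs$site_id[i]; sb <- planted_pairs$partner_site[i]
    any(!is.na(origin_a) & origin_a == sa & !is.na(origin_b) & origin_b == sb)
  }, logical(1))
  pair_recovery <- mean(pair_rec)

  cand <- study$candidates[study$candidates$candidate, , drop = FALSE]
  cand_origin <- paste(map_a[cand$tss_a], map_b[cand$tss_b])
  tc <- truth$consistent_candidates
  extreme_rec <- if (nrow(tc)) {
    mean(paste(tc$site_a, tc$site_b) %in% cand_origin)
  } else NA_real_

  list(
    tss_recovery = tss_recovery,
    pair_recovery = pair_recovery,
    n_false_matches = n_false_matches,
    n_matched_beyond_cutoff = sum(mp1$column_distance >
                                    study$cfg$max_col_dist),
    extreme_candidate_recovery = extreme_rec,
    n_planted = nrow(planted),
    n_planted_pairs = nrow(planted_pairs),
    n_planted_extreme = nrow(tc),
    n_candidates = nrow(cand)
  )
}

#' Write the study report
#'
#' Writes the master TSS tables, ortholog table, orthologous-TSS pair
#' table, fold-change candidate table, per-class count table and test
#' results as TSV files.
#'
#' @param study a [run_comparative_study()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_master_table(study$tss$species_a, file.path(dir, "tss_species_a.tsv"))
  write_master_table(study$tss$species_b, file.path(dir, "tss_species_b.tsv"))
  write_ortholog_table(study$orthologs, file.path(dir, "orthologs.tsv"))
  write.table(study$pairs, file.path(dir, "ortho_tss_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidate_table(study$candidates, file.path(dir, "candidates.tsv"))
  write.table(study$class_table, file.path(dir, "class_count_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$fisher, file.path(dir, "fisher_fdr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
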