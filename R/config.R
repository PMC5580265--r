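#' Pipeline configuration
#'
#' Collects every threshold used by the TSS inference and comparative stages
#' in one validated list. Defaults are the operational values of the study
#' design this package implements: 50 bp single-end dRNA-seq reads, a 20 nt
#' minimum read length after poly-A/poly-T clipping, alignments kept when they
#' span at least 80\% of the read with at most 4 mismatches and no gaps,
#' 30 bp TSS clustering within a condition, a 35 bp window for unifying TSSs
#' across conditions and for positional TSS orthology, a 1000 nt 5'-UTR
#' window for genic classification, a 30\% global-identity floor for
#' single-copy orthologs, and a 5\% tail for consistent fold-change
#' candidates.
#'
#' @param min_read_len minimum read length (nt) after clipping.
#' @param min_aln_frac minimum alignment length as a fraction of read length.
#' @param max_mismatches maximum mismatches per kept alignment.
#' @param max_evalue maximum e-value for a read alignment.
#' @param min_step minimum 5'-end coverage step (normalized units) for a TSS.
#' @param min_enrich minimum TEX(+)/TEX(-) pseudocounted enrichment ratio.
#' @param cluster_distance chain-linkage clustering distance (bp) within a
#'   condition.
#' @param unify_window clustering window (bp) when unifying TSSs across
#'   conditions.
#' @param utr_threshold 5'-UTR length (nt) used for genic classification and
#'   UTR alignments.
#' @param pribnow_window offsets (nt upstream of the TSS, inclusive range)
#'   scanned for the -10 box hexamer.
#' @param ortho_max_evalue maximum e-value for candidate protein hits when
#'   external tabular hits are supplied.
#' @param min_local_identity minimum percent identity for candidate protein
#'   hits.
#' @param min_global_identity minimum percent identity of the global protein
#'   alignment for a retained ortholog pair.
#' @param max_col_dist maximum alignment-column distance (columns, gaps
#'   included) for two TSSs to be called positional orthologs.
#' @param locus_flank flank (nt) on each side of a TSS defining its locus
#'   window.
#' @param candidate_fraction fraction of fold-change pairs flagged as extreme
#'   consistent candidates.
#' @param combine_stat statistic combining the two species' log2 fold
#'   changes when ranking candidates: `"sum"`, `"min"` or `"product"`.
#'
#' @return A list of class `tss_pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$max_col_dist
pipeline_config <- function(min_read_len = 20,
                            min_aln_frac = 0.8,
                            max_mismatches = 4,
                            max_evalue = 1e-4,
                            min_step = 5,
                            min_enrich = 2,
                            cluster_distance = 30,
                            unify_window = 35,
                            utr_threshold = 1000,
                            pribnow_window = c(1, 20),
                            ortho_max_evalue = 1e-10,
                            min_local_identity = 30,
                            min_global_identity = 30,
                            max_col_dist = 35,
                            locus_flank = 35,
                            candidate_fraction = 0.05,
                            combine_stat = c("sum", "min", "product")) {
  combine_stat <- match.arg(combine_stat)
  cfg <- list(
    min_read_len = min_read_len, min_aln_frac = min_aln_frac,
    max_mismatches = max_mismatches, max_evalue = max_evalue,
    min_step = min_step, min_enrich = min_enrich,
    cluster_distance = cluster_distance, unify_window = unify_window,
    utr_threshold = utr_threshold, pribnow_window = pribnow_window,
    ortho_max_evalue = ortho_max_evalue,
    min_local_identity = min_local_identity,
    min_global_identity = min_global_identity,
    max_col_dist = max_col_dist, locus_flank = locus_flank,
    candidate_fraction = candidate_fraction, combine_stat = combine_stat
  )
  stopifnot(
    min_read_len >= 1, min_aln_frac > 0, min_aln_frac <= 1,
    max_mismatches >= 0, cluster_distance >= 0, unify_window >= 0,
    utr_threshold >= 1, max_col_dist >= 0, locus_flank >= 0,
    candidate_fraction >= 0, candidate_fraction <= 1
  )
  structure(cfg, class = "tss_pipeline_config")
}

#' Synthetic-study configuration
#'
#' Parameters of the two-species synthetic study that the generator in
#' [generate_truth()] and [simulate_libraries()] emulates: two diverged
#' genomes of single-copy orthologous ORFs, planted orthologous and
#' lineage-specific TSSs of the genic/internal/antisense/intergenic classes,
#' TEX(+)/TEX(-) 5'-end libraries in two phenotypic conditions, and a planted
#' subset of orthologous TSS pairs with consistent extreme fold changes.
#'
#' @param n_ortholog_pairs number of single-copy orthologous ORF pairs.
#' @param n_lineage_specific_tss extra lineage-specific TSSs planted per
#'   species, beyond the per-locus orthology lottery.
#' @param n_intergenic_tss intergenic (nTSS) sites planted per species in the
#'   gene-free tail of the replicon.
#' @param divergence per-site substitution probability separating the two
#'   genomes.
#' @param fraction_ortho_tss probability that a planted TSS locus is
#'   orthologous (present in both species at the homologous position);
#'   either a scalar or a named vector with entries `g`, `i`, `a` for
#'   class-specific conservation.
#' @param planted_extreme_fraction fraction of orthologous TSS loci given a
#'   consistent extreme fold change in both species.
#' @param p_gtss,p_itss,p_atss per-gene probabilities of planting a genic,
#'   internal, antisense TSS locus.
#' @param step_height_range range (normalized coverage units) of planted TSS
#'   base heights, drawn uniformly.
#' @param tex_enrichment expected TEX(+)/TEX(-) signal ratio at primary 5'
#'   ends; `Inf` removes all TEX(-) signal.
#' @param background_noise_rate expected background 5' ends per position and
#'   strand (Poisson).
#' @param jitter_sd standard deviation (nt) of the truncated Gaussian jitter
#'   applied to read 5' ends; 0 disables jitter.
#' @param count_noise logical; draw per-TSS read counts from a Poisson
#'   distribution (`TRUE`) or use the expected counts deterministically.
#' @param library_sizes optional vector of exact 5'-end totals per library
#'   (recycled over the TEX-by-condition design); `NULL` lets totals follow
#'   the planted intensities.
#' @param decoy_fraction fraction of extra reads per library emitted with a
#'   sub-threshold alignment span (exercises the alignment filters).
#' @param multimap_fraction fraction of extra reads per library emitted with
#'   two equally scoring alignments (exercises the multi-mapper filter).
#' @param aa_len_range ORF lengths in amino acids (uniform range).
#' @param spacer_range intergenic spacer lengths in nt (uniform range).
#' @param tail_len gene-free tail (nt) appended to the replicon, hosting the
#'   planted intergenic TSSs.
#' @param seed integer seed making the whole study reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ortholog_pairs = 200,
                       n_lineage_specific_tss = 20,
                       n_intergenic_tss = 10,
                       divergence = 0.05,
                       fraction_ortho_tss = 0.7,
                       planted_extreme_fraction = 0.03,
                       p_gtss = 0.9, p_itss = 0.5, p_atss = 0.45,
                       step_height_range = c(100, 400),
                       tex_enrichment = 10,
                       background_noise_rate = 0.1,
                       jitter_sd = 1,
                       count_noise = TRUE,
                       library_sizes = NULL,
                       decoy_fraction = 0.02,
                       multimap_fraction = 0.005,
                       aa_len_range = c(120, 280),
                       spacer_range = c(250, 500),
                       tail_len = 5000,
                       seed = 1L) {
  cfg <- list(
    n_ortholog_pairs = n_ortholog_pairs,
    n_lineage_specific_tss = n_lineage_specific_tss,
    n_intergenic_tss = n_intergenic_tss,
    divergence = divergence,
    fraction_ortho_tss = fraction_ortho_tss,
    planted_extreme_fraction = planted_extreme_fraction,
    p_gtss = p_gtss, p_itss = p_itss, p_atss = p_atss,
    step_height_range = step_height_range,
    tex_enrichment = tex_enrichment,
    background_noise_rate = background_noise_rate,
    jitter_sd = jitter_sd,
    count_noise = count_noise,
    library_sizes = library_sizes,
    decoy_fraction = decoy_fraction,
    multimap_fraction = multimap_fraction,
    aa_len_range = aa_len_range,
    spacer_range = spacer_range,
    tail_len = tail_len,
    seed = as.integer(seed)
  )
  if (!length(fraction_ortho_tss) %in% c(1L, 3L)) {
    stop("fraction_ortho_tss must be a scalar or a length-3 vector (g, i, a)")
  }
  fot <- fraction_ortho_tss
  if (is.null(names(fot))) {
    names(fot) <- rep("fraction_ortho_tss", length(fot))
  }
  fracs <- c(divergence = divergence, fot,
             planted_extreme_fraction = planted_extreme_fraction,
             p_gtss = p_gtss, p_itss = p_itss, p_atss = p_atss,
             decoy_fraction = decoy_fraction,
             multimap_fraction = multimap_fraction)
  bad <- fracs < 0 | fracs > 1 | !is.finite(fracs)
  if (any(bad)) {
    stop("sim_config fractions must lie in [0, 1]: ",
         paste(names(fracs)[bad], collapse = ", "))
  }
  if (background_noise_rate < 0) stop("background_noise_rate must be >= 0")
  if (tex_enrichment <= 0) stop("tex_enrichment must be > 0 (Inf allowed)")
  structure(cfg, class = "sim_config")
}

# The two phenotypic conditions of the study design.
CONDITIONS <- c("branchless", "true_branching")
TEX_STATES <- c("plus", "minus")
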