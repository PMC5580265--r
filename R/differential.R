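#' Condition log2 fold change of a TSS
#'
#' `log2(level_branchless / level_true_branching)`, defined only when both
#' levels are strictly positive; a TSS silent in either condition is
#' excluded (`NA`), with no pseudocount smoothing.
#'
#' @param level_bl,level_tb normalized transcription levels (vectors).
#' @return Numeric vector of log2 fold changes, `NA` where excluded.
#' @export
#' @examples
#' fold_change(8, 2)
fold_change <- function(level_bl, level_tb) {
  if (any(level_bl < 0, na.rm = TRUE) || any(level_tb < 0, na.rm = TRUE)) {
    stop("negative transcription level")
  }
  ifelse(level_bl > 0 & level_tb > 0, log2(level_bl / level_tb), NA_real_)
}

quadrant_of <- function(fc_a, fc_b) {
  ifelse(is.na(fc_a) | is.na(fc_b) | fc_a == 0 | fc_b == 0, NA_character_,
         ifelse(fc_a > 0 & fc_b > 0, "I",
                ifelse(fc_a < 0 & fc_b > 0, "II",
                       ifelse(fc_a < 0 & fc_b < 0, "III", "IV"))))
}

combined_fc <- function(fc_a, fc_b, stat = "sum") {
  switch(stat,
         sum = fc_a + fc_b,
         min = sign(fc_a) * pmin(abs(fc_a), abs(fc_b)),
         product = fc_a * fc_b,
         stop("unknown combine_stat"))
}

#' Fold-change consistency records for orthologous TSS pairs
#'
#' Builds, for every matched orthologous TSS pair, the per-species log2
#' fold changes, the fold-change quadrant (I: up in both species in the
#' branchless condition; III: down in both; II/IV: inconsistent) and the
#' combined score used to rank candidates. Pairs where either species'
#' fold change is undefined (zero level in a condition) are dropped. A pair
#' matched under several TSS classes is counted once.
#'
#' @param pairs data frame of orthologous pairs (rows of
#'   [ortho_tss_pairs()] with `pair_status == "ortholog"`).
#' @param tss_a,tss_b unified TSS tables carrying `level_branchless` and
#'   `level_true_branching` columns.
#' @param combine_stat ranking statistic, see [pipeline_config()].
#' @return Data frame with `tss_a`, `tss_b`, `classes`, `fc_a`, `fc_b`,
#'   `quadrant`, `combined_score`.
#' @export
consistency_records <- function(pairs, tss_a, tss_b, combine_stat = "sum") {
  p <- pairs[pairs$pair_status == "ortholog", , drop = FALSE]
  if (!nrow(p)) {
    return(data.frame(tss_a = character(), tss_b = character(),
                      classes = character(), fc_a = numeric(),
                      fc_b = numeric(), quadrant = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(p$tss_a, p$tss_b)
  classes <- vapply(split(p$class, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  first <- !duplicated(key)
  p <- p[first, , drop = FALSE]
  p$classes <- classes[paste(p$tss_a, p$tss_b)]
  ia <- match(p$tss_a, tss_a$tss_id)
  ib <- match(p$tss_b, tss_b$tss_id)
  fc_a <- fold_change(tss_a$level_branchless[ia],
                      tss_a$level_true_branching[ia])
  fc_b <- fold_change(tss_b$level_branchless[ib],
                      tss_b$level_true_branching[ib])
  ok <- !is.na(fc_a) & !is.na(fc_b)
  data.frame(tss_a = p$tss_a[ok], tss_b = p$tss_b[ok],
             classes = p$classes[ok], fc_a = fc_a[ok], fc_b = fc_b[ok],
             quadrant = quadrant_of(fc_a[ok], fc_b[ok]),
             combined_score = combined_fc(fc_a[ok], fc_b[ok], combine_stat),
             stringsAsFactors = FALSE)
}

#' Select consistent extreme fold-change candidates
#'
#' Flags the `ceil(fraction * n)` records (n = all records with both fold
#' changes defined) whose combined fold change is most extreme, restricted
#' to same-sign records (quadrants I and III); inconsistent pairs are never
#' candidates. Ties are broken deterministically towards the smaller
#' species-a TSS id.
#'
#' @param records data frame from [consistency_records()].
#' @param fraction tail fraction of the fold-change distribution.
#' @return `records` with a logical `candidate` column.
#' @export
select_consistent_candidates <- function(records, fraction = 0.05) {
  records$candidate <- logical(nrow(records))
  n_total <- nrow(records)
  if (!n_total) return(records)
  k <- ceiling(fraction * n_total)
  eligible <- which(records$quadrant %in% c("I", "III"))
  if (!length(eligible) || k == 0L) return(records)
  ord <- eligible[order(-abs(records$combined_score[eligible]),
                        records$tss_a[eligible])]
  records$candidate[ord[seq_len(min(k, length(ord)))]] <- TRUE
  records
}

#' Write the candidate table as TSV
#'
#' @param records output of [select_consistent_candidates()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
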