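#' Call TSSs from TEX(+)/TEX(-) coverage
#'
#' A position is called as a TSS when the 5'-end coverage in the
#' TEX(+) (primary-transcript-enriched) library rises by at least `min_step`
#' relative to the immediately upstream position, and the pseudocounted
#' TEX(+)/TEX(-) ratio `(texplus + 1) / (texminus + 1)` is at least
#' `min_enrich`. The step discriminates transcript 5' ends from internal
#' coverage; the enrichment discriminates primary (5'-PPP) from processed
#' (5'-P) ends, which survive the exonuclease in the TEX(-) library.
#'
#' @param tex_plus,tex_minus coverage tracks (elements of
#'   [coverage_from_alignments()] output) over the same replicons/strands.
#' @param min_step minimum coverage step (normalized units).
#' @param min_enrich minimum enrichment ratio.
#' @return Data frame with columns `replicon`, `position`, `strand`,
#'   `step_height`, `enrichment`, `level` (TEX(+) coverage at the position).
#' @export
call_tss <- function(tex_plus, tex_minus, min_step = 5, min_enrich = 2) {
  if (!identical(sort(names(tex_plus$cov)), sort(names(tex_minus$cov)))) {
    stop("TEX(+) and TEX(-) tracks cover different replicons/strands")
  }
  out <- list()
  for (k in names(tex_plus$cov)) {
    p <- tex_plus$cov[[k]]
    m <- tex_minus$cov[[k]]
    if (length(p) != length(m)) stop("mismatched track lengths for ", k)
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    # replicon-edge positions have no upstream neighbour and are not callable
    upstream <- if (parts[2L] == "+") c(p[1L], p[-length(p)]) else
      c(p[-1L], p[length(p)])
    step <- p - upstream
    enrich <- (p + 1) / (m + 1)
    hit <- which(step >= min_step & enrich >= min_enrich)
    if (length(hit)) {
      out[[k]] <- data.frame(
        replicon = parts[1L], position = hit, strand = parts[2L],
        step_height = step[hit], enrichment = enrich[hit], level = p[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(replicon = character(), position = integer(),
                      strand = character(), step_height = numeric(),
                      enrichment = numeric(), level = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Chain-linkage clustering of sorted positions: consecutive positions no more
# than `distance` apart join one cluster. Returns an integer cluster id per
# row of `pos` (which must be sorted ascending).
chain_clusters <- function(pos, distance) {
  if (!length(pos)) return(integer(0))
  cumsum(c(1L, as.integer(diff(pos) > distance)))
}

#' Cluster called TSSs
#'
#' Chain-linkage clustering per replicon and strand: consecutive sorted
#' positions at most `distance` bp apart join one cluster, and each cluster
#' is reduced to its highest-step member (ties broken towards the smallest
#' coordinate). Opposite strands are never clustered together.
#'
#' @param tss data frame as returned by [call_tss()].
#' @param distance clustering distance in bp.
#' @return Data frame of cluster representatives, same columns as `tss`.
#' @export
cluster_tss <- function(tss, distance = 30) {
  if (!nrow(tss)) return(tss)
  pieces <- split(tss, paste(tss$replicon, tss$strand))
  out <- lapply(pieces, function(d) {
    d <- d[order(d$position), , drop = FALSE]
    cl <- chain_clusters(d$position, distance)
    keep <- vapply(split(seq_len(nrow(d)), cl), function(idx) {
      h <- d$step_height[idx]
      idx[h == max(h)][1L]  # sorted by position, so first max = smallest coord
    }, integer(1))
    d[sort(keep), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$replicon, res$strand, res$position), , drop = FALSE]
}

#' Unify per-condition TSS sets
#'
#' Pools the clustered TSS lists of all conditions and re-clusters them with
#' a (chain-linkage) sliding window, keeping the highest-step TSS of each
#' cluster as the representative position. The per-condition transcription
#' level of every unified TSS is then read from each condition's normalized
#' TEX(+) coverage at the representative position (0 when the TSS is silent
#' in that condition).
#'
#' @param per_condition_tss named list (condition -> clustered TSS data
#'   frame from [cluster_tss()]).
#' @param tex_plus_tracks named list (condition -> TEX(+) coverage track).
#' @param window clustering window in bp.
#' @return Data frame with columns `tss_id`, `replicon`, `position`,
#'   `strand`, `step_height`, `enrichment` and one `level_<condition>`
#'   column per condition.
#' @export
unify_conditions <- function(per_condition_tss, tex_plus_tracks, window = 35) {
  conds <- names(per_condition_tss)
  stopifnot(length(conds) >= 1L, all(conds %in% names(tex_plus_tracks)))
  pooled <- do.call(rbind, lapply(conds, function(cn) {
    d <- per_condition_tss[[cn]]
    if (nrow(d)) cbind(d, condition = cn, stringsAsFactors = FALSE) else NULL
  }))
  lev_cols <- paste0("level_", conds)
  if (is.null(pooled) || !nrow(pooled)) {
    empty <- data.frame(tss_id = character(), replicon = character(),
                        position = integer(), strand = character(),
                        step_height = numeric(), enrichment = numeric())
    for (lc in lev_cols) empty[[lc]] <- numeric(0)
    return(empty)
  }
  pieces <- split(pooled, paste(pooled$replicon, pooled$strand))
  reps <- lapply(pieces, function(d) {
    d <- d[order(d$position, -d$step_height), , drop = FALSE]
    cl <- chain_clusters(d$position, window)
    keep <- vapply(split(seq_len(nrow(d)), cl), function(idx) {
      h <- d$step_height[idx]
      idx[h == max(h)][1L]
    }, integer(1))
    d[sort(keep), , drop = FALSE]
  })
  res <- do.call(rbind, reps)
  for (cn in conds) {
    cov <- tex_plus_tracks[[cn]]$cov
    key <- paste0(res$replicon, "|", res$strand)
    res[[paste0("level_", cn)]] <- vapply(seq_len(nrow(res)), function(i) {
      cov[[key[i]]][res$position[i]]
    }, numeric(1))
  }
  res <- res[order(res$replicon, res$strand, res$position), , drop = FALSE]
  res$tss_id <- sprintf("tss:%s:%d:%s", res$replicon, res$position, res$strand)
  rownames(res) <- NULL
  res[, c("tss_id", "replicon", "position", "strand", "step_height",
          "enrichment", lev_cols)]
}

#' Write a TSS master table
#'
#' Writes the unified, classified TSS table as TSV (one row per TSS with
#' position, step height, enrichment, per-condition levels and class flags).
#'
#' @param tss unified (optionally classified) TSS data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_master_table <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
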