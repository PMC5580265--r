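#' Per-class TSS conservation counts
#'
#' Assembles the per-class summary of positional TSS orthology: total TSSs
#' of the class found in orthologous genes (both species pooled), the number
#' of orthologous gene pairs contributing at least one TSS of the class in
#' either species, the mean number of TSSs per contributing gene pair
#' (2 decimals), the number of orthologous TSSs (members of matched pairs;
#' two per pair), the lineage-specific (singleton) count, and
#' integer-rounded percentages.
#'
#' @param n_tss,n_ortho_genes,n_ortho_tss numeric vectors, one entry per
#'   class.
#' @param classes class labels.
#' @return Data frame with one row per class and columns `class`, `n_tss`,
#'   `n_ortho_genes`, `mean_tss_per_pair`, `n_ortho_tss`, `n_singleton`,
#'   `pct_ortho`, `pct_singleton`.
#' @export
#' @examples
#' class_count_table(5112, 2264, 1622, classes = "g")
class_count_table <- function(n_tss, n_ortho_genes, n_ortho_tss,
                              classes = c("g", "a", "i")) {
  stopifnot(length(n_tss) == length(classes),
            length(n_ortho_genes) == length(classes),
            length(n_ortho_tss) == length(classes),
            all(n_ortho_tss <= n_tss))
  mean_tss <- ifelse(n_ortho_genes > 0, round(n_tss / n_ortho_genes, 2), 0)
  pct_ortho <- ifelse(n_tss > 0, round(100 * n_ortho_tss / n_tss), 0)
  data.frame(
    class = classes, n_tss = n_tss, n_ortho_genes = n_ortho_genes,
    mean_tss_per_pair = mean_tss, n_ortho_tss = n_ortho_tss,
    n_singleton = n_tss - n_ortho_tss,
    pct_ortho = pct_ortho,
    pct_singleton = ifelse(n_tss > 0, 100 - pct_ortho, 0),
    stringsAsFactors = FALSE
  )
}

#' Per-class conservation counts from matched TSS pairs
#'
#' Derives the [class_count_table()] inputs from the output of
#' [ortho_tss_pairs()]: a matched pair contributes two orthologous TSSs of
#' its class, a singleton row contributes one lineage-specific TSS, and a
#' gene pair is counted for a class when it carries at least one TSS of the
#' class in either species.
#'
#' @param pairs data frame from [ortho_tss_pairs()].
#' @param classes classes to tabulate.
#' @return A [class_count_table()] data frame.
#' @export
class_count_table_from_pairs <- function(pairs, classes = c("g", "a", "i")) {
  n_tss <- n_genes <- n_ortho <- integer(length(classes))
  for (k in seq_along(classes)) {
    d <- pairs[pairs$class == classes[k], , drop = FALSE]
    npair <- sum(d$pair_status == "ortholog")
    nsing <- sum(d$pair_status != "ortholog")
    n_ortho[k] <- 2L * npair
    n_tss[k] <- 2L * npair + nsing
    n_genes[k] <- length(unique(d$gene_a))
  }
  class_count_table(n_tss, n_genes, n_ortho, classes)
}

#' Build the 2x2 conservation contingency table for two classes
#'
#' Rows are orthologous vs lineage-specific TSS counts, columns the two
#' classes compared.
#'
#' @param tab a [class_count_table()] data frame.
#' @param class_x,class_y the two classes.
#' @return A 2x2 integer matrix.
#' @export
conservation_contingency <- function(tab, class_x, class_y) {
  rx <- tab[tab$class == class_x, ]
  ry <- tab[tab$class == class_y, ]
  m <- matrix(c(rx$n_ortho_tss, rx$n_singleton,
                ry$n_ortho_tss, ry$n_singleton), nrow = 2,
              dimnames = list(c("ortholog", "singleton"),
                              c(class_x, class_y)))
  m
}

#' Fisher's exact tests with Benjamini-Hochberg correction
#'
#' Two-sided Fisher's exact test per 2x2 table, with BH-adjusted q-values
#' over the supplied family of comparisons. A table with a zero margin
#' carries no information about association and gets p = 1 by convention.
#'
#' @param tables named list of 2x2 matrices (e.g. from
#'   [conservation_contingency()]).
#' @return Data frame with `comparison`, `p`, `q`.
#' @export
fisher_conservation_fdr <- function(tables) {
  p <- vapply(tables, function(m) {
    m <- as.matrix(m)
    stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("table_", seq_along(tables))
  data.frame(comparison = nm, p = unname(p),
             q = stats::p.adjust(unname(p), method = "BH"),
             stringsAsFactors = FALSE)
}

#' Chi-square test for linear trend in proportions
#'
#' Cochran-Armitage test of a linear trend in the proportion of orthologous
#' TSSs across ordered bins (by default equally spaced scores), as used to
#' ask whether TSS conservation increases with protein sequence similarity.
#'
#' @param n_ortholog,n_total integer vectors per ordered bin.
#' @param scores bin scores (default equally spaced).
#' @return List with `statistic` (chi-square, 1 df), `p`, `direction`
#'   (`"increasing"`, `"decreasing"` or `"flat"`), and `n_bins` used.
#' @export
trend_test_linear <- function(n_ortholog, n_total,
                              scores = seq_along(n_total)) {
  stopifnot(length(n_ortholog) == length(n_total),
            all(n_ortholog <= n_total))
  keep <- n_total > 0
  if (sum(keep) < 2L) stop("need at least 2 non-empty bins")
  x <- n_ortholog[keep]; n <- n_total[keep]; s <- scores[keep]
  tt <- suppressWarnings(stats::prop.trend.test(x, n, score = s))
  prop <- x / n
  w <- n
  slope <- sum(w * (s - stats::weighted.mean(s, w)) *
                 (prop - stats::weighted.mean(prop, w)))
  direction <- if (abs(slope) < .Machine$double.eps^0.5) "flat" else
    if (slope > 0) "increasing" else "decreasing"
  list(statistic = unname(tt$statistic), p = tt$p.value,
       direction = direction, n_bins = sum(keep))
}

#' Bin TSS conservation by protein identity
#'
#' Tabulates, per protein-identity bin of the ortholog pairs, how many TSSs
#' are orthologous and how many exist in total, the input of
#' [trend_test_linear()].
#'
#' @param pairs data frame from [ortho_tss_pairs()].
#' @param ortho_table ortholog table (`gene_a`, `protein_identity`).
#' @param breaks identity bin breaks (percent).
#' @param class optional single class to restrict to.
#' @return Data frame with `bin`, `n_ortholog`, `n_total`.
#' @export
tss_conservation_by_identity <- function(pairs, ortho_table,
                                         breaks = seq(30, 100, by = 10),
                                         class = NULL) {
  if (!is.null(class)) pairs <- pairs[pairs$class == class, , drop = FALSE]
  ident <- ortho_table$protein_identity[match(pairs$gene_a,
                                              ortho_table$gene_a)]
  bin <- cut(ident, breaks = breaks, include.lowest = TRUE, right = TRUE)
  weight <- ifelse(pairs$pair_status == "ortholog", 2L, 1L)
  is_ortho <- pairs$pair_status == "ortholog"
  n_total <- tapply(weight, bin, sum, default = 0L)
  n_ortholog <- tapply(weight * is_ortho, bin, sum, default = 0L)
  data.frame(bin = levels(bin), n_ortholog = as.integer(n_ortholog),
             n_total = as.integer(n_total), stringsAsFactors = FALSE)
}

# exact signed-rank two-sided p by full enumeration over sign assignments,
# midranks for tied |d|
signed_rank_exact_p <- function(d) {
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  m <- 2L^n
  bits <- outer(0:(m - 1L), 2L^(0:(n - 1L)),
                function(x, y) bitwAnd(x %/% y, 1L))
  v_all <- as.vector(bits %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired differences (zero differences
#' dropped), used to compare TSS-locus nucleotide identity with the protein
#' identity of the associated orthologs. For 14 or fewer informative pairs
#' the exact null distribution is obtained by full enumeration over sign
#' assignments (midranks under ties); larger samples delegate to
#' [stats::wilcox.test()] (exact when tie-free and n < 50).
#'
#' @param x,y paired numeric vectors.
#' @return List with `p`, `direction` (`"greater"`, `"less"` or `"none"`,
#'   the sign of the median difference x - y), `n_informative`, `method`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p = 1, direction = "none", n_informative = 0L,
                method = "degenerate"))
  }
  md <- stats::median(d)
  direction <- if (md > 0) "greater" else if (md < 0) "less" else "none"
  if (n <= 14L) {
    p <- signed_rank_exact_p(d)
    method <- "exact enumeration"
  } else {
    exact <- n < 50L && !any(duplicated(abs(d)))
    wt <- suppressWarnings(stats::wilcox.test(d, exact = exact))
    p <- wt$p.value
    method <- if (exact) "exact" else "normal approximation"
  }
  list(p = p, direction = direction, n_informative = n, method = method)
}
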