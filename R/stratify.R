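# Stratification statistics: correlation/clustering of protein signals vs
# model parameters, biomarker-stratified rank-sum screens over sensitivity
# matrices, and hypergeometric enrichment of canonical gene sets.

#' Spearman correlation of feature columns against parameter columns
#'
#' Rank correlations (average ranks for ties) between every protein
#' measurement and every model parameter, pairwise over non-missing values.
#' Constant columns yield `NA`.
#'
#' @param features,params data.frames or matrices with named numeric
#'   columns; equal row counts (samples).
#' @return matrix, rows = features, columns = parameters.
#' @export
spearman_matrix <- function(features, params) {
  features <- as.matrix(features); params <- as.matrix(params)
  if (nrow(features) != nrow(params)) {
    stop("spearman_matrix: row mismatch", call. = FALSE)
  }
  ok <- stats::complete.cases(features, params)
  if (sum(ok) < 3) stop("spearman_matrix: need >= 3 paired observations",
                        call. = FALSE)
  suppressWarnings(stats::cor(features, params, method = "spearman",
                              use = "pairwise.complete.obs"))
}

#' Hierarchical clustering of a correlation (or profile) matrix
#'
#' Agglomerative average-linkage clustering with distance
#' `1 - Pearson correlation` between row profiles; columns are clustered the
#' same way on the transpose. Deterministic for a fixed input.
#'
#' @param m numeric matrix with finite entries.
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`.
#' @export
hier_cluster <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("hier_cluster: non-finite entries",
                               call. = FALSE)
  one_way <- function(x) {
    d <- stats::as.dist(1 - suppressWarnings(stats::cor(t(x))))
    d[!is.finite(d)] <- 2  # constant profiles: maximally distant
    stats::hclust(d, method = "average")
  }
  rh <- one_way(m); ch <- one_way(t(m))
  list(row_hclust = rh, col_hclust = ch,
       row_order = rh$order, col_order = ch$order)
}

#' Membership above an empirical percentile
#'
#' The threshold is the linearly interpolated empirical percentile
#' (`quantile` type 7); membership is strict (`value > threshold`), so an
#' all-equal input yields no members.
#'
#' @param values numeric vector.
#' @param pct percentile in (0, 100), e.g. 67 for the HER2-high cut.
#' @return logical membership vector.
#' @export
percentile_threshold <- function(values, pct) {
  if (!length(values)) stop("percentile_threshold: empty input", call. = FALSE)
  if (pct <= 0 || pct >= 100) stop("percentile_threshold: pct in (0,100)",
                                   call. = FALSE)
  values > stats::quantile(values, pct / 100, type = 7, names = FALSE,
                           na.rm = TRUE)
}

#' Median-cut stratification into high and low groups
#'
#' Values strictly above the median form the high group, strictly below the
#' low group; values exactly at the median are excluded so the strata are
#' unambiguous on small panels.
#'
#' @param values named (or unnamed) numeric vector, length `>= 2`.
#' @return list with logical vectors `hi` and `lo` (and the `median`).
#' @export
median_stratify <- function(values) {
  if (length(values) < 2) stop("median_stratify: need >= 2 values",
                               call. = FALSE)
  med <- stats::median(values, na.rm = TRUE)
  hi <- !is.na(values) & values > med
  lo <- !is.na(values) & values < med
  if (!any(hi) && !any(lo)) {
    stop("median_stratify: all values equal; no strata", call. = FALSE)
  }
  list(hi = hi, lo = lo, median = med)
}

#' Two-sided rank-sum (Mann-Whitney) test
#'
#' Exact p-value when the combined sample is small and tie-free, normal
#' approximation with tie and continuity correction otherwise. The reported
#' direction is positive when the first group's median is larger.
#'
#' @param a,b numeric group values (`>= 3` non-missing each).
#' @return list `(statistic, p, direction)` with `direction` in
#'   \{`"hi-sensitive"`, `"lo-sensitive"`, `"none"`\} interpreting `a` as the
#'   high-biomarker group.
#' @export
ranksum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("ranksum_test: need >= 3 non-missing values per group",
         call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  dmed <- stats::median(a) - stats::median(b)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       direction = if (dmed > 0) "hi-sensitive"
                   else if (dmed < 0) "lo-sensitive" else "none")
}

#' Signed p-value score
#'
#' `-log10(p)` signed by the direction of the difference (positive when the
#' first group is higher), as used to display differential-expression
#' comparisons.
#'
#' @param p p-value in (0, 1].
#' @param direction `"hi-sensitive"`/`"hi"`/positive-ish values sign
#'   positively; anything indicating the low group negative.
#' @export
signed_p <- function(p, direction) {
  if (any(p <= 0) || any(p > 1)) stop("signed_p: p in (0,1]", call. = FALSE)
  sgn <- if (is.character(direction)) {
    ifelse(direction %in% c("hi-sensitive", "hi", "up", "positive"), 1,
           ifelse(direction == "none", 0, -1))
  } else sign(direction)
  sgn * -log10(p)
}

#' Biomarker-stratified differential-sensitivity screen
#'
#' For every column of a sensitivity matrix (drug IC50s or knockdown
#' scores), compares the stratification's high vs low rows by rank-sum test.
#' Hits are columns with `p < alpha` (strict) and, when `effect_filter` is
#' set, an absolute median group difference exceeding it. Columns with fewer
#' than 3 non-missing values in either group are untestable and excluded
#' from `n_total`.
#'
#' @param m numeric matrix (rows = cell lines, columns = agents/genes) with
#'   row and column names; `NA` allowed.
#' @param strat list with `hi` and `lo` row-id character vectors (or logical
#'   vectors over rows), as from [median_stratify()] applied to a biomarker.
#' @param alpha hit threshold on the raw two-sided p-value (no multiplicity
#'   correction, by design).
#' @param effect_filter optional minimum `|median(hi) - median(lo)|`.
#' @return a `screen_result` list: per-column `stats` data.frame
#'   (`id, statistic, p, direction, median_diff`), `hits`, `n_total`,
#'   `n_hits`, `alpha`, `untestable`.
#' @export
differential_sensitivity_screen <- function(m, strat, alpha = 0.05,
                                            effect_filter = NULL) {
  m <- as.matrix(m)
  rid <- rownames(m)
  pick <- function(g) {
    if (is.logical(g)) which(g) else match(g, rid)
  }
  hi <- pick(strat$hi); lo <- pick(strat$lo)
  hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
  if (!length(hi) || !length(lo)) {
    stop("differential_sensitivity_screen: empty stratum", call. = FALSE)
  }
  if (length(intersect(hi, lo))) {
    stop("differential_sensitivity_screen: strata overlap", call. = FALSE)
  }
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("col", seq_len(ncol(m)))
  res <- vector("list", ncol(m))
  untestable <- character(0)
  for (j in seq_len(ncol(m))) {
    va <- m[hi, j]; vb <- m[lo, j]
    if (sum(!is.na(va)) < 3 || sum(!is.na(vb)) < 3) {
      untestable <- c(untestable, cols[j])
      next
    }
    rt <- ranksum_test(va, vb)
    res[[j]] <- data.frame(id = cols[j], statistic = rt$statistic, p = rt$p,
                           direction = rt$direction,
                           median_diff = stats::median(va, na.rm = TRUE) -
                             stats::median(vb, na.rm = TRUE),
                           stringsAsFactors = FALSE)
  }
  stats_df <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(stats_df)) stats_df <- data.frame(id = character(0),
    statistic = numeric(0), p = numeric(0), direction = character(0),
    median_diff = numeric(0))
  # strict p < alpha; alpha >= 1 disables the p-threshold entirely (exact
  # and continuity-corrected tests can return p = 1)
  is_hit <- if (alpha >= 1) rep(TRUE, nrow(stats_df)) else stats_df$p < alpha
  if (!is.null(effect_filter)) {
    is_hit <- is_hit & abs(stats_df$median_diff) > effect_filter
  }
  structure(list(stats = stats_df, hits = stats_df$id[is_hit],
                 n_total = nrow(stats_df), n_hits = sum(is_hit),
                 alpha = alpha, effect_filter = effect_filter,
                 untestable = untestable),
            class = "screen_result")
}

#' Upper tail of the hypergeometric distribution
#'
#' Probability of observing at least `r` marked elements when drawing `K`
#' from a population of `N` containing `n` marked, by exact summation of
#' the hypergeometric mass.
#'
#' @param N population size (genes tested).
#' @param n marked elements (screen hits).
#' @param K draws (canonical gene-set size).
#' @param r observed marked draws (canonical hits).
#' @return `P(X >= r)` in (0, 1].
#' @export
hypergeometric_tail <- function(N, n, K, r) {
  if (r < 0 || r > K || K > N || n > N || n < 0) {
    stop("hypergeometric_tail: need 0 <= r <= K <= N and 0 <= n <= N",
         call. = FALSE)
  }
  if (r == 0) return(1)
  sum(stats::dhyper(r:K, n, N - n, K))
}

#' Canonical gene-set enrichment of a screen's hit list
#'
#' Tests whether the canonical pathway nodes (default AKT1, PIK3CA, MTOR,
#' MAP2K1, MAPK1) are over-represented among the screen's hits, via the
#' hypergeometric upper tail over (N = genes tested, n = hits, K = set
#' size, r = canonical hits). Canonical ids that were not testable in the
#' screen are dropped from `K` with a warning.
#'
#' @param screen a [differential_sensitivity_screen()] result.
#' @param canonical_ids character vector of gene ids.
#' @return an `enrichment_result` list: `N`, `n`, `K`, `r`, `p`,
#'   `canonical_hits`.
#' @export
canonical_enrichment <- function(screen,
                                 canonical_ids = c("AKT1", "PIK3CA", "MTOR",
                                                   "MAP2K1", "MAPK1")) {
  tested <- screen$stats$id
  untested <- setdiff(canonical_ids, tested)
  if (length(untested)) {
    warning("canonical_enrichment: untested ids dropped from the set: ",
            paste(untested, collapse = ", "))
    canonical_ids <- intersect(canonical_ids, tested)
  }
  r_hits <- intersect(canonical_ids, screen$hits)
  structure(list(N = screen$n_total, n = screen$n_hits,
                 K = length(canonical_ids), r = length(r_hits),
                 p = hypergeometric_tail(screen$n_total, screen$n_hits,
                                         length(canonical_ids),
                                         length(r_hits)),
                 canonical_hits = r_hits),
            class = "enrichment_result")
}

#' Read and write score matrices (rows = cell lines, columns = agents)
#'
#' CSV with row identifiers in the first column; empty cells are missing
#' values and are preserved on write.
#'
#' @param m numeric matrix with dimnames.
#' @param file path.
#' @export
write_matrix <- function(m, file) {
  df <- data.frame(row_id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "row_id") {
    stop("read_matrix: first column must be 'row_id'", call. = FALSE)
  }
  if (anyDuplicated(df$row_id)) {
    stop("read_matrix: duplicated row ids", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$row_id
  m
}
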