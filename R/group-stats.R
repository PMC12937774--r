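#' Per-subject stimulus ranks from distances
#'
#' Rank 1 is the smallest distance (best stimulus) within each subject
#' column; ties receive average ranks.
#'
#' @param dist stimuli x subjects distance matrix.
#' @return matrix of the same shape with within-column ranks.
#' @export
subject_ranks <- function(dist) {
  apply(as.matrix(dist), 2, rank, ties.method = "average")
}

#' Median stimulus rank per category and subject
#'
#' Categories with fewer than `min_size` stimuli (the two singletons in the
#' default library) are excluded, leaving 35 categories.
#'
#' @param rank_mat stimuli x subjects rank matrix with stim-id rownames.
#' @param library stimulus library (provides the category grouping).
#' @param min_size minimum category size to retain (default 2).
#' @return categories x subjects matrix of median ranks; rownames are
#'   category ids, with a `sizes` attribute.
#' @export
median_ranks_by_category <- function(rank_mat, library, min_size = 2L) {
  rank_mat <- as.matrix(rank_mat)
  tab <- library_table(library)
  tab <- tab[tab$stim_id %in% as.integer(rownames(rank_mat)), ]
  sizes <- table(tab$category_id)
  if (any(sizes == 0)) stop("category with zero member stimuli")
  keep <- names(sizes)[sizes >= min_size]
  v <- vapply(keep, function(cid) {
    ids <- as.character(tab$stim_id[tab$category_id == as.integer(cid)])
    apply(rank_mat[ids, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(rank_mat)))
  med <- if (is.matrix(v)) t(v) else matrix(v, ncol = 1, dimnames = list(keep, NULL))
  rownames(med) <- keep
  colnames(med) <- colnames(rank_mat)
  attr(med, "sizes") <- as.integer(sizes[keep])
  med
}

#' Kendall's coefficient of concordance (tie-corrected)
#'
#' Measures agreement of `m` raters (columns) over `k` items (rows). Values
#' are re-ranked within each rater with average ties;
#' `W = 12 S / (m^2 (k^3 - k) - m sum(T))` where `S` is the sum of squared
#' deviations of item rank sums and `T` the per-rater tie correction. The
#' p-value uses the chi-square approximation `chi2 = m (k - 1) W` with
#' `k - 1` degrees of freedom.
#'
#' @param x items x raters matrix (e.g. category median ranks per subject).
#' @return list with `W`, `chi2`, `df`, `p`.
#' @export
kendalls_w <- function(x) {
  x <- as.matrix(x)
  k <- nrow(x); m <- ncol(x)
  if (k < 3) stop("Kendall's W needs at least 3 items")
  if (m < 2) stop("Kendall's W needs at least 2 raters")
  R <- apply(x, 2, rank, ties.method = "average")
  rs <- rowSums(R)
  S <- sum((rs - mean(rs))^2)
  T_corr <- sum(apply(R, 2, function(r) {
    t_sizes <- table(r)
    sum(t_sizes^3 - t_sizes)
  }))
  denom <- m^2 * (k^3 - k) - m * T_corr
  W <- if (denom > 0) 12 * S / denom else 0
  chi2 <- m * (k - 1) * W
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  list(W = W, chi2 = chi2, df = k - 1, p = p)
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_i = min_{j >= i} (m p_(j) / j)` over the sorted p-values; rejections
#' are `q <= q_threshold`, which reproduces the classic step-up rejection
#' set exactly (including its closed boundary).
#'
#' @param p p-values in \[0, 1\].
#' @param q_threshold rejection threshold on q.
#' @return list with `q` (same order as `p`) and logical `reject`.
#' @export
bh_fdr <- function(p, q_threshold = 0.1) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, reject = q <= q_threshold)
}

#' One-tailed category enrichment of favourable ranks
#'
#' For each retained category, a one-tailed Wilcoxon rank-sum test of the
#' member stimuli's global SES-derived ranks against all non-member ranks
#' (`alternative = "less"`: lower ranks are better), followed by
#' Benjamini-Hochberg correction across categories. Exact p-values are used
#' where `stats::wilcox.test` supports them (small samples, no ties);
#' otherwise the normal approximation with continuity correction.
#'
#' @param ranks global rank per stimulus (1..n, from [rank_stimuli()]).
#' @param category_id category of each stimulus (same order as `ranks`).
#' @param min_size minimum category size to retain.
#' @param q_threshold BH rejection threshold (default 0.1).
#' @return data.frame `category_id`, `size`, `median_rank`, `p`, `q`,
#'   `significant`.
#' @export
category_wilcoxon <- function(ranks, category_id, min_size = 2L,
                              q_threshold = 0.1) {
  sizes <- table(category_id)
  keep <- names(sizes)[sizes >= min_size]
  res <- lapply(keep, function(cid) {
    inside <- category_id == cid
    if (all(inside)) stop("empty complement for category ", cid)
    p <- stats::wilcox.test(ranks[inside], ranks[!inside],
                            alternative = "less")$p.value
    data.frame(category_id = if (is.numeric(category_id)) as.integer(cid) else cid,
               size = as.integer(sizes[cid]),
               median_rank = stats::median(ranks[inside]), p = p)
  })
  res <- do.call(rbind, res)
  adj <- bh_fdr(res$p, q_threshold)
  res$q <- adj$q
  res$significant <- adj$reject
  res
}

#' Spearman correlation between two SES vectors
#'
#' Tie-averaged rank correlation with a two-sided p-value from the
#' t approximation `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param a,b numeric vectors of equal length (e.g. Stim-interval and
#'   PostStim-interval SES).
#' @return list with `rho` and `p`.
#' @export
spearman_ses <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  n <- length(a)
  rho <- stats::cor(rank(a), rank(b))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Per-channel paired-t interval comparison maps
#'
#' For one biomarker and one group: a paired t-test per channel across
#' trials (paired by subject and stimulus) for each interval comparison,
#' with Benjamini-Hochberg correction within each channel map.
#'
#' @param df long data.frame from [cohort_channel_biomarkers()] restricted
#'   to one group, with a `value` column (or pass `marker` naming the
#'   column).
#' @param marker column name holding the biomarker value.
#' @param comparisons list of `c(interval_a, interval_b)` pairs; defaults to
#'   the three canonical comparisons.
#' @param q_threshold significance threshold on q (default 0.05).
#' @return data.frame `comparison`, `channel`, `t`, `p`, `q`, `neglog10_q`,
#'   `significant`.
#' @export
interval_ttest_maps <- function(df, marker,
                                comparisons = list(c("pre", "stim"),
                                                   c("stim", "post"),
                                                   c("pre", "post")),
                                q_threshold = 0.05) {
  out <- list()
  for (cmp in comparisons) {
    a <- df[df$interval == cmp[1], c("subject_id", "stim_id", "channel", marker)]
    b <- df[df$interval == cmp[2], c("subject_id", "stim_id", "channel", marker)]
    mg <- merge(a, b, by = c("subject_id", "stim_id", "channel"),
                suffixes = c("_a", "_b"))
    channels <- unique(mg$channel)
    rows <- lapply(channels, function(ch) {
      sub <- mg[mg$channel == ch, ]
      if (nrow(sub) < 3) stop("fewer than 3 paired trials for channel ", ch)
      d <- sub[[paste0(marker, "_a")]] - sub[[paste0(marker, "_b")]]
      if (stats::sd(d) == 0) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- stats::t.test(d)
      }
      data.frame(comparison = paste(cmp, collapse = "_vs_"), channel = ch,
                 t = unname(tt$statistic), p = tt$p.value)
    })
    map <- do.call(rbind, rows)
    adj <- bh_fdr(map$p, q_threshold)
    map$q <- adj$q
    map$neglog10_q <- -log10(pmax(map$q, 1e-300))
    map$significant <- adj$reject
    out[[length(out) + 1L]] <- map
  }
  do.call(rbind, out)
}
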