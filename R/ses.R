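#' TOPSIS stimulus evaluation scores
#'
#' Aggregates the per-subject distances into a single Stimulus Evaluation
#' Score (SES) per stimulus: distances are inverted (larger = better),
#' columns are normalized per subject, and each stimulus row is scored by
#' its relative closeness `d_anti / (d_ideal + d_anti)` to the ideal
#' (column-wise maximum) versus anti-ideal (column-wise minimum) reference
#' points, with equal subject weights.
#'
#' @name ses_ranking
NULL

#' Inverse-distance decision matrix
#'
#' `1 / (dist + eps)`; the small `eps` keeps exact-zero distances finite
#' without materially reordering non-degenerate entries.
#'
#' @param dist stimuli x subjects matrix of non-negative distances.
#' @param eps regularizer (default 1e-9).
#' @return matrix of inverse distances.
#' @export
decision_matrix <- function(dist, eps = 1e-9) {
  dist <- as.matrix(dist)
  if (any(dist < 0)) stop("distances must be non-negative")
  1 / (dist + eps)
}

#' Per-subject column normalization
#'
#' Default `"vector"` normalization divides each column by its Euclidean
#' norm (the canonical TOPSIS step); `"minmax"` and `"sum"` are provided as
#' configurable alternatives.
#'
#' @param m stimuli x subjects matrix (entries >= 0).
#' @param method normalization method.
#' @return matrix with normalized columns.
#' @export
normalize_columns <- function(m, method = c("vector", "minmax", "sum")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  norms <- switch(method,
    vector = sqrt(colSums(m^2)),
    sum = colSums(m),
    minmax = NULL)
  if (method == "minmax") {
    rng <- apply(m, 2, range)
    span <- rng[2, ] - rng[1, ]
    if (any(span == 0)) stop("constant column: min-max normalization undefined")
    return(sweep(sweep(m, 2, rng[1, ]), 2, span, "/"))
  }
  if (any(norms == 0)) stop("all-zero column: cannot normalize")
  sweep(m, 2, norms, "/")
}

#' SES from a normalized decision matrix
#'
#' @param normalized stimuli x subjects matrix with normalized columns.
#' @return data.frame `stim_id` (rownames if present, else row index),
#'   `d_ideal`, `d_anti`, `ses`, `rank`.
#' @export
topsis_ses <- function(normalized) {
  normalized <- as.matrix(normalized)
  ideal <- apply(normalized, 2, max)
  anti <- apply(normalized, 2, min)
  d_ideal <- sqrt(rowSums(sweep(normalized, 2, ideal)^2))
  d_anti <- sqrt(rowSums(sweep(normalized, 2, anti)^2))
  tot <- d_ideal + d_anti
  ses <- ifelse(tot > 0, d_anti / tot, 0.5)
  ids <- rownames(normalized)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(normalized)))
  data.frame(stim_id = as.integer(ids), d_ideal = d_ideal, d_anti = d_anti,
             ses = ses, rank = rank_stimuli(ses), row.names = NULL)
}

#' Rank stimuli by SES
#'
#' Rank 1 is the highest SES; ties receive the average rank.
#'
#' @param ses numeric SES values.
#' @return numeric ranks.
#' @export
rank_stimuli <- function(ses) {
  rank(-ses, ties.method = "average")
}

#' Full SES table from a distance matrix
#'
#' Chains [decision_matrix()], [normalize_columns()] and [topsis_ses()] and
#' attaches the normalized per-subject columns.
#'
#' @param dist stimuli x subjects distance matrix (rownames = stim ids).
#' @param eps inverse-distance regularizer.
#' @param method column normalization method.
#' @return data.frame: `stim_id`, `ses`, `rank`, `d_ideal`, `d_anti`, then
#'   one `norm_<subject>` column per subject.
#' @export
ses_table <- function(dist, eps = 1e-9, method = "vector") {
  normalized <- normalize_columns(decision_matrix(dist, eps), method)
  tab <- topsis_ses(normalized)
  nm <- colnames(normalized)
  if (is.null(nm)) nm <- paste0("s", seq_len(ncol(normalized)))
  norm_df <- as.data.frame(normalized, row.names = NULL)
  names(norm_df) <- paste0("norm_", nm)
  cbind(tab[, c("stim_id", "ses", "rank", "d_ideal", "d_anti")], norm_df)
}
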