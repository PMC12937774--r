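#' Leave-one-subject-out LASSO composite model
#'
#' Trains an L1-regularized logistic model (HC vs PD) on pre-stimulation
#' biomarker vectors with leave-one-subject-out (LOSO) outer folds. Within
#' each fold, features are z-scored on the training subjects, the
#' regularization strength is selected by the one-standard-error (1SE) rule
#' from an inner subject-grouped cross-validation on binomial deviance, and
#' the selected coefficients are mapped back to a common standardization so
#' folds can be averaged. The final composite score is the fold-averaged
#' linear predictor.
#'
#' @param x n x 16 matrix of pre-stimulation biomarker vectors (columns in
#'   [biomarker_names()] order).
#' @param subject subject id per row.
#' @param group `"HC"`/`"PD"` per row (PD is the positive class).
#' @param inner_folds inner CV folds (subjects are assigned whole to folds,
#'   class-balanced round-robin; capped at the number of training subjects).
#' @param lambda_choice `"1se"` (default) or `"min"`.
#' @return object of class `composite_model`: `weights` (16, on the scale of
#'   the pooled standardization), `intercept`, `feature_means`,
#'   `feature_sds`, `per_fold_weights`, `per_fold_intercepts`,
#'   `lambda_per_fold`, `fold_subjects`, `fold_accuracy`.
#' @export
train_loso_lasso <- function(x, subject, group, inner_folds = 5L,
                             lambda_choice = c("1se", "min")) {
  lambda_choice <- match.arg(lambda_choice)
  x <- as.matrix(x)
  subject <- as.character(subject)
  group <- as.character(group)
  stopifnot(nrow(x) == length(subject), nrow(x) == length(group))
  subj_group <- tapply(group, subject, function(g) g[1])
  subs <- names(subj_group)
  if (sum(subj_group == "HC") < 2 || sum(subj_group == "PD") < 2) {
    stop("need at least 2 subjects per class for LOSO training")
  }
  y <- as.integer(group == "PD")
  nb <- ncol(x)

  mean_g <- colMeans(x)
  sd_g <- apply(x, 2, stats::sd)
  if (any(sd_g <= 0)) stop("constant feature column(s): ",
                           paste(which(sd_g <= 0), collapse = ", "))

  nf <- length(subs)
  W <- matrix(0, nf, nb, dimnames = list(subs, colnames(x)))
  b0 <- numeric(nf)
  lambda <- numeric(nf)
  acc <- numeric(nf)

  for (f in seq_len(nf)) {
    held <- subs[f]
    tr <- subject != held
    xt <- x[tr, , drop = FALSE]
    yt <- y[tr]
    st <- subject[tr]
    m_t <- colMeans(xt)
    s_t <- apply(xt, 2, stats::sd)
    s_t[s_t <= 0] <- 1
    xs <- sweep(sweep(xt, 2, m_t), 2, s_t, "/")

    # inner subject-grouped folds, class-balanced round-robin
    tr_subs <- subs[subs != held]
    k_inner <- min(inner_folds, length(tr_subs))
    fold_of <- integer(length(tr_subs)); names(fold_of) <- tr_subs
    nxt <- 0L
    for (cls in c("HC", "PD")) {
      for (s in tr_subs[subj_group[tr_subs] == cls]) {
        fold_of[s] <- (nxt %% k_inner) + 1L
        nxt <- nxt + 1L
      }
    }
    foldid <- fold_of[st]
    # grouped folds require every fold's complement to contain both classes;
    # with very small cohorts fall back to trial-stratified folds
    ok <- all(vapply(seq_len(k_inner), function(k) {
      length(unique(yt[foldid != k])) == 2
    }, logical(1)))
    if (!ok || k_inner < 3) {
      k_inner <- max(k_inner, 3L)
      foldid <- integer(length(yt))
      for (cls in 0:1) {
        idx <- which(yt == cls)
        foldid[idx] <- (seq_along(idx) - 1L) %% k_inner + 1L
      }
    }

    # balanced class weights: outer folds train on 5/4 splits, and an
    # unweighted intercept-only null model would then systematically
    # misclassify the held-out subject instead of sitting at chance
    wts <- ifelse(yt == 1, 0.5 / mean(yt == 1), 0.5 / mean(yt == 0))
    cv <- glmnet::cv.glmnet(xs, yt, family = "binomial", alpha = 1,
                            weights = wts, foldid = foldid,
                            standardize = FALSE, type.measure = "deviance")
    s_lam <- if (lambda_choice == "1se") cv$lambda.1se else cv$lambda.min
    co <- as.numeric(stats::coef(cv, s = s_lam))
    beta_std <- co[-1]
    b_std <- co[1]
    beta_orig <- beta_std / s_t
    b_orig <- b_std - sum(beta_std * m_t / s_t)
    # express on the pooled standardization scale
    W[f, ] <- beta_orig * sd_g
    b0[f] <- b_orig + sum(beta_orig * mean_g)
    lambda[f] <- s_lam

    # held-out accuracy on pre-stim trials
    ho <- !tr
    eta <- b_orig + x[ho, , drop = FALSE] %*% beta_orig
    acc[f] <- mean((eta > 0) == (y[ho] == 1))
  }

  structure(list(weights = colMeans(W), intercept = mean(b0),
                 feature_means = mean_g, feature_sds = sd_g,
                 per_fold_weights = W, per_fold_intercepts = b0,
                 lambda_per_fold = lambda, fold_subjects = subs,
                 fold_groups = unname(subj_group[subs]),
                 fold_accuracy = acc),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model: %d folds, mean LOSO accuracy %.3f>\n",
              length(x$fold_subjects), mean(x$fold_accuracy)))
  nz <- sum(abs(x$weights) > 0)
  cat(sprintf("  nonzero averaged weights: %d of %d\n", nz, length(x$weights)))
  invisible(x)
}

#' Composite score of feature vectors
#'
#' `score = intercept + sum_b w_b (x_b - mean_b) / sd_b` -- the averaged
#' LOSO linear predictor (log-odds of PD). Deterministic.
#'
#' @param model a `composite_model`.
#' @param x matrix (n x 16) or a single feature vector.
#' @return numeric scores.
#' @export
score_features <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$weights)) {
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         length(model$weights))
  }
  xs <- sweep(sweep(x, 2, model$feature_means), 2, model$feature_sds, "/")
  as.numeric(model$intercept + xs %*% model$weights)
}

#' Score table for a features data frame
#'
#' @param model a `composite_model`.
#' @param features data.frame from [cohort_features()] (any intervals).
#' @return data.frame `subject_id`, `group`, `stim_id`, `interval`, `score`.
#' @export
score_table <- function(model, features) {
  x <- as.matrix(features[, biomarker_names()])
  data.frame(subject_id = features$subject_id, group = features$group,
             stim_id = features$stim_id, interval = features$interval,
             score = score_features(model, x), stringsAsFactors = FALSE)
}

#' Healthy pre-stimulation reference score
#'
#' Arithmetic mean of the composite score over all pre-stimulation trials of
#' all healthy-control subjects. Refuses to impute: every HC subject must
#' contribute a complete, equal-sized set of finite scores.
#'
#' @param scores data.frame with `subject_id` and `score` columns (HC
#'   pre-stimulation rows), or a plain numeric vector.
#' @return scalar reference score.
#' @export
healthy_reference <- function(scores) {
  if (is.numeric(scores)) {
    if (anyNA(scores)) stop("missing trial scores; no imputation")
    return(mean(scores))
  }
  if (anyNA(scores$score)) stop("missing trial scores; no imputation")
  counts <- table(scores$subject_id)
  if (length(unique(as.integer(counts))) != 1) {
    stop("unequal trial counts across subjects; no imputation")
  }
  mean(scores$score)
}

#' Distances from the healthy reference
#'
#' `Dist(subj, stim) = |Score(subj, stim) - reference|`. The distance
#' quantity is later inverted (1/Dist) for the decision matrix, so the
#' absolute value is required for it to behave as a distance.
#'
#' @param score_mat stimuli x subjects matrix of stimulation-interval scores
#'   (see [score_matrix()]).
#' @param reference scalar from [healthy_reference()].
#' @return matrix of the same shape.
#' @export
reference_distances <- function(score_mat, reference) {
  abs(score_mat - reference)
}

#' Reshape a score table into a stimuli x subjects matrix
#'
#' @param score_df output of [score_table()].
#' @param interval which interval to extract.
#' @param subjects optional subject ordering (default: sorted unique ids).
#' @return matrix with stimulus rows (sorted by `stim_id`) and subject
#'   columns.
#' @export
score_matrix <- function(score_df, interval, subjects = NULL) {
  d <- score_df[score_df$interval == interval, ]
  if (is.null(subjects)) subjects <- sort(unique(d$subject_id))
  stims <- sort(unique(d$stim_id))
  m <- matrix(NA_real_, length(stims), length(subjects),
              dimnames = list(stims, subjects))
  for (s in subjects) {
    ds <- d[d$subject_id == s, ]
    m[as.character(ds$stim_id), s] <- ds$score
  }
  if (anyNA(m)) stop("incomplete score table: missing (subject, stimulus) cells")
  m
}

#' LOSO classification accuracy per interval
#'
#' For each outer fold, the fold's own model (trained without the held-out
#' subject) predicts the held-out subject's trials in each interval at a 0.5
#' probability threshold; fractions correct are aggregated over folds.
#'
#' @param model a `composite_model`.
#' @param features data.frame from [cohort_features()] containing the
#'   intervals of interest.
#' @return named vector of accuracies, one per interval present.
#' @export
interval_accuracy <- function(model, features) {
  ivs <- unique(features$interval)
  x <- as.matrix(features[, biomarker_names()])
  xs <- sweep(sweep(x, 2, model$feature_means), 2, model$feature_sds, "/")
  y <- as.integer(features$group == "PD")
  out <- stats::setNames(numeric(length(ivs)), ivs)
  for (iv in ivs) {
    correct <- 0L; total <- 0L
    for (f in seq_along(model$fold_subjects)) {
      held <- model$fold_subjects[f]
      sel <- features$interval == iv & features$subject_id == held
      if (!any(sel)) next
      eta <- model$per_fold_intercepts[f] +
        xs[sel, , drop = FALSE] %*% model$per_fold_weights[f, ]
      correct <- correct + sum((eta > 0) == (y[sel] == 1))
      total <- total + sum(sel)
    }
    out[iv] <- correct / total
  }
  out
}

#' Serialize / restore a composite model as JSON
#'
#' @param model a `composite_model`.
#' @param path JSON file path.
#' @return `write_composite_model`: path invisibly; `read_composite_model`:
#'   the model.
#' @export
write_composite_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_composite_model
#' @export
read_composite_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$weights <- stats::setNames(as.numeric(raw$weights), biomarker_names())
  raw$feature_means <- stats::setNames(as.numeric(raw$feature_means), biomarker_names())
  raw$feature_sds <- stats::setNames(as.numeric(raw$feature_sds), biomarker_names())
  raw$per_fold_weights <- matrix(unlist(raw$per_fold_weights),
                                 nrow = length(raw$fold_subjects), byrow = FALSE,
                                 dimnames = list(raw$fold_subjects, biomarker_names()))
  structure(raw, class = "composite_model")
}
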