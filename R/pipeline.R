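#' Pipeline configuration
#'
#' Bundles every tunable decision of the screening pipeline with its
#' default: the cohort generator settings, biomarker band edges and
#' estimator parameters, LASSO cross-validation design, MCDA normalization,
#' inverse-distance regularizer, and BH thresholds (q < 0.1 for category
#' significance, q < 0.05 for channel maps). Serializable to YAML.
#'
#' @param cohort a [cohort_config()].
#' @param opts a [biomarker_options()] list.
#' @param inner_folds inner CV folds of the LASSO 1SE selection.
#' @param lambda_choice `"1se"` or `"min"`.
#' @param mcda_normalization `"vector"`, `"minmax"` or `"sum"`.
#' @param eps inverse-distance regularizer.
#' @param category_q BH threshold for category significance.
#' @param channel_q BH threshold for channel maps.
#' @param central_channels channels averaged for the composite features.
#' @param out_dir artifact directory (`NULL` = return results only).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            opts = biomarker_options(),
                            inner_folds = 5L, lambda_choice = "1se",
                            mcda_normalization = "vector", eps = 1e-9,
                            category_q = 0.1, channel_q = 0.05,
                            central_channels = central_electrodes(),
                            out_dir = NULL) {
  structure(list(cohort = cohort, opts = opts, inner_folds = inner_folds,
                 lambda_choice = lambda_choice,
                 mcda_normalization = mcda_normalization, eps = eps,
                 category_q = category_q, channel_q = channel_q,
                 central_channels = central_channels, out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config`: path invisibly; `read_pipeline_config`:
#'   the configuration.
#' @export
write_pipeline_config <- function(cfg, path) {
  # yaml serializes named atomic vectors as plain sequences (names lost);
  # promote them to lists so they round-trip as maps
  promote <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), promote)
    } else if (!is.null(names(x)) && length(x) > 0) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(promote(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  co <- raw$cohort
  cohort <- cohort_config(co$n_hc, co$n_pd, co$n_trials, co$fs,
                          unlist(co$channel_names),
                          unlist(co$trial_layout),
                          unlist(co$effect_map), co$master_seed)
  op <- raw$opts
  opts <- biomarker_options(unlist(op$beta_band), unlist(op$gamma_band),
                            unlist(op$broad_band), unlist(op$fit_range),
                            op$pac_bins, op$burst_min_s, op$burst_quantile,
                            op$entropy_m, op$entropy_r)
  pipeline_config(cohort, opts, raw$inner_folds, raw$lambda_choice,
                  raw$mcda_normalization, raw$eps, raw$category_q,
                  raw$channel_q, unlist(raw$central_channels), raw$out_dir)
}

#' Extract features from an EDF session directory
#'
#' Reads a session written by [simulate_cohort()] and computes the
#' channel-averaged trial features for every subject, with burst thresholds
#' pooled over each subject's pre-stimulation windows.
#'
#' @param session output of [read_session()] or a session directory path.
#' @param central_channels channels to average over.
#' @param opts a [biomarker_options()] list.
#' @return features data.frame as in [cohort_features()] (without `delta`).
#' @export
session_features <- function(session, central_channels = central_electrodes(),
                             opts = biomarker_options()) {
  if (is.character(session)) session <- read_session(session)
  out <- list()
  for (sid in names(session$trials)) {
    trials <- session$trials[[sid]]
    fs <- trials[[1]]$fs
    thr <- vapply(central_channels, function(ch) {
      burst_threshold(lapply(trials, function(tr) tr$data[ch, 1:(2 * fs)]),
                      fs, opts)
    }, numeric(1))
    for (tr in trials) {
      ft <- extract_features(tr, thr, central_channels, opts)
      for (iv in c("pre", "stim", "post")) {
        out[[length(out) + 1L]] <- c(
          list(subject_id = sid, stim_id = tr$stim_id, interval = iv),
          as.list(ft[[iv]]))
      }
    }
  }
  df <- data.table::rbindlist(out)
  data.table::setnames(df, c("subject_id", "stim_id", "interval",
                             biomarker_names()))
  as.data.frame(df)
}

# SES + group statistics for one interval's score matrix
.interval_inference <- function(score_mat_pd, reference, library, cfg) {
  dist <- reference_distances(score_mat_pd, reference)
  ses <- ses_table(dist, eps = cfg$eps, method = cfg$mcda_normalization)
  ranks <- subject_ranks(dist)
  med <- median_ranks_by_category(ranks, library)
  W <- kendalls_w(med)
  lt <- library_table(library)
  cat_of <- lt$category_id[match(ses$stim_id, lt$stim_id)]
  cw <- category_wilcoxon(ses$rank, cat_of, q_threshold = cfg$category_q)
  cw$category_label <- lt$category_label[match(cw$category_id, lt$category_id)]
  list(ses = ses, ranks = ranks, median_ranks = med, concordance = W,
       categories = cw)
}

#' Run the full screening pipeline on a synthetic cohort
#'
#' Chains every stage: streamed feature extraction, LOSO LASSO training,
#' composite scoring of all intervals, healthy reference (mean HC pre-stim
#' score), per-subject distances, TOPSIS SES and ranking, category medians,
#' Kendall's W, one-tailed Wilcoxon with BH correction -- for the Stim
#' interval and (as the transience control) the PostStim interval -- plus
#' the Spearman correlation between Stim-SES and PostStim-SES. Ground truth
#' (planted deltas) is consulted only by the final recovery summary.
#'
#' @param cfg a [pipeline_config()].
#' @param library stimulus library (default [build_default_library()]).
#' @param features optional precomputed features data.frame (skips
#'   generation).
#' @return list with `features`, `model`, `accuracy`, `scores`, `reference`,
#'   `stim` and `post` inference blocks, `spearman`, `report`.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         library = build_default_library(),
                         features = NULL) {
  if (is.null(features)) {
    features <- cohort_features(cfg$cohort, library,
                                central_channels = cfg$central_channels,
                                opts = cfg$opts)
  }
  pre <- features[features$interval == "pre", ]
  model <- train_loso_lasso(as.matrix(pre[, biomarker_names()]),
                            pre$subject_id, pre$group,
                            inner_folds = cfg$inner_folds,
                            lambda_choice = cfg$lambda_choice)
  accuracy <- interval_accuracy(model, features)
  scores <- score_table(model, features)
  hc_pre <- scores[scores$interval == "pre" & scores$group == "HC", ]
  reference <- healthy_reference(hc_pre)
  pd_subjects <- sort(unique(scores$subject_id[scores$group == "PD"]))

  stim_mat <- score_matrix(scores[scores$group == "PD", ], "stim", pd_subjects)
  stim_inf <- .interval_inference(stim_mat, reference, library, cfg)

  post_inf <- NULL
  spearman <- NULL
  if ("post" %in% features$interval) {
    post_mat <- score_matrix(scores[scores$group == "PD", ], "post", pd_subjects)
    post_inf <- .interval_inference(post_mat, reference, library, cfg)
    spearman <- spearman_ses(stim_inf$ses$ses, post_inf$ses$ses)
  }

  lt <- library_table(library)
  sham_id <- lt$stim_id[lt$family == "sham"]
  sham_rank <- stim_inf$ses$rank[stim_inf$ses$stim_id == sham_id]
  planted <- sort(as.integer(names(cfg$cohort$effect_map)[cfg$cohort$effect_map > 0]))
  found <- sort(stim_inf$categories$category_id[stim_inf$categories$significant])

  report <- list(
    n_subjects = cfg$cohort$n_hc + cfg$cohort$n_pd,
    n_trials = cfg$cohort$n_trials,
    accuracy = as.list(accuracy),
    reference = reference,
    sham_rank = if (length(sham_rank)) sham_rank else NA_real_,
    kendalls_w_stim = stim_inf$concordance$W,
    kendalls_w_stim_p = stim_inf$concordance$p,
    kendalls_w_post = if (!is.null(post_inf)) post_inf$concordance$W else NA_real_,
    kendalls_w_post_p = if (!is.null(post_inf)) post_inf$concordance$p else NA_real_,
    spearman_rho = if (!is.null(spearman)) spearman$rho else NA_real_,
    spearman_p = if (!is.null(spearman)) spearman$p else NA_real_,
    significant_categories = found,
    planted_categories = planted,
    recovered_exactly = identical(found, planted),
    top50 = utils::head(stim_inf$ses[order(stim_inf$ses$rank),
                                     c("stim_id", "ses", "rank")], 50),
    master_seed = cfg$cohort$master_seed
  )

  res <- list(features = features, model = model, accuracy = accuracy,
              scores = scores, reference = reference, stim = stim_inf,
              post = post_inf, spearman = spearman, report = report)

  if (!is.null(cfg$out_dir)) .write_pipeline_artifacts(res, cfg)
  res
}

.write_pipeline_artifacts <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, ...)
  utils::write.csv(res$features, p("features.csv"), row.names = FALSE)
  utils::write.csv(res$scores, p("scores.csv"), row.names = FALSE)
  write_composite_model(res$model, p("model.json"))
  jsonlite::write_json(as.list(res$accuracy), p("accuracy.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$stim$ses, p("ses_stim.csv"), row.names = FALSE)
  utils::write.csv(res$stim$categories, p("group_stats_stim.csv"),
                   row.names = FALSE)
  if (!is.null(res$post)) {
    utils::write.csv(res$post$ses, p("ses_post.csv"), row.names = FALSE)
    utils::write.csv(res$post$categories, p("group_stats_post.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(cfg$out_dir)
}
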