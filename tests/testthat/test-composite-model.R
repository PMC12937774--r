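# constructed feature sets: 10 subjects x n trials x 16 biomarkers
make_features <- function(n_per = 30, informative = 0, sep = 2, seed = 1) {
  set.seed(seed)
  subs <- c(paste0("hc", 1:5), paste0("pd", 1:5))
  grp <- rep(c("HC", "PD"), each = 5)
  x <- matrix(rnorm(10 * n_per * 16), 10 * n_per, 16,
              dimnames = list(NULL, biomarker_names()))
  subject <- rep(subs, each = n_per)
  group <- rep(grp, each = n_per)
  if (informative > 0) {
    x[, informative] <- ifelse(group == "PD", sep / 2, -sep / 2) +
      rnorm(10 * n_per, sd = 0.1)
  }
  list(x = x, subject = subject, group = group)
}

test_that("LOSO LASSO recovers a planted sparse signal and separates perfectly", {
  d <- make_features(informative = 5, sep = 2)
  m <- train_loso_lasso(d$x, d$subject, d$group)
  w <- abs(m$weights)
  expect_identical(unname(which.max(w)), 5L)
  expect_true(all(w[-5] <= w[5] / 10))
  expect_identical(mean(m$fold_accuracy), 1)

  feats <- data.frame(subject_id = d$subject, group = d$group,
                      stim_id = rep(seq_len(30), 10), interval = "pre",
                      d$x, check.names = FALSE)
  expect_identical(unname(interval_accuracy(m, feats)["pre"]), 1)
})

test_that("pure-noise features give chance-level LOSO accuracy", {
  d <- make_features(informative = 0, seed = 42)
  m <- train_loso_lasso(d$x, d$subject, d$group)
  expect_gte(mean(m$fold_accuracy), 0.40)
  expect_lte(mean(m$fold_accuracy), 0.60)
})

test_that("duplicating every subject's trials leaves the model unchanged", {
  d <- make_features(informative = 3, sep = 1.2, seed = 7)
  m1 <- train_loso_lasso(d$x, d$subject, d$group)
  m2 <- train_loso_lasso(rbind(d$x, d$x), c(d$subject, d$subject),
                         c(d$group, d$group))
  # equality up to floating-point jitter of the CV lambda-grid selection
  expect_equal(m2$weights, m1$weights, tolerance = 1e-2)
  expect_equal(m2$intercept, m1$intercept, tolerance = 1e-2)
})

test_that("training is deterministic and affine-invariant in feature scale", {
  d <- make_features(informative = 2, sep = 1.5, seed = 3)
  m1 <- train_loso_lasso(d$x, d$subject, d$group)
  m2 <- train_loso_lasso(d$x, d$subject, d$group)
  expect_identical(m1$weights, m2$weights)

  x_scaled <- d$x
  x_scaled[, 4] <- x_scaled[, 4] * 37
  x_scaled[, 9] <- x_scaled[, 9] * 0.001
  m3 <- train_loso_lasso(x_scaled, d$subject, d$group)
  expect_equal(score_features(m3, x_scaled), score_features(m1, d$x),
               tolerance = 1e-8)
})

test_that("training validates its inputs", {
  d <- make_features()
  one_class <- rep("PD", length(d$group))
  expect_error(train_loso_lasso(d$x, d$subject, one_class), "2 subjects")
})

test_that("scoring follows the standardized linear predictor exactly", {
  model <- structure(list(
    weights = stats::setNames(c(2, rep(0, 15)), biomarker_names()),
    intercept = 0,
    feature_means = stats::setNames(rep(0, 16), biomarker_names()),
    feature_sds = stats::setNames(rep(1, 16), biomarker_names())),
    class = "composite_model")
  x <- matrix(0, 1, 16); x[1] <- 1.5
  expect_identical(score_features(model, x), 3.0)

  model$weights[] <- 0
  expect_identical(score_features(model, matrix(rnorm(32), 2, 16)), c(0, 0))

  model$weights[] <- rnorm(16)
  model$intercept <- 1.23
  model$feature_means[] <- rnorm(16)
  expect_equal(score_features(model, model$feature_means), 1.23)

  expect_error(score_features(model, matrix(0, 2, 15)), "15 columns")
})

test_that("healthy reference is a guarded arithmetic mean", {
  expect_identical(healthy_reference(c(1, 2, 3)), 2)
  df <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                   score = c(5, 5, 5, 5, 5, 5))
  expect_identical(healthy_reference(df), 5)
  expect_identical(healthy_reference(df[sample(6), ]), 5)
  expect_error(healthy_reference(data.frame(subject_id = c("a", "a", "b"),
                                            score = c(1, 2, 3))), "unequal")
  df$score[2] <- NA
  expect_error(healthy_reference(df), "imputation")
})

test_that("reference distances are absolute deviations", {
  m <- matrix(c(2, 0.5, -1), 3, 1)
  d <- reference_distances(m, 0.5)
  expect_identical(as.numeric(d), c(1.5, 0, 1.5))
})

test_that("model JSON round-trips and reproduces scores", {
  d <- make_features(informative = 1, sep = 1.5, seed = 11)
  m <- train_loso_lasso(d$x, d$subject, d$group)
  path <- withr::local_tempfile(fileext = ".json")
  write_composite_model(m, path)
  m2 <- read_composite_model(path)
  expect_equal(score_features(m2, d$x), score_features(m, d$x),
               tolerance = 1e-12)
  expect_equal(m2$lambda_per_fold, m$lambda_per_fold)
})
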