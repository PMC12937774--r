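test_that("subject ranks are within-column with the rank-sum identity", {
  d <- matrix(c(0.1, 0.3, 0.2,
                0.5, 0.4, 0.6), 3, 2)
  r <- subject_ranks(d)
  expect_identical(r[, 1], c(1, 3, 2))
  expect_identical(r[, 2], c(2, 1, 3))
  set.seed(2)
  big <- matrix(runif(304 * 5), 304, 5)
  expect_true(all(colSums(subject_ranks(big)) == 304 * 305 / 2))
  tied <- subject_ranks(matrix(c(1, 1, 2), 3, 1))
  expect_identical(tied[, 1], c(1.5, 1.5, 3))
})

test_that("category medians exclude singletons and use standard medians", {
  lib <- build_default_library()
  set.seed(1)
  dist <- matrix(runif(304 * 5), 304, 5,
                 dimnames = list(as.character(1:304), paste0("pd", 1:5)))
  med <- median_ranks_by_category(subject_ranks(dist), lib)
  expect_identical(dim(med), c(35L, 5L))
  expect_false(any(rownames(med) %in% c("1", "37")))  # the two singletons

  # hand-checked medians via a 5-stimulus toy grouping
  toy_rank <- matrix(c(10, 20, 300, 10, 20), 5, 1,
                     dimnames = list(as.character(1:5), "s"))
  toy_lib <- list(
    stimulus_spec(1L, "sinusoid", list(carrier_hz = 1), 1, 1L, "a"),
    stimulus_spec(2L, "sinusoid", list(carrier_hz = 2), 1, 1L, "a"),
    stimulus_spec(3L, "sinusoid", list(carrier_hz = 3), 1, 1L, "a"),
    stimulus_spec(4L, "sinusoid", list(carrier_hz = 4), 1, 2L, "b"),
    stimulus_spec(5L, "sinusoid", list(carrier_hz = 5), 1, 2L, "b"))
  toy <- median_ranks_by_category(toy_rank, toy_lib)
  expect_identical(toy["1", "s"], 20)
  expect_identical(toy["2", "s"], 15)
})

test_that("Kendall's W spans perfect agreement to exact disagreement", {
  base <- 1:35
  perfect <- matrix(rep(base, 5), 35, 5)
  w <- kendalls_w(perfect)
  expect_equal(w$W, 1)
  expect_lt(w$p, 1e-10)

  reversed <- cbind(base, rev(base))
  expect_equal(kendalls_w(reversed)$W, 0)

  expect_error(kendalls_w(matrix(1:4, 2, 2)), "3 items")
  expect_error(kendalls_w(matrix(1:3, 3, 1)), "2 raters")
})

test_that("Kendall's W chi-square p-values are null-calibrated", {
  set.seed(99)
  ps <- replicate(400, {
    x <- replicate(5, sample(35))
    kendalls_w(x)$p
  })
  # W is discrete under the null, so ks.test warns about tied values
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))$p.value
  expect_gt(ks, 0.01)
})

test_that("category rank-sum test matches the exhaustive permutation oracle", {
  # category {1,2} vs complement {3,4,5}: minimal rank sum
  res <- category_wilcoxon(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "b"))
  # oracle: enumerate all C(5,2) member-rank subsets
  combs <- utils::combn(5, 2)
  sums <- colSums(matrix(c(1:5)[combs], 2))
  p_exact <- mean(sums <= sum(c(1, 2)))
  expect_equal(p_exact, 0.1)
  expect_equal(res$p[1], 0.1)

  expect_error(category_wilcoxon(c(1, 2), c("a", "a")), "complement")
})

test_that("category test type-I error is calibrated at the 304-rank scale", {
  lib_cats <- library_table(build_default_library())$category_id
  set.seed(31)
  rej <- replicate(400, {
    ranks <- sample(304)
    cat8 <- sample(304, 8)
    inside <- seq_len(304) %in% cat8
    p <- stats::wilcox.test(ranks[inside], ranks[!inside],
                            alternative = "less")$p.value
    p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("BH q-values equal the brute-force step-up rule", {
  r <- bh_fdr(c(0.005, 0.02, 0.03, 0.1), q_threshold = 0.1)
  expect_true(all(r$reject))
  expect_identical(bh_fdr(rep(1, 6))$reject, rep(FALSE, 6))
  r1 <- bh_fdr(0.04, q_threshold = 0.05)
  expect_identical(r1$q, 0.04)
  expect_true(r1$reject)
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")

  brute_force_q <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
    }
    q
  }
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$q, brute_force_q(p), tolerance = 1e-12)
  }
  # agreement with the reference implementation
  p <- runif(25)
  expect_equal(bh_fdr(p)$q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("Spearman correlation handles monotone extremes and the null", {
  x <- runif(304)
  expect_equal(spearman_ses(x, x)$rho, 1)
  expect_equal(spearman_ses(x, -x)$rho, -1)
  expect_error(spearman_ses(rep(1, 10), runif(10)), "constant")

  set.seed(55)
  sims <- replicate(400, {
    s <- spearman_ses(runif(304), runif(304))
    c(s$rho, s$p)
  })
  expect_equal(mean(sims[1, ]), 0, tolerance = 0.01)
  expect_gt(stats::ks.test(sims[2, ], "punif")$p.value, 0.01)
})

test_that("paired-t channel maps: null difference gives t 0, p 1, q 1", {
  set.seed(6)
  grid <- expand.grid(subject_id = c("p1", "p2"), stim_id = 1:5,
                      channel = c("Cz", "C3"), stringsAsFactors = FALSE)
  vals <- runif(nrow(grid))
  df <- rbind(cbind(grid, interval = "pre", value = vals),
              cbind(grid, interval = "stim", value = vals))
  maps <- interval_ttest_maps(df, "value", comparisons = list(c("pre", "stim")))
  expect_identical(nrow(maps), 2L)
  expect_true(all(maps$t == 0))
  expect_true(all(maps$p == 1))
  expect_true(all(maps$q == 1))
  expect_true(all(maps$neglog10_q == 0))

  tiny <- df[df$stim_id <= 1, ]
  expect_error(interval_ttest_maps(tiny, "value",
                                   comparisons = list(c("pre", "stim"))),
               "3 paired")
})

test_that("paired-t maps detect a planted per-channel shift", {
  set.seed(23)
  grid <- expand.grid(subject_id = paste0("p", 1:3), stim_id = 1:20,
                      channel = paste0("ch", 1:6), stringsAsFactors = FALSE)
  pre <- cbind(grid, interval = "pre", value = rnorm(nrow(grid)))
  stim <- cbind(grid, interval = "stim", value = rnorm(nrow(grid)))
  stim$value[stim$channel %in% c("ch1", "ch2")] <-
    stim$value[stim$channel %in% c("ch1", "ch2")] + 2
  maps <- interval_ttest_maps(rbind(pre, stim), "value",
                              comparisons = list(c("pre", "stim")))
  expect_identical(sort(maps$channel[maps$significant]), c("ch1", "ch2"))
})
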