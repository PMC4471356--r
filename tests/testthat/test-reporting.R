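test_that("window deviations match direct computation", {
  fs <- 100
  set.seed(50)
  m <- small_montage(3)
  data <- rbind(rnorm(10 * fs), rep(4, 10 * fs), rnorm(10 * fs, 0, 8))
  rec <- recording(data, fs, m)
  D <- compute_window_deviations(rec)
  expect_equal(dim(D), c(3L, 10L))
  expect_lt(abs(mean(D[1, ]) - 1), 0.15)          # unit-variance noise
  expect_equal(unname(D[2, ]), rep(0, 10))        # constant channel
  expect_gt(median(D[3, ]) / median(D[1, ]), 6)   # 8x amplitude channel
  # direct oracle on one window
  expect_equal(unname(D[1, 3]), 0.7413 * (quantile7_oracle(data[1, 201:300], .75) -
                                    quantile7_oracle(data[1, 201:300], .25)),
               tolerance = 1e-12)
})

test_that("dataset summary fields are coherent on a clean run", {
  rec <- toy_recording(n_sec = 20, nch = 8, seed = 51)
  pr <- perform_reference(rec, seed = 52)
  s <- dataset_summary(pr$recording, pr$result, original = rec,
                       stage = "final")
  expect_equal(s$interpolated_fraction, 0)
  expect_gt(s$reference_correlation, 1 - 1e-9)
  expect_true(s$mean_max_correlation > 0.4 && s$mean_max_correlation <= 1)
  # deviation ratio: definition vs oracle over the flattened array
  D <- compute_window_deviations(pr$recording)
  expect_equal(s$deviation_ratio,
               robust_sd(as.vector(D)) / median(as.vector(D)),
               tolerance = 1e-12)
  expect_error(dataset_summary(pr$recording,
                               structure(list(), class = "reference_result"),
                               stage = "final"), "snapshot")
})

test_that("issue flags implement the three criteria", {
  mk <- function(mean_max, med_max, mean_med, interp) {
    structure(list(mean_max_correlation = mean_max,
                   median_max_correlation = med_max,
                   mean_median_max_correlation = mean_med,
                   interpolated_fraction = interp),
              class = "dataset_summary")
  }
  base <- mk(0.85, 0.90, 0.85, 0)
  # 9 of 32 channels interpolated = 0.28 > 0.25
  f1 <- flag_issues(base, mk(0.85, 0.90, 0.85, 9 / 32))
  expect_true(f1$too_many_interpolated)
  f2 <- flag_issues(base, mk(0.85, 0.90, 0.85, 0.25))
  expect_false(f2$too_many_interpolated)
  # correlation-too-high needs both cutoffs exceeded
  expect_false(flag_issues(base, mk(0.85, 0.90, 0.85, 0))$corr_too_high)
  expect_true(flag_issues(base, mk(0.93, 0.96, 0.93, 0))$corr_too_high)
  expect_false(flag_issues(base, mk(0.93, 0.94, 0.93, 0))$corr_too_high)
  # not-moved-closer: outside interval and no improvement
  before <- mk(0.9, 0.9, 0.75, 0)
  expect_true(flag_issues(before, mk(0.9, 0.9, 0.74, 0))$corr_not_improved)
  expect_false(flag_issues(before, mk(0.9, 0.9, 0.85, 0))$corr_not_improved)
  # inside the interval initially: never flagged
  expect_false(flag_issues(mk(.9, .9, .85, 0),
                           mk(.9, .9, .70, 0))$corr_not_improved)
  # monotone in interpolated fraction
  flags <- vapply(seq(0, 0.5, by = 0.05), function(p)
    flag_issues(base, mk(0.85, 0.9, 0.85, p))$too_many_interpolated,
    logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("collection summary aggregates and lists issues", {
  mk <- function(x) structure(list(
    mean_max_correlation = x, mean_median_max_correlation = x,
    median_max_correlation = x, median_window_deviation = 5,
    deviation_ratio = 0.4, interpolated_fraction = 0,
    reference_correlation = 1), class = "dataset_summary")
  tab1 <- collection_summary(list(mk(0.9)))
  expect_equal(nrow(tab1), 2L)
  expect_equal(tab1$mean_max_correlation[1], tab1$mean_max_correlation[2])
  tab <- collection_summary(list(mk(0.8), mk(0.9), mk(0.85)),
                            flags = list(
                              structure(list(corr_not_improved = FALSE,
                                             corr_too_high = TRUE,
                                             too_many_interpolated = FALSE),
                                        class = "issue_flags"),
                              structure(list(corr_not_improved = FALSE,
                                             corr_too_high = FALSE,
                                             too_many_interpolated = FALSE),
                                        class = "issue_flags"),
                              structure(list(corr_not_improved = FALSE,
                                             corr_too_high = FALSE,
                                             too_many_interpolated = FALSE),
                                        class = "issue_flags")),
                            ids = c("a", "b", "c"))
  expect_equal(tab$mean_max_correlation[4], 0.85)
  expect_identical(attr(tab, "issues"), list(a = "corr_too_high"))
  expect_error(collection_summary(list()), "empty")
})

test_that("the stored container reproduces the report deterministically", {
  rec <- toy_recording(n_sec = 15, nch = 8, seed = 53)
  pr <- perform_reference(rec, seed = 54)
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "result.json")
  write_result(pr$recording, pr$result, cpath)
  live <- write_report(pr$recording, pr$result, original = NULL,
                       path = file.path(dir, "live.json"))
  stored <- run_report(cpath, file.path(dir, "stored.json"))
  for (stage in c("original", "before_interp", "final")) {
    for (k in c("mean_max_correlation", "median_max_correlation",
                "median_window_deviation", "deviation_ratio"))
      expect_equal(stored$summary[[stage]][[k]], live$summary[[stage]][[k]],
                   tolerance = 1e-12)
  }
  expect_identical(stored$interpolated, live$interpolated)
})
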