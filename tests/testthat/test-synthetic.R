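test_that("generation is deterministic given the seed", {
  sp <- synthetic_spec(duration_seconds = 10, seed = 60)
  r1 <- generate_clean(sp)
  r2 <- generate_clean(sp)
  expect_identical(r1$data, r2$data)
  r3 <- generate_clean(synthetic_spec(duration_seconds = 10, seed = 61))
  expect_false(identical(r1$data, r3$data))
})

test_that("the clean spectrum has the stated features", {
  sp <- synthetic_spec(duration_seconds = 60, seed = 62)
  rec <- generate_clean(sp)
  hp <- fir_filter(rec, kind = "highpass", cutoff_hz = 1)
  p <- periodogram_db(hp$data[5, ], rec$fs)
  # approximate 1/f: power at 4 Hz well above power at 30 Hz
  band <- function(lo, hi) mean(p$p[p$f >= lo & p$f <= hi])
  expect_gt(band(3, 5) - band(25, 35), 6)
  # 60 Hz line present before removal, gone after
  peak <- function(v) {
    q <- periodogram_db(v, rec$fs)
    max(q$p[q$f > 59 & q$f < 61]) -
      stats::median(q$p[(q$f > 55 & q$f < 58) | (q$f > 62 & q$f < 65)])
  }
  expect_gt(peak(hp$data[5, ]), 15)
  cl <- remove_line_noise_filtered(hp)
  expect_gt(peak(hp$data[5, ]) - peak(cl$clean$data[5, ]), 12)
})

test_that("drift slopes span the configured range", {
  sp <- synthetic_spec(duration_seconds = 30, seed = 63)
  rec <- generate_clean(sp)
  slopes <- apply(rec$data, 1L, function(v) fit_linear_trend(v)$slope)
  expect_gt(max(slopes), 4)
  expect_lt(min(slopes), 0.5)
  expect_true(all(slopes > -1.5 & slopes < 8.5))
})

test_that("injections have their stated signatures", {
  sp <- synthetic_spec(duration_seconds = 30, seed = 64)
  rec <- generate_clean(sp)
  labs <- rec$montage$labels
  plan <- ground_truth(c(F3 = "gaussian", Pz = "shuffled",
                         O1 = "correlated_pair", O2 = "correlated_pair",
                         C4 = "low_amplitude"), "t")
  set.seed(65)
  donor <- eegpipe:::pink_series(ncol(rec$data), rec$fs) * 30
  inj <- inject_bad_channels(rec, plan, donor = donor, seed = 66)
  # gaussian: sd multiplied by ~sqrt(1 + 8^2)
  expect_lt(abs(sd(inj$data["F3", ]) / sd(rec$data["F3", ]) - sqrt(65)) /
              sqrt(65), 0.05)
  # shuffled: identical marginal distribution
  expect_identical(sort(inj$data["Pz", ]), sort(rec$data["Pz", ]))
  expect_lt(abs(cor(inj$data["Pz", ], rec$data["Pz", ])), 0.1)
  # correlated pair: exactly correlated, amplitude-normalized
  expect_equal(cor(inj$data["O1", ], inj$data["O2", ]), 1)
  expect_equal(robust_sd(inj$data["O1", ]), robust_sd(rec$data["O1", ]),
               tolerance = 1e-9)
  # low amplitude: scalp signal scaled to one tenth
  expect_lt(sd(inj$data["C4", ]) / sd(rec$data["C4", ]), 0.2)
  # untouched channels bit-identical
  expect_identical(inj$data["Fz", ], rec$data["Fz", ])
  expect_error(inject_bad_channels(rec, ground_truth(c(XX = "gaussian"))),
               "unknown channels")
  expect_error(ground_truth(c(F3 = "sparkle")), "unknown injection")
  expect_error(ground_truth(c(F3 = "correlated_pair")), "pairs")
})

test_that("benchmark bookkeeping matches the published design", {
  tab <- eegpipe:::benchmark_sessions()
  expect_identical(tab$session, c("5", "14", "30", "31", "68"))
  totals <- rowSums(tab[, -1])
  expect_equal(totals, c(7, 7, 8, 10, 10))
  expect_equal(sum(totals), 42)
  expect_equal(unlist(tab[tab$session == "30", -1], use.names = FALSE),
               c(4L, 1L, 1L, 2L))
  expect_equal(unlist(tab[tab$session == "31", -1], use.names = FALSE),
               c(5L, 1L, 2L, 2L))
})

test_that("build_benchmark injects per plan with distinct channels", {
  # small/fast: skip the preprocessing stage, geometry unchanged
  sp <- synthetic_spec(duration_seconds = 20, seed = 67)
  bench <- build_benchmark(seed = 67, spec = sp, preprocess = FALSE)
  expect_length(bench, 5L)
  n_inj <- vapply(bench, function(b) length(b$truth$injected), 0L)
  expect_equal(n_inj, c(7L, 7L, 8L, 10L, 10L))
  expect_equal(sum(vapply(bench, function(b) nrow(b$recording$data), 0L)),
               160L)
  for (b in bench) {
    expect_false(anyDuplicated(names(b$truth$injected)) > 0)
    pair <- names(b$truth$injected)[b$truth$injected == "correlated_pair"]
    expect_equal(cor(b$recording$data[pair[1], ],
                     b$recording$data[pair[2], ]), 1)
  }
})

test_that("scoring implements the stated rates", {
  m <- montage_std32()
  truth <- ground_truth(stats::setNames(rep("gaussian", 4), m$labels[1:4]))
  mk_res <- function(detected) {
    structure(list(bad_all = detected, channels = m$labels),
              class = "noisy_channels")
  }
  perfect <- score_detection(list(mk_res(m$labels[1:4])), list(truth))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  nothing <- score_detection(list(mk_res(character(0))), list(truth))
  expect_equal(nothing$sensitivity, 0)
  expect_equal(nothing$specificity, 1)
  # frozen published confusion: TP=34 FP=3 TN=115 FN=8 -> 81% / 97%
  expect_equal(round(100 * 34 / (34 + 8)), 81)
  expect_equal(round(100 * 115 / (115 + 3)), 97)
  # order invariance
  truth2 <- ground_truth(stats::setNames("shuffled", m$labels[9]))
  a <- score_detection(list(mk_res(m$labels[1:3]), mk_res(m$labels[9])),
                       list(truth, truth2))
  b <- score_detection(list(mk_res(m$labels[9]), mk_res(m$labels[1:3])),
                       list(truth2, truth))
  expect_equal(a[c("tp", "fp", "tn", "fn")], b[c("tp", "fp", "tn", "fn")])
  expect_error(score_detection(list(mk_res("x")), list(truth, truth2)),
               "length")
})

test_that("realism gate: clean sessions produce no flags", {
  # deeper, many-seed verification happens through the acceptance
  # benchmark (specificity); here a direct spot check on two seeds
  for (seed in c(70, 71)) {
    sp <- synthetic_spec(duration_seconds = 120, seed = seed)
    rec <- generate_clean(sp)
    cl <- clean_line_noise(rec)$clean
    nz <- find_noisy_channels(cl, seed = seed)
    expect_length(nz$bad_all, 0)
  }
})
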