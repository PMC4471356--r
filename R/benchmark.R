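# Per-session injected-channel counts of the five-session benchmark:
# columns gaussian / low_amplitude / shuffled / correlated_pair.
benchmark_sessions <- function() {
  data.frame(session = c("5", "14", "30", "31", "68"),
             gaussian = c(3L, 3L, 4L, 5L, 5L),
             low_amplitude = c(1L, 1L, 1L, 1L, 1L),
             shuffled = c(1L, 1L, 1L, 2L, 2L),
             correlated_pair = c(2L, 2L, 2L, 2L, 2L),
             stringsAsFactors = FALSE)
}

#' Build the five-session synthetic bad-channel benchmark
#'
#' Generates five clean synthetic 32-channel sessions, preprocesses
#' each (temporary 1 Hz high-pass + multitaper line-noise removal, as
#' the detection battery assumes), then injects bad channels with the
#' per-session counts of the benchmark design: 42 injected bad
#' channels over 5 x 32 = 160 channel decisions.  Injected channel
#' identities are drawn at random per seed; the correlated-pair donor
#' is the highest-robust-SD channel of the next session's clean data.
#'
#' @param seed integer seed (controls generation and injection).
#' @param spec base [synthetic_spec()]; its seed field is overridden
#'   per session.
#' @param preprocess apply the 1 Hz high-pass + line-noise removal to
#'   the clean base before injection (default `TRUE`).
#' @param line_params a [line_noise_params()].
#' @return list of five elements, each a list with `recording`
#'   (injected), `clean` (preprocessed base) and `truth`
#'   (a [ground_truth()]).
#' @export
build_benchmark <- function(seed = 1L, spec = synthetic_spec(),
                            preprocess = TRUE,
                            line_params = line_noise_params()) {
  tab <- benchmark_sessions()
  nses <- nrow(tab)
  cleaned <- vector("list", nses)
  for (i in seq_len(nses)) {
    sp <- spec
    sp$seed <- (as.integer(seed) * 131L + i) %% 2147483647L
    raw <- generate_clean(sp)
    cleaned[[i]] <- if (preprocess) {
      hp <- fir_filter(raw, kind = "highpass",
                       cutoff_hz = line_params$detection_highpass_hz)
      remove_line_noise_filtered(hp, line_params)$clean
    } else raw
  }
  out <- vector("list", nses)
  for (i in seq_len(nses)) {
    rec <- cleaned[[i]]
    counts <- tab[i, c("gaussian", "low_amplitude", "shuffled",
                       "correlated_pair")]
    types <- rep(names(counts), times = unlist(counts))
    plan <- with_seed(seed * 977L + i, {
      chans <- sample(rec$montage$labels, length(types))
      ground_truth(stats::setNames(types, chans),
                   session_id = tab$session[i])
    })
    donor_rec <- cleaned[[i %% nses + 1L]]
    donor_ch <- names(which.max(apply(donor_rec$data, 1L, robust_sd)))
    out[[i]] <- list(
      recording = inject_bad_channels(rec, plan,
                                      donor = donor_rec$data[donor_ch, ],
                                      noise_floor = spec$noise_floor,
                                      seed = seed * 613L + i),
      clean = rec, truth = plan)
  }
  out
}

#' Run the detection battery on a benchmark
#'
#' Applies [find_noisy_channels()] with default thresholds to each
#' session of a [build_benchmark()] result.
#'
#' @param bench a benchmark list.
#' @param params a [noisy_params()].
#' @param seed RANSAC seed.
#' @return list of `noisy_channels` results, one per session.
#' @export
detect_benchmark <- function(bench, params = noisy_params(), seed = 1L) {
  lapply(seq_along(bench), function(i)
    find_noisy_channels(bench[[i]]$recording, params,
                        seed = seed * 389L + i))
}

#' Score detection results against ground truth
#'
#' Confusion counts over all channel decisions: a channel counts as
#' detected when it appears in any bad category.  Sensitivity is
#' TP/(TP+FN), specificity TN/(TN+FP).
#'
#' @param results list of `noisy_channels` results (or character
#'   vectors of detected labels).
#' @param truths list of [ground_truth()] objects, same length.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `n_decisions` and `by_type` (per-injection-type
#'   detected / injected counts).
#' @export
score_detection <- function(results, truths) {
  if (length(results) != length(truths))
    stop("results and truths differ in length")
  tp <- fp <- tn <- fn <- 0L
  types <- c("gaussian", "low_amplitude", "shuffled", "correlated_pair")
  by_type <- matrix(0L, 2L, length(types),
                    dimnames = list(c("detected", "injected"), types))
  n_dec <- 0L
  for (i in seq_along(results)) {
    r <- results[[i]]
    detected <- if (inherits(r, "noisy_channels")) r$bad_all
    else as.character(r)
    truth <- truths[[i]]
    stopifnot(inherits(truth, "ground_truth"))
    all_ch <- if (inherits(r, "noisy_channels")) r$channels
    else union(detected, names(truth$injected))
    bad_true <- names(truth$injected)
    n_dec <- n_dec + length(all_ch)
    tp <- tp + length(intersect(detected, bad_true))
    fp <- fp + length(setdiff(detected, bad_true))
    fn <- fn + length(setdiff(bad_true, detected))
    tn <- tn + length(setdiff(all_ch, union(detected, bad_true)))
    for (ty in types) {
      inj <- names(truth$injected)[truth$injected == ty]
      by_type["injected", ty] <- by_type["injected", ty] + length(inj)
      by_type["detected", ty] <- by_type["detected", ty] +
        length(intersect(inj, detected))
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n_decisions = n_dec, by_type = by_type)
}

#' Benchmark sensitivity and specificity over several seeds
#'
#' Full end-to-end run: for each seed, build the five-session
#' benchmark, run the detection battery, score against ground truth;
#' rates are averaged over seeds.
#'
#' @param seeds integer vector of seeds.
#' @param spec base [synthetic_spec()].
#' @param params a [noisy_params()].
#' @param verbose print one line per seed.
#' @return list with `sensitivity`, `specificity` (mean over seeds),
#'   `per_seed` data.frame and `n_decisions` (total).
#' @export
run_benchmark <- function(seeds = 1:10, spec = synthetic_spec(),
                          params = noisy_params(), verbose = FALSE) {
  rows <- lapply(seeds, function(sd) {
    bench <- build_benchmark(sd, spec)
    res <- detect_benchmark(bench, params, seed = sd)
    sc <- score_detection(res, lapply(bench, `[[`, "truth"))
    if (verbose)
      message(sprintf("seed %d: sens %.3f spec %.3f (TP %d FP %d TN %d FN %d)",
                      sd, sc$sensitivity, sc$specificity,
                      sc$tp, sc$fp, sc$tn, sc$fn))
    data.frame(seed = sd, sensitivity = sc$sensitivity,
               specificity = sc$specificity, tp = sc$tp, fp = sc$fp,
               tn = sc$tn, fn = sc$fn, n_decisions = sc$n_decisions)
  })
  per_seed <- do.call(rbind, rows)
  list(sensitivity = mean(per_seed$sensitivity),
       specificity = mean(per_seed$specificity),
       per_seed = per_seed, n_decisions = sum(per_seed$n_decisions))
}
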