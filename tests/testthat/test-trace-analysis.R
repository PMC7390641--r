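test_that("trace constructor enforces uniform sampling", {
  expect_error(fluorescence_trace(c(0, 0.05, 0.09), rep(1, 3)), "10 samples")
  expect_error(fluorescence_trace(seq(0, 1, 0.1)[c(1:9, 11)], rep(1, 10)),
               "uniform")
  tr <- fluorescence_trace(seq(0, 0.45, 0.05), 1:10)
  expect_equal(tr$frame_period, 0.05)
})

test_that("baseline estimation recovers flat traces and generator truth", {
  flat <- fluorescence_trace(seq(0, 9.95, 0.05), rep(42, 200))
  expect_equal(estimate_baseline(flat), 42)
  # zero-noise synthetic trial: baseline equals the generator truth
  sim <- quick_trial(5, noise_sd = 0)
  expect_equal(estimate_baseline(sim$trace), 100, tolerance = 1e-3)
  # explicit peak regions
  pk <- data.frame(t_onset = 2, t_offset = 4)
  tr <- fluorescence_trace(seq(0, 9.95, 0.05), c(rep(10, 40), rep(99, 41),
                                                 rep(10, 119)))
  expect_equal(estimate_baseline(tr, pk), 10)
  all_pk <- data.frame(t_onset = 0, t_offset = 10)
  expect_error(estimate_baseline(tr, all_pk), "inter-peak")
})

test_that("noisy baseline error respects the median sampling bound", {
  errs <- vapply(1:20, function(s) {
    sim <- quick_trial(5, tau_decay = 1.4, amplitude = 0.25,
                       noise_sd = 0.02, seed = s)
    an <- analyze_trace(sim$trace)
    pad <- data.frame(t_onset = an$peaks$t_onset,
                      t_offset = an$peaks$t_offset +
                        3 * (an$peaks$t_offset - an$peaks$t_max))
    n_base <- sum(sim$trace$times < an$peaks$t_onset[1]) +
      sum(sim$trace$times > max(pad$t_offset))
    c(abs(an$f_base - 100), 3 * 0.02 * 100 / sqrt(n_base))
  }, numeric(2))
  # Monte-Carlo: the mean error sits well inside the 3-sigma-of-the-median
  # bound, and no single replicate strays far beyond it
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
  expect_lt(max(errs[1, ] / errs[2, ]), 1.5)
})

test_that("peak detection finds each stimulus-locked transient", {
  flat <- fluorescence_trace(seq(0, 9.95, 0.05), rep(7, 200))
  expect_equal(nrow(detect_peaks(flat)), 0)
  # single kernel event at zero noise: one peak at the analytic peak time
  k <- kernel_params(0.05, 0.7, 0.2)
  times <- seq(0, 30, by = 0.05)
  tr <- fluorescence_trace(times, 100 * (1 + gcamp_kernel(times - 10, k)))
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$t_max - (10 + kernel_peak_time(k))), 0.05 + 1e-9)
  expect_gt(pk$f_max, pk$f_base)
  # ten-cycle trial at default noise: ten transients
  sim <- quick_trial(5, noise_sd = 0.02, seed = 12L)
  expect_equal(nrow(detect_peaks(sim$trace)), 10)
})

test_that("detected peaks are sorted, non-overlapping and base-bracketed", {
  sim <- quick_trial(4.5, noise_sd = 0.02, seed = 21L)
  pk <- detect_peaks(sim$trace)
  expect_sorted(pk$t_onset)
  expect_true(all(pk$t_onset < pk$t_max & pk$t_max < pk$t_offset))
  expect_true(all(pk$t_onset[-1] >= pk$t_offset[-nrow(pk)] - 1e-9))
  expect_equal(pk$duration, pk$t_offset - pk$t_onset)
  expect_true(all(pk$fwhm <= pk$duration + 1e-9))
})

test_that("detection count matches event count at any sub-amplitude prominence", {
  sim <- quick_trial(5, amplitude = 0.2, noise_sd = 0)
  for (prom in c(1, 5, 15)) {  # a.u., all below the 20 a.u. amplitude
    expect_equal(nrow(detect_peaks(sim$trace, min_prominence = prom)),
                 length(sim$event_times))
  }
})

test_that("double tops merge into one peak and merging is idempotent", {
  k <- kernel_params(0.05, 0.7, 0.2)
  times <- seq(0, 40, by = 0.05)
  two <- function(gap, at = 15) {
    fluorescence_trace(times, 100 * (1 + gcamp_kernel(times - at, k) +
                                       gcamp_kernel(times - at - gap, k)))
  }
  # 0.3 s apart: valley stays high -> one merged peak
  tr <- two(0.3)
  pk <- detect_peaks(tr, min_separation = 0.1)
  expect_equal(nrow(pk), 2)
  merged <- merge_double_tops(pk, tr, merge_window = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$merged_from, 2L)
  expect_equal(merged$t_onset, pk$t_onset[1])
  expect_equal(merged$t_offset, pk$t_offset[2])
  # idempotent
  expect_equal(merge_double_tops(merged, tr, 1), merged)
  # well-separated peaks pass through unchanged
  tr2 <- two(8)
  pk2 <- detect_peaks(tr2)
  expect_equal(merge_double_tops(pk2, tr2, 1), pk2)
})

test_that("artifact rules flag spikes and pre-stimulus onsets", {
  sim <- quick_trial(5, noise_sd = 0.02, seed = 31L)
  pk <- flag_artifacts(detect_peaks(sim$trace), sim$trace,
                       t_move_start = 10)
  expect_equal(sum(pk$is_artifact), 0)
  # inject a one-frame spike of 10x the transient amplitude
  v <- sim$trace$values
  i_spike <- which.min(abs(sim$trace$times - 60.2))
  v[i_spike] <- 100 + 10 * 20
  tr_sp <- fluorescence_trace(sim$trace$times, v)
  pks <- detect_peaks(tr_sp)
  pks <- flag_artifacts(pks, tr_sp, t_move_start = 10)
  spike_row <- which.min(abs(pks$t_max - 60.2))
  expect_true(pks$is_artifact[spike_row])
  # a peak whose onset precedes motion start is flagged
  pk2 <- detect_peaks(sim$trace)
  expect_true(all(flag_artifacts(pk2, sim$trace,
                                 t_move_start = 200)$is_artifact))
})

test_that("first-five selection drops artifacts then truncates", {
  sim <- quick_trial(5, noise_sd = 0)
  pk <- detect_peaks(sim$trace)
  expect_equal(nrow(pk), 10)
  expect_equal(nrow(select_first_n(pk)), 5)
  expect_equal(select_first_n(pk)$t_onset, pk$t_onset[1:5])
  expect_equal(nrow(select_first_n(pk[1:3, ])), 3)
  # flagging peak 2 promotes peak 6
  pk$is_artifact[2] <- TRUE
  sel <- select_first_n(pk)
  expect_equal(sel$t_onset, pk$t_onset[c(1, 3, 4, 5, 6)])
})

test_that("fwhm matches closed forms for triangular and Gaussian peaks", {
  # symmetric triangle of base width 4 s -> fwhm = 2 s
  times <- seq(0, 30, by = 0.05)
  tri <- pmax(0, 1 - abs(times - 15) / 2)
  tr <- fluorescence_trace(times, 10 + 20 * tri)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_equal(fwhm(pk, tr), 2, tolerance = 0.05 / 2)
  # Gaussian sigma = 0.4 -> 2 sqrt(2 log 2) * 0.4 = 0.9419 s
  g <- gaussian_trace(sigma = 0.4)
  pkg_ <- detect_peaks(g)
  expect_lt(abs(fwhm(pkg_, g) - 2 * sqrt(2 * log(2)) * 0.4), 0.05)
  # random widths: estimator error below one frame period
  set.seed(8)
  for (sigma in runif(50, 0.15, 1.5)) {
    gt <- gaussian_trace(sigma = sigma, t_end = 25)
    p <- detect_peaks(gt)
    expect_equal(nrow(p), 1)
    expect_lt(abs(fwhm(p, gt) - 2 * sqrt(2 * log(2)) * sigma), 0.05)
  }
})

test_that("fwhm errors when the half level is not bracketed", {
  g <- gaussian_trace(sigma = 0.4)
  pk <- detect_peaks(g)
  pk$t_onset <- pk$t_max - 0.01  # squeeze the bracket inside the half level
  pk$t_offset <- pk$t_max + 0.01
  expect_error(fwhm(pk, g), "bracketed")
})

test_that("shape metrics follow the generator periodicity", {
  sim <- quick_trial(5, noise_sd = 0)
  pk <- detect_peaks(sim$trace)
  expect_equal(length(inter_peak_intervals(pk)), nrow(pk) - 1)
  period <- cycle_period(default_kin())
  expect_equal(inter_peak_intervals(pk),
               rep(period, 9) - duration(pk)[1:9], tolerance = 0.05)
  expect_equal(fmax_fbase(pk), pk$f_max / pk$f_base)
  expect_equal(inter_peak_intervals(pk[1, , drop = FALSE]), numeric(0))
})

test_that("maxima agree with an independent peak finder", {
  sim <- quick_trial(5, noise_sd = 0.02, seed = 55L)
  pk <- detect_peaks(sim$trace)
  expect_equal(nrow(pk), 10)
  if (requireNamespace("pracma", quietly = TRUE)) {
    ref <- pracma::findpeaks(sim$trace$values, minpeakheight = 110,
                             minpeakdistance = 20, sortstr = TRUE)
    ref_t <- sort(sim$trace$times[ref[, 2]])
    expect_equal(nrow(pk), nrow(ref))
    expect_equal(pk$t_max, ref_t, tolerance = 0.11)
  }
})

test_that("metrics are invariant under affine rescaling except the ratio", {
  sim <- quick_trial(5, noise_sd = 0.02, seed = 44L)
  tr <- sim$trace
  pk <- detect_peaks(tr)
  resc <- function(a, b) {
    fluorescence_trace(tr$times, a * tr$values + b, tr$frame_period)
  }
  pk_s <- detect_peaks(resc(3, 0))    # pure scaling
  pk_ab <- detect_peaks(resc(2, 57))  # affine
  expect_equal(nrow(pk_s), nrow(pk))
  expect_equal(nrow(pk_ab), nrow(pk))
  expect_equal(pk_s$t_onset, pk$t_onset, tolerance = 1e-8)
  expect_equal(duration(pk_ab), duration(pk), tolerance = 1e-8)
  expect_equal(pk_ab$fwhm, pk$fwhm, tolerance = 1e-8)
  # f_max/f_base invariant under pure scaling only
  expect_equal(fmax_fbase(pk_s), fmax_fbase(pk), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(fmax_fbase(pk_ab), fmax_fbase(pk))))
})
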