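test_that("a flat trace yields no events", {
  tr <- lfp_trace(rep(0, 100000), fs_hz = 10000)
  expect_equal(nrow(detect_events(tr)), 0)
})

test_that("planted events are recovered at their true times", {
  g <- generate_spwr_trace(spwr_gen_params(20, event_rate_hz = 1,
                                           sw_amplitude_mv = 0.1,
                                           noise_sd_mv = 0.01, seed = 17L))
  ev <- detect_events(g$trace)
  truth_t <- g$truth$event_times_s
  expect_equal(nrow(ev), length(truth_t))
  matched <- vapply(truth_t, function(tt) min(abs(ev$t_peak_s - tt)),
                    numeric(1))
  expect_lt(max(matched), 0.005)  # within 5 ms
})

test_that("deflections closer than the merge window fuse into one event", {
  fs <- 10000
  t <- (0:(5 * fs - 1)) / fs
  g1 <- 0.1 * exp(-(t - 2.00)^2 / (2 * 0.004^2))
  g2 <- 0.08 * exp(-(t - 2.02)^2 / (2 * 0.004^2))  # 20 ms apart
  set.seed(31)
  tr <- lfp_trace(g1 + g2 + rnorm(length(t), sd = 0.002), fs)
  ev <- detect_events(tr, spwr_detect_params(merge_ms = 50))
  expect_equal(nrow(ev), 1)
  # and with merging off the pair resolves
  ev2 <- detect_events(tr, spwr_detect_params(merge_ms = 10))
  expect_equal(nrow(ev2), 2)
})

test_that("event metrics recover planted amplitude, ripples and frequency", {
  g <- generate_spwr_trace(spwr_gen_params(30, event_rate_hz = 1,
                                           sw_amplitude_mv = 0.1,
                                           ripple_freq_hz = 180,
                                           noise_sd_mv = 0.002, seed = 23L))
  res <- analyze_spwr(g$trace)
  ev <- res$events
  expect_equal(nrow(ev), length(g$truth$event_times_s))
  # amplitude within +-10% of the planted 0.1 mV
  expect_true(all(ev$amplitude_mv > 0.09 & ev$amplitude_mv < 0.11))
  # ripple frequency within +-10 Hz of 180 where ripples were counted
  with_rip <- ev$ripple_count >= 2
  expect_true(any(with_rip))
  expect_true(all(abs(ev$ripple_freq_hz[with_rip] - 180) < 10))
  # noise inflates the ripple-band SD slightly, so allow one cycle slack
  expect_true(all(abs(ev$ripple_count - g$truth$ripple_cycles) <= 1))
})

test_that("noise-free ripple counts equal the generator oracle exactly", {
  g <- generate_spwr_trace(spwr_gen_params(30, event_rate_hz = 1,
                                           ripple_freq_hz = 180,
                                           noise_sd_mv = 0, seed = 23L))
  res <- analyze_spwr(g$trace)
  expect_equal(res$events$ripple_count, g$truth$ripple_cycles)
})

test_that("ripple cycles below 3 SD of the ripple band are not counted", {
  # ripple amplitude far below the noise-dominated ripple-band SD
  g <- generate_spwr_trace(spwr_gen_params(20, event_rate_hz = 1,
                                           sw_amplitude_mv = 0.1,
                                           ripple_rel_amp = 0.005,
                                           noise_sd_mv = 0.02, seed = 29L))
  res <- analyze_spwr(g$trace)
  expect_true(all(res$events$ripple_count <= 1))
  expect_true(all(res$events$ripple_freq_hz[res$events$ripple_count < 2] == 0))
})

test_that("ripple counting agrees with a brute-force threshold scan", {
  g <- generate_spwr_trace(spwr_gen_params(20, seed = 37L))
  params <- spwr_detect_params()
  ev <- detect_events(g$trace, params)
  ev <- event_metrics(g$trace, ev, params)
  ripple <- fft_bandpass(g$trace, params$ripple_band)$samples
  thr <- 3 * sd(ripple)
  for (k in seq_len(nrow(ev))) {
    seg <- ripple[ev$i_start[k]:ev$i_end[k]]
    brute <- 0L
    for (i in 2:(length(seg) - 1)) {
      if (seg[i] > seg[i - 1] && seg[i] >= seg[i + 1] && seg[i] > thr) {
        brute <- brute + 1L
      }
    }
    expect_equal(ev$ripple_count[k], brute)
  }
})

test_that("detection count never rises with a stricter threshold", {
  g <- generate_spwr_trace(spwr_gen_params(30, noise_sd_mv = 0.03,
                                           seed = 41L))
  counts <- vapply(c(2, 3, 4, 5, 6), function(k) {
    nrow(detect_events(g$trace, spwr_detect_params(detect_k_sd = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected events are disjoint, ordered and above threshold", {
  g <- generate_spwr_trace(spwr_gen_params(30, event_rate_hz = 3,
                                           refractory_ms = 100, seed = 43L))
  params <- spwr_detect_params()
  ev <- detect_events(g$trace, params)
  expect_true(all(diff(ev$t_peak_s) > 0))
  expect_true(all(ev$t_start_s <= ev$t_peak_s))
  expect_true(all(ev$t_peak_s <= ev$t_end_s))
  expect_true(all(ev$t_start_s[-1] > ev$t_end_s[-nrow(ev)] - 1e-9))
  slow <- fft_bandpass(g$trace, params$slow_band)$samples
  dev <- abs(slow - median(slow))
  expect_true(all(dev[ev$i_peak] > 3 * sd(slow)))
})

test_that("slice inclusion applies the amplitude and incidence rules", {
  mk <- function(n, amp) {
    data.frame(amplitude_mv = rep(amp, n), duration_ms = rep(50, n),
               ripple_count = rep(5L, n), ripple_freq_hz = rep(180, n),
               auc_mv_ms = rep(3, n))
  }
  s1 <- summarize_slice(mk(90, 0.06), 60)   # 90/min, 0.06 mV
  expect_equal(s1$incidence_per_min, 90)
  expect_true(s1$accepted)
  expect_equal(s1$rejection_reason, "none")

  s2 <- summarize_slice(mk(30, 0.06), 60)   # 0.5 Hz
  expect_false(s2$accepted)
  expect_equal(s2$rejection_reason, "incidence")

  s3 <- summarize_slice(mk(120, 0.03), 60)  # 2 Hz but 0.03 mV
  expect_false(s3$accepted)
  expect_equal(s3$rejection_reason, "amplitude")

  s4 <- summarize_slice(mk(30, 0.03), 60)
  expect_equal(s4$rejection_reason, "both")

  s0 <- summarize_slice(mk(0, 0.1)[0, ], 60)
  expect_equal(s0$n_events, 0)
  expect_false(s0$accepted)
})
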