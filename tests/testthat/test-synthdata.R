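test_that("generators are seed-deterministic", {
  p <- spwr_gen_params(10, seed = 5L)
  a <- generate_spwr_trace(p)
  b <- generate_spwr_trace(p)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth$event_times_s, b$truth$event_times_s)

  q <- gamma_gen_params(10, seed = 5L)
  expect_identical(generate_gamma_trace(q)$trace$samples,
                   generate_gamma_trace(q)$trace$samples)

  s <- puncta_gen_params(shape_px = 64L, n_sites = 10L,
                         singles_per_channel = 3L, seed = 5L)
  expect_identical(generate_puncta_stack(s)$stack$voxels,
                   generate_puncta_stack(s)$stack$voxels)
})

test_that("silent parameters give an all-zero trace and empty truth", {
  g <- generate_spwr_trace(spwr_gen_params(5, event_rate_hz = 0,
                                           noise_sd_mv = 0))
  expect_true(all(g$trace$samples == 0))
  expect_length(g$truth$event_times_s, 0)
  expect_length(g$truth$ripple_cycles, 0)
})

test_that("planted event rate matches the Poisson oracle band", {
  # rate 2 Hz over 60 s: the Poisson(120/min) +-3 sigma band is [96, 144]
  counts <- vapply(1:20, function(s) {
    g <- generate_spwr_trace(spwr_gen_params(60, noise_sd_mv = 0, seed = s))
    stopifnot(all(g$truth$event_times_s >= 0),
              all(g$truth$event_times_s <= 60),
              length(g$truth$event_amplitudes_mv) ==
                length(g$truth$event_times_s))
    length(g$truth$event_times_s)
  }, numeric(1))
  expect_gte(mean(counts), 96)
  expect_lte(mean(counts), 144)
})

test_that("refractory interval separates every planted event pair", {
  g <- generate_spwr_trace(spwr_gen_params(120, event_rate_hz = 3,
                                           refractory_ms = 250, seed = 9L))
  expect_gte(min(diff(g$truth$event_times_s)), 0.25)
})

test_that("parameter validation names the offending field", {
  expect_error(spwr_gen_params(-1), "duration_s")
  expect_error(spwr_gen_params(10, ripple_freq_hz = 500), "ripple_freq_hz")
  expect_error(spwr_gen_params(10, event_rate_hz = 5, refractory_ms = 250),
               "event_rate_hz")
  expect_error(gamma_gen_params(10, osc_freq_hz = 0), "osc_freq_hz")
  expect_error(gamma_gen_params(10, phase_diffusion = -1), "phase_diffusion")
  expect_error(puncta_gen_params(triple_fraction = 1.5), "triple_fraction")
  expect_error(puncta_gen_params(punctum_radius_px = 0), "punctum_radius_px")
})

test_that("coherent gamma is a pure tone at the carrier frequency", {
  g <- generate_gamma_trace(gamma_gen_params(10, phase_diffusion = 0,
                                             noise_sd_mv = 0))
  x <- g$trace$samples
  n <- length(x)
  spec <- Mod(fft(x))^2
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * g$trace$fs_hz / n
  expect_lte(abs(f[which.max(spec)] - 40), g$trace$fs_hz / n)
  # >= 99% of power within +-5 Hz of the carrier
  expect_gt(sum(spec[abs(f - 40) <= 5]) / sum(spec), 0.99)
  expect_identical(g$truth$coherence_tau_ms, Inf)
})

test_that("generator-oracle coherence time falls with phase diffusion", {
  taus <- vapply(c(0.1, 1, 10), function(d) {
    generate_gamma_trace(gamma_gen_params(60, phase_diffusion = d,
                                          noise_sd_mv = 0,
                                          seed = 21L))$truth$coherence_tau_ms
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("puncta truth table encodes the planted design exactly", {
  g <- generate_puncta_stack(puncta_gen_params(
    shape_px = 200L, n_sites = 100L, triple_fraction = 0.3,
    singles_per_channel = 0L, jitter_px = 0, noise_sd = 0, seed = 3L))
  tab <- g$truth$site_table
  expect_equal(nrow(tab), 100)
  expect_equal(sum(tab$triple), 30)
  expect_true(all(rowSums(tab[, c("ch1", "ch2", "ch3")]) >= 2))

  blank <- generate_puncta_stack(puncta_gen_params(
    shape_px = 64L, n_sites = 0L, singles_per_channel = 0L, noise_sd = 0))
  expect_true(all(blank$stack$voxels == 0))
  expect_equal(nrow(blank$truth$site_table), 0)
})

test_that("rendered disk counts match truth presence counts per channel", {
  g <- generate_puncta_stack(puncta_gen_params(
    shape_px = 128L, n_sites = 25L, triple_fraction = 0.4,
    singles_per_channel = 5L, noise_sd = 0, blur_sigma_px = 0, seed = 8L))
  tab <- g$truth$site_table
  for (ch in 1:3) {
    proj <- max_projection(g$stack, ch)
    n_oracle <- brute_component_count(proj > 0, connectivity = 8L)
    expect_equal(n_oracle, sum(tab[[paste0("ch", ch)]]))
  }
})

test_that("impossible puncta densities raise a generation error", {
  expect_error(
    generate_puncta_stack(puncta_gen_params(
      shape_px = 32L, n_sites = 300L, punctum_radius_px = 4L)),
    "density")
})

test_that("puncta stacks round-trip through multi-page TIFF", {
  g <- generate_puncta_stack(puncta_gen_params(shape_px = 48L,
                                               n_sites = 5L,
                                               singles_per_channel = 2L,
                                               seed = 2L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_puncta_stack(g$stack, path)
  back <- read_puncta_stack(path)
  expect_equal(dim(back$voxels), dim(g$stack$voxels))
  # 16-bit quantization: agreement to 1/65535
  expect_lt(max(abs(back$voxels - g$stack$voxels)), 1 / 65534)
  expect_equal(back$channel_names, g$stack$channel_names)
})
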