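test_that("max projection equals the per-pixel maximum oracle", {
  vox <- array(3, dim = c(4, 4, 8, 3))
  expect_true(all(max_projection(puncta_stack(vox, 0.2), 1) == 3))
  vox[2, 3, 5, 1] <- 100
  st <- puncta_stack(vox, 0.2)
  expect_equal(max_projection(st, 1)[2, 3], 100)

  g <- generate_puncta_stack(puncta_gen_params(shape_px = 64L,
                                               n_sites = 8L,
                                               singles_per_channel = 2L,
                                               noise_sd = 0.05,
                                               seed = 6L))
  proj <- max_projection(g$stack, 2)
  oracle <- apply(g$stack$voxels[, , , 2], c(1, 2), max)
  expect_identical(proj, oracle)
  expect_error(max_projection(g$stack, 9), "range")
})

test_that("ROI mean intensity is the plain arithmetic mean", {
  img <- matrix(7, 20, 20)
  expect_equal(roi_mean_intensity(img, c(row = 3, col = 3, nrow = 5,
                                         ncol = 5)), 7)
  img2 <- cbind(matrix(0, 10, 5), matrix(10, 10, 5))
  expect_equal(roi_mean_intensity(img2, c(row = 1, col = 1, nrow = 10,
                                          ncol = 10)), 5)
  set.seed(9)
  img3 <- matrix(runif(400), 20, 20)
  roi <- c(row = 4, col = 7, nrow = 6, ncol = 9)
  acc <- 0
  for (r in 4:9) for (cc in 7:15) acc <- acc + img3[r, cc]
  expect_equal(roi_mean_intensity(img3, roi), acc / (6 * 9))
  expect_error(roi_mean_intensity(img3, c(row = 18, col = 1, nrow = 5,
                                          ncol = 5)), "bounds")
})

test_that("threshold segmentation counts planted disks", {
  expect_equal(attr(segment_channel(matrix(0, 32, 32),
                                    segmentation_params("fixed",
                                                        fixed_threshold = 0.5)),
                    "n_puncta"), 0)
  g <- generate_puncta_stack(puncta_gen_params(shape_px = 200L,
                                               n_sites = 50L,
                                               triple_fraction = 1,
                                               singles_per_channel = 0L,
                                               noise_sd = 0, seed = 12L))
  proj <- max_projection(g$stack, 1)
  lab <- segment_channel(proj, segmentation_params("fixed",
                                                   fixed_threshold = 0.4))
  expect_equal(attr(lab, "n_puncta"), 50)
})

test_that("connectivity 4 splits diagonal contacts that 8 joins", {
  img <- matrix(0, 16, 16)
  img[4:6, 4:6] <- 1
  img[7:9, 7:9] <- 1  # touches the first square only at a diagonal
  p8 <- segmentation_params("fixed", fixed_threshold = 0.5, min_area_px = 1,
                            connectivity = 8)
  p4 <- segmentation_params("fixed", fixed_threshold = 0.5, min_area_px = 1,
                            connectivity = 4)
  expect_equal(attr(segment_channel(img, p8), "n_puncta"), 1)
  expect_equal(attr(segment_channel(img, p4), "n_puncta"), 2)
  # EBImage's labeller (4-connectivity) as independent oracle
  expect_equal(attr(segment_channel(img, p4), "n_puncta"),
               max(EBImage::bwlabel(img)))
})

test_that("segmentation count is monotone in threshold and area filter", {
  g <- generate_puncta_stack(puncta_gen_params(shape_px = 128L,
                                               n_sites = 20L,
                                               singles_per_channel = 5L,
                                               noise_sd = 0.08,
                                               blur_sigma_px = 1,
                                               seed = 13L))
  proj <- max_projection(g$stack, 1)
  counts_thr <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(th) {
    attr(segment_channel(proj, segmentation_params(
      "fixed", fixed_threshold = th, min_area_px = 1)), "n_puncta")
  }, numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_area <- vapply(c(1, 4, 10, 20, 40), function(a) {
    attr(segment_channel(proj, segmentation_params(
      "fixed", fixed_threshold = 0.3, min_area_px = a)), "n_puncta")
  }, numeric(1))
  expect_true(all(diff(counts_area) <= 0))
})

seg_all <- function(stack, thr = 0.4) {
  lapply(1:3, function(ch) {
    segment_channel(max_projection(stack, ch),
                    segmentation_params("fixed", fixed_threshold = thr))
  })
}

test_that("colocalization trivials: identical and disjoint masks", {
  g <- generate_puncta_stack(puncta_gen_params(shape_px = 96L,
                                               n_sites = 8L,
                                               triple_fraction = 1,
                                               singles_per_channel = 0L,
                                               noise_sd = 0, seed = 14L))
  masks <- seg_all(g$stack)
  res <- colocalize_triple(masks[[1]], masks[[2]], masks[[3]])
  expect_equal(res$triple_count, 8)
  expect_equal(unname(res$pairwise_counts), c(8, 8, 8))

  a <- matrix(0L, 10, 10); a[2:3, 2:3] <- 1L
  b <- matrix(0L, 10, 10); b[6:7, 6:7] <- 1L
  cc <- matrix(0L, 10, 10); cc[9, 9] <- 1L
  res2 <- colocalize_triple(a, b, cc)
  expect_equal(res2$triple_count, 0)
  expect_equal(unname(res2$pairwise_counts), c(0, 0, 0))
  expect_error(colocalize_triple(a, b[1:5, ], cc), "shape")
})

test_that("triple counts recover the planted colocalization design", {
  for (seed in c(1L, 2L, 3L)) {
    g <- generate_puncta_stack(puncta_gen_params(
      shape_px = 256L, n_sites = 100L, triple_fraction = 0.3,
      singles_per_channel = 10L, jitter_px = 0, noise_sd = 0, seed = seed))
    masks <- seg_all(g$stack)
    res <- colocalize_triple(masks[[1]], masks[[2]], masks[[3]],
                             pixel_size_um = 0.18)
    expect_equal(res$triple_count, 30)
    # counting hierarchy
    expect_lte(res$triple_count, min(res$pairwise_counts[c("AB", "AC")]))
    expect_lte(res$pairwise_counts[["AB"]], res$per_channel_counts[["A"]])
    expect_gt(res$triple_density_per_100um2, 0)
  }
})

test_that("colocalization agrees with a brute-force pixel scan", {
  g <- generate_puncta_stack(puncta_gen_params(
    shape_px = 128L, n_sites = 30L, triple_fraction = 0.5,
    singles_per_channel = 5L, noise_sd = 0, seed = 15L))
  masks <- seg_all(g$stack)
  res <- colocalize_triple(masks[[1]], masks[[2]], masks[[3]])
  # oracle: loop over reference labels and scan every pixel
  a <- masks[[1]]; b <- masks[[2]]; cc <- masks[[3]]
  brute_triple <- 0L
  for (lab in seq_len(max(a))) {
    px <- which(a == lab)
    if (any(b[px] > 0) && any(cc[px] > 0)) brute_triple <- brute_triple + 1L
  }
  expect_equal(res$triple_count, brute_triple)
})

test_that("Otsu segmentation tolerates blur within 5% of the plant", {
  hits <- vapply(c(21L, 22L, 23L), function(seed) {
    g <- generate_puncta_stack(puncta_gen_params(
      shape_px = 256L, n_sites = 100L, triple_fraction = 0.3,
      singles_per_channel = 10L, noise_sd = 0.02, blur_sigma_px = 1,
      seed = seed))
    masks <- lapply(1:3, function(ch) {
      segment_channel(max_projection(g$stack, ch), segmentation_params("otsu"))
    })
    colocalize_triple(masks[[1]], masks[[2]], masks[[3]])$triple_count
  }, numeric(1))
  expect_true(all(abs(hits - 30) <= 1.5))
})

test_that("reference normalization maps the reference mean to 1", {
  out <- normalize_to_reference(list(WT = c(2, 2, 2), TG = c(3, 3)), "WT")
  expect_equal(out$WT, c(1, 1, 1))
  expect_equal(out$TG, c(1.5, 1.5))
  expect_error(normalize_to_reference(list(WT = c(0, 0), TG = 1), "WT"),
               "positive")
  set.seed(33)
  g <- list(ref = rlnorm(10), test = rlnorm(7))
  expect_equal(mean(normalize_to_reference(g, "ref")$ref), 1)
})
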