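#' Parameters for the synthetic puncta-stack generator
#'
#' Emulates triple-immunolabelled confocal stacks: disk-shaped puncta
#' planted at random non-overlapping sites across three channels, a
#' controlled fraction of sites positive in all three channels, plus extra
#' single-positive puncta per channel. Defaults mimic a 63x field reduced
#' to 256 px for desk-scale work; the acquisition convention being
#' emulated is an 8-section z-stack.
#'
#' @param shape_px Image height/width in pixels.
#' @param n_sections Number of optical sections (default 8).
#' @param pixel_size_um Microns per pixel.
#' @param n_sites Number of planted synapse sites (each positive in at
#'   least two channels).
#' @param triple_fraction Fraction of sites positive in all 3 channels.
#' @param singles_per_channel Extra single-positive puncta per channel.
#' @param punctum_radius_px Disk radius in pixels (>= 1).
#' @param jitter_px Maximum per-channel centre offset at colocalized
#'   sites (0 = perfectly aligned).
#' @param intensity Foreground intensity (images live on a 0..1 scale).
#' @param noise_sd Background Gaussian noise SD.
#' @param blur_sigma_px Gaussian blur SD applied per section (0 = none;
#'   requires the EBImage package when positive).
#' @param seed Integer RNG seed.
#' @return A validated list of class `puncta_gen_params`.
#' @export
puncta_gen_params <- function(shape_px = 256L, n_sections = 8L,
                              pixel_size_um = 0.18, n_sites = 100L,
                              triple_fraction = 0.3,
                              singles_per_channel = 20L,
                              punctum_radius_px = 3L, jitter_px = 0,
                              intensity = 0.8, noise_sd = 0,
                              blur_sigma_px = 0, seed = 1L) {
  p <- list(shape_px = as.integer(shape_px),
            n_sections = as.integer(n_sections),
            pixel_size_um = pixel_size_um, n_sites = as.integer(n_sites),
            triple_fraction = triple_fraction,
            singles_per_channel = as.integer(singles_per_channel),
            punctum_radius_px = as.integer(punctum_radius_px),
            jitter_px = jitter_px, intensity = intensity,
            noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
            seed = as.integer(seed))
  if (p$triple_fraction < 0 || p$triple_fraction > 1) {
    stop("invalid 'triple_fraction': must be in [0, 1]", call. = FALSE)
  }
  if (p$punctum_radius_px < 1L) {
    stop("invalid 'punctum_radius_px': must be >= 1", call. = FALSE)
  }
  if (p$n_sections < 1L) {
    stop("invalid 'n_sections': must be >= 1", call. = FALSE)
  }
  if (p$shape_px < 8L) stop("invalid 'shape_px'", call. = FALSE)
  if (p$n_sites < 0L || p$singles_per_channel < 0L) {
    stop("invalid site counts", call. = FALSE)
  }
  structure(p, class = "puncta_gen_params")
}

#' 3-channel puncta stack container
#'
#' @param voxels 4-D numeric array `[row, col, section, channel]` with
#'   intensities on a 0..1 scale.
#' @param pixel_size_um Microns per pixel (in-plane).
#' @param z_step_um Optical-section spacing in microns (0.5 typical).
#' @param channel_names Character vector, one name per channel (the
#'   conventional markers are PV, gephyrin and VGAT).
#' @return An object of class `puncta_stack`.
#' @export
puncta_stack <- function(voxels, pixel_size_um, z_step_um = 0.5,
                         channel_names = c("PV", "gephyrin", "VGAT")) {
  d <- dim(voxels)
  if (length(d) != 4L) stop("'voxels' must be a 4-D array", call. = FALSE)
  if (any(voxels < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (length(channel_names) != d[4]) {
    stop("one channel name per channel required", call. = FALSE)
  }
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel_names = channel_names),
            class = "puncta_stack")
}

# Rejection-sample centres at least `min_dist` apart, bounded retries.
place_centres <- function(n, shape, margin, min_dist, max_tries) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("puncta density too high: could not place ", n,
           " non-overlapping sites after ", max_tries, " tries",
           call. = FALSE)
    }
    x <- stats::runif(1, margin + 1, shape - margin)
    y <- stats::runif(1, margin + 1, shape - margin)
    if (length(xs) == 0 ||
        min((xs - x)^2 + (ys - y)^2) >= min_dist^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(row = round(ys), col = round(xs))
}

draw_disk <- function(img, r0, c0, radius, value) {
  n <- nrow(img)
  rows <- max(1L, r0 - radius):min(n, r0 + radius)
  cols <- max(1L, c0 - radius):min(ncol(img), c0 + radius)
  dr <- outer(rows - r0, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - c0)
  hit <- dr^2 + dc^2 <= radius^2
  sub <- img[rows, cols, drop = FALSE]
  sub[hit] <- pmax(sub[hit], value)
  img[rows, cols] <- sub
  img
}

#' Generate a synthetic 3-channel puncta stack with ground truth
#'
#' Sites are placed without overlap (bounded rejection sampling; an error
#' is raised if the requested density cannot be achieved). A fraction
#' `triple_fraction` of sites is rendered in all three channels; the
#' remaining sites in two randomly chosen channels (partial
#' colocalization); `singles_per_channel` additional puncta are rendered
#' in a single channel each. Every punctum is drawn as a filled disk in a
#' contiguous run of optical sections, so the maximum-intensity
#' projection shows the complete disk.
#'
#' @param params A [puncta_gen_params()].
#' @return List with `stack` (a [puncta_stack()]) and `truth` (class
#'   `synth_truth`) whose `site_table` has one row per planted punctum
#'   with columns `row`, `col`, `ch1`, `ch2`, `ch3` (presence flags),
#'   `triple` and `kind` ("site" or "single").
#' @export
generate_puncta_stack <- function(params) {
  stopifnot(inherits(params, "puncta_gen_params"))
  set.seed(params$seed)
  shp <- params$shape_px
  r <- params$punctum_radius_px
  n_total <- params$n_sites + 3L * params$singles_per_channel
  min_dist <- 2 * r + 2 * ceiling(params$jitter_px) + 2
  margin <- r + ceiling(params$jitter_px) + 1
  centres <- if (n_total > 0) {
    place_centres(n_total, shp, margin, min_dist, max_tries = 200L * n_total)
  } else {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  }
  n_triple <- round(params$n_sites * params$triple_fraction)
  pres <- matrix(FALSE, n_total, 3L)
  kind <- character(n_total)
  if (params$n_sites > 0) {
    site_idx <- seq_len(params$n_sites)
    kind[site_idx] <- "site"
    pres[site_idx[seq_len(n_triple)], ] <- TRUE
    if (params$n_sites > n_triple) {
      for (i in site_idx[(n_triple + 1L):params$n_sites]) {
        pres[i, sample.int(3L, 2L)] <- TRUE
      }
    }
  }
  if (params$singles_per_channel > 0) {
    off <- params$n_sites
    for (ch in 1:3) {
      idx <- off + seq_len(params$singles_per_channel)
      pres[idx, ch] <- TRUE
      kind[idx] <- "single"
      off <- off + params$singles_per_channel
    }
  }
  vox <- array(0, dim = c(shp, shp, params$n_sections, 3L))
  span <- min(3L, params$n_sections)
  for (i in seq_len(n_total)) {
    s0 <- if (params$n_sections > span) {
      sample.int(params$n_sections - span + 1L, 1L)
    } else 1L
    secs <- s0:(s0 + span - 1L)
    for (ch in 1:3) {
      if (!pres[i, ch]) next
      jr <- jc <- 0L
      if (params$jitter_px > 0 && ch > 1 && sum(pres[i, ]) > 1) {
        jr <- round(stats::runif(1, -params$jitter_px, params$jitter_px))
        jc <- round(stats::runif(1, -params$jitter_px, params$jitter_px))
      }
      for (s in secs) {
        vox[, , s, ch] <- draw_disk(vox[, , s, ch],
                                    centres[i, "row"] + jr,
                                    centres[i, "col"] + jc,
                                    r, params$intensity)
      }
    }
  }
  if (params$noise_sd > 0) {
    vox <- vox + stats::rnorm(length(vox), 0, params$noise_sd)
    vox[vox < 0] <- 0
  }
  if (params$blur_sigma_px > 0) {
    for (ch in 1:3) for (s in seq_len(params$n_sections)) {
      vox[, , s, ch] <- EBImage::gblur(vox[, , s, ch],
                                       sigma = params$blur_sigma_px)
    }
  }
  vox[vox > 1] <- 1
  stack <- puncta_stack(vox, params$pixel_size_um)
  site_table <- data.frame(
    row = centres[, "row"], col = centres[, "col"],
    ch1 = pres[, 1], ch2 = pres[, 2], ch3 = pres[, 3],
    triple = pres[, 1] & pres[, 2] & pres[, 3],
    kind = kind, stringsAsFactors = FALSE)
  truth <- structure(list(site_table = site_table,
                          params = unclass(params)),
                     class = "synth_truth")
  list(stack = stack, truth = truth)
}

#' Write / read a puncta stack as multi-page TIFF
#'
#' Pages are ordered channel-major, section-minor (all sections of channel
#' 1, then channel 2, ...). Geometry and channel names that TIFF cannot
#' carry are written to a JSON sidecar at `<path>.json`.
#'
#' @param stack A [puncta_stack()].
#' @param path TIFF file path.
#' @return `write_puncta_stack()` returns `path` invisibly;
#'   `read_puncta_stack()` returns a [puncta_stack()].
#' @export
write_puncta_stack <- function(stack, path) {
  stopifnot(inherits(stack, "puncta_stack"))
  d <- dim(stack$voxels)
  pages <- list()
  for (ch in seq_len(d[4])) for (s in seq_len(d[3])) {
    pages[[length(pages) + 1L]] <- stack$voxels[, , s, ch]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(n_sections = d[3], n_channels = d[4],
                  pixel_size_um = stack$pixel_size_um,
                  z_step_um = stack$z_step_um,
                  channel_names = stack$channel_names,
                  page_order = "channel-major")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_puncta_stack
#' @export
read_puncta_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  }
  side <- jsonlite::fromJSON(sidecar_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != side$n_sections * side$n_channels) {
    stop("page count does not match sidecar geometry", call. = FALSE)
  }
  d1 <- dim(pages[[1]])
  vox <- array(0, dim = c(d1[1], d1[2], side$n_sections, side$n_channels))
  i <- 1L
  for (ch in seq_len(side$n_channels)) for (s in seq_len(side$n_sections)) {
    vox[, , s, ch] <- pages[[i]]
    i <- i + 1L
  }
  puncta_stack(vox, side$pixel_size_um, side$z_step_um, side$channel_names)
}
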