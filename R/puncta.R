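#' Maximum-intensity projection of one channel
#'
#' Per-pixel maximum across all optical sections of the chosen channel —
#' the projection on which intensities and puncta are quantified.
#'
#' @param stack A [puncta_stack()].
#' @param channel Channel index or name.
#' @return A numeric matrix (rows x cols).
#' @export
max_projection <- function(stack, channel) {
  stopifnot(inherits(stack, "puncta_stack"))
  d <- dim(stack$voxels)
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name", call. = FALSE)
  }
  if (channel < 1 || channel > d[4]) stop("channel out of range", call. = FALSE)
  if (d[1] == 0 || d[2] == 0 || d[3] == 0) stop("empty stack", call. = FALSE)
  out <- stack$voxels[, , 1L, channel]
  for (s in seq_len(d[3])[-1]) {
    out <- pmax(out, stack$voxels[, , s, channel])
  }
  out
}

#' Mean intensity over a rectangular ROI
#'
#' @param image Numeric matrix (typically a [max_projection()]).
#' @param roi_rect Named integer vector `c(row, col, nrow, ncol)`: top-left
#'   pixel and extent, in pixels.
#' @return Arithmetic mean intensity over the ROI.
#' @export
roi_mean_intensity <- function(image, roi_rect) {
  r0 <- roi_rect[["row"]]; c0 <- roi_rect[["col"]]
  nr <- roi_rect[["nrow"]]; nc <- roi_rect[["ncol"]]
  if (r0 < 1 || c0 < 1 || nr < 1 || nc < 1 ||
      r0 + nr - 1 > nrow(image) || c0 + nc - 1 > ncol(image)) {
    stop("ROI outside image bounds", call. = FALSE)
  }
  mean(image[r0:(r0 + nr - 1), c0:(c0 + nc - 1)])
}

#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (automatic, via EBImage) or `"fixed"`.
#' @param fixed_threshold Intensity threshold when `method = "fixed"`.
#' @param min_area_px,max_area_px Component area bounds in pixels;
#'   components outside the range are discarded.
#' @param connectivity Pixel connectivity, 4 or 8.
#' @return A validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                min_area_px = 4L, max_area_px = 10000L,
                                connectivity = 8L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && !is.finite(fixed_threshold)) {
    stop("'fixed_threshold' required for fixed thresholding", call. = FALSE)
  }
  if (min_area_px < 1L || min_area_px > max_area_px) {
    stop("need 1 <= min_area_px <= max_area_px", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) {
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  }
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

# Connected-component labeling by breadth-first flood fill over foreground
# pixels, with configurable 4/8 connectivity. Cost is proportional to the
# foreground size, so sparse puncta masks label quickly even at 1024 px.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offsets <- if (connectivity == 8L) {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  fg <- which(mask)
  lab <- 0L
  stack <- integer(length(fg))
  for (p in fg) {
    if (labels[p] != 0L) next
    lab <- lab + 1L
    labels[p] <- lab
    stack[1L] <- p
    top <- 1L
    while (top > 0L) {
      q <- stack[top]; top <- top - 1L
      qr <- ((q - 1L) %% nr) + 1L
      qc <- ((q - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offsets))) {
        rr <- qr + offsets[k, 1L]; cc <- qc + offsets[k, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        idx <- (cc - 1L) * nr + rr
        if (mask[idx] && labels[idx] == 0L) {
          labels[idx] <- lab
          top <- top + 1L
          stack[top] <- idx
        }
      }
    }
  }
  labels
}

#' Threshold segmentation of a channel projection
#'
#' Binarizes the image at a fixed or Otsu-derived threshold, labels
#' connected components at the requested connectivity, removes components
#' outside the `[min_area_px, max_area_px]` range and relabels the
#' survivors contiguously from 1.
#'
#' @param image Numeric matrix (a channel projection).
#' @param params A [segmentation_params()].
#' @return Integer label matrix with attributes `n_puncta` (label count),
#'   `threshold` (the threshold used) and `areas_px` (per-label areas).
#' @export
segment_channel <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image), inherits(params, "segmentation_params"))
  thr <- if (params$threshold_method == "fixed") {
    params$fixed_threshold
  } else {
    rng <- range(image)
    if (diff(rng) == 0) {
      Inf  # flat image: nothing to segment
    } else {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("Otsu thresholding requires the EBImage package", call. = FALSE)
      }
      EBImage::otsu(image, range = rng, levels = 256L)
    }
  }
  mask <- image > thr
  labels <- label_components(mask, params$connectivity)
  n <- max(labels)
  if (n > 0L) {
    areas <- tabulate(labels[labels > 0L], nbins = n)
    keep <- which(areas >= params$min_area_px & areas <= params$max_area_px)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  attr(labels, "n_puncta") <- length(areas)
  attr(labels, "threshold") <- thr
  attr(labels, "areas_px") <- areas
  labels
}

#' Triple-channel colocalization of segmented puncta
#'
#' A punctum in the reference channel A counts as pairwise-colocalized
#' with channel B if its pixel set shares at least `overlap_min_px`
#' foreground pixels with B's mask, and as triple-positive if it overlaps
#' both B and C. The BC pairwise count uses B as its reference. Densities
#' are reported per 100 square microns when a pixel size is given.
#'
#' @param mask_a,mask_b,mask_c Label matrices from [segment_channel()]
#'   (same shape); A is the reference channel.
#' @param overlap_min_px Minimum shared foreground pixels (default 1).
#' @param pixel_size_um Microns per pixel, for density reporting
#'   (optional).
#' @return An object of class `coloc_result`: list with
#'   `per_channel_counts`, `pairwise_counts` (AB, AC, BC),
#'   `triple_count`, `roi_area_um2`, `triple_density_per_100um2` and
#'   `punctum_table` (per reference-channel punctum: label, area_px,
#'   overlap pixel counts with B and C, and flags).
#' @export
colocalize_triple <- function(mask_a, mask_b, mask_c, overlap_min_px = 1L,
                              pixel_size_um = NULL) {
  if (!all(dim(mask_a) == dim(mask_b)) || !all(dim(mask_a) == dim(mask_c))) {
    stop("masks must have identical shape", call. = FALSE)
  }
  n_a <- max(mask_a); n_b <- max(mask_b); n_c <- max(mask_c)
  tab_overlap <- function(ref_labels, other_mask, n_ref) {
    if (n_ref == 0L) return(integer(0))
    hit <- ref_labels[other_mask > 0L]
    tabulate(hit[hit > 0L], nbins = n_ref)
  }
  ov_ab <- tab_overlap(mask_a, mask_b, n_a)
  ov_ac <- tab_overlap(mask_a, mask_c, n_a)
  ov_bc <- tab_overlap(mask_b, mask_c, n_b)
  with_b <- ov_ab >= overlap_min_px
  with_c <- ov_ac >= overlap_min_px
  triple <- with_b & with_c
  areas_a <- if (n_a > 0L) tabulate(mask_a[mask_a > 0L], nbins = n_a) else integer(0)
  punctum_table <- data.frame(
    label = seq_len(n_a), area_px = areas_a,
    overlap_b_px = ov_ab, overlap_c_px = ov_ac,
    overlaps_b = with_b, overlaps_c = with_c, triple = triple)
  roi_area_um2 <- if (is.null(pixel_size_um)) NA_real_ else {
    length(mask_a) * pixel_size_um^2
  }
  res <- list(
    per_channel_counts = c(A = n_a, B = n_b, C = n_c),
    pairwise_counts = c(AB = sum(with_b), AC = sum(with_c),
                        BC = sum(ov_bc >= overlap_min_px)),
    triple_count = sum(triple),
    roi_area_um2 = roi_area_um2,
    triple_density_per_100um2 = if (is.na(roi_area_um2)) NA_real_ else {
      sum(triple) / roi_area_um2 * 100
    },
    punctum_table = punctum_table)
  class(res) <- "coloc_result"
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result> per-channel:",
      paste(names(x$per_channel_counts), x$per_channel_counts,
            sep = "=", collapse = " "),
      "| pairwise:",
      paste(names(x$pairwise_counts), x$pairwise_counts,
            sep = "=", collapse = " "),
      "| triple:", x$triple_count, "\n")
  invisible(x)
}

#' Normalize group values to a reference group
#'
#' Divides every value by the mean of the reference group, so the
#' reference group maps to mean 1 — the convention used for reporting
#' immunofluorescence intensities and immunoblot band intensities
#' relative to wild type (or to a loading control such as beta-actin).
#'
#' @param groups Named list of numeric vectors.
#' @param reference Name of the reference group within `groups`.
#' @return Named list of the same shape with scaled values.
#' @export
normalize_to_reference <- function(groups, reference) {
  if (!reference %in% names(groups)) {
    stop("reference group '", reference, "' not found", call. = FALSE)
  }
  m <- mean(groups[[reference]])
  if (!is.finite(m) || m <= 0) {
    stop("normalization error: reference mean must be positive",
         call. = FALSE)
  }
  lapply(groups, function(v) v / m)
}
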