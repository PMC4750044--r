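#' Relative-difference filter
#'
#' Normalises a fluorescence frame against its own smooth local baseline:
#' `(I - B) / (B + eps)`, where `B` is a Gaussian blur of `I` at
#' `baseline_scale_px` and `eps` is 1\% of the frame median (a guard against
#' division by zero). The output is close to zero over background and is
#' invariant under global multiplicative rescaling of the illumination, which
#' is what makes the downstream segmentation unsupervised and gain-free.
#'
#' @param frame numeric matrix of intensities.
#' @param baseline_scale_px baseline blur sigma in pixels; should exceed a
#'   nucleus diameter so nuclei do not dominate their own baseline.
#' @return numeric matrix of the same shape, in relative (dimensionless)
#'   units.
#' @export
relative_difference_filter <- function(frame, baseline_scale_px = 25) {
  ek_assert(is.matrix(frame) && length(frame) > 0, "frame must be a ",
            "non-empty numeric matrix")
  ek_assert(baseline_scale_px > 0, "baseline_scale_px must be positive")
  # the Gaussian brush must fit inside the frame
  sigma <- min(baseline_scale_px, (min(dim(frame)) - 1) / 6.5)
  b <- as.matrix(EBImage::gblur(EBImage::Image(frame), sigma = sigma))
  eps <- 0.01 * median(frame)
  if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  (frame - b) / (b + eps)
}

#' Segment nuclei in a filtered frame
#'
#' Thresholds the relative-difference-filtered frame (automatic bimodal
#' threshold by default), groups foreground pixels into connected components,
#' discards components below `min_area_px`, and optionally splits touching
#' nuclei by a distance-transform watershed.
#'
#' @param filtered matrix from [relative_difference_filter()].
#' @param min_area_px discard components smaller than this (pixels).
#' @param threshold_rule `"otsu"` (automatic, per frame) or `"fixed"`.
#' @param fixed_threshold threshold in relative units when
#'   `threshold_rule = "fixed"`.
#' @param split_touching split merged components with more than one distance
#'   maximum.
#' @param min_contrast minimum relative amplitude for a frame to contain
#'   foreground at all; frames whose filtered dynamic range is below this are
#'   returned empty rather than segmented into noise.
#' @return integer label matrix (`0` background, labels `1..n`), class
#'   `label_mask`.
#' @export
segment_nuclei <- function(filtered, min_area_px = 9,
                           threshold_rule = c("otsu", "fixed"),
                           fixed_threshold = 0.5,
                           split_touching = TRUE,
                           min_contrast = 0.2) {
  threshold_rule <- match.arg(threshold_rule)
  ek_assert(is.matrix(filtered) && length(filtered) > 0,
            "filtered must be a non-empty matrix")
  rng <- range(filtered, finite = TRUE)
  empty <- matrix(0L, nrow(filtered), ncol(filtered))
  class(empty) <- c("label_mask", class(empty))
  if (threshold_rule == "otsu") {
    # featureless frame: dynamic range indistinguishable from the pixel
    # noise floor (robust scale estimate), or simply too flat
    guard <- max(min_contrast, 10 * stats::mad(filtered))
    if (diff(rng) < guard) return(empty)
    y <- (filtered - rng[1]) / diff(rng)
    thr <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(y), range = c(0, 1), levels = 256)
  } else {
    thr <- fixed_threshold
  }
  fg <- filtered > thr
  if (!any(fg)) return(empty)
  mask <- EBImage::Image(fg * 1)
  lab <- EBImage::bwlabel(mask)
  if (split_touching) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1)
  }
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    relabel <- integer(max(lab))
    relabel[keep] <- seq_along(keep)
    pos <- lab > 0
    out[pos] <- relabel[lab[pos]]
  }
  class(out) <- c("label_mask", class(out))
  out
}

#' Per-frame features from a label mask
#'
#' @param mask label matrix from [segment_nuclei()].
#' @param frame original intensity frame (same shape).
#' @param pixel_size_um microns per pixel (areas are emitted in um^2).
#' @param time_min frame time stamp in minutes.
#' @return one-row data frame: `time_min`, `nucleus_count`,
#'   `mean_nuclear_area_um2`, `mean_nuclear_area_px`, `total_area_um2`,
#'   `mean_intensity`. When no nuclei are present the areas and intensity are
#'   `NA` (missing, never zero, so kinetics minima cannot be segmentation
#'   dropouts).
#' @export
compute_features <- function(mask, frame, pixel_size_um = 1, time_min = 0) {
  ek_assert(all(dim(mask) == dim(frame)),
            "mask and frame must have the same shape")
  labs <- mask[mask > 0]
  count <- if (length(labs)) max(labs) else 0L
  px2 <- pixel_size_um^2
  if (count == 0L) {
    return(data.frame(time_min = time_min, nucleus_count = 0L,
                      mean_nuclear_area_um2 = NA_real_,
                      mean_nuclear_area_px = NA_real_,
                      total_area_um2 = NA_real_,
                      mean_intensity = NA_real_))
  }
  sizes <- tabulate(labs, nbins = count)
  data.frame(time_min = time_min, nucleus_count = count,
             mean_nuclear_area_um2 = mean(sizes) * px2,
             mean_nuclear_area_px = mean(sizes),
             total_area_um2 = sum(sizes) * px2,
             mean_intensity = mean(frame[mask > 0]))
}

#' Segment a whole stack into a feature trajectory
#'
#' Maps [relative_difference_filter()], [segment_nuclei()] and
#' [compute_features()] over every frame of a stack; deterministic, one
#' feature row per frame.
#'
#' @param stack an [image_stack()].
#' @param baseline_scale_px baseline blur sigma (pixels).
#' @param min_area_px minimum component area; default is the area of a circle
#'   of 2 um diameter at the stack's pixel size (rejects hot pixels).
#' @param ... passed to [segment_nuclei()].
#' @return an `area_trajectory` data frame (columns `time_min`, `area`,
#'   `count`) whose full feature table is in `attr(, "features")`.
#' @export
segment_stack <- function(stack, baseline_scale_px = 25, min_area_px = NULL,
                          ...) {
  ek_assert(inherits(stack, "image_stack"), "stack must be an image_stack")
  if (is.null(min_area_px))
    min_area_px <- max(4, round(pi * (1 / stack$pixel_size_um)^2))
  dt_min <- stack$frame_interval_s / 60
  rows <- lapply(seq_along(stack$frames), function(f) {
    frame <- stack$frames[[f]]
    filt <- relative_difference_filter(frame, baseline_scale_px)
    mask <- segment_nuclei(filt, min_area_px = min_area_px, ...)
    compute_features(mask, frame, stack$pixel_size_um, (f - 1) * dt_min)
  })
  feats <- do.call(rbind, rows)
  traj <- as_area_trajectory(
    data.frame(time_min = feats$time_min,
               area = feats$mean_nuclear_area_um2,
               count = feats$nucleus_count),
    frame_interval_s = stack$frame_interval_s)
  attr(traj, "features") <- feats
  traj
}
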