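#' Stack rendering geometry
#'
#' Geometry of the synthetic end-on (dorsal-ventral plane) view: bright
#' nuclei sit on an annulus (the embryo periphery) over a dim cytoplasmic
#' background.
#'
#' @param frame_px frame side length in pixels (square frames).
#' @param pixel_size_um microns per pixel.
#' @param annulus_r_um annulus (periphery) radius in microns.
#' @param annulus_w_um annulus width; alternate nuclei are staggered inward /
#'   outward by half this width so that late cycles fit without overlap.
#' @param background,amplitude background offset and nuclear peak amplitude in
#'   detector counts (16-bit range).
#' @param noise logical; add Poisson shot noise to each frame.
#' @return a `stack_geometry` object.
#' @export
stack_geometry <- function(frame_px = 480, pixel_size_um = 0.5,
                           annulus_r_um = 100, annulus_w_um = 12,
                           background = 100, amplitude = 2000,
                           noise = TRUE) {
  ek_assert(frame_px > 16 && pixel_size_um > 0, "invalid frame geometry")
  ek_assert(annulus_r_um + annulus_w_um <
              frame_px * pixel_size_um / 2,
            "annulus does not fit inside the frame")
  structure(list(frame_px = as.integer(frame_px),
                 pixel_size_um = pixel_size_um,
                 annulus_r_um = annulus_r_um, annulus_w_um = annulus_w_um,
                 background = background, amplitude = amplitude,
                 noise = noise),
            class = "stack_geometry")
}

# place n spots on the annulus: equal angular spacing with a per-embryo
# angular offset, alternate spots staggered to the inner/outer annulus edge.
# Errors if the requested count cannot be placed without overlap.
place_spots <- function(n, geom, radius_um, angle0, vff_push_um = 0) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  th <- angle0 + 2 * pi * (seq_len(n) - 1) / n
  stag <- rep_len(c(-0.5, 0.5), n) * geom$annulus_w_um
  if (n %% 2L == 1L) stag[n] <- 0     # avoid adjacent equal stagger at wrap
  r <- geom$annulus_r_um + stag
  # ventral arc (bottom of the frame) moves inward at furrow formation
  if (vff_push_um > 0) {
    ventral <- abs(((th - 3 * pi / 2) + pi) %% (2 * pi) - pi) < pi / 6
    r[ventral] <- r[ventral] - vff_push_um
  }
  cx <- geom$frame_px * geom$pixel_size_um / 2
  data.frame(x = cx + r * cos(th), y = cx + r * sin(th))
}

check_overlap <- function(pos, radius_um) {
  n <- nrow(pos)
  if (n < 2) return(TRUE)
  d2 <- as.matrix(stats::dist(pos))^2
  diag(d2) <- Inf
  min(d2) > (2 * radius_um)^2
}

# render flat-top (antialiased hard-edge) disks: the half-maximum contour of
# each spot has area pi * radius^2, so the measured thresholded area tracks
# the generating trace regardless of the exact threshold level.
render_frame <- function(pos, radius_um, geom, amp_scale = 1) {
  npx <- geom$frame_px
  img <- matrix(0, npx, npx)
  if (nrow(pos) && radius_um > 0) {
    r_px <- radius_um / geom$pixel_size_um
    half <- ceiling(r_px + 2)
    ctr <- seq_len(npx) - 0.5
    for (i in seq_len(nrow(pos))) {
      px <- pos$x[i] / geom$pixel_size_um
      py <- pos$y[i] / geom$pixel_size_um
      xi <- max(1, floor(px - half)):min(npx, ceiling(px + half))
      yi <- max(1, floor(py - half)):min(npx, ceiling(py + half))
      dx <- ctr[xi] - px
      dy <- ctr[yi] - py
      d <- sqrt(outer(dx^2, dy^2, `+`))
      img[xi, yi] <- img[xi, yi] + pmin(1, pmax(0, r_px + 0.5 - d))
    }
  }
  geom$background + geom$amplitude * amp_scale * img
}

#' Generate a synthetic Histone-GFP image stack with ground truth
#'
#' Renders the embryo periphery as non-overlapping flat-top spots on an
#' annulus, one frame per sampling interval. Spot count and spot area follow
#' the same phase model as [generate_trace()]: the count doubles at each
#' telophase, the per-nucleus area tracks the area waveform, an anoxic pulse
#' freezes spots at the hypercondensed size, and the failed-recovery phenotype
#' renders fusing daughter pairs followed by signal decay to background
#' (delamination). Ventral-arc spots move inward after ventral furrow onset.
#'
#' @inheritParams generate_trace
#' @param geometry a [stack_geometry()] object.
#' @return list with `stack` (an `image_stack`: list of 16-bit-range integer
#'   matrices plus pixel size and frame interval), `truth` (the
#'   [generate_trace()] ground truth augmented with per-frame true spot count,
#'   per-spot true area, and spot positions) and `trace` (the underlying
#'   noiseless area trajectory).
#' @export
generate_stack <- function(cp = cycle_params(), ap = NULL,
                           geometry = stack_geometry(), seed = 1,
                           embryo_id = "embryo") {
  ek_assert(inherits(geometry, "stack_geometry"),
            "geometry must be a stack_geometry object")
  cp_noiseless <- cp
  cp_noiseless$noise_sd <- 0
  g <- generate_trace(cp_noiseless, ap, seed = seed, embryo_id = embryo_id)
  with_seed(seed + 1L, {
    angle0 <- runif(1, 0, 2 * pi)
    tr <- g$trace
    th <- g$truth
    nfr <- nrow(tr)
    frames <- vector("list", nfr)
    areas <- tr$area
    counts <- tr$count
    failed <- !th$recovered
    rel <- th$release_time_min
    vff <- th$vff_time_min
    dip_end <- if (!is.null(th$arrest_interval)) th$arrest_interval[2] else NA
    for (f in seq_len(nfr)) {
      t <- tr$time_min[f]
      n <- counts[f]
      a <- areas[f]
      amp_scale <- 1
      fuse_sep <- NULL
      if (failed && !is.na(rel) && t >= dip_end) {
        # fusing daughter pairs, then delamination: fade to background
        tf <- t - dip_end
        n <- th$nucleus_count_per_frame[f]
        if (tf < 3) {
          fuse_sep <- 1 - tf / 3     # pair separation, fraction of diameter
          a <- cp$area_telophase
        } else {
          a <- 0.5 * cp$area_interphase
          amp_scale <- max(0, 1 - max(0, tf - 11) / 10)
        }
        if (n == 0) { a <- NA; amp_scale <- 0 }
      }
      if (is.na(a) || n == 0) {
        frames[[f]] <- render_frame(data.frame(x = 0, y = 0)[0, ], 0, geometry)
        next
      }
      r_um <- sqrt(a / pi)
      push <- if (!is.na(vff) && t > vff) min(15, 2 * (t - vff)) else 0
      pos <- place_spots(n, geometry, geometry$annulus_r_um, angle0, push)
      if (!is.null(fuse_sep)) {
        # each "nucleus" is an unresolved daughter pair collapsing together
        off <- fuse_sep * r_um
        ang <- atan2(pos$y - geometry$frame_px * geometry$pixel_size_um / 2,
                     pos$x - geometry$frame_px * geometry$pixel_size_um / 2)
        pos <- data.frame(x = c(pos$x + off * cos(ang + pi / 2),
                                pos$x - off * cos(ang + pi / 2)),
                          y = c(pos$y + off * sin(ang + pi / 2),
                                pos$y - off * sin(ang + pi / 2)))
      } else if (!check_overlap(pos, r_um)) {
        ek_stop(sprintf(
          "cannot place %d non-overlapping nuclei of radius %.2f um on the annulus (frame %d)",
          n, r_um, f))
      }
      img <- render_frame(pos, r_um, geometry, amp_scale)
      if (geometry$noise) img <- matrix(rpois(length(img), img), nrow(img))
      frames[[f]] <- pmin(img, 65535)
    }
    stack <- image_stack(frames, pixel_size_um = geometry$pixel_size_um,
                         frame_interval_s = cp$frame_interval_s)
    th$true_area_per_frame <- areas
    th$geometry <- geometry
    list(stack = stack, truth = th, trace = tr)
  })
}

#' Image stack container
#'
#' @param frames list of numeric matrices (one per frame, identical shape).
#' @param pixel_size_um microns per pixel.
#' @param frame_interval_s seconds between frames.
#' @return an `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s) {
  ek_assert(is.list(frames) && length(frames) >= 1,
            "frames must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  ek_assert(all(dims == dims[, 1]), "all frames must have the same shape")
  ek_assert(pixel_size_um > 0 && frame_interval_s > 0,
            "pixel size and frame interval must be positive")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %dx%d px, %.3g um/px, %.3g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              x$frame_interval_s))
  invisible(x)
}
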