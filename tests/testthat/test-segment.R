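test_that("relative-difference filter is zero on uniform frames and ~1 for a 2x spot", {
  frame <- matrix(100, 96, 96)
  out <- relative_difference_filter(frame, 10)
  expect_lt(max(abs(out)), 1e-6)
  # isolated spot of amplitude 2B over baseline B -> peak ~ (2B - B)/B = 1
  spot <- frame
  spot[44:52, 44:52] <- 200
  out <- relative_difference_filter(spot, 20)
  expect_lt(abs(max(out) - 1), 0.3)
  expect_lt(abs(median(out)), 0.05)          # background stays near zero
  expect_error(relative_difference_filter(frame, -3),
               class = "embryokin_error")
})

test_that("segmentation is invariant under global illumination rescaling", {
  gs <- clean_stack()
  frame <- gs$stack$frames[[frame_at(gs$trace, 60)]]
  base <- segment_nuclei(relative_difference_filter(frame, 25))
  for (g in c(0.2, 0.7, 5)) {
    lab <- segment_nuclei(relative_difference_filter(frame * g, 25))
    expect_identical(unclass(lab), unclass(base))
  }
})

test_that("nucleus counts are recovered exactly on noiseless non-overlapping frames", {
  gs <- clean_stack()
  tr <- gs$trace
  for (t in c(30, 45, 60, 81)) {
    f <- frame_at(tr, t)
    traj <- segment_stack(image_stack(gs$stack$frames[f],
                                      gs$stack$pixel_size_um, 60))
    expect_identical(traj$count[1], as.integer(tr$count[f]))
  }
})

test_that("counts survive realistic shot noise (SNR >= 5)", {
  gs <- fixture("noisy_stack", function()
    generate_stack(cp_clean(), geometry = stack_geometry(noise = TRUE),
                   seed = 2))
  f <- frame_at(gs$trace, 60)
  traj <- segment_stack(image_stack(gs$stack$frames[f], 0.5, 60))
  expect_identical(traj$count[1], 64L)
})

test_that("featureless frames yield an empty mask, never noise objects", {
  flat <- relative_difference_filter(matrix(100, 64, 64), 10)
  expect_equal(max(segment_nuclei(flat)), 0)
  noisy <- matrix(rpois(64 * 64, 100), 64)
  expect_equal(max(segment_nuclei(relative_difference_filter(noisy, 10))), 0)
})

test_that("watershed splitting separates touching nuclei", {
  # two overlapping disks -> one component with two distance maxima
  frame <- matrix(50, 80, 80)
  for (ctr in list(c(34, 40), c(48, 40))) {
    d <- sqrt(outer((1:80 - ctr[1])^2, (1:80 - ctr[2])^2, `+`))
    frame <- frame + 500 * (d < 9)
  }
  filt <- relative_difference_filter(frame, 20)
  expect_equal(max(segment_nuclei(filt, split_touching = TRUE)), 2)
  expect_equal(max(segment_nuclei(filt, split_touching = FALSE)), 1)
})

test_that("feature computation follows the area/count contracts", {
  mask <- matrix(0L, 20, 20)
  mask[1:2, 1:5] <- 1L    # 10 px
  mask[5:8, 1:5] <- 2L    # 20 px
  mask[11:16, 1:5] <- 3L  # 30 px
  frame <- matrix(7, 20, 20)
  fe <- compute_features(mask, frame, pixel_size_um = 1, time_min = 2)
  expect_equal(fe$nucleus_count, 3L)
  expect_equal(fe$mean_nuclear_area_um2, 20)
  expect_equal(fe$total_area_um2, 60)
  # the identity mean * count = total holds by construction
  expect_equal(fe$mean_nuclear_area_um2 * fe$nucleus_count, fe$total_area_um2)
  # empty mask: missing, not zero
  fe0 <- compute_features(matrix(0L, 4, 4), matrix(0, 4, 4), 1, 0)
  expect_equal(fe0$nucleus_count, 0L)
  expect_true(is.na(fe0$mean_nuclear_area_um2))
  expect_error(compute_features(mask, matrix(0, 3, 3)),
               class = "embryokin_error")
})

test_that("a blank frame yields a missing value at that frame only", {
  gs <- clean_stack()
  f <- frame_at(gs$trace, 60)
  blank <- matrix(100, gs$truth$geometry$frame_px, gs$truth$geometry$frame_px)
  st <- image_stack(list(gs$stack$frames[[f]], blank,
                         gs$stack$frames[[f + 1]]), 0.5, 60)
  traj <- segment_stack(st)
  expect_false(anyNA(traj$area[c(1, 3)]))
  expect_true(is.na(traj$area[2]))
})

test_that("segmenting a noiseless stack reproduces the generating trace (MAE < 5%)", {
  gs <- clean_stack()
  tr <- gs$trace
  # frames spanning a full nuclear cycle plus stage-5 plateau
  sel <- c(frame_at(tr, 55):frame_at(tr, 72), frame_at(tr, 90))
  traj <- segment_stack(image_stack(gs$stack$frames[sel], 0.5, 60))
  mae <- mean(abs(traj$area - tr$area[sel]), na.rm = TRUE)
  expect_lt(mae, 0.05 * cp_clean()$area_interphase)
  expect_equal(traj$count, tr$count[sel])
  # area monotonicity transfer: the prophase->telophase decline stays
  # non-increasing in the measured areas (one-frame slack)
  dec <- frame_at(tr, 64):frame_at(tr, 70)
  m <- traj$area[match(dec, sel)]
  expect_true(all(diff(m) < 0.5))
})
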