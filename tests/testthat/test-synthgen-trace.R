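test_that("telophase spacings equal the generating durations by construction", {
  cp <- cp_clean(durations_min = list(NC10 = 8, NC11 = 10, NC12 = 11,
                                      NC13 = 17, stage5 = 59))
  g <- generate_trace(cp, seed = 3)
  expect_equal(unname(diff(g$truth$nd_times)), c(8, 10, 11, 17))
  # and the minima detector recovers them exactly on the 1-min grid
  minima <- detect_minima(g$trace)
  expect_equal(diff(tail(minima$time_min, 4)), c(10, 11, 17))
})

test_that("default stage-5 plateau lasts 59.3 minutes", {
  g <- generate_trace(cp_clean(), seed = 1)
  expect_equal(g$truth$durations_min[["stage5"]], 59.3)
  an <- annotate_cycles(g$trace)
  expect_lte(abs(an$cycles$duration[5] - 59.3), 1)  # one-frame quantisation
})

test_that("anoxia extends the affected cycle by window + lag - time already spent past anaphase", {
  cp <- cp_clean()
  ctrl <- generate_trace(cp, seed = 7)
  ap <- ap_clean(cp)
  trt <- generate_trace(cp, ap, seed = 7)
  # oracle: direct simulation difference of the two truths
  ext_oracle <- trt$truth$durations_min[["NC13"]] -
    ctrl$truth$durations_min[["NC13"]]
  expect_equal(trt$truth$extension_min, ext_oracle)
  # and the closed-form: release (t_off + lag) minus the control division
  release <- ap$t_off_min + ap$recovery_lag_min
  expect_equal(ext_oracle, release - ctrl$truth$nd_times[["ND13"]])
  # downstream cycles shift rigidly; earlier cycles are untouched
  expect_equal(trt$truth$durations_min[c("NC10", "NC11", "NC12")],
               ctrl$truth$durations_min[c("NC10", "NC11", "NC12")])
})

test_that("identical parameters and seed give bit-identical traces", {
  cp <- cycle_params()
  a <- generate_trace(cp, default_anoxia_window(cp), seed = 11)
  b <- generate_trace(cp, default_anoxia_window(cp), seed = 11)
  expect_identical(a, b)
  c <- generate_trace(cp, default_anoxia_window(cp), seed = 12)
  expect_false(identical(a$trace$area, c$trace$area))
})

test_that("nucleus counts double exactly at each division", {
  g <- generate_trace(cycle_params(), seed = 21)
  counts <- sort(unique(g$truth$nucleus_count_per_frame))
  expect_equal(counts, c(0, 8, 16, 32, 64, 128))
  # counts change only at recorded division times
  tr <- g$trace
  changes <- tr$time_min[which(diff(tr$count) != 0) + 1L]
  nd <- g$truth$nd_times
  for (t in changes)
    expect_true(any(t - nd >= 0 & t - nd < 1 + 1e-9))
})

test_that("non-recovering embryos never rise again and counts collapse", {
  ap <- default_anoxia_window(fail_prob = 1)
  g <- generate_trace(cp_clean(), ap, seed = 4)
  expect_false(g$truth$recovered)
  expect_true(is.na(g$truth$vff_time_min))
  tail_counts <- tail(g$truth$nucleus_count_per_frame, 20)
  expect_true(all(tail_counts == 0))
  # the area signal never returns to the interphase plateau after arrest
  post <- g$trace$area[g$trace$time_min > g$truth$release_time_min]
  expect_lt(max(post, na.rm = TRUE), 0.8 * cp_clean()$area_interphase)
})

test_that("invalid parameters and windows are rejected", {
  expect_error(cycle_params(durations_min = list(NC10 = -1, NC11 = 10,
                                                 NC12 = 11, NC13 = 17,
                                                 stage5 = 59)),
               class = "embryokin_error")
  expect_error(cycle_params(area_telophase = 30),
               class = "embryokin_error")
  expect_error(generate_trace(cp_clean(), anoxia_params(500, 510), seed = 1),
               class = "embryokin_error")
  expect_error(anoxia_params(10, 5), class = "embryokin_error")
})
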