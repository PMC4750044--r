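test_that("minima of a triangular wave sit at every period", {
  t <- 0:60
  area <- 10 + 5 * abs(((t %% 10) - 5) / 5)    # minima at 5, 15, 25, ...
  traj <- as_area_trajectory(data.frame(time_min = t, area = area))
  m <- detect_minima(traj, smooth_win_frames = 1)
  expect_equal(m$time_min, seq(5, 55, by = 10))
  expect_error(detect_minima(as_area_trajectory(
    data.frame(time_min = 0:9, area = NA_real_))), class = "embryokin_error")
})

test_that("interior missing values are bridged before smoothing", {
  g <- generate_trace(cp_clean(), seed = 3)
  tr <- g$trace
  tr$area[frame_at(tr, 50)] <- NA               # drop one interphase frame
  m <- detect_minima(tr)
  nd <- g$truth$nd_times[-1]
  for (t in nd) expect_true(any(abs(m$time_min - ceiling(t)) <= 1))
})

test_that("truncated recordings yield partial annotations", {
  g <- generate_trace(cp_clean(), seed = 5)
  cut <- g$trace[g$trace$time_min <= 100, ]     # stops mid-stage-5
  an <- annotate_cycles(as_area_trajectory(cut))
  expect_true(is.na(an$cycles$duration[an$cycles$cycle == "stage5"]))
  expect_false(anyNA(an$cycles$duration[1:4]))
})

test_that("ND12 alignment is shift-equivariant", {
  g <- generate_trace(cycle_params(), seed = 8)
  tr <- g$trace
  shifted <- tr
  shifted$time_min <- shifted$time_min + 5
  al <- align_at_nd12(list(tr, shifted))
  expect_equal(al[[1]]$time_min, al[[2]]$time_min)
  expect_equal(al[[1]]$area, al[[2]]$area)
  # a jittered cohort has zero variance at the anchor by construction
  co <- generate_cohort(8, cycle_params(), seed = 9)
  anns <- lapply(co, function(g) annotate_cycles(g$trace))
  al <- align_at_nd12(lapply(co, `[[`, "trace"), anns)
  nd12_aligned <- vapply(seq_along(al), function(i) {
    anns[[i]]$nd12_time_min - attr(al[[i]], "nd12_shift_min")
  }, numeric(1))
  expect_equal(var(nd12_aligned), 0)
  # missing ND12 is an error
  short <- as_area_trajectory(tr[tr$time_min <= 40, ])
  expect_error(align_at_nd12(list(short)), class = "embryokin_error")
})

test_that("cohort averaging follows the mean/S.E.M. formulas", {
  g <- generate_trace(cycle_params(), seed = 10)
  trs <- rep(list(g$trace), 10)
  anns <- lapply(trs, annotate_cycles)
  cs <- cohort_average(align_at_nd12(trs, anns), anns)
  expect_lt(max(cs$curve$sem_area), 1e-6)
  expect_equal(cs$curve$n, rep(10, nrow(cs$curve)))
  ok <- !is.na(g$trace$area)
  expect_equal(sort(cs$curve$mean_area), sort(g$trace$area[ok]))
  # durations {10, 12, 14} -> mean 12, S.E.M. 2/sqrt(3)
  fake_ann <- function(d) {
    a <- annotate_cycles(g$trace)
    a$cycles$duration[a$cycles$cycle == "NC12"] <- d
    a
  }
  cs2 <- cohort_average(align_at_nd12(trs[1:3], anns[1:3]),
                        lapply(c(10, 12, 14), fake_ann))
  row <- cs2$durations[cs2$durations$cycle == "NC12", ]
  expect_equal(row$mean, 12)
  expect_equal(row$sem, 2 / sqrt(3))
  expect_equal(row$n, 3)
})

test_that("cycle durations tile the telophase-to-telophase span exactly", {
  for (g in control_cohort()[1:6]) {
    an <- annotate_cycles(g$trace)
    nd <- an$telophase_times_min
    expect_equal(sum(an$cycles$duration[1:4]),
                 nd[["ND13"]] - nd[["ND9"]])
  }
})

test_that("the whole annotation is time-shift equivariant", {
  g <- generate_trace(cycle_params(), seed = 13)
  tr <- g$trace
  tr2 <- tr
  tr2$time_min <- tr2$time_min + 17
  a1 <- annotate_cycles(tr)
  a2 <- annotate_cycles(tr2)
  expect_equal(a2$telophase_times_min, a1$telophase_times_min + 17)
  expect_equal(a2$cycles$duration, a1$cycles$duration)
  expect_equal(a2$vff_time_min, a1$vff_time_min + 17)
})

test_that("30-second sampling changes durations by at most one minute", {
  cp60 <- cp_clean()
  cp30 <- cp_clean(frame_interval_s = 30)
  d60 <- annotate_cycles(generate_trace(cp60, seed = 14)$trace)$cycles$duration
  d30 <- annotate_cycles(generate_trace(cp30, seed = 14)$trace)$cycles$duration
  expect_true(all(abs(d60 - d30) <= 1 + 1e-9))
})

test_that("noisy minima stay within one frame of truth in >= 95% of seeds", {
  cp <- cycle_params(noise_sd = 0.05, per_embryo_jitter_sd = 0.05)
  hits <- misses <- 0
  for (s in 1:100) {
    g <- generate_trace(cp, seed = 1000 + s)
    m <- detect_minima(g$trace)
    for (t in g$truth$nd_times[-1]) {
      if (any(abs(m$time_min - ceiling(t)) <= 1 + 1e-9)) hits <- hits + 1
      else misses <- misses + 1
    }
  }
  expect_gte(hits / (hits + misses), 0.95)
})
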