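test_that("a normal metaphase residence never registers as arrest", {
  g <- generate_trace(cycle_params(), seed = 31)
  expect_null(detect_arrest(g$trace, default_anoxia_window()))
  # a window over the interphase plateau of an unperturbed trace: absent
  expect_null(detect_arrest(g$trace, anoxia_window(58, 62)))
  expect_error(detect_arrest(g$trace, anoxia_window(500, 510)),
               class = "embryokin_error")
})

test_that("detected arrest length matches the generator truth within one frame", {
  cp <- cycle_params()
  ap <- default_anoxia_window(cp, fail_prob = 0)
  for (s in 41:46) {
    g <- generate_trace(cp, ap, seed = s)
    arr <- detect_arrest(g$trace, ap)
    expect_false(is.null(arr))
    truth <- g$truth$arrest_interval
    expect_lte(abs(diff(arr) - diff(truth)), 1 + 1e-9)
  }
})

test_that("recovery-to-anaphase time equals the injected lag", {
  cp <- cp_clean()
  # noiseless, fixed lag: exact to within half a frame
  for (lag in c(7.9, 0)) {
    ap <- ap_clean(cp, recovery_lag_min = lag)
    g <- generate_trace(cp, ap, seed = 51)
    arr <- detect_arrest(g$trace, ap)
    rt <- recovery_time(g$trace, ap, arr)
    expect_lte(abs(rt - lag), 1)
  }
  # plateau that never ends before the recording does: absent
  cp_short <- cycle_params(noise_sd = 0, per_embryo_jitter_sd = 0,
                           total_min = 140)
  ap_late <- ap_clean(cp_short, recovery_lag_min = 70)
  g <- generate_trace(cp_short, ap_late, seed = 52)
  arr <- c(g$truth$arrest_interval[1], 140)
  expect_true(is.na(recovery_time(g$trace, ap_late, arr)))
  # invariant to rescaling of the area axis
  ap <- ap_clean(cp)
  g <- generate_trace(cp, ap, seed = 53)
  arr <- detect_arrest(g$trace, ap)
  g2 <- g$trace
  g2$area <- g2$area * 3.7
  expect_equal(recovery_time(g2, ap, detect_arrest(g2, ap)),
               recovery_time(g$trace, ap, arr))
})

test_that("recovery classification matches the generator phenotype", {
  cp <- cycle_params()
  ok <- generate_trace(cp, default_anoxia_window(cp, fail_prob = 0),
                       seed = 61)
  bad <- generate_trace(cp, default_anoxia_window(cp, fail_prob = 1),
                        seed = 61)
  win <- default_anoxia_window(cp)
  arr_ok <- detect_arrest(ok$trace, win)
  arr_bad <- detect_arrest(bad$trace, win)
  expect_true(classify_recovery(ok$trace, arrest = arr_ok)$recovered)
  cls_bad <- classify_recovery(bad$trace, arrest = arr_bad)
  expect_false(cls_bad$recovered)
  expect_true(cls_bad$count_collapse)
})

test_that("the recovered fraction converges to the failure-probability complement", {
  cp <- cycle_params()
  ap <- default_anoxia_window(cp)          # fail_prob = 5/14
  n <- 100
  co <- generate_cohort(n, cp, ap, seed = 71)
  rec <- vapply(co, function(g) {
    arr <- detect_arrest(g$trace, ap)
    classify_recovery(g$trace, arrest = arr)$recovered
  }, logical(1))
  p <- 9 / 14
  expect_lt(abs(mean(rec) - p), 3 * sqrt(p * (1 - p) / n))
  # and classification agrees with the generator truth embryo by embryo
  truth <- vapply(co, function(g) g$truth$recovered, logical(1))
  expect_gte(mean(rec == truth), 0.97)
})

test_that("milestones are reported relative to stage-4 start", {
  g <- generate_trace(cp_clean(), seed = 81)
  ms <- milestone_times(annotate_cycles(g$trace))
  expect_equal(ms[["ND13"]], 7.8 + 9.9 + 11.4 + 16.9)   # 46.0 on-grid
  expect_true(all(diff(ms) > 0))
  # arrested embryo: ND10-12 unchanged, ND13 and VFF shifted by the arrest
  ga <- generate_trace(cp_clean(), ap_clean(), seed = 81)
  msa <- milestone_times(annotate_cycles(ga$trace))
  expect_equal(msa[c("ND10", "ND11", "ND12")],
               ms[c("ND10", "ND11", "ND12")])
  expect_lte(abs((msa[["ND13"]] - ms[["ND13"]]) - ga$truth$extension_min), 1)
  # VFF delay equals the arrest extension exactly at the truth level
  expect_equal(ga$truth$vff_time_min - g$truth$vff_time_min,
               ga$truth$extension_min)
  # truncated trace: VFF absent
  cut <- as_area_trajectory(g$trace[g$trace$time_min <= 100, ])
  expect_true(is.na(milestone_times(annotate_cycles(cut))[["VFF"]]))
})

test_that("identical groups compare as no difference, p = 1 under zero variance", {
  recs <- lapply(control_cohort()[1:5], function(g)
    perturbation_record(g$trace))
  cmp <- compare_groups(recs, recs)
  expect_true(all(abs(cmp$difference) < 1e-12))
  # degenerate zero-variance groups
  r <- recs[[1]]
  cmp0 <- compare_groups(list(r, r), list(r, r))
  expect_true(all(cmp0$p[!is.na(cmp0$p)] == 1))
})

test_that("pre-exposure milestones are equivalent between arms (~alpha rejections)", {
  cp <- cycle_params()
  ap <- default_anoxia_window(cp)
  rejections <- 0
  for (s in 1:20) {
    ctrl <- generate_cohort(6, cp, seed = 3000 + s)
    trt <- generate_cohort(6, cp, ap, seed = 4000 + s)
    rc <- lapply(ctrl, function(g) perturbation_record(g$trace))
    rt <- lapply(trt, function(g) perturbation_record(g$trace, ap))
    cmp <- compare_groups(rc, rt)
    p <- cmp$p[cmp$metric == "ND11"]
    if (!is.na(p) && p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 4)   # Binomial(20, 0.05): P(>4) < 0.003
})
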