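#' Nuclear-cycle generator parameters
#'
#' Bundles the parameters of the synthetic nuclear-cycle phase model: the
#' mean-nuclear-area waveform rises from a telophase minimum to an interphase
#' plateau, declines through prophase to a metaphase shoulder, and drops to the
#' next telophase minimum; stage 5 is one long interphase-14 plateau ending
#' with the terminal decline used as the ventral-furrow-formation (VFF) proxy.
#'
#' @param durations_min named list/vector of cycle durations in minutes; must
#'   contain `NC10`, `NC11`, `NC12`, `NC13` and `stage5`. Defaults are the
#'   on-chip cohort means (7.8, 9.9, 11.4, 16.9, 59.3 min).
#' @param pre_stage4_min minutes of recording before nuclei appear at the
#'   periphery (stage-4 onset); the trace is missing there (no nuclei).
#' @param metaphase_hold_min normal metaphase residence time in minutes.
#' @param frame_interval_s sampling interval in seconds (one frame per minute).
#' @param total_min total recording length in minutes.
#' @param noise_sd additive Gaussian noise s.d. on the area signal, as a
#'   fraction of `area_interphase`. The per-frame signal is a mean over on the
#'   order of a hundred nuclei, so the default is small (2\%).
#' @param area_interphase mean nuclear area at interphase (um^2). The absolute
#'   scale is a free parameter; all kinetic quantities live in time units.
#' @param area_telophase minimum (telophase) area (um^2).
#' @param per_embryo_jitter_sd s.d. of the multiplicative log-normal jitter
#'   applied independently to each duration (and the pre-stage-4 span) per
#'   embryo; 0.05 gives cohort S.E.M.s of the observed order.
#' @param count_nc10 number of peripheral nuclei visible at NC10 interphase;
#'   counts double exactly at each division.
#' @param rise_frac,decline_frac fraction of each cycle spent in the
#'   telophase-to-interphase rise and the prophase decline.
#' @param meta_shoulder_frac metaphase-entry area, as a fraction of the
#'   interphase-telophase range above the telophase floor.
#' @param telo_floor_min duration of the telophase floor (minutes; at least
#'   one frame).
#' @param stage5_rise_min minutes for the interphase-14 chromatin expansion at
#'   stage-5 entry.
#' @param vff_decline_min duration of the terminal (gastrulation-onset)
#'   decline in minutes.
#' @param post_vff_frac post-VFF signal level as a fraction of
#'   `area_interphase`.
#'
#' @return an object of class `cycle_params`.
#' @seealso [generate_trace()], [anoxia_params()]
#' @export
cycle_params <- function(durations_min = list(NC10 = 7.8, NC11 = 9.9,
                                              NC12 = 11.4, NC13 = 16.9,
                                              stage5 = 59.3),
                         pre_stage4_min = 25,
                         metaphase_hold_min = 1.5,
                         frame_interval_s = 60,
                         total_min = 180,
                         noise_sd = 0.02,
                         area_interphase = 28,
                         area_telophase = 8,
                         per_embryo_jitter_sd = 0.05,
                         count_nc10 = 8,
                         rise_frac = 0.2,
                         decline_frac = 0.3,
                         meta_shoulder_frac = 0.25,
                         telo_floor_min = 1,
                         stage5_rise_min = 4,
                         vff_decline_min = 5,
                         post_vff_frac = 0.4) {
  durations_min <- as.list(durations_min)
  need <- c("NC10", "NC11", "NC12", "NC13", "stage5")
  ek_assert(all(need %in% names(durations_min)),
            "durations_min must name NC10, NC11, NC12, NC13 and stage5")
  d <- unlist(durations_min[need])
  ek_assert(all(is.finite(d)) && all(d > 0), "all durations must be > 0")
  ek_assert(frame_interval_s > 0, "frame_interval_s must be > 0")
  ek_assert(area_telophase < area_interphase,
            "area_telophase must be smaller than area_interphase")
  ek_assert(pre_stage4_min >= 0 && total_min > 0, "times must be non-negative")
  ek_assert(rise_frac > 0 && decline_frac > 0 && rise_frac + decline_frac < 1,
            "rise_frac and decline_frac must be positive and sum below 1")
  dt_min <- frame_interval_s / 60
  telo_floor_min <- max(telo_floor_min, dt_min)
  slack <- (1 - rise_frac - decline_frac)
  ek_assert(all(d[1:4] * slack >= telo_floor_min + metaphase_hold_min),
            "cycle durations too short for the telophase floor plus ",
            "metaphase hold at the given rise/decline fractions")
  ek_assert(total_min >= pre_stage4_min + sum(d) + vff_decline_min,
            "total_min must cover pre-stage-4, NC10-NC13, stage 5 and the ",
            "terminal decline")
  structure(list(
    durations_min = as.list(d), pre_stage4_min = pre_stage4_min,
    metaphase_hold_min = metaphase_hold_min,
    frame_interval_s = frame_interval_s, total_min = total_min,
    noise_sd = noise_sd, area_interphase = area_interphase,
    area_telophase = area_telophase,
    per_embryo_jitter_sd = per_embryo_jitter_sd, count_nc10 = count_nc10,
    rise_frac = rise_frac, decline_frac = decline_frac,
    meta_shoulder_frac = meta_shoulder_frac, telo_floor_min = telo_floor_min,
    stage5_rise_min = stage5_rise_min, vff_decline_min = vff_decline_min,
    post_vff_frac = post_vff_frac), class = "cycle_params")
}

#' Anoxia perturbation parameters
#'
#' Describes a transient anoxic pulse delivered through the device and the
#' arrest/recovery phenotype it induces. Under anoxia, nuclei proceed to
#' metaphase, hypercondense, and hold there until several minutes after
#' normoxia is restored; release goes through a pronounced anaphase/telophase
#' minimum before interphase-14 chromatin expansion. Embryos fail to recover
#' with probability `fail_prob` (fused daughter nuclei, then delamination).
#'
#' @param t_on_min,t_off_min anoxia window on the experiment clock (minutes).
#' @param recovery_lag_min mean time from reoxygenation to anaphase onset.
#' @param recovery_lag_sd_min per-embryo s.d. of the recovery lag (truncated
#'   at zero).
#' @param hypercondensed_area_frac arrested-plateau area as a fraction of the
#'   telophase area (<= 1: hypercondensed chromatin is at least as compact as
#'   a normal telophase).
#' @param release_dip_frac area of the post-arrest anaphase/telophase minimum,
#'   as a fraction of the telophase area. Prolonged arrest leaves chromatin
#'   maximally condensed at release, so this transient dip sits well below the
#'   arrest plateau and marks the telophase ending the arrested cycle.
#' @param release_dip_min duration of that dip in minutes.
#' @param fail_prob probability that the embryo does not recover.
#' @param fail_mode failure phenotype; only
#'   `"fused_nuclei_then_delamination"` is modelled.
#' @param stage5_delay_mean_min,stage5_delay_sd_min post-recovery overhead
#'   added to stage 5 in recovered embryos (minutes): beyond the arrest
#'   extension itself, recovered embryos reach ventral furrow formation a few
#'   minutes later still, with a large embryo-to-embryo spread; the defaults
#'   reproduce the observed mean VFF delay and its dispersion while leaving
#'   stage-5 durations statistically indistinguishable from controls.
#'
#' @return an object of class `anoxia_params`.
#' @seealso [default_anoxia_window()], [generate_trace()]
#' @export
anoxia_params <- function(t_on_min, t_off_min,
                          recovery_lag_min = 7.9,
                          recovery_lag_sd_min = 2.6,
                          hypercondensed_area_frac = 0.8,
                          release_dip_frac = 0.3,
                          release_dip_min = 2,
                          fail_prob = 5 / 14,
                          fail_mode = "fused_nuclei_then_delamination",
                          stage5_delay_mean_min = 3,
                          stage5_delay_sd_min = 12) {
  ek_assert(t_on_min < t_off_min, "t_on must precede t_off")
  ek_assert(recovery_lag_min >= 0, "recovery_lag_min must be >= 0")
  ek_assert(fail_prob >= 0 && fail_prob <= 1, "fail_prob must be in [0, 1]")
  ek_assert(hypercondensed_area_frac > 0 && hypercondensed_area_frac <= 1,
            "hypercondensed_area_frac must be in (0, 1]")
  ek_assert(release_dip_frac > 0 &&
              release_dip_frac < hypercondensed_area_frac,
            "release_dip_frac must be below hypercondensed_area_frac")
  fail_mode <- match.arg(fail_mode, "fused_nuclei_then_delamination")
  structure(list(
    t_on_min = t_on_min, t_off_min = t_off_min,
    recovery_lag_min = recovery_lag_min,
    recovery_lag_sd_min = recovery_lag_sd_min,
    hypercondensed_area_frac = hypercondensed_area_frac,
    release_dip_frac = release_dip_frac, release_dip_min = release_dip_min,
    fail_prob = fail_prob, fail_mode = fail_mode,
    stage5_delay_mean_min = stage5_delay_mean_min,
    stage5_delay_sd_min = stage5_delay_sd_min), class = "anoxia_params")
}

#' Default 10-minute anoxia window during NC13
#'
#' Places the anoxic pulse on the experiment clock so that, for an embryo with
#' nominal cycle durations, the window opens `offset_in_nc13_min` minutes
#' after nuclear division 12 (mid-NC13). With the default offset, window
#' length and recovery lag, the arrested NC13 (telophase to telophase) is
#' 10.1 + 10 + 7.9 = 28.0 minutes -- the observed arrested-cycle duration.
#'
#' @param cp a [cycle_params()] object (nominal, unjittered timing).
#' @param offset_in_nc13_min minutes between ND12 and anoxia onset.
#' @param duration_min window length in minutes.
#' @param ... passed on to [anoxia_params()].
#' @return an `anoxia_params` object.
#' @export
default_anoxia_window <- function(cp = cycle_params(),
                                  offset_in_nc13_min = 10.1,
                                  duration_min = 10, ...) {
  d <- cp$durations_min
  nd12 <- cp$pre_stage4_min + d$NC10 + d$NC11 + d$NC12
  anoxia_params(t_on_min = nd12 + offset_in_nc13_min,
                t_off_min = nd12 + offset_in_nc13_min + duration_min, ...)
}

# ---- piecewise-linear signal machinery ------------------------------------

# segments: data.frame(t0, t1, v0, v1); half-open [t0, t1)
seg <- function(t0, t1, v0, v1 = v0) {
  if (t1 <= t0) return(NULL)
  data.frame(t0 = t0, t1 = t1, v0 = v0, v1 = v1)
}

sample_segments <- function(segments, times) {
  v <- rep(NA_real_, length(times))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    in_seg <- times >= s$t0 & times < s$t1
    if (any(in_seg)) {
      frac <- (times[in_seg] - s$t0) / (s$t1 - s$t0)
      v[in_seg] <- s$v0 + (s$v1 - s$v0) * frac
    }
  }
  v
}

# normal cycle waveform on [s, s+T): floor, rise, interphase plateau,
# prophase decline to the metaphase shoulder, metaphase hold down to the
# next telophase. `clip_at` truncates (for arrest onset).
cycle_segments <- function(s, T, cp, clip_at = Inf, rise_from = NULL,
                           rise_start = NULL) {
  a_int <- cp$area_interphase
  a_tel <- cp$area_telophase
  a_met <- a_tel + cp$meta_shoulder_frac * (a_int - a_tel)
  fl <- cp$telo_floor_min
  tr <- cp$rise_frac * T
  td <- cp$decline_frac * T
  hold <- cp$metaphase_hold_min
  segs <- list()
  if (is.null(rise_start)) {
    segs$floor <- seg(s, s + fl, a_tel)
    rise_start <- s + fl
    rise_from <- a_tel
  }
  segs$rise <- seg(rise_start, rise_start + tr, rise_from, a_int)
  segs$plateau <- seg(rise_start + tr, s + T - hold - td, a_int)
  segs$decline <- seg(s + T - hold - td, s + T - hold, a_int, a_met)
  segs$hold <- seg(s + T - hold, s + T, a_met, a_tel)
  out <- do.call(rbind, segs)
  clip_segments(out, clip_at)
}

stage5_segments <- function(s, T5, cp, total, rise_from = NULL,
                            rise_start = NULL) {
  a_int <- cp$area_interphase
  a_tel <- cp$area_telophase
  a_post <- cp$post_vff_frac * a_int
  fl <- cp$telo_floor_min
  segs <- list()
  if (is.null(rise_start)) {
    segs$floor <- seg(s, s + fl, a_tel)
    rise_start <- s + fl
    rise_from <- a_tel
  }
  r5 <- cp$stage5_rise_min
  segs$rise <- seg(rise_start, rise_start + r5, rise_from, a_int)
  segs$plateau <- seg(rise_start + r5, s + T5, a_int)
  segs$vff <- seg(s + T5, s + T5 + cp$vff_decline_min, a_int, a_post)
  # open-ended so the final frame (t == total) is covered
  segs$tail <- seg(s + T5 + cp$vff_decline_min,
                   max(total, s + T5 + cp$vff_decline_min) + 1, a_post)
  do.call(rbind, segs)
}

clip_segments <- function(segments, clip_at) {
  if (is.infinite(clip_at)) return(segments)
  keep <- segments$t0 < clip_at
  segments <- segments[keep, , drop = FALSE]
  n <- nrow(segments)
  if (n && segments$t1[n] > clip_at) {
    frac <- (clip_at - segments$t0[n]) / (segments$t1[n] - segments$t0[n])
    segments$v1[n] <- segments$v0[n] + (segments$v1[n] - segments$v0[n]) * frac
    segments$t1[n] <- clip_at
  }
  segments
}

value_at <- function(segments, t) sample_segments(segments, t)

# ---- generator -------------------------------------------------------------

#' Generate a synthetic mean-nuclear-area trajectory with ground truth
#'
#' Simulates the per-frame mean nuclear area and nucleus count of one embryo
#' developing through NC10-NC13 and stage 5, optionally perturbed by a
#' transient anoxic pulse. Identical `(cp, ap, seed)` give bit-identical
#' output.
#'
#' @param cp a [cycle_params()] object.
#' @param ap optional [anoxia_params()] object; `NULL` for an unperturbed
#'   control embryo.
#' @param seed integer seed; every random draw (per-embryo jitter, noise,
#'   recovery lag, failure) derives from it.
#' @param embryo_id identifier stored with the trajectory.
#'
#' @return a list with components `trace` (an `area_trajectory` data frame
#'   with columns `time_min`, `area`, `count`; `area` is `NA` where no nuclei
#'   are present) and `truth` (an `embryo_truth` list: jittered durations,
#'   division times `ND9`-`ND13`, labelled cycle intervals, `vff_time_min`,
#'   `arrest_interval`, `release_time_min`, `recovery_lag_min`,
#'   `extension_min`, `recovered`, and per-frame counts).
#' @examples
#' tr <- generate_trace(cycle_params(noise_sd = 0), seed = 1)
#' diff(tr$truth$nd_times)  # the generating NC11-NC13 durations
#' @export
generate_trace <- function(cp = cycle_params(), ap = NULL, seed = 1,
                           embryo_id = "embryo") {
  ek_assert(inherits(cp, "cycle_params"), "cp must be a cycle_params object")
  if (!is.null(ap))
    ek_assert(inherits(ap, "anoxia_params"), "ap must be an anoxia_params")
  with_seed(seed, generate_trace_impl(cp, ap, embryo_id))
}

generate_trace_impl <- function(cp, ap, embryo_id) {
  dt <- cp$frame_interval_s / 60
  jit <- function(x) {
    s <- cp$per_embryo_jitter_sd
    if (s <= 0) x else x * rlnorm(length(x), meanlog = -s^2 / 2, sdlog = s)
  }
  pre <- jit(cp$pre_stage4_min)
  d <- vapply(cp$durations_min, identity, numeric(1))
  d[] <- jit(d)
  # keep the jittered cycles renderable
  slack <- 1 - cp$rise_frac - cp$decline_frac
  d[1:4] <- pmax(d[1:4], (cp$telo_floor_min + cp$metaphase_hold_min) / slack)

  starts <- pre + c(0, cumsum(d[c("NC10", "NC11", "NC12")]))
  names(starts) <- c("NC10", "NC11", "NC12", "NC13")
  s14 <- starts[["NC13"]] + d[["NC13"]]         # normal ND13 / stage-5 start
  total <- cp$total_min

  arrest <- NULL
  release <- NA_real_
  lag_i <- NA_real_
  recovered <- TRUE
  s5_delay <- 0
  ext <- 0
  k <- NA_integer_

  if (!is.null(ap)) {
    ek_assert(ap$t_on_min >= 0 && ap$t_off_min <= total,
              "anoxia window outside the simulated time span")
    ek_assert(ap$t_on_min >= starts[["NC10"]] && ap$t_on_min < s14,
              "anoxia window must open during a nuclear cycle (NC10-NC13)")
    k <- max(which(starts <= ap$t_on_min))
    s_k <- starts[[k]]
    T_k <- d[[k]]
    meta_entry <- s_k + T_k - cp$metaphase_hold_min
    arrest_start <- max(meta_entry, ap$t_on_min)
    if (ap$t_off_min > arrest_start) {
      lag_i <- max(0, rnorm(1, ap$recovery_lag_min, ap$recovery_lag_sd_min))
      release <- ap$t_off_min + lag_i
      recovered <- runif(1) >= ap$fail_prob
      s5_delay <- rnorm(1, ap$stage5_delay_mean_min, ap$stage5_delay_sd_min)
      ext <- release - (s_k + T_k)
      arrest <- c(arrest_start, release + ap$release_dip_min)
    }
  }

  a_int <- cp$area_interphase
  a_tel <- cp$area_telophase
  cyc_names <- c("NC10", "NC11", "NC12", "NC13")
  segs <- list()
  nd <- setNames(rep(NA_real_, 5), c("ND9", "ND10", "ND11", "ND12", "ND13"))
  nd[["ND9"]] <- pre

  if (is.null(arrest)) {
    for (j in 1:4) {
      segs[[cyc_names[j]]] <- cycle_segments(starts[[j]], d[[j]], cp)
      nd[[j + 1L]] <- starts[[j]] + d[[j]]
    }
    segs$stage5 <- stage5_segments(s14, d[["stage5"]], cp, total)
    vff <- s14 + d[["stage5"]]
  } else {
    hyper <- ap$hypercondensed_area_frac * a_tel
    dip <- ap$release_dip_frac * a_tel
    dip_len <- ap$release_dip_min
    arrest_start <- arrest[1]
    for (j in seq_len(k - 1)) {
      segs[[cyc_names[j]]] <- cycle_segments(starts[[j]], d[[j]], cp)
      nd[[j + 1L]] <- starts[[j]] + d[[j]]
    }
    pre_arrest <- cycle_segments(starts[[k]], d[[k]], cp,
                                 clip_at = arrest_start)
    v0 <- value_at(pre_arrest, max(starts[[k]],
                                   arrest_start - 1e-9))
    if (is.na(v0)) v0 <- a_tel
    condense <- min(1, release - arrest_start)
    segs[[cyc_names[k]]] <- rbind(
      pre_arrest,
      seg(arrest_start, arrest_start + condense, v0, hyper),
      seg(arrest_start + condense, release, hyper),
      seg(release, release + dip_len, dip))
    nd[[k + 1L]] <- release                       # telophase ending NC k
    # the recorded arrest interval is the span the rendered signal spends
    # at or below the telophase-level band (10% above telophase area):
    # from the crossing inside the hypercondensation drop to the crossing
    # inside the post-release rise
    band <- 1.1 * a_tel
    if (v0 > band && v0 > hyper)
      arrest[1] <- arrest_start + condense * (v0 - band) / (v0 - hyper)
    rise_target <- if (recovered) a_int else 0.5 * a_int
    rise_time <- if (!recovered) 3
                 else if (k < 4) cp$rise_frac * d[[k + 1]]
                 else cp$stage5_rise_min
    if (rise_target > band)
      arrest[2] <- arrest[2] +
        (band - dip) * rise_time / (rise_target - dip)
    if (recovered) {
      rise_start <- release + dip_len
      if (k < 4) {
        for (j in (k + 1):4) {
          sj <- starts[[j]] + ext
          if (j == k + 1) {
            segs[[cyc_names[j]]] <- cycle_segments(sj, d[[j]], cp,
                                                   rise_from = dip,
                                                   rise_start = rise_start)
          } else {
            segs[[cyc_names[j]]] <- cycle_segments(sj, d[[j]], cp)
          }
          nd[[j + 1L]] <- sj + d[[j]]
        }
        segs$stage5 <- stage5_segments(s14 + ext, d[["stage5"]] + s5_delay,
                                       cp, total)
      } else {
        segs$stage5 <- stage5_segments(release, d[["stage5"]] + s5_delay,
                                       cp, total, rise_from = dip,
                                       rise_start = rise_start)
      }
      vff <- (if (k < 4) s14 + ext else release) + d[["stage5"]] + s5_delay
    } else {
      # fused daughter nuclei, then delamination: no further divisions
      fused_level <- 0.5 * a_int
      fuse_rise <- 3
      fuse_hold <- 8
      delam <- 10
      t0 <- release + dip_len
      segs$fused <- rbind(
        seg(t0, t0 + fuse_rise, dip, fused_level),
        seg(t0 + fuse_rise, t0 + fuse_rise + fuse_hold, fused_level),
        seg(t0 + fuse_rise + fuse_hold, t0 + fuse_rise + fuse_hold + delam,
            fused_level, 0))
      vff <- NA_real_
    }
  }

  segments <- do.call(rbind, segs)
  times <- seq(0, total, by = dt)
  area <- sample_segments(segments, times)

  # nucleus counts: n0 at stage-4 onset, doubling at each division
  n0 <- cp$count_nc10
  count <- integer(length(times))
  bounds <- c(nd[["ND9"]], nd[-1L][!is.na(nd[-1L])])
  for (b in seq_along(bounds)) {
    count[times >= bounds[b]] <- n0 * 2^(b - 1L)
  }
  if (!is.null(arrest) && !recovered) {
    # the attempted division fails: counts never double after arrest,
    # then nuclei delaminate and the count collapses to zero
    lvl <- n0 * 2^(k - 1L)
    count[times >= release] <- lvl
    t0 <- release + ap$release_dip_min + 3 + 8    # delamination onset
    dec <- times >= t0
    count[dec] <- round(lvl * 2^(-(times[dec] - t0) / 3))
    count[times >= t0 + 10] <- 0L
  }
  area[count == 0L] <- NA_real_
  if (cp$noise_sd > 0) {
    ok <- !is.na(area)
    area[ok] <- area[ok] + rnorm(sum(ok), 0, cp$noise_sd * a_int)
  }

  cycles <- data.frame(
    cycle = c(cyc_names, "stage5"),
    start = c(nd[["ND9"]], nd[["ND10"]], nd[["ND11"]], nd[["ND12"]],
              nd[["ND13"]]),
    end = c(nd[["ND10"]], nd[["ND11"]], nd[["ND12"]], nd[["ND13"]], vff))
  cycles$duration <- cycles$end - cycles$start

  trace <- as_area_trajectory(data.frame(time_min = times, area = area,
                                         count = count),
                              embryo_id = embryo_id,
                              frame_interval_s = cp$frame_interval_s)
  truth <- structure(list(
    embryo_id = embryo_id,
    durations_min = cycles$duration[match(c(cyc_names, "stage5"),
                                          cycles$cycle)],
    nd_times = nd,
    cycle_intervals = cycles,
    vff_time_min = vff,
    arrest_interval = arrest,
    release_time_min = release,
    recovery_lag_min = lag_i,
    extension_min = if (is.null(arrest)) 0 else ext,
    stage5_delay_min = if (is.null(arrest) || !recovered) NA_real_
                       else s5_delay,
    recovered = recovered,
    nucleus_count_per_frame = count,
    affected_cycle = if (is.null(arrest)) NA_character_ else cyc_names[k]),
    class = "embryo_truth")
  names(truth$durations_min) <- c(cyc_names, "stage5")
  list(trace = trace, truth = truth)
}

#' Generate a cohort of synthetic embryos
#'
#' @param n number of embryos.
#' @param cp a [cycle_params()] object shared by the cohort.
#' @param ap optional [anoxia_params()] applied to every embryo.
#' @param seed master seed; per-embryo seeds are drawn from it, so the whole
#'   cohort is reproducible from a single integer.
#' @param prefix embryo-id prefix.
#' @return a list of `generate_trace()` results.
#' @export
generate_cohort <- function(n, cp = cycle_params(), ap = NULL, seed = 1,
                            prefix = "embryo") {
  ek_assert(n >= 1, "n must be at least 1")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    generate_trace(cp, ap, seed = seeds[i],
                   embryo_id = sprintf("%s_%02d", prefix, i))
  })
}

#' Area-trajectory container
#'
#' A data frame with columns `time_min` (strictly increasing, uniformly
#' spaced), `area` (mean nuclear area per frame, um^2, `NA` allowed) and
#' `count` (nuclei per frame), carrying `embryo_id` and `frame_interval_s`
#' attributes.
#'
#' @param x data frame with at least `time_min` and `area`; `count` defaults
#'   to `NA`. Columns named as written by [write_features_csv()]
#'   (`mean_nuclear_area_um2`, `nucleus_count`) are recognised.
#' @param embryo_id identifier.
#' @param frame_interval_s frame interval; inferred from `time_min` if absent.
#' @return an `area_trajectory` object.
#' @export
as_area_trajectory <- function(x, embryo_id = "embryo",
                               frame_interval_s = NULL) {
  x <- as.data.frame(x)
  if (!"area" %in% names(x) && "mean_nuclear_area" %in% names(x))
    x$area <- x$mean_nuclear_area
  if (!"area" %in% names(x) && "mean_nuclear_area_um2" %in% names(x))
    x$area <- x$mean_nuclear_area_um2
  if (!"count" %in% names(x) && "nucleus_count" %in% names(x))
    x$count <- x$nucleus_count
  ek_assert(all(c("time_min", "area") %in% names(x)),
            "need columns time_min and area (or mean_nuclear_area[_um2])")
  if (!"count" %in% names(x)) x$count <- NA_integer_
  dt <- diff(x$time_min)
  ek_assert(all(dt > 0), "time_min must be strictly increasing")
  ek_assert(length(dt) == 0 || max(abs(dt - dt[1])) < 1e-6,
            "time_min must be uniformly spaced")
  if (is.null(frame_interval_s))
    frame_interval_s <- if (length(dt)) dt[1] * 60 else 60
  out <- x[, c("time_min", "area", "count")]
  attr(out, "embryo_id") <- embryo_id
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- c("area_trajectory", "data.frame")
  out
}

frame_minutes <- function(traj) attr(traj, "frame_interval_s") / 60

#' @export
print.area_trajectory <- function(x, ...) {
  cat(sprintf("<area_trajectory> %s: %d frames, %.3g min/frame, %d with nuclei\n",
              attr(x, "embryo_id"), nrow(x), frame_minutes(x),
              sum(!is.na(x$area))))
  invisible(x)
}
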