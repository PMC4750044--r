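#' Anoxia window descriptor
#'
#' @param t_on_min,t_off_min window on the experiment clock, minutes.
#' @return an `anoxia_window` object.
#' @export
anoxia_window <- function(t_on_min, t_off_min) {
  ek_assert(t_on_min < t_off_min, "t_on must precede t_off")
  structure(list(t_on_min = t_on_min, t_off_min = t_off_min),
            class = "anoxia_window")
}

as_anoxia_window <- function(win) {
  if (inherits(win, "anoxia_window")) return(win)
  if (inherits(win, "anoxia_params"))
    return(anoxia_window(win$t_on_min, win$t_off_min))
  ek_stop("win must be an anoxia_window or anoxia_params object")
}

#' Detect anoxia-induced metaphase arrest
#'
#' An arrest is a run of frames at or below the telophase-level area band
#' that overlaps the anoxia window and lasts longer than
#' `hold_threshold_min`. A normal metaphase residence (1-2 min) never
#' qualifies; the hypercondensed arrest plateau (window plus recovery lag)
#' does.
#'
#' @param traj an `area_trajectory`.
#' @param win an [anoxia_window()] (or [anoxia_params()]).
#' @param hold_threshold_min minimum duration, in minutes, for a low-area run
#'   to count as arrest.
#' @param band_frac the telophase band extends to `(1 + band_frac)` times the
#'   telophase reference level.
#' @param annotation optional [annotate_cycles()] result (supplies the
#'   telophase reference level; computed if `NULL`).
#' @param smooth_win_frames moving-average window used on the trace.
#' @return numeric `c(start, end)` in minutes (half-open), or `NULL` when no
#'   arrest is present.
#' @export
detect_arrest <- function(traj, win, hold_threshold_min = 3,
                          band_frac = 0.10, annotation = NULL,
                          smooth_win_frames = 3) {
  win <- as_anoxia_window(win)
  ek_assert(win$t_on_min >= min(traj$time_min) &&
              win$t_off_min <= max(traj$time_min),
            "anoxia window outside the trajectory span")
  if (is.null(annotation)) annotation <- annotate_cycles(traj)
  sm <- smoothed_valid(traj, smooth_win_frames)
  # running median: robust to noise without smearing the plateau edges
  k <- max(3L, smooth_win_frames + (1L - smooth_win_frames %% 2L))
  y <- stats::runmed(bridge_na(traj$area)[sm$index], k, endrule = "median")
  tm <- traj$time_min[sm$index]
  telo <- median(traj$area[annotation$minima$index], na.rm = TRUE)
  if (!is.finite(telo)) return(NULL)
  low <- y <= telo * (1 + band_frac)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- frame_minutes(traj)
  best <- NULL
  for (q in which(r$values)) {
    t0 <- tm[starts[q]]
    t1 <- tm[ends[q]] + dt
    if (t1 - t0 > hold_threshold_min &&
        t0 < win$t_off_min + 2 * dt && t1 > win$t_on_min) {
      if (is.null(best) || (t1 - t0) > (best[2] - best[1]))
        best <- c(t0, t1)
    }
  }
  best
}

#' Time from reoxygenation to anaphase onset
#'
#' Anaphase onset is taken as the end of the hypercondensed arrest plateau:
#' the first sustained (two-frame) departure of the trace from the
#' hypercondensed band after the anoxia window closes. Reported as
#' `onset - t_off`, with a half-frame midpoint correction so the estimate is
#' unbiased on the sampling grid. The estimate depends only on times and
#' relative levels, so it is invariant to rescaling of the area axis.
#'
#' @inheritParams detect_arrest
#' @param arrest arrest interval from [detect_arrest()].
#' @param band_frac half-width of the hypercondensed band as a fraction of
#'   the telophase reference level.
#' @return minutes (`NA` if the plateau never ends before the recording
#'   does).
#' @export
recovery_time <- function(traj, win, arrest, band_frac = 0.10,
                          annotation = NULL, smooth_win_frames = 3) {
  win <- as_anoxia_window(win)
  ek_assert(!is.null(arrest) && length(arrest) == 2, "arrest must be present")
  if (is.null(annotation)) annotation <- annotate_cycles(traj)
  sm <- smoothed_valid(traj, smooth_win_frames)
  # a running median suppresses noise without smearing the plateau edge
  # backwards in time the way a moving average would
  k <- max(3L, smooth_win_frames + (1L - smooth_win_frames %% 2L))
  y <- stats::runmed(bridge_na(traj$area)[sm$index], k, endrule = "median")
  tm <- traj$time_min[sm$index]
  telo <- median(traj$area[annotation$minima$index], na.rm = TRUE)
  in_plateau <- tm >= max(arrest[1], win$t_on_min) & tm <= win$t_off_min
  if (!any(in_plateau)) in_plateau <- tm >= arrest[1] & tm < arrest[2]
  level <- median(y[in_plateau])
  half <- band_frac * telo
  after <- which(tm > win$t_off_min)
  if (length(after) < 3) return(NA_real_)
  outside <- abs(y[after] - level) > half
  i <- first_run_of(outside, 3L)
  if (is.na(i)) return(NA_real_)
  dt <- frame_minutes(traj)
  (tm[after[i]] - dt / 2) - win$t_off_min
}

#' Classify recovery from arrest
#'
#' Successful recovery is the observation of gastrulation -- a ventral-furrow
#' event (the stage-5 terminal decline) -- after arrested development. The
#' failure phenotype (fused daughter nuclei followed by nuclear delamination)
#' is additionally flagged when the nucleus count fails to double after the
#' arrest or collapses.
#'
#' @param traj an `area_trajectory`.
#' @param annotation optional [annotate_cycles()] result.
#' @param arrest optional arrest interval (from [detect_arrest()]); when
#'   present, the furrow must occur after it.
#' @return list with `recovered` (logical), `count_collapse` (logical flag)
#'   and `vff_time_min`.
#' @export
classify_recovery <- function(traj, annotation = NULL, arrest = NULL) {
  if (is.null(annotation)) annotation <- annotate_cycles(traj)
  vff <- annotation$vff_time_min
  recovered <- !is.na(vff) &&
    (is.null(arrest) || vff > arrest[2])
  collapse <- FALSE
  if (!is.null(arrest) && !all(is.na(traj$count))) {
    pre <- traj$count[traj$time_min < arrest[1] & traj$count > 0]
    post <- traj$count[traj$time_min >= arrest[2]]
    if (length(pre) && length(post)) {
      lvl <- max(pre)
      doubled <- any(post >= 2 * lvl, na.rm = TRUE)
      collapsed <- any(post < 0.5 * lvl, na.rm = TRUE)
      collapse <- !doubled || collapsed
    }
  }
  list(recovered = recovered && !collapse, count_collapse = collapse,
       vff_time_min = vff)
}

#' Milestone times relative to stage-4 start
#'
#' Nuclear divisions 10-13 (the telophase minima ending NC10-NC13) and
#' ventral furrow formation, each reported relative to the start of stage 4
#' (ND9, the first peripheral interphase onset).
#'
#' @param annotation a [annotate_cycles()] result.
#' @return named numeric vector (`ND10`, `ND11`, `ND12`, `ND13`, `VFF`) in
#'   minutes; `NA` where undetected.
#' @export
milestone_times <- function(annotation) {
  nd <- annotation$telophase_times_min
  s4 <- annotation$stage4_start_min
  out <- c(nd[["ND10"]], nd[["ND11"]], nd[["ND12"]], nd[["ND13"]],
           annotation$vff_time_min) - s4
  names(out) <- c("ND10", "ND11", "ND12", "ND13", "VFF")
  out
}

#' Per-embryo perturbation record
#'
#' Runs arrest detection, recovery timing, recovery classification and
#' milestone extraction for one embryo.
#'
#' @param traj an `area_trajectory`.
#' @param win optional anoxia window ([anoxia_window()] or
#'   [anoxia_params()]); `NULL` for control embryos.
#' @param ... passed to [detect_arrest()].
#' @return a `perturbation_record` list: `embryo_id`, `arrest_interval`,
#'   `recovery_time_min`, `milestones`, `durations`, `recovered`,
#'   `count_collapse`.
#' @export
perturbation_record <- function(traj, win = NULL, ...) {
  annotation <- annotate_cycles(traj)
  arrest <- NULL
  rec_t <- NA_real_
  if (!is.null(win)) {
    win <- as_anoxia_window(win)
    arrest <- detect_arrest(traj, win, annotation = annotation, ...)
    if (!is.null(arrest))
      rec_t <- recovery_time(traj, win, arrest, annotation = annotation)
  }
  cls <- classify_recovery(traj, annotation, arrest)
  durs <- setNames(annotation$cycles$duration, annotation$cycles$cycle)
  structure(list(embryo_id = annotation$embryo_id,
                 arrest_interval = arrest,
                 recovery_time_min = rec_t,
                 milestones = milestone_times(annotation),
                 durations = durs,
                 recovered = cls$recovered,
                 count_collapse = cls$count_collapse),
            class = "perturbation_record")
}

#' Control-versus-treated group comparison
#'
#' Welch two-sample two-sided t-tests on every milestone time and cycle
#' duration, reported as treated minus control. No multiple-testing
#' correction is applied (raw per-metric p-values).
#'
#' @param control,treated lists of [perturbation_record()] objects (each
#'   group at least 2 embryos).
#' @return data frame with one row per metric: `metric`, `mean_control`,
#'   `mean_treated`, `difference`, `se_difference`, `t`, `p`, `n_control`,
#'   `n_treated`.
#' @export
compare_groups <- function(control, treated) {
  ek_assert(length(control) >= 2 && length(treated) >= 2,
            "each group needs at least 2 embryos")
  pull <- function(recs, field, name)
    vapply(recs, function(r) as.numeric(r[[field]][[name]]), numeric(1))
  metrics <- c(ND10 = "milestones", ND11 = "milestones", ND12 = "milestones",
               ND13 = "milestones", VFF = "milestones",
               NC10 = "durations", NC11 = "durations", NC12 = "durations",
               NC13 = "durations", stage5 = "durations")
  rows <- lapply(seq_along(metrics), function(i) {
    nm <- names(metrics)[i]
    x <- pull(treated, metrics[i], nm)
    y <- pull(control, metrics[i], nm)
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(metric = nm, mean_control = mean(y),
                        mean_treated = mean(x),
                        difference = mean(x) - mean(y),
                        se_difference = NA_real_, t = NA_real_, p = NA_real_,
                        n_control = length(y), n_treated = length(x)))
    if (sd(x) == 0 && sd(y) == 0) {
      # degenerate: no within-group variability
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      return(data.frame(metric = nm, mean_control = mean(y),
                        mean_treated = mean(x),
                        difference = mean(x) - mean(y), se_difference = 0,
                        t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                        n_control = length(y), n_treated = length(x)))
    }
    tt <- t.test(x, y, var.equal = FALSE)
    data.frame(metric = nm, mean_control = mean(y), mean_treated = mean(x),
               difference = mean(x) - mean(y),
               se_difference = tt$stderr, t = unname(tt$statistic),
               p = tt$p.value, n_control = length(y), n_treated = length(x))
  })
  do.call(rbind, rows)
}
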