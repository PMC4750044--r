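#' Detect telophase minima in an area trajectory
#'
#' Interior missing values are bridged by linear interpolation, the trace is
#' smoothed with a centred moving average, and local minima are kept when
#' their prominence (the smaller of the two rises separating them from deeper
#' minima or the trace ends) is at least `prominence_frac` of the smoothed
#' dynamic range. Times are reported on the original frame grid; for
#' equal-valued plateau minima the earliest frame wins.
#'
#' @param traj an `area_trajectory` (see [as_area_trajectory()]).
#' @param smooth_win_frames moving-average window (frames).
#' @param prominence_frac minimum prominence as a fraction of the smoothed
#'   global max minus min.
#' @return data frame with `index` (frame index) and `time_min`.
#' @export
detect_minima <- function(traj, smooth_win_frames = 3,
                          prominence_frac = 0.1) {
  ek_assert(nrow(traj) >= 3, "need at least 3 frames")
  ok <- which(!is.na(traj$area))
  ek_assert(length(ok) >= 3, "trace is all-missing (or nearly so)")
  sm <- smoothed_valid(traj, smooth_win_frames)
  idx <- local_minima(sm$y, prominence_frac * diff(range(sm$y)))
  # refine each smoothed minimum on the raw (bridged) trace within one
  # frame: the moving average blurs the sharp telophase floor
  raw <- bridge_na(traj$area)
  idx <- vapply(idx, function(i) {
    cand <- intersect(i + (-1L:1L), seq_along(sm$y))
    vals <- raw[sm$index[cand]]
    cand[which.min(vals)]                    # ties -> earliest frame
  }, integer(1))
  idx <- sort(unique(idx))
  data.frame(index = sm$index[idx], time_min = traj$time_min[sm$index[idx]])
}

# smooth the valid span (interior NAs bridged); returns y + original indices
smoothed_valid <- function(traj, win) {
  x <- bridge_na(traj$area)
  ok <- which(!is.na(x))
  span <- ok[1]:ok[length(ok)]
  list(y = moving_average(x[span], win), index = span)
}

# interior local minima with prominence >= prom; plateaus collapse to their
# earliest frame
local_minima <- function(y, prom) {
  n <- length(y)
  if (n < 3) return(integer(0))
  # candidate minima: first index of each non-increasing-to-increasing turn
  d <- diff(y)
  d[d == 0] <- NA                      # flats resolved by neighbours
  dir <- zoo_fill(sign(d))             # -1 falling, +1 rising
  cand <- which(dir[-1] > 0 & dir[-length(dir)] < 0) + 1L
  if (!length(cand)) return(integer(0))
  # collapse plateaus: keep earliest index with the same value run
  cand <- vapply(cand, function(i) {
    while (i > 1L && y[i - 1L] == y[i]) i <- i - 1L
    i
  }, integer(1))
  cand <- sort(unique(cand))
  keep <- vapply(cand, function(i) {
    left <- y[seq_len(i - 1L)]
    right <- y[(i + 1L):n]
    lower_l <- which(left < y[i])
    lower_r <- which(right < y[i])
    hi_l <- if (length(lower_l)) max(left[(max(lower_l) + 1L):(i - 1L)])
            else max(left)
    hi_r <- if (length(lower_r)) max(right[seq_len(min(lower_r) - 1L)])
            else max(right)
    min(hi_l - y[i], hi_r - y[i]) >= prom
  }, logical(1))
  cand[keep]
}

# forward/backward fill of NAs in a vector (helper for flat runs)
zoo_fill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(1, length(x)))
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  x[idx == 0L] <- x[which(ok)[1L]]
  idx[idx == 0L] <- which(ok)[1L]
  x[seq_along(x)] <- x[idx]
  x
}

#' Annotate nuclear cycles from detected minima
#'
#' Cycle labels are assigned by counting backward from the stage-5 plateau
#' (the terminal span after the last detected minimum): the four
#' inter-minimum intervals preceding it are NC13, NC12, NC11 and NC10 in
#' reverse. ND9 (the start of NC10) is usually not an interior minimum --
#' nuclei arrive at the periphery in telophase of division 9 -- so the first
#' valid frame is used as ND9 when its area sits at the telophase level;
#' otherwise NC10 is reported missing rather than measured from recording
#' start. Stage 5 ends at the onset of the terminal sustained decline (the
#' ventral-furrow proxy); if the recording stops first, stage 5 is missing.
#'
#' @param traj an `area_trajectory`.
#' @param minima optional output of [detect_minima()]; computed if `NULL`.
#' @param smooth_win_frames,prominence_frac passed to [detect_minima()].
#' @return a `cycle_annotation`: list with `telophase_times_min` (named
#'   `ND9`..`ND13`, `NA` where undetected), `cycles` (data frame `cycle`,
#'   `start`, `end`, `duration`), `nd12_time_min`, `vff_time_min`,
#'   `stage4_start_min` and `embryo_id`.
#' @export
annotate_cycles <- function(traj, minima = NULL, smooth_win_frames = 3,
                            prominence_frac = 0.1) {
  if (is.null(minima))
    minima <- detect_minima(traj, smooth_win_frames, prominence_frac)
  sm <- smoothed_valid(traj, smooth_win_frames)
  minima <- prune_non_divisions(traj, sm, minima)
  mt <- minima$time_min
  nd <- setNames(rep(NA_real_, 5), c("ND9", "ND10", "ND11", "ND12", "ND13"))
  k <- length(mt)
  # interior minima, counted backward from the terminal (stage-5) span
  for (j in seq_len(min(k, 4)))
    nd[[6 - j]] <- mt[k - j + 1]
  # telophase reference level from the detected minima
  telo_level <- if (k) median(traj$area[minima$index], na.rm = TRUE) else NA
  # ND9: nuclei appear at the periphery in telophase of division 9
  first_valid <- sm$index[1]
  if (!is.na(telo_level) && !is.na(traj$area[first_valid]) &&
      traj$area[first_valid] <= telo_level * 1.25 &&
      (!k || traj$time_min[first_valid] < mt[1]))
    nd[["ND9"]] <- traj$time_min[first_valid]

  vff <- if (!is.na(nd[["ND13"]]))
    detect_terminal_decline(traj, sm, from_time = nd[["ND13"]])
  else NA_real_

  cyc <- data.frame(
    cycle = c("NC10", "NC11", "NC12", "NC13", "stage5"),
    start = c(nd[["ND9"]], nd[["ND10"]], nd[["ND11"]], nd[["ND12"]],
              nd[["ND13"]]),
    end = c(nd[["ND10"]], nd[["ND11"]], nd[["ND12"]], nd[["ND13"]], vff))
  cyc$duration <- cyc$end - cyc$start
  structure(list(telophase_times_min = nd, cycles = cyc,
                 nd12_time_min = nd[["ND12"]], vff_time_min = vff,
                 stage4_start_min = nd[["ND9"]],
                 minima = minima,
                 embryo_id = attr(traj, "embryo_id")),
            class = "cycle_annotation")
}

# A telophase minimum is followed by chromatin re-expansion: the trace must
# rise by a fair fraction of its dynamic range within the next few minutes.
# Noise dips in the low post-furrow tail (or in collapsing signal) have no
# such rise and are not divisions.
prune_non_divisions <- function(traj, sm, minima, lookahead_min = 6,
                                rise_frac = 0.25) {
  if (!nrow(minima)) return(minima)
  raw <- bridge_na(traj$area)
  rng <- diff(range(sm$y))
  dt <- frame_minutes(traj)
  ahead <- max(2L, round(lookahead_min / dt))
  keep <- vapply(seq_len(nrow(minima)), function(i) {
    j <- minima$index[i]
    upto <- min(j + ahead, length(raw))
    if (upto - j < 2L) return(FALSE)          # truncated: cannot confirm
    vals <- raw[j:upto]
    max(vals, na.rm = TRUE) - raw[j] >= rise_frac * rng
  }, logical(1))
  minima[keep, , drop = FALSE]
}

# Stage-5 end / ventral-furrow proxy. After the interphase-14 rise, find the
# first sustained (>= 3 frames) excursion below the midpoint between the
# stage-5 plateau and the terminal level, then backtrack to where the
# smoothed trace first left the plateau band (3 x a robust noise scale):
# the decline onset. A collapse towards zero signal (nuclear delamination in
# non-recovering embryos) is not a furrow: the terminal level must remain a
# substantial fraction of the plateau.
detect_terminal_decline <- function(traj, sm, from_time) {
  sel <- which(traj$time_min[sm$index] > from_time)
  if (length(sel) < 6) return(NA_real_)
  y <- sm$y[sel]
  plateau <- quantile(y, 0.9, names = FALSE)
  up <- which(y >= 0.9 * plateau)[1]          # skip the stage-5 entry rise
  if (is.na(up) || length(y) - up < 5) return(NA_real_)
  sel <- sel[up:length(sel)]
  y <- y[up:length(y)]
  terminal <- min(y)
  if (plateau - terminal < 0.2 * plateau) return(NA_real_)  # no decline yet
  if (terminal < 0.15 * plateau) return(NA_real_)           # signal collapse
  # unbiased plateau level: median of the frames classified as plateau
  plateau <- median(y[y >= (plateau + terminal) / 2])
  mid <- (plateau + terminal) / 2
  i <- first_run_of(y < mid, 3L)
  if (is.na(i)) return(NA_real_)
  # backtrack on the raw trace: the moving average leaks the decline onset
  # into the preceding frames
  raw <- bridge_na(traj$area)[sm$index[sel]]
  noise <- stats::mad(diff(raw[seq_len(max(3, i - 3))])) / sqrt(2)
  band <- max(3 * noise, 1e-9)
  j <- i
  while (j > 1L && raw[j - 1L] < plateau - band) j <- j - 1L
  traj$time_min[sm$index[sel[j]]]
}

#' Align trajectories at nuclear division 12
#'
#' Shifts each embryo's time axis so that its ND12 minimum (the division
#' between NC12 and NC13) is at time zero; no resampling is performed (the
#' grids are uniform with a common interval).
#'
#' @param trajs list of `area_trajectory` objects.
#' @param annotations optional list of matching [annotate_cycles()] results;
#'   computed if `NULL`.
#' @return list of aligned trajectories (attribute `nd12_shift_min` records
#'   the applied shift).
#' @export
align_at_nd12 <- function(trajs, annotations = NULL) {
  if (inherits(trajs, "area_trajectory")) trajs <- list(trajs)
  if (is.null(annotations)) annotations <- lapply(trajs, annotate_cycles)
  mapply(function(tr, an) {
    nd12 <- an$nd12_time_min
    ek_assert(!is.na(nd12), "trajectory ",
              attr(tr, "embryo_id"), " lacks an annotated ND12 minimum")
    tr$time_min <- tr$time_min - nd12
    attr(tr, "nd12_shift_min") <- nd12
    tr
  }, trajs, annotations, SIMPLIFY = FALSE)
}

#' Cohort average of ND12-aligned trajectories
#'
#' Pointwise mean and standard error of the mean over the embryos
#' contributing at each aligned time, plus pooled per-cycle duration
#' statistics (each cycle pooled over the embryos in which it was annotated,
#' so `n` may differ between cycles).
#'
#' @param aligned list of aligned trajectories from [align_at_nd12()].
#' @param annotations optional list of [annotate_cycles()] results (on the
#'   unaligned trajectories) used for the duration table.
#' @param min_n drop aligned timepoints with fewer contributors than this.
#' @return a `cohort_summary`: `curve` (data frame `aligned_time_min`,
#'   `mean_area`, `sem_area`, `n`) and `durations` (data frame `cycle`,
#'   `mean`, `sd`, `sem`, `n`).
#' @export
cohort_average <- function(aligned, annotations = NULL, min_n = 2) {
  ek_assert(length(aligned) >= 2, "need at least 2 embryos")
  dt <- frame_minutes(aligned[[1]])
  grid <- sort(unique(round(unlist(lapply(aligned, `[[`, "time_min")) / dt)))
  acc_n <- acc_s <- acc_ss <- numeric(length(grid))
  for (tr in aligned) {
    key <- match(round(tr$time_min / dt), grid)
    ok <- !is.na(tr$area)
    acc_n[key[ok]] <- acc_n[key[ok]] + 1
    acc_s[key[ok]] <- acc_s[key[ok]] + tr$area[ok]
    acc_ss[key[ok]] <- acc_ss[key[ok]] + tr$area[ok]^2
  }
  keep <- acc_n >= min_n
  m <- acc_s[keep] / acc_n[keep]
  v <- pmax(0, (acc_ss[keep] - acc_n[keep] * m^2) / pmax(1, acc_n[keep] - 1))
  curve <- data.frame(aligned_time_min = grid[keep] * dt, mean_area = m,
                      sem_area = sqrt(v / acc_n[keep]), n = acc_n[keep])
  durations <- NULL
  if (!is.null(annotations)) {
    tab <- do.call(rbind, lapply(annotations, function(a) a$cycles))
    durations <- do.call(rbind, lapply(split(tab, tab$cycle), function(g) {
      d <- g$duration[!is.na(g$duration)]
      data.frame(cycle = g$cycle[1], mean = mean(d), sd = sd(d),
                 sem = sd(d) / sqrt(length(d)), n = length(d))
    }))
    durations <- durations[match(c("NC10", "NC11", "NC12", "NC13", "stage5"),
                                 durations$cycle), ]
    rownames(durations) <- NULL
  }
  structure(list(curve = curve, durations = durations,
                 n_embryos = length(aligned)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d embryos, %d aligned timepoints\n",
              x$n_embryos, nrow(x$curve)))
  if (!is.null(x$durations)) {
    cat("per-cycle durations (min):\n")
    print(transform(x$durations, mean = round(mean, 2), sd = round(sd, 2),
                    sem = round(sem, 3)), row.names = FALSE)
  }
  invisible(x)
}
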