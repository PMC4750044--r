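#' Read a multi-page TIFF stack
#'
#' Reads an 8- or 16-bit single-channel multi-page TIFF into an
#' [image_stack()]. Pixel values are kept as raw integer counts so that a
#' write/read round trip is bit-identical.
#'
#' @param path TIFF file.
#' @param pixel_size_um,frame_interval_s acquisition metadata (TIFF pages do
#'   not carry them portably); if a metadata sidecar written by
#'   [write_stack()] exists (`<path>.json`), it is used as the default.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  ek_assert(file.exists(path), "no such file: ", path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (is.null(frame_interval_s)) frame_interval_s <- meta$frame_interval_s
  }
  ek_assert(!is.null(pixel_size_um) && !is.null(frame_interval_s),
            "pixel_size_um and frame_interval_s are required (no metadata ",
            "sidecar found)")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L)
      ek_stop("frame ", i, " has ", dim(p)[3], " channels; ",
              "only single-channel stacks are supported",
              class = c("embryokin_channel_error", "embryokin_error"))
    storage.mode(p) <- "integer"
    p
  })
  image_stack(frames, pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s)
}

#' Write a stack as a 16-bit multi-page TIFF (plus metadata sidecar)
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; a `<path>.json` sidecar stores pixel size
#'   and frame interval.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  ek_assert(inherits(stack, "image_stack"), "stack must be an image_stack")
  pages <- lapply(stack$frames, function(f) {
    ek_assert(max(f) <= 65535 && min(f) >= 0, "16-bit range exceeded")
    round(f) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            frame_interval_s = stack$frame_interval_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an area-trajectory CSV
#'
#' Canonical trace format: columns `time_min`, `mean_nuclear_area`,
#' `nucleus_count` (UTF-8, `.` decimal, comma separator).
#'
#' @param traj an `area_trajectory`.
#' @param path CSV path.
#' @return `path` (write) or an `area_trajectory` (read).
#' @export
write_trace_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$time_min,
                   mean_nuclear_area = traj$area,
                   nucleus_count = traj$count)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param embryo_id identifier for the loaded trajectory.
#' @export
read_trace_csv <- function(path, embryo_id = basename(path)) {
  ek_assert(file.exists(path), "no such file: ", path)
  as_area_trajectory(read.csv(path), embryo_id = embryo_id)
}

#' Write a per-frame feature table CSV
#'
#' @param traj output of [segment_stack()] (carries the feature table).
#' @param path CSV path.
#' @export
write_features_csv <- function(traj, path) {
  feats <- attr(traj, "features")
  ek_assert(!is.null(feats), "trajectory carries no feature table")
  write.csv(feats, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cycle annotation as JSON
#'
#' @param annotation a [annotate_cycles()] result.
#' @param path JSON path.
#' @export
write_annotation_json <- function(annotation, path) {
  payload <- list(
    embryo_id = annotation$embryo_id,
    telophase_times_min = as.list(annotation$telophase_times_min),
    cycles = annotation$cycles,
    nd12_time_min = annotation$nd12_time_min,
    vff_time_min = annotation$vff_time_min,
    stage4_start_min = annotation$stage4_start_min)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  ek_assert(file.exists(path), "no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nd <- unlist(raw$telophase_times_min)
  nd <- setNames(as.numeric(nd), names(nd))
  cyc <- as.data.frame(raw$cycles)
  for (cl in c("start", "end", "duration"))
    cyc[[cl]] <- as.numeric(cyc[[cl]])
  structure(list(telophase_times_min = nd, cycles = cyc,
                 nd12_time_min = null_na(raw$nd12_time_min),
                 vff_time_min = null_na(raw$vff_time_min),
                 stage4_start_min = null_na(raw$stage4_start_min),
                 minima = NULL, embryo_id = raw$embryo_id),
            class = "cycle_annotation")
}

null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Write a perturbation report (JSON + CSV)
#'
#' Serialises per-embryo [perturbation_record()]s and the
#' [compare_groups()] table. The CSV holds the milestone layout (one row per
#' embryo: ND10-ND13, VFF, recovery).
#'
#' @param records list of `perturbation_record`s.
#' @param comparisons optional [compare_groups()] data frame.
#' @param path output path without extension (writes `<path>.json` and
#'   `<path>.csv`).
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(records, comparisons = NULL, path) {
  rows <- lapply(records, function(r) {
    data.frame(embryo_id = r$embryo_id,
               ND10 = r$milestones[["ND10"]], ND11 = r$milestones[["ND11"]],
               ND12 = r$milestones[["ND12"]], ND13 = r$milestones[["ND13"]],
               VFF = r$milestones[["VFF"]],
               arrest_start = if (is.null(r$arrest_interval)) NA_real_
                              else r$arrest_interval[1],
               arrest_end = if (is.null(r$arrest_interval)) NA_real_
                            else r$arrest_interval[2],
               recovery_time_min = r$recovery_time_min,
               recovered = r$recovered,
               count_collapse = r$count_collapse)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(embryo_id = character(0))
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  jsonlite::write_json(list(embryos = tab, comparisons = comparisons),
                       json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  json_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  ek_assert(file.exists(json_path), "no such file: ", json_path)
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
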