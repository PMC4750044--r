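#' Run configuration
#'
#' A single seeded configuration drives the whole pipeline; every run writes
#' its fully resolved configuration next to its outputs (reproducibility
#' contract).
#'
#' @param seed master seed; all randomness in the run derives from it.
#' @param out_dir output directory.
#' @param n_control,n_treated synthetic cohort sizes.
#' @param mode `"trace"` simulates area trajectories directly; `"stack"`
#'   renders image stacks and segments them (slower).
#' @param cycle named list of [cycle_params()] overrides.
#' @param anoxia named list of [anoxia_params()] overrides (`NULL` disables
#'   the treated arm). The window defaults to [default_anoxia_window()].
#' @param segment named list of [segment_stack()] arguments.
#' @param kinetics named list: `smooth_win_frames`, `prominence_frac`,
#'   `min_n`.
#' @param oxygen `NULL`, or a named list of [oxygen_config()] overrides to
#'   also run the oxygen model.
#' @return a `run_config` object.
#' @export
run_config <- function(seed = 1, out_dir = "embryokin_run",
                       n_control = 20, n_treated = 0,
                       mode = c("trace", "stack"),
                       cycle = list(), anoxia = list(),
                       segment = list(), kinetics = list(),
                       oxygen = NULL) {
  mode <- match.arg(mode)
  structure(list(seed = seed, out_dir = out_dir, n_control = n_control,
                 n_treated = n_treated, mode = mode, cycle = cycle,
                 anoxia = anoxia, segment = segment, kinetics = kinetics,
                 oxygen = oxygen,
                 version = as.character(utils::packageVersion("embryokin"))),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of the [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ek_assert(file.exists(path), "no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config()
  known <- setdiff(names(base), "version")
  bad <- setdiff(names(raw), known)
  ek_assert(!length(bad), "unknown config fields: ",
            paste(bad, collapse = ", "))
  for (nm in intersect(names(raw), known)) base[[nm]] <- raw[[nm]]
  base$mode <- match.arg(base$mode, c("trace", "stack"))
  base
}

#' Run the end-to-end pipeline
#'
#' Stages: simulate (or segment) -> per-embryo kinetics -> ND12-aligned
#' cohort -> perturbation report (when a treated arm is configured) ->
#' optional oxygen model. Each stage logs its outputs; a completed stage is
#' skipped on re-run when `resume = TRUE` and its outputs exist. All outputs
#' are deterministic functions of the configuration (byte-identical CSVs on
#' re-run with the same seed).
#'
#' @param cfg a [run_config()] or path to its JSON form.
#' @param resume skip stages whose outputs already exist.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of output paths per stage.
#' @export
run_pipeline <- function(cfg = run_config(), resume = FALSE, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  ek_assert(inherits(cfg, "run_config"), "cfg must be a run_config")
  say <- function(...) if (!quiet) message("[embryokin] ", ...)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  paths <- list(config = file.path(out, "config.json"))

  cp <- do.call(cycle_params, cfg$cycle)
  ap <- NULL
  if (cfg$n_treated > 0)
    ap <- do.call(default_anoxia_window, c(list(cp = cp), cfg$anoxia))

  # --- stage: simulate / ingest -------------------------------------------
  trace_dir <- file.path(out, "traces")
  stamp <- file.path(trace_dir, "DONE")
  groups <- list(control = cfg$n_control,
                 treated = if (cfg$n_treated > 0) cfg$n_treated else NULL)
  if (resume && file.exists(stamp)) {
    say("simulate: outputs exist, skipping")
    trajs <- lapply(list.files(trace_dir, pattern = "\\.csv$",
                               full.names = TRUE), read_trace_csv)
    names(trajs) <- vapply(trajs, attr, "", "embryo_id")
  } else {
    dir.create(trace_dir, showWarnings = FALSE)
    trajs <- list()
    for (grp in names(groups)) {
      if (is.null(groups[[grp]])) next
      this_ap <- if (grp == "treated") ap else NULL
      seed <- cfg$seed + (if (grp == "treated") 500000L else 0L)
      say(sprintf("simulate: %d %s embryos (mode=%s)", groups[[grp]], grp,
                  cfg$mode))
      n <- groups[[grp]]
      seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
      for (i in seq_len(n)) {
        id <- sprintf("%s_%02d", grp, i)
        if (cfg$mode == "stack") {
          gs <- generate_stack(cp, this_ap, seed = seeds[i], embryo_id = id)
          tr <- do.call(segment_stack, c(list(gs$stack), cfg$segment))
          attr(tr, "embryo_id") <- id
        } else {
          tr <- generate_trace(cp, this_ap, seed = seeds[i],
                               embryo_id = id)$trace
        }
        write_trace_csv(tr, file.path(trace_dir, paste0(id, ".csv")))
        trajs[[id]] <- tr
      }
    }
    file.create(stamp)
  }
  paths$traces <- trace_dir

  # --- stage: kinetics -----------------------------------------------------
  kin <- cfg$kinetics
  ann_dir <- file.path(out, "cycles")
  dir.create(ann_dir, showWarnings = FALSE)
  say(sprintf("kinetics: annotating %d trajectories", length(trajs)))
  anns <- lapply(trajs, function(tr)
    annotate_cycles(tr,
                    smooth_win_frames = kin$smooth_win_frames %||% 3,
                    prominence_frac = kin$prominence_frac %||% 0.1))
  for (an in anns)
    write_annotation_json(an, file.path(ann_dir,
                                        paste0(an$embryo_id, ".json")))
  paths$cycles <- ann_dir

  # --- stage: cohort -------------------------------------------------------
  is_ctrl <- grepl("^control", names(trajs))
  say("cohort: ND12 alignment and averaging")
  aligned <- align_at_nd12(trajs[is_ctrl], anns[is_ctrl])
  cs <- cohort_average(aligned, anns[is_ctrl],
                       min_n = kin$min_n %||% 2)
  write.csv(cs$curve, file.path(out, "cohort_curve.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cs$durations, file.path(out, "cohort_durations.csv"),
            row.names = FALSE, quote = FALSE)
  paths$cohort <- file.path(out, "cohort_curve.csv")

  # --- stage: perturb ------------------------------------------------------
  if (cfg$n_treated > 0) {
    say("perturb: arrest/recovery analysis and group comparison")
    rc <- lapply(trajs[is_ctrl], perturbation_record)
    rt <- lapply(trajs[!is_ctrl], perturbation_record, win = ap)
    cmp <- compare_groups(rc, rt)
    paths$report <- write_report(c(rc, rt), cmp, file.path(out, "report"))
  }

  # --- stage: oxygen -------------------------------------------------------
  if (!is.null(cfg$oxygen)) {
    say("oxygen: transient convection-diffusion model")
    ocfg <- do.call(oxygen_config, cfg$oxygen)
    field <- simulate_oxygen(ocfg)
    prof <- do.call(rbind, lapply(field$times_s, function(t)
      cbind(t_s = t, channel_profile(field, t))))
    write.csv(prof, file.path(out, "oxygen_profiles.csv"),
              row.names = FALSE, quote = FALSE)
    paths$oxygen <- file.path(out, "oxygen_profiles.csv")
  }
  say("done")
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
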