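# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noiseless, jitter-free nominal parameters (fast deterministic checks)
cp_clean <- function(...) {
  cycle_params(noise_sd = 0, per_embryo_jitter_sd = 0, ...)
}

# deterministic perturbation (no lag jitter, no failures, no overhead)
ap_clean <- function(cp = cp_clean(), ...) {
  default_anoxia_window(cp, recovery_lag_sd_min = 0, fail_prob = 0,
                        stage5_delay_mean_min = 0, stage5_delay_sd_min = 0,
                        ...)
}

# control cohort at the study conditions (35 embryos, default noise/jitter)
control_cohort <- function() fixture("control_cohort", function() {
  generate_cohort(35, cycle_params(), seed = 1, prefix = "control")
})

control_annotations <- function() fixture("control_annotations", function() {
  lapply(control_cohort(), function(g) annotate_cycles(g$trace))
})

# treated cohort: 10-min anoxia during NC13 (14 embryos, defaults)
treated_cohort <- function() fixture("treated_cohort", function() {
  generate_cohort(14, cycle_params(), default_anoxia_window(), seed = 2,
                  prefix = "treated")
})

# small noiseless stack shared by segmentation tests
clean_stack <- function() fixture("clean_stack", function() {
  generate_stack(cp_clean(), geometry = stack_geometry(noise = FALSE),
                 seed = 1)
})

# frame index of a trace at a given time
frame_at <- function(traj, t) which(abs(traj$time_min - t) < 1e-9)[1]
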