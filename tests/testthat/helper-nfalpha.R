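# Shared fixtures, all generated in code.

# one-run schedule used where the full 10-run design is unnecessary
short_schedule <- function(n_runs = 1) {
  build_schedule(n_runs = n_runs)
}

# minimal two-ROI effect table
tiny_roi <- function() {
  data.frame(roi = c("A", "B"), psc_up_view = c(1, 0.86),
             psc_up_rest = c(1.2, 0.70), stringsAsFactors = FALSE)
}

# fully null cohort spec at reduced size (no planted effects anywhere)
null_cohort_spec <- function(n_exp = 4, n_ctl = 4, n_runs = 2, n_rois = 6,
                             master_seed = 1) {
  roi <- data.frame(roi = paste0("r", seq_len(n_rois)), psc_up_view = 0,
                    psc_up_rest = 0, stringsAsFactors = FALSE)
  cohort_spec(schedule = build_schedule(n_runs = n_runs),
              n_experimental = n_exp, n_control = n_ctl,
              eeg = eeg_sim_params(asym_effect = 0),
              roi = roi, delta_edges = NULL, master_seed = master_seed)
}

# synthetic run-block asymmetry table with the published design counts
make_asym_table <- function(n_exp = 18, n_ctl = 14, n_runs = 10, seed = 1,
                            up_shift_exp = 0) {
  set.seed(seed)
  grid <- expand.grid(run = seq_len(n_runs),
                      block = c("Rest", "View", "Upregulation"),
                      stringsAsFactors = FALSE)
  mk <- function(ids, group, shift) do.call(rbind, lapply(ids, function(id) {
    g <- grid
    g$subject <- id
    g$group <- group
    g$mean_asym <- stats::rnorm(nrow(g), 0, 0.3) +
      ifelse(g$block == "Upregulation", shift, 0)
    g
  }))
  rbind(mk(sprintf("e%02d", seq_len(n_exp)), "experimental", up_shift_exp),
        mk(sprintf("c%02d", seq_len(n_ctl)), "control", 0))
}

# constant-amplitude recording whose F4 is a pointwise multiple of F3
ratio_recording <- function(schedule, ratio = 2, seed = 1) {
  set.seed(seed)
  n <- floor(schedule$total_duration * schedule$eeg_rate)
  base <- 3 * sin(2 * pi * 10 * (seq_len(n) - 1) / schedule$eeg_rate) +
    stats::rnorm(n, sd = 0.5)
  rec <- simulate_eeg(schedule, eeg_sim_params(asym_effect = 0), "control",
                      seed = seed)
  rec$data[, "F3"] <- base
  rec$data[, "F4"] <- ratio * base
  rec
}
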