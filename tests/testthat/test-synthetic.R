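test_that("EEG generator is deterministic and band-checked", {
  s <- short_schedule()
  r1 <- simulate_eeg(s, eeg_sim_params(), "experimental", seed = 4)
  r2 <- simulate_eeg(s, eeg_sim_params(), "experimental", seed = 4)
  expect_identical(r1$data, r2$data)
  expect_error(simulate_eeg(s, eeg_sim_params(alpha_band = c(8, 200))),
               "Nyquist")
})

test_that("null profile has no asymmetry; planted effect is recovered", {
  s <- short_schedule()
  per_seed <- function(seed, effect, profile) {
    rec <- simulate_eeg(s, eeg_sim_params(asym_effect = effect), profile, seed)
    aw <- asymmetry_series(rec, s)
    m <- tapply(aw$asym, aw$block, mean)
    m[["Upregulation"]] - m[["View"]]
  }
  nulls <- vapply(1:25, per_seed, 0, effect = 0, profile = "experimental")
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(length(nulls)))

  eff <- vapply(1:25, per_seed, 0, effect = 0.3, profile = "experimental")
  expect_lt(abs(mean(eff) - 0.3), 0.05)

  ctl <- vapply(1:25, per_seed, 0, effect = 0.3, profile = "control")
  expect_lt(abs(mean(ctl)), 3 * sd(ctl) / sqrt(length(ctl)))
})

test_that("ECG carries recoverable R peaks", {
  s <- short_schedule()
  rec <- simulate_eeg(s, eeg_sim_params(), "experimental", seed = 12)
  got <- detect_r_peaks(rec$data[, "ECG"], s$eeg_rate)
  truth <- rec$planted$r_peaks
  hits <- vapply(truth, function(p) any(abs(got - p) <= 0.02), TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("gradient artifact is exactly invertible by its stored template", {
  s <- short_schedule()
  clean <- simulate_eeg(s, eeg_sim_params(), "experimental", seed = 3)
  dirty <- add_gradient_artifact(clean, period_s = 2, amplitude = 50, seed = 2)
  tpl <- dirty$planted$gradient_template
  n <- nrow(dirty$data)
  art <- rep(tpl, ceiling(n / length(tpl)))[seq_len(n)]
  expect_equal(dirty$data[, "F4"] - art, clean$data[, "F4"], tolerance = 1e-12)
  expect_equal(dirty$data[, "ECG"], clean$data[, "ECG"])
})

test_that("ROI BOLD plants exact PSC and the Upregulation correlation shift", {
  s <- build_schedule()
  x0 <- simulate_roi_bold(s, tiny_roi(), noise_sd = 0, seed = 1)
  expect_equal(nrow(x0), 650)
  psc <- roi_percent_signal_change(x0, s)
  expect_equal(psc$psc_up_view, c(1, 0.86), tolerance = 1e-8)
  expect_equal(psc$psc_up_rest, c(1.2, 0.70), tolerance = 1e-8)

  expect_identical(simulate_roi_bold(s, tiny_roi(), seed = 5),
                   simulate_roi_bold(s, tiny_roi(), seed = 5))

  de <- data.frame(roi_i = "A", roi_j = "B", delta_r = 0.3)
  hit <- vapply(1:200, function(sd) {
    x <- simulate_roi_bold(s, tiny_roi(), delta_edges = de, base_corr = 0.2,
                           seed = sd)
    bc <- blockwise_correlations(x, s)
    mean(bc$r[bc$block == "Upregulation"]) > mean(bc$r[bc$block == "View"])
  }, TRUE)
  expect_gte(mean(hit), 0.95)

  expect_error(simulate_roi_bold(s, tiny_roi(),
                                 delta_edges = data.frame(roi_i = "A",
                                                          roi_j = "Z",
                                                          delta_r = 0.1)),
               "unknown ROI")
})

test_that("voxel volumes carry signal exactly in the planted cluster", {
  s <- build_schedule(n_runs = 2)
  vox <- cluster_cube(c(8, 8, 4))
  vol <- simulate_voxel_bold(c(16, 16, 8), list(list(voxels = vox, psc = 2)),
                             s, noise_sd = 0, seed = 1)
  X <- nfalpha:::hrf_regressors(s)
  D <- build_design(s)
  tm <- nfalpha:::voxel_tmap(vol, D, nfalpha:::contrast_weights(D, "Up>Rest"))
  active <- attr(vol, "planted")$active
  expect_true(all(tm$t[active] > 0))           # infinite t on noiseless signal
  expect_true(all(tm$t[!active] == 0))

  expect_error(simulate_voxel_bold(c(8, 8, 4),
                                   list(list(voxels = cluster_cube(c(8, 8, 4)),
                                             psc = 1)), s),
               "outside grid")
  expect_identical(simulate_voxel_bold(c(6, 6, 4), list(), s, seed = 2),
                   simulate_voxel_bold(c(6, 6, 4), list(), s, seed = 2))
})

test_that("cohorts are deterministic and write a readable dataset", {
  spec <- null_cohort_spec(n_exp = 1, n_ctl = 1, n_runs = 1, master_seed = 3)
  t0 <- Sys.time()
  c1 <- simulate_cohort(spec)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$psych, c2$psych)
  expect_identical(cohort_roi(c1, "sub01"), cohort_roi(c2, "sub01"))
  expect_identical(cohort_eeg(c1, "sub02")$data, cohort_eeg(c2, "sub02")$data)

  dir <- withr::local_tempdir()
  write_cohort(c1, dir, write_eeg = TRUE)
  expect_true(all(file.exists(file.path(dir,
    c("events.tsv", "psych.tsv", "subjects.tsv", "manifest.json",
      "roi_sub01.tsv", "eeg_sub01.tsv")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$master_seed, 3)
  roi_back <- as.matrix(read.delim(file.path(dir, "roi_sub01.tsv")))
  expect_equal(dim(roi_back), dim(cohort_roi(c1, "sub01")))

  full <- simulate_cohort(cohort_spec(master_seed = 1))
  expect_equal(table(full$subjects$group)[["experimental"]], 18)
  expect_equal(table(full$subjects$group)[["control"]], 14)
})
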