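test_that("window band power obeys the Parseval and scaling oracles", {
  rate <- 250
  t <- (0:(2 * rate - 1)) / rate
  x10 <- sin(2 * pi * 10 * t)
  expect_equal(window_band_power(x10, rate, c(8, 12)), 0.5, tolerance = 0.05)
  expect_lt(window_band_power(sin(2 * pi * 20 * t), rate, c(8, 12)), 1e-10)
  expect_equal(window_band_power(2 * x10, rate, c(8, 12)),
               4 * window_band_power(x10, rate, c(8, 12)), tolerance = 1e-12)
  expect_error(window_band_power(x10, rate, c(8, 200)), "invalid parameter")
})

test_that("asymmetry is log power ratio with exact window counts", {
  s <- short_schedule()
  rec <- ratio_recording(s, ratio = 2)
  aw <- asymmetry_series(rec, s)
  expect_true(all(abs(aw$asym - log(4)) < 1e-9))   # power ratio 4
  cnt <- table(aw$block)
  expect_equal(unname(cnt[c("Rest", "View", "Upregulation")]),
               c(19L, 39L, 59L), ignore_attr = TRUE)

  rec$data[, "F4"] <- rec$data[, "F3"]
  aw0 <- asymmetry_series(rec, s)
  expect_true(all(abs(aw0$asym) < 1e-12))

  rec$channels <- c("F3", "Fz", "ECG")
  colnames(rec$data) <- rec$channels
  expect_error(asymmetry_series(rec, s), "channel not found")
})

test_that("asymmetry and bars are invariant to common channel scaling", {
  s <- short_schedule()
  rec <- simulate_eeg(s, eeg_sim_params(), "experimental", seed = 2)
  tr1 <- run_closed_loop(rec, s, "real")
  rec$data[, c("F3", "F4")] <- 7.3 * rec$data[, c("F3", "F4")]
  tr2 <- run_closed_loop(rec, s, "real")
  expect_equal(tr1$bar, tr2$bar, tolerance = 1e-10)
  expect_equal(tr1$color, tr2$color)
})

test_that("view baseline is the mean of View-window asymmetries", {
  aw <- data.frame(block = c("View", "View"), asym = c(0.1, 0.3))
  expect_equal(view_baseline(aw), 0.2)
  expect_equal(view_baseline(data.frame(block = "View", asym = rep(0.7, 5))), 0.7)
  expect_error(view_baseline(data.frame(block = "Rest", asym = 1)),
               "baseline unavailable")
  s <- short_schedule()
  aw <- asymmetry_series(simulate_eeg(s, seed = 3), s)
  expect_equal(sum(aw$block == "View"), 39)
})

test_that("bar smoothing and colour rule follow the display definition", {
  run_seq <- function(rels) {
    st <- nfalpha:::new_feedback_state(baseline = 0)
    out <- lapply(rels, function(x) {
      fb <- feedback_bar(st, x)
      st <<- fb$state
      fb[c("bar", "color")]
    })
    list(bar = vapply(out, `[[`, 0, "bar"),
         color = vapply(out, `[[`, "", "color"))
  }
  inc <- run_seq(1:5)
  expect_equal(inc$bar, c(1, 1.5, 2, 3, 4))      # running 3-mean
  expect_true(all(inc$color == "blue"))
  dec <- run_seq(c(1, 0, -1))
  expect_equal(dec$bar, c(1, 0.5, 0))
  expect_equal(dec$color, c("blue", "red", "red"))
  flat <- run_seq(rep(0, 4))                     # asym == baseline
  expect_true(all(flat$bar == 0) && all(flat$color == "blue"))
})

test_that("sham feedback is deterministic, bounded, and EEG-independent", {
  s <- build_schedule()
  tr1 <- sham_feedback(s, seed = 9)
  expect_identical(as.data.frame(tr1), as.data.frame(sham_feedback(s, seed = 9)))
  expect_true(all(abs(tr1$bar) <= 2))
  expect_equal(nrow(tr1), 59 * 10)

  rec <- simulate_eeg(s, eeg_sim_params(), "experimental", seed = 1)
  real <- run_closed_loop(rec, s, "real")
  cors <- vapply(1:50, function(sd)
    abs(cor(sham_feedback(s, seed = sd)$bar, real$raw_asym)), 0)
  expect_gte(mean(cors < 0.2), 0.95)
})

test_that("closed loop is causal and recovers the planted effect", {
  s <- short_schedule()
  rec <- simulate_eeg(s, eeg_sim_params(asym_effect = 0.4), "experimental",
                      seed = 6)
  tr <- run_closed_loop(rec, s, "real")
  expect_equal(nrow(tr), 59)
  expect_gt(mean(tr$bar), 0)

  # corrupting samples after t leaves all updates at time <= t unchanged
  t_cut <- 90
  rec2 <- rec
  ix <- (floor(t_cut * s$eeg_rate) + 1):nrow(rec2$data)
  rec2$data[ix, c("F3", "F4")] <- 100 * matrix(rnorm(2 * length(ix)), ncol = 2)
  tr2 <- run_closed_loop(rec2, s, "real")
  keep <- tr$time <= t_cut
  expect_equal(tr$bar[keep], tr2$bar[keep], tolerance = 1e-10)
})

test_that("template subtraction removes the planted periodic artifact", {
  s <- short_schedule()
  clean <- simulate_eeg(s, eeg_sim_params(), "experimental", seed = 10)
  dirty <- add_gradient_artifact(clean, period_s = 2, amplitude = 100, seed = 1)
  art_pow <- mean((dirty$data[, "F3"] - clean$data[, "F3"])^2)
  expect_gt(art_pow, 100 * var(clean$data[, "F3"]))   # artifact dominates

  fixed <- template_subtract(dirty, period_s = 2, n_average = 10)
  resid <- fixed$data[, "F3"] - clean$data[, "F3"]
  skip_warmup <- (20 * s$eeg_rate):nrow(fixed$data)   # past first 10 epochs
  expect_lt(mean(resid[skip_warmup]^2), 0.01 * art_pow)

  expect_identical(add_gradient_artifact(clean, amplitude = 0), clean)

  # alpha-band content preserved with a long template average (power bias
  # is 1/n_average; measured over a 100-s post-warm-up stretch)
  s2 <- short_schedule(n_runs = 2)
  clean2 <- simulate_eeg(s2, eeg_sim_params(), "experimental", seed = 11)
  dirty2 <- add_gradient_artifact(clean2, period_s = 2, amplitude = 100,
                                  seed = 1)
  fixed40 <- template_subtract(dirty2, period_s = 2, n_average = 40)
  bp <- function(r) {
    seg <- r$data[(120 * 250 + 1):(220 * 250), "F3"]
    window_band_power(seg, 250, c(8, 12))
  }
  expect_equal(bp(fixed40), bp(clean2), tolerance = 0.05)

  expect_warning(template_subtract(clean, period_s = 200, n_average = 10),
                 "passthrough")
})

test_that("feedback traces round-trip through TSV", {
  s <- short_schedule()
  tr <- sham_feedback(s, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feedback_trace(tr, tmp)
  back <- read_feedback_trace(tmp)
  expect_equal(back$bar, tr$bar, tolerance = 1e-12)
  expect_equal(back$color, tr$color)
})
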