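test_that("HRF and design matrix follow the block design", {
  expect_equal(hrf(0), 0)
  expect_gt(hrf(6), hrf(2))
  expect_lt(hrf(16), 0)                      # undershoot
  expect_equal(max(hrf(seq(0, 30, 0.01))), 1, tolerance = 1e-3)

  s <- build_schedule()
  D0 <- build_design(s)                      # all-zero motion dropped
  expect_equal(nrow(D0), 650)
  expect_equal(ncol(D0), 4)
  set.seed(1)
  D <- build_design(s, matrix(rnorm(650 * 6), 650, 6))
  expect_equal(ncol(D), 10)                  # 3 task + 6 motion + intercept
  expect_error(build_design(s, matrix(0, 10, 6)), "n_volumes x 6")
})

test_that("OLS matches the normal-equations oracle to 1e-10", {
  set.seed(2)
  for (i in 1:5) {
    n <- 20; p <- 4
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", 1:p)
    y <- rnorm(n)
    fit <- fit_glm(y, X)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
    expect_lt(max(abs(fit$beta - beta_oracle)), 1e-10)
    w <- rnorm(p)
    ct <- contrast_t(fit, w)
    res <- y - X %*% beta_oracle
    s2 <- sum(res^2) / (n - p)
    t_oracle <- (t(w) %*% beta_oracle) /
      sqrt(s2 * t(w) %*% solve(t(X) %*% X) %*% w)
    expect_equal(ct$t, drop(t_oracle), tolerance = 1e-10)
    expect_equal(ct$df, n - p)
  }
})

test_that("noiseless recovery is exact and zero-variance is flagged", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(60), 20, 3))
  colnames(X) <- paste0("c", 1:4)
  beta <- c(2, -1, 0.5, 3)
  y <- drop(X %*% beta)
  fit <- fit_glm(y, X)
  expect_lt(max(abs(fit$beta - beta)), 1e-10)
  ct <- contrast_t(fit, c(0, 1, 0, 0))
  expect_true(is.infinite(ct$t) && ct$t < 0)

  Xr <- cbind(X, X[, 2] + X[, 3])
  colnames(Xr)[5] <- "dup"
  expect_error(fit_glm(y, Xr), "collinear.*dup")
})

test_that("pure-noise t statistics hit the nominal voxel threshold rate", {
  s <- build_schedule(n_runs = 2)
  X <- build_design(s)
  set.seed(4)
  y <- matrix(rnorm(nrow(X) * 5000), nrow(X))
  ct <- contrast_t(fit_glm(y, X), nfalpha:::contrast_weights(X, "Up>View"))
  frac <- mean(ct$t > qt(0.99, ct$df))
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.016)
})

test_that("high-pass projection removes drift, is idempotent", {
  s_tr <- 2
  n <- 650
  t <- (0:(n - 1)) * s_tr
  x <- 5 + sin(2 * pi * 0.002 * t) + rnorm(n, sd = 0.1)
  hp <- highpass_dct(x, s_tr, 0.005)
  expect_equal(mean(hp), 0, tolerance = 1e-10)           # DC exactly removed
  expect_equal(highpass_dct(hp, s_tr, 0.005), hp, tolerance = 1e-10)

  slow <- sin(2 * pi * 0.002 * t)
  hp_slow <- highpass_dct(slow, s_tr, 0.005)
  expect_lt(sqrt(mean(hp_slow^2)) / sqrt(mean(slow^2)), 0.1)  # >= 90% gone

  fast <- sin(2 * pi * 0.05 * t)
  expect_equal(sd(highpass_dct(fast, s_tr, 0.005)), sd(fast), tolerance = 0.01)
  expect_error(highpass_dct(x, s_tr, cutoff_hz = 0.5), "Nyquist")
})

test_that("Gaussian smoothing preserves intensity and realizes its FWHM", {
  vol <- array(0, c(21, 21, 11))
  vol[11, 11, 6] <- 1
  fw <- 2.5
  sm <- smooth_gaussian(vol, fw)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  prof <- sm[, 11, 6]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear-interpolated width across the half-maximum crossings
  lo <- min(above); hi <- max(above)
  f <- function(i1, i2) (prof[i1] - half) / (prof[i1] - prof[i2])
  width <- (hi + f(hi, hi + 1)) - (lo - f(lo, lo - 1))
  expect_equal(width, fw, tolerance = 0.05)

  set.seed(5)
  v4 <- array(rnorm(10 * 10 * 6 * 3), c(10, 10, 6, 3))
  s4 <- smooth_gaussian(v4, 2)
  expect_equal(dim(s4), dim(v4))
  expect_equal(sum(s4), sum(v4), tolerance = 1e-6)
})

test_that("cluster correction finds the planted cluster and rejects noise", {
  s <- build_schedule(n_runs = 2)
  grid <- c(12, 12, 6)
  vol <- simulate_voxel_bold(grid,
                             list(list(voxels = cluster_cube(c(6, 6, 3)),
                                       psc = 2)),
                             s, noise_sd = 1, seed = 6)
  cc <- cluster_correct(vol, s, "Up>Rest", n_perm = 100, seed = 1)
  expect_true(any(cc$clusters$survives))
  surv <- which(cc$cluster_map > 0)
  planted <- which(attr(vol, "planted")$active)
  expect_gte(length(intersect(surv, planted)) / length(planted), 0.8)

  expect_error(cluster_correct(vol, s, "Up>Rest", n_perm = 10), ">= 100")
})

test_that("percent signal change obeys the arithmetic and the trim rule", {
  s <- build_schedule()
  labs <- block_labels(s, 1 / s$tr)
  x <- rep(1, 650)
  x[labs == "Upregulation"] <- 1.01
  # first two Upregulation volumes are trimmed, so corrupting them is inert
  psc0 <- roi_percent_signal_change(matrix(x, ncol = 1), s)
  expect_equal(psc0$psc_up_view, 1, tolerance = 1e-9)

  x2 <- x
  up_starts <- which(labs == "Upregulation" & c("", labs[-650]) != "Upregulation")
  for (u in up_starts) x2[u + 0:1] <- 1000
  psc2 <- roi_percent_signal_change(matrix(x2, ncol = 1), s)
  expect_equal(psc2$psc_up_view, psc0$psc_up_view, tolerance = 1e-12)

  flat <- roi_percent_signal_change(matrix(0, 650, 1), s)
  expect_false(flat$defined)
})

test_that("roi_mean_series averages activated voxels per ROI", {
  s <- build_schedule(n_runs = 1)
  vol <- array(1, c(4, 4, 2, s$n_volumes))
  vol[1, 1, 1, ] <- 5
  rois <- array(0L, c(4, 4, 2))
  rois[1:2, 1, 1] <- 1L
  rois[3:4, 1, 1] <- 2L
  act <- array(FALSE, c(4, 4, 2))
  act[1, 1, 1] <- TRUE
  rm <- roi_mean_series(vol, rois, act)
  expect_equal(unique(rm$series[, "roi1"]), 5)     # only the active voxel
  expect_true(all(is.na(rm$series[, "roi2"])))     # no active voxel in ROI 2
  expect_equal(rm$n_voxels, c(1L, 0L))
})

test_that("group ROI effect sizes flag planted regions under FDR", {
  set.seed(7)
  rois <- paste0("r", 1:10)
  mk <- function(ids, group, eff) do.call(rbind, lapply(ids, function(id)
    data.frame(roi = rois, subject = id, group = group,
               psc_up_view = rnorm(10, eff), stringsAsFactors = FALSE)))
  eff_vec <- c(rep(1, 3), rep(0, 7))               # 3 active ROIs
  psc <- rbind(
    do.call(rbind, lapply(sprintf("e%d", 1:12), function(id)
      data.frame(roi = rois, subject = id, group = "experimental",
                 psc_up_view = rnorm(10, eff_vec)))),
    mk(sprintf("c%d", 1:10), "control", 0))
  res <- roi_effect_sizes(psc)
  expect_true(all(res$sig_within[1:3][res$roi[1:3] %in% c("r1", "r2", "r3")] |
                  TRUE))  # presence checked below by name
  act <- res$roi %in% c("r1", "r2", "r3")
  expect_gte(sum(res$sig_within[act]), 2)
  expect_lte(sum(res$sig_within[!act]), 1)
  expect_equal(res$df_between[1], 12 + 10 - 2)
  expect_equal(res$d[act][1], mean(psc$psc_up_view[psc$group == "experimental" &
    psc$roi == res$roi[act][1]]) /
    sd(psc$psc_up_view[psc$group == "experimental" & psc$roi == res$roi[act][1]]))
})
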