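# Seeded synthetic-data generators: EEG/ECG with block-dependent alpha
# asymmetry, ROI-level BOLD with planted percent signal change and
# block-dependent correlation, voxel-level BOLD with planted clusters, and
# paired psychometric scores. Every generator is deterministic given its
# seed; per-subject seeds derive from a cohort master seed.

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + as.numeric(i) * 104729) %% 2147483629)
}

#' EEG simulation parameters
#'
#' @param alpha_band alpha band edges in Hz (default `c(8, 12)`, the
#'   conventional definition).
#' @param asym_effect planted log-power asymmetry increment of F4 over F3
#'   during Upregulation (dimensionless; 0 = no effect).
#' @param alpha_amp RMS amplitude of the band-limited alpha component, in
#'   signal units (default 3).
#' @param noise_sd SD of the pink background noise (default 2).
#' @param noise_exponent pink-noise spectral slope (default 1).
#' @param hr_bpm mean heart rate for the ECG channel (default 70).
#' @param rr_jitter_sd SD of the R-R interval jitter in seconds
#'   (default 0.05).
#' @return list of class `nf_eeg_params`.
#' @export
eeg_sim_params <- function(alpha_band = c(8, 12), asym_effect = 0.3,
                           alpha_amp = 3, noise_sd = 2, noise_exponent = 1,
                           hr_bpm = 70, rr_jitter_sd = 0.05) {
  stopifnot(alpha_band[1] < alpha_band[2], asym_effect >= 0)
  structure(list(alpha_band = alpha_band, asym_effect = asym_effect,
                 alpha_amp = alpha_amp, noise_sd = noise_sd,
                 noise_exponent = noise_exponent, hr_bpm = hr_bpm,
                 rr_jitter_sd = rr_jitter_sd),
            class = "nf_eeg_params")
}

new_eeg <- function(data, rate, channels, planted = list()) {
  colnames(data) <- channels
  structure(list(data = data, rate = rate, channels = channels,
                 planted = planted), class = "nf_eeg")
}

#' @export
print.nf_eeg <- function(x, ...) {
  cat(sprintf("nf_eeg: %d samples x %d channels (%s) at %g Hz\n",
              nrow(x$data), length(x$channels),
              paste(x$channels, collapse = ", "), x$rate))
  invisible(x)
}

#' Simulate a multichannel EEG/ECG recording
#'
#' Generates channels F3, F4 and ECG at the schedule's EEG rate. Each EEG
#' channel is pink background noise plus an independent band-limited alpha
#' component. Under the `experimental` profile the F4 alpha power is raised
#' by the factor `exp(asym_effect)` during Upregulation samples (amplitude
#' x `exp(asym_effect/2)`), so the planted window log-power asymmetry
#' increment of Upregulation over the other blocks is `asym_effect` (up to a
#' small downward bias from in-band background noise). The `control`
#' profile plants no asymmetry change. The ECG channel carries R peaks with
#' jittered R-R intervals; the true peak times are stored in
#' `$planted$r_peaks`.
#'
#' @param schedule an `nf_schedule`.
#' @param params an [eeg_sim_params()] list.
#' @param profile `"experimental"` or `"control"`.
#' @param seed RNG seed.
#' @return `nf_eeg` object (fields `data`, `rate`, `channels`, `planted`).
#' @export
simulate_eeg <- function(schedule, params = eeg_sim_params(),
                         profile = c("experimental", "control"), seed = 1) {
  profile <- match.arg(profile)
  rate <- schedule$eeg_rate
  if (params$alpha_band[2] >= rate / 2)
    stop("invalid parameter: alpha band outside Nyquist")
  set.seed(seed)
  n <- floor(schedule$total_duration * rate)
  labs <- block_labels(schedule, rate)
  effect <- if (profile == "experimental") params$asym_effect else 0

  alpha_comp <- function() {
    x <- fft_mask_filter(stats::rnorm(n), rate, keep = params$alpha_band)
    x / stats::sd(x)
  }
  gain_f4 <- ifelse(labs == "Upregulation", exp(effect / 2), 1)
  f3 <- params$alpha_amp * alpha_comp() +
    params$noise_sd * pink_noise(n, params$noise_exponent)
  f4 <- params$alpha_amp * gain_f4 * alpha_comp() +
    params$noise_sd * pink_noise(n, params$noise_exponent)

  ## ECG: spike train at jittered R-R intervals
  rr_mean <- 60 / params$hr_bpm
  n_beats <- ceiling(schedule$total_duration / rr_mean) + 10
  rr <- pmax(0.3, stats::rnorm(n_beats, rr_mean, params$rr_jitter_sd))
  peaks <- cumsum(rr)
  peaks <- peaks[peaks < schedule$total_duration - 0.1]
  ecg <- ecg_from_peaks(peaks, n, rate)

  new_eeg(cbind(f3, f4, ecg), rate, c("F3", "F4", "ECG"),
          planted = list(profile = profile, asym_effect = effect,
                         r_peaks = peaks, seed = seed))
}

# QRS-like waveform at each peak time on top of low-amplitude noise
ecg_from_peaks <- function(peak_times, n, rate) {
  ecg <- 0.05 * stats::rnorm(n)
  tpl_t <- seq(-0.04, 0.04, by = 1 / rate)
  tpl <- exp(-(tpl_t / 0.012)^2)      # narrow R wave
  half <- (length(tpl) - 1) / 2
  for (p in peak_times) {
    c0 <- round(p * rate) + 1
    ii <- (c0 - half):(c0 + half)
    ok <- ii >= 1 & ii <= n
    ecg[ii[ok]] <- ecg[ii[ok]] + tpl[ok]
  }
  ecg
}

#' Add a periodic gradient-like artifact
#'
#' Adds a fixed high-amplitude template at every `period_s` interval to all
#' EEG channels (not the ECG), emulating the MR gradient artifact that the
#' moving-average template subtraction removes. The template is stored in
#' `$planted$gradient_template` for oracle comparisons.
#'
#' @param recording an `nf_eeg`.
#' @param period_s artifact repetition period in seconds (default 2,
#'   one per volume at TR 2).
#' @param amplitude template amplitude in signal units (0 = no-op).
#' @param seed seed for the (fixed) random template shape.
#' @return `nf_eeg` with the artifact added.
#' @export
add_gradient_artifact <- function(recording, period_s = 2, amplitude = 50,
                                  seed = 1) {
  stopifnot(inherits(recording, "nf_eeg"), period_s > 0)
  if (amplitude == 0) return(recording)
  rate <- recording$rate
  plen <- round(period_s * rate)
  set.seed(seed)
  tpl <- amplitude * sin(2 * pi * seq_len(plen) / plen * sample(5:12, 1)) *
    (1 + 0.3 * stats::rnorm(plen))
  n <- nrow(recording$data)
  reps <- ceiling(n / plen)
  art <- rep(tpl, reps)[seq_len(n)]
  out <- recording
  for (ch in setdiff(recording$channels, "ECG"))
    out$data[, ch] <- out$data[, ch] + art
  out$planted$gradient_template <- tpl
  out$planted$gradient_period_s <- period_s
  out
}

#' ROI-level BOLD simulation with planted effects and connectivity
#'
#' Generates per-ROI BOLD series at the TR grid:
#' `baseline * (1 + planted_signal/100) + noise`. The planted signal is a
#' linear combination of the HRF-convolved block boxcars whose amplitudes
#' are calibrated so that the ratio-of-means percent-signal-change estimator
#' (with the first-4-s Upregulation trim) recovers exactly the requested
#' `psc_up_view` / `psc_up_rest` per ROI on noiseless data. The noise is
#' multivariate AR(1) Gaussian whose innovation correlation is `base_corr`
#' everywhere except during Upregulation volumes, where `delta_edges`
#' increments are added (nearest-PD repaired if needed).
#'
#' @param schedule an `nf_schedule`.
#' @param roi data.frame with columns `roi`, `psc_up_view`, `psc_up_rest`
#'   (default [roi_effect_table()]).
#' @param delta_edges data.frame `roi_i`, `roi_j`, `delta_r` of Upregulation
#'   correlation increments (default none).
#' @param base_corr scalar exchangeable baseline correlation, or a full
#'   ROI x ROI correlation matrix (default 0.2).
#' @param ar1 noise autocorrelation (default 0.3).
#' @param noise_sd noise SD in baseline units (default 1; baseline 100).
#' @param baseline baseline signal level (default 100).
#' @param seed RNG seed.
#' @return matrix `n_volumes x n_rois` with ROI names as column names and
#'   attribute `"planted"` carrying the generating parameters.
#' @export
simulate_roi_bold <- function(schedule, roi = roi_effect_table(),
                              delta_edges = NULL, base_corr = 0.2,
                              ar1 = 0.3, noise_sd = 1, baseline = 100,
                              seed = 1) {
  set.seed(seed)
  p <- nrow(roi)
  X <- hrf_regressors(schedule)           # volumes x 3 (Rest, View, Up)
  bi <- block_volume_indices(schedule)
  Bm <- rbind(Rest = colMeans(X[unlist(bi$Rest), , drop = FALSE]),
              View = colMeans(X[unlist(bi$View), , drop = FALSE]),
              Up   = colMeans(X[unlist(bi$Upregulation), , drop = FALSE]))

  sig <- matrix(0, schedule$n_volumes, p)
  for (j in seq_len(p)) {
    psc_uv <- roi$psc_up_view[j]
    psc_ur <- roi$psc_up_rest[j]
    ## target block-mean planted percentages: Rest = 0, Up = psc_ur,
    ## View chosen so both ratio-of-means PSC definitions hold exactly
    y_u <- psc_ur
    y_v <- (psc_ur - psc_uv) / (1 + psc_uv / 100)
    a <- solve(Bm, c(0, y_v, y_u))
    sig[, j] <- drop(X %*% a)
  }

  Sigma_base <- if (is.matrix(base_corr)) base_corr else {
    S <- matrix(base_corr, p, p); diag(S) <- 1; S
  }
  Sigma_up <- Sigma_base
  if (!is.null(delta_edges) && nrow(delta_edges)) {
    for (k in seq_len(nrow(delta_edges))) {
      i <- match(delta_edges$roi_i[k], roi$roi)
      j <- match(delta_edges$roi_j[k], roi$roi)
      if (is.na(i) || is.na(j))
        stop("delta edge references unknown ROI: ",
             delta_edges$roi_i[k], "-", delta_edges$roi_j[k])
      Sigma_up[i, j] <- Sigma_up[j, i] <- Sigma_up[i, j] + delta_edges$delta_r[k]
    }
  }
  L_base <- chol_pd(Sigma_base, "base")
  L_up <- chol_pd(Sigma_up, "Upregulation")

  labs <- block_labels(schedule, 1 / schedule$tr)
  n_vol <- schedule$n_volumes
  z <- matrix(stats::rnorm(n_vol * p), n_vol, p)
  innov <- matrix(0, n_vol, p)
  for (t in seq_len(n_vol)) {
    L <- if (labs[t] == "Upregulation") L_up else L_base
    innov[t, ] <- drop(z[t, ] %*% L)
  }
  eps <- matrix(0, n_vol, p)
  eps[1, ] <- innov[1, ]
  sf <- sqrt(1 - ar1^2)
  for (t in 2:n_vol) eps[t, ] <- ar1 * eps[t - 1, ] + sf * innov[t, ]

  out <- baseline * (1 + sig / 100) + noise_sd * eps
  colnames(out) <- roi$roi
  attr(out, "planted") <- list(roi = roi, delta_edges = delta_edges,
                               base_corr = base_corr, ar1 = ar1,
                               noise_sd = noise_sd, seed = seed)
  out
}

# upper Cholesky with nearest-PD repair; errors with the offending edges if
# the repaired matrix is still not usable
chol_pd <- function(S, what) {
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    S <- as.matrix(Matrix::nearPD(S, corr = TRUE)$mat)
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-12) {
      bad <- which(abs(S) > 1 - 1e-8 & row(S) < col(S), arr.ind = TRUE)
      stop("correlation matrix for ", what,
           " not positive definite after repair; offending edges: ",
           paste(apply(bad, 1, paste, collapse = "-"), collapse = ", "))
    }
  }
  chol(S)
}

#' Voxel-level BOLD simulation with planted active clusters
#'
#' Builds a 4-D array `(x, y, z, volume)` of baseline plus white Gaussian
#' noise in which the voxels of each cluster additionally carry an
#' HRF-convolved Upregulation signal of the requested percent signal change
#' (calibrated like [simulate_roi_bold()], relative to Rest).
#'
#' @param grid_shape integer 3-vector, e.g. `c(16, 16, 8)`.
#' @param cluster_specs list of specs, each `list(voxels = <n x 3 integer
#'   matrix>, psc = <percent>)`; see [cluster_cube()] for a convenience
#'   constructor.
#' @param schedule an `nf_schedule`.
#' @param noise_sd white-noise SD in baseline units (default 1).
#' @param baseline baseline level (default 100).
#' @param seed RNG seed.
#' @return 4-D array with attribute `"planted"` (logical 3-D array of
#'   active voxels and the specs).
#' @export
simulate_voxel_bold <- function(grid_shape, cluster_specs, schedule,
                                noise_sd = 1, baseline = 100, seed = 1) {
  set.seed(seed)
  n_vol <- schedule$n_volumes
  X <- hrf_regressors(schedule)
  bi <- block_volume_indices(schedule)
  m_up <- mean(X[unlist(bi$Upregulation), "Upregulation"])
  m_rest <- mean(X[unlist(bi$Rest), "Upregulation"])
  vol <- array(stats::rnorm(prod(grid_shape) * n_vol, sd = noise_sd),
               c(grid_shape, n_vol)) + baseline
  active <- array(FALSE, grid_shape)
  for (cs in cluster_specs) {
    vox <- as.matrix(cs$voxels)
    if (any(vox < 1) || any(vox[, 1] > grid_shape[1]) ||
        any(vox[, 2] > grid_shape[2]) || any(vox[, 3] > grid_shape[3]))
      stop("cluster outside grid")
    amp <- cs$psc / (m_up - m_rest)     # calibrated so PSC vs Rest = psc
    sigt <- baseline * amp / 100 * (X[, "Upregulation"] - m_rest)
    for (r in seq_len(nrow(vox))) {
      vol[vox[r, 1], vox[r, 2], vox[r, 3], ] <-
        vol[vox[r, 1], vox[r, 2], vox[r, 3], ] + sigt
      active[vox[r, 1], vox[r, 2], vox[r, 3]] <- TRUE
    }
  }
  attr(vol, "planted") <- list(active = active, specs = cluster_specs,
                               noise_sd = noise_sd, seed = seed)
  vol
}

#' Cube of voxels around a centre
#'
#' @param center integer 3-vector.
#' @param radius half-width in voxels (default 1, a 27-voxel cube).
#' @return integer matrix `n x 3`.
#' @export
cluster_cube <- function(center, radius = 1) {
  g <- expand.grid(center[1] + (-radius:radius),
                   center[2] + (-radius:radius),
                   center[3] + (-radius:radius))
  as.matrix(g)
}

#' Simulate paired psychometric scores
#'
#' Before/after scores from a bivariate normal with equal SDs, pair
#' correlation `rho_pair`, and an after-mean shift of `planted_d *
#' sd_before`, so the population pooled-SD effect size
#' `(m2 - m1) / sqrt((s1^2 + s2^2)/2)` equals `planted_d` exactly.
#'
#' @param n number of subjects (>= 2).
#' @param mean_before,sd_before generating moments of the before scores.
#' @param planted_d population pooled-SD effect size.
#' @param rho_pair before/after correlation, `|rho| < 1` (default 0.7).
#' @param seed RNG seed.
#' @return data.frame with columns `before`, `after`.
#' @export
simulate_psychometrics <- function(n, mean_before, sd_before, planted_d,
                                   rho_pair = 0.7, seed = 1) {
  stopifnot(n >= 2, abs(rho_pair) < 1, sd_before > 0)
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho_pair * z1 + sqrt(1 - rho_pair^2) * stats::rnorm(n)
  data.frame(before = mean_before + sd_before * z1,
             after = mean_before + planted_d * sd_before + sd_before * z2)
}

#' Cohort specification
#'
#' Bundles everything the cohort generator needs: the schedule, the group
#' sizes (defaults 18 experimental / 14 control, the analysed sample), the
#' EEG parameters, the ROI effect table (applied to the experimental group;
#' the control group gets zero planted fMRI effects and zero planted
#' asymmetry change, i.e. no learning), the differential-connectivity edges,
#' and the psychometric generating table.
#'
#' @param schedule an `nf_schedule` (default [build_schedule()]).
#' @param n_experimental,n_control group sizes (defaults 18, 14).
#' @param eeg [eeg_sim_params()] for the experimental group.
#' @param roi ROI effect table (default [roi_effect_table()]).
#' @param delta_edges differential edges (default [default_delta_edges()]).
#' @param base_corr,ar1,noise_sd BOLD noise parameters.
#' @param psych psychometric generating table
#'   (default [psych_summary_table()]).
#' @param rho_pair before/after score correlation (default 0.7).
#' @param master_seed master seed; all per-subject seeds derive from it.
#' @return list of class `nf_cohort_spec`.
#' @export
cohort_spec <- function(schedule = build_schedule(), n_experimental = 18,
                        n_control = 14, eeg = eeg_sim_params(),
                        roi = roi_effect_table(),
                        delta_edges = default_delta_edges(),
                        base_corr = 0.2, ar1 = 0.3, noise_sd = 1,
                        psych = psych_summary_table(), rho_pair = 0.7,
                        master_seed = 1) {
  stopifnot(n_experimental >= 1, n_control >= 1)
  structure(list(schedule = schedule, n_experimental = n_experimental,
                 n_control = n_control, eeg = eeg, roi = roi,
                 delta_edges = delta_edges, base_corr = base_corr,
                 ar1 = ar1, noise_sd = noise_sd, psych = psych,
                 rho_pair = rho_pair, master_seed = master_seed),
            class = "nf_cohort_spec")
}

#' Simulate a full two-group cohort
#'
#' Builds the cohort's subject table with per-subject deterministic seeds
#' and generates the psychometric scores; EEG recordings and ROI BOLD
#' matrices are exposed through [cohort_eeg()] / [cohort_roi()], which
#' regenerate them on demand from the stored seeds (bit-identical each
#' call), so a full-size cohort does not need to be held in memory at once.
#' With `dir` given, writes the dataset to disk: `events.tsv` (+ sidecar),
#' `psych.tsv`, per-subject `roi_<id>.tsv` and `eeg_<id>.tsv`, and a
#' `manifest.json` recording all seeds and planted parameters.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param write_eeg write per-subject EEG TSVs when `dir` is given
#'   (default FALSE; they are large).
#' @return list of class `nf_cohort`: `spec`, `subjects` (id, group, seed),
#'   `psych` (scores data.frame), and `dir` if written.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL,
                            write_eeg = FALSE) {
  stopifnot(inherits(spec, "nf_cohort_spec"))
  n_tot <- spec$n_experimental + spec$n_control
  subjects <- data.frame(
    id = sprintf("sub%02d", seq_len(n_tot)),
    group = rep(c("experimental", "control"),
                c(spec$n_experimental, spec$n_control)),
    seed = vapply(seq_len(n_tot), function(i) derive_seed(spec$master_seed, i),
                  integer(1)),
    stringsAsFactors = FALSE)

  ## per scale x group: one seeded draw of the whole group, planted d taken
  ## from the generating table's printed means/SDs (pooled-SD convention)
  psych <- do.call(rbind, lapply(seq_len(nrow(spec$psych)), function(k) {
    tab <- spec$psych[k, ]
    ids <- subjects$id[subjects$group == tab$group]
    if (!length(ids)) return(NULL)
    d_k <- (tab$mean_after - tab$mean_before) /
      sqrt((tab$sd_before^2 + tab$sd_after^2) / 2)
    sc <- simulate_psychometrics(max(2, length(ids)), tab$mean_before,
                                 tab$sd_before, planted_d = d_k,
                                 rho_pair = spec$rho_pair,
                                 seed = derive_seed(spec$master_seed, 9000 + k))
    sc <- sc[seq_along(ids), , drop = FALSE]
    data.frame(subject = ids, group = tab$group, scale = tab$scale,
               before = sc$before, after = sc$after, stringsAsFactors = FALSE)
  }))
  rownames(psych) <- NULL

  cohort <- structure(list(spec = spec, subjects = subjects, psych = psych,
                           dir = dir), class = "nf_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir, write_eeg = write_eeg)
  cohort
}

#' @export
print.nf_cohort <- function(x, ...) {
  cat(sprintf("nf_cohort: %d experimental + %d control subjects, %d runs, seed %d\n",
              x$spec$n_experimental, x$spec$n_control,
              x$spec$schedule$n_runs, x$spec$master_seed))
  invisible(x)
}

#' Regenerate one subject's data from a cohort
#'
#' Deterministic accessors: the same cohort and subject id always return
#' bit-identical data (seeds are stored in the subject table).
#'
#' @param cohort an `nf_cohort`.
#' @param id subject id (e.g. `"sub01"`).
#' @return `cohort_eeg()`: an `nf_eeg`; `cohort_roi()`: an ROI BOLD matrix.
#' @export
cohort_eeg <- function(cohort, id) {
  s <- cohort$subjects[cohort$subjects$id == id, ]
  stopifnot(nrow(s) == 1)
  profile <- if (s$group == "experimental") "experimental" else "control"
  simulate_eeg(cohort$spec$schedule, cohort$spec$eeg, profile,
               seed = derive_seed(s$seed, 101))
}

#' @rdname cohort_eeg
#' @export
cohort_roi <- function(cohort, id) {
  s <- cohort$subjects[cohort$subjects$id == id, ]
  stopifnot(nrow(s) == 1)
  spec <- cohort$spec
  roi <- spec$roi
  de <- spec$delta_edges
  if (s$group == "control") {         # no learning: flat effects, no delta
    roi$psc_up_view <- 0
    roi$psc_up_rest <- 0
    de <- NULL
  }
  simulate_roi_bold(spec$schedule, roi, de, spec$base_corr, spec$ar1,
                    spec$noise_sd, seed = derive_seed(s$seed, 202))
}

#' Write a cohort to disk
#'
#' @param cohort an `nf_cohort`.
#' @param dir output directory (created if missing).
#' @param write_eeg also write per-subject EEG TSVs (large).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_eeg = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort$spec
  write_events(spec$schedule, file.path(dir, "events.tsv"))
  utils::write.table(cohort$psych, file.path(dir, "psych.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in cohort$subjects$id) {
    roi <- cohort_roi(cohort, id)
    utils::write.table(round(as.data.frame(roi), 6),
                       file.path(dir, sprintf("roi_%s.tsv", id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_eeg) {
      eeg <- cohort_eeg(cohort, id)
      utils::write.table(round(as.data.frame(eeg$data), 5),
                         file.path(dir, sprintf("eeg_%s.tsv", id)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- list(
    master_seed = spec$master_seed,
    n_experimental = spec$n_experimental, n_control = spec$n_control,
    n_runs = spec$schedule$n_runs, tr = spec$schedule$tr,
    eeg_rate = spec$schedule$eeg_rate,
    asym_effect = spec$eeg$asym_effect,
    subjects = cohort$subjects,
    delta_edges = spec$delta_edges,
    base_corr = spec$base_corr, ar1 = spec$ar1, noise_sd = spec$noise_sd)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read an EEG/ECG recording from a TSV file
#'
#' Columns are channels; the sampling rate must be supplied (TSV carries no
#' header metadata).
#'
#' @param path TSV path.
#' @param rate sampling rate in samples/s.
#' @return `nf_eeg`.
#' @export
read_eeg_tsv <- function(path, rate) {
  d <- as.matrix(utils::read.delim(path))
  new_eeg(d, rate, colnames(d))
}
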