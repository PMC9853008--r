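# Offline EEG analysis: preprocessing (downsample to 250 Hz, low-pass
# 100 Hz, band-stop notches at the slice-frequency harmonics), per-block
# asymmetry tables, the group statistics on frontal alpha asymmetry, and
# heart-rate variability per block.

#' Offline EEG preprocessing
#'
#' Anti-aliased downsampling to 250 samples/s, zero-phase low-pass at
#' 100 Hz, and zero-phase band-stop notches at 15, 30, 45, 60, 75 and
#' 90 Hz (width +/- `notch_halfwidth` Hz), applied to the EEG channels
#' (the ECG channel is downsampled but not notch-filtered).
#'
#' @param recording an `nf_eeg` with rate >= 250.
#' @param target_rate output rate (default 250).
#' @param lowpass_hz low-pass cutoff (default 100).
#' @param notch_hz notch centres (default `seq(15, 90, 15)`).
#' @param notch_halfwidth half width of each notch in Hz (default 1).
#' @return preprocessed `nf_eeg` at `target_rate`.
#' @export
preprocess_eeg <- function(recording, target_rate = 250, lowpass_hz = 100,
                           notch_hz = seq(15, 90, by = 15),
                           notch_halfwidth = 1) {
  stopifnot(inherits(recording, "nf_eeg"))
  if (recording$rate < target_rate)
    stop("input rate must be >= ", target_rate)
  drop_bands <- cbind(notch_hz - notch_halfwidth, notch_hz + notch_halfwidth)
  chans <- recording$channels
  ds <- lapply(chans, function(ch)
    decimate_fft(recording$data[, ch], recording$rate, target_rate))
  n <- length(ds[[1]])
  out <- matrix(0, n, length(chans))
  for (k in seq_along(chans)) {
    x <- ds[[k]]
    if (chans[k] != "ECG")
      x <- fft_mask_filter(x, target_rate, keep = c(0, lowpass_hz),
                           drop = drop_bands)
    out[, k] <- x
  }
  res <- new_eeg(out, target_rate, chans, planted = recording$planted)
  res
}

#' Per-block mean asymmetry table
#'
#' One record per subject x run x block: the mean of the 2-s/50%-overlap
#' window asymmetries within the block (same windowing as the feedback
#' engine; Buffer segments excluded by construction).
#'
#' @param recording an `nf_eeg` (preprocessed).
#' @param schedule an `nf_schedule`.
#' @param subject,group identifiers copied into the output.
#' @param band,win_s,step_s analysis parameters (defaults 8-12 Hz, 2 s, 1 s).
#' @return data.frame: `subject`, `group`, `run`, `block`, `mean_asym`,
#'   `n_windows`.
#' @export
block_asymmetry_table <- function(recording, schedule, subject = "sub01",
                                  group = "experimental", band = c(8, 12),
                                  win_s = 2, step_s = 1) {
  aw <- asymmetry_series(recording, schedule, win_s, step_s, band)
  agg <- stats::aggregate(asym ~ run + block, aw,
                          function(v) c(mean(v), length(v)))
  data.frame(subject = subject, group = group, run = agg$run,
             block = agg$block, mean_asym = agg$asym[, 1],
             n_windows = agg$asym[, 2], stringsAsFactors = FALSE)
}

#' Cohort-level block asymmetry table
#'
#' Applies [block_asymmetry_table()] to every subject of a synthetic
#' cohort, regenerating each EEG recording from its stored seed.
#'
#' @param cohort an `nf_cohort`.
#' @param ... passed to [block_asymmetry_table()].
#' @return stacked data.frame over subjects.
#' @export
cohort_block_asymmetry <- function(cohort, ...) {
  do.call(rbind, lapply(cohort$subjects$id, function(id) {
    rec <- cohort_eeg(cohort, id)
    block_asymmetry_table(rec, cohort$spec$schedule, subject = id,
                          group = cohort$subjects$group[
                            cohort$subjects$id == id], ...)
  }))
}

#' Group statistics on frontal alpha asymmetry
#'
#' Reproduces the published testing scheme on run-block units:
#' Kolmogorov-Smirnov normality per condition; omnibus ANOVA across
#' Rest/View/Upregulation (`mode = "pooled"` one-way, error df = N - 3,
#' matching the printed df; `mode = "classical"` repeated measures);
#' pairwise condition ANOVAs; two-sample pooled t tests between groups on
#' the per-run-block (Up - View) and (Up - Rest) differences; and
#' Benjamini-Hochberg FDR at level `q` over the between-group family.
#'
#' @param tab data.frame from [block_asymmetry_table()] /
#'   [cohort_block_asymmetry()] covering one or two groups.
#' @param q FDR level (default 0.05).
#' @param mode `"pooled"` (reproduction mode, default) or `"classical"`.
#' @return list: `normality` (per condition `nf_test`s), `omnibus`,
#'   `pairwise` (list of `nf_test`s), `between` (data.frame with contrast,
#'   t, df, p, q, significant; NULL with one group).
#' @export
asymmetry_group_stats <- function(tab, q = 0.05,
                                  mode = c("pooled", "classical")) {
  mode <- match.arg(mode)
  conds <- c("Rest", "View", "Upregulation")
  exp_tab <- tab[tab$group == "experimental", ]
  if (!nrow(exp_tab)) exp_tab <- tab
  cells <- split(exp_tab$mean_asym, factor(exp_tab$block, levels = conds))
  if (any(lengths(cells) < 2)) {
    empty <- conds[lengths(cells) < 2]
    stop("degenerate cell (fewer than 2 records): ", paste(empty, collapse = ", "))
  }
  normality <- lapply(cells, ks_normality)

  omnibus <- if (mode == "pooled") oneway_anova(cells) else {
    m <- matrix(NA_real_, nrow = length(cells[[1]]), ncol = 3,
                dimnames = list(NULL, conds))
    for (cn in conds) m[, cn] <- cells[[cn]]
    rm_anova(m)
  }
  pairwise <- list(
    "Up_vs_Rest" = oneway_anova(cells[c("Upregulation", "Rest")]),
    "Up_vs_View" = oneway_anova(cells[c("Upregulation", "View")]))

  between <- NULL
  if (length(unique(tab$group)) == 2) {
    diffs <- function(g, ref) {
      s <- tab[tab$group == g, ]
      wide <- merge(s[s$block == "Upregulation", c("subject", "run", "mean_asym")],
                    s[s$block == ref, c("subject", "run", "mean_asym")],
                    by = c("subject", "run"), suffixes = c("_up", "_ref"))
      wide$mean_asym_up - wide$mean_asym_ref
    }
    rows <- lapply(c("View", "Rest"), function(ref) {
      tt <- two_sample_t(diffs("experimental", ref), diffs("control", ref))
      data.frame(contrast = paste0("Up-", ref), t = tt$statistic,
                 df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    })
    between <- do.call(rbind, rows)
    fdr <- bh_fdr(between$p, q)
    between$q_value <- fdr$q_values
    between$significant <- fdr$reject
  }
  list(normality = normality, omnibus = omnibus, pairwise = pairwise,
       between = between, mode = mode)
}

#' R-peak detection on an ECG channel
#'
#' Threshold-on-derivative detector: the signal is differenced, squared and
#' smoothed (120-ms moving average); local maxima above `threshold_frac`
#' of the 98th percentile, separated by a 250-ms refractory period, are
#' peaks. On the synthetic ECG it recovers the planted peaks within one
#' smoothing width.
#'
#' @param ecg numeric vector, the ECG channel.
#' @param rate sampling rate in samples/s.
#' @param threshold_frac detection threshold as a fraction of the 98th
#'   percentile of the detection function (default 0.3).
#' @param refractory_s refractory period (default 0.25).
#' @return numeric vector of peak times in seconds (empty, with a warning,
#'   for flat signals).
#' @export
detect_r_peaks <- function(ecg, rate, threshold_frac = 0.3,
                           refractory_s = 0.25) {
  if (stats::sd(ecg) == 0) {
    warning("flat ECG signal; no peaks")
    return(numeric(0))
  }
  ## QRS energy lives around 5-20 Hz; band-passing first suppresses the
  ## wideband noise floor before the derivative stage
  x <- fft_mask_filter(ecg, rate, keep = c(5, 20))
  d <- c(0, diff(x))
  det <- d^2
  w <- max(1L, round(0.08 * rate))
  kern <- rep(1 / w, w)
  det <- as.numeric(stats::filter(det, kern, sides = 2))
  det[is.na(det)] <- 0
  thr <- threshold_frac * stats::quantile(det, 0.98)
  if (thr <= 0) {
    warning("no peaks above threshold")
    return(numeric(0))
  }
  refr <- round(refractory_s * rate)
  cand <- which(det > thr)
  if (!length(cand)) {
    warning("no peaks above threshold")
    return(numeric(0))
  }
  ## group above-threshold samples into events separated by >= refractory,
  ## then refine each event to the raw-signal maximum
  breaks <- which(diff(cand) >= refr)
  ev_start <- cand[c(1, breaks + 1)]
  ev_end <- cand[c(breaks, length(cand))]
  peaks <- mapply(function(a, b) {
    lo <- max(1, a - w); hi <- min(length(ecg), b + w)
    lo + which.max(ecg[lo:hi]) - 1
  }, ev_start, ev_end)
  peaks <- peaks[c(TRUE, diff(peaks) >= refr)]
  (peaks - 1) / rate
}

#' Heart-rate variability per block
#'
#' Assigns each R-R interval to the block containing the earlier beat and
#' summarizes per block: SDNN (SD of R-R intervals, ms), RMSSD (root mean
#' square of successive differences, ms) and beat count. Also runs a
#' per-subject one-way ANOVA of the R-R intervals across the three task
#' blocks (the per-subject HRV comparison).
#'
#' @param peak_times R-peak times in seconds (e.g. [detect_r_peaks()]).
#' @param schedule an `nf_schedule`.
#' @return list: `records` data.frame (`block`, `sdnn`, `rmssd`,
#'   `n_beats`, `missing`), `anova` (`nf_test` or NULL when any block has
#'   fewer than 2 intervals).
#' @export
hrv_by_block <- function(peak_times, schedule) {
  labs <- function(t) {
    b <- schedule$blocks
    out <- rep(NA_character_, length(t))
    for (i in seq_len(nrow(b)))
      out[t >= b$onset[i] & t < b$onset[i] + b$duration[i]] <- b$trial_type[i]
    out
  }
  if (length(peak_times) < 3)
    return(list(records = data.frame(), anova = NULL))
  rr <- diff(peak_times) * 1000            # ms
  rr_block <- labs(peak_times[-length(peak_times)])
  conds <- c("Rest", "View", "Upregulation")
  records <- do.call(rbind, lapply(conds, function(cb) {
    v <- rr[rr_block %in% cb]
    if (length(v) < 2)
      return(data.frame(block = cb, sdnn = NA_real_, rmssd = NA_real_,
                        n_beats = length(v), missing = TRUE))
    data.frame(block = cb, sdnn = stats::sd(v),
               rmssd = sqrt(mean(diff(v)^2)), n_beats = length(v),
               missing = FALSE)
  }))
  groups <- lapply(conds, function(cb) rr[rr_block %in% cb])
  anova <- if (all(lengths(groups) >= 2))
    tryCatch(oneway_anova(groups), error = function(e) NULL) else NULL
  list(records = records, anova = anova)
}
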