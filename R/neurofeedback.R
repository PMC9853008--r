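# The closed-loop feedback engine. The displayed quantity is the sliding
# 2-s-window alpha log-power asymmetry ln P(F4) - ln P(F3), referenced to
# the mean asymmetry of the preceding View block, smoothed over the current
# and two previous windows; the bar is blue when it maintains or increases
# relative to the previous bar, red otherwise. Sham mode replaces the bar
# by a bounded random walk independent of the EEG.

#' Sliding-window alpha asymmetry series
#'
#' Computes `asym = ln P(F4) - ln P(F3)` with [window_band_power()] in
#' windows of `win_s` seconds advancing by `step_s` (defaults 2 s / 1 s,
#' i.e. 50% overlap), aligned to the start of each block so windows never
#' straddle a block boundary: a block of duration D yields
#' `floor((D - win_s)/step_s) + 1` windows (59 for a 60-s Upregulation
#' block, 39 for a 40-s View block). Windows with non-positive power in
#' either channel are flagged invalid and excluded.
#'
#' @param recording an `nf_eeg` with channels F3 and F4.
#' @param schedule an `nf_schedule`.
#' @param win_s,step_s window length and step in seconds (defaults 2, 1).
#' @param band alpha band in Hz (default `c(8, 12)`).
#' @return data.frame: `run`, `block`, `t_start` (s), `ln_p_f4`, `ln_p_f3`,
#'   `asym`.
#' @export
asymmetry_series <- function(recording, schedule, win_s = 2, step_s = 1,
                             band = c(8, 12)) {
  stopifnot(inherits(recording, "nf_eeg"))
  if (!all(c("F3", "F4") %in% recording$channels))
    stop("channel not found: need F3 and F4")
  stopifnot(step_s > 0, step_s <= win_s)
  rate <- recording$rate
  wlen <- round(win_s * rate)
  b <- schedule$blocks
  out <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    if (b$trial_type[i] == "Buffer") next
    n_win <- floor((b$duration[i] - win_s) / step_s) + 1
    if (n_win < 1) next
    starts <- b$onset[i] + (seq_len(n_win) - 1) * step_s
    rows <- lapply(starts, function(t0) {
      i0 <- floor(t0 * rate) + 1
      seg <- recording$data[i0:(i0 + wlen - 1), , drop = FALSE]
      p4 <- window_band_power(seg[, "F4"], rate, band)
      p3 <- window_band_power(seg[, "F3"], rate, band)
      if (p4 <= 0 || p3 <= 0) return(NULL)
      data.frame(run = b$run[i], block = b$trial_type[i], t_start = t0,
                 ln_p_f4 = log(p4), ln_p_f3 = log(p3),
                 asym = log(p4) - log(p3))
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' View-block baseline asymmetry
#'
#' Arithmetic mean of the valid View-block asymmetry values of one run; the
#' reference subtracted from every Upregulation window of the same run.
#'
#' @param asym_windows data.frame from [asymmetry_series()] (or any frame
#'   with columns `block` and `asym`), already restricted to one run.
#' @return scalar baseline.
#' @export
view_baseline <- function(asym_windows) {
  v <- asym_windows$asym[asym_windows$block == "View"]
  v <- v[is.finite(v)]
  if (!length(v)) stop("baseline unavailable: no valid View windows")
  mean(v)
}

#' One feedback-bar update
#'
#' Applies the display rule to a new raw asymmetry value: subtract the View
#' baseline, average with up to the two previous relative values (fewer at
#' block start), and colour blue when the bar maintains or exceeds the
#' previous bar, red otherwise. The first bar of a block is blue.
#'
#' @param state list with `baseline` (scalar), `history` (numeric, last <= 2
#'   relative values), `prev_bar` (scalar or NULL).
#' @param new_asym raw window asymmetry.
#' @return list `bar`, `color`, `state` (updated).
#' @export
feedback_bar <- function(state, new_asym) {
  stopifnot(!is.null(state$baseline))
  rel <- new_asym - state$baseline
  vals <- c(state$history, rel)
  bar <- mean(vals)
  color <- if (is.null(state$prev_bar) || bar >= state$prev_bar) "blue" else "red"
  state$history <- utils::tail(c(state$history, rel), 2)
  state$prev_bar <- bar
  list(bar = bar, color = color, state = state)
}

new_feedback_state <- function(baseline) {
  list(baseline = baseline, history = numeric(0), prev_bar = NULL)
}

#' Sham feedback trace
#'
#' Bar heights for every Upregulation block drawn from a bounded Gaussian
#' random walk (step SD `step_sd`, reflected at `+/-bound`), statistically
#' independent of any EEG. Colours follow the same maintain-or-increase
#' rule as real feedback.
#'
#' @param schedule an `nf_schedule`.
#' @param seed RNG seed.
#' @param step_sd random-walk step SD (default 0.2).
#' @param bound reflecting bound (default 2).
#' @param win_s,step_s window geometry (defaults 2, 1), fixing the number
#'   of updates per block.
#' @return `nf_feedback_trace` data.frame: `run`, `time`, `bar`, `color`,
#'   `raw_asym`, `relative_asym` (NA in sham mode), with attributes `mode`
#'   and `seed`.
#' @export
sham_feedback <- function(schedule, seed = 1, step_sd = 0.2, bound = 2,
                          win_s = 2, step_s = 1) {
  set.seed(seed)
  b <- schedule$blocks
  ub <- b[b$trial_type == "Upregulation", ]
  out <- lapply(seq_len(nrow(ub)), function(i) {
    n_win <- floor((ub$duration[i] - win_s) / step_s) + 1
    x <- numeric(n_win)
    x[1] <- stats::runif(1, -bound / 2, bound / 2)
    for (t in seq_len(n_win - 1)) {
      nx <- x[t] + stats::rnorm(1, 0, step_sd)
      # reflect into [-bound, bound]
      while (abs(nx) > bound) nx <- sign(nx) * (2 * bound) - nx
      x[t + 1] <- nx
    }
    color <- c("blue", ifelse(diff(x) >= 0, "blue", "red"))
    data.frame(run = ub$run[i],
               time = ub$onset[i] + (seq_len(n_win) - 1) * step_s + win_s,
               bar = x, color = color, raw_asym = NA_real_,
               relative_asym = NA_real_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, mode = "sham", seed = seed, class = c("nf_feedback_trace", "data.frame"))
}

#' Run the closed feedback loop over a recording
#'
#' Real mode chains [asymmetry_series()] -> [view_baseline()] ->
#' [feedback_bar()] causally per run: each update at time t uses only
#' samples up to t (the window ending at t), and the baseline comes from
#' the same run's View block, which precedes every Upregulation window.
#' Sham mode ignores the EEG entirely and delegates to [sham_feedback()].
#'
#' @param recording an `nf_eeg` (ignored in sham mode).
#' @param schedule an `nf_schedule`.
#' @param mode `"real"` or `"sham"`.
#' @param band alpha band (default `c(8, 12)`).
#' @param win_s,step_s window geometry (defaults 2, 1).
#' @param seed sham seed.
#' @return `nf_feedback_trace` data.frame (one row per Upregulation-window
#'   update): `run`, `time` (window end, s), `bar`, `color`, `raw_asym`,
#'   `relative_asym`.
#' @export
run_closed_loop <- function(recording, schedule, mode = c("real", "sham"),
                            band = c(8, 12), win_s = 2, step_s = 1, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "sham")
    return(sham_feedback(schedule, seed = seed, win_s = win_s, step_s = step_s))
  aw <- asymmetry_series(recording, schedule, win_s, step_s, band)
  out <- lapply(sort(unique(aw$run)), function(r) {
    ar <- aw[aw$run == r, ]
    base <- view_baseline(ar)
    up <- ar[ar$block == "Upregulation", ]
    if (!nrow(up)) return(NULL)
    st <- new_feedback_state(base)
    rows <- vector("list", nrow(up))
    for (i in seq_len(nrow(up))) {
      fb <- feedback_bar(st, up$asym[i])
      st <- fb$state
      rows[[i]] <- data.frame(run = r, time = up$t_start[i] + win_s,
                              bar = fb$bar, color = fb$color,
                              raw_asym = up$asym[i],
                              relative_asym = up$asym[i] - base,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, mode = "real", class = c("nf_feedback_trace", "data.frame"))
}

#' Moving-average gradient-template subtraction
#'
#' Removes a periodic artifact by subtracting, from each artifact epoch,
#' the moving average of the previous `n_average` epochs (the first
#' `n_average` epochs use the average of all epochs seen so far; the very
#' first epoch uses the first `n_average` epochs' mean so the output is
#' usable from the start). With a stationary template the planted artifact
#' is attenuated essentially completely while in-band neural content is
#' preserved, because the average of many signal epochs tends to the
#' (near-zero) mean signal.
#'
#' @param recording an `nf_eeg` containing the artifact.
#' @param period_s artifact period in seconds.
#' @param n_average number of epochs averaged (default 10).
#' @return cleaned `nf_eeg`. If fewer than `n_average` full epochs exist,
#'   the recording passes through with a warning.
#' @export
template_subtract <- function(recording, period_s, n_average = 10) {
  stopifnot(inherits(recording, "nf_eeg"), period_s > 0)
  rate <- recording$rate
  plen <- round(period_s * rate)
  n <- nrow(recording$data)
  n_ep <- floor(n / plen)
  if (n_ep < n_average) {
    warning("fewer epochs than n_average; passthrough")
    return(recording)
  }
  out <- recording
  for (ch in setdiff(recording$channels, "ECG")) {
    x <- recording$data[, ch]
    ep <- matrix(x[seq_len(n_ep * plen)], nrow = plen)
    cleaned <- ep
    for (e in seq_len(n_ep)) {
      from <- max(1, e - n_average)
      # causal: previous epochs only; epoch 1 has none, so it warms up on
      # the first n_average epochs (the only anticausal sample)
      tmpl <- if (e == 1) rowMeans(ep[, seq_len(n_average), drop = FALSE])
              else rowMeans(ep[, from:(e - 1), drop = FALSE])
      cleaned[, e] <- ep[, e] - tmpl
    }
    x[seq_len(n_ep * plen)] <- as.vector(cleaned)
    if (n_ep * plen < n) {            # tail shorter than one epoch
      tail_len <- n - n_ep * plen
      x[(n_ep * plen + 1):n] <- x[(n_ep * plen + 1):n] -
        rowMeans(ep[, (n_ep - n_average + 1):n_ep, drop = FALSE])[seq_len(tail_len)]
    }
    out$data[, ch] <- x
  }
  out
}

#' Write / read a feedback trace TSV
#'
#' @param trace an `nf_feedback_trace`.
#' @param path TSV path.
#' @return `read_feedback_trace()` returns the data.frame.
#' @export
write_feedback_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feedback_trace
#' @export
read_feedback_trace <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
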