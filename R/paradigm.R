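BLOCK_LABELS <- c("Rest", "View", "Upregulation", "Buffer")

#' Build the block-design experiment schedule
#'
#' Constructs the timeline of the neurofeedback paradigm: `n_runs` runs, each
#' composed of a Rest, a View and an Upregulation block in that order, plus an
#' optional Buffer segment (instruction/transition time excluded from all
#' analyses) closing each run. With the defaults the schedule reproduces the
#' published design exactly: 10 runs of 130 s (20 + 40 + 60 + 10), 1300 s in
#' total, i.e. 650 BOLD volumes at TR = 2 s.
#'
#' All intervals are half-open `[start, end)` in seconds from experiment
#' onset, and boundaries are floored to the sample grid when mapped to
#' samples, so every sample belongs to exactly one block.
#'
#' @param n_runs number of runs (default 10).
#' @param rest_s,view_s,up_s,buffer_s block durations in seconds
#'   (defaults 20, 40, 60, 10). `buffer_s` may be 0.
#' @param tr BOLD repetition time in seconds (default 2).
#' @param eeg_rate EEG sampling rate in samples/s (default 250).
#'
#' @return An object of class `nf_schedule`: a list with a `blocks`
#'   data.frame (`run`, `trial_type`, `onset`, `duration`), `n_runs`,
#'   `run_duration`, `total_duration`, `tr`, `eeg_rate`, `n_volumes`.
#' @examples
#' sch <- build_schedule()
#' sch$total_duration  # 1300
#' sch$n_volumes       # 650
#' @export
build_schedule <- function(n_runs = 10, rest_s = 20, view_s = 40, up_s = 60,
                           buffer_s = 10, tr = 2, eeg_rate = 250) {
  if (!is.finite(tr) || tr <= 0) stop("invalid parameter: tr must be > 0")
  if (!is.finite(eeg_rate) || eeg_rate <= 0)
    stop("invalid parameter: eeg_rate must be > 0")
  durs <- c(Rest = rest_s, View = view_s, Upregulation = up_s,
            Buffer = buffer_s)
  if (any(!is.finite(durs)) || any(durs < 0))
    stop("invalid parameter: block durations must be non-negative")
  if (any(durs[c("Rest", "View", "Upregulation")] == 0))
    stop("invalid parameter: Rest/View/Upregulation durations must be > 0")
  if (n_runs < 1) stop("invalid parameter: n_runs must be >= 1")

  per_run <- data.frame(
    trial_type = names(durs),
    duration   = unname(durs),
    stringsAsFactors = FALSE
  )
  per_run <- per_run[per_run$duration > 0, , drop = FALSE]
  run_duration <- sum(per_run$duration)

  blocks <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    onset <- (r - 1) * run_duration + cumsum(c(0, per_run$duration))[seq_len(nrow(per_run))]
    data.frame(run = r, trial_type = per_run$trial_type, onset = onset,
               duration = per_run$duration, stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL

  structure(list(
    blocks = blocks,
    n_runs = n_runs,
    run_duration = run_duration,
    total_duration = n_runs * run_duration,
    tr = tr,
    eeg_rate = eeg_rate,
    n_volumes = floor(n_runs * run_duration / tr)
  ), class = "nf_schedule")
}

#' @export
print.nf_schedule <- function(x, ...) {
  cat(sprintf(
    "nf_schedule: %d runs x %g s = %g s total (%d volumes at TR=%g s, EEG %g Hz)\n",
    x$n_runs, x$run_duration, x$total_duration, x$n_volumes, x$tr, x$eeg_rate))
  tab <- stats::aggregate(duration ~ trial_type, x$blocks[x$blocks$run == 1, ], sum)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-13s %g s/run\n", tab$trial_type[i], tab$duration[i]))
  invisible(x)
}

#' Per-sample block labels
#'
#' Maps every sample of a regular grid at `rate` samples/s onto its block
#' label under the half-open interval convention: sample `i` (0-based) at
#' time `i / rate` gets the label of the block whose `[onset, onset+dur)`
#' interval contains that time.
#'
#' @param schedule an `nf_schedule`.
#' @param rate sampling rate in samples/s; e.g. `1 / schedule$tr` gives one
#'   label per BOLD volume, `schedule$eeg_rate` one per EEG sample.
#' @return character vector of length `floor(total_duration * rate)` with
#'   values in `c("Rest","View","Upregulation","Buffer")`.
#' @export
block_labels <- function(schedule, rate) {
  stopifnot(inherits(schedule, "nf_schedule"))
  if (!is.finite(rate) || rate <= 0) stop("invalid parameter: rate must be > 0")
  n <- floor(schedule$total_duration * rate)
  t <- (seq_len(n) - 1) / rate
  lab <- rep(NA_character_, n)
  b <- schedule$blocks
  for (i in seq_len(nrow(b))) {
    sel <- t >= b$onset[i] & t < b$onset[i] + b$duration[i]
    lab[sel] <- b$trial_type[i]
  }
  lab
}

#' Per-sample run indices
#'
#' @inheritParams block_labels
#' @return integer vector of run indices, same length as [block_labels()].
#' @export
run_index <- function(schedule, rate) {
  stopifnot(inherits(schedule, "nf_schedule"))
  n <- floor(schedule$total_duration * rate)
  t <- (seq_len(n) - 1) / rate
  pmin(schedule$n_runs, floor(t / schedule$run_duration) + 1L)
}

#' Write / read a BIDS-style events table
#'
#' `write_events()` serializes a schedule as a tab-separated events file with
#' columns `onset`, `duration`, `trial_type`, `run`, plus a JSON sidecar
#' (`<path>.json`) carrying the sampling parameters (`tr`, `eeg_rate`) so the
#' round trip is exact. `read_events()` reconstructs the schedule and
#' validates it: labels must come from the closed block set and intervals
#' within a run must not overlap.
#'
#' @param schedule an `nf_schedule`.
#' @param path file path of the events TSV.
#' @return `write_events()` returns `path` invisibly; `read_events()` an
#'   `nf_schedule`.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "nf_schedule"))
  utils::write.table(schedule$blocks[, c("onset", "duration", "trial_type", "run")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = schedule$tr, eeg_rate = schedule$eeg_rate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @param tr,eeg_rate sampling parameters used when no JSON sidecar is found.
#' @export
read_events <- function(path, tr = 2, eeg_rate = 250) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "run")
  if (!all(need %in% names(ev)))
    stop("parse error: events file must have columns onset, duration, trial_type, run")
  bad <- which(!ev$trial_type %in% BLOCK_LABELS)
  if (length(bad))
    stop(sprintf("parse error in events row %d: unknown trial_type '%s'",
                 bad[1], ev$trial_type[bad[1]]))
  bad <- which(!is.finite(ev$onset) | !is.finite(ev$duration) | ev$duration < 0)
  if (length(bad))
    stop(sprintf("parse error in events row %d: bad onset/duration", bad[1]))
  for (r in unique(ev$run)) {
    er <- ev[ev$run == r, ]
    er <- er[order(er$onset), ]
    if (nrow(er) > 1) {
      ends <- er$onset + er$duration
      ov <- which(er$onset[-1] < ends[-nrow(er)] - 1e-9)
      if (length(ov)) {
        row_id <- which(ev$onset == er$onset[ov[1] + 1] & ev$run == r)[1]
        stop(sprintf("parse error in events row %d: overlapping intervals in run %s",
                     row_id, r))
      }
    }
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    tr <- meta$tr; eeg_rate <- meta$eeg_rate
  }
  run1 <- ev[ev$run == min(ev$run), ]
  run1 <- run1[order(run1$onset), ]
  durs <- stats::setNames(rep(0, 4), BLOCK_LABELS)
  durs[run1$trial_type] <- run1$duration
  build_schedule(n_runs = length(unique(ev$run)),
                 rest_s = durs[["Rest"]], view_s = durs[["View"]],
                 up_s = durs[["Upregulation"]], buffer_s = durs[["Buffer"]],
                 tr = tr, eeg_rate = eeg_rate)
}

#' @exportS3Method base::all.equal
all.equal.nf_schedule <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}
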