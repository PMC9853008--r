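# Block-design GLM analysis: canonical HRF, design construction, temporal
# high-pass by discrete-cosine projection, Gaussian spatial smoothing, OLS
# with t contrasts, permutation cluster-extent correction, and ROI percent
# signal change with the first-4-s Upregulation trim.

#' Canonical double-gamma haemodynamic response function
#'
#' `hrf(t)` evaluates the canonical double-gamma HRF (response peak 6 s,
#' undershoot peak 16 s, peak-to-undershoot ratio 6), scaled to unit peak.
#' `hrf(0) == 0`.
#'
#' @param t time in seconds (vectorized).
#' @param peak,undershoot,ratio shape parameters (defaults 6, 16, 6).
#' @return numeric vector of amplitudes.
#' @export
hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- ifelse(t <= 0, 0,
              stats::dgamma(t, shape = peak, rate = 1) -
                stats::dgamma(t, shape = undershoot, rate = 1) / ratio)
  tt <- seq(0, 32, by = 0.01)
  hmax <- max(stats::dgamma(tt, shape = peak, rate = 1) -
                stats::dgamma(tt, shape = undershoot, rate = 1) / ratio)
  h / hmax
}

# HRF-convolved block regressors sampled at the TR grid, one column per
# task label (Rest, View, Upregulation), computed on a 0.1-s grid and
# decimated. Peak-normalized jointly (max of Upregulation column = 1).
hrf_regressors <- function(schedule, dt = 0.1) {
  labs_fine <- block_labels(schedule, 1 / dt)
  n_fine <- length(labs_fine)
  kern <- hrf(seq(0, 32, by = dt))
  task_labels <- c("Rest", "View", "Upregulation")
  X <- sapply(task_labels, function(L) {
    box <- as.numeric(labs_fine == L)
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_fine)] * dt
    conv
  })
  vols <- floor(seq(0, schedule$n_volumes - 1) * schedule$tr / dt) + 1
  X <- X[vols, , drop = FALSE]
  X / max(X[, "Upregulation"])
}

#' Build a block-design GLM design matrix
#'
#' Columns: HRF-convolved boxcars for Rest, View and Upregulation, six
#' motion confounds, and an intercept (10 columns with defaults). Task
#' boxcars are sampled on a 0.1-s grid, convolved with the canonical
#' double-gamma [hrf()], and decimated to the TR grid.
#'
#' @param schedule an `nf_schedule`.
#' @param motion optional numeric matrix `n_volumes x 6` of motion
#'   confounds; defaults to zeros (dropped from the design, as all-zero
#'   confound columns carry no information).
#' @return numeric matrix `n_volumes x p` with named columns; attribute
#'   `"task_cols"` marks the three task columns.
#' @export
build_design <- function(schedule, motion = NULL) {
  X <- hrf_regressors(schedule)
  if (any(colSums(abs(X)) == 0)) stop("zero-duration task block produced an all-zero column")
  if (is.null(motion)) motion <- matrix(0, schedule$n_volumes, 6)
  motion <- as.matrix(motion)
  if (nrow(motion) != schedule$n_volumes || ncol(motion) != 6)
    stop("motion table must be n_volumes x 6")
  keep <- apply(motion, 2, function(z) stats::sd(z) > 0)
  M <- motion[, keep, drop = FALSE]
  if (ncol(M)) colnames(M) <- paste0("motion", which(keep))
  D <- cbind(X, M, intercept = 1)
  attr(D, "task_cols") <- colnames(X)
  D
}

#' Temporal high-pass filter by discrete-cosine projection
#'
#' Projects out the DCT basis functions with frequency below `cutoff_hz`
#' (including the constant), the standard fMRI drift removal. Idempotent.
#'
#' @param series numeric vector or matrix (time in rows).
#' @param tr repetition time, s.
#' @param cutoff_hz cutoff frequency, Hz (default 0.005).
#' @return filtered series, same shape.
#' @export
highpass_dct <- function(series, tr, cutoff_hz = 0.005) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (cutoff_hz >= 1 / (2 * tr)) stop("cutoff must be below Nyquist")
  total_t <- n * tr
  k_max <- floor(2 * total_t * cutoff_hz)
  t_idx <- seq_len(n) - 0.5
  B <- cbind(rep(1 / sqrt(n), n),
             if (k_max >= 1)
               sapply(seq_len(k_max), function(k)
                 sqrt(2 / n) * cos(pi * k * t_idx / n)))
  res <- x - B %*% (t(B) %*% x)
  if (is.vector(series)) drop(res) else res
}

# 1-D Gaussian kernel for FWHM in voxel units
gauss_kernel <- function(fwhm) {
  sigma <- fwhm / 2.3548
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# symmetric (reflective) padding 1-D convolution along one array dimension;
# symmetric padding + symmetric kernel conserves total intensity exactly
conv_along <- function(a, k, dim_i) {
  r <- (length(k) - 1) / 2
  perm <- c(dim_i, setdiff(seq_along(dim(a)), dim_i))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, d[1], prod(d[-1]))
  n <- nrow(m)
  stopifnot(r < n)
  pidx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  mp <- m[pidx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1) + seq_len(n), , drop = FALSE]
  dim(out) <- d
  aperm(out, order(perm))
}

#' Gaussian spatial smoothing of a 3-D or 4-D volume
#'
#' Separable Gaussian smoothing with full-width-at-half-maximum `fwhm`
#' expressed in voxel units (`sigma = fwhm / 2.3548`), reflective padding
#' at the edges so total intensity is preserved.
#'
#' @param vol numeric array, 3-D `(x,y,z)` or 4-D `(x,y,z,t)`.
#' @param fwhm FWHM in voxels (scalar, applied along x, y, z).
#' @return smoothed array, same shape.
#' @export
smooth_gaussian <- function(vol, fwhm) {
  if (fwhm <= 0) return(vol)
  k <- gauss_kernel(fwhm)
  nd <- length(dim(vol))
  out <- vol
  for (d in 1:3) out <- conv_along(out, k, d)
  stopifnot(length(dim(out)) == nd)
  out
}

#' Ordinary least squares GLM fit
#'
#' Fits `y = X b + e` by OLS for one or many response series and returns
#' coefficient estimates, residual variance and `(X'X)^{-1}` for contrast
#' inference. `contrast_t()` computes `t = c'b / sqrt(s2 * c'(X'X)^{-1}c)`
#' with `df = n - rank(X)`.
#'
#' @param y numeric vector or matrix (time in rows, series in columns).
#' @param X design matrix (e.g. from [build_design()]).
#' @return list of class `nf_glm` with `beta`, `sigma2`, `df`, `xtx_inv`.
#' @export
fit_glm <- function(y, X) {
  y <- as.matrix(y)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  yscale <- colMeans(y^2)
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 xtx_inv = chol2inv(qr.R(qrX)), X = X, yscale = yscale),
            class = "nf_glm")
}

#' @rdname fit_glm
#' @param fit an `nf_glm` object.
#' @param weights contrast vector `c` (length = columns of the design).
#' @return `contrast_t()`: list with per-series `t` (infinite where the
#'   residual variance is exactly 0 but the contrast is nonzero), `df`, `p`.
#' @export
contrast_t <- function(fit, weights) {
  stopifnot(inherits(fit, "nf_glm"), length(weights) == nrow(as.matrix(fit$beta)))
  cb <- drop(t(weights) %*% fit$beta)
  vc <- drop(t(weights) %*% fit$xtx_inv %*% weights)
  se <- sqrt(fit$sigma2 * vc)
  # residual variance at rounding level: the fit is exact, so the contrast
  # is either exactly explained signal (t = +/-Inf flag) or exactly zero
  degen <- fit$sigma2 <= 1e-16 * pmax(fit$yscale, .Machine$double.xmin)
  t <- ifelse(degen | se == 0,
              ifelse(abs(cb) > 1e-6 * sqrt(pmax(fit$yscale, 1e-300)),
                     sign(cb) * Inf, 0),
              cb / se)
  list(t = t, df = fit$df, p = stats::pt(t, fit$df, lower.tail = FALSE))
}

# label 26-connected clusters of TRUE voxels in a 3-D logical array;
# returns integer array of cluster ids (0 = background)
label_clusters_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, d)
      cand <- sweep(nb, 2, as.integer(co), "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      li <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
      new <- li[mask[li] & lab[li] == 0L]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  lab
}

# t-map for one 4-D volume: voxels x time GLM with the given contrast
voxel_tmap <- function(vol4d, X, weights) {
  d <- dim(vol4d)
  y <- t(matrix(vol4d, prod(d[1:3]), d[4]))
  fit <- fit_glm(y, X)
  ct <- contrast_t(fit, weights)
  list(t = array(ct$t, d[1:3]), df = ct$df)
}

#' Permutation cluster-extent correction of a voxelwise contrast
#'
#' Thresholds the t map at the one-sided voxel threshold `voxel_p`
#' (cluster-forming), labels 26-connected clusters, and compares each
#' observed cluster extent against a null maximum-cluster-size distribution
#' obtained by recomputing the t map under random circular time shifts of
#' the task regressors (which destroy the task-signal alignment while
#' preserving the autocorrelation of the data). A cluster survives when its
#' corrected p (proportion of null maxima at least as large) is <=
#' `cluster_p`.
#'
#' @param vol4d numeric 4-D array `(x,y,z,t)`.
#' @param schedule an `nf_schedule` matching `dim(vol4d)[4]` volumes.
#' @param contrast named contrast, `"Up>View"` or `"Up>Rest"`.
#' @param voxel_p cluster-forming voxel p threshold (default 0.01).
#' @param cluster_p corrected cluster p threshold (default 0.01).
#' @param n_perm number of permutations (>= 100; default 200).
#' @param seed RNG seed for the permutation shifts.
#' @return list with `t_map`, `df`, `threshold`, `clusters` (data.frame:
#'   id, size, p_corrected, survives), `cluster_map` (integer array of
#'   surviving-cluster labels), `null_max_sizes`.
#' @export
cluster_correct <- function(vol4d, schedule, contrast = c("Up>View", "Up>Rest"),
                            voxel_p = 0.01, cluster_p = 0.01,
                            n_perm = 200, seed = 1) {
  contrast <- match.arg(contrast)
  if (n_perm < 100) stop("n_perm must be >= 100")
  X <- build_design(schedule)
  w <- contrast_weights(X, contrast)
  obs <- voxel_tmap(vol4d, X, w)
  thr <- stats::qt(1 - voxel_p, obs$df)
  lab <- label_clusters_26(obs$t > thr)
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)

  task_cols <- attr(X, "task_cols")
  n_vol <- dim(vol4d)[4]
  set.seed(seed)
  ## random time permutation of the task regressors (circular shifts would
  ## realign a periodic multi-run design with itself)
  null_max <- vapply(seq_len(n_perm), function(i) {
    Xp <- X
    Xp[, task_cols] <- X[sample(n_vol), task_cols]
    tp <- voxel_tmap(vol4d, Xp, w)
    lp <- label_clusters_26(tp$t > thr)
    if (max(lp) > 0) max(tabulate(lp[lp > 0])) else 0L
  }, integer(1))

  clusters <- data.frame(id = seq_along(sizes), size = sizes)
  clusters$p_corrected <- vapply(sizes, function(s)
    (1 + sum(null_max >= s)) / (1 + n_perm), 0)
  clusters$survives <- clusters$p_corrected <= cluster_p
  keep <- clusters$id[clusters$survives]
  cmap <- lab
  cmap[!(lab %in% keep)] <- 0L
  list(t_map = obs$t, df = obs$df, threshold = thr, clusters = clusters,
       cluster_map = cmap, null_max_sizes = null_max)
}

contrast_weights <- function(X, contrast) {
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (contrast == "Up>View") {
    w["Upregulation"] <- 1; w["View"] <- -1
  } else if (contrast == "Up>Rest") {
    w["Upregulation"] <- 1; w["Rest"] <- -1
  } else stop("unknown contrast: ", contrast)
  w
}

# volume indices per block label, with the first `trim_volumes` volumes of
# every Upregulation block removed (the first 4 s = two samples at TR 2)
block_volume_indices <- function(schedule, trim_up_volumes = 2) {
  labs <- block_labels(schedule, 1 / schedule$tr)
  runs <- run_index(schedule, 1 / schedule$tr)
  out <- list()
  for (lb in c("Rest", "View", "Upregulation")) {
    idx_by_run <- lapply(seq_len(schedule$n_runs), function(r) {
      ii <- which(labs == lb & runs == r)
      if (lb == "Upregulation" && length(ii) > trim_up_volumes)
        ii <- ii[-seq_len(trim_up_volumes)]
      ii
    })
    out[[lb]] <- idx_by_run
  }
  out
}

#' ROI percent signal change with the Upregulation trim rule
#'
#' For each ROI: `PSC = 100 * (mean(Up') - mean(ref)) / mean(ref)` over the
#' selected series, where `Up'` drops the first two volumes (4 s at TR 2 s)
#' of every Upregulation block to remove the haemodynamic carry-over of the
#' preceding View block, and `ref` is View or Rest.
#'
#' @param roi_series numeric matrix `n_volumes x n_rois` of ROI-mean BOLD
#'   series (for voxel data, average the activated voxels inside each ROI
#'   mask first; see [roi_mean_series()]).
#' @param schedule an `nf_schedule`.
#' @param trim_up_volumes number of leading Upregulation volumes dropped
#'   (default 2).
#' @return data.frame with `roi`, `psc_up_view`, `psc_up_rest`, `defined`.
#' @export
roi_percent_signal_change <- function(roi_series, schedule, trim_up_volumes = 2) {
  roi_series <- as.matrix(roi_series)
  stopifnot(nrow(roi_series) == schedule$n_volumes)
  bi <- block_volume_indices(schedule, trim_up_volumes)
  iu <- unlist(bi$Upregulation); iv <- unlist(bi$View); ir <- unlist(bi$Rest)
  mu <- colMeans(roi_series[iu, , drop = FALSE])
  mv <- colMeans(roi_series[iv, , drop = FALSE])
  mr <- colMeans(roi_series[ir, , drop = FALSE])
  defined <- mv != 0 & mr != 0
  data.frame(
    roi = colnames(roi_series) %||% paste0("roi", seq_along(mu)),
    psc_up_view = ifelse(defined, 100 * (mu - mv) / mv, NA_real_),
    psc_up_rest = ifelse(defined, 100 * (mu - mr) / mr, NA_real_),
    defined = defined, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROI-mean series of activated voxels
#'
#' Averages, per volume, the voxels of a 4-D array that lie inside an ROI
#' label and inside an activation mask (e.g. the surviving-cluster map of
#' [cluster_correct()]). ROIs with no activated voxel are flagged.
#'
#' @param vol4d 4-D array.
#' @param roi_labels integer 3-D array of ROI labels (0 = outside).
#' @param active_mask logical/integer 3-D array of activated voxels
#'   (default: all voxels).
#' @return list with `series` (matrix volumes x ROIs, NA columns where
#'   empty) and `n_voxels` per ROI.
#' @export
roi_mean_series <- function(vol4d, roi_labels, active_mask = NULL) {
  d <- dim(vol4d)
  if (is.null(active_mask)) active_mask <- array(TRUE, d[1:3])
  rois <- sort(unique(roi_labels[roi_labels > 0]))
  y <- matrix(vol4d, prod(d[1:3]), d[4])
  out <- sapply(rois, function(r) {
    sel <- which(roi_labels == r & active_mask > 0)
    if (!length(sel)) return(rep(NA_real_, d[4]))
    colMeans(y[sel, , drop = FALSE])
  })
  colnames(out) <- paste0("roi", rois)
  list(series = out,
       n_voxels = vapply(rois, function(r) sum(roi_labels == r & active_mask > 0), 0L))
}

#' Group ROI effect sizes with FDR control
#'
#' Per ROI: one-sample t of the per-subject PSC values against 0 within each
#' group with pooled-SD Cohen's d (`mean / sd`), a two-sample pooled t
#' between groups, and Benjamini-Hochberg FDR over the ROI family for both
#' the within-experimental-group and the between-group tests.
#'
#' @param psc data.frame with columns `roi`, `subject`, `group`, and a PSC
#'   column named by `value`.
#' @param value name of the PSC column (default `"psc_up_view"`).
#' @param q FDR level (default 0.05).
#' @param family_size FDR family size; defaults to the number of ROIs.
#' @return data.frame per ROI: n per group, within-group t/df/p/d,
#'   between-group t/df/p, q values and decisions.
#' @export
roi_effect_sizes <- function(psc, value = "psc_up_view", q = 0.05,
                             family_size = NULL) {
  stopifnot(all(c("roi", "subject", "group", value) %in% names(psc)))
  groups <- sort(unique(psc$group))
  stopifnot(length(groups) == 2)
  # within-group statistics describe the experimental (real-feedback) group
  g1 <- if ("experimental" %in% groups) "experimental" else groups[1]
  g2 <- setdiff(groups, g1)
  rows <- lapply(split(psc, psc$roi), function(s) {
    a <- s[[value]][s$group == g1]
    b <- s[[value]][s$group == g2]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(roi = s$roi[1], n1 = length(a), n2 = length(b),
                        t_within = NA, df_within = NA, p_within = NA, d = NA,
                        t_between = NA, df_between = NA, p_between = NA))
    tw <- mean(a) / (stats::sd(a) / sqrt(length(a)))
    dfw <- length(a) - 1
    tb <- two_sample_t(a, b)
    data.frame(roi = s$roi[1], n1 = length(a), n2 = length(b),
               t_within = tw, df_within = dfw,
               p_within = 2 * stats::pt(-abs(tw), dfw),
               d = mean(a) / stats::sd(a),
               t_between = tb$statistic, df_between = tb$df, p_between = tb$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- family_size %||% nrow(out)
  pad <- function(p) c(p, rep(1, max(0, m - length(p))))
  ok <- is.finite(out$p_within)
  fw <- bh_fdr(pad(out$p_within[ok]), q)
  fb <- bh_fdr(pad(out$p_between[ok]), q)
  out$q_within <- out$q_between <- NA_real_
  out$sig_within <- out$sig_between <- NA
  out$q_within[ok] <- fw$q_values[seq_len(sum(ok))]
  out$sig_within[ok] <- fw$reject[seq_len(sum(ok))]
  out$q_between[ok] <- fb$q_values[seq_len(sum(ok))]
  out$sig_between[ok] <- fb$reject[seq_len(sum(ok))]
  out
}
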