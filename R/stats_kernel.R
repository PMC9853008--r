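# Shared statistical kernel. Textbook estimators implemented explicitly so
# the reported degrees of freedom match the published design counts exactly:
# paired df = n-1, pooled two-sample df = n1+n2-2, one-way error df = N-k.

new_test_result <- function(name, statistic, df, p, ...) {
  structure(list(test = name, statistic = unname(statistic), df = unname(df),
                 p = unname(p), ...), class = "nf_test")
}

#' @export
print.nf_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.3g\n",
              x$test, x$statistic, dfs, x$p))
  invisible(x)
}

#' Paired t test
#'
#' @param before,after numeric vectors of equal length (paired scores).
#' @return `nf_test` with fields `statistic`, `df` (= n-1), `p` (two-sided).
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after))
  d <- after - before
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero variance of paired differences")
  t <- mean(d) / (sd_d / sqrt(n))
  new_test_result("paired t", t, n - 1, 2 * stats::pt(-abs(t), n - 1))
}

#' Two-sample pooled-variance t test
#'
#' Classical pooled-variance (not Welch) test, so df = n1 + n2 - 2 as in the
#' published group comparisons (e.g. 180 + 140 - 2 = 318).
#'
#' @param a,b numeric vectors.
#' @return `nf_test`.
#' @export
two_sample_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per sample")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 == 0) stop("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  new_test_result("two-sample t (pooled)", t, df, 2 * stats::pt(-abs(t), df))
}

#' One-way (between) ANOVA
#'
#' Pooled one-way F across condition groups; error df = N - k. This is the
#' "reproduction mode" used for the omnibus asymmetry statistics (error df
#' 537 for 3 x 180 run-block values).
#'
#' @param groups list of numeric vectors, one per condition.
#' @return `nf_test` with `df = c(k-1, N-k)`.
#' @export
oneway_anova <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs >= 2 observations")
  N <- sum(n)
  gm <- mean(unlist(groups))
  ss_b <- sum(n * (vapply(groups, mean, 0) - gm)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ss_w == 0) stop("zero within-group variance")
  df1 <- k - 1; df2 <- N - k
  f <- (ss_b / df1) / (ss_w / df2)
  new_test_result("one-way ANOVA", f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Classical repeated-measures ANOVA
#'
#' One within factor (columns = conditions, rows = subjects/units); F =
#' MS(condition) / MS(condition x subject), df = (k-1, (k-1)(n-1)). Provided
#' alongside [oneway_anova()] because the published omnibus statistic labels
#' the analysis repeated-measures but prints pooled one-way df.
#'
#' @param m numeric matrix, units x conditions.
#' @return `nf_test`.
#' @export
rm_anova <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2, k >= 2)
  gm <- mean(m)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_err <= 0) stop("degenerate error sum of squares")
  f <- (ss_cond / df1) / (ss_err / df2)
  new_test_result("repeated-measures ANOVA", f, c(df1, df2),
                  stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the standardized sample against the standard
#' normal CDF: `D = sup_x |ECDF(x) - Phi((x - mean)/sd)|`, with the
#' asymptotic Kolmogorov p value. Parameters are estimated from the sample
#' (as in common practice), so the p value is approximate and intended as a
#' screening check, matching its published use.
#'
#' @param x numeric vector, n >= 4.
#' @return `nf_test` with the D statistic (df = n).
#' @export
ks_normality <- function(x) {
  n <- length(x)
  stopifnot(n >= 4)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance")
  z <- sort((x - mean(x)) / s)
  cdf <- stats::pnorm(z)
  d_plus <- max(seq_len(n) / n - cdf)
  d_minus <- max(cdf - (seq_len(n) - 1) / n)
  d <- max(d_plus, d_minus)
  # asymptotic Kolmogorov tail
  t <- sqrt(n) * d
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  new_test_result("Kolmogorov-Smirnov normality", d, n, min(max(p, 0), 1))
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Given m p values, finds the largest k with `p_(k) <= k/m * q` and rejects
#' the k smallest hypotheses; also returns BH-adjusted q values (monotone
#' step-up adjustment).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param q target FDR level (default 0.05).
#' @return list with `reject` (logical, original order), `q_values`
#'   (adjusted), `k` (number of rejections), `q`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)$reject
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  thresh <- seq_len(m) / m * q
  below <- which(ps <= thresh)
  k <- if (length(below)) max(below) else 0L
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  qv <- ps * m / seq_len(m)
  qv <- rev(cummin(rev(qv)))
  qv <- pmin(qv, 1)
  q_values <- numeric(m)
  q_values[ord] <- qv
  list(reject = reject, q_values = q_values, k = k, q = q)
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' Effect size of a before/after change computed from summary statistics:
#' `d = (m2 - m1) / sqrt((s1^2 + s2^2) / 2)`. In `printed` mode the value is
#' truncated toward zero at `digits` decimals, which is the convention that
#' reproduces every published psychometric effect size from its printed
#' means/SDs (rounding would not: e.g. -1.2766 prints as -1.27, not -1.28).
#'
#' @param m1,s1 mean and SD before.
#' @param m2,s2 mean and SD after.
#' @param mode `"full"` (exact value) or `"printed"` (truncated).
#' @param digits decimals used in printed mode (default 2).
#' @return list with `d` (per `mode`), `d_full`, `convention`.
#' @examples
#' cohens_d_pooled(24.6, 10.9, 17, 6.9, mode = "printed")$d  # -0.83
#' @export
cohens_d_pooled <- function(m1, s1, m2, s2, mode = c("full", "printed"),
                            digits = 2) {
  mode <- match.arg(mode)
  stopifnot(s1 > 0, s2 > 0)
  d <- (m2 - m1) / sqrt((s1^2 + s2^2) / 2)
  out <- d
  if (mode == "printed") out <- trunc(d * 10^digits) / 10^digits
  list(d = out, d_full = d, convention = "pooled-sd")
}

#' Cohen's d from two samples (pooled SD)
#'
#' @param a,b numeric vectors (e.g. before and after scores).
#' @return numeric d.
#' @export
cohens_d_samples <- function(a, b) {
  s1 <- stats::sd(a); s2 <- stats::sd(b)
  if (s1 == 0 && s2 == 0) {
    if (mean(a) == mean(b)) return(0)       # identical degenerate samples
    stop("zero variance with unequal means: d undefined")
  }
  cohens_d_pooled(mean(a), max(s1, 1e-300), mean(b), max(s2, 1e-300))$d
}

#' Pre/post psychometric analysis
#'
#' For each scale and group: paired t on before vs after and pooled-SD
#' Cohen's d; between groups: two-sample pooled t on the change scores
#' (after - before), giving df = n1 + n2 - 2 (30 for 18 + 14 subjects).
#'
#' @param scores data.frame with columns `subject`, `group`, `scale`,
#'   `before`, `after`. Incomplete pairs are dropped with a warning.
#' @return list with `within` (data.frame: scale, group, n, t, df, p, d) and
#'   `between` (data.frame: scale, t, df, p).
#' @export
psych_report <- function(scores) {
  need <- c("subject", "group", "scale", "before", "after")
  stopifnot(all(need %in% names(scores)))
  ok <- stats::complete.cases(scores[, c("before", "after")])
  if (!all(ok)) {
    warning(sprintf("dropping %d incomplete pairs", sum(!ok)))
    scores <- scores[ok, ]
  }
  within <- do.call(rbind, lapply(split(scores, scores[, c("scale", "group")], drop = TRUE),
    function(s) {
      # identical before/after tables: d = 0 and no rejection rather than a
      # zero-variance error
      tt <- tryCatch(paired_t(s$before, s$after),
                     error = function(e) list(statistic = NA_real_,
                                              df = nrow(s) - 1, p = 1))
      data.frame(scale = s$scale[1], group = s$group[1], n = nrow(s),
                 t = tt$statistic, df = tt$df, p = tt$p,
                 d = cohens_d_samples(s$before, s$after),
                 stringsAsFactors = FALSE)
    }))
  rownames(within) <- NULL
  groups <- sort(unique(scores$group))
  between <- NULL
  if (length(groups) == 2) {
    between <- do.call(rbind, lapply(split(scores, scores$scale), function(s) {
      ch <- s$after - s$before
      a <- ch[s$group == groups[1]]
      b <- ch[s$group == groups[2]]
      tt <- tryCatch(two_sample_t(a, b),
                     error = function(e) list(statistic = NA_real_,
                                              df = length(a) + length(b) - 2,
                                              p = 1))
      data.frame(scale = s$scale[1], t = tt$statistic, df = tt$df, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
    rownames(between) <- NULL
  }
  list(within = within, between = between)
}
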