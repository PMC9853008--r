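# Blockwise ROI functional connectivity: zero-lag Pearson correlation per
# unordered ROI pair per block per run (with the first-4-s Upregulation
# trim), Fisher z variance stabilization, per-edge condition and group
# tests with BH-FDR at q over the 703-edge family (38 ROIs), and
# differential-network extraction.

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

edge_index <- function(p) {
  ij <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' Blockwise Pearson correlations of ROI series
#'
#' For each run and each block (Rest, View, Upregulation with the first two
#' volumes trimmed), the Pearson correlation of every unordered ROI pair
#' over the block's volumes, with Fisher z alongside. Segments where either
#' series has zero variance yield an undefined (NA) edge for that segment.
#'
#' @param roi_series matrix `n_volumes x n_rois` (column names = ROI
#'   names), e.g. from [simulate_roi_bold()] or [roi_mean_series()].
#' @param schedule an `nf_schedule`.
#' @param trim_up_volumes leading Upregulation volumes dropped (default 2).
#' @return data.frame: `run`, `block`, `roi_i`, `roi_j`, `r`, `z`.
#' @export
blockwise_correlations <- function(roi_series, schedule, trim_up_volumes = 2) {
  roi_series <- as.matrix(roi_series)
  p <- ncol(roi_series)
  rois <- colnames(roi_series) %||% paste0("roi", seq_len(p))
  bi <- block_volume_indices(schedule, trim_up_volumes)
  ij <- edge_index(p)
  out <- list()
  for (lb in names(bi)) for (r in seq_len(schedule$n_runs)) {
    idx <- bi[[lb]][[r]]
    if (length(idx) < 3) next
    seg <- roi_series[idx, , drop = FALSE]
    sds <- apply(seg, 2, stats::sd)
    C <- suppressWarnings(stats::cor(seg))
    rv <- C[ij]
    rv[sds[ij[, 1]] == 0 | sds[ij[, 2]] == 0] <- NA_real_
    out[[paste(lb, r)]] <- data.frame(
      run = r, block = lb, roi_i = rois[ij[, 1]], roi_j = rois[ij[, 2]],
      r = rv, z = fisher_z(rv), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort-level blockwise correlations
#'
#' @param cohort an `nf_cohort`.
#' @param ... passed to [blockwise_correlations()].
#' @return stacked data.frame with `subject` and `group` columns.
#' @export
cohort_blockwise_correlations <- function(cohort, ...) {
  do.call(rbind, lapply(seq_len(nrow(cohort$subjects)), function(i) {
    id <- cohort$subjects$id[i]
    bc <- blockwise_correlations(cohort_roi(cohort, id),
                                 cohort$spec$schedule, ...)
    bc$subject <- id
    bc$group <- cohort$subjects$group[i]
    bc
  }))
}

#' Per-edge condition and group tests with FDR
#'
#' For every unordered ROI pair: a paired t test of `z(Up) - z(View)` over
#' the experimental group's run-blocks (df = n_runblocks - 1 = 179 with 18
#' subjects x 10 runs), a pooled two-sample t of those run-block
#' differences between groups (df = 318 with 180 vs 140), and
#' Benjamini-Hochberg FDR at level `q` within each family (703 edges for
#' 38 ROIs). An edge survives when significant in BOTH families, the
#' conjunction that attributes the connectivity change to the
#' neurofeedback. Run-blocks with an undefined correlation in either
#' condition are excluded for that edge, not imputed.
#'
#' @param bc data.frame from [cohort_blockwise_correlations()] (must have
#'   `subject`, `group`, `run`, `block`, `roi_i`, `roi_j`, `z`).
#' @param q FDR level (default 0.05).
#' @return data.frame of class `nf_edge_stats`, one row per edge:
#'   mean z difference per group, condition t/df/p/q, group t/df/p/q,
#'   `sig_condition`, `sig_group`, `survives`, `weight` (group contrast of
#'   mean z differences).
#' @export
edge_condition_tests <- function(bc, q = 0.05) {
  need <- c("subject", "group", "run", "block", "roi_i", "roi_j", "z")
  stopifnot(all(need %in% names(bc)))
  bc <- bc[bc$block %in% c("Upregulation", "View"), ]
  key <- paste(bc$subject, bc$run, bc$roi_i, bc$roi_j, sep = "\r")
  up <- bc[bc$block == "Upregulation", ]
  vw <- bc[bc$block == "View", ]
  kv <- paste(vw$subject, vw$run, vw$roi_i, vw$roi_j, sep = "\r")
  ku <- paste(up$subject, up$run, up$roi_i, up$roi_j, sep = "\r")
  m <- match(ku, kv)
  dz <- data.frame(subject = up$subject, group = up$group, run = up$run,
                   roi_i = up$roi_i, roi_j = up$roi_j,
                   dz = up$z - vw$z[m], stringsAsFactors = FALSE)
  dz <- dz[is.finite(dz$dz), ]

  ekey <- factor(paste(dz$roi_i, dz$roi_j, sep = "\r"))
  lev <- levels(ekey)
  parts <- do.call(rbind, strsplit(lev, "\r", fixed = TRUE))

  moments <- function(sel) {
    k <- ekey[sel]
    n <- as.numeric(rowsum(rep(1, sum(sel)), k)[lev, 1])
    n[is.na(n)] <- 0
    s1 <- rep(NA_real_, length(lev)); s2 <- s1
    agg1 <- rowsum(dz$dz[sel], k); agg2 <- rowsum(dz$dz[sel]^2, k)
    s1[match(rownames(agg1), lev)] <- agg1[, 1]
    s2[match(rownames(agg2), lev)] <- agg2[, 1]
    mean_ <- ifelse(n > 0, s1 / n, NA_real_)
    var_ <- ifelse(n > 1, (s2 - n * mean_^2) / (n - 1), NA_real_)
    var_ <- pmax(var_, 0)
    list(n = n, mean = mean_, var = var_)
  }
  me <- moments(dz$group == "experimental")
  mc <- moments(dz$group == "control")

  t_c <- ifelse(me$n >= 2 & me$var > 0,
                me$mean / sqrt(me$var / me$n), NA_real_)
  df_c <- ifelse(me$n >= 2, me$n - 1, NA_real_)
  p_c <- 2 * stats::pt(-abs(t_c), df_c)

  df_g <- ifelse(me$n >= 2 & mc$n >= 2, me$n + mc$n - 2, NA_real_)
  sp2 <- ((me$n - 1) * me$var + (mc$n - 1) * mc$var) / df_g
  t_g <- ifelse(is.finite(df_g) & sp2 > 0,
                (me$mean - mc$mean) / sqrt(sp2 * (1 / me$n + 1 / mc$n)),
                NA_real_)
  p_g <- 2 * stats::pt(-abs(t_g), df_g)

  out <- data.frame(roi_i = parts[, 1], roi_j = parts[, 2],
                    n_exp = me$n, n_ctl = mc$n,
                    dz_exp = me$mean, dz_ctl = mc$mean,
                    t_condition = t_c, df_condition = df_c, p_condition = p_c,
                    t_group = t_g, df_group = df_g, p_group = p_g,
                    stringsAsFactors = FALSE)
  out <- out[order(out$roi_i, out$roi_j), ]
  rownames(out) <- NULL
  okc <- is.finite(out$p_condition)
  okg <- is.finite(out$p_group)
  out$q_condition <- out$q_group <- NA_real_
  out$sig_condition <- out$sig_group <- FALSE
  if (any(okc)) {
    f <- bh_fdr(out$p_condition[okc], q)
    out$q_condition[okc] <- f$q_values
    out$sig_condition[okc] <- f$reject
  }
  if (any(okg)) {
    f <- bh_fdr(out$p_group[okg], q)
    out$q_group[okg] <- f$q_values
    out$sig_group[okg] <- f$reject
  }
  out$survives <- out$sig_condition & out$sig_group
  out$weight <- out$dz_exp - ifelse(is.na(out$dz_ctl), 0, out$dz_ctl)
  class(out) <- c("nf_edge_stats", "data.frame")
  attr(out, "q") <- q
  out
}

#' Differential connectivity network
#'
#' Extracts the surviving edges of an [edge_condition_tests()] table as a
#' graph: nodes, weighted edge list (weight = group contrast of mean
#' Fisher-z Upregulation-minus-View differences), deterministic edge
#' ordering. An empty network is a valid result.
#'
#' @param stats an `nf_edge_stats` table.
#' @param nodes optional full node list (defaults to all ROIs in the table).
#' @return list of class `nf_network`: `nodes`, `edges` (data.frame
#'   `roi_i`, `roi_j`, `weight`), `q`.
#' @export
differential_network <- function(stats, nodes = NULL) {
  stopifnot(inherits(stats, "nf_edge_stats"))
  ed <- as.data.frame(stats)[stats$survives %in% TRUE,
                             c("roi_i", "roi_j", "weight")]
  ed <- ed[order(ed$roi_i, ed$roi_j), ]
  rownames(ed) <- NULL
  structure(list(nodes = nodes %||% sort(unique(c(stats$roi_i, stats$roi_j))),
                 edges = ed, q = attr(stats, "q")),
            class = "nf_network")
}

#' @export
print.nf_network <- function(x, ...) {
  cat(sprintf("nf_network: %d nodes, %d significant edges (q = %g)\n",
              length(x$nodes), nrow(x$edges), x$q))
  invisible(x)
}

#' Write / read a differential network
#'
#' TSV edge list plus a JSON graph document (nodes, edges, q); the round
#' trip through `read_network()` is exact.
#'
#' @param network an `nf_network`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return `read_network()` returns the `nf_network`.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(nodes = network$nodes, edges = network$edges,
                            q = network$q),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- as.data.frame(g$edges, stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(roi_i = character(0), roi_j = character(0),
                        weight = numeric(0))
  structure(list(nodes = g$nodes, edges = edges, q = g$q),
            class = "nf_network")
}

#' Connectivity distributions over significant edges
#'
#' Pools the blockwise correlations of the surviving edges per condition
#' (Upregulation vs View), summarizes them (mean, quantiles), and tests
#' the location shift with a pooled two-sample t.
#'
#' @param bc blockwise correlation table (with `block`, `roi_i`, `roi_j`,
#'   `r`; typically the experimental group's rows).
#' @param network an `nf_network` (its edges define the pooled set).
#' @return list: `summary` data.frame per condition, `shift`
#'   (`nf_test` or NULL when a side is degenerate), `values` (the pooled
#'   r values per condition).
#' @export
connectivity_distributions <- function(bc, network) {
  ed <- network$edges
  if (!nrow(ed))
    return(list(summary = data.frame(), shift = NULL,
                values = list(Upregulation = numeric(0), View = numeric(0))))
  keys <- paste(bc$roi_i, bc$roi_j)
  sel <- keys %in% paste(ed$roi_i, ed$roi_j)
  vals <- lapply(c(Upregulation = "Upregulation", View = "View"), function(b)
    bc$r[sel & bc$block == b & is.finite(bc$r)])
  summ <- do.call(rbind, lapply(names(vals), function(b) {
    v <- vals[[b]]
    data.frame(block = b, n = length(v), mean_r = mean(v),
               q25 = stats::quantile(v, 0.25), median = stats::median(v),
               q75 = stats::quantile(v, 0.75), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  shift <- NULL
  if (all(lengths(vals) >= 2) &&
      stats::sd(vals$Upregulation) > 0 && stats::sd(vals$View) > 0)
    shift <- two_sample_t(vals$Upregulation, vals$View)
  list(summary = summ, shift = shift, values = vals)
}
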