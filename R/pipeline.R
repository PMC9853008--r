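# End-to-end orchestration: simulate a two-group cohort, run the feedback
# engine, the EEG group statistics, the ROI percent-signal-change and
# effect-size analysis, the differential-connectivity network and the
# psychometric report, and write a reproducible report bundle.

#' Default pipeline configuration
#'
#' Nested list mirroring the analysis defaults: the paradigm (10 runs,
#' 20/40/60 s blocks + 10 s buffer, TR 2 s, EEG 250 Hz), the cohort
#' (18 + 14 subjects, planted asymmetry 0.3, published ROI effects and
#' differential edges), and the analysis thresholds (voxel p 0.01, cluster
#' p 0.01, q 0.05, alpha band 8-12 Hz).
#'
#' @param master_seed master seed (default 1).
#' @return nested config list.
#' @export
default_config <- function(master_seed = 1) {
  list(
    paradigm = list(n_runs = 10, rest_s = 20, view_s = 40, up_s = 60,
                    buffer_s = 10, tr = 2, eeg_rate = 250),
    cohort = list(n_experimental = 18, n_control = 14, asym_effect = 0.3,
                  delta_r = 0.3, base_corr = 0.2, ar1 = 0.3, noise_sd = 1,
                  master_seed = master_seed),
    analysis = list(voxel_p = 0.01, cluster_p = 0.01, q = 0.05,
                    band = c(8, 12)),
    voxel = list(enabled = FALSE, grid = c(16, 16, 8), psc = 2,
                 n_perm = 200))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return config list.
#' @export
read_config <- function(path) {
  ov <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (sec in names(ov)) {
    if (!sec %in% names(cfg))
      stop("config validation error: unknown section '", sec, "'")
    for (k in names(ov[[sec]])) {
      if (!k %in% names(cfg[[sec]]))
        stop("config validation error: unknown field '", sec, ".", k, "'")
      cfg[[sec]][[k]] <- ov[[sec]][[k]]
    }
  }
  cfg
}

validate_config <- function(cfg) {
  bad <- character(0)
  for (f in c("voxel_p", "cluster_p", "q"))
    if (!(cfg$analysis[[f]] > 0 && cfg$analysis[[f]] < 1))
      bad <- c(bad, paste0("analysis.", f))
  if (cfg$paradigm$tr <= 0) bad <- c(bad, "paradigm.tr")
  if (cfg$paradigm$eeg_rate <= 0) bad <- c(bad, "paradigm.eeg_rate")
  if (cfg$cohort$n_experimental < 1) bad <- c(bad, "cohort.n_experimental")
  if (cfg$cohort$n_control < 1) bad <- c(bad, "cohort.n_control")
  if (length(bad))
    stop("config validation error in fields: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] stage %s: %s",
                  format(Sys.time(), "%H:%M:%S"), stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> feedback -> EEG statistics -> ROI percent signal
#' change and effect sizes -> differential connectivity -> psychometrics
#' on a synthetic cohort defined by `config`, writing TSV/JSON outputs and
#' a manifest (seeds, config, package version) under `out_dir`. Stage
#' failures halt with an error naming the stage. Identical config and
#' seeds yield identical outputs.
#'
#' @param config nested list as from [default_config()] / [read_config()].
#' @param out_dir output directory (default: not written).
#' @return report list: `cohort` sizes, `feedback` (per-group mean bar),
#'   `eeg` ([asymmetry_group_stats()] output), `roi` (effect-size table),
#'   `network` (`nf_network`), `connectivity_shift`, `psych`
#'   ([psych_report()] output), `voxel` (optional cluster results),
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  pg <- config$paradigm
  schedule <- build_schedule(pg$n_runs, pg$rest_s, pg$view_s, pg$up_s,
                             pg$buffer_s, pg$tr, pg$eeg_rate)
  ch <- config$cohort
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  stage_msg("simulate", "cohort %d+%d, master seed %d",
            ch$n_experimental, ch$n_control, ch$master_seed)
  cohort <- run_stage("simulate", simulate_cohort(cohort_spec(
    schedule = schedule, n_experimental = ch$n_experimental,
    n_control = ch$n_control,
    eeg = eeg_sim_params(asym_effect = ch$asym_effect,
                         alpha_band = config$analysis$band),
    delta_edges = default_delta_edges(ch$delta_r),
    base_corr = ch$base_corr, ar1 = ch$ar1, noise_sd = ch$noise_sd,
    master_seed = ch$master_seed)))

  stage_msg("feedback", "closed loop per subject")
  feedback <- run_stage("feedback", {
    per_sub <- vapply(seq_len(nrow(cohort$subjects)), function(i) {
      id <- cohort$subjects$id[i]
      if (cohort$subjects$group[i] == "experimental") {
        tr <- run_closed_loop(cohort_eeg(cohort, id), schedule, "real",
                              band = config$analysis$band)
      } else {
        tr <- run_closed_loop(NULL, schedule, "sham",
                              seed = derive_seed(cohort$subjects$seed[i], 303))
      }
      mean(tr$bar)
    }, 0)
    data.frame(subject = cohort$subjects$id, group = cohort$subjects$group,
               mean_bar = per_sub, stringsAsFactors = FALSE)
  })

  stage_msg("eeg", "block asymmetry + group statistics")
  eeg <- run_stage("eeg", {
    tab <- cohort_block_asymmetry(cohort, band = config$analysis$band)
    list(table = tab, stats = asymmetry_group_stats(tab, q = config$analysis$q))
  })

  stage_msg("roi", "percent signal change + effect sizes")
  roi <- run_stage("roi", {
    psc <- do.call(rbind, lapply(cohort$subjects$id, function(id) {
      r <- roi_percent_signal_change(cohort_roi(cohort, id), schedule)
      r$subject <- id
      r$group <- cohort$subjects$group[cohort$subjects$id == id]
      r
    }))
    list(psc = psc,
         effects = roi_effect_sizes(psc, q = config$analysis$q))
  })

  stage_msg("connectivity", "blockwise correlations + differential network")
  conn <- run_stage("connectivity", {
    bc <- cohort_blockwise_correlations(cohort)
    st <- edge_condition_tests(bc, q = config$analysis$q)
    nw <- differential_network(st, nodes = cohort$spec$roi$roi)
    dist <- connectivity_distributions(bc[bc$group == "experimental", ], nw)
    list(stats = st, network = nw, distributions = dist)
  })

  stage_msg("psych", "pre/post scores")
  psych <- run_stage("psych", psych_report(cohort$psych))

  voxel <- NULL
  if (isTRUE(config$voxel$enabled)) {
    stage_msg("voxel", "GLM + permutation cluster correction")
    voxel <- run_stage("voxel", {
      g <- config$voxel$grid
      vol <- simulate_voxel_bold(
        g, list(list(voxels = cluster_cube(round(g / 2)), psc = config$voxel$psc)),
        schedule, seed = derive_seed(ch$master_seed, 404))
      cluster_correct(vol, schedule, "Up>Rest",
                      voxel_p = config$analysis$voxel_p,
                      cluster_p = config$analysis$cluster_p,
                      n_perm = config$voxel$n_perm,
                      seed = derive_seed(ch$master_seed, 505))
    })
  }

  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("nfalpha")),
                   subjects = cohort$subjects)
  report <- list(cohort = list(n_experimental = ch$n_experimental,
                               n_control = ch$n_control),
                 feedback = feedback, eeg = eeg, roi = roi,
                 network = conn$network, connectivity = conn,
                 psych = psych, voxel = voxel, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(feedback, "feedback_summary.tsv")
    wt(eeg$table, "block_asymmetry.tsv")
    wt(eeg$stats$between, "asymmetry_group_tests.tsv")
    wt(roi$effects, "roi_effects.tsv")
    wt(as.data.frame(conn$stats), "edge_stats.tsv")
    write_network(conn$network, file.path(out_dir, "differential_network"))
    wt(psych$within, "psych_within.tsv")
    wt(psych$between, "psych_between.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
  }
  report
}
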