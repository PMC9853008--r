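# Published summary tables used as generator defaults and reproduction
# inputs. These are inputs to the synthetic-data generators (the planted
# ground truth), not outputs of any analysis here.

#' Default ROI percent-signal-change effect table
#'
#' The 38 regions of the functional-connectivity analysis (19 bilateral
#' pairs) with the reported percent signal change of Upregulation vs View
#' and vs Rest, the ROI t score and Cohen's d for the experimental group.
#' Four right-hemisphere regions were not reported as significantly active
#' (right lingual gyrus, right posterior cingulate, right supramarginal,
#' right postcentral); they carry 0 effects but remain network nodes.
#'
#' @return data.frame with columns `roi`, `psc_up_view`, `psc_up_rest`,
#'   `t_up_view`, `d_up_view`.
#' @export
roi_effect_table <- function() {
  tab <- read.delim(text = "roi\tpsc_up_view\tpsc_up_rest\tt_up_view\td_up_view
L_amygdala\t0.86\t0.70\t4.9\t0.87
R_amygdala\t0.65\t0.72\t3.9\t0.70
L_insula\t1\t0.64\t7.7\t0.85
R_insula\t0.91\t0.62\t6.4\t0.88
L_ACC\t0.97\t0.81\t4.2\t0.95
R_ACC\t0.64\t0.38\t4.4\t0.86
L_cuneus\t0.45\t1.56\t4.5\t0.61
R_cuneus\t0.40\t1.90\t3.9\t0.75
L_lingual\t1.21\t1.39\t4.2\t0.83
R_lingual\t0\t0\tNA\tNA
L_PCC\t0.49\t0.33\t5\t0.66
R_PCC\t0\t0\tNA\tNA
L_thalamus\t1.07\t0.85\t4.9\t0.93
R_thalamus\t0.86\t0.65\t6.9\t0.90
L_caudate\t0.86\t0.65\t5.7\t0.80
R_caudate\t0.74\t0.49\t8\t0.80
L_hippocampus\t0.57\t0.56\t4.3\t0.85
R_hippocampus\t0.44\t0.59\t4.2\t0.80
L_DMPFC\t0.85\t1.02\t5.1\t0.99
R_DMPFC\t0.37\t0.81\t4.1\t0.89
L_OFC\t1.13\t1.04\t6\t1
R_OFC\t1.12\t0.81\t6.5\t0.85
L_MTG\t0.66\t0.59\t5.9\t0.87
R_MTG\t0.69\t0.70\t5.9\t0.70
L_ventral_striatum\t1.17\t0.84\t6.1\t1.03
R_ventral_striatum\t0.81\t0.66\t7.7\t0.65
L_VLPFC\t0.67\t0.81\t5.6\t0.82
R_VLPFC\t0.65\t0.58\t9.3\t0.60
L_DLPFC\t0.84\t0.90\t5.3\t0.97
R_DLPFC\t0.76\t0.75\t6.7\t0.88
L_superior_parietal\t0.46\t0.69\t4.9\t0.81
R_superior_parietal\t0.33\t0.89\t5.3\t0.57
L_inferior_parietal\t0.60\t0.41\t5.9\t0.85
R_inferior_parietal\t1.32\t0.53\t4.2\t1.01
L_supramarginal\t0.87\t0.42\t8.1\t1.04
R_supramarginal\t0\t0\tNA\tNA
L_postcentral\t0.67\t0.56\t6.8\t0.88
R_postcentral\t0\t0\tNA\tNA
", stringsAsFactors = FALSE)
  tab
}

#' Published psychometric summary (pre/post means, SDs, effect sizes)
#'
#' Scale-level summary statistics for the five mood scales in both groups:
#' mean +/- SD before and after the neurofeedback session, the printed
#' pooled-SD Cohen's d and the number of decimals it was printed with.
#' Used (a) as generating parameters for [simulate_psychometrics()] and
#' (b) as the input from which [cohens_d_pooled()] reproduces every printed
#' effect size.
#'
#' @return data.frame with columns `scale`, `group`, `mean_before`,
#'   `sd_before`, `mean_after`, `sd_after`, `d_printed`, `digits`.
#' @export
psych_summary_table <- function() {
  read.delim(text = "scale\tgroup\tmean_before\tsd_before\tmean_after\tsd_after\td_printed\tdigits
PANAS\texperimental\t52.2\t11.5\t51.6\t8.8\t-0.058\t3
PANAS\tcontrol\t54.2\t5.9\t53\t4.8\t-0.22\t2
PANAS_negative\texperimental\t20.8\t7.2\t14.1\t4.8\t-1.09\t2
PANAS_negative\tcontrol\t22.1\t6\t19.3\t5\t-0.50\t2
PANAS_positive\texperimental\t31.4\t6.1\t37.5\t6.4\t0.97\t2
PANAS_positive\tcontrol\t32.1\t5.7\t33.7\t5.6\t0.28\t2
POMS\texperimental\t24.6\t10.9\t17\t6.9\t-0.83\t2
POMS\tcontrol\t27.1\t11.3\t22.8\t11.1\t-0.38\t2
TMD\texperimental\t7.5\t11.5\t-4.7\t7.1\t-1.27\t2
TMD\tcontrol\t6.6\t11.2\t3.6\t11.7\t-0.26\t2
", stringsAsFactors = FALSE)
}

#' Default differential-connectivity edges
#'
#' The ROI pairs reported to gain connectivity during Upregulation relative
#' to View (and relative to the sham group): limbic-limbic, limbic-prefrontal
#' and prefrontal-prefrontal links. Used as the planted `delta_edges` of the
#' synthetic BOLD generator, all with the same correlation increment.
#'
#' @param delta_r correlation increment applied during Upregulation
#'   (default 0.3).
#' @return data.frame with columns `roi_i`, `roi_j`, `delta_r`.
#' @export
default_delta_edges <- function(delta_r = 0.3) {
  pairs <- rbind(
    c("L_amygdala", "L_thalamus"),
    c("L_amygdala", "L_DMPFC"),
    c("L_thalamus", "L_ventral_striatum"),
    c("L_insula",   "L_DMPFC"),
    c("L_thalamus", "L_DMPFC"),
    c("L_thalamus", "L_insula"),
    c("L_thalamus", "L_OFC"),
    c("L_thalamus", "L_VLPFC"),
    c("L_thalamus", "L_postcentral"),
    c("L_DMPFC",    "L_ventral_striatum"),
    c("L_OFC",      "L_VLPFC"))
  data.frame(roi_i = pairs[, 1], roi_j = pairs[, 2], delta_r = delta_r,
             stringsAsFactors = FALSE)
}
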