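#!/usr/bin/env Rscript
# End-to-end run: cohort simulation, imaging-path check, staging, and the
# full statistical battery (descriptives, Kruskal-Wallis + Dunn, ANOVA,
# ROC/Youden for both binary groupings, ICC and Bland-Altman agreement) on
# all patients and on the HBV subgroup separately.
suppressPackageStartupMessages(library(vmre))

run <- run_all(simulation_config(seed = 1), outdir = "results/run")
rep <- run$report

message(sprintf("VMRE inter-reader ICC: %.3f",
                rep$agreement$vmre_readers$icc))
message(sprintf("USE AUC F0-2 vs F3-4 (all): %.2f, cutoff %.2f kPa",
                rep$statistics$all$roc$use_F02_vs_F34$auc,
                rep$statistics$all$roc$use_F02_vs_F34$cutoff))
message(sprintf("VMRE AUC F0-1 vs F2-4 (HBV): %.2f",
                rep$statistics$hbv$roc$vmre_F01_vs_F24$auc))
message(sprintf("staging: %d%% exact, %d%% within one stage",
                rep$staging$all$exact_pct, rep$staging$all$within_one_pct))
message("full report: results/run/report.json")
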