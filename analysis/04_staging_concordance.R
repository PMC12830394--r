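#!/usr/bin/env Rscript
# Stage the reader-averaged virtual-stiffness values against the fixed MRE
# thresholds and summarize concordance with the simulated true stages.
suppressPackageStartupMessages(library(vmre))

cohort <- read_cohort_csv("results/cohort.csv")
v <- combine_readers(cohort$vmre_r1, cohort$vmre_r2)
pred <- classify_stage(v, stage_threshold_table())

summarize <- function(idx, label) {
  cs <- concordance_summary(pred[idx], cohort$stage[idx])
  message(sprintf("%s (n=%d): exact %d (%d%%), within one stage %d (%d%%)",
                  label, cs$n, cs$exact_count, cs$exact_pct,
                  cs$within_one_count, cs$within_one_pct))
  list(n = cs$n, exact_count = cs$exact_count, exact_pct = cs$exact_pct,
       within_one_count = cs$within_one_count,
       within_one_pct = cs$within_one_pct,
       binary = cs$binary)
}
out <- list(all = summarize(seq_len(nrow(cohort)), "all patients"),
            hbv = summarize(cohort$etiology == "HBV", "HBV subgroup"))
jsonlite::write_json(out, "results/staging.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/staging.json")
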