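#!/usr/bin/env Rscript
# Phantom imaging path: for each fibrosis stage, generate a noisy DWI block
# phantom, compute sADC and virtual-stiffness maps, and check how well the
# median reconstructed stiffness recovers the generating stage mean.
suppressPackageStartupMessages(library(vmre))

dir.create("results", showWarnings = FALSE)
cfg <- simulation_config(seed = 2)

rows <- lapply(c("F0", "F1", "F2", "F3", "F4"), function(st) {
  ph <- generate_phantom(cfg, st)
  vm <- sadc_to_vmre(compute_sadc_map(ph$dwi))
  lab <- ph$label == 1
  data.frame(stage = st,
             true_mean_kpa = mean(ph$stiffness[lab]),
             recon_median_kpa = median(vm$values[lab]),
             labeled_voxels = sum(lab))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/phantom_recovery.csv", row.names = FALSE)
print(tab, digits = 4)

# one color-map export for inspection
ph <- generate_phantom(cfg, "F2")
vm <- sadc_to_vmre(compute_sadc_map(ph$dwi))
export_color_map(vm, c(0, 8), out_prefix = "results/vmre_F2",
                 slices = dim(vm$values)[3] %/% 2)
message("wrote results/phantom_recovery.csv and a mid-slice color map")
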