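#!/usr/bin/env Rscript
# Stage 1 — synthetic study generation.
#
# Two ground-truth interaction networks (control and disease strains)
# drive linear expression dynamics across organs; sampled trajectories are
# emitted as replicate-level Ct tables with per-gene offsets, measurement
# noise, one dropped organ/age cell and sporadic missing values.

library(hmfnet)
source("analysis/00_settings.R")

control_model <- generate_network(STUDY$n_organs, STUDY$n_genes,
                                  STUDY$density, STUDY$coeff_scale,
                                  seed = SEED + 1, times = STUDY$times)
n_edges <- sum(control_model$K_true != 0) - length(control_model$nodes)
models <- list(
  control = control_model,
  # the disease strain shares most of the control wiring, with about a
  # third of the interactions rewired and a few signs flipped
  disease = rewire_model(control_model, n_rewire = round(n_edges / 3),
                         n_flip = round(n_edges / 8), seed = SEED + 2)
)

for (strain in c("control", "disease")) {
  model <- models[[strain]]
  truth <- simulate_truth(model)
  ct <- generate_ct_dataset(truth, strain = strain,
                            replicates = STUDY$replicates,
                            noise_sd = STUDY$noise_sd,
                            missing_rate = STUDY$missing_rate,
                            drop_cells = STUDY$drop_cells,
                            seed = SEED + 10 + match(strain, c("control",
                                                               "disease")))
  write_ct_dataset(ct, model, file.path(DATA_DIR,
                                        sprintf("ct_%s.csv", strain)))
  msg("%s: %d nodes, %d true edges, %d Ct rows (%d missing)",
      strain, length(model$nodes),
      sum(model$K_true != 0) - length(model$nodes), nrow(ct),
      sum(is.na(ct$ct)))
}
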