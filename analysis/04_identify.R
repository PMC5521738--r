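#!/usr/bin/env Rscript
# Stage 4 — continuous-time network identification.
#
# For each strain, HMF spectra of the scaled mean profiles are assembled
# into the block regression and solved by elastic net across the
# (m-set, alpha, lambda) grid; candidates are ranked by the
# variance-penalized simulation objective J_sim.

library(hmfnet)
source("analysis/00_settings.R")

profiles <- read.csv(file.path(OUT, "profiles.csv"))
class(profiles) <- c("profile_set", "data.frame")

for (strain in c("control", "disease")) {
  fit <- grid_search_identify(profiles, strain,
                              alpha_grid = IDENTIFY$alpha_grid,
                              n_lambda = IDENTIFY$n_lambda,
                              n_m_sets = IDENTIFY$n_m_sets,
                              keep_models = "all")
  write.csv(fit$fits, file.path(OUT, sprintf("fit_scores_%s.csv", strain)),
            row.names = FALSE)
  write.csv(coefficient_table(fit$best$K),
            file.path(OUT, sprintf("network_%s.csv", strain)),
            row.names = FALSE)
  saveRDS(fit, file.path("scratch", sprintf("fit_%s.rds", strain)))
  msg("%s: best of %d fits at M=%d, alpha=%.1f, lambda=%.2e (J_sim=%.3g, %d edges)",
      strain, nrow(fit$fits), fit$best$M, fit$best$alpha, fit$best$lambda,
      fit$best$j_sim, sum(fit$best$K != 0))
}
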