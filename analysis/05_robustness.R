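#!/usr/bin/env Rscript
# Stage 5 — identification robustness and network topology.
#
# The best fit of each strain is compared against every near-optimal fit
# (J_sim within an order of magnitude): Spearman correlation and sign
# contingency (Fisher's exact test, odds ratio) over coefficients passing
# the two-standard-deviation strength filter in both networks, with BH
# adjustment.  Graph-topology metrics summarize the thresholded networks.

library(hmfnet)
source("analysis/00_settings.R")

metrics_rows <- list()
for (strain in c("control", "disease")) {
  fit <- readRDS(file.path("scratch", sprintf("fit_%s.rds", strain)))
  near <- setdiff(which(fit$fits$j_sim < fit$best$j_sim * 10 &
                          is.finite(fit$fits$j_sim)),
                  which.min(fit$fits$j_sim))
  batch <- compare_network_batch(fit$best$K,
                                 setNames(fit$models[near],
                                          sprintf("fit%03d", near)))
  write.csv(batch, file.path(OUT, sprintf("robustness_%s.csv", strain)),
            row.names = FALSE)
  ok <- batch[batch$comparable, ]
  msg("%s: %d/%d near-optimal fits comparable; min rho %.2f; %d/%d infinite odds ratios",
      strain, nrow(ok), nrow(batch),
      if (nrow(ok)) min(ok$spearman_rho) else NA,
      sum(is.infinite(ok$odds_ratio)), nrow(ok))

  gm <- graph_metrics(fit$best$K)
  metrics_rows[[strain]] <- data.frame(
    strain = strain, n_edges = gm$n_edges,
    avg_path_length = gm$avg_path_length, transitivity = gm$transitivity,
    power_exponent = gm$power_exponent, ks_p = gm$ks_p
  )
  msg("%s topology: %d strong edges, <l> = %.2f, transitivity = %.2f, gamma = %.2f (K-S p = %.2f)",
      strain, gm$n_edges, gm$avg_path_length, gm$transitivity,
      gm$power_exponent, gm$ks_p)
}
write.csv(do.call(rbind, metrics_rows),
          file.path(OUT, "graph_metrics.csv"), row.names = FALSE)
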