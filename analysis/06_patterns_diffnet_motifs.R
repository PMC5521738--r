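#!/usr/bin/env Rscript
# Stage 6 — dynamic patterns, differential rewiring, adaptation motifs.
#
# Scaled profiles are classified into peaks/valleys/monotone trends and
# ordered into cascades; the strain networks are differenced into added /
# removed / switched edges; feed-forward loops of the thresholded disease
# network are enumerated and sign-classified for adaptation capability.

library(hmfnet)
source("analysis/00_settings.R")

profiles <- read.csv(file.path(OUT, "profiles.csv"))
class(profiles) <- c("profile_set", "data.frame")

calls <- classify_profiles(profiles)
write.csv(calls, file.path(OUT, "extremum_calls.csv"), row.names = FALSE)
for (by in c("peak", "valley")) {
  cascade <- order_cascade(calls, by, reference_strain = "disease")
  write.csv(cascade$ordering,
            file.path(OUT, sprintf("cascade_%s.csv", by)),
            row.names = FALSE)
  msg("%s cascade: %d profiles, times %s", by, nrow(cascade$ordering),
      paste(range(cascade$ordering$time), collapse = "-"))
}

fit_d <- readRDS("scratch/fit_disease.rds")
fit_c <- readRDS("scratch/fit_control.rds")
edges <- differential_edges(fit_d$best$K, fit_c$best$K)
write.csv(edges, file.path(OUT, "differential_edges.csv"),
          row.names = FALSE)
if (nrow(edges) > 0) {
  write_sif(edges, file.path(OUT, "differential_edges.sif"))
}
msg("differential network: %s",
    paste(names(table(edges$class)), table(edges$class),
          sep = "=", collapse = ", "))

signed <- threshold_and_scale(fit_d$best$K)$scaled
ffl <- enumerate_ffl(signed)
write.csv(ffl, file.path(OUT, "motifs_ffl.csv"), row.names = FALSE)
msg("feed-forward loops in the disease network: %d total, %d incoherent (adaptation-capable)",
    nrow(ffl), sum(ffl$adaptation_capable))
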