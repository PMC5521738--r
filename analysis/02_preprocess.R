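#!/usr/bin/env Rscript
# Stage 2 — normalization and profile construction.
#
# Raw Ct values are normalized against the per-sample median pseudo
# reference (-ddCt), the pseudo reference's stability is ranked against
# every single-gene candidate, missing values are imputed by k-nearest
# samples within organ, replicates are averaged and profiles min-max
# scaled for identification.

library(hmfnet)
source("analysis/00_settings.R")

ct <- do.call(rbind, lapply(c("control", "disease"), function(st) {
  read.csv(file.path(DATA_DIR, sprintf("ct_%s.csv", st)))
}))
class(ct) <- c("ct_table", "data.frame")

stability <- rank_pseudo_reference(ct)
write.csv(stability, file.path(OUT, "pseudo_reference_stability.csv"),
          row.names = FALSE)
msg("pseudo-reference median rank across %d organ/age cells: %.1f (of %d)",
    nrow(stability), mean(stability$median_rank),
    stability$n_candidates[1])

expr <- impute_missing(normalize_ct(ct), k = 10)
profiles <- scale_profiles(mean_profiles(expr))
write.csv(expr, file.path(OUT, "expression_normalized.csv"),
          row.names = FALSE)
write.csv(profiles, file.path(OUT, "profiles.csv"), row.names = FALSE)
msg("normalized %d measurements into %d profile points",
    nrow(expr), nrow(profiles))
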