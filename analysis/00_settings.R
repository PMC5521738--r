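# Shared settings for the analysis drivers.
#
# The study emulates a two-strain, multi-organ qPCR time course.  The
# compact geometry (3 organs x 8 genes) keeps each driver in the
# minutes range while exercising every stage; the package itself handles
# the full 5 x 22 geometry (110 nodes, 12,100 candidate interactions).

SEED <- 20260925L
OUT <- "results"
DATA_DIR <- file.path(OUT, "data")

STUDY <- list(
  n_organs = 3L, n_genes = 8L, density = 0.08, coeff_scale = 0.35,
  times = c(4, 6, 8, 12, 16), replicates = 3L, noise_sd = 0.05,
  missing_rate = 0.02,
  drop_cells = data.frame(organ = "organ02", age_weeks = 12)
)

IDENTIFY <- list(
  alpha_grid = c(0, 0.2, 1), n_lambda = 6L, n_m_sets = 4L
)

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
msg <- function(...) cat(sprintf(...), "\n")
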