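#' Parameter-recovery benchmarking against ground truth
#'
#' @name benchmark
NULL

#' Sign agreement on the strongest estimated coefficients
#'
#' Takes the `n_top` largest-magnitude *nonzero* estimated coefficients —
#' the connections the analysis would actually report — and returns the
#' fraction whose sign matches the true matrix at the same position (a
#' position that is zero in the truth counts as a mismatch, so the measure
#' also penalizes support errors).  When the estimate carries fewer than
#' `n_top` nonzero entries, only those are graded.
#'
#' @param K_hat,K_true estimated and true coefficient matrices.
#' @param n_top number of top coefficients; defaults to the true support
#'   size.
#' @return fraction in [0, 1]; `NA` for an all-zero estimate.
#' @export
sign_agreement_top <- function(K_hat, K_true, n_top = NULL) {
  stopifnot(identical(dim(K_hat), dim(K_true)))
  if (is.null(n_top)) n_top <- sum(K_true != 0)
  nz <- which(K_hat != 0)
  if (length(nz) == 0) return(NA_real_)
  idx <- nz[order(abs(K_hat[nz]), decreasing = TRUE)]
  idx <- idx[seq_len(min(n_top, length(idx)))]
  mean(sign(K_hat[idx]) == sign(K_true[idx]))
}

#' Spearman correlation on the union support
#'
#' @param K_hat,K_true estimated and true coefficient matrices.
#' @return Spearman rank correlation between the matrices over entries
#'   nonzero in either.
#' @export
union_support_spearman <- function(K_hat, K_true) {
  idx <- which(K_hat != 0 | K_true != 0)
  stats::cor(K_hat[idx], K_true[idx], method = "spearman")
}

#' Run the standard synthetic parameter-recovery benchmark
#'
#' Generates a 12-node ground-truth network (density 0.15), simulates it at
#' the study ages, emits a 3-replicate Ct dataset with 0.05 Ct noise, runs
#' the full preprocessing and identification pipeline at a reduced
#' hyperparameter grid, maps the best-fit coefficients back to the
#' expression scale and compares them with the truth.
#'
#' @param seed integer seed controlling network, trajectories and noise.
#' @param n_organs,n_genes benchmark geometry (3 x 4 = 12 nodes).
#' @param density,noise_sd,replicates study conditions.
#' @param alpha_grid,n_lambda,n_m_sets reduced identification grid.
#' @return list with `model`, `fit` (the `network_identification`),
#'   `K_hat` (expression scale), `sign_agreement`, `spearman_rho`,
#'   `j_sim_best`, `j_sim_null` (all-zero model score).
#' @export
run_recovery_benchmark <- function(seed = 1L, n_organs = 3L, n_genes = 4L,
                                   density = 0.15, noise_sd = 0.05,
                                   replicates = 3L,
                                   alpha_grid = c(0.2, 1), n_lambda = 5L,
                                   n_m_sets = 3L) {
  model <- generate_network(n_organs, n_genes, density, seed = seed)
  truth <- simulate_truth(model)
  ct <- generate_ct_dataset(truth, strain = "disease",
                            replicates = replicates, noise_sd = noise_sd,
                            seed = seed + 1L)
  expr <- normalize_ct(ct)
  profiles <- scale_profiles(mean_profiles(expr))
  fit <- grid_search_identify(profiles, "disease", alpha_grid = alpha_grid,
                              n_lambda = n_lambda, n_m_sets = n_m_sets)
  K_hat <- unscale_coefficients(fit$best$K, profiles, "disease")
  null_score <- simulate_and_score(matrix(0, length(model$nodes),
                                          length(model$nodes),
                                          dimnames = list(model$nodes,
                                                          model$nodes)),
                                   profiles, "disease")
  list(model = model, fit = fit, K_hat = K_hat,
       sign_agreement = sign_agreement_top(K_hat, model$K_true),
       spearman_rho = union_support_spearman(K_hat, model$K_true),
       j_sim_best = fit$best$j_sim, j_sim_null = null_score$j_sim)
}
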