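#' End-to-end pipeline orchestration
#'
#' [run_pipeline()] executes synthetic data generation, preprocessing,
#' differential-dynamics testing, per-strain network identification,
#' robustness comparison, pattern/cascade analysis, differential-network
#' calls and motif enumeration from a single configuration with one master
#' seed, writing every table and a JSON run manifest to an output
#' directory.
#'
#' @name cli_pipeline
NULL

# deterministic per-stage child seed below 2^31
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + sum(utf8ToInt(stage)) * 131) %%
               2147483647)
}

#' Default pipeline configuration
#'
#' All numeric defaults of the analysis live here: spline df = 3, extremum
#' thresholds E_th = 0.5 / E_th0 = 0.1, frequency floor 1e-6, variance
#' floor 1e-10, alpha grid \{0, 0.2, 0.4, 0.6, 0.8, 1\}, 10 lambdas, 10
#' m-sets, differential cutoffs 0.15/0.15/0.2, FDR threshold 0.1 and the
#' power-law K-S acceptance level 0.8.  The synthetic block defaults to the
#' full study geometry (2 strains x 5 organs x 22 genes x ages 4-16 weeks,
#' one organ missing one age); tests and examples shrink it.
#'
#' @param seed master seed; every stage derives its own child seed from it.
#' @param out_dir output directory (NULL = nothing written).
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(synthetic = TRUE, preprocess = TRUE, dynamics = TRUE,
                  identify = TRUE, compare = TRUE, patterns = TRUE,
                  diffnet = TRUE, motifs = TRUE),
    synthetic = list(n_organs = 5L, n_genes = 22L, density = 0.05,
                     coeff_scale = 0.35, times = c(4, 6, 8, 12, 16),
                     replicates = 3L, noise_sd = 0.05, missing_rate = 0.02,
                     drop_organ = "organ02", drop_age = 12),
    preprocess = list(impute_k = 10L),
    dynamics = list(df = 3L, n_perm = 499L, q_threshold = 0.1),
    identify = list(alpha_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                    n_lambda = 10L, n_m_sets = 10L, M_max = NULL,
                    standardize = FALSE, eps_freq = 1e-6, eps_var = 1e-10),
    compare = list(min_shared = 5L, near_optimal_factor = 10,
                   ks_p_accept = 0.8),
    patterns = list(e_th = 0.5, e_th0 = 0.1),
    diffnet = list(cutoffs = c(added = 0.15, removed = 0.15,
                               switched = 0.2)),
    motifs = list(restrict_to = NULL)
  )
}

write_table <- function(df, out_dir, name) {
  if (!is.null(out_dir)) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
}

#' Run the full analysis pipeline
#'
#' Stages execute in order; disabling `identify` skips the downstream
#' network stages with a notice.  Identical configuration and seed yield
#' identical output tables.
#'
#' @param config a configuration as produced by [default_config()]
#'   (possibly modified).
#' @return invisible list of all stage results; tables and `manifest.json`
#'   are written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config = default_config()) {
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()
  strains <- c("control", "disease")

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (config$stages$synthetic) {
    res$synthetic <- run_stage("synthetic", {
      sy <- config$synthetic
      drop <- if (!is.null(sy$drop_organ)) {
        data.frame(organ = sy$drop_organ, age_weeks = sy$drop_age)
      } else NULL
      control <- generate_network(sy$n_organs, sy$n_genes, sy$density,
                                  sy$coeff_scale,
                                  seed = stage_seed(config$seed, "truth_c"),
                                  times = sy$times)
      n_edges <- sum(control$K_true != 0) - length(control$nodes)
      models <- list(
        control = control,
        # disease: the control network with ~1/3 of its interactions
        # rewired and a couple of sign flips
        disease = rewire_model(control,
                               n_rewire = max(1L, round(n_edges / 3)),
                               n_flip = max(1L, round(n_edges / 8)),
                               seed = stage_seed(config$seed, "truth_d"))
      )
      ct <- do.call(rbind, lapply(strains, function(st) {
        generate_ct_dataset(simulate_truth(models[[st]]), strain = st,
                            replicates = sy$replicates,
                            noise_sd = sy$noise_sd,
                            missing_rate = sy$missing_rate,
                            drop_cells = drop,
                            seed = stage_seed(config$seed,
                                              paste0("ct_", st)))
      }))
      class(ct) <- c("ct_table", "data.frame")
      write_table(ct, out_dir, "ct_raw")
      list(models = models, ct = ct)
    })
  }

  if (config$stages$preprocess) {
    res$preprocess <- run_stage("preprocess", {
      ct <- res$synthetic$ct
      expr <- impute_missing(normalize_ct(ct), k = config$preprocess$impute_k)
      profiles <- scale_profiles(mean_profiles(expr))
      stability <- rank_pseudo_reference(ct)
      write_table(expr, out_dir, "expression_normalized")
      write_table(profiles, out_dir, "profiles")
      write_table(stability, out_dir, "pseudo_reference_stability")
      list(expr = expr, profiles = profiles, stability = stability)
    })
  }

  if (config$stages$dynamics) {
    res$dynamics <- run_stage("dynamics", {
      dt <- run_dynamics_tests(res$preprocess$expr, df = config$dynamics$df,
                               n_perm = config$dynamics$n_perm,
                               seed = stage_seed(config$seed, "dynamics"),
                               q_threshold = config$dynamics$q_threshold)
      write_table(dt, out_dir, "dynamics_tests")
      dt
    })
  }

  if (config$stages$identify) {
    res$identify <- run_stage("identify", {
      idc <- config$identify
      fits <- lapply(strains, function(st) {
        grid_search_identify(res$preprocess$profiles, st,
                             alpha_grid = idc$alpha_grid,
                             n_lambda = idc$n_lambda,
                             n_m_sets = idc$n_m_sets, M_max = idc$M_max,
                             standardize = idc$standardize,
                             eps_freq = idc$eps_freq, eps_var = idc$eps_var,
                             keep_models = "all")
      })
      names(fits) <- strains
      for (st in strains) {
        write_table(fits[[st]]$fits, out_dir, paste0("fit_scores_", st))
        write_table(coefficient_table(fits[[st]]$best$K), out_dir,
                    paste0("network_", st))
      }
      fits
    })
  } else {
    message("identify stage disabled; skipping compare, diffnet and motifs")
  }

  if (config$stages$compare && !is.null(res$identify)) {
    res$compare <- run_stage("compare", {
      out <- lapply(strains, function(st) {
        fit <- res$identify[[st]]
        near <- which(fit$fits$j_sim <
                        fit$best$j_sim * config$compare$near_optimal_factor &
                        is.finite(fit$fits$j_sim))
        near <- setdiff(near, which.min(fit$fits$j_sim))
        others <- fit$models[near]
        names(others) <- sprintf("fit%03d", near)
        batch <- if (length(others) > 0) {
          compare_network_batch(fit$best$K, others,
                                min_shared = config$compare$min_shared)
        } else NULL
        metrics <- graph_metrics(fit$best$K)
        if (!is.null(batch)) {
          write_table(batch, out_dir, paste0("robustness_", st))
        }
        list(batch = batch, metrics = metrics)
      })
      names(out) <- strains
      out
    })
  }

  if (config$stages$patterns) {
    res$patterns <- run_stage("patterns", {
      calls <- classify_profiles(res$preprocess$profiles,
                                 e_th = config$patterns$e_th,
                                 e_th0 = config$patterns$e_th0)
      cascades <- list(
        peak = order_cascade(calls, "peak", reference_strain = "disease"),
        valley = order_cascade(calls, "valley", reference_strain = "disease")
      )
      write_table(calls, out_dir, "extremum_calls")
      write_table(cascades$peak$ordering, out_dir, "cascade_peak")
      write_table(cascades$valley$ordering, out_dir, "cascade_valley")
      list(calls = calls, cascades = cascades)
    })
  }

  if (config$stages$diffnet && !is.null(res$identify)) {
    res$diffnet <- run_stage("diffnet", {
      edges <- differential_edges(res$identify$disease$best$K,
                                  res$identify$control$best$K,
                                  cutoffs = config$diffnet$cutoffs)
      write_table(edges, out_dir, "differential_edges")
      if (!is.null(out_dir) && nrow(edges) > 0) {
        write_sif(edges, file.path(out_dir, "differential_edges.sif"))
      }
      edges
    })
  }

  if (config$stages$motifs && !is.null(res$identify)) {
    res$motifs <- run_stage("motifs", {
      signed <- threshold_and_scale(res$identify$disease$best$K)$scaled
      ffl <- enumerate_ffl(signed, restrict_to = config$motifs$restrict_to)
      write_table(ffl, out_dir, "motifs_ffl")
      ffl
    })
  }

  if (!is.null(out_dir)) {
    manifest <- list(
      config = config,
      stages_run = names(res),
      table_rows = lapply(res, function(x) {
        if (is.data.frame(x)) nrow(x) else NA_integer_
      })
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(res)
}
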