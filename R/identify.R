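#' Continuous-time network identification
#'
#' The HMF spectra of all scaled profiles of one strain are assembled into
#' the regression y = X beta, where each target node contributes a block
#' whose response is its derivative spectrum Hbar1(m w0) and whose design
#' columns are the spectra Hbar(m w0) of every node, one row per m value.
#' The blocks share one design matrix, so the global block-diagonal system
#' separates exactly: each target's coefficient row of K is estimated
#' independently by elastic net,
#'
#'   J_reg = min_beta ||y - X beta||^2 +
#'           lambda (alpha ||beta||_1 + (1 - alpha) ||beta||_2^2)
#'
#' and candidate models across the (m-set, alpha, lambda) grid are ranked by
#' the variance-penalized simulation objective
#'
#'   J_sim = sum (yhat - ybar)^2 / (Var(yhat) + eps)
#'
#' which disqualifies the trivially flat all-zero model.
#'
#' @name network_identify
NULL

#' Build the grid of modulating-function index sets
#'
#' Each set has the form m = 0, +/-1, ..., +/-M (size 2M + 1).  M ranges
#' from M_min = ceiling(n_nodes / 2) — the smallest value giving at least
#' n_nodes + 1 equations per block — to `M_max`, with `n_grid` evenly spaced
#' values.
#'
#' @param n_nodes number of nodes (regression columns per block).
#' @param n_grid number of m-sets.
#' @param M_max largest half-width; defaults to `n_nodes`.
#' @return list of integer vectors, each `-M:M`.
#' @export
build_m_sets <- function(n_nodes, n_grid = 10L, M_max = NULL) {
  M_min <- ceiling(n_nodes / 2)
  if (is.null(M_max)) M_max <- n_nodes
  if (M_max < M_min) stop("M_max (", M_max, ") below M_min (", M_min, ")")
  Ms <- unique(round(seq(M_min, M_max, length.out = n_grid)))
  lapply(Ms, function(M) seq.int(-M, M))
}

#' Assemble the HMF regression system for one strain
#'
#' @param profiles a scaled `profile_set`.
#' @param strain strain to assemble.
#' @param m_set integer vector of modulating-function indices.
#' @param eps_freq degenerate-frequency replacement (see [hmf_spec()]).
#' @param value profile column used as the signal (default `"scaled"`).
#' @return an object of class `"hmf_regression_system"`: list with `X`
#'   (|m_set| x n_nodes spectra), `Y` (|m_set| x n_nodes derivative spectra,
#'   one column per target), `m_set`, `nodes`, `spec`, `strain`, `series`.
#' @export
build_regression_system <- function(profiles, strain, m_set,
                                    eps_freq = 1e-6, value = "scaled") {
  series <- profile_series(profiles, strain, value)
  nodes <- names(series)
  if (length(m_set) < length(nodes)) {
    stop("m_set size (", length(m_set), ") below number of nodes (",
         length(nodes), "); system underdetermined")
  }
  all_times <- unlist(lapply(series, `[[`, "times"))
  spec <- hmf_spec(max(all_times) - min(all_times), n = 1L,
                   eps_freq = eps_freq)
  X <- matrix(0, length(m_set), length(nodes),
              dimnames = list(NULL, nodes))
  Y <- X
  for (nd in seq_along(nodes)) {
    s <- series[[nd]]
    for (mi in seq_along(m_set)) {
      X[mi, nd] <- hmf_spectrum(s$times, s$values, m_set[mi], spec)
      Y[mi, nd] <- hmf_derivative_spectrum(s$times, s$values, m_set[mi], spec)
    }
  }
  structure(list(X = X, Y = Y, m_set = m_set, nodes = nodes, spec = spec,
                 strain = strain, series = series),
            class = "hmf_regression_system")
}

#' Materialize the global block-diagonal regression
#'
#' The stacked response holds every target's derivative spectra; the design
#' is block-diagonal with one copy of the shared spectral matrix per target
#' (off-block entries are structural zeros).  Used to assert block
#' separability; fitting itself works block-wise.
#'
#' @param system an `hmf_regression_system`.
#' @return list with dense `y` (length |m_set| * n_nodes) and `X`
#'   (|m_set| n_nodes x n_nodes^2).
#' @export
block_diagonal_system <- function(system) {
  n <- length(system$nodes)
  X_full <- kronecker(diag(n), system$X)
  list(y = as.vector(system$Y), X = X_full)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# plain cyclic coordinate descent on the package objective; only used for
# corner cases the main solver rejects (e.g. a constant nonzero response)
cd_fallback <- function(X, y, alpha, lambda, n_iter = 10000L,
                        tol = 1e-12) {
  p <- ncol(X)
  beta <- rep(0, p)
  xx <- colSums(X^2)
  for (it in seq_len(n_iter)) {
    old <- beta
    for (j in seq_len(p)) {
      r <- y - X[, -j, drop = FALSE] %*% beta[-j]
      z <- sum(X[, j] * r)
      beta[j] <- soft_threshold(z, lambda * alpha / 2) /
        (xx[j] + lambda * (1 - alpha))
    }
    if (max(abs(beta - old)) < tol) break
  }
  beta
}

# elastic-net solve of one block for a vector of lambdas (our objective:
# RSS + lambda*(alpha*L1 + (1-alpha)*L2^2)); returns p x n_lambda matrix.
# glmnet solves (1/2n)RSS + lg*(ag*L1 + (1-ag)/2*L2^2); the exact mapping is
# lg = lambda*(2-alpha)/(2n), ag = alpha/(2-alpha).
solve_block <- function(X, y, alpha, lambdas, standardize = FALSE) {
  p <- ncol(X); n <- nrow(X)
  out <- matrix(0, p, length(lambdas))
  zero <- lambdas == 0
  if (any(zero)) {
    beta0 <- ls_fit(X, y)$coef
    out[, zero] <- beta0
  }
  pos <- which(!zero)
  if (length(pos) == 0) return(out)
  lam <- lambdas[pos]
  if (all(y == 0)) {
    return(out)  # beta = 0 is exactly optimal for a zero response
  }
  if (stats::var(y) == 0) {
    for (i in seq_along(lam)) {
      out[, pos[i]] <- cd_fallback(X, y, alpha, lam[i])
    }
    return(out)
  }
  if (alpha == 0) {
    # ridge closed form
    XtX <- crossprod(X); Xty <- crossprod(X, y)
    for (i in seq_along(lam)) {
      out[, pos[i]] <- solve(XtX + lam[i] * diag(p), Xty)
    }
  } else if (p == 1) {
    xy <- sum(X * y); xx <- sum(X^2)
    out[1, pos] <- soft_threshold(xy, lam * alpha / 2) /
      (xx + lam * (1 - alpha))
  } else {
    # solve along a descending warm-started path for accuracy, then pick
    # out the requested lambdas
    lmax_loc <- max(2 * max(abs(crossprod(X, y))) / alpha, max(lam))
    warmup <- 10^seq(log10(lmax_loc), log10(min(lam)), length.out = 30)
    lam_all <- sort(unique(c(lam, warmup)), decreasing = TRUE)
    alpha_g <- alpha / (2 - alpha)
    lam_g <- lam_all * (2 - alpha) / (2 * n)
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha_g,
                          lambda = lam_g, standardize = standardize,
                          intercept = FALSE, thresh = 1e-14, maxit = 1e7)
    beta <- as.matrix(fit$beta)
    if (ncol(beta) != length(lam_g)) {
      stop("elastic-net solver did not converge over the full lambda path")
    }
    out[, pos] <- beta[, match(lam, lam_all)]
  }
  out
}

#' Largest useful regularization strength
#'
#' The smallest lambda whose solution is identically zero follows from the
#' subgradient condition at beta = 0: lambda_max = 2 max_j |X_j' y| / alpha,
#' maximized over target blocks.  Pure ridge (alpha = 0) has no finite
#' lambda_max; the value at alpha = 0.001 is used as a stand-in and flagged
#' via the `"ridge_standin"` attribute.
#'
#' @param system an `hmf_regression_system`.
#' @param alpha elastic-net mixing weight.
#' @return lambda_max (a single number).
#' @export
lambda_max <- function(system, alpha) {
  standin <- alpha <= 0
  alpha_eff <- if (standin) 0.001 else alpha
  lm <- max(abs(crossprod(system$X, system$Y))) * 2 / alpha_eff
  attr(lm, "ridge_standin") <- standin
  lm
}

#' Log-spaced lambda path over four decades
#'
#' @inheritParams lambda_max
#' @param n_lambda path length.
#' @return decreasing vector from lambda_max down to lambda_max * 1e-4.
#' @export
lambda_path <- function(system, alpha, n_lambda = 10L) {
  lmax <- as.numeric(lambda_max(system, alpha))
  10^seq(log10(lmax), log10(lmax * 1e-4), length.out = n_lambda)
}

#' Solve the regression at one (lambda, alpha)
#'
#' @param system an `hmf_regression_system`.
#' @param lambda,alpha elastic-net parameters of the objective
#'   `||y - X b||^2 + lambda (alpha ||b||_1 + (1 - alpha) ||b||_2^2)`.
#' @param standardize standardize predictors inside the solver (off by
#'   default so coefficients live on the spectral scale).
#' @return the estimated interaction matrix K (row = target, column =
#'   source), dimnamed by node.
#' @export
elastic_net_solve <- function(system, lambda, alpha, standardize = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  n <- length(system$nodes)
  K <- matrix(0, n, n, dimnames = list(system$nodes, system$nodes))
  for (nd in seq_len(n)) {
    K[nd, ] <- solve_block(system$X, system$Y[, nd], alpha, lambda,
                           standardize)[, 1]
  }
  K
}

#' Simulate a candidate model and compute the selection objective
#'
#' Integrates dE/dt = K E from the scaled data at the first sample time and
#' scores the fit by J_sim = sum over nodes and times of
#' (yhat - ybar)^2 / (Var(yhat) + eps_var), with Var the sample variance of
#' the simulated node across its own sample times.  Flat simulations (e.g.
#' the all-zero model) are heavily penalized; diverging integrations return
#' `Inf` with `diverged = TRUE`.
#'
#' @param K interaction matrix in the frozen node order.
#' @param profiles scaled `profile_set`.
#' @param strain strain whose data are scored.
#' @param eps_var variance-penalty floor.
#' @param value profile column scored against.
#' @return list with `j_sim`, `yhat` (list of per-node simulated values at
#'   that node's times) and `diverged`.
#' @export
simulate_and_score <- function(K, profiles, strain, eps_var = 1e-10,
                               value = "scaled") {
  series <- profile_series(profiles, strain, value)
  stopifnot(nrow(K) == length(series))
  E0 <- vapply(series, function(s) s$values[1], numeric(1))
  grid <- sort(unique(unlist(lapply(series, `[[`, "times"))))
  traj <- try(integrate_linear_system(K, E0, grid), silent = TRUE)
  if (inherits(traj, "try-error")) {
    return(list(j_sim = Inf, yhat = NULL, diverged = TRUE))
  }
  j_sim <- 0
  yhat <- vector("list", length(series))
  names(yhat) <- names(series)
  for (nd in seq_along(series)) {
    s <- series[[nd]]
    yh <- traj[match(s$times, grid), nd]
    yhat[[nd]] <- yh
    j_sim <- j_sim + sum((yh - s$values)^2) / (stats::var(yh) + eps_var)
  }
  list(j_sim = j_sim, yhat = yhat, diverged = FALSE)
}

#' Grid-search system identification
#'
#' Runs the full identification loop for one strain: for every m-set and
#' every alpha, a lambda path is computed and each (m-set, alpha, lambda)
#' triple is solved and scored by simulation.  The defaults (10 m-sets, 6
#' alphas, 10 lambdas) yield 600 fits.
#'
#' @param profiles scaled `profile_set`.
#' @param strain strain to identify.
#' @param alpha_grid elastic-net mixing weights.
#' @param n_lambda lambdas per (m-set, alpha).
#' @param n_m_sets number of m-sets.
#' @param M_max largest m-set half-width (default `n_nodes`).
#' @param subset_organs,subset_genes optional restriction of the node set
#'   before identification (subset reanalyses).
#' @param standardize passed to the solver.
#' @param eps_freq,eps_var numerical floors (see [hmf_spec()] and
#'   [simulate_and_score()]).
#' @param keep_models `"best"` or `"all"`: whether the K of every grid point
#'   is retained (needed for robustness comparisons).
#' @return an object of class `"network_identification"`: list with `best`
#'   (a `network_model`: `K`, `E0`, `nodes`, `strain`, `M`, `alpha`,
#'   `lambda`, `j_sim`), `fits` (one row per grid point), `models`
#'   (list of K matrices or NULL), `nodes`, `strain`.
#' @export
grid_search_identify <- function(profiles, strain,
                                 alpha_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                 n_lambda = 10L, n_m_sets = 10L,
                                 M_max = NULL, subset_organs = NULL,
                                 subset_genes = NULL, standardize = FALSE,
                                 eps_freq = 1e-6, eps_var = 1e-10,
                                 keep_models = c("best", "all")) {
  keep_models <- match.arg(keep_models)
  stopifnot(length(alpha_grid) > 0, n_lambda >= 1, n_m_sets >= 1)
  if (!is.null(subset_organs)) {
    profiles <- profiles[profiles$organ %in% subset_organs, ]
  }
  if (!is.null(subset_genes)) {
    profiles <- profiles[profiles$gene %in% subset_genes, ]
  }
  n_nodes <- length(profile_series(profiles, strain))
  m_sets <- build_m_sets(n_nodes, n_m_sets, M_max)

  fits <- list(); models <- list(); best <- NULL
  row <- 0L
  for (ms in seq_along(m_sets)) {
    system <- build_regression_system(profiles, strain, m_sets[[ms]],
                                      eps_freq = eps_freq)
    for (alpha in alpha_grid) {
      path <- lambda_path(system, alpha, n_lambda)
      beta_path <- lapply(seq_along(system$nodes), function(nd) {
        solve_block(system$X, system$Y[, nd], alpha, path, standardize)
      })
      for (li in seq_along(path)) {
        K <- t(vapply(beta_path, function(b) b[, li],
                      numeric(length(system$nodes))))
        dimnames(K) <- list(system$nodes, system$nodes)
        score <- simulate_and_score(K, profiles, strain, eps_var = eps_var)
        row <- row + 1L
        fits[[row]] <- data.frame(
          m_index = ms, M = max(m_sets[[ms]]), alpha = alpha,
          lambda = path[li], j_sim = score$j_sim,
          n_nonzero = sum(K != 0), diverged = score$diverged
        )
        if (keep_models == "all") models[[row]] <- K
        if (is.null(best) || score$j_sim < best$j_sim) {
          best <- list(K = K, E0 = vapply(system$series,
                                          function(s) s$values[1],
                                          numeric(1)),
                       nodes = system$nodes, strain = strain,
                       M = max(m_sets[[ms]]), alpha = alpha,
                       lambda = path[li], j_sim = score$j_sim)
          class(best) <- "network_model"
        }
      }
    }
  }
  fits <- do.call(rbind, fits)
  if (is.null(best) || !is.finite(best$j_sim)) {
    stop("all candidate fits diverged or scored non-finite")
  }
  structure(list(best = best, fits = fits,
                 models = if (keep_models == "all") models else NULL,
                 nodes = best$nodes, strain = strain),
            class = "network_identification")
}

#' Map identified coefficients back to the unscaled expression scale
#'
#' Identification runs on min-max scaled profiles; with
#' E_scaled,i = (E_i - min_i) / range_i, the coefficient linking scaled
#' variables relates to the coefficient on the expression scale by
#' k_ij = k_scaled,ij * range_i / range_j.  Constant profiles (range 0)
#' keep a unit range.
#'
#' @param K identified matrix on the scaled variables.
#' @param profiles the scaled `profile_set` used for identification.
#' @param strain strain of `K`.
#' @return K on the expression scale.
#' @export
unscale_coefficients <- function(K, profiles, strain) {
  series <- profile_series(profiles, strain)
  rng <- vapply(series, function(s) {
    r <- s$scale_max - s$scale_min
    if (is.na(r) || r <= 0) 1 else r
  }, numeric(1))
  stopifnot(nrow(K) == length(rng))
  K * outer(rng, 1 / rng)
}

#' Export an interaction matrix as a labelled edge table
#'
#' @param K interaction matrix (row = target, column = source).
#' @return data.frame (coefficient `k_to_from` name, source, target, k).
#' @export
coefficient_table <- function(K) {
  nodes <- rownames(K)
  data.frame(
    name = paste0("k_", rep(nodes, ncol(K)), "_", rep(nodes, each = nrow(K))),
    target = rep(nodes, ncol(K)),
    source = rep(nodes, each = nrow(K)),
    k = as.vector(K)
  )
}
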