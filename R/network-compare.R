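#' Network agreement statistics and graph topology metrics
#'
#' Robustness of the identification is quantified by comparing coefficient
#' sets between networks fitted under different hyperparameters or data
#' subsets (Spearman correlation, Fisher's exact test on coefficient signs,
#' odds ratio), and by summarizing graph structure (average shortest path,
#' transitivity, power-law degree fit).
#'
#' @name network_compare
NULL

#' Filter a coefficient matrix to its strong entries
#'
#' Retains entries with |k| > |2 sd(k) - med(k)| over all matrix entries.
#' With the median near zero — as holds for sparse identified networks —
#' this coincides with the two-standard-deviations-from-the-median rule.
#'
#' @param K coefficient matrix.
#' @return logical matrix marking retained entries.
#' @export
filter_coefficients <- function(K) {
  stopifnot(length(K) > 0)
  thr <- abs(2 * stats::sd(K) - stats::median(K))
  abs(K) > thr
}

#' Compare two identified networks
#'
#' On the coefficients passing [filter_coefficients()] in *both* networks,
#' computes the Spearman rank correlation and a 2x2 sign contingency table
#' (sign in A x sign in B) analyzed by Fisher's exact test; the odds ratio
#' is the cross-product (n++ n--)/(n+- n-+), reported as `Inf` when both
#' disagreement cells are empty.  Fewer than `min_shared` shared entries
#' yields a skipped comparison (`comparable = FALSE`).
#'
#' @param K_a,K_b coefficient matrices over the same node set.
#' @param min_shared minimum shared filtered coefficients.
#' @return list of class `"network_comparison"`: `n_compared`,
#'   `spearman_rho`, `spearman_p`, `fisher_p`, `odds_ratio`, `sign_table`,
#'   `comparable`, `note`.
#' @export
compare_networks <- function(K_a, K_b, min_shared = 5L) {
  stopifnot(identical(dim(K_a), dim(K_b)))
  shared <- filter_coefficients(K_a) & filter_coefficients(K_b)
  n <- sum(shared)
  if (n < min_shared) {
    return(structure(list(n_compared = n, spearman_rho = NA_real_,
                          spearman_p = NA_real_, fisher_p = NA_real_,
                          odds_ratio = NA_real_, sign_table = NULL,
                          comparable = FALSE,
                          note = sprintf("only %d shared coefficients (< %d)",
                                         n, min_shared)),
                     class = "network_comparison"))
  }
  a <- K_a[shared]; b <- K_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rho <- NA_real_; rho_p <- NA_real_
    note <- "constant coefficient vector; correlation undefined"
  } else {
    ct <- suppressWarnings(
      stats::cor.test(a, b, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
    note <- ""
  }
  tab <- matrix(c(sum(a > 0 & b > 0), sum(a > 0 & b <= 0),
                  sum(a <= 0 & b > 0), sum(a <= 0 & b <= 0)),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("pos", "neg"), B = c("pos", "neg")))
  fe <- fisher_exact_stats(tab)
  fp <- fe$p
  or <- fe$odds_ratio
  structure(list(n_compared = n, spearman_rho = rho, spearman_p = rho_p,
                 fisher_p = fp, odds_ratio = or, sign_table = tab,
                 comparable = TRUE, note = note),
            class = "network_comparison")
}

#' Fisher's exact test and odds ratio of a 2x2 sign table
#'
#' Two-sided Fisher exact p-value together with the plain cross-product
#' odds ratio (a d)/(b c) — not the conditional-maximum-likelihood estimate
#' — reported as `Inf` when both off-diagonal cells are empty.
#'
#' @param tab 2x2 integer matrix.
#' @return list with `p` and `odds_ratio`.
#' @export
fisher_exact_stats <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)) || all(dim(tab) == 2))
  p <- stats::fisher.test(tab)$p.value
  or <- if (tab[1, 2] == 0 && tab[2, 1] == 0) {
    Inf
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  list(p = p, odds_ratio = or)
}

#' Fit a discrete power law to a degree sequence
#'
#' Maximum-likelihood fit of P(k) ~ k^(-gamma) with x_min = 1, plus a
#' Kolmogorov-Smirnov goodness-of-fit p-value obtained by parametric
#' bootstrap: replicate degree sequences are drawn from the fitted law and
#' refitted, and the p-value is the add-one fraction of replicates whose
#' K-S statistic reaches the observed one.  Only high p-values
#' (conventionally > 0.8) warrant reporting the exponent.
#'
#' @param degrees positive integer degree sequence (zeros are dropped).
#' @param n_boot bootstrap replicates for the K-S p-value.
#' @param k_max support cap for bootstrap draws.
#' @return list with `power_exponent`, `ks_stat` and `ks_p`.
#' @export
power_law_fit <- function(degrees, n_boot = 100L, k_max = 10000L) {
  degrees <- degrees[degrees > 0]
  if (length(degrees) < 5 || length(unique(degrees)) < 2) {
    return(list(power_exponent = NA_real_, ks_stat = NA_real_,
                ks_p = NA_real_))
  }
  fit <- igraph::fit_power_law(degrees, xmin = 1, implementation = "plfit")
  support <- seq_len(k_max)
  prob <- support^(-fit$alpha)
  n <- length(degrees)
  boot <- vapply(seq_len(n_boot), function(b) {
    x <- sample(support, n, replace = TRUE, prob = prob)
    tryCatch(igraph::fit_power_law(x, xmin = 1,
                                   implementation = "plfit")$KS.stat,
             error = function(e) NA_real_)
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  list(power_exponent = fit$alpha, ks_stat = fit$KS.stat,
       ks_p = (1 + sum(boot >= fit$KS.stat)) / (1 + length(boot)))
}

#' Batch network comparisons with multiplicity adjustment
#'
#' @param reference reference coefficient matrix (e.g. the best fit).
#' @param others named list of comparison matrices.
#' @param min_shared passed to [compare_networks()].
#' @return data.frame (id, n_compared, spearman_rho, spearman_p,
#'   spearman_q, fisher_p, fisher_q, odds_ratio, comparable) with
#'   Benjamini-Hochberg adjusted columns.
#' @export
compare_network_batch <- function(reference, others, min_shared = 5L) {
  rows <- lapply(names(others), function(id) {
    cmp <- compare_networks(reference, others[[id]], min_shared)
    data.frame(id = id, n_compared = cmp$n_compared,
               spearman_rho = cmp$spearman_rho, spearman_p = cmp$spearman_p,
               fisher_p = cmp$fisher_p, odds_ratio = cmp$odds_ratio,
               comparable = cmp$comparable)
  })
  out <- do.call(rbind, rows)
  out$spearman_q <- stats::p.adjust(out$spearman_p, method = "BH")
  out$fisher_q <- stats::p.adjust(out$fisher_p, method = "BH")
  out
}

#' Graph topology metrics of an identified network
#'
#' The adjacency is taken from the filtered (or all nonzero) entries of K;
#' average shortest path length and transitivity are computed on the
#' undirected skeleton, degrees are kept directed, and a discrete power law
#' is fitted to the total-degree sequence by maximum likelihood (x_min = 1)
#' with a Kolmogorov-Smirnov goodness-of-fit p-value.  The exponent is only
#' meaningful alongside its `ks_p` (the convention here follows the rule of
#' accepting fits with high K-S p only).
#'
#' @param K coefficient matrix (row = target, column = source).
#' @param threshold `"filtered"` (default, [filter_coefficients()]) or
#'   `"nonzero"`.
#' @return list: `n_nodes`, `n_edges`, `avg_path_length`, `transitivity`,
#'   `power_exponent`, `ks_p`, `deg_in`, `deg_out`, `deg_all`, `empty`.
#' @export
graph_metrics <- function(K, threshold = c("filtered", "nonzero")) {
  threshold <- match.arg(threshold)
  mask <- if (threshold == "filtered") filter_coefficients(K) else K != 0
  diag(mask) <- FALSE
  if (!any(mask)) {
    return(list(n_nodes = nrow(K), n_edges = 0L, avg_path_length = NA_real_,
                transitivity = NA_real_, power_exponent = NA_real_,
                ks_p = NA_real_, deg_in = NULL, deg_out = NULL,
                deg_all = NULL, empty = TRUE))
  }
  # K[i, j] is the influence of source j on target i => edge j -> i
  g <- igraph::graph_from_adjacency_matrix(t(mask * 1), mode = "directed")
  gu <- igraph::as_undirected(g, mode = "collapse")
  deg_all <- igraph::degree(g, mode = "all")
  pl <- tryCatch(power_law_fit(deg_all),
                 error = function(e) list(power_exponent = NA_real_,
                                          ks_p = NA_real_))
  list(n_nodes = nrow(K), n_edges = sum(mask),
       avg_path_length = igraph::mean_distance(gu, directed = FALSE,
                                               unconnected = TRUE),
       transitivity = igraph::transitivity(gu, type = "global"),
       power_exponent = pl$power_exponent, ks_p = pl$ks_p,
       deg_in = igraph::degree(g, mode = "in"),
       deg_out = igraph::degree(g, mode = "out"),
       deg_all = deg_all, empty = FALSE)
}
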