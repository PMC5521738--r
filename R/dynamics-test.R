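#' Differential-dynamics testing
#'
#' For each (organ, gene), temporal profiles are modelled by natural cubic
#' splines (df = 3 by default).  A null model fits one spline to the pooled
#' disease + control data; the alternative fits one spline per strain.  The
#' goodness-of-fit statistic is
#'
#'   F = (SS0 - SSA) / SSA
#'
#' with SS0 and SSA the residual sums of squares of null and alternative
#' fits.  Its null distribution is estimated by permuting strain labels
#' within each time point (preserving the time-grid design), and p-values
#' are Benjamini-Hochberg adjusted across the test family.
#'
#' @name dynamics_test
NULL

# natural-spline design matrix (with intercept); rank-deficient bases are
# fine because fitting uses minimum-norm least squares
spline_basis <- function(times, df = 3L) {
  if (length(unique(times)) < 2) stop("need at least 2 distinct times")
  cbind(1, splines::ns(times, df = df))
}

# minimum-norm least-squares fit; returns fitted values and residual SS
ls_fit <- function(B, y) {
  sv <- svd(B)
  pos <- sv$d > max(sv$d) * 1e-10
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  fitted <- as.vector(B %*% coef)
  list(fitted = fitted, ss = sum((y - fitted)^2), coef = as.vector(coef))
}

#' Natural cubic spline fit of a time course
#'
#' @param times observation times (weeks), replicates allowed.
#' @param values observed expression values.
#' @param df spline degrees of freedom.
#' @return list with `fitted`, `ss` (residual sum of squares) and `coef`.
#' @export
spline_fit <- function(times, values, df = 3L) {
  stopifnot(length(times) == length(values))
  ls_fit(spline_basis(times, df), values)
}

#' Spline F statistic for strain-differential dynamics
#'
#' @param times,values observations for one (organ, gene), both strains.
#' @param labels strain label per observation (exactly two levels present).
#' @param df spline degrees of freedom.
#' @return list with `F`, `ss0`, `ssa` and `saturated` (TRUE when the
#'   alternative fit is exact, making F infinite).
#' @export
dynamics_f <- function(times, values, labels, df = 3L) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) stop("need exactly two strain labels")
  B <- spline_basis(times, df)
  ss0 <- ls_fit(B, values)$ss
  ssa <- 0
  for (lv in unique(labels)) {
    sel <- labels == lv
    ssa <- ssa + ls_fit(B[sel, , drop = FALSE], values[sel])$ss
  }
  if (ssa <= .Machine$double.eps * max(1, ss0)) {
    return(list(F = Inf, ss0 = ss0, ssa = ssa, saturated = TRUE))
  }
  list(F = (ss0 - ssa) / ssa, ss0 = ss0, ssa = ssa, saturated = FALSE)
}

#' Permutation p-value for the spline F statistic
#'
#' Strain labels are permuted within each time point; the p-value uses the
#' add-one rule p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @inheritParams dynamics_f
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `F`, `ss0`, `ssa`, `p`.
#' @export
permutation_test <- function(times, values, labels, df = 3L, n_perm = 499L,
                             seed = 1L) {
  stopifnot(n_perm >= 100)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("all labels identical; test degenerate")
  obs <- dynamics_f(times, values, labels, df)
  B <- spline_basis(times, df)
  groups <- split(seq_along(times), times)

  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- labels
    for (g in groups) perm[g] <- perm[sample(g)]
    ssa <- 0
    for (lv in unique(perm)) {
      sel <- perm == lv
      ssa <- ssa + ls_fit(B[sel, , drop = FALSE], values[sel])$ss
    }
    f_perm <- if (ssa <= .Machine$double.eps) Inf else (obs$ss0 - ssa) / ssa
    if (f_perm >= obs$F) count <- count + 1L
  }
  list(F = obs$F, ss0 = obs$ss0, ssa = obs$ssa,
       p = (1 + count) / (1 + n_perm))
}

#' Run the differential-dynamics test family
#'
#' Applies [permutation_test()] to every (organ, gene) with both strains
#' present and adjusts p-values by Benjamini-Hochberg across the family.
#'
#' @param expr an `expression_table` (replicate level, both strains).
#' @param df spline degrees of freedom.
#' @param n_perm permutations per test.
#' @param seed integer seed; each test gets a distinct derived seed.
#' @param q_threshold FDR level for the `significant` column.
#' @return data.frame (organ, gene, F, ss0, ssa, p, q, significant).
#' @export
run_dynamics_tests <- function(expr, df = 3L, n_perm = 499L, seed = 1L,
                               q_threshold = 0.1) {
  cells <- unique(expr[, c("organ", "gene")])
  cells <- cells[order(cells$organ, cells$gene), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- expr[expr$organ == cells$organ[i] & expr$gene == cells$gene[i] &
                 !is.na(expr$value), ]
    if (length(unique(cc$strain)) < 2) return(NULL)
    res <- permutation_test(cc$age_weeks, cc$value, cc$strain, df = df,
                            n_perm = n_perm,
                            seed = (seed + i * 131L) %% .Machine$integer.max)
    data.frame(organ = cells$organ[i], gene = cells$gene[i], F = res$F,
               ss0 = res$ss0, ssa = res$ssa, p = res$p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}
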