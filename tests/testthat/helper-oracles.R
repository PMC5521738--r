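# Independent brute-force oracles used across the suite.  These
# deliberately avoid the code paths they check.

# cyclic coordinate descent for RSS + lambda*(alpha*L1 + (1-alpha)*L2^2)
cd_elastic_net <- function(X, y, lambda, alpha, n_iter = 5000,
                           tol = 1e-12) {
  p <- ncol(X)
  beta <- rep(0, p)
  xx <- colSums(X^2)
  for (it in seq_len(n_iter)) {
    old <- beta
    for (j in seq_len(p)) {
      r <- y - X[, -j, drop = FALSE] %*% beta[-j]
      z <- sum(X[, j] * r)
      num <- sign(z) * max(abs(z) - lambda * alpha / 2, 0)
      beta[j] <- num / (xx[j] + lambda * (1 - alpha))
    }
    if (max(abs(beta - old)) < tol) break
  }
  beta
}

# two-sided Fisher exact p and cross-product odds ratio for a 2x2 table by
# explicit hypergeometric enumeration over all tables with the same margins
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b == 0 && c == 0) Inf else (a * d) / (b * c)
  list(p = p, or = or)
}

# all-pairs shortest paths on an undirected adjacency by BFS; mean over
# connected ordered pairs, plus global transitivity by triple enumeration
bfs_graph_metrics <- function(adj) {
  n <- nrow(adj)
  adj <- (adj | t(adj)) & !diag(n)
  dists <- c()
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & is.infinite(d))
        d[nb] <- d[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    dists <- c(dists, d[-s])
  }
  finite <- dists[is.finite(dists)]
  closed <- 0; connected_triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && adj[i, j] && adj[j, k]) {
      connected_triples <- connected_triples + 1
      if (adj[i, k]) closed <- closed + 1
    }
  }
  list(
    avg_path_length = if (length(finite)) mean(finite) else NA_real_,
    transitivity = if (connected_triples) closed / connected_triples
                   else NaN
  )
}

# all ordered feed-forward triples of a signed adjacency (A[target, source])
ffl_brute <- function(A) {
  n <- nrow(A)
  out <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    if (length(unique(c(a, b, cc))) < 3) next
    if (A[b, a] != 0 && A[cc, b] != 0 && A[cc, a] != 0) {
      out <- rbind(out, c(a, b, cc))
    }
  }
  out
}

# assemble a profile_set from a times x nodes value matrix (nodes named
# organ.gene); scaled column equals the values as given
matrix_profile_set <- function(times, values, strain = "disease") {
  nodes <- colnames(values)
  og <- do.call(rbind, strsplit(nodes, ".", fixed = TRUE))
  out <- data.frame(
    strain = strain,
    organ = rep(og[, 1], each = length(times)),
    gene = rep(og[, 2], each = length(times)),
    age_weeks = rep(times, ncol(values)),
    mean = as.vector(values), n_rep = 1L,
    scale_min = 0, scale_max = 1, scaled = as.vector(values)
  )
  class(out) <- c("profile_set", "data.frame")
  out
}

# random piecewise-linear profile on the study ages
random_profile <- function(n_pts = 5, times = c(4, 6, 8, 12, 16)) {
  list(times = times[seq_len(n_pts)], values = stats::runif(n_pts))
}
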